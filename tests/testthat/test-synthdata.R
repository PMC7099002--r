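test_that("master trees are rooted, binary, ultrametric in time and seeded", {
  tt <- generateMasterTree(4, 300, seed = 1)
  phy <- asPhylo(tt)
  expect_s4_class(tt, "TimeTree")
  expect_equal(ape::Ntip(phy), 5L)  # 4 ingroup + outgroup
  a <- ages(tt)
  ing <- ingroupNodes(tt)
  expect_length(ing, 3L)            # 3 ingroup internal nodes
  expect_true(all(a[ing] > 0 & a[ing] <= 300))
  expect_equal(max(a[ing]), 300)

  big <- generateMasterTree(248, 350, seed = 7)
  expect_length(ingroupNodes(big), 247L)
  bphy <- asPhylo(big)
  ids <- secalib:::nodeIds(bphy)
  dif <- ages(big)[ids[bphy$edge[, 1L]]] - ages(big)[ids[bphy$edge[, 2L]]]
  expect_true(all(dif > 0))         # parent strictly older everywhere
  expect_true(all(abs(ages(big)[bphy$tip.label]) < 1e-8))

  expect_identical(ape::write.tree(asPhylo(generateMasterTree(30, 100, seed = 3))),
                   ape::write.tree(asPhylo(generateMasterTree(30, 100, seed = 3))))
  expect_false(identical(
    ape::write.tree(asPhylo(generateMasterTree(30, 100, seed = 3))),
    ape::write.tree(asPhylo(generateMasterTree(30, 100, seed = 4)))))
  expect_error(generateMasterTree(3, 300, seed = 1), "nTaxa")
})

test_that("the nested split preserves ages and overlaps in exactly two lineages", {
  master <- generateMasterTree(24, 220, seed = 5)
  sp <- splitNested(master, overlapRelDepth = 0.7, targetFrac = 0.3)
  expect_s4_class(sp, "NestedSplit")
  ov <- sp@overlapNode
  expect_equal(ages(sp@treeA)[[ov]], ages(sp@master)[[ov]])
  expect_equal(ages(sp@treeB)[[ov]], ages(sp@master)[[ov]])
  inA <- taxa(sp@treeA); inB <- taxa(sp@treeB)
  expect_setequal(intersect(inA, inB), sp@sharedLineages)
  expect_length(sp@sharedLineages, 2L)
  expect_setequal(union(inA, inB), taxa(master))
  ## every retained node keeps its master age (lossless on ages)
  for (tt in list(sp@treeA, sp@treeB)) {
    shared <- intersect(names(ages(tt)), names(ages(master)))
    expect_equal(ages(tt)[shared], ages(master)[shared], tolerance = 1e-10)
  }
  ## the overlap node is internal to both subtrees
  expect_true(ov %in% ingroupNodes(sp@treeA))
  expect_true(ov %in% ingroupNodes(sp@treeB))
})

test_that("gene profiles respect their bounds and the total-length anchor", {
  pr <- sampleGeneProfiles(446, seed = 2)
  expect_equal(nrow(pr), 446L)
  expect_true(all(pr$length >= 1))
  expect_true(all(pr$gc > 0.3 & pr$gc < 0.7))
  expect_true(all(pr$kappa > 2 & pr$kappa < 8))
  expect_true(all(pr$base_rate > 0.75 * 0.002 & pr$base_rate < 1.25 * 0.002))
  ## expected total ~ 446 * 1354 = 603,884 sites; total SD = 1354*0.5*sqrt(446)
  expect_lt(abs(sum(pr$length) - 446 * 1354), 3 * 1354 * 0.5 * sqrt(446))
  ## degenerate ranges collapse to points
  one <- sampleGeneProfiles(1, lengthMean = 500, lengthCV = 0,
                            gcRange = c(0.4, 0.4), kappaRange = c(3, 3),
                            rateRange = c(1, 1), meanRate = 0.001, seed = 1)
  expect_equal(one$length, 500L)
  expect_equal(one$gc, 0.4)
  expect_equal(one$kappa, 3)
  expect_equal(one$base_rate, 0.001)
  expect_identical(sampleGeneProfiles(20, seed = 9),
                   sampleGeneProfiles(20, seed = 9))
})

test_that("nu = 0 reproduces a strict clock exactly", {
  tt <- generateMasterTree(12, 150, seed = 3)
  pr <- quickProfile(100, base_rate = 0.003)
  r <- evolveRates(tt, pr, rateModelParams(nu = 0))
  expect_true(all(branchRates(r) == 0.003))
  phy <- asPhylo(tt)
  ids <- secalib:::nodeIds(phy)
  dur <- ages(tt)[ids[phy$edge[, 1L]]] - ages(tt)[ids[phy$edge[, 2L]]]
  expect_equal(unname(branchLengths(r)[ids[phy$edge[, 2L]]]),
               unname(0.003 * dur))
})

test_that("autocorrelated rates stay within the deviation bound and are mean-centered", {
  tt <- generateMasterTree(12, 150, seed = 3)
  pr <- quickProfile(100, base_rate = 0.002)
  ## hard bound holds even under a strongly diffusing walk
  rBig <- evolveRates(tt, pr, rateModelParams(nu = 25), seed = 1)
  dev <- abs(branchRates(rBig) - 0.002) / 0.002
  expect_true(all(dev <= 0.25 + 1e-12))
  expect_gt(max(dev), 0.2)  # the clip is actually exercised
  ## Monte-Carlo: mean branch rate over many genes ~ base rate (martingale)
  means <- vapply(seq_len(400), function(i)
    mean(branchRates(evolveRates(tt, pr, rateModelParams(nu = 1), seed = i))),
    numeric(1L))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 0.002), 3 * se)
  ## determinism
  expect_identical(branchRates(evolveRates(tt, pr, seed = 42)),
                   branchRates(evolveRates(tt, pr, seed = 42)))
})

test_that("calibration nodes sit at the requested depths in distinct clades", {
  master <- generateMasterTree(40, 220, seed = 5)
  sp <- splitNested(master, targetFrac = 0.3)
  cal <- pickCalibrationNodes(sp)
  expect_length(cal, 3L)
  expect_false(sp@overlapNode %in% cal)
  phyA <- asPhylo(sp@treeA)
  rootA <- ape::getMRCA(phyA, taxa(sp@treeA))
  expect_false(secalib:::nodeIds(phyA)[rootA] %in% cal)
  ## the two deep nodes descend from different children of A's root
  kids <- secalib:::childList(phyA)[[rootA]]
  side <- vapply(cal[c("deep1", "deep2")], function(n) {
    nn <- match(n, secalib:::nodeIds(phyA))
    which(vapply(kids, function(k)
      nn %in% c(k, phangorn::Descendants(phyA, k, type = "all")),
      logical(1L)))
  }, numeric(1L))
  expect_equal(length(unique(side)), 2L)
})
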
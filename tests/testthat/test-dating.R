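test_that("two-taxon ML branch length matches the JC69 closed form", {
  ## 1000 sites, 300 mismatches, balanced composition; kappa fixed at 1
  ## with equal frequencies reduces HKY to JC69, whose MLE has the closed
  ## form -3/4 log(1 - 4 p / 3).
  s1 <- strrep(c("A", "C", "G", "T"), 250)
  s1 <- paste(rep(c("A", "C", "G", "T"), each = 250), collapse = "")
  sub <- c(A = "G", C = "T", G = "A", T = "C")
  x <- strsplit(s1, "")[[1L]]
  y <- x
  idx <- seq(1L, 1000L, length.out = 300)
  y[idx] <- sub[x[idx]]
  aln <- methods::new("MultiGeneAlignment",
    seqs = Biostrings::DNAStringSet(c(A = s1, B = paste(y, collapse = ""))),
    genes = data.frame(gene_id = "g", start = 1L, end = 1000L))
  phy <- ape::read.tree(text = "(A:1,B:1)R;")
  blt <- estimateBranchLengths(aln, phy, bf = rep(0.25, 4), fixKappa = 1)
  est <- sum(asPhylo(blt)$edge.length)
  expect_lt(abs(est - (-3 / 4 * log(1 - 4 * 0.3 / 3))), 1e-6)

  ## identical sequences push the length to the lower bound 0
  same <- methods::new("MultiGeneAlignment",
    seqs = Biostrings::DNAStringSet(c(A = s1, B = s1)),
    genes = data.frame(gene_id = "g", start = 1L, end = 1000L))
  blt0 <- estimateBranchLengths(same, phy, bf = rep(0.25, 4), fixKappa = 1)
  expect_lt(sum(asPhylo(blt0)$edge.length), 1e-8)
})

test_that("branch lengths are recovered within their standard errors", {
  tt <- generateMasterTree(16, 200, seed = 6)
  sim <- simulateOn(tt, 30000, nu = 0, seed = 5)
  blt <- estimateBranchLengths(sim$aln, tt)
  est <- branchLengths(blt)
  se <- blt@se
  truth <- branchLengths(sim$rated)
  shared <- intersect(names(truth), names(est))
  ## the outgroup pendant and the ingroup-root stem are confounded under
  ## the unrooted fit, so only ingroup branches are compared
  phyA <- asPhylo(tt)
  ingRoot <- secalib:::nodeIds(phyA)[ape::getMRCA(phyA, taxa(tt))]
  shared <- setdiff(shared, c(outgroup(tt), ingRoot))
  z <- abs(est[shared] - truth[shared]) / pmax(se[shared], 1e-9)
  expect_gte(mean(z <= 3), 0.95)
})

test_that("the relative-age recursion matches hand-computed values", {
  ## ((A:2,B:2):1,(C:1,D:1):2): D(AB)=2, D(CD)=1, D(root)=3
  blt <- madeBlt("((A:2,B:2)X:1,(C:1,D:1)Y:2)R;")
  rt <- relativeAges(blt)
  a <- relAges(rt)
  expect_equal(a[["X"]], 2 / 3)
  expect_equal(a[["Y"]], 1 / 3)
  expect_equal(a[["R"]], 1)
  expect_equal(unname(a[c("A", "B", "C", "D")]), rep(0, 4))
  ## clock-like lengths: all relative lineage rates equal
  expect_equal(unname(branchRates(rt)), rep(1, 6))

  ## non-clock case pins the equal-weight averaging: D(X)=mean(3,1)=2,
  ## D(root)=mean(2+1, 1+2)=3
  rt2 <- relativeAges(madeBlt("((A:3,B:1)X:1,(C:1,D:1)Y:2)R;"))
  expect_equal(relAges(rt2)[["X"]], 2 / 3)
  expect_equal(relAges(rt2)[["Y"]], 1 / 3)
})

test_that("relative ages are invariant to rescaling branch lengths", {
  blt <- madeBlt("((A:2,B:2)X:1,(C:1,D:1)Y:2)R;")
  a0 <- relAges(relativeAges(blt))
  for (c_ in c(1e-4, 0.37, 12, 1e5)) {
    bltC <- blt
    bltC@tree$edge.length <- blt@tree$edge.length * c_
    expect_equal(relAges(relativeAges(bltC)), a0, tolerance = 1e-12)
  }
})

test_that("calibration scaling follows the factor-interval rules", {
  rt <- madeRelTree(aX = 0.5, aY = 0.3)
  ## point calibration: f = 100 / 0.5 = 200
  res <- calibrate(rt, calibrationConstraints("X", 100, 100))
  expect_equal(res@f, 200)
  expect_equal(nodeTable(res)$ET[nodeTable(res)$node_id == "R"], 200)
  expect_true(res@feasible)

  ## two constraints: [180,220] * [150,260] intersect to [180,220],
  ## f = sqrt(180 * 220)
  cons <- calibrationConstraints(c("X", "R"), c(90, 150), c(110, 260))
  res2 <- calibrate(rt, cons)
  expect_equal(res2@fInterval, c(180, 220))
  expect_equal(res2@f, sqrt(180 * 220), tolerance = 1e-9)
  expect_equal(nodeTable(res2)$ET[nodeTable(res2)$node_id == "R"],
               sqrt(180 * 220), tolerance = 1e-6)

  ## empty intersection: [200,204] vs [300,310]; fallback f is bracketed
  cons3 <- calibrationConstraints(c("X", "R"), c(100, 300), c(102, 310))
  res3 <- calibrate(rt, cons3)
  expect_false(res3@feasible)
  expect_gt(res3@f, 204)
  expect_lt(res3@f, 300)

  ## calibrated nodes are clamped into their own bounds
  nd <- nodeTable(res2)
  for (i in seq_len(nrow(cons))) {
    et <- nd$ET[nd$node_id == cons$node_id[i]]
    expect_gte(et, cons$min[i]); expect_lte(et, cons$max[i])
  }
  expect_error(calibrate(rt, calibrationConstraints("A", 5, 10)),
               "zero relative age")
  expect_error(calibrate(rt, calibrationConstraints("nope", 5, 10)),
               "absent")
})

test_that("CIs collapse to the point estimate without uncertainty sources", {
  blt <- madeBlt("((A:2,B:2)X:1,(C:1,D:1)Y:2)R;", se = 0)
  res <- nodeCIs(blt, calibrationConstraints("X", 100, 100), B = 100, seed = 1)
  nd <- nodeTable(res)
  expect_equal(nd$ci_lo, nd$ET, tolerance = 1e-12)
  expect_equal(nd$ci_hi, nd$ET, tolerance = 1e-12)
})

test_that("CI bounds follow the factor-times-percentile product rule", {
  ## zero branch-length SEs freeze the relative-age percentiles at the
  ## point values, so with one constraint [90,110] at a = 2/3 the factor
  ## interval is [135, 165] and every CI is [135 a(u), 165 a(u)].
  blt <- madeBlt("((A:2,B:2)X:1,(C:1,D:1)Y:2)R;", se = 0)
  res <- nodeCIs(blt, calibrationConstraints("X", 90, 110), B = 100, seed = 1)
  expect_equal(res@fInterval, c(135, 165))
  nd <- nodeTable(res)
  r <- nd[nd$node_id == "R", ]
  expect_equal(c(r$ci_lo, r$ci_hi), c(135, 165))
  y <- nd[nd$node_id == "Y", ]
  expect_equal(c(y$ci_lo, y$ci_hi), c(135 / 3, 55))
  ## the calibrated node itself is intersected with its constraint
  x <- nd[nd$node_id == "X", ]
  expect_equal(c(x$ci_lo, x$ci_hi), c(90, 110))
})

test_that("widening the calibration interval never narrows any CI", {
  tt <- generateMasterTree(10, 150, seed = 8)
  sim <- simulateOn(tt, 2000, nu = 1, seed = 3)
  blt <- estimateBranchLengths(sim$aln, tt)
  rt <- relativeAges(blt)
  node <- names(sort(relAges(rt), decreasing = TRUE))[2L]
  TT <- 100
  prev <- NULL
  for (w in c(0, 2, 5, 10, 20, 40)) {
    res <- nodeCIs(blt, calibrationConstraints(node, TT - w, TT + w),
                   B = 100, seed = 11, rt = rt)
    nd <- nodeTable(res)
    nd <- nd[!nd$calibrated, ]
    if (!is.null(prev)) {
      expect_true(all(nd$ci_lo <= prev$ci_lo + 1e-12))
      expect_true(all(nd$ci_hi >= prev$ci_hi - 1e-12))
    }
    prev <- nd
  }
})

test_that("recycling a CI as a calibration compounds, never shrinks, CIs", {
  tt <- generateMasterTree(10, 150, seed = 8)
  sim <- simulateOn(tt, 2000, nu = 1, seed = 3)
  blt <- estimateBranchLengths(sim$aln, tt)
  rt <- relativeAges(blt)
  node <- names(sort(relAges(rt), decreasing = TRUE))[2L]
  run1 <- nodeCIs(blt, calibrationConstraints(node, 95, 105), B = 100,
                  seed = 4, rt = rt)
  r1 <- nodeTable(run1)[nodeTable(run1)$node_id == node, ]
  withCI <- nodeCIs(blt, calibrationConstraints(node, r1$ci_lo, r1$ci_hi),
                    B = 100, seed = 5, rt = rt)
  withPt <- nodeCIs(blt, calibrationConstraints(node, r1$ET, r1$ET),
                    B = 100, seed = 5, rt = rt)
  a <- nodeTable(withCI); b <- nodeTable(withPt)
  expect_true(all(a$ci_hi - a$ci_lo >= b$ci_hi - b$ci_lo - 1e-12))
})

test_that("dating results are deterministic given the seed", {
  tt <- generateMasterTree(10, 150, seed = 8)
  sim <- simulateOn(tt, 1000, nu = 1, seed = 3)
  blt <- estimateBranchLengths(sim$aln, tt)
  ing <- ingroupNodes(tt)
  cons <- calibrationConstraints(ing[which.max(ages(tt)[ing])], 140, 160)
  r1 <- nodeCIs(blt, cons, B = 80, seed = 9)
  r2 <- nodeCIs(blt, cons, B = 80, seed = 9)
  expect_identical(nodeTable(r1), nodeTable(r2))
})
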
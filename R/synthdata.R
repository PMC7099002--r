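## Synthetic-data generators: master timetree, nested A/B split, gene
## profiles and autocorrelated branch rates.

#' Generate a master ultrametric timetree with an outgroup
#'
#' Simulates a pure-birth (Yule) topology for the ingroup, rescales node
#' heights so the ingroup root sits at `rootAge`, and attaches a single
#' outgroup tip above the ingroup root.  Deterministic given `seed`.
#'
#' @param nTaxa Number of ingroup tips (>= 4).
#' @param rootAge Age of the ingroup root, in millions of years (my).
#' @param seed Integer seed.
#' @param outgroupFrac The stem above the ingroup root, as a fraction of
#'   `rootAge`; the tree root sits at `rootAge * (1 + outgroupFrac)`.
#' @return A [TimeTree] whose node ids are `N001 ...` and whose ingroup
#'   tips are `T001 ...`; the outgroup tip is `"OUT"`.
#' @export
generateMasterTree <- function(nTaxa, rootAge, seed, outgroupFrac = 0.25) {
  stopifnot2(nTaxa >= 4, "nTaxa must be >= 4")
  stopifnot2(rootAge > 0, "rootAge must be positive")
  ing <- withSeed(deriveSeed(seed, "yule"), ape::rphylo(nTaxa, 1, 0))
  ing$tip.label <- sprintf("T%03d", seq_len(nTaxa))
  ing$edge.length <- ing$edge.length * rootAge /
    max(ape::node.depth.edgelength(ing))
  base <- ape::read.tree(text = "(ING:1,OUT:2);")
  base$edge.length <- c(rootAge * outgroupFrac, rootAge * (1 + outgroupFrac))
  phy <- ape::bind.tree(base, ing, where = which(base$tip.label == "ING"))
  phy$node.label <- sprintf("N%03d", seq_len(phy$Nnode))
  newTimeTree(phy, outgroup = "OUT")
}

## Construct a TimeTree from a phylo in the time dialect, recomputing ages
## and snapping tiny numerical offsets so tips are exactly contemporaneous.
newTimeTree <- function(phy, outgroup = character()) {
  if (is.null(phy$node.label))
    phy$node.label <- sprintf("N%03d", seq_len(phy$Nnode))
  ages <- nodeAges(phy)
  ids <- nodeIds(phy)
  ## tips are contemporaneous by contract (callers validate ultrametricity
  ## within their own tolerance); snap them to exactly 0 and rebuild edge
  ## lengths from the ages so the consistency invariant is exact
  ages[seq_len(ape::Ntip(phy))] <- 0
  phy$edge.length <- ages[ids[phy$edge[, 1L]]] - ages[ids[phy$edge[, 2L]]]
  methods::new("TimeTree", tree = phy, ages = ages, outgroup = outgroup)
}

#' Split a master timetree into two nested subtrees with one overlap node
#'
#' Chooses an internal ingroup node X whose age is closest to
#' `overlapRelDepth` times the ingroup root age (optionally restricted to
#' candidates whose smaller child clade holds a target fraction of the
#' ingroup).  Subtree B's ingroup is the smaller child clade of X plus one
#' shared lineage taken from the other child; subtree A's ingroup is the
#' rest of the master ingroup plus one shared lineage taken from the B-side
#' clade.  X is therefore internal to both trees, the two ingroups overlap
#' in exactly the two shared lineages, and every retained node keeps its
#' master age.  The outgroup is appended to both subtrees.
#'
#' @param master A [TimeTree] with >= 8 ingroup taxa.
#' @param overlapRelDepth Target age of the overlap node as a fraction of
#'   the ingroup root age.
#' @param targetFrac Optional target fraction of ingroup taxa for subtree
#'   B's core clade; candidates outside (0.5, 1.5) times the target are
#'   discarded before the age criterion is applied.
#' @param seed Integer seed (reserved; the split itself is deterministic).
#' @return A [NestedSplit].
#' @export
splitNested <- function(master, overlapRelDepth = 0.76, targetFrac = NULL,
                        seed = 1L) {
  stopifnot2(length(taxa(master)) >= 8, "master needs >= 8 ingroup taxa")
  phy <- master@tree
  ids <- nodeIds(phy)
  og <- master@outgroup
  ntip <- ape::Ntip(phy)
  ingRoot <- ape::getMRCA(phy, setdiff(phy$tip.label, og))
  rootAge <- master@ages[ids[ingRoot]]
  ch <- childList(phy)
  tipsUnder <- function(n) {
    d <- phangorn::Descendants(phy, n, type = "tips")[[1L]]
    phy$tip.label[d]
  }
  cand <- setdiff(which(seq_len(ntip + phy$Nnode) > ntip), ingRoot)
  cand <- intersect(cand, c(ingRoot, phangorn::Descendants(phy, ingRoot,
                                                           type = "all")))
  cand <- setdiff(cand, seq_len(ntip))
  info <- lapply(cand, function(n) {
    k <- ch[[n]]
    sz <- vapply(k, function(x) length(tipsUnder(x)), integer(1L))
    small <- k[which.min(sz)]
    list(node = n, small = small, big = setdiff(k, small),
         smallSize = min(sz), age = master@ages[ids[n]])
  })
  info <- Filter(function(x) x$smallSize >= 2L, info)
  stopifnot2(length(info) > 0, "no internal node yields a feasible B ingroup")
  if (!is.null(targetFrac)) {
    n_ing <- length(taxa(master))
    frac <- vapply(info, function(x) x$smallSize / n_ing, numeric(1L))
    keep <- frac > 0.5 * targetFrac & frac < 1.5 * targetFrac
    if (any(keep)) info <- info[keep]
  }
  tgt <- overlapRelDepth * rootAge
  X <- info[[which.min(vapply(info, function(x) abs(x$age - tgt), numeric(1L)))]]
  coreB <- tipsUnder(X$small)
  otherSide <- tipsUnder(X$big)
  s1 <- sort(coreB)[1L]       # shared lineage kept in tree A
  s2 <- sort(otherSide)[1L]   # shared lineage added to tree B
  allIn <- taxa(master)
  tipsB <- c(coreB, s2)
  tipsA <- c(setdiff(allIn, coreB), s1)
  treeA <- subsetTimeTree(master, c(tipsA, og))
  treeB <- subsetTimeTree(master, c(tipsB, og))
  methods::new("NestedSplit", master = master, treeA = treeA, treeB = treeB,
               overlapNode = ids[X$node], sharedLineages = c(s1, s2),
               outgroup = og)
}

#' Restrict a TimeTree to a subset of its tips
#'
#' True ages of all retained nodes are preserved.
#'
#' @param x A [TimeTree].
#' @param tips Tip labels to keep.
#' @return A [TimeTree].
#' @export
subsetTimeTree <- function(x, tips) {
  phy <- ape::keep.tip(x@tree, tips)
  og <- intersect(x@outgroup, tips)
  methods::new("TimeTree", tree = phy,
               ages = x@ages[nodeIds(phy)], outgroup = og)
}

#' Sample per-gene evolutionary profiles
#'
#' Gene lengths come from a lognormal with mean `lengthMean` and
#' coefficient of variation `lengthCV`; GC content, ti/tv ratio kappa and
#' the gene's base substitution rate are uniform draws within the given
#' ranges (the rate range is relative to `meanRate`).  Deterministic given
#' `seed`; each gene also receives its own derived seed.
#'
#' @param nGenes Number of genes (>= 1).
#' @param lengthMean Mean gene length in sites.
#' @param lengthCV Coefficient of variation of gene length.
#' @param gcRange,kappaRange Uniform bounds for GC content and kappa.
#' @param rateRange Uniform bounds for the per-gene rate multiplier.
#' @param meanRate Global mean substitution rate, subs/site/my.
#' @param seed Integer seed.
#' @return data.frame with columns `gene_id`, `length`, `gc`, `kappa`,
#'   `base_rate`, `seed`.
#' @export
sampleGeneProfiles <- function(nGenes, lengthMean = 1354, lengthCV = 0.5,
                               gcRange = c(0.3, 0.7), kappaRange = c(2, 8),
                               rateRange = c(0.75, 1.25), meanRate = 0.002,
                               seed = 1L) {
  stopifnot2(nGenes >= 1, "nGenes must be >= 1")
  stopifnot2(lengthMean >= 1 && lengthCV >= 0, "invalid length parameters")
  withSeed(deriveSeed(seed, "profiles"), {
    sdlog <- sqrt(log(1 + lengthCV^2))
    len <- if (sdlog > 0) {
      rlnorm(nGenes, meanlog = log(lengthMean) - sdlog^2 / 2, sdlog = sdlog)
    } else rep(lengthMean, nGenes)
    data.frame(
      gene_id = sprintf("g%03d", seq_len(nGenes)),
      length = pmax(1L, as.integer(round(len))),
      gc = runif(nGenes, gcRange[1L], gcRange[2L]),
      kappa = runif(nGenes, kappaRange[1L], kappaRange[2L]),
      base_rate = meanRate * runif(nGenes, rateRange[1L], rateRange[2L]),
      seed = vapply(seq_len(nGenes), function(i)
        deriveSeed(seed, "gene", i), integer(1L)))
  })
}

#' Rate-model parameters for autocorrelated branch rates
#'
#' `nu` scales the variance of the lognormal rate walk per unit time;
#' `maxDev` is the hard bound on the relative deviation of any branch rate
#' from the gene's base rate.  With the default `nu = 1` the walk is
#' calibrated so the central 95% of root-to-tip rate deviations spans
#' about `+/- maxDev` before clipping.
#'
#' @param nu Autocorrelation variance multiplier (>= 0).
#' @param maxDev Maximum relative rate deviation, in (0, 1].
#' @return list with class `RateModelParams`.
#' @export
rateModelParams <- function(nu = 1, maxDev = 0.25) {
  stopifnot2(nu >= 0, "nu must be >= 0")
  stopifnot2(maxDev >= 0 && maxDev <= 1, "maxDev must be in [0,1]")
  structure(list(nu = nu, maxDev = maxDev), class = "RateModelParams")
}

#' Evolve autocorrelated branch rates along a timetree
#'
#' The root lineage starts at the gene's base rate; each child branch rate
#' is drawn from a lognormal centered (in mean) on the parent rate, with
#' log-variance `nu_eff * branch duration`.  `nu_eff` is
#' `nu * (log(1 + maxDev) / 1.96)^2 / rootAge`, so that at the tips the
#' central 95% of rates deviates by about `maxDev` from the base rate when
#' `nu = 1`; rates are then hard-clipped to
#' `base_rate * [1 - maxDev, 1 + maxDev]`.  Branch lengths are rate times
#' branch duration.  With `nu = 0` every branch rate equals the base rate
#' exactly (strict clock).
#'
#' @param timetree A [TimeTree].
#' @param profile One row of [sampleGeneProfiles()] output (or any list
#'   with `base_rate`).
#' @param params A [rateModelParams()] object.
#' @param seed Integer seed (defaults to the profile's own seed).
#' @return A [RatedTree].
#' @export
evolveRates <- function(timetree, profile, params = rateModelParams(),
                        seed = profile$seed) {
  phy <- timetree@tree
  ids <- nodeIds(phy)
  base <- profile$base_rate
  stopifnot2(is.numeric(base) && base > 0, "profile base_rate must be > 0")
  rootAge <- max(timetree@ages)
  nuEff <- params$nu * (log(1 + params$maxDev) / 1.96)^2 / rootAge
  nnode <- ape::Ntip(phy) + phy$Nnode
  lograte <- rep(log(base), nnode)
  ord <- rev(ape::postorder(phy))  # preorder over edges
  withSeed(deriveSeed(seed, "rates"), {
    for (i in ord) {
      p <- phy$edge[i, 1L]; c_ <- phy$edge[i, 2L]
      dur <- phy$edge.length[i]
      s2 <- nuEff * dur
      lograte[c_] <- rnorm(1L, mean = lograte[p] - s2 / 2, sd = sqrt(s2))
    }
  })
  kids <- phy$edge[, 2L]
  r <- if (params$nu == 0) rep(base, length(kids)) else exp(lograte[kids])
  r <- pmin(pmax(r, base * (1 - params$maxDev)), base * (1 + params$maxDev))
  rates <- setNames(r, ids[kids])
  lens <- setNames(r * phy$edge.length, ids[kids])
  methods::new("RatedTree", timetree = timetree, rates = rates, lengths = lens)
}

#' Choose calibration nodes in subtree A
#'
#' Picks the three primary-calibration nodes the study places in subtree
#' A: one relatively shallow node and two deep nodes lying in different
#' child clades of A's ingroup root, each chosen as the internal node whose
#' true age is closest to the requested fraction of A's root age.  The
#' overlap node and the root itself are never selected.
#'
#' @param split A [NestedSplit].
#' @param shallowRelDepth,deepRelDepth Target ages as fractions of A's
#'   ingroup root age.
#' @return Named character vector of node ids
#'   (`shallow`, `deep1`, `deep2`).
#' @export
pickCalibrationNodes <- function(split, shallowRelDepth = 0.29,
                                 deepRelDepth = 0.95) {
  tt <- split@treeA
  phy <- tt@tree
  ids <- nodeIds(phy)
  ing <- ingroupNodes(tt)
  rootA <- ape::getMRCA(phy, taxa(tt))
  rootAge <- tt@ages[ids[rootA]]
  avoid <- c(ids[rootA], split@overlapNode)
  pool <- setdiff(ing, avoid)
  stopifnot2(length(pool) >= 3, "tree A too small to place 3 calibrations")
  pickIn <- function(poolIds, tgt) {
    poolIds[which.min(abs(tt@ages[poolIds] - tgt))]
  }
  shallow <- pickIn(pool, shallowRelDepth * rootAge)
  kidsA <- childList(phy)[[rootA]]
  deep <- character(0)
  for (k in kidsA) {
    sub <- phangorn::Descendants(phy, k, type = "all")
    sub <- c(k, sub[sub > ape::Ntip(phy)])
    cand <- setdiff(intersect(ids[sub], pool), shallow)
    if (length(cand))
      deep <- c(deep, pickIn(cand, deepRelDepth * rootAge))
  }
  if (length(deep) < 2L) {
    ## one side of the root has no eligible internal node (it may have
    ## been reduced to a single shared lineage by the split); fall back to
    ## the best pair of deep nodes on disjoint lineages
    tgt <- deepRelDepth * rootAge
    ranked <- setdiff(pool, shallow)
    ranked <- ranked[order(abs(tt@ages[ranked] - tgt))]
    deep <- character(0)
    for (first in ranked) {
      n1 <- match(first, ids)
      lineage <- c(phangorn::Ancestors(phy, n1, type = "all"), n1,
                   phangorn::Descendants(phy, n1, type = "all"))
      cand <- setdiff(ranked, c(first, ids[lineage]))
      if (length(cand)) {
        deep <- c(first, pickIn(cand, tgt))
        break
      }
    }
    stopifnot2(length(deep) == 2L,
               "could not place two deep calibrations in distinct clades")
  }
  c(shallow = shallow, deep1 = deep[1L], deep2 = deep[2L])
}
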
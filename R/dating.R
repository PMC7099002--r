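## Divergence-time engine: ML branch lengths on the fixed true topology,
## relative node ages by a relative-rate recursion, calibration-constrained
## scaling and resampling-based confidence intervals.

#' Maximum-likelihood branch lengths under HKY on a fixed topology
#'
#' Fits HKY branch lengths (and kappa, unless fixed) on the given rooted
#' topology with empirical base frequencies and uniform rates among sites.
#' The tree is optimized unrooted (the two branches incident to the root
#' are confounded under a reversible model) and re-rooted on the outgroup
#' afterwards, so all ingroup branch lengths are identifiable.  Per-branch
#' standard errors come from the curvature of the log-likelihood in each
#' branch length at the optimum (central finite differences on the
#' profile).
#'
#' For two-taxon alignments the single pairwise branch length is optimized
#' directly over the exact HKY likelihood (bounded \[0, 10\]).
#'
#' @param aln A [MultiGeneAlignment-class] whose taxa equal the topology's
#'   tips.
#' @param topology A [TimeTree] (only its topology and outgroup are used)
#'   or an ape `phylo` with node labels.
#' @param bf Base frequencies; `NULL` (default) uses empirical
#'   frequencies.
#' @param fixKappa Fix kappa at this value instead of estimating it.
#' @return A [BranchLengthTree-class].
#' @export
estimateBranchLengths <- function(aln, topology, bf = NULL, fixKappa = NULL) {
  og <- character()
  phy <- if (methods::is(topology, "TimeTree")) {
    og <- topology@outgroup
    topology@tree
  } else topology
  stopifnot2(setequal(names(alnSeqs(aln)), phy$tip.label),
             "alignment taxa must equal topology tips")
  dat <- asPhyDat(aln)
  stopifnot2(attr(dat, "nr") >= 1, "empty alignment")
  if (is.null(bf)) bf <- as.numeric(phangorn::baseFreq(dat))
  if (ape::Ntip(phy) == 2L)
    return(estimatePairBranchLength(aln, phy, bf, fixKappa))

  tru <- ape::unroot(phy)
  tru$edge.length <- rep(0.05, nrow(tru$edge))
  k0 <- if (is.null(fixKappa)) 2 else fixKappa
  fit <- phangorn::pml(tru, dat, bf = bf, Q = c(1, k0, 1, 1, k0, 1), k = 1)
  fit <- phangorn::optim.pml(
    fit, optEdge = TRUE, optQ = is.null(fixKappa),
    model = if (is.null(fixKappa)) "HKY" else NULL,
    control = phangorn::pml.control(trace = 0, epsilon = 1e-8, maxit = 25))
  kappa <- fit$Q[2L]
  se <- edgeCurvatureSE(fit)
  rooted <- if (length(og) == 1L) {
    ape::root(fit$tree, outgroup = og, resolve.root = TRUE)
  } else fit$tree
  rooted$edge.length[rooted$edge.length < 0] <- 0
  methods::new("BranchLengthTree", tree = rooted, se = se, kappa = kappa,
               bf = bf, logLik = as.numeric(fit$logLik), outgroup = og)
}

## Curvature-based SE for every edge of a fitted pml object, keyed by the
## id of the edge's child node.  d2 < 0 is expected at an interior optimum;
## at the zero lower bound (or flat profile) a conservative fallback based
## on the step size is used.
edgeCurvatureSE <- function(fit) {
  tr <- fit$tree
  ids <- nodeIds(tr)
  nE <- nrow(tr$edge)
  ll0 <- fit$logLik
  se <- numeric(nE)
  for (i in seq_len(nE)) {
    t0 <- tr$edge.length[i]
    h <- max(1e-5, 0.05 * t0)
    evalAt <- function(x) {
      tr2 <- tr
      tr2$edge.length[i] <- x
      stats::update(fit, tree = tr2)$logLik
    }
    if (t0 - h > 0) {
      d2 <- (evalAt(t0 + h) - 2 * ll0 + evalAt(t0 - h)) / h^2
    } else {
      d2 <- (evalAt(t0 + 2 * h) - 2 * evalAt(t0 + h) + ll0) / h^2
    }
    se[i] <- if (is.finite(d2) && d2 < 0) sqrt(-1 / d2) else h
  }
  setNames(se, ids[tr$edge[, 2L]])
}

## Exact HKY likelihood optimization for a 2-taxon alignment.
estimatePairBranchLength <- function(aln, phy, bf, fixKappa) {
  m <- as.matrix(alnSeqs(aln))
  a <- match(m[1L, ], NUC)
  b <- match(m[2L, ], NUC)
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  kappa <- if (is.null(fixKappa)) 2 else fixKappa
  model <- hkyModel(bf, kappa)
  nll <- function(t) {
    P <- hkyTransitionProbs(model, t)
    -sum(log(model@bf[a] * P[cbind(a, b)]))
  }
  opt <- optimize(nll, c(0, 10), tol = 1e-10)
  t0 <- if (nll(0) <= opt$objective) 0 else opt$minimum
  h <- max(1e-6, 1e-3 * t0)
  d2 <- if (t0 - h > 0) {
    (-nll(t0 + h) + 2 * nll(t0) - nll(t0 - h)) / h^2
  } else -Inf
  se <- if (is.finite(d2) && d2 < 0) sqrt(-1 / d2) else h
  tr <- phy
  ## split the path length evenly across the two pendant edges
  tr$edge.length <- rep(t0 / 2, nrow(tr$edge))
  ids <- nodeIds(tr)
  methods::new("BranchLengthTree", tree = tr,
               se = setNames(rep(se / 2, nrow(tr$edge)), ids[tr$edge[, 2L]]),
               kappa = kappa, bf = as.numeric(bf), logLik = -nll(t0),
               outgroup = character())
}

## Relative node depths for one or many branch-length vectors.
## phy: rooted ingroup tree; lens: matrix (edges x B) of branch lengths in
## edge order.  Returns node depths, matrix (nodes x B): tips 0, internal
## nodes the average over the two child lineages.
relDepths <- function(phy, lens) {
  if (is.vector(lens)) lens <- matrix(lens, ncol = 1L)
  nnode <- ape::Ntip(phy) + phy$Nnode
  D <- matrix(0, nrow = nnode, ncol = ncol(lens))
  po <- ape::postorder(phy)
  edge <- phy$edge
  acc <- matrix(0, nrow = nnode, ncol = ncol(lens))  # sum of (D(child)+b)
  cnt <- integer(nnode)
  for (i in po) {
    p <- edge[i, 1L]; ch <- edge[i, 2L]
    acc[p, ] <- acc[p, ] + D[ch, ] + lens[i, ]
    cnt[p] <- cnt[p] + 1L
    if (cnt[p] == 2L) D[p, ] <- acc[p, ] / 2
  }
  D
}

#' Relative node ages from estimated branch lengths
#'
#' Implements the relative-rate recursion: tip depths are zero and the
#' depth of an internal node is the average over its two children `v, w`
#' of `D(child) + b(child)`.  Relative ages are depths divided by the
#' ingroup-root depth (tips 0, root 1).  Relative lineage rates are
#' `b(v) / (D(parent) - D(v))`, and are `NA` (undefined) on branches with
#' non-positive elapsed relative time.  The outgroup is used only for
#' rooting and is pruned before computation.
#'
#' @param blt A [BranchLengthTree-class].
#' @return A [RelativeTimeTree-class] over the ingroup.
#' @export
relativeAges <- function(blt) {
  phy <- blt@tree
  if (length(blt@outgroup) == 1L && blt@outgroup %in% phy$tip.label)
    phy <- ape::drop.tip(phy, blt@outgroup)
  ids <- nodeIds(phy)
  D <- relDepths(phy, phy$edge.length)[, 1L]
  root <- rootNode(phy)
  stopifnot2(D[root] > 0, "tree has zero depth: no divergence signal")
  a <- pmin(pmax(D / D[root], 0), 1)
  a[seq_len(ape::Ntip(phy))] <- 0
  elapsed <- D[phy$edge[, 1L]] - D[phy$edge[, 2L]]
  r <- ifelse(elapsed > 0, phy$edge.length / elapsed, NA_real_)
  methods::new("RelativeTimeTree", tree = phy,
               relAges = setNames(a, ids),
               relRates = setNames(r, ids[phy$edge[, 2L]]),
               depth = D[root])
}

## Factor interval implied by the constraints at the point relative ages:
## [max_i min_i/a_i, min_i max_i/a_i] (possibly empty, lo > hi).
factorInterval <- function(rt, constraints) {
  a <- rt@relAges[constraints$node_id]
  stopifnot2(!anyNA(a), "constraint on a node absent from the tree")
  stopifnot2(all(a > 0), "constraint on a node with zero relative age")
  c(max(constraints$min / a), min(constraints$max / a))
}

#' Calibrate relative ages to absolute times
#'
#' Each constraint i at a node with relative age a_i admits scaling
#' factors in `[min_i / a_i, max_i / a_i]`.  If the intersection of these
#' intervals is non-empty, the factor f is its geometric midpoint
#' `sqrt(f_lo * f_hi)`; otherwise f minimizes the sum of squared
#' log-distances to the individual intervals (1-D search on log f) and the
#' result is flagged infeasible.  Estimated times are `f * a(u)`;
#' calibrated nodes are clamped into their own bounds.
#'
#' @param rt A [RelativeTimeTree-class].
#' @param constraints data.frame from [calibrationConstraints()].
#' @param timetree Optional [TimeTree] supplying true ages for the `TT`
#'   column.
#' @return A [DatingResult-class] with point estimates (CIs `NA`).
#' @export
calibrate <- function(rt, constraints, timetree = NULL) {
  fi <- factorInterval(rt, constraints)
  feasible <- fi[1L] <= fi[2L]
  f <- if (feasible) {
    sqrt(fi[1L] * fi[2L])
  } else {
    a <- rt@relAges[constraints$node_id]
    lologs <- log(constraints$min / a)
    hilogs <- log(constraints$max / a)
    obj <- function(lf)
      sum(pmax(0, lologs - lf, lf - hilogs)^2)
    exp(optimize(obj, range(c(lologs, hilogs)), tol = 1e-12)$minimum)
  }
  a <- rt@relAges
  ET <- f * a
  cal <- names(a) %in% constraints$node_id
  idx <- match(names(a)[cal], constraints$node_id)
  ET[cal] <- pmin(pmax(ET[cal], constraints$min[idx]), constraints$max[idx])
  TT <- if (is.null(timetree)) NA_real_ else
    unname(timetree@ages[names(a)])
  nodes <- data.frame(node_id = names(a), relative_age = unname(a),
                      TT = TT, ET = unname(ET),
                      ci_lo = NA_real_, ci_hi = NA_real_, calibrated = cal)
  methods::new("DatingResult", nodes = nodes, f = f, fInterval = fi,
               feasible = feasible, constraints = constraints)
}

#' Calibrated node ages with confidence intervals
#'
#' Uncertainty from the data and from the calibrations is propagated
#' multiplicatively.  `B` branch-length vectors are drawn from independent
#' normals centered at the ML estimates with the curvature standard
#' errors (truncated at 0), relative ages are recomputed for each draw and
#' summarized by their 2.5/97.5 percentiles `[a_lo(u), a_hi(u)]`.  The
#' calibrations bound the scaling factor by
#' `[f_lo, f_hi] = [max_i min_i/a_i, min_i max_i/a_i]` at the point
#' relative ages, and `CI(u) = [f_lo * a_lo(u), f_hi * a_hi(u)]`.  When
#' the factor interval is empty the CI falls back to the point factor
#' plus/minus the widest single-constraint relative half-width, and the
#' result is flagged.  Calibrated nodes' CIs are intersected with their
#' own bounds.  Deterministic given `seed`.
#'
#' @param blt A [BranchLengthTree-class].
#' @param constraints data.frame from [calibrationConstraints()].
#' @param B Number of resampled branch-length vectors (>= 50).
#' @param seed Integer seed.
#' @param rt Optional precomputed [RelativeTimeTree-class].
#' @param timetree Optional [TimeTree] supplying the `TT` column.
#' @param percentiles Lower/upper percentiles of the resampled relative
#'   ages.
#' @return A [DatingResult-class] with CIs.
#' @export
nodeCIs <- function(blt, constraints, B = 200, seed = 1L, rt = NULL,
                    timetree = NULL, percentiles = c(0.025, 0.975)) {
  stopifnot2(B >= 50, "B must be >= 50")
  if (is.null(rt)) rt <- relativeAges(blt)
  pt <- calibrate(rt, constraints, timetree = timetree)
  phy <- rt@tree
  ids <- nodeIds(phy)
  mle <- phy$edge.length
  se <- blt@se[ids[phy$edge[, 2L]]]
  nE <- length(mle)
  draws <- withSeed(deriveSeed(seed, "ci-draws"), {
    matrix(pmax(rnorm(nE * B, mean = mle, sd = se), 0), nrow = nE)
  })
  D <- relDepths(phy, draws)
  root <- rootNode(phy)
  ok <- D[root, ] > 0
  A <- sweep(D[, ok, drop = FALSE], 2L, D[root, ok], "/")
  aLo <- apply(A, 1L, quantile, probs = percentiles[1L], names = FALSE)
  aHi <- apply(A, 1L, quantile, probs = percentiles[2L], names = FALSE)
  fi <- pt@fInterval
  if (pt@feasible) {
    lo <- fi[1L] * aLo
    hi <- fi[2L] * aHi
  } else {
    w <- max((pt@constraints$max - pt@constraints$min) /
               (pt@constraints$max + pt@constraints$min))
    lo <- pt@f * (1 - w) * aLo
    hi <- pt@f * (1 + w) * aHi
  }
  nodes <- pt@nodes
  m <- match(nodes$node_id, ids)
  nodes$ci_lo <- lo[m]
  nodes$ci_hi <- hi[m]
  cal <- nodes$calibrated
  idx <- match(nodes$node_id[cal], constraints$node_id)
  nodes$ci_lo[cal] <- pmax(nodes$ci_lo[cal], constraints$min[idx])
  nodes$ci_hi[cal] <- pmin(nodes$ci_hi[cal], constraints$max[idx])
  nodes$ci_lo <- pmin(nodes$ci_lo, nodes$ET)
  nodes$ci_hi <- pmax(nodes$ci_hi, nodes$ET)
  methods::new("DatingResult", nodes = nodes, f = pt@f, fInterval = fi,
               feasible = pt@feasible, constraints = constraints)
}

#' One-stop dating of an alignment on a known topology
#'
#' Convenience wrapper: ML branch lengths, relative ages, calibration and
#' CIs in one call.
#'
#' @inheritParams estimateBranchLengths
#' @inheritParams nodeCIs
#' @param timetree A [TimeTree] giving topology, outgroup and true ages.
#' @return A [DatingResult-class].
#' @export
dateTree <- function(aln, timetree, constraints, B = 200, seed = 1L,
                     bf = NULL, fixKappa = NULL) {
  blt <- estimateBranchLengths(aln, timetree, bf = bf, fixKappa = fixKappa)
  rt <- relativeAges(blt)
  nodeCIs(blt, constraints, B = B, seed = seed, rt = rt, timetree = timetree)
}
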
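#' @import methods
#' @importFrom stats optimize quantile rnorm rlnorm runif sd setNames
#' @importFrom utils read.csv write.csv head packageVersion
NULL

setOldClass("phylo")

#' TimeTree: a rooted binary timetree with true node ages
#'
#' Wraps an ape `phylo` whose edge lengths are time durations (millions of
#' years, my).  Tips are contemporaneous (age 0), every parent is strictly
#' older than its children, and each node carries a unique identifier
#' (tip label for tips, node label for internal nodes).  One designated
#' outgroup tip subtends the ingroup.
#'
#' @slot tree `phylo`; edge lengths in my, `node.label` holds node ids.
#' @slot ages named numeric; true age of every node, names are node ids.
#' @slot outgroup character; label of the outgroup tip (may be empty).
#' @exportClass TimeTree
setClass("TimeTree",
  representation(tree = "phylo", ages = "numeric", outgroup = "character"))

setValidity("TimeTree", function(object) {
  phy <- object@tree
  if (!ape::is.rooted(phy)) return("tree must be rooted")
  if (!ape::is.binary(phy)) return("tree must be binary")
  ids <- nodeIds(phy)
  if (anyDuplicated(ids)) return("node ids must be unique")
  if (!setequal(names(object@ages), ids)) return("ages must be named by node id")
  ages <- object@ages[ids]
  ntip <- ape::Ntip(phy)
  if (any(abs(ages[seq_len(ntip)]) > 1e-8)) return("tip ages must all be 0")
  dif <- ages[phy$edge[, 1L]] - ages[phy$edge[, 2L]]
  if (any(dif <= 0)) return("every parent age must exceed both child ages")
  if (any(abs(dif - phy$edge.length) > 1e-6 * max(ages)))
    return("edge lengths must equal parent age minus child age")
  if (length(object@outgroup) == 1L && !object@outgroup %in% phy$tip.label)
    return("outgroup is not a tip of the tree")
  TRUE
})

#' NestedSplit: two nested timetrees sharing one overlapping node
#'
#' Result of splitting a master timetree into subtree A and subtree B such
#' that one internal node (the overlap node) is present in both, the two
#' ingroups intersect in exactly two shared lineages, and every retained
#' node keeps its true age from the master tree.
#'
#' @slot master,treeA,treeB [TimeTree] objects.
#' @slot overlapNode character; node id present in master, A and B.
#' @slot sharedLineages character(2); the taxa present in both ingroups.
#' @slot outgroup character; outgroup tip label (kept in all three trees).
#' @exportClass NestedSplit
setClass("NestedSplit",
  representation(master = "TimeTree", treeA = "TimeTree", treeB = "TimeTree",
                 overlapNode = "character", sharedLineages = "character",
                 outgroup = "character"))

setValidity("NestedSplit", function(object) {
  a <- object@treeA@ages; b <- object@treeB@ages; m <- object@master@ages
  ov <- object@overlapNode
  if (!(ov %in% names(a) && ov %in% names(b) && ov %in% names(m)))
    return("overlap node must be present in master, A and B")
  if (max(abs(c(a[ov] - m[ov], b[ov] - m[ov]))) > 1e-8 * m[ov])
    return("overlap node age must be identical in master, A and B")
  og <- object@outgroup
  inA <- setdiff(object@treeA@tree$tip.label, og)
  inB <- setdiff(object@treeB@tree$tip.label, og)
  if (!setequal(intersect(inA, inB), object@sharedLineages))
    return("ingroups must intersect exactly in the shared lineages")
  if (length(object@sharedLineages) != 2L) return("exactly 2 shared lineages")
  inM <- setdiff(object@master@tree$tip.label, og)
  if (!setequal(union(inA, inB), inM))
    return("A and B ingroups must jointly cover the master ingroup")
  TRUE
})

#' RatedTree: per-branch rates and branch lengths on a TimeTree
#'
#' One gene's realization of autocorrelated branch-rate variation.  Rates
#' (substitutions/site/my) and the implied branch lengths
#' (substitutions/site, rate times branch duration) are indexed by the id
#' of the child node of each branch.
#'
#' @slot timetree [TimeTree].
#' @slot rates named numeric; branch rate keyed by child node id.
#' @slot lengths named numeric; branch length keyed by child node id.
#' @exportClass RatedTree
setClass("RatedTree",
  representation(timetree = "TimeTree", rates = "numeric", lengths = "numeric"))

setValidity("RatedTree", function(object) {
  phy <- object@timetree@tree
  ids <- nodeIds(phy)
  kids <- ids[phy$edge[, 2L]]
  if (!setequal(names(object@rates), kids)) return("rates must be keyed by child node id")
  if (!setequal(names(object@lengths), kids)) return("lengths must be keyed by child node id")
  if (any(object@rates <= 0)) return("all rates must be positive")
  dur <- object@timetree@ages[ids[phy$edge[, 1L]]] - object@timetree@ages[kids]
  expct <- object@rates[kids] * dur
  if (max(abs(object@lengths[kids] - expct)) > 1e-10 * max(expct))
    return("branch length must equal rate times branch duration")
  TRUE
})

#' MultiGeneAlignment: nucleotide alignment with gene boundaries
#'
#' Equal-length nucleotide sequences (one per taxon) plus a bookkeeping
#' table of the genes concatenated into the alignment, with 1-based
#' start/end site offsets.
#'
#' @slot seqs [Biostrings::DNAStringSet] named by taxon.
#' @slot genes data.frame with columns `gene_id`, `start`, `end`.
#' @exportClass MultiGeneAlignment
setClass("MultiGeneAlignment",
  representation(seqs = "ANY", genes = "data.frame"))

setValidity("MultiGeneAlignment", function(object) {
  s <- object@seqs
  if (!methods::is(s, "DNAStringSet")) return("seqs must be a DNAStringSet")
  w <- Biostrings::width(s)
  if (length(unique(w)) > 1L) return("all sequences must have equal length")
  if (anyDuplicated(names(s))) return("taxon labels must be unique")
  g <- object@genes
  if (!all(c("gene_id", "start", "end") %in% names(g)))
    return("genes table needs gene_id, start, end")
  if (nrow(g) && sum(g$end - g$start + 1L) != w[1L])
    return("alignment length must equal the sum of gene lengths")
  TRUE
})

#' HKYModel: HKY85 substitution model parameters
#'
#' @slot bf named numeric(4); base frequencies in A, C, G, T order.
#' @slot kappa numeric; transition/transversion rate ratio.
#' @exportClass HKYModel
setClass("HKYModel", representation(bf = "numeric", kappa = "numeric"))

setValidity("HKYModel", function(object) {
  if (length(object@bf) != 4L || any(object@bf <= 0) ||
      abs(sum(object@bf) - 1) > 1e-8)
    return("bf must be 4 positive frequencies summing to 1")
  if (object@kappa <= 0) return("kappa must be positive")
  TRUE
})

#' BranchLengthTree: ML branch lengths with curvature standard errors
#'
#' The fitted tree is rooted via the outgroup and keeps the node ids of the
#' topology it was estimated on.  Branch lengths (substitutions/site) and
#' their standard errors are keyed by child node id.
#'
#' @slot tree `phylo` with ML edge lengths.
#' @slot se named numeric; per-branch standard error, keyed by child id.
#' @slot kappa numeric; fitted ti/tv ratio.
#' @slot bf numeric(4); base frequencies used.
#' @slot logLik numeric; maximized log-likelihood.
#' @slot outgroup character.
#' @exportClass BranchLengthTree
setClass("BranchLengthTree",
  representation(tree = "phylo", se = "numeric", kappa = "numeric",
                 bf = "numeric", logLik = "numeric", outgroup = "character"))

setValidity("BranchLengthTree", function(object) {
  if (any(object@tree$edge.length < -1e-12)) return("branch lengths must be >= 0")
  if (any(object@se < 0)) return("standard errors must be >= 0")
  if (!is.finite(object@logLik)) return("log-likelihood must be finite")
  TRUE
})

#' RelativeTimeTree: relative node ages before calibration
#'
#' Relative ages lie in [0, 1] (tips 0, ingroup root 1); relative lineage
#' rates are branch length divided by elapsed relative time and are `NA`
#' where the elapsed time is zero.
#'
#' @slot tree `phylo`; the ingroup topology (outgroup pruned).
#' @slot relAges named numeric in [0, 1], keyed by node id.
#' @slot relRates named numeric, keyed by child node id.
#' @slot depth numeric; the root relative depth in substitutions/site.
#' @exportClass RelativeTimeTree
setClass("RelativeTimeTree",
  representation(tree = "phylo", relAges = "numeric", relRates = "numeric",
                 depth = "numeric"))

setValidity("RelativeTimeTree", function(object) {
  a <- object@relAges
  if (any(a < -1e-12 | a > 1 + 1e-12)) return("relative ages must lie in [0,1]")
  ids <- nodeIds(object@tree)
  ra <- a[ids[rootNode(object@tree)]]
  if (abs(ra - 1) > 1e-12) return("root relative age must be 1")
  tips <- object@tree$tip.label
  if (any(abs(a[tips]) > 1e-12)) return("tip relative ages must be 0")
  TRUE
})

#' DatingResult: calibrated node ages with confidence intervals
#'
#' @slot nodes data.frame: `node_id`, `relative_age`, `TT` (true age when
#'   known, else `NA`), `ET` (estimated age, my), `ci_lo`, `ci_hi`,
#'   `calibrated` (logical).
#' @slot f numeric; absolute-per-relative-unit scaling factor (my).
#' @slot fInterval numeric(2); the feasible factor interval used for CIs.
#' @slot feasible logical; FALSE when the calibration intersection was empty.
#' @slot constraints data.frame of the applied constraints.
#' @exportClass DatingResult
setClass("DatingResult",
  representation(nodes = "data.frame", f = "numeric", fInterval = "numeric",
                 feasible = "logical", constraints = "data.frame"))

setValidity("DatingResult", function(object) {
  nd <- object@nodes
  if (object@f <= 0) return("scaling factor must be positive")
  ok <- is.na(nd$ci_lo) | (nd$ci_lo <= nd$ET + 1e-9 & nd$ET <= nd$ci_hi + 1e-9)
  if (!all(ok)) return("every CI must contain its point estimate")
  TRUE
})
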
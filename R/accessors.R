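#' @rdname accessors
#' @export
setMethod("ages", "TimeTree", function(x) x@ages)

#' @rdname accessors
#' @export
setMethod("taxa", "TimeTree", function(x)
  setdiff(x@tree$tip.label, x@outgroup))

#' @rdname accessors
#' @export
setMethod("outgroup", "TimeTree", function(x) x@outgroup)

#' @rdname accessors
#' @export
setMethod("asPhylo", "TimeTree", function(x) x@tree)

#' @rdname accessors
#' @export
setMethod("asPhylo", "BranchLengthTree", function(x) x@tree)

#' @rdname accessors
#' @export
setMethod("asPhylo", "RelativeTimeTree", function(x) x@tree)

#' @rdname accessors
#' @export
setMethod("relAges", "RelativeTimeTree", function(x) x@relAges)

#' @rdname accessors
#' @export
setMethod("branchRates", "RatedTree", function(x) x@rates)

#' @rdname accessors
#' @export
setMethod("branchRates", "RelativeTimeTree", function(x) x@relRates)

#' @rdname accessors
#' @export
setMethod("branchLengths", "RatedTree", function(x) x@lengths)

#' @rdname accessors
#' @export
setMethod("branchLengths", "BranchLengthTree", function(x) {
  ids <- nodeIds(x@tree)
  setNames(x@tree$edge.length, ids[x@tree$edge[, 2L]])
})

#' @rdname accessors
#' @export
setMethod("nodeTable", "DatingResult", function(x) x@nodes)

#' @rdname accessors
#' @export
setMethod("geneTable", "MultiGeneAlignment", function(x) x@genes)

#' Internal node ids of the ingroup of a TimeTree
#'
#' Returns the ids of the internal nodes that carry a true age of interest
#' for the accuracy measures: every internal node of the ingroup subtree
#' (outgroup and root-of-outgroup excluded).
#'
#' @param x A [TimeTree].
#' @return Character vector of node ids.
#' @export
ingroupNodes <- function(x) {
  stopifnot2(methods::is(x, "TimeTree"), "x must be a TimeTree")
  phy <- x@tree
  ids <- nodeIds(phy)
  if (length(x@outgroup) == 1L && x@outgroup %in% phy$tip.label) {
    ing <- ape::getMRCA(phy, setdiff(phy$tip.label, x@outgroup))
    desc <- phangorn::Descendants(phy, ing, type = "all")
    keep <- c(ing, desc[desc > ape::Ntip(phy)])
  } else {
    keep <- ape::Ntip(phy) + seq_len(phy$Nnode)
  }
  ids[sort(keep)]
}

#' @describeIn ingroupNodes Number of tips, counting the outgroup.
#' @export
nTaxa <- function(x) ape::Ntip(x@tree)
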
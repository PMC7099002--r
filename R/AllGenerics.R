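#' Accessor generics
#'
#' Small accessor verbs for the S4 containers: `ages()` returns true node
#' ages, `taxa()` the ingroup taxon labels, `outgroup()` the outgroup tip,
#' `asPhylo()` the underlying ape tree, `relAges()` relative node ages,
#' `branchRates()` per-branch rates, `nodeTable()` the per-node result
#' table of a [DatingResult].
#'
#' @param x An object of one of the secalib S4 classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("ages", function(x) standardGeneric("ages"))

#' @rdname accessors
#' @export
setGeneric("taxa", function(x) standardGeneric("taxa"))

#' @rdname accessors
#' @export
setGeneric("outgroup", function(x) standardGeneric("outgroup"))

#' @rdname accessors
#' @export
setGeneric("asPhylo", function(x) standardGeneric("asPhylo"))

#' @rdname accessors
#' @export
setGeneric("relAges", function(x) standardGeneric("relAges"))

#' @rdname accessors
#' @export
setGeneric("branchRates", function(x) standardGeneric("branchRates"))

#' @rdname accessors
#' @export
setGeneric("branchLengths", function(x) standardGeneric("branchLengths"))

#' @rdname accessors
#' @export
setGeneric("nodeTable", function(x) standardGeneric("nodeTable"))

#' @rdname accessors
#' @export
setGeneric("geneTable", function(x) standardGeneric("geneTable"))
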
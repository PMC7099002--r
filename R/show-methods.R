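#' @describeIn TimeTree-class Compact display.
#' @export
setMethod("show", "TimeTree", function(object) {
  cat("TimeTree:", length(taxa(object)), "ingroup taxa",
      if (length(object@outgroup)) sprintf("+ outgroup '%s'", object@outgroup),
      "\n  root age:", format(max(object@ages), digits = 6), "my\n")
})

#' @describeIn NestedSplit-class Compact display.
#' @export
setMethod("show", "NestedSplit", function(object) {
  cat("NestedSplit\n")
  cat("  master :", length(taxa(object@master)), "ingroup taxa\n")
  cat("  tree A :", length(taxa(object@treeA)), "ingroup taxa (",
      ape::Ntip(object@treeA@tree), "with outgroup )\n")
  cat("  tree B :", length(taxa(object@treeB)), "ingroup taxa (",
      ape::Ntip(object@treeB@tree), "with outgroup )\n")
  cat("  overlap node:", object@overlapNode, "at",
      format(object@master@ages[object@overlapNode], digits = 6), "my\n")
  cat("  shared lineages:", paste(object@sharedLineages, collapse = ", "), "\n")
})

#' @describeIn RatedTree-class Compact display.
#' @export
setMethod("show", "RatedTree", function(object) {
  r <- object@rates
  cat("RatedTree:", length(r), "branches; rate range",
      format(min(r), digits = 4), "-", format(max(r), digits = 4),
      "subs/site/my\n")
})

#' @describeIn MultiGeneAlignment-class Compact display.
#' @export
setMethod("show", "MultiGeneAlignment", function(object) {
  cat("MultiGeneAlignment:", length(object@seqs), "taxa x",
      Biostrings::width(object@seqs)[1L], "sites;",
      nrow(object@genes), "gene(s)\n")
})

#' @describeIn HKYModel-class Compact display.
#' @export
setMethod("show", "HKYModel", function(object) {
  cat("HKYModel: kappa =", format(object@kappa, digits = 4),
      "; bf =", paste(format(object@bf, digits = 3), collapse = " "), "\n")
})

#' @describeIn BranchLengthTree-class Compact display.
#' @export
setMethod("show", "BranchLengthTree", function(object) {
  cat("BranchLengthTree:", ape::Ntip(object@tree), "tips; lnL =",
      format(object@logLik, digits = 10),
      "; kappa =", format(object@kappa, digits = 4), "\n")
})

#' @describeIn RelativeTimeTree-class Compact display.
#' @export
setMethod("show", "RelativeTimeTree", function(object) {
  cat("RelativeTimeTree:", ape::Ntip(object@tree), "tips;",
      sum(!is.na(object@relRates)), "branch rates defined\n")
})

#' @describeIn DatingResult-class Compact display.
#' @export
setMethod("show", "DatingResult", function(object) {
  cat("DatingResult:", nrow(object@nodes), "nodes; f =",
      format(object@f, digits = 6),
      if (!object@feasible) "(calibration intersection empty)", "\n")
})
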
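## Readers and writers: Newick (time and substitutions dialects), FASTA,
## calibration / profile / result CSVs, and the run manifest.

#' Write and read timetrees as Newick
#'
#' The time dialect encodes node ages through branch lengths in my and
#' carries node ids as internal node labels.  `readTimeTree()` validates
#' that the tree is rooted, binary and ultrametric in time (all tips at
#' equal depth) and reconstructs node ages from root-to-tip sums.
#'
#' @param x A [TimeTree].
#' @param file Path to write to / read from.
#' @param text Newick string (alternative to `file`).
#' @param outgroup Outgroup tip label, if any.
#' @param tol Relative tolerance on tip-depth equality.
#' @return `readTimeTree()` returns a [TimeTree]; `writeTimeTree()` its
#'   file path, invisibly.
#' @export
writeTimeTree <- function(x, file) {
  ape::write.tree(x@tree, file = file)
  invisible(file)
}

#' @rdname writeTimeTree
#' @export
readTimeTree <- function(file = NULL, text = NULL, outgroup = character(),
                         tol = 1e-6) {
  phy <- if (is.null(text)) ape::read.tree(file) else ape::read.tree(text = text)
  stopifnot2(inherits(phy, "phylo"), "malformed Newick input")
  stopifnot2(ape::is.rooted(phy), "tree must be rooted")
  stopifnot2(ape::is.binary(phy), "polytomies are not supported")
  depth <- ape::node.depth.edgelength(phy)
  tipd <- depth[seq_len(ape::Ntip(phy))]
  stopifnot2(diff(range(tipd)) <= tol * max(tipd),
             "tips are at unequal depths: not a timetree")
  newTimeTree(phy, outgroup = outgroup)
}

#' Read a Newick tree in the substitutions dialect
#'
#' Branch lengths are taken as substitutions/site; no ultrametricity is
#' required.
#'
#' @inheritParams readTimeTree
#' @return An ape `phylo` with node labels assigned where missing.
#' @export
readNewick <- function(file = NULL, text = NULL) {
  phy <- if (is.null(text)) ape::read.tree(file) else ape::read.tree(text = text)
  stopifnot2(inherits(phy, "phylo"), "malformed Newick input")
  if (is.null(phy$node.label))
    phy$node.label <- sprintf("N%03d", seq_len(phy$Nnode))
  phy
}

#' Write / read an alignment as FASTA
#'
#' @param aln A [MultiGeneAlignment-class].
#' @param file Path; `writeAlignment` also writes a `<file>.genes.csv`
#'   sidecar with the gene offsets when the alignment holds several genes.
#' @return `readAlignment()` returns a [MultiGeneAlignment-class].
#' @export
writeAlignment <- function(aln, file) {
  Biostrings::writeXStringSet(alnSeqs(aln), filepath = file)
  if (nrow(aln@genes) > 1L)
    write.csv(aln@genes, paste0(file, ".genes.csv"), row.names = FALSE)
  invisible(file)
}

#' @rdname writeAlignment
#' @export
readAlignment <- function(file) {
  seqs <- Biostrings::readDNAStringSet(file)
  sidecar <- paste0(file, ".genes.csv")
  genes <- if (file.exists(sidecar)) {
    read.csv(sidecar, stringsAsFactors = FALSE)
  } else {
    data.frame(gene_id = "gene", start = 1L,
               end = Biostrings::width(seqs)[1L])
  }
  methods::new("MultiGeneAlignment", seqs = seqs, genes = genes)
}

#' Calibration constraint tables
#'
#' Constraints are kept as a plain data.frame with columns `node_id`,
#' `min`, `max` (ages in my), mirroring the on-disk CSV format.
#'
#' @param node_id Character vector of node ids.
#' @param min,max Numeric age bounds, `0 < min <= max`.
#' @return data.frame of constraints.
#' @export
calibrationConstraints <- function(node_id, min, max) {
  stopifnot2(all(min > 0) && all(min <= max),
             "constraints need 0 < min <= max")
  data.frame(node_id = as.character(node_id), min = as.numeric(min),
             max = as.numeric(max))
}

#' @rdname calibrationConstraints
#' @param file CSV path.
#' @export
readCalibrations <- function(file) {
  x <- read.csv(file, stringsAsFactors = FALSE)
  calibrationConstraints(x$node_id, x$min, x$max)
}

#' @rdname calibrationConstraints
#' @param constraints data.frame of constraints.
#' @export
writeCalibrations <- function(constraints, file) {
  write.csv(constraints, file, row.names = FALSE)
  invisible(file)
}

#' Write a dating result as a per-node CSV
#'
#' Columns: node_id, ET, ci_lo, ci_hi, relative_age, calibrated, feasible.
#'
#' @param x A [DatingResult-class].
#' @param file CSV path.
#' @export
writeDatingResult <- function(x, file) {
  nd <- x@nodes
  nd$feasible <- x@feasible
  write.csv(nd, file, row.names = FALSE)
  invisible(file)
}

#' Write a run manifest
#'
#' Records the configuration snapshot, master seed, artifact paths and a
#' timestamp as structured JSON.
#'
#' @param config Study configuration list.
#' @param paths Character vector of artifact paths.
#' @param file Output path.
#' @export
writeManifest <- function(config, paths, file) {
  manifest <- list(
    package = "secalib",
    version = as.character(utils::packageVersion("secalib")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    artifacts = as.list(paths))
  jsonlite::write_json(manifest, file, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(file)
}
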
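## Gene-wise HKY sequence simulation along rated trees, and concatenation.

NUC <- c("A", "C", "G", "T")

#' Simulate one gene alignment under HKY along a rated tree
#'
#' The root sequence is drawn site-wise from the stationary frequencies of
#' the gene's HKY model; each child sequence is obtained by applying the
#' exact transition-probability matrix for its branch length independently
#' at every site (uniform rates among sites, no indels).  Deterministic
#' given `seed`.
#'
#' @param rated A [RatedTree] carrying the gene's branch lengths.
#' @param profile The gene's profile row (gives length, GC, kappa, seed).
#' @param seed Integer seed (defaults to the profile's own seed).
#' @return A [MultiGeneAlignment-class] with one gene and one sequence per
#'   tip of the tree (outgroup included).
#' @export
simulateGeneAlignment <- function(rated, profile, seed = profile$seed) {
  phy <- rated@timetree@tree
  ids <- nodeIds(phy)
  lens <- rated@lengths[ids[phy$edge[, 2L]]]
  stopifnot2(all(is.finite(lens)) && all(lens >= 0),
             "branch lengths must be finite and >= 0")
  L <- as.integer(profile$length)
  model <- profileModel(profile)
  ntip <- ape::Ntip(phy)
  nnode <- ntip + phy$Nnode
  states <- matrix(0L, nrow = nnode, ncol = L)
  ord <- rev(ape::postorder(phy))  # preorder: parents before children
  withSeed(deriveSeed(seed, "seq"), {
    root <- rootNode(phy)
    states[root, ] <- sample.int(4L, L, replace = TRUE, prob = model@bf)
    for (i in ord) {
      p <- phy$edge[i, 1L]; ch <- phy$edge[i, 2L]
      P <- hkyTransitionProbs(model, lens[i])
      out <- integer(L)
      for (s in 1:4) {
        idx <- which(states[p, ] == s)
        if (length(idx))
          out[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = P[s, ])
      }
      states[ch, ] <- out
    }
  })
  seqs <- apply(states[seq_len(ntip), , drop = FALSE], 1L, function(z)
    paste(NUC[z], collapse = ""))
  dss <- Biostrings::DNAStringSet(setNames(seqs, phy$tip.label))
  methods::new("MultiGeneAlignment", seqs = dss,
               genes = data.frame(gene_id = as.character(profile$gene_id),
                                  start = 1L, end = L))
}

#' Concatenate gene alignments into supermatrices
#'
#' Builds `nSets` concatenations; each samples genes uniformly at random
#' without replacement (within a set; genes may recur across sets) until
#' the total length reaches `minLen` sites.  Gene membership and offsets
#' are recorded in the result's gene table.  Deterministic given `seed`.
#'
#' @param genes List of single-gene [MultiGeneAlignment-class] objects
#'   sharing one taxon set.
#' @param nSets Number of concatenations.
#' @param minLen Minimum concatenation length in sites.
#' @param seed Integer seed.
#' @return List of [MultiGeneAlignment-class] objects.
#' @export
buildConcatenations <- function(genes, nSets = 10, minLen = 30000, seed = 1L) {
  stopifnot2(length(genes) >= 1, "need at least one gene")
  tax <- names(alnSeqs(genes[[1L]]))
  for (g in genes)
    stopifnot2(setequal(names(alnSeqs(g)), tax), "genes must share one taxon set")
  lens <- vapply(genes, function(g) Biostrings::width(alnSeqs(g))[1L], numeric(1L))
  stopifnot2(sum(lens) >= minLen,
             "total available gene length is below minLen")
  lapply(seq_len(nSets), function(s) {
    withSeed(deriveSeed(seed, "concat", s), {
      ord <- sample.int(length(genes))
      take <- ord[seq_len(which(cumsum(lens[ord]) >= minLen)[1L])]
      concatenateAlignments(genes[take])
    })
  })
}

#' Concatenate a list of alignments end-to-end
#'
#' @param alns List of [MultiGeneAlignment-class] objects with identical
#'   taxon sets.
#' @return One [MultiGeneAlignment-class]; the gene table records offsets.
#' @export
concatenateAlignments <- function(alns) {
  tax <- names(alnSeqs(alns[[1L]]))
  parts <- lapply(alns, function(a) as.character(alnSeqs(a)[tax]))
  seqs <- Biostrings::DNAStringSet(setNames(
    do.call(paste0, parts), tax))
  w <- vapply(alns, function(a) Biostrings::width(alnSeqs(a))[1L], numeric(1L))
  ends <- cumsum(w)
  genes <- data.frame(
    gene_id = vapply(alns, function(a) a@genes$gene_id[1L], character(1L)),
    start = c(1L, head(ends, -1L) + 1L),
    end = ends)
  methods::new("MultiGeneAlignment", seqs = seqs, genes = genes)
}

#' Restrict an alignment to a subset of taxa
#'
#' @param aln A [MultiGeneAlignment-class].
#' @param tax Taxon labels to keep.
#' @return A [MultiGeneAlignment-class].
#' @export
subsetAlignment <- function(aln, tax) {
  stopifnot2(all(tax %in% names(alnSeqs(aln))), "unknown taxa requested")
  methods::new("MultiGeneAlignment", seqs = alnSeqs(aln)[tax], genes = aln@genes)
}

## Convert to phangorn's phyDat for likelihood work.
asPhyDat <- function(aln) {
  m <- as.matrix(alnSeqs(aln))
  phangorn::phyDat(m, type = "DNA")
}
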
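## Internal helpers shared across modules.

#' Derive a reproducible child seed from a master seed and context tags
#'
#' Every stochastic step of the pipeline draws its own seed from the master
#' seed plus a character context (e.g. `c("gene", "g007")`), so that runs are
#' reproducible and individual steps are independent of execution order.
#' The result is always a positive integer below 2^31 - 1.
#'
#' @param seed Integer master seed.
#' @param ... Character or numeric tags identifying the consumer.
#' @return A single integer seed.
#' @export
deriveSeed <- function(seed, ...) {
  tags <- paste(c(seed, ...), collapse = "/")
  m <- 2147483647
  h <- 17
  for (k in utf8ToInt(tags)) h <- (h * 31 + k) %% m
  as.integer(if (h == 0L) 1L else h)
}

## Run code with a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

## Label of every node of a phylo, indexed by node number (tips then internals).
nodeIds <- function(phy) {
  lab <- phy$node.label
  if (is.null(lab)) lab <- paste0("N", seq_len(phy$Nnode))
  c(phy$tip.label, lab)
}

## Named vector of node ages (time before present) for an ultrametric phylo
## whose edge lengths are time durations.
nodeAges <- function(phy, tol = 1e-8) {
  depth <- ape::node.depth.edgelength(phy)
  ages <- max(depth) - depth
  ages[ages < tol & ages > -tol] <- 0
  names(ages) <- nodeIds(phy)
  ages
}

## children of each node as a list indexed by node number
childList <- function(phy) {
  n <- ape::Ntip(phy) + phy$Nnode
  ch <- vector("list", n)
  for (i in seq_len(nrow(phy$edge)))
    ch[[phy$edge[i, 1L]]] <- c(ch[[phy$edge[i, 1L]]], phy$edge[i, 2L])
  ch
}

rootNode <- function(phy) ape::Ntip(phy) + 1L

## Slot reader for MultiGeneAlignment@seqs: XStringSet objects restored
## from serialized files realize their names lazily, so touch them once
## before use.
alnSeqs <- function(aln) {
  invisible(names(aln@seqs))
  aln@seqs
}

stopifnot2 <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
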
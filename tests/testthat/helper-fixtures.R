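## Shared fixtures, all built in code at test time.

## One-row gene profile with explicit parameters.
quickProfile <- function(length, gc = 0.5, kappa = 4, base_rate = 0.002,
                         seed = 101L, gene_id = "g001") {
  data.frame(gene_id = gene_id, length = as.integer(length), gc = gc,
             kappa = kappa, base_rate = base_rate, seed = as.integer(seed))
}

## Simulate one alignment on a timetree under a given rate model.
simulateOn <- function(tt, length, gc = 0.45, kappa = 4.2,
                       base_rate = 0.002, nu = 0, seed = 101L) {
  pr <- quickProfile(length, gc = gc, kappa = kappa, base_rate = base_rate,
                     seed = seed)
  rated <- evolveRates(tt, pr, rateModelParams(nu = nu))
  list(profile = pr, rated = rated,
       aln = simulateGeneAlignment(rated, pr))
}

## A hand-built RelativeTimeTree over ((A,B)X,(C,D)Y)R with chosen
## relative ages; branch lengths are set consistent with the ages.
madeRelTree <- function(aX = 0.5, aY = 0.3) {
  phy <- ape::read.tree(text = "((A:1,B:1)X:1,(C:1,D:1)Y:1)R;")
  ids <- secalib:::nodeIds(phy)
  a <- setNames(c(0, 0, 0, 0, 1, aX, aY), ids)
  methods::new("RelativeTimeTree", tree = phy, relAges = a,
               relRates = setNames(rep(1, 6), ids[phy$edge[, 2L]]),
               depth = 1)
}

## BranchLengthTree wrapping a phylo with given per-branch SEs.
madeBlt <- function(text, se = 0, outgroup = character()) {
  phy <- ape::read.tree(text = text)
  if (is.null(phy$node.label))
    phy$node.label <- paste0("N", seq_len(phy$Nnode))
  ids <- secalib:::nodeIds(phy)
  kid <- ids[phy$edge[, 2L]]
  methods::new("BranchLengthTree", tree = phy,
               se = setNames(rep_len(se, nrow(phy$edge)), kid),
               kappa = 4, bf = rep(0.25, 4), logLik = -1,
               outgroup = outgroup)
}

## Tiny study configuration for orchestration tests.
tinyConfig <- function(...) {
  studyConfig(nTaxa = 16, rootAge = 200, targetFracB = 6 / 16,
              nGenes = 8, lengthMean = 300, nConcat = 2, minLen = 800,
              B = 60, scenarios = c("10B", "20H"), seed = 7L, ...)
}

## random base-frequency vector bounded away from 0
randomFreqs <- function() {
  x <- runif(4, 0.1, 1)
  x / sum(x)
}
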
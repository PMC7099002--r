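## HKY85 substitution model: constructor and exact transition probabilities.

#' Construct an HKY85 model
#'
#' @param bf Base frequencies in A, C, G, T order (positive, sum 1).
#' @param kappa Transition/transversion rate ratio (> 0).
#' @return An [HKYModel-class] object.
#' @export
hkyModel <- function(bf, kappa) {
  bf <- setNames(as.numeric(bf), c("A", "C", "G", "T"))
  methods::new("HKYModel", bf = bf / sum(bf), kappa = as.numeric(kappa))
}

#' HKY model implied by a gene profile
#'
#' GC content is split equally between G and C (and AT equally between A
#' and T).
#'
#' @param profile A row of [sampleGeneProfiles()] output.
#' @return An [HKYModel-class] object.
#' @export
profileModel <- function(profile) {
  gc <- profile$gc
  hkyModel(c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2), profile$kappa)
}

#' Exact HKY transition probability matrix
#'
#' Closed-form spectral solution of the HKY85 chain, with the rate matrix
#' normalized so that branch lengths are expected substitutions per site
#' at stationarity.  Rows index the parent state, columns the child state,
#' in A, C, G, T order.
#'
#' @param model An [HKYModel-class] object.
#' @param t Branch length, substitutions/site (>= 0).
#' @return 4 x 4 stochastic matrix.
#' @export
hkyTransitionProbs <- function(model, t) {
  stopifnot2(t >= 0, "branch length must be >= 0")
  p <- model@bf
  k <- model@kappa
  piA <- p[["A"]]; piC <- p[["C"]]; piG <- p[["G"]]; piT <- p[["T"]]
  piR <- piA + piG
  piY <- piC + piT
  ## normalizer: mean instantaneous rate = 1
  beta <- 1 / (2 * (piR * piY + k * (piA * piG + piC * piT)))
  e2 <- exp(-beta * t)
  eR <- exp(-beta * t * (1 + piR * (k - 1)))
  eY <- exp(-beta * t * (1 + piY * (k - 1)))
  P <- matrix(0, 4, 4, dimnames = list(names(p), names(p)))
  grp <- c(A = "R", C = "Y", G = "R", T = "Y")
  for (i in names(p)) for (j in names(p)) {
    pij <- p[[j]]
    if (grp[[i]] != grp[[j]]) {            # transversion
      P[i, j] <- pij * (1 - e2)
    } else {
      piS <- if (grp[[j]] == "R") piR else piY
      eS <- if (grp[[j]] == "R") eR else eY
      P[i, j] <- if (i == j) {
        pij + pij * (1 / piS - 1) * e2 + ((piS - pij) / piS) * eS
      } else {
        pij + pij * (1 / piS - 1) * e2 - (pij / piS) * eS
      }
    }
  }
  P
}
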
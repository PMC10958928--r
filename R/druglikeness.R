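# Asymmetric double sigmoid (ADS) desirability parameters for the eight QED
# descriptors, as published by Bickerton et al. (columns a, b, c, d, e, f
# and the normalizing maximum). Desirabilities are the ADS value divided by
# its maximum, so each d_i lies in (0, 1].
.qed_ads <- local({
  p <- rbind(
    MW     = c(2.817065973, 392.5754953, 290.7489764, 2.419764353,
               49.22325677, 65.37051707, 104.9805561),
    ALOGP  = c(3.172690585, 137.8624751, 2.534937431, 4.581497897,
               0.822739154, 0.576295591, 131.3186604),
    HBA    = c(2.948620388, 160.4605972, 3.615294657, 4.435986202,
               0.290141953, 1.300669958, 148.7763046),
    HBD    = c(1.618662227, 1010.051101, 0.985094388, 0.000000001,
               0.713820843, 0.920922555, 258.1632616),
    PSA    = c(1.876861559, 125.2232657, 62.90773554, 87.83366614,
               12.01999824, 28.51324732, 104.5686167),
    ROTB   = c(0.010000000, 272.4121427, 2.558379970, 1.565547684,
               1.271567166, 2.758063707, 105.4420403),
    AROM   = c(3.217788970, 957.7374108, 2.274627939, 0.000000001,
               1.317690384, 0.375760881, 312.3372610),
    ALERTS = c(0.010000000, 1199.094025, -0.09002883, 0.000000001,
               0.185904477, 0.875193782, 417.7253140))
  colnames(p) <- c("a", "b", "c", "d", "e", "f", "dmax")
  p
})

# Mean-weight scheme (QEDw,mo): weights maximizing information content
# averaged over Bickerton's reference set.
.qed_weights_mean <- c(MW = 0.66, ALOGP = 0.46, HBA = 0.05, HBD = 0.61,
                       PSA = 0.06, ROTB = 0.65, AROM = 0.48, ALERTS = 0.95)

ads_desirability <- function(x, p) {
  e1 <- 1 + exp(-(x - p["c"] + p["d"] / 2) / p["e"])
  e2 <- 1 + exp(-(x - p["c"] - p["d"] / 2) / p["f"])
  (p["a"] + p["b"] / e1 * (1 - 1 / e2)) / p["dmax"]
}

#' Default QED descriptor weights
#'
#' The mean-weight scheme over the eight descriptors (molecular weight,
#' ALOGP, H-bond acceptors/donors, polar surface area, rotatable bonds,
#' aromatic rings, structural alerts).
#'
#' @return named numeric vector of length 8.
#' @export
qed_weights <- function() .qed_weights_mean

#' Quantitative estimate of drug-likeness (QED)
#'
#' Computes the QED of one or more compounds as the weighted geometric mean
#' of eight descriptor desirability functions,
#' `QED = exp( sum(w_i log d_i) / sum(w_i) )`, where each `d_i` is an
#' asymmetric double sigmoid with published parameters. Desirabilities are
#' floored at `1e-6` before taking logs so extreme descriptors cannot
#' produce `-Inf`.
#'
#' All arguments are vectorized and recycled to a common length.
#'
#' @param mw molecular weight (Da), positive.
#' @param alogp octanol-water logP.
#' @param hba,hbd hydrogen-bond acceptor and donor counts (>= 0).
#' @param psa polar surface area (A^2, >= 0).
#' @param rotb rotatable-bond count (>= 0).
#' @param arom aromatic-ring count (>= 0).
#' @param alerts structural-alert count (>= 0).
#' @param weights optional named 8-vector of descriptor weights; defaults
#'   to [qed_weights()].
#' @return numeric vector of QED values in `[0, 1]`.
#' @examples
#' qed(300, 2.5, 3, 1, 60, 3, 2, 0)
#' @export
qed <- function(mw, alogp, hba, hbd, psa, rotb, arom, alerts,
                weights = NULL) {
  x <- cbind(MW = mw, ALOGP = alogp, HBA = hba, HBD = hbd, PSA = psa,
             ROTB = rotb, AROM = arom, ALERTS = alerts)
  if (anyNA(x)) nf_stop("QED descriptors must not contain missing values")
  if (any(x[, "MW"] <= 0)) nf_stop("MW must be positive")
  if (any(x[, c("HBA", "HBD", "PSA", "ROTB", "AROM", "ALERTS")] < 0))
    nf_stop("descriptor counts and PSA must be non-negative")
  w <- weights %||% .qed_weights_mean
  if (length(w) != 8L) nf_stop("'weights' must have length 8")
  if (is.null(names(w))) names(w) <- rownames(.qed_ads)
  w <- w[rownames(.qed_ads)]
  if (anyNA(w) || any(w < 0) || sum(w) == 0)
    nf_stop("'weights' must be non-negative, named after the 8 descriptors")
  d <- vapply(rownames(.qed_ads),
              function(nm) pmax(ads_desirability(x[, nm], .qed_ads[nm, ]), 1e-6),
              numeric(nrow(x)))
  d <- matrix(d, nrow = nrow(x))
  unname(exp(as.vector(log(d) %*% w) / sum(w)))
}

#' Lipinski rule-of-five violation count
#'
#' Counts how many of the four oral drug-likeness criteria a compound
#' violates: more than 5 H-bond donors, more than 10 H-bond acceptors,
#' molecular weight above 500 Da, logP above 5. Boundary values ("no more
#' than") pass. Vectorized.
#'
#' @param mw molecular weight (Da).
#' @param alogp octanol-water logP.
#' @param hbd,hba hydrogen-bond donor and acceptor counts.
#' @return integer vector in 0..4.
#' @export
lipinski_violations <- function(mw, alogp, hbd, hba) {
  as.integer((hbd > 5) + (hba > 10) + (mw > 500) + (alogp > 5))
}

#' Veber rule violation count
#'
#' Two criteria for oral bioavailability: no more than 10 rotatable bonds,
#' and polar surface area no more than 140 A^2 *or* no more than 12 H-bond
#' donors plus acceptors (the second criterion fails only when both
#' alternatives fail). Vectorized.
#'
#' @param rotb rotatable-bond count.
#' @param psa polar surface area (A^2).
#' @param hbd,hba hydrogen-bond donor and acceptor counts.
#' @return integer vector in 0..2.
#' @export
veber_violations <- function(rotb, psa, hbd, hba) {
  as.integer((rotb > 10) + ((psa > 140) & (hbd + hba > 12)))
}

#' Drug-likeness screen of a compound table
#'
#' Scores every compound by QED and the Lipinski and Veber violation
#' counts, and flags the ones passing all three thresholds of the
#' configuration (`qed >= qed_min`, `lipinski <= lipinski_max_violations`,
#' `veber <= veber_max_violations`). An empty pass-set is a valid outcome.
#'
#' @param compounds compound table from [read_compound_table()].
#' @param config an [nf_config()].
#' @return a `data.frame` with columns `compound_id`, `qed`,
#'   `lipinski_violations`, `veber_violations`, `passed`, sorted by `qed`
#'   descending (ties by `compound_id`).
#' @export
screen_compounds <- function(compounds, config = nf_config()) {
  if (!nrow(compounds)) nf_stop("'compounds' must be non-empty")
  res <- data.frame(
    compound_id = compounds$compound_id,
    qed = qed(compounds$MW, compounds$ALOGP, compounds$HBA, compounds$HBD,
              compounds$PSA, compounds$ROTB, compounds$AROM,
              compounds$ALERTS),
    lipinski_violations = lipinski_violations(compounds$MW, compounds$ALOGP,
                                              compounds$HBD, compounds$HBA),
    veber_violations = veber_violations(compounds$ROTB, compounds$PSA,
                                        compounds$HBD, compounds$HBA),
    stringsAsFactors = FALSE)
  res$passed <- res$qed >= config$qed_min &
    res$lipinski_violations <= config$lipinski_max_violations &
    res$veber_violations <= config$veber_max_violations
  res <- res[order(-res$qed, res$compound_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
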
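# Charge model: every ionizable group contributes a Henderson-Hasselbalch
# occupancy term. Basic groups (H, K, R side chains, N-terminus) carry
# +1/(1 + 10^(pH - pKa)); acidic groups (D, E, C, Y side chains, C-terminus)
# carry -1/(1 + 10^(pKa - pH)). One N- and one C-terminal group per chain.
# Ambiguity residues (X, B, Z, U, O) contribute no charge.

.AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                  "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
.AA_AMBIG <- c("X", "B", "Z", "U", "O")
.AA_VALID <- c(.AA_STANDARD, .AA_AMBIG)

# counts of ionizable residues, in scale$side_chain order
.ionizable_counts <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  vapply(c("D", "E", "C", "Y", "H", "K", "R"),
         function(a) sum(chars == a), integer(1))
}

# Z(pH) from precomputed counts; vectorized over pH
.charge_from_counts <- function(counts, pH, scale) {
  pka_b <- c(scale$n_term, scale$side_chain[c("H", "K", "R")])
  n_b <- c(1, counts[c("H", "K", "R")])
  pka_a <- c(scale$c_term, scale$side_chain[c("D", "E", "C", "Y")])
  n_a <- c(1, counts[c("D", "E", "C", "Y")])
  z <- numeric(length(pH))
  for (i in seq_along(pka_b)) z <- z + n_b[[i]] / (1 + 10^(pH - pka_b[[i]]))
  for (i in seq_along(pka_a)) z <- z - n_a[[i]] / (1 + 10^(pka_a[[i]] - pH))
  unname(z)
}

#' Net charge of a polypeptide as a function of pH
#'
#' Sums Henderson-Hasselbalch occupancies over all ionizable groups: the
#' side chains of D, E, C, Y (acidic) and H, K, R (basic) plus one
#' N-terminal amino and one C-terminal carboxyl group. The result is
#' strictly decreasing in pH. Ambiguity residues (X, B, Z, U, O) are
#' allowed in the sequence but carry no charge.
#'
#' @param seq Amino-acid sequence (single string; validated and uppercased).
#' @param pH Numeric vector of pH values in \[0, 14\].
#' @param scale A [pka_scale()] object or scale name.
#' @return Numeric vector of net charges (elementary-charge units), one per
#'   pH value.
#' @examples
#' net_charge("ACDEFGHIKLMNPQRSTVWY", 7.0)
#' net_charge("G", c(0, 14))  # termini only: near +1 and -1
#' @export
net_charge <- function(seq, pH, scale = pka_scale("EMBOSS")) {
  scale <- pka_scale(scale)
  seq <- .validate_seq(seq)
  stopifnot(is.numeric(pH), all(pH >= 0 & pH <= 14))
  .charge_from_counts(.ionizable_counts(seq), pH, scale)
}

#' Isoelectric point of a polypeptide
#'
#' Finds the unique pH in \[0, 14\] at which the net charge crosses zero,
#' by bisection (the charge function is strictly monotone decreasing, so
#' the root is unique). The bracket is narrowed to width `tol` or a
#' 200-iteration cap, whichever comes first.
#'
#' @inheritParams net_charge
#' @param tol Bracket width at termination, pH units (default 1e-4).
#' @param id Optional protein identifier carried into the result.
#' @param threshold Acidity classification threshold, pH units.
#' @return A one-row data.frame (`protein_id`, `pi`, `scale_name`,
#'   `acidity_class`).
#' @examples
#' isoelectric_point("KKKKK")$pi > 7
#' isoelectric_point("DDDDD")$pi < 7
#' @export
isoelectric_point <- function(seq, scale = pka_scale("EMBOSS"), tol = 1e-4,
                              id = NA_character_, threshold = 7.0) {
  scale <- pka_scale(scale)
  stopifnot(tol > 0)
  seq <- .validate_seq(seq)
  pi <- .pi_bisect(.ionizable_counts(seq), scale, tol)
  data.frame(protein_id = id, pi = pi, scale_name = scale$name,
             acidity_class = classify_acidity(pi, threshold),
             stringsAsFactors = FALSE)
}

.pi_bisect <- function(counts, scale, tol = 1e-4) {
  lo <- 0; hi <- 14
  z_lo <- .charge_from_counts(counts, lo, scale)
  z_hi <- .charge_from_counts(counts, hi, scale)
  if (z_lo <= 0 || z_hi >= 0) {
    stop("net charge does not change sign on [0, 14] under this scale")
  }
  for (it in seq_len(200)) {
    if (hi - lo <= tol) break
    mid <- (lo + hi) / 2
    if (.charge_from_counts(counts, mid, scale) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Isoelectric points for every protein of a proteome
#'
#' @param proteome A [proteome()] object.
#' @inheritParams isoelectric_point
#' @return A data.frame with one row per protein: `protein_id`, `pi`,
#'   `scale_name`, `acidity_class`.
#' @export
proteome_pis <- function(proteome, scale = pka_scale("EMBOSS"), tol = 1e-4,
                         threshold = 7.0) {
  stopifnot(inherits(proteome, "proteome"))
  scale <- pka_scale(scale)
  pis <- vapply(proteome$seq,
                function(s) .pi_bisect(.ionizable_counts(s), scale, tol),
                numeric(1), USE.NAMES = FALSE)
  data.frame(protein_id = proteome$id, pi = pis, scale_name = scale$name,
             acidity_class = classify_acidity(pis, threshold),
             stringsAsFactors = FALSE)
}

#' Classify a pI value as acidic, basic or neutral
#'
#' Values below the threshold are "acidic", above it "basic"; a pI equal to
#' the threshold (within `tol`) is "neutral" and is excluded from both the
#' pI < 7 and pI > 7 counts downstream, so no protein is counted twice.
#'
#' @param pi Numeric vector of pI values in \[0, 14\].
#' @param threshold Classification threshold, pH units (default 7).
#' @param tol Half-width of the neutral band (default 1e-9).
#' @return Character vector over \{"acidic", "basic", "neutral"\}.
#' @examples
#' classify_acidity(c(6.2, 7.0, 9.3))
#' @export
classify_acidity <- function(pi, threshold = 7.0, tol = 1e-9) {
  stopifnot(is.numeric(pi), all(pi >= 0 & pi <= 14))
  out <- rep("neutral", length(pi))
  out[pi < threshold - tol] <- "acidic"
  out[pi > threshold + tol] <- "basic"
  out
}
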
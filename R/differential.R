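# Differential abundance and the pI-shift contrast between up- and
# down-regulated proteins: the pipeline's core stage.

#' Keep proteins quantifiable in at least one group
#'
#' A protein is quantifiable when it has non-missing intensities in at
#' least `min_reps` replicates of at least one treatment group. Protein
#' order is preserved; the filter is idempotent.
#'
#' @param matrix An [abundance_matrix()].
#' @param min_reps Minimum replicates with a value (default 2);
#'   `min_reps = 0` is the identity filter.
#' @return A filtered [abundance_matrix()].
#' @export
filter_quantifiable <- function(matrix, min_reps = 2) {
  stopifnot(inherits(matrix, "abundance_matrix"), min_reps >= 0)
  if (min_reps > min(table(matrix$design))) {
    stop("min_reps exceeds the smallest group size")
  }
  if (min_reps == 0) return(matrix)
  groups <- split(names(matrix$design), matrix$design)
  keep <- Reduce(`|`, lapply(groups, function(smp) {
    rowSums(!is.na(matrix$values[, smp, drop = FALSE])) >= min_reps
  }))
  abundance_matrix(matrix$values[keep, , drop = FALSE], matrix$design)
}

# MinProb-style left-censored imputation on the log2 scale: missing cells
# draw from N(per-sample observed 1st percentile - shift, sd). shift = 0 is
# the MinProb convention (anchor at the detection floor); shift = 1.8 gives
# a Perseus-style downshifted draw.
.impute_left_censored <- function(log2_mat, shift = 0, sd = 0.3) {
  for (j in seq_len(ncol(log2_mat))) {
    miss <- is.na(log2_mat[, j])
    if (!any(miss)) next
    obs <- log2_mat[!miss, j]
    if (!length(obs)) stop("sample '", colnames(log2_mat)[j],
                           "' has no observed values to anchor imputation")
    mu <- stats::quantile(obs, 0.01, names = FALSE) - shift
    log2_mat[miss, j] <- stats::rnorm(sum(miss), mu, sd)
  }
  log2_mat
}

# Row-wise Welch t-tests between two sample blocks (complete data).
# Degenerate rows (zero pooled variance) get p = 1 when the means agree
# and p = 0 otherwise.
.welch_rows <- function(x1, x2) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  deg <- se2 == 0
  p[deg] <- ifelse(m1[deg] == m2[deg], 1, 0)
  list(diff = m1 - m2, p = p)
}

#' Differential protein abundance between two groups
#'
#' Intensities are log2-transformed, remaining missing values are imputed
#' by seeded left-censored draws — normal around each sample's observed
#' 1st percentile (the MinProb convention for label-free data; set
#' `impute_shift = 1.8` for a Perseus-style downshifted draw), sd 0.3 —
#' and each protein is tested with a two-sample Welch t-test. P-values
#' are Benjamini-Hochberg adjusted across all tested proteins; a protein
#' is "up" when fdr < alpha and log2fc > 0, "down" when fdr < alpha and
#' log2fc < 0, otherwise "ns".
#'
#' Note that proteins whose intensities sit entirely below the detection
#' limit in one group have their apparent fold change compressed toward
#' the imputation anchor; power for such proteins is intrinsically
#' limited whatever the imputation convention (see the package vignette).
#'
#' @param matrix An [abundance_matrix()], already quantifiability-filtered.
#' @param treatment,control Group labels present in the design.
#' @param alpha FDR threshold for direction calls (default 0.05).
#' @param seed Integer seed for the imputation draws.
#' @param log2_transform Set FALSE if intensities are already log2.
#' @param impute_shift,impute_sd Left-censored imputation parameters
#'   (log2 units).
#' @return Data.frame of class `dap_table`: `protein_id`, `log2fc`
#'   (treatment minus control), `p`, `fdr`, `direction`.
#' @export
differential <- function(matrix, treatment, control, alpha = 0.05,
                         seed = 1L, log2_transform = TRUE,
                         impute_shift = 0, impute_sd = 0.3) {
  stopifnot(inherits(matrix, "abundance_matrix"))
  for (g in c(treatment, control)) {
    if (!g %in% matrix$design) stop("group '", g, "' not in design")
  }
  s_t <- names(matrix$design)[matrix$design == treatment]
  s_c <- names(matrix$design)[matrix$design == control]
  if (length(s_t) < 2 || length(s_c) < 2) {
    stop("both groups need at least 2 samples")
  }
  x <- matrix$values[, c(s_t, s_c), drop = FALSE]
  if (log2_transform) x <- log2(x)
  set.seed(seed)
  x <- .impute_left_censored(x, impute_shift, impute_sd)
  w <- .welch_rows(x[, s_t, drop = FALSE], x[, s_c, drop = FALSE])
  fdr <- stats::p.adjust(w$p, method = "BH")
  direction <- rep("ns", nrow(x))
  direction[fdr < alpha & w$diff > 0] <- "up"
  direction[fdr < alpha & w$diff < 0] <- "down"
  out <- data.frame(protein_id = rownames(matrix$values),
                    log2fc = unname(w$diff), p = unname(w$p),
                    fdr = unname(fdr), direction = direction,
                    stringsAsFactors = FALSE)
  class(out) <- c("dap_table", "data.frame")
  out
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact hypergeometric enumeration with the probability-mass rule: the
#' two-sided p-value is the sum of the probabilities of all tables with
#' the observed margins whose probability does not exceed that of the
#' observed table (within a 1e-7 relative tie tolerance, the usual
#' guard against floating-point near-ties).
#'
#' @param a,b,c,d Cell counts, row-wise: `a` `b` / `c` `d`.
#' @return The two-sided p-value.
#' @examples
#' fisher_exact_2x2(3, 1, 1, 3)  # 34/70
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  k <- max(0, c1 - r2):min(r1, c1)
  pk <- stats::dhyper(k, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  min(1, sum(pk[pk <= p_obs * (1 + 1e-7)]))
}

#' Acidity shift between up- and down-regulated proteins
#'
#' The headline contrast: given direction calls and per-protein pI
#' values, cross-classifies direction (up/down) against acidity class
#' (pI below vs above the threshold; exactly-neutral proteins are
#' excluded from the counts), tests the 2x2 association with the exact
#' Fisher test, and tests the difference of median pI between the up and
#' down sets with a label-permutation test: labels are reshuffled
#' preserving set sizes and the permutation p-value is
#' `(1 + #{|delta*| >= |delta|}) / (n_perm + 1)`.
#'
#' @param daps A `dap_table` from [differential()], or any data.frame
#'   with `protein_id` and `direction`.
#' @param pis Per-protein pI: a named numeric vector, or a data.frame
#'   with `protein_id` and `pi` (as from [proteome_pis()]).
#' @param n_perm Number of label permutations (default 10000).
#' @param seed Integer seed for the permutations.
#' @param threshold Acidity threshold, pH units (default 7).
#' @return Object of class `acidity_shift`: counts (`n_up_acidic`,
#'   `n_up_basic`, `n_down_acidic`, `n_down_basic`), `delta_median_pi`
#'   (median pI(up) - median pI(down)), `fisher_p`, `perm_p`, `n_perm`,
#'   `seed`, set sizes and the raw pI vectors.
#' @export
acidity_shift <- function(daps, pis, n_perm = 10000L, seed = 1L,
                          threshold = 7.0) {
  stopifnot(all(c("protein_id", "direction") %in% names(daps)), n_perm >= 1)
  if (is.data.frame(pis)) {
    pis <- stats::setNames(pis$pi, pis$protein_id)
  }
  up_ids <- daps$protein_id[daps$direction == "up"]
  down_ids <- daps$protein_id[daps$direction == "down"]
  if (!length(up_ids) || !length(down_ids)) {
    stop("need at least one protein in each direction")
  }
  missing_pi <- setdiff(c(up_ids, down_ids), names(pis))
  if (length(missing_pi)) {
    stop("no pI for ", length(missing_pi), " protein(s), e.g. '",
         missing_pi[1], "'")
  }
  up_pi <- unname(pis[up_ids]); down_pi <- unname(pis[down_ids])
  up_cls <- classify_acidity(up_pi, threshold)
  down_cls <- classify_acidity(down_pi, threshold)
  counts <- c(n_up_acidic = sum(up_cls == "acidic"),
              n_up_basic = sum(up_cls == "basic"),
              n_down_acidic = sum(down_cls == "acidic"),
              n_down_basic = sum(down_cls == "basic"))
  fisher_p <- fisher_exact_2x2(counts["n_up_acidic"], counts["n_up_basic"],
                               counts["n_down_acidic"],
                               counts["n_down_basic"])
  delta <- stats::median(up_pi) - stats::median(down_pi)
  # sorted pool: perm_p depends only on the two pI multisets, not on
  # protein ordering or labels
  pool <- sort(c(up_pi, down_pi))
  n_up <- length(up_pi)
  set.seed(seed)
  obs <- abs(delta)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample.int(length(pool), n_up)
    d <- stats::median(pool[idx]) - stats::median(pool[-idx])
    if (abs(d) >= obs - 1e-12) hits <- hits + 1L
  }
  structure(list(counts = counts,
                 n_up = n_up, n_down = length(down_pi),
                 delta_median_pi = delta,
                 fisher_p = unname(fisher_p),
                 perm_p = (1 + hits) / (n_perm + 1),
                 n_perm = n_perm, seed = seed, threshold = threshold,
                 up_pi = up_pi, down_pi = down_pi),
            class = "acidity_shift")
}

#' @export
print.acidity_shift <- function(x, ...) {
  cat("Acidity shift, up- vs down-regulated proteins\n")
  cat(sprintf("  up:   n = %d (pI<%g: %d, pI>%g: %d), median pI %.2f\n",
              x$n_up, x$threshold, x$counts["n_up_acidic"], x$threshold,
              x$counts["n_up_basic"], stats::median(x$up_pi)))
  cat(sprintf("  down: n = %d (pI<%g: %d, pI>%g: %d), median pI %.2f\n",
              x$n_down, x$threshold, x$counts["n_down_acidic"], x$threshold,
              x$counts["n_down_basic"], stats::median(x$down_pi)))
  cat(sprintf("  delta median pI (up - down): %+.3f\n", x$delta_median_pi))
  cat(sprintf("  Fisher exact p (2x2 direction x acidity): %.4g\n",
              x$fisher_p))
  cat(sprintf("  permutation p (|delta median|, %d perms): %.4g\n",
              x$n_perm, x$perm_p))
  invisible(x)
}

#' @export
summary.acidity_shift <- function(object, ...) {
  data.frame(n_up = object$n_up, n_down = object$n_down,
             n_up_acidic = unname(object$counts["n_up_acidic"]),
             n_up_basic = unname(object$counts["n_up_basic"]),
             n_down_acidic = unname(object$counts["n_down_acidic"]),
             n_down_basic = unname(object$counts["n_down_basic"]),
             delta_median_pi = object$delta_median_pi,
             fisher_p = object$fisher_p, perm_p = object$perm_p,
             n_perm = object$n_perm, seed = object$seed)
}
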
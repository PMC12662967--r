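# Cross-species comparison of genome-encoded proteome pI distributions:
# acidic/basic fractions, binned density summaries, and two-sample
# distribution-shift tests.

#' Summarize the pI distribution of a proteome
#'
#' Computes a pI per protein, the fractions below/above the acidity
#' threshold, the median pI, and a normalized histogram (densities over
#' \[0, 14\]; sum(density) * binwidth = 1). All statistics are computed on
#' the raw pI values; the binning is for display only.
#'
#' @param proteome A [proteome()] object, or a precomputed pI table from
#'   [proteome_pis()].
#' @param scale pKa scale used when computing pIs.
#' @param binwidth Histogram bin width, pH units (must divide 14).
#' @param threshold Acidity threshold, pH units.
#' @return Object of class `pi_summary`: `label`, `n`, `acidic_fraction`,
#'   `basic_fraction`, `median_pi`, `histogram` (data.frame `mid`,
#'   `density`), `binwidth` and the raw `pis`.
#' @export
summarize_pi <- function(proteome, scale = pka_scale("EMBOSS"),
                         binwidth = 0.2, threshold = 7.0) {
  stopifnot(binwidth > 0)
  if (inherits(proteome, "proteome")) {
    label <- proteome$label
    pis <- proteome_pis(proteome, scale)$pi
  } else {
    stopifnot(is.data.frame(proteome), "pi" %in% names(proteome))
    label <- attr(proteome, "label") %||% "proteome"
    pis <- proteome$pi
  }
  if (!length(pis)) stop("empty proteome")
  breaks <- seq(0, 14, by = binwidth)
  if (abs(breaks[length(breaks)] - 14) > 1e-9) {
    stop("binwidth must divide the [0, 14] pH range evenly")
  }
  h <- graphics::hist(pis, breaks = breaks, plot = FALSE)
  cls <- classify_acidity(pis, threshold)
  structure(list(label = label, n = length(pis),
                 acidic_fraction = mean(cls == "acidic"),
                 basic_fraction = mean(cls == "basic"),
                 median_pi = stats::median(pis),
                 histogram = data.frame(mid = h$mids, density = h$density),
                 binwidth = binwidth, threshold = threshold, pis = pis),
            class = "pi_summary")
}

#' @export
print.pi_summary <- function(x, ...) {
  cat(sprintf("pI distribution '%s': n = %d\n", x$label, x$n))
  cat(sprintf("  acidic (pI<%g): %.1f%%   basic (pI>%g): %.1f%%   median pI %.2f\n",
              x$threshold, 100 * x$acidic_fraction, x$threshold,
              100 * x$basic_fraction, x$median_pi))
  invisible(x)
}

#' @export
plot.pi_summary <- function(x, ...) {
  graphics::plot(x$histogram$mid, x$histogram$density, type = "h",
                 xlab = "isoelectric point (pH)", ylab = "density",
                 main = x$label, ...)
  graphics::abline(v = x$threshold, lty = 2)
  invisible(x)
}

#' Contrast two proteome pI distributions
#'
#' Two-sample Kolmogorov-Smirnov test on the raw pI vectors, plus the
#' difference in basic fraction (a - b) to carry the direction of the
#' shift in the field's acidic/basic framing.
#'
#' @param a,b `pi_summary` objects from [summarize_pi()].
#' @return Object of class `pi_contrast`: `label_a`, `label_b`, `ks_d`,
#'   `ks_p`, `delta_basic_fraction`, `delta_median_pi`.
#' @export
contrast_pi <- function(a, b) {
  stopifnot(inherits(a, "pi_summary"), inherits(b, "pi_summary"))
  kt <- suppressWarnings(stats::ks.test(a$pis, b$pis))
  structure(list(label_a = a$label, label_b = b$label,
                 ks_d = unname(kt$statistic), ks_p = kt$p.value,
                 delta_basic_fraction = a$basic_fraction - b$basic_fraction,
                 delta_median_pi = a$median_pi - b$median_pi),
            class = "pi_contrast")
}

#' @export
print.pi_contrast <- function(x, ...) {
  cat(sprintf("pI distribution contrast: %s vs %s\n", x$label_a, x$label_b))
  cat(sprintf("  KS D = %.3f, p = %.3g\n", x$ks_d, x$ks_p))
  cat(sprintf("  delta basic fraction (a-b): %+.3f; delta median pI: %+.3f\n",
              x$delta_basic_fraction, x$delta_median_pi))
  invisible(x)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
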
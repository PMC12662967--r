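# Correlation of protein-set abundance with seawater carbonate chemistry.

#' Per-sample abundance of a protein set
#'
#' Summarizes the intensities of a set of proteins within each sample,
#' ignoring missing values; a sample with no observed member becomes
#' missing.
#'
#' @param matrix An [abundance_matrix()].
#' @param ids Protein ids (must all be present in the matrix).
#' @param summarizer One of `"mean"`, `"sum"`, `"median"`.
#' @return Named numeric vector, one value per sample.
#' @export
set_abundance <- function(matrix, ids, summarizer = c("mean", "sum",
                                                      "median")) {
  stopifnot(inherits(matrix, "abundance_matrix"))
  summarizer <- match.arg(summarizer)
  if (!length(ids)) stop("empty protein set")
  absent <- setdiff(ids, rownames(matrix$values))
  if (length(absent)) {
    stop(length(absent), " id(s) not in matrix, e.g. '", absent[1], "'")
  }
  sub <- matrix$values[ids, , drop = FALSE]
  f <- switch(summarizer, mean = mean, sum = sum, median = stats::median)
  out <- apply(sub, 2, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else f(v)
  })
  out
}

# chemistry parameter name -> column in a speciated chemistry table
.chem_param_column <- function(parameter, chem) {
  alias <- c(co2 = "co2", hco3 = "hco3", co3 = "co3", ph = "pH",
             alkalinity = "TA", ta = "TA", dic = "dic", buffer = "buffer")
  key <- tolower(parameter)
  col <- if (key %in% names(alias)) alias[[key]] else parameter
  if (!col %in% names(chem)) {
    stop("chemistry parameter '", parameter, "' not found")
  }
  col
}

#' Correlate protein-set abundances with chemistry parameters
#'
#' For every (set, parameter) pair, computes a rank (Spearman, default)
#' or Pearson correlation over pairwise-complete samples and adjusts the
#' p-values Benjamini-Hochberg across the whole grid. A constant vector
#' yields a cell with missing rho and a warning.
#'
#' @param abund_vectors Named list of per-sample abundance vectors (as
#'   from [set_abundance()]), names taken as set labels.
#' @param chem Chemistry table with `sample_id` and the requested
#'   parameter columns (a speciated table from [speciate_table()] covers
#'   all defaults).
#' @param parameters Parameters to test; default CO2, HCO3, CO3, pH and
#'   alkalinity.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return Data.frame of class `correlation_grid`: `set_label`,
#'   `parameter`, `rho`, `p`, `fdr`, `n`.
#' @export
correlate_grid <- function(abund_vectors, chem,
                           parameters = c("CO2", "HCO3", "CO3", "pH",
                                          "alkalinity"),
                           method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(is.list(abund_vectors), length(abund_vectors) >= 1,
            !is.null(names(abund_vectors)), "sample_id" %in% names(chem))
  rows <- list()
  for (lab in names(abund_vectors)) {
    av <- abund_vectors[[lab]]
    for (par in parameters) {
      col <- .chem_param_column(par, chem)
      cv <- stats::setNames(chem[[col]], chem$sample_id)
      common <- intersect(names(av), names(cv))
      x <- av[common]; y <- cv[common]
      ok <- !is.na(x) & !is.na(y)
      x <- x[ok]; y <- y[ok]
      n <- length(x)
      if (n < 3) stop("fewer than 3 complete samples for set '", lab,
                      "' vs ", par)
      if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        warning("constant vector for set '", lab, "' vs ", par,
                "; correlation undefined")
        rho <- NA_real_; p <- NA_real_
      } else {
        ct <- suppressWarnings(
          stats::cor.test(x, y, method = method, exact = FALSE))
        rho <- unname(ct$estimate); p <- ct$p.value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        set_label = lab, parameter = par, rho = rho, p = p, n = n,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out <- out[, c("set_label", "parameter", "rho", "p", "fdr", "n")]
  class(out) <- c("correlation_grid", "data.frame")
  out
}
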
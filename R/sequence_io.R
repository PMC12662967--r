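# Domain containers and readers for protein FASTA and tabular inputs.
# Sequences admit the 20 standard residues plus ambiguity codes X, B, Z, U, O;
# they are stored uppercase with '*' stop characters and whitespace stripped.

.validate_seq <- function(seq, id = NULL) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(gsub("[*[:space:]]", "", seq))
  if (nchar(seq) < 1L) {
    stop("empty sequence", if (!is.null(id)) paste0(" for '", id, "'"))
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% .AA_VALID)
  if (length(bad)) {
    stop("illegal residue '", chars[bad[1]], "' at position ", bad[1],
         if (!is.null(id)) paste0(" in '", id, "'"))
  }
  seq
}

#' Construct a proteome
#'
#' A proteome is an ordered collection of protein records: unique
#' identifiers paired with amino-acid sequences (20 standard letters plus
#' ambiguity codes X, B, Z, U, O), tagged with a species/dataset label.
#' Sequences are normalized to uppercase with stop characters and
#' whitespace removed.
#'
#' @param id Character vector of protein identifiers (non-empty, unique).
#' @param seq Character vector of amino-acid sequences, same length.
#' @param label Species or dataset label.
#' @return An object of class `proteome`: a list with `label`, `id`, `seq`.
#' @examples
#' p <- proteome(c("p1", "p2"), c("MKR", "DDE"), label = "demo")
#' length(p)
#' @export
proteome <- function(id, seq, label = "proteome") {
  stopifnot(is.character(id), is.character(seq), length(id) == length(seq),
            length(id) >= 1L)
  if (any(!nzchar(id))) stop("protein ids must be non-empty")
  dup <- unique(id[duplicated(id)])
  if (length(dup)) {
    stop("duplicate protein id(s): ", paste(dup, collapse = ", "))
  }
  seq <- vapply(seq_along(seq), function(i) .validate_seq(seq[i], id[i]),
                character(1))
  structure(list(label = label, id = id, seq = seq), class = "proteome")
}

#' @export
length.proteome <- function(x) length(x$id)

#' @export
print.proteome <- function(x, ...) {
  cat("proteome '", x$label, "': ", length(x$id), " proteins, ",
      "median length ", stats::median(nchar(x$seq)), " aa\n", sep = "")
  invisible(x)
}

#' Read a protein FASTA file into a proteome
#'
#' Entries are returned in file order; wrapped (multi-line) sequences are
#' concatenated. Sequences are uppercased and stripped of '*' and
#' whitespace. Duplicate header ids and illegal residue letters are errors.
#'
#' @param path Path to a FASTA file.
#' @param label Proteome label (defaults to the file name sans extension).
#' @return A [proteome()] object.
#' @export
read_fasta <- function(path, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  recs <- tryCatch(
    seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                       forceDNAtolower = FALSE, whole.header = FALSE),
    error = function(e) stop("empty or malformed FASTA file: ", path,
                             " (", conditionMessage(e), ")", call. = FALSE))
  if (length(recs) == 0L) stop("empty FASTA file: ", path)
  proteome(id = names(recs),
           seq = vapply(recs, function(r) as.character(r)[1], character(1),
                        USE.NAMES = FALSE),
           label = label)
}

#' Write a proteome to FASTA
#'
#' @param proteome A [proteome()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteome, path) {
  stopifnot(inherits(proteome, "proteome"))
  seqinr::write.fasta(as.list(proteome$seq), names = proteome$id,
                      file.out = path, as.string = TRUE, nbchar = 60)
  invisible(path)
}

#' Construct an abundance matrix
#'
#' Samples-by-proteins label-free intensities with an experimental design.
#' Stored proteins-in-rows; `design` maps every sample (column) to a
#' treatment group.
#'
#' @param values Numeric matrix, proteins in rows (rownames = protein ids),
#'   samples in columns (colnames = sample ids); `NA` marks missing.
#' @param design Named character vector mapping sample id to group label,
#'   or a data.frame with columns `sample_id` and `group`.
#' @return An object of class `abundance_matrix`: list with `values`
#'   (matrix) and `design` (named character vector).
#' @export
abundance_matrix <- function(values, design) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have protein rownames and sample colnames")
  }
  if (is.data.frame(design)) {
    stopifnot(all(c("sample_id", "group") %in% names(design)))
    design <- stats::setNames(as.character(design$group),
                              as.character(design$sample_id))
  }
  missing_in_design <- setdiff(colnames(values), names(design))
  if (length(missing_in_design)) {
    stop("sample(s) missing from design: ",
         paste(missing_in_design, collapse = ", "))
  }
  extra <- setdiff(names(design), colnames(values))
  if (length(extra)) {
    stop("design sample(s) absent from matrix: ",
         paste(extra, collapse = ", "))
  }
  structure(list(values = values, design = design[colnames(values)]),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat("abundance matrix: ", nrow(x$values), " proteins x ",
      ncol(x$values), " samples (", sum(is.na(x$values)), " missing)\n",
      sep = "")
  grp <- table(x$design)
  cat("  groups:", paste(sprintf("%s(%d)", names(grp), grp),
                         collapse = " "), "\n")
  invisible(x)
}

#' Read a label-free abundance TSV and its design
#'
#' The TSV must have a header row of sample ids and protein ids in the
#' first column. Empty cells are missing; zero intensities are treated as
#' missing by default (label-free zero means not detected).
#'
#' @param path Abundance TSV path.
#' @param design Design as accepted by [abundance_matrix()], or a path to a
#'   two-column TSV (`sample_id`, `group`).
#' @param zero_as_missing Treat exact zeros as missing (default TRUE).
#' @param proteome Optional [proteome()]; protein ids absent from it
#'   trigger one warning reporting the unmatched count.
#' @return An [abundance_matrix()] object.
#' @export
read_abundance <- function(path, design, zero_as_missing = TRUE,
                           proteome = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                           na.strings = c("", "NA"))
  if (ncol(raw) < 2L) stop("abundance TSV needs protein ids plus >= 1 sample")
  ids <- raw[[1]]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-numeric cell at row ", bad[1, 1], " (protein '",
         ids[bad[1, 1]], "'), column '", colnames(vals)[bad[1, 2]], "'")
  }
  if (zero_as_missing) num[num == 0] <- NA_real_
  dimnames(num) <- list(ids, colnames(vals))
  if (is.character(design) && length(design) == 1L && file.exists(design)) {
    design <- read_design(design)
  }
  if (!is.null(proteome)) {
    unmatched <- setdiff(ids, proteome$id)
    if (length(unmatched)) {
      warning(length(unmatched), " protein id(s) not found in proteome '",
              proteome$label, "'")
    }
  }
  abundance_matrix(num, design)
}

#' Read a two-column design TSV (sample_id, group)
#'
#' @param path Design TSV path.
#' @return Data.frame with columns `sample_id`, `group`.
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE,
                         colClasses = "character")
  if (!all(c("sample_id", "group") %in% names(d))) {
    stop("design TSV must have columns 'sample_id' and 'group'")
  }
  d[, c("sample_id", "group")]
}

#' Read a per-sample seawater chemistry TSV
#'
#' Requires columns `sample_id`, `TA` (µmol/kg), `pH` (total scale),
#' `temp` (°C), `sal` (practical salinity); extra columns (measured or
#' previously computed speciation) are kept.
#'
#' @param path Chemistry TSV path.
#' @return Data.frame with the required columns coerced to numeric.
#' @export
read_chemistry <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  need <- c("sample_id", "TA", "pH", "temp", "sal")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("chemistry TSV missing column(s): ", paste(miss, collapse = ", "))
  }
  for (cn in c("TA", "pH", "temp", "sal")) d[[cn]] <- as.numeric(d[[cn]])
  d$sample_id <- as.character(d$sample_id)
  d
}

# shared TSV writer: deterministic, tab-separated, no quoting surprises
.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
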
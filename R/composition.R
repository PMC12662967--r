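# Residue-class scheme: acidic {D,E}, basic {K,H,R},
# nonpolar {G,A,V,L,I,M,F,W,P}, polar {S,T,C,Y,N,Q}.
# Disjoint, and together exactly the 20 standard residues.

#' The four-way residue-class scheme
#'
#' @return Named list of character vectors: `acidic`, `basic`, `nonpolar`,
#'   `polar`.
#' @export
residue_classes <- function() {
  list(acidic = c("D", "E"),
       basic = c("K", "H", "R"),
       nonpolar = c("G", "A", "V", "L", "I", "M", "F", "W", "P"),
       polar = c("S", "T", "C", "Y", "N", "Q"))
}

#' Residue and residue-class composition of a sequence
#'
#' Fractions are counts divided by total sequence length; ambiguity
#' residues (X, B, Z, U, O) count toward the length but belong to no
#' class, so residue fractions always sum to 1 while class fractions can
#' sum to slightly less.
#'
#' @param seq Amino-acid sequence, or a one-protein slice of a proteome.
#' @param id Optional protein identifier.
#' @return List of class `composition_profile` with `protein_id`,
#'   `fractions` (named over the 25 admissible letters) and
#'   `class_fractions` (named over the four classes).
#' @examples
#' residue_fractions("DEKR")$class_fractions
#' @export
residue_fractions <- function(seq, id = NA_character_) {
  seq <- .validate_seq(seq, id)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  counts <- vapply(.AA_VALID, function(a) sum(chars == a), integer(1))
  fr <- counts / length(chars)
  cls <- vapply(residue_classes(), function(m) sum(fr[m]), numeric(1))
  structure(list(protein_id = id, fractions = fr, class_fractions = cls),
            class = "composition_profile")
}

#' Per-protein composition table for a proteome
#'
#' @param proteome A [proteome()] object.
#' @return Data.frame: `protein_id`, one column per standard residue
#'   fraction, and the four class fractions (`acidic`, `basic`,
#'   `nonpolar`, `polar`).
#' @export
composition_table <- function(proteome) {
  stopifnot(inherits(proteome, "proteome"))
  profs <- lapply(seq_along(proteome$id), function(i)
    residue_fractions(proteome$seq[i], proteome$id[i]))
  res <- t(vapply(profs, function(p) p$fractions[.AA_STANDARD],
                  numeric(length(.AA_STANDARD))))
  cls <- t(vapply(profs, function(p) p$class_fractions, numeric(4)))
  out <- data.frame(protein_id = proteome$id, res, cls,
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Proteins richest in a given residue
#'
#' Ranks proteins by the fraction (or, optionally, absolute count) of one
#' residue and returns the ids of the top `n`, descending. Ties are broken
#' by protein id (lexicographic ascending) for run-to-run determinism. If
#' the proteome holds fewer than `n` proteins, all ids are returned with a
#' warning.
#'
#' @param proteome A [proteome()] object.
#' @param residue One of the 20 standard amino-acid letters.
#' @param n Number of proteins to return.
#' @param by Ranking key: `"fraction"` (length-normalized, default) or
#'   `"count"`.
#' @return Character vector of protein ids, highest first.
#' @examples
#' p <- proteome(c("p1", "p2", "p3"), c("DDDD", "DDKK", "KKKK"))
#' top_n_by_residue(p, "D", 2)
#' @export
top_n_by_residue <- function(proteome, residue, n,
                             by = c("fraction", "count")) {
  stopifnot(inherits(proteome, "proteome"), n >= 1)
  by <- match.arg(by)
  residue <- toupper(residue)
  if (!residue %in% .AA_STANDARD) {
    stop("unknown residue letter '", residue, "'")
  }
  counts <- vapply(strsplit(proteome$seq, "", fixed = TRUE),
                   function(ch) sum(ch == residue), integer(1))
  key <- if (by == "fraction") counts / nchar(proteome$seq) else counts
  ord <- order(-key, proteome$id)
  if (length(proteome$id) < n) {
    warning("proteome has only ", length(proteome$id),
            " proteins; returning all")
    n <- length(proteome$id)
  }
  proteome$id[ord[seq_len(n)]]
}
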
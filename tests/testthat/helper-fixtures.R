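# Shared fixtures and independent oracles, built in code at test time.

aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
          "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_peptide <- function(len, ambig = FALSE) {
  pool <- if (ambig) c(aa20, "X", "B", "Z", "U", "O") else aa20
  paste(sample(pool, len, replace = TRUE), collapse = "")
}

random_proteome <- function(n, len_range = c(30, 120), label = "rand") {
  proteome(sprintf("rp%04d", seq_len(n)),
           vapply(sample(len_range[1]:len_range[2], n, replace = TRUE),
                  random_peptide, character(1)),
           label = label)
}

write_temp_fasta <- function(ids, seqs, wrap = NULL) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  lines <- unlist(lapply(seq_along(ids), function(i) {
    s <- seqs[i]
    body <- if (is.null(wrap)) s else {
      starts <- seq(1, nchar(s), by = wrap)
      substring(s, starts, pmin(starts + wrap - 1, nchar(s)))
    }
    c(paste0(">", ids[i]), body)
  }))
  writeLines(lines, path)
  path
}

write_temp_tsv <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  path
}

# dense-grid root oracle for the isoelectric point: evaluate the charge on
# a fixed pH grid, locate the sign change, return the bracket midpoint
grid_pi_oracle <- function(seq, scale = pka_scale("EMBOSS"), step = 1e-4) {
  grid <- seq(0, 14, by = step)
  z <- net_charge(seq, grid, scale)
  i <- which(z <= 0)[1]
  (grid[i - 1] + grid[i]) / 2
}

# exhaustive two-sided Fisher oracle from first principles (choose(),
# not dhyper): sum of probabilities of all tables with the observed
# margins whose probability <= that of the observed table
fisher_enum_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  ks <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, ks) + lchoose(r2, c1 - ks) - lchoose(r1 + r2, c1)
  pk <- exp(logp)
  p_obs <- pk[ks == a]
  min(1, sum(pk[pk <= p_obs * (1 + 1e-7)]))
}

# small complete synthetic experiment for pipeline-level tests
small_generator_config <- function(seed = 11, ...) {
  generator_config(n_proteins = 150, length_range = c(40, 90),
                   treatments = c(control = 3, HC = 3, HA = 3),
                   n_dap_up = 15, n_dap_down = 15, seed = seed, ...)
}
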
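# Synthetic proteomes, label-free abundance matrices and chemistry tables
# with known ground truth, emulating a 5-treatment x 4-replicate
# carbonate-chemistry exposure: control seawater, high CO2 (HC), high
# alkalinity (HA) and two combined treatments (HCHA1/HCHA2).

.default_chem_profile <- function() {
  data.frame(group = c("control", "HC", "HA", "HCHA1", "HCHA2"),
             TA = c(2300, 2300, 3200, 3000, 3000),
             pH = c(8.13, 7.58, 8.21, 7.94, 7.94),
             temp = 26, sal = 33, stringsAsFactors = FALSE)
}

#' Configuration for the synthetic-experiment generator
#'
#' Defaults emulate the study conditions the pipeline is built for: a
#' ~4,000-protein proteome with a bimodal pI distribution (acidic and
#' basic residue classes both elevated over a purely uniform
#' composition), a 5-treatment x 4-replicate label-free design whose
#' chemistry follows the control/HC/HA/HCHA treatment pattern (control
#' pH 8.13, HC 7.58, HA 8.21, HCHA 7.94; alkalinity enriched in the
#' HA/HCHA groups), 200 up- and 200 down-regulated proteins with a
#' direction-dependent pI bias, 2 log2-unit effects, 0.3 log2 noise and
#' 10% intensity-dependent missingness.
#'
#' @param n_proteins Number of proteins.
#' @param length_range Sequence length range (residues), inclusive.
#' @param baseline_class_weights Named sampling weights for the four
#'   residue classes of [residue_classes()]; uniform within a class.
#' @param treatments Named integer vector: group label -> replicate
#'   count. The FIRST group is the control/reference.
#' @param n_dap_up,n_dap_down Number of truly up-/down-regulated
#'   proteins.
#' @param pi_shift_delta Target mean pI(up) - mean pI(down), pH units.
#'   Zero means an exchangeable random assignment (no shift); nonzero
#'   values are hit to within ±0.05 by matched selection.
#' @param lfc_effect Injected |log2 fold change| for DAPs.
#' @param noise_sd Per-cell log2 noise sd.
#' @param missing_rate Overall missingness fraction; missingness is
#'   intensity-dependent (logistic in the true log2 intensity), mirroring
#'   left-censoring of label-free data.
#' @param missing_slope Steepness of the censoring curve, per log2 unit
#'   of intensity (default 3, i.e. the detection probability falls from
#'   ~90% to ~10% over about 1.5 log2 units — a realistic detection-limit
#'   width for label-free MS).
#' @param alk_coupling Chemistry-composition coupling (log2 units per SD
#'   of group alkalinity per SD of a protein's acidic-minus-basic
#'   composition score). Zero (default) keeps the truth table the sole
#'   source of differential signal; set positive to make acidic-rich
#'   protein abundance rise with alkalinity.
#' @param chem_profile Data.frame `group`, `TA`, `pH`, `temp`, `sal`
#'   covering every treatment group.
#' @param seed Integer seed; all generator draws are functions of it.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_proteins = 4000,
                             length_range = c(100, 600),
                             baseline_class_weights = c(acidic = 0.14,
                                                        basic = 0.14,
                                                        nonpolar = 0.47,
                                                        polar = 0.25),
                             treatments = c(control = 4, HC = 4, HA = 4,
                                            HCHA1 = 4, HCHA2 = 4),
                             n_dap_up = 200, n_dap_down = 200,
                             pi_shift_delta = -0.8,
                             lfc_effect = 2, noise_sd = 0.3,
                             missing_rate = 0.1, missing_slope = 3,
                             alk_coupling = 0,
                             chem_profile = .default_chem_profile(),
                             seed = 1L) {
  stopifnot(n_proteins >= 1,
            length(length_range) == 2, length_range[1] >= 1,
            length_range[1] <= length_range[2],
            n_dap_up >= 0, n_dap_down >= 0,
            n_dap_up + n_dap_down <= n_proteins,
            missing_rate >= 0, missing_rate < 1, missing_slope > 0,
            noise_sd >= 0, all(treatments >= 2),
            !is.null(names(treatments)))
  if (!setequal(names(baseline_class_weights), names(residue_classes())) ||
      any(baseline_class_weights < 0) || sum(baseline_class_weights) <= 0) {
    stop("baseline_class_weights must be non-negative over acidic, basic, ",
         "nonpolar, polar")
  }
  miss_grp <- setdiff(names(treatments), chem_profile$group)
  if (length(miss_grp)) {
    stop("chem_profile missing group(s): ", paste(miss_grp, collapse = ", "))
  }
  structure(list(n_proteins = n_proteins, length_range = length_range,
                 baseline_class_weights = baseline_class_weights,
                 treatments = treatments, n_dap_up = n_dap_up,
                 n_dap_down = n_dap_down, pi_shift_delta = pi_shift_delta,
                 lfc_effect = lfc_effect, noise_sd = noise_sd,
                 missing_rate = missing_rate, missing_slope = missing_slope,
                 alk_coupling = alk_coupling,
                 chem_profile = chem_profile, seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a synthetic proteome
#'
#' Sequences are sampled residue-by-residue from the configured
#' residue-class weights (uniform within each class). With both charged
#' classes elevated, the binomial spread of the acidic-minus-basic count
#' makes the resulting pI distribution bimodal around neutrality, as in
#' real proteomes.
#'
#' @param cfg A [generator_config()].
#' @param label Proteome label.
#' @return A [proteome()] object; deterministic under `cfg$seed`.
#' @export
gen_proteome <- function(cfg, label = "synthetic") {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  cls <- residue_classes()
  letters20 <- unlist(cls, use.names = FALSE)
  prob <- unlist(lapply(names(cls), function(cn)
    rep(cfg$baseline_class_weights[[cn]] / length(cls[[cn]]),
        length(cls[[cn]]))))
  len <- sample(cfg$length_range[1]:cfg$length_range[2], cfg$n_proteins,
                replace = TRUE)
  chars <- sample(letters20, sum(len), replace = TRUE, prob = prob)
  seqs <- vapply(split(chars, rep.int(seq_len(cfg$n_proteins), len)),
                 paste, character(1), collapse = "")
  proteome(sprintf("P%05d", seq_len(cfg$n_proteins)), unname(seqs),
           label = label)
}

# Choose up/down truth sets whose pI contrast hits delta.
# delta == 0: exchangeable random split (keeps the permutation null
# exact). delta != 0: paired selection — each down member is accepted
# only together with an unused partner whose pI lies within eps of
# (pI + delta), so the up set is a pointwise location shift of the down
# set and both the mean and the median pI difference equal delta to
# within eps. eps starts at 0.04 and is doubled (up to 0.16) where the
# pI density is too sparse to pair at the tighter width.
.select_shift_sets <- function(pis, n_up, n_down, delta, tol = 0.05) {
  ids <- names(pis)
  n <- length(pis)
  stopifnot(n_up + n_down <= n)
  if (delta == 0) {
    idx <- sample.int(n, n_up + n_down)
    return(list(up = ids[idx[seq_len(n_up)]],
                down = ids[idx[n_up + seq_len(n_down)]]))
  }
  srt <- sort(pis)
  max_d <- mean(srt[(n - n_up + 1):n]) - mean(srt[seq_len(n_down)])
  min_d <- mean(srt[seq_len(n_up)]) - mean(srt[(n - n_down + 1):n])
  if (delta > max_d || delta < min_d) {
    stop(sprintf(
      "pi_shift_delta = %.2f unattainable; attainable range [%.2f, %.2f]",
      delta, min_d, max_d))
  }
  used <- rep(FALSE, n)
  # pair a set of anchors with partners offset by `off`; returns index
  # pairs (anchor, partner), marking both used
  pair_up <- function(n_pairs, off) {
    anchors <- integer(n_pairs); partners <- integer(n_pairs)
    got <- 0L
    eps <- 0.04
    while (got < n_pairs && eps <= 0.16) {
      for (i in sample(which(!used))) {
        if (got >= n_pairs) break
        if (used[i]) next
        free <- which(!used)
        free <- free[free != i]
        if (!length(free)) break
        j <- free[which.min(abs(pis[free] - (pis[i] + off)))]
        if (abs(pis[j] - (pis[i] + off)) <= eps) {
          got <- got + 1L
          anchors[got] <- i; partners[got] <- j
          used[c(i, j)] <<- TRUE
        }
      }
      eps <- eps * 2
    }
    if (got < n_pairs) {
      stop(sprintf(paste0("pi_shift_delta = %.2f unattainable: only %d of ",
                          "%d pI pairs available at this proteome size"),
                   delta, got, n_pairs))
    }
    list(anchor = anchors, partner = partners)
  }
  m <- min(n_up, n_down)
  pr <- pair_up(m, delta)
  down_idx <- pr$anchor
  up_idx <- pr$partner
  if (n_up > m) {        # extra up members, targets re-drawn from down
    extra <- pair_up(n_up - m, delta)
    up_idx <- c(up_idx, extra$partner)
    used[extra$anchor] <- FALSE
  } else if (n_down > m) {
    extra <- pair_up(n_down - m, -delta)
    down_idx <- c(down_idx, extra$partner)
    used[extra$anchor] <- FALSE
  }
  list(up = ids[up_idx], down = ids[down_idx])
}

#' Generate a synthetic label-free experiment with ground truth
#'
#' Builds an abundance matrix, a matching per-sample chemistry table and
#' a truth table on top of a (generated or supplied) proteome. Baseline
#' log2 intensities are N(25, 2); the up/down truth sets are chosen from
#' the proteome's pI strata so that mean pI(up) - mean pI(down) hits
#' `pi_shift_delta`; treatment effects of ±`lfc_effect` log2 units apply
#' in every non-control group; cells are perturbed with N(0, `noise_sd`)
#' noise; missingness is logistic in the true log2 intensity (left-
#' censored) calibrated to the overall `missing_rate`; chemistry
#' replicates jitter the group profile (1% multiplicative on TA,
#' ±0.01 additive on pH) and are fully speciated.
#'
#' @param cfg A [generator_config()].
#' @param proteome Optional [proteome()] (defaults to `gen_proteome(cfg)`).
#' @param pis Optional precomputed pI table for `proteome` (from
#'   [proteome_pis()]), to avoid recomputation across repeated runs.
#' @param scale pKa scale for pI computation when `pis` is not supplied.
#' @return List with `abundance` ([abundance_matrix()]), `chemistry`
#'   (speciated `carbonate_state` with `group` column), `truth`
#'   (data.frame `protein_id`, `role`, `true_lfc`, `pi`, `score_z`),
#'   `proteome` and `pis`. Deterministic under `cfg$seed`.
#' @export
gen_experiment <- function(cfg, proteome = NULL, pis = NULL,
                           scale = pka_scale("EMBOSS")) {
  stopifnot(inherits(cfg, "generator_config"))
  if (is.null(proteome)) proteome <- gen_proteome(cfg)
  if (is.null(pis)) pis <- proteome_pis(proteome, scale)
  pi_vec <- stats::setNames(pis$pi, pis$protein_id)
  set.seed(cfg$seed + 1L)

  comp <- composition_table(proteome)
  score <- comp$acidic - comp$basic
  score_z <- if (stats::sd(score) > 0) (score - mean(score)) / stats::sd(score)
             else rep(0, length(score))

  sets <- if (cfg$n_dap_up > 0 && cfg$n_dap_down > 0) {
    .select_shift_sets(pi_vec, cfg$n_dap_up, cfg$n_dap_down,
                       cfg$pi_shift_delta)
  } else list(up = character(0), down = character(0))
  role <- rep("null", length(proteome$id))
  names(role) <- proteome$id
  role[sets$up] <- "up"; role[sets$down] <- "down"
  lfc <- c(up = cfg$lfc_effect, down = -cfg$lfc_effect, null = 0)[role]

  groups <- rep(names(cfg$treatments), cfg$treatments)
  reps <- unlist(lapply(cfg$treatments, seq_len), use.names = FALSE)
  sample_ids <- paste(groups, reps, sep = "_")
  control <- names(cfg$treatments)[1]

  prof <- cfg$chem_profile[match(names(cfg$treatments),
                                 cfg$chem_profile$group), ]
  ta_g <- stats::setNames(prof$TA, prof$group)
  zalk <- if (stats::sd(ta_g) > 0) (ta_g - mean(ta_g)) / stats::sd(ta_g)
          else ta_g * 0

  base <- stats::rnorm(length(proteome$id), 25, 2)
  mu <- outer(base, rep(1, length(sample_ids)))
  for (j in seq_along(sample_ids)) {
    g <- groups[j]
    mu[, j] <- base + lfc * (g != control) +
      cfg$alk_coupling * zalk[[g]] * score_z
  }
  x <- mu + stats::rnorm(length(mu), 0, cfg$noise_sd)
  dimnames(x) <- list(proteome$id, sample_ids)

  if (cfg$missing_rate > 0) {
    ctr <- x - stats::median(x)
    a <- stats::uniroot(
      function(a) mean(stats::plogis(a - cfg$missing_slope * ctr)) -
        cfg$missing_rate,
      c(-200, 200))$root
    miss <- stats::runif(length(x)) <
      stats::plogis(a - cfg$missing_slope * ctr)
    x[miss] <- NA_real_
  }
  intensities <- 2^x

  chem_in <- data.frame(
    sample_id = sample_ids,
    TA = ta_g[groups] * (1 + 0.01 * stats::rnorm(length(sample_ids))),
    pH = stats::setNames(prof$pH, prof$group)[groups] +
      0.01 * stats::rnorm(length(sample_ids)),
    temp = stats::setNames(prof$temp, prof$group)[groups],
    sal = stats::setNames(prof$sal, prof$group)[groups],
    stringsAsFactors = FALSE)
  chemistry <- speciate_table(chem_in)
  chemistry$group <- groups

  truth <- data.frame(protein_id = proteome$id, role = unname(role),
                      true_lfc = unname(lfc), pi = unname(pi_vec),
                      score_z = score_z, stringsAsFactors = FALSE)
  list(abundance = abundance_matrix(intensities,
                                    stats::setNames(groups, sample_ids)),
       chemistry = chemistry, truth = truth,
       proteome = proteome, pis = pis)
}
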
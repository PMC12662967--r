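# Seawater carbonate-system speciation from total alkalinity and pH.
# Total-scale pH throughout; concentrations in µmol/kg at the interface,
# mol/kg internally. Alkalinity model: TA = HCO3 + 2*CO3 + B(OH)4 + OH - H
# (carbonate, borate and water terms only; no phosphate/silicate/ammonia).

#' Equilibrium constants for the carbonate system
#'
#' Evaluates the dissociation constants at a given temperature and
#' salinity: carbonic acid K1/K2 per the Lueker et al. (2000) refit of
#' Mehrbach on the total pH scale, boric acid KB per Dickson (1990), water
#' KW per Millero (1995), and total borate proportional to salinity
#' (Uppström 1974). These are the common defaults of CO2SYS-style
#' calculators; any element can be overridden for custom or degenerate
#' systems.
#'
#' @param temp Temperature, °C (0-40).
#' @param sal Practical salinity (0-40).
#' @param name Constants-set label; only `"lueker"` is registered.
#' @return List of class `constants_set`: `name`, `K1`, `K2`, `KB`, `KW`
#'   (mol/kg, total scale) and `BT` (total borate, mol/kg).
#' @export
carbonate_constants <- function(temp = 26, sal = 35, name = "lueker") {
  stopifnot(temp >= 0, temp <= 40, sal >= 0, sal <= 40)
  if (tolower(name) != "lueker") stop("unknown constants set '", name, "'")
  TK <- temp + 273.15
  lnTK <- log(TK)
  s <- sal
  pK1 <- 3633.86 / TK - 61.2172 + 9.67770 * lnTK -
    0.011555 * s + 0.0001152 * s^2
  pK2 <- 471.78 / TK + 25.9290 - 3.16967 * lnTK -
    0.01781 * s + 0.0001122 * s^2
  lnKB <- (-8966.90 - 2890.53 * sqrt(s) - 77.942 * s +
             1.728 * s^1.5 - 0.0996 * s^2) / TK +
    148.0248 + 137.1942 * sqrt(s) + 1.62142 * s +
    (-24.4344 - 25.085 * sqrt(s) - 0.2474 * s) * lnTK +
    0.053105 * sqrt(s) * TK
  lnKW <- 148.9652 - 13847.26 / TK - 23.6521 * lnTK +
    (118.67 / TK - 5.977 + 1.0495 * lnTK) * sqrt(s) - 0.01615 * s
  structure(list(name = name,
                 K1 = 10^(-pK1), K2 = 10^(-pK2),
                 KB = exp(lnKB), KW = exp(lnKW),
                 BT = 0.0004157 * s / 35),
            class = "constants_set")
}

# carbonate speciation fractions at proton concentration H (mol/kg)
.carb_alphas <- function(H, K1, K2) {
  D <- H^2 + H * K1 + K1 * K2
  list(a0 = H^2 / D, a1 = H * K1 / D, a2 = K1 * K2 / D)
}

# non-carbonate alkalinity (mol/kg): borate plus water self-ionization.
# KW == 0 selects a pure carbonate(-borate) system: the water term,
# including the free-proton correction, is dropped entirely so that
# TA = HCO3 + 2*CO3 (+ borate) holds exactly.
.minor_alkalinity <- function(H, k) {
  borate <- if (k$BT > 0) k$BT * k$KB / (k$KB + H) else 0
  water <- if (k$KW > 0) k$KW / H - H else 0
  borate + water
}

#' Speciate the carbonate system from TA and pH
#'
#' Given total alkalinity, total-scale pH, temperature and salinity,
#' computes CO2(aq), bicarbonate, carbonate, and DIC. Carbonate
#' alkalinity is obtained by subtracting the borate and water terms from
#' TA; DIC follows from the speciation fractions at the given proton
#' concentration, so the returned state reproduces the input TA exactly
#' (to solver round-off) when alkalinity is reconstructed from it.
#'
#' @param TA Total alkalinity, µmol/kg (vector allowed).
#' @param pH Total-scale pH in \[6, 9\] (vector allowed, recycled).
#' @param temp,sal Temperature (°C) and salinity; recycled.
#' @param constants A [carbonate_constants()] list, or NULL to evaluate
#'   the default set at each (temp, sal). Pass a custom list (e.g.
#'   `BT = 0`, `KW = 0`) for degenerate systems.
#' @param sample_id Optional sample identifiers.
#' @return Data.frame of class `carbonate_state`: `sample_id`, `TA`,
#'   `pH`, `temp`, `sal`, `co2`, `hco3`, `co3`, `dic` (all µmol/kg).
#' @examples
#' speciate(2300, 8.10, temp = 26, sal = 35)
#' @export
speciate <- function(TA, pH, temp = 26, sal = 35, constants = NULL,
                     sample_id = NULL) {
  stopifnot(all(TA > 0), all(pH >= 6 & pH <= 9))
  n <- max(length(TA), length(pH), length(temp), length(sal))
  TA <- rep_len(TA, n); pH <- rep_len(pH, n)
  temp <- rep_len(temp, n); sal <- rep_len(sal, n)
  if (is.null(sample_id)) sample_id <- sprintf("S%d", seq_len(n))
  out <- data.frame(sample_id = as.character(sample_id),
                    TA = TA, pH = pH, temp = temp, sal = sal,
                    co2 = NA_real_, hco3 = NA_real_, co3 = NA_real_,
                    dic = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    k <- if (is.null(constants)) carbonate_constants(temp[i], sal[i])
         else constants
    H <- 10^(-pH[i])
    CA <- TA[i] * 1e-6 - .minor_alkalinity(H, k)
    if (CA <= 0) stop("alkalinity inconsistent with pH for sample '",
                      sample_id[i], "'")
    al <- .carb_alphas(H, k$K1, k$K2)
    dic <- CA / (al$a1 + 2 * al$a2)
    out$co2[i] <- dic * al$a0 * 1e6
    out$hco3[i] <- dic * al$a1 * 1e6
    out$co3[i] <- dic * al$a2 * 1e6
    out$dic[i] <- dic * 1e6
  }
  class(out) <- c("carbonate_state", "data.frame")
  out
}

#' Reconstruct total alkalinity from DIC and pH
#'
#' The inverse of [speciate()]: TA = DIC*(a1 + 2*a2) plus the borate and
#' water terms. Used for round-trip validation and inside the
#' buffer-capacity derivative.
#'
#' @param dic DIC, µmol/kg.
#' @inheritParams speciate
#' @return TA in µmol/kg.
#' @export
alkalinity_from_dic <- function(dic, pH, temp = 26, sal = 35,
                                constants = NULL) {
  n <- max(length(dic), length(pH), length(temp), length(sal))
  dic <- rep_len(dic, n); pH <- rep_len(pH, n)
  temp <- rep_len(temp, n); sal <- rep_len(sal, n)
  vapply(seq_len(n), function(i) {
    k <- if (is.null(constants)) carbonate_constants(temp[i], sal[i])
         else constants
    H <- 10^(-pH[i])
    al <- .carb_alphas(H, k$K1, k$K2)
    (dic[i] * 1e-6 * (al$a1 + 2 * al$a2) + .minor_alkalinity(H, k)) * 1e6
  }, numeric(1))
}

#' Seawater buffer capacity at fixed alkalinity
#'
#' The magnitude of the change of DIC per unit pH at constant TA,
#' estimated by a central difference: beta = |DIC(pH+h) - DIC(pH-h)| / 2h.
#' Seawater with a larger carbonate-ion share of DIC resists pH change
#' more, so beta tracks the CO3/DIC ratio across treatments.
#'
#' @param state A `carbonate_state` (from [speciate()]) or a data.frame
#'   with columns `TA`, `pH`, `temp`, `sal`.
#' @param constants Optional [carbonate_constants()] override.
#' @param step Half-width of the central difference, pH units.
#' @return Numeric vector of buffer capacities, mmol/kg per pH unit
#'   (positive).
#' @export
buffer_capacity <- function(state, constants = NULL, step = 1e-3) {
  stopifnot(all(c("TA", "pH", "temp", "sal") %in% names(state)), step > 0)
  hi <- speciate(state$TA, state$pH + step, state$temp, state$sal, constants)
  lo <- speciate(state$TA, state$pH - step, state$temp, state$sal, constants)
  abs(hi$dic - lo$dic) / (2 * step) / 1000
}

#' @export
print.carbonate_state <- function(x, digits = 1, ...) {
  cat("carbonate system state (", nrow(x), " sample",
      if (nrow(x) != 1) "s", ", µmol/kg, total-scale pH):\n", sep = "")
  print.data.frame(x, digits = digits + 4, row.names = FALSE, ...)
  invisible(x)
}

#' Speciate every row of a chemistry table
#'
#' Convenience wrapper: takes a chemistry data.frame (as from
#' [read_chemistry()]), speciates each sample and appends `co2`, `hco3`,
#' `co3`, `dic`, `buffer` and an `alkalinity` alias of TA.
#'
#' @param chem Data.frame with `sample_id`, `TA`, `pH`, `temp`, `sal`.
#' @param constants Optional [carbonate_constants()] override.
#' @return A `carbonate_state` data.frame with a `buffer` column.
#' @export
speciate_table <- function(chem, constants = NULL) {
  st <- speciate(chem$TA, chem$pH, chem$temp, chem$sal, constants,
                 sample_id = chem$sample_id)
  st$buffer <- buffer_capacity(st, constants)
  st$alkalinity <- st$TA
  st
}
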
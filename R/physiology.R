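#' Arterial oxygen content
#'
#' `CaO2 = 1.36 * Hb[g/dL] * (SaO2/100) + 0.003 * PaO2` in mL O2 per dL of
#' blood; 1.36 is the O2 binding capacity of hemoglobin and 0.003 the
#' dissolved-O2 solubility at 37 C. Hemoglobin is supplied in g/L (the blood
#' analyzer unit) and converted to g/dL internally.
#'
#' @param hb_g_per_l hemoglobin concentration, g/L.
#' @param sao2_pct arterial oxygen saturation, percent (0-100).
#' @param pao2_mmhg arterial oxygen partial pressure, mmHg.
#' @return CaO2 in mL/dL (vectorized).
#' @export
cao2 <- function(hb_g_per_l, sao2_pct, pao2_mmhg) {
  if (any(stats::na.omit(c(hb_g_per_l, sao2_pct, pao2_mmhg)) < 0))
    stop("inputs must be non-negative", call. = FALSE)
  if (any(stats::na.omit(sao2_pct) > 100))
    stop("SaO2 cannot exceed 100%", call. = FALSE)
  1.36 * (hb_g_per_l / 10) * (sao2_pct / 100) + 0.003 * pao2_mmhg
}

#' Stimulus index
#'
#' `PaCO2 / PaO2` — a single ratio summarizing the opposing vascular effects
#' of hypocapnia and hypoxemia.
#'
#' @param paco2_mmhg arterial CO2 partial pressure, mmHg.
#' @param pao2_mmhg arterial O2 partial pressure, mmHg (> 0).
#' @return The ratio (vectorized).
#' @export
stimulus_index <- function(paco2_mmhg, pao2_mmhg) {
  if (any(stats::na.omit(pao2_mmhg) <= 0))
    stop("PaO2 must be positive", call. = FALSE)
  paco2_mmhg / pao2_mmhg
}

#' Mean arterial pressure
#'
#' `MAP = SBP/3 + 2*DBP/3` in mmHg.
#'
#' @param sbp systolic pressure, mmHg.
#' @param dbp diastolic pressure, mmHg; must satisfy `sbp >= dbp > 0`.
#' @return MAP in mmHg (vectorized).
#' @export
mean_arterial_pressure <- function(sbp, dbp) {
  ok <- stats::complete.cases(sbp, dbp)
  if (any(dbp[ok] <= 0)) stop("pressures must be positive", call. = FALSE)
  if (any(sbp[ok] < dbp[ok])) stop("systolic must be >= diastolic", call. = FALSE)
  sbp / 3 + 2 * dbp / 3
}

#' Per-subject day deltas
#'
#' For each subject and variable, `value(day) - value(ref_day)`, computed
#' only for subjects observed on both days (complete-case); subjects missing
#' the reference day are dropped and the count reported via a message.
#'
#' @param table long physiology tibble (`subject`, `day`, `variable`, `value`).
#' @param ref_day reference day label.
#' @return A tibble (`subject`, `day`, `variable`, `delta`), days other than
#'   the reference only.
#' @export
day_deltas <- function(table, ref_day) {
  stopifnot(all(c("subject", "day", "variable", "value") %in% names(table)))
  if (!ref_day %in% table$day) stop(sprintf("ref_day '%s' not present", ref_day), call. = FALSE)
  ref <- dplyr::filter(table, .data$day == ref_day, !is.na(.data$value))
  ref <- dplyr::select(ref, "subject", "variable", ref_value = "value")
  oth <- dplyr::filter(table, .data$day != ref_day)
  n_before <- nrow(dplyr::distinct(oth, .data$subject, .data$variable, .data$day))
  joined <- dplyr::inner_join(oth, ref, by = c("subject", "variable"))
  joined <- dplyr::filter(joined, !is.na(.data$value))
  n_dropped <- n_before - nrow(joined)
  if (n_dropped > 0)
    message(sprintf("day_deltas: %d subject-variable-day cells dropped (incomplete pairs)",
                    n_dropped))
  dplyr::select(dplyr::mutate(joined, delta = .data$value - .data$ref_value),
                "subject", "day", "variable", "delta")
}

#' Summarize day deltas as mean and SD
#'
#' @param deltas output of [day_deltas()].
#' @return A tibble (`day`, `variable`, `n`, `mean_delta`, `sd_delta`).
#' @export
summarise_deltas <- function(deltas) {
  dplyr::summarise(dplyr::group_by(deltas, .data$day, .data$variable),
                   n = dplyr::n(),
                   mean_delta = mean(.data$delta),
                   sd_delta = stats::sd(.data$delta),
                   .groups = "drop")
}
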
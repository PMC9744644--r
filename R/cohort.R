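#' Cohort parameters for the synthetic physiology generator
#'
#' Defaults reproduce the study's day-wise group means and SDs for arterial
#' blood and cardiorespiratory variables at low altitude (day 0) and on days
#' 2 and 9 of high-altitude exposure. Only mean arterial pressure is reported
#' by the source tables, so systolic/diastolic defaults are backed out from
#' the MAP means assuming a 40 mmHg pulse pressure (DBP = MAP - PP/3).
#'
#' Repeated-measures structure: for each variable, a subject random intercept
#' (shared across days) and a day-level residual split each day's total SD:
#' within-SD = `within_subject_sd * SD`, between-SD = `sqrt(1 - rho^2) * SD`,
#' so per-day sample SDs converge to the configured values as n grows.
#'
#' Two derived outcome variables are planted with known structure:
#' `rvpd_au` (retinal vascular perfusion density, a.u.) depends linearly on
#' the subject-day PaO2 through `rvpd_pao2_slope` (plus per-day offsets
#' emulating the day-9 normalization), and `rt_um` (retinal thickness) carries
#' fixed day means. Both get subject intercepts.
#'
#' @param n_subjects number of subjects.
#' @param days character day labels.
#' @param day_stats named list: per variable a list of `mean` and `sd`
#'   vectors over `days`. Defaults are the study values.
#' @param within_subject_sd fraction `rho` in `[0, 1]` of each day SD that is
#'   within-subject (day-level) variation.
#' @param rvpd_pao2_slope planted slope of rvpd_au on PaO2 (a.u. per mmHg).
#' @param rvpd_day_offsets_au additive day offsets on rvpd_au beyond the PaO2
#'   dependence (emulates the day-9 return toward baseline).
#' @param rt_day_means_um planted day means of retinal thickness.
#' @param seed RNG seed; fixed seed reproduces the cohort exactly.
#' @return A validated list of class `cohort_params`.
#' @export
cohort_params <- function(n_subjects = 18,
                          days = c("0", "2", "9"),
                          day_stats = default_day_stats(days),
                          within_subject_sd = 0.5,
                          rvpd_pao2_slope = -0.0185,
                          rvpd_day_offsets_au = NULL,
                          rt_day_means_um = NULL,
                          seed = 1L) {
  days <- as.character(days)
  canon <- match(days, c("0", "2", "9"))
  if (is.null(rvpd_day_offsets_au)) {
    if (anyNA(canon)) stop("provide rvpd_day_offsets_au for non-standard day labels", call. = FALSE)
    rvpd_day_offsets_au <- c(0, 0, -0.35)[canon]
  }
  if (is.null(rt_day_means_um)) {
    if (anyNA(canon)) stop("provide rt_day_means_um for non-standard day labels", call. = FALSE)
    rt_day_means_um <- c(300.1, 299.6, 297.4)[canon]
  }
  p <- list(n_subjects = as.integer(n_subjects), days = as.character(days),
            day_stats = day_stats, within_subject_sd = within_subject_sd,
            rvpd_pao2_slope = rvpd_pao2_slope,
            rvpd_day_offsets_au = rvpd_day_offsets_au,
            rt_day_means_um = rt_day_means_um, seed = as.integer(seed))
  if (p$n_subjects <= 0) stop("n_subjects must be positive", call. = FALSE)
  if (length(p$days) < 1) stop("at least one day label required", call. = FALSE)
  for (v in names(day_stats)) {
    st <- day_stats[[v]]
    if (length(st$mean) != length(p$days) || length(st$sd) != length(p$days))
      stop(sprintf("day_stats[['%s']] must have one mean and sd per day", v), call. = FALSE)
    if (any(st$sd < 0)) stop(sprintf("negative SD for '%s'", v), call. = FALSE)
  }
  if (within_subject_sd < 0 || within_subject_sd > 1)
    stop("within_subject_sd is a fraction in [0, 1]", call. = FALSE)
  if (length(p$rvpd_day_offsets_au) != length(p$days) ||
      length(p$rt_day_means_um) != length(p$days))
    stop("rvpd_day_offsets_au and rt_day_means_um need one value per day", call. = FALSE)
  class(p) <- "cohort_params"
  p
}

#' @rdname cohort_params
#' @export
default_day_stats <- function(days = c("0", "2", "9")) {
  canon <- match(as.character(days), c("0", "2", "9"))
  if (anyNA(canon))
    stop("default day statistics exist only for days 0, 2 and 9", call. = FALSE)
  full <- list(
    SaO2  = list(mean = c(96.3, 87.3, 88.6),   sd = c(0.96, 3.1, 1.9)),
    PaCO2 = list(mean = c(37.9, 33.3, 30.4),   sd = c(3.7, 3.2, 1.9)),
    PaO2  = list(mean = c(84.8, 52.5, 54.5),   sd = c(9.1, 5.1, 4.0)),
    pH    = list(mean = c(7.41, 7.43, 7.42),   sd = c(0.02, 0.2, 0.01)),
    HCO3  = list(mean = c(24.2, 22.0, 19.6),   sd = c(1.8, 2.2, 1.4)),
    Hb    = list(mean = c(150.7, 153.2, 165.4), sd = c(13.0, 13.4, 13.0)),
    Hct   = list(mean = c(43.7, 43.8, 46.6),   sd = c(3.4, 2.8, 2.9)),
    HR    = list(mean = c(64.0, 74.7, 68.7),   sd = c(12.4, 10.1, 11.4)),
    SBP   = list(mean = c(87.7, 87.8, 83.6) + 40 * 2 / 3, sd = c(10.3, 12.7, 9.2)),
    DBP   = list(mean = c(87.7, 87.8, 83.6) - 40 / 3,     sd = c(10.3, 12.7, 9.2)),
    VE    = list(mean = c(8.9, 10.3, 10.2),    sd = c(3.2, 2.8, 1.8))
  )
  lapply(full, function(st) list(mean = st$mean[canon], sd = st$sd[canon]))
}

#' Generate a synthetic physiology cohort
#'
#' Produces a long-format tibble `(subject, day, variable, value)` with
#' repeated-measures structure (subject random intercepts), day-wise means
#' and SDs as configured, and planted `rvpd_au` / `rt_um` outcomes (see
#' [cohort_params()]). Sex is assigned deterministically (11 M / 7 F pattern
#' scaled to `n_subjects`) and carried as variable `male` (0/1).
#'
#' @param params a [cohort_params()] object.
#' @return A tibble with columns `subject`, `day`, `variable`, `value`.
#' @export
generate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  n <- params$n_subjects
  days <- params$days
  nd <- length(days)
  rho <- params$within_subject_sd
  subj <- sprintf("S%02d", seq_len(n))
  male <- as.numeric(seq_len(n) <= round(n * 11 / 18))

  withr::with_seed(derive_seed(params$seed, "cohort"), {
    rows <- list()
    for (v in names(params$day_stats)) {
      st <- params$day_stats[[v]]
      # subject intercept on a unit scale; per-day between-SD rescales it so
      # each day's total SD matches the configured value exactly in expectation
      u <- stats::rnorm(n)
      for (d in seq_len(nd)) {
        between <- sqrt(max(1 - rho^2, 0)) * st$sd[d]
        within <- rho * st$sd[d]
        val <- st$mean[d] + u * between + stats::rnorm(n, 0, within)
        rows[[length(rows) + 1]] <- tibble::tibble(
          subject = subj, day = days[d], variable = v, value = val)
      }
    }
    tbl <- dplyr::bind_rows(rows)

    # planted outcomes
    pao2 <- tbl$value[tbl$variable == "PaO2"]
    pao2_by <- matrix(pao2, nrow = n)           # n x nd, day-major fill
    u_rvpd <- stats::rnorm(n, 0, 0.35)
    u_rt <- stats::rnorm(n, 0, 12)
    out_rows <- list()
    for (d in seq_len(nd)) {
      rvpd <- 4.4 + params$rvpd_pao2_slope * (pao2_by[, d] - 84.8) +
        params$rvpd_day_offsets_au[d] + u_rvpd + stats::rnorm(n, 0, 0.15)
      rt <- params$rt_day_means_um[d] + u_rt + stats::rnorm(n, 0, 1.5)
      out_rows[[length(out_rows) + 1]] <- tibble::tibble(
        subject = subj, day = days[d], variable = "rvpd_au", value = rvpd)
      out_rows[[length(out_rows) + 1]] <- tibble::tibble(
        subject = subj, day = days[d], variable = "rt_um", value = rt)
    }
    sex_rows <- tibble::tibble(subject = subj, day = days[1], variable = "male",
                               value = male)
    dplyr::arrange(dplyr::bind_rows(tbl, out_rows, sex_rows),
                   .data$subject, .data$day, .data$variable)
  })
}
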
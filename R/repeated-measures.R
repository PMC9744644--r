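#' Repeated-measures correlation
#'
#' The common within-subject association between two repeatedly measured
#' variables: y is fit with subject-specific intercepts and one shared slope
#' (the ANCOVA parameterization), and
#' `r_rm = sign(slope) * sqrt(SS_x / (SS_x + SS_error))` where `SS_x` is the
#' sum of squares removed by x after adjusting for subject. Degrees of
#' freedom are `n_obs - n_subjects - 1`; the p value comes from the
#' corresponding `F(1, df)`.
#'
#' The estimator is computed in closed form on within-subject centred data
#' (equivalent to the ANCOVA normal equations): rows with missing x or y are
#' dropped, and every subject must contribute at least two complete pairs of
#' non-constant x.
#'
#' @param data a data frame with one row per observation.
#' @param subject,x,y bare column names (tidy evaluation).
#' @return An object of class `rmcorr_fit` with elements `r_rm`, `df`,
#'   `p_value`, `slope`, `n_subjects`, `n_obs`, `intercepts`, `data`.
#'   [generics::tidy()] and [generics::glance()] methods are provided.
#' @export
rmcorr <- function(data, subject, x, y) {
  sub <- as.character(dplyr::pull(data, {{ subject }}))
  xv <- as.numeric(dplyr::pull(data, {{ x }}))
  yv <- as.numeric(dplyr::pull(data, {{ y }}))
  keep <- stats::complete.cases(xv, yv) & !is.na(sub)
  sub <- sub[keep]; xv <- xv[keep]; yv <- yv[keep]
  counts <- table(sub)
  use <- sub %in% names(counts)[counts >= 2]
  sub <- sub[use]; xv <- xv[use]; yv <- yv[use]
  if (length(unique(sub)) < 2)
    stop("rmcorr needs >= 2 subjects with >= 2 complete pairs each", call. = FALSE)
  f <- factor(sub)
  xc <- xv - stats::ave(xv, f)
  yc <- yv - stats::ave(yv, f)
  ssx_within <- sum(xc^2)
  if (ssx_within <= .Machine$double.eps)
    stop("x is constant within every subject; rmcorr undefined", call. = FALSE)
  slope <- sum(xc * yc) / ssx_within
  ss_x <- slope^2 * ssx_within            # SS removed by x after subject
  ss_err <- sum((yc - slope * xc)^2)
  df <- length(xv) - nlevels(f) - 1L
  if (df < 1) stop("not enough residual degrees of freedom", call. = FALSE)
  r_rm <- sign(slope) * sqrt(ss_x / (ss_x + ss_err))
  fstat <- if (ss_err == 0) Inf else (ss_x / 1) / (ss_err / df)
  p <- stats::pf(fstat, 1, df, lower.tail = FALSE)
  intercepts <- tapply(yv, f, mean) - slope * tapply(xv, f, mean)
  structure(list(r_rm = r_rm, df = df, p_value = p, slope = slope,
                 n_subjects = nlevels(f), n_obs = length(xv),
                 intercepts = intercepts,
                 data = tibble::tibble(subject = sub, x = xv, y = yv)),
            class = "rmcorr_fit")
}

#' @export
print.rmcorr_fit <- function(x, ...) {
  cat(sprintf("Repeated-measures correlation: r_rm = %.3f, df = %d, p = %.3g\n",
              x$r_rm, x$df, x$p_value))
  invisible(x)
}

#' @rdname rmcorr
#' @param x an `rmcorr_fit`.
#' @param ... unused.
#' @export
tidy.rmcorr_fit <- function(x, ...) {
  tibble::tibble(term = c("common slope"), estimate = x$slope,
                 r_rm = x$r_rm, df = x$df, p.value = x$p_value)
}

#' @rdname rmcorr
#' @export
glance.rmcorr_fit <- function(x, ...) {
  tibble::tibble(r_rm = x$r_rm, df = x$df, p.value = x$p_value,
                 n_subjects = x$n_subjects, n_obs = x$n_obs)
}

#' Ordinary least-squares regression of y on x
#'
#' A thin tibble-first wrapper over [stats::lm()] reporting slope, intercept,
#' R^2 and the two-sided slope p value.
#'
#' @param data a data frame.
#' @param x,y bare column names.
#' @return A one-row tibble: `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
linregress <- function(data, x, y) {
  xv <- as.numeric(dplyr::pull(data, {{ x }}))
  yv <- as.numeric(dplyr::pull(data, {{ y }}))
  keep <- stats::complete.cases(xv, yv)
  xv <- xv[keep]; yv <- yv[keep]
  if (length(xv) < 3) stop("linregress needs >= 3 complete points", call. = FALSE)
  if (stats::sd(xv) == 0) stop("x has zero variance", call. = FALSE)
  fit <- stats::lm(yv ~ xv)
  sm <- summary(fit)
  tibble::tibble(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients[2, 4],
                 n = length(xv))
}

#' One-way repeated-measures ANOVA with Bonferroni pairwise comparisons
#'
#' Complete-case: subjects missing any day are dropped (with a message). The
#' standard subject/day/error decomposition is fit with [stats::aov()] using
#' an `Error(subject)` stratum; pairwise paired t-tests are Bonferroni
#' adjusted (`p * m`, capped at 1). Degenerate data with no day-to-day
#' variation yield `F = 0` and all pairwise p = 1.
#'
#' @param data a data frame.
#' @param subject,day,value bare column names.
#' @return An object of class `rm_anova`: `f_statistic`, `df`, `p_value`,
#'   `pairwise` (tibble with raw and adjusted p), `n_subjects`, `dropped`.
#'   `tidy()` and `glance()` methods are provided.
#' @export
rm_anova_bonferroni <- function(data, subject, day, value) {
  d <- tibble::tibble(subject = as.character(dplyr::pull(data, {{ subject }})),
                      day = as.character(dplyr::pull(data, {{ day }})),
                      value = as.numeric(dplyr::pull(data, {{ value }})))
  d <- dplyr::filter(d, !is.na(.data$value))
  days <- sort(unique(d$day))
  if (length(days) < 2) stop("need >= 2 days", call. = FALSE)
  complete <- dplyr::filter(dplyr::count(dplyr::distinct(d, .data$subject, .data$day),
                                         .data$subject), .data$n == length(days))
  dropped <- setdiff(unique(d$subject), complete$subject)
  if (length(dropped) > 0)
    message(sprintf("rm_anova: %d incomplete subject(s) dropped", length(dropped)))
  d <- dplyr::filter(d, .data$subject %in% complete$subject)
  if (length(unique(d$subject)) < 2) stop("need >= 2 complete subjects", call. = FALSE)
  d$subject <- factor(d$subject); d$day <- factor(d$day, levels = days)

  ss_day <- {
    grand <- mean(d$value)
    means <- tapply(d$value, d$day, mean)
    length(unique(d$subject)) * sum((means - grand)^2)
  }
  if (ss_day <= 1e-25) {
    fstat <- 0; p <- 1
    df <- c(length(days) - 1L,
            (length(days) - 1L) * (length(unique(d$subject)) - 1L))
  } else {
    fit <- stats::aov(value ~ day + Error(subject), data = d)
    tab <- summary(fit)[["Error: Within"]][[1]]
    fstat <- tab["day", "F value"]
    p <- tab["day", "Pr(>F)"]
    df <- c(tab["day", "Df"], tab["Residuals", "Df"])
  }

  wide <- tidyr::pivot_wider(d, names_from = "day", values_from = "value")
  prs <- utils::combn(days, 2, simplify = FALSE)
  m <- length(prs)
  pairwise <- purrr::map_dfr(prs, function(pr) {
    a <- wide[[pr[1]]]; b <- wide[[pr[2]]]
    diffs <- b - a
    raw <- if (stats::sd(diffs) == 0) 1 else stats::t.test(b, a, paired = TRUE)$p.value
    tibble::tibble(day_a = pr[1], day_b = pr[2], mean_diff = mean(diffs),
                   p_raw = raw, p_adjusted = min(1, raw * m))
  })
  structure(list(f_statistic = fstat, df = df, p_value = p, pairwise = pairwise,
                 n_subjects = length(unique(d$subject)), dropped = dropped),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("RM-ANOVA: F(%d, %d) = %.3f, p = %.3g; %d complete subjects\n",
              x$df[1], x$df[2], x$f_statistic, x$p_value, x$n_subjects))
  invisible(x)
}

#' @rdname rm_anova_bonferroni
#' @param x an `rm_anova` object.
#' @param ... unused.
#' @export
tidy.rm_anova <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(term = "day (main effect)", statistic = x$f_statistic,
                   df1 = x$df[1], df2 = x$df[2], p.value = x$p_value),
    dplyr::mutate(dplyr::rename(x$pairwise, p.value = "p_adjusted"),
                  term = paste("day", .data$day_a, "vs", .data$day_b),
                  statistic = NA_real_, df1 = NA_real_, df2 = NA_real_)[,
      c("term", "statistic", "df1", "df2", "p.value")]
  )
}

#' @rdname rm_anova_bonferroni
#' @export
glance.rm_anova <- function(x, ...) {
  tibble::tibble(f_statistic = x$f_statistic, df1 = x$df[1], df2 = x$df[2],
                 p.value = x$p_value, n_subjects = x$n_subjects)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
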
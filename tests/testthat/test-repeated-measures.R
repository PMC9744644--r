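# ---- rmcorr ----------------------------------------------------------------

test_that("subjects on parallel lines give |r_rm| = 1 with the slope's sign", {
  d <- tibble::tibble(subject = rep(c("A", "B", "C"), each = 3),
                      x = rep(1:3, 3),
                      y = c(1, 2, 3, 11, 12, 13, 5, 6, 7))
  up <- rmcorr(d, subject, x, y)
  expect_equal(up$r_rm, 1)
  expect_equal(up$slope, 1)
  down <- rmcorr(dplyr::mutate(d, y = -y), subject, x, y)
  expect_equal(down$r_rm, -1)
})

test_that("rmcorr matches the explicit normal-equations ANCOVA", {
  tbl <- generate_cohort(cohort_params(n_subjects = 30, seed = 5))
  w <- tidyr::pivot_wider(dplyr::filter(tbl, variable %in% c("PaO2", "rvpd_au")),
                          names_from = "variable", values_from = "value")
  fit <- rmcorr(w, subject, PaO2, rvpd_au)
  oracle <- rmcorr_normal_equations(w$subject, w$PaO2, w$rvpd_au)
  expect_equal(fit$r_rm, oracle$r_rm, tolerance = 1e-8)
  expect_equal(fit$slope, unname(oracle$slope), tolerance = 1e-8)
  expect_equal(fit$p_value, oracle$p, tolerance = 1e-8)
  expect_equal(fit$df, oracle$df)
})

test_that("rmcorr df follows total pairs minus subjects minus one", {
  d <- tibble::tibble(subject = rep(sprintf("S%d", 1:14), each = 2),
                      x = rnorm(28), y = rnorm(28))
  fit <- rmcorr(d, subject, x, y)
  expect_equal(fit$df, 28 - 14 - 1)
})

test_that("degenerate rmcorr inputs are rejected", {
  d <- tibble::tibble(subject = rep(c("A", "B"), each = 2),
                      x = c(1, 1, 2, 2), y = rnorm(4))
  expect_error(rmcorr(d, subject, x, y), "constant")
  single <- tibble::tibble(subject = "A", x = 1:4, y = rnorm(4))
  expect_error(rmcorr(single, subject, x, y), "subjects")
})

test_that("tidy and glance expose the fit in broom shape", {
  d <- tibble::tibble(subject = rep(c("A", "B", "C"), each = 3),
                      x = rep(1:3, 3), y = rnorm(9))
  fit <- rmcorr(d, subject, x, y)
  td <- tidy(fit); gl <- glance(fit)
  expect_true(all(c("estimate", "r_rm", "p.value") %in% names(td)))
  expect_equal(gl$n_subjects, 3)
})

# ---- linear regression -----------------------------------------------------

test_that("exact lines and hand-computed fits are reproduced", {
  d <- tibble::tibble(x = 1:6, y = 2 * (1:6))
  fit <- suppressWarnings(linregress(d, x, y))  # lm warns on a perfect fit
  expect_equal(fit$slope, 2)
  expect_equal(fit$r_squared, 1)
  # 5-point hand set: closed-form slope = Sxy/Sxx
  h <- tibble::tibble(x = c(1, 2, 3, 4, 5), y = c(2.1, 3.9, 6.2, 7.8, 10.1))
  sl <- sum((h$x - 3) * (h$y - mean(h$y))) / sum((h$x - 3)^2)
  fit2 <- linregress(h, x, y)
  expect_equal(fit2$slope, sl, tolerance = 1e-12)
  expect_equal(fit2$intercept, mean(h$y) - sl * 3, tolerance = 1e-12)
})

test_that("a null slope at large n gives near-zero R squared", {
  withr::with_seed(2, d <- tibble::tibble(x = rnorm(1e4), y = rnorm(1e4)))
  expect_lt(linregress(d, x, y)$r_squared, 0.01)
})

test_that("degenerate regression inputs error", {
  expect_error(linregress(tibble::tibble(x = c(1, 2), y = c(1, 2)), x, y), "3")
  expect_error(linregress(tibble::tibble(x = rep(1, 5), y = rnorm(5)), x, y),
               "variance")
})

# ---- RM-ANOVA --------------------------------------------------------------

test_that("no day-to-day variation gives F = 0 and unit pairwise p", {
  d <- tibble::tibble(subject = rep(c("A", "B", "C"), each = 3),
                      day = rep(c("0", "2", "9"), 3),
                      value = rep(c(5, 8, 11), each = 3))
  fit <- rm_anova_bonferroni(d, subject, day, value)
  expect_equal(fit$f_statistic, 0)
  expect_equal(fit$p_value, 1)
  expect_true(all(fit$pairwise$p_adjusted == 1))
})

test_that("a planted day effect far above noise is detected", {
  withr::with_seed(9, {
    n <- 18
    d <- tidyr::expand_grid(subject = sprintf("S%02d", 1:n), day = c("0", "2", "9"))
    shift <- c("0" = 0, "2" = 3, "9" = 1)
    d$value <- rnorm(nrow(d), 10 + shift[d$day], 0.5) + rep(rnorm(n), each = 3)
  })
  fit <- rm_anova_bonferroni(d, subject, day, value)
  expect_lt(fit$p_value, 0.001)
  expect_lt(fit$pairwise$p_adjusted[fit$pairwise$day_b == "2" &
                                      fit$pairwise$day_a == "0"], 0.001)
})

test_that("Bonferroni adjustment is raw p times the number of comparisons", {
  withr::with_seed(10, {
    d <- tidyr::expand_grid(subject = sprintf("S%02d", 1:10), day = c("0", "2", "9"))
    d$value <- rnorm(nrow(d), 10, 1)
  })
  fit <- rm_anova_bonferroni(d, subject, day, value)
  w <- tidyr::pivot_wider(d, names_from = "day", values_from = "value")
  raw02 <- t.test(w[["2"]], w[["0"]], paired = TRUE)$p.value
  row <- fit$pairwise[fit$pairwise$day_a == "0" & fit$pairwise$day_b == "2", ]
  expect_equal(row$p_raw, raw02, tolerance = 1e-12)
  expect_equal(row$p_adjusted, min(1, raw02 * 3), tolerance = 1e-12)
})

test_that("incomplete subjects are dropped with a message and the rest fit", {
  d <- tibble::tibble(subject = rep(c("A", "B", "C"), each = 2),
                      day = rep(c("0", "2"), 3),
                      value = c(1, 2, 1.5, 2.5, 3, NA))
  expect_message(fit <- rm_anova_bonferroni(d, subject, day, value), "dropped")
  expect_equal(fit$n_subjects, 2)
  expect_error(rm_anova_bonferroni(d[d$day == "0", ], subject, day, value), "2 days")
})
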
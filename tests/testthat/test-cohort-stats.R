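test_that("composites are standardized sums of standardized scores", {
  sc <- data.frame(a = c(1, 2, 3), b = c(10, 30, 20))
  comp <- build_composites(sc, list(mem = "a", exe = "b"))
  expect_equal(mean(comp$cognition_mem), 0, tolerance = 1e-12)
  expect_equal(sd(comp$cognition_mem), 1, tolerance = 1e-12)
  expect_equal(mean(comp$cognition_global), 0, tolerance = 1e-12)
  expect_equal(sd(comp$cognition_global), 1, tolerance = 1e-12)
  # single task (1,2,3) -> composite proportional to (-1, 0, 1)
  expect_equal(comp$cognition_mem, c(-1, 0, 1))
  # lower-is-better orientation reverses the sign
  rev <- build_composites(sc, list(mem = "a"), higher_better = c(a = FALSE))
  expect_equal(rev$cognition_mem, -comp$cognition_mem)
  expect_error(build_composites(data.frame(a = c(2, 2, 2)), list(m = "a")),
               "degenerate-score-error")
})

test_that("r2_beta reproduces the printed F / effect-size pairings", {
  expect_equal(r2_beta(14.15, 1, 95), 0.13, tolerance = 0.005 / 0.13)
  expect_equal(r2_beta(8.16, 1, 95), 0.079, tolerance = 0.005 / 0.079)
  expect_equal(r2_beta(0, 1, 95), 0)
  expect_true(all(r2_beta(c(0.3, 3, 30), 2, 100) >= 0 &
                  r2_beta(c(0.3, 3, 30), 2, 100) < 1))
})

test_that("Cook's distance scan flags gross outliers and only those", {
  # simple regression with one gross outlier: its distance dominates
  x <- c(1, 2, 3, 4, 5)
  y <- c(1.1, 1.9, 3.2, 4.0, 15)
  fit <- lm(y ~ x)
  sc <- cooks_outlier_scan(fit)
  expect_equal(unname(which.max(sc$distances)), 5L)
  expect_gt(sc$max, 1)
  expect_equal(sc$flags, c("5" = 5L))
  # hand computation via the leverage/residual formula for point 5
  h <- hatvalues(fit)[5]
  r <- resid(fit)[5]
  s2 <- sum(resid(fit)^2) / fit$df.residual
  d5 <- r^2 / (2 * s2) * h / (1 - h)^2
  expect_equal(unname(sc$distances[5]), unname(d5))
  # well-behaved data: all below 0.4, nothing flagged
  set.seed(81)
  fit2 <- lm(y2 ~ x2, data.frame(x2 = 1:50, y2 = 1:50 + rnorm(50, 0, 2)))
  sc2 <- cooks_outlier_scan(fit2)
  expect_lt(sc2$max, 0.4)
  expect_equal(sc2$n_flagged, 0L)
})

test_that("spearman correlation handles ties like the midrank formula", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_cor(x, x)$r, 1)
  expect_equal(spearman_cor(x, -x)$r, -1)
  set.seed(82)
  xt <- sample(1:4, 30, replace = TRUE)
  yt <- xt + sample(0:2, 30, replace = TRUE)
  expect_equal(spearman_cor(xt, yt)$r, bf_spearman(xt, yt))
  expect_error(spearman_cor(rep(1, 10), rnorm(10)), "zero-variance")
  expect_error(spearman_cor(1:2, 2:1), "at least 3")
})

test_that("the amyloid model recovers planted slope signs and structure", {
  co <- simulate_cohort(cohort_config(seed = 21, n_subjects = 100))
  m <- fit_abeta_model(co)
  expect_s3_class(m, "arousal_model")
  expect_lt(coef(m$fit)[["dens_TmMp"]], 0)
  expect_gt(coef(m$fit)[["dens_TpMm"]], 0)
  expect_equal(m$anova$DenDF, rep(95, 4))        # n=100, 5 parameters
  expect_equal(m$anova$R2_beta,
               r2_beta(m$anova$F, m$anova$NumDF, m$anova$DenDF))
  expect_true(all(m$anova$p >= 0 & m$anova$p <= 1))
  expect_gt(m$contrasts$t, 0)                    # T+M- slope above T-M+
  expect_lt(m$diagnostics$max_cook, 1)
  # duplicating every subject leaves point estimates unchanged,
  # and strict mode refuses duplicate ids
  co2 <- rbind(co, co)
  m2 <- fit_abeta_model(co2)
  expect_equal(coef(m2$fit), coef(m$fit))
  expect_error(fit_abeta_model(co2, strict = TRUE), "duplicate-id")
  # all-four-types variant fits and keeps the headline signs
  m4 <- fit_abeta_model(co, all_types = TRUE)
  expect_lt(coef(m4$fit)[["dens_TmMp"]], 0)
})

test_that("the cognition model finds the planted attention association", {
  co <- simulate_cohort(cohort_config(seed = 22, n_subjects = 100))
  ma <- fit_cognition_model(co, "attention")
  expect_true("education" %in% ma$anova$term)
  expect_gt(coef(ma$fit)[["dens_TmMp"]], 0)
  mg <- fit_cognition_model(co, "global")
  expect_equal(mg$anova$DenDF, rep(94, 5))       # education adds a parameter
})

test_that("the density mixed model reports the full factorial with effect sizes", {
  co <- simulate_cohort(cohort_config(seed = 23, n_subjects = 60))
  m <- suppressMessages(fit_density_model(co))
  expect_true(all(c("t_status", "m_status", "t_status:m_status",
                    "t_status:m_status:abeta_z") %in% m$anova$term))
  expect_true(m$family %in% c("normal", "lognormal", "gamma"))
  # the type cells genuinely differ in the generator
  expect_lt(m$anova$p[m$anova$term == "t_status:m_status"], 0.01)
  expect_equal(m$anova$R2_beta,
               r2_beta(m$anova$F, m$anova$NumDF, m$anova$DenDF))
  # Tukey adjustment never reduces a p value below its unadjusted version
  em <- emmeans::emmeans(m$fit, ~ t_status:m_status)
  raw <- as.data.frame(emmeans::contrast(em, "pairwise", adjust = "none"))
  adj <- as.data.frame(emmeans::contrast(em, "pairwise", adjust = "tukey"))
  expect_true(all(adj$p.value >= raw$p.value - 1e-12))
})

test_that("rescaling a normal-family response leaves F statistics unchanged", {
  co <- simulate_cohort(cohort_config(seed = 24, n_subjects = 40))
  m1 <- suppressMessages(fit_density_model(co, family = "normal"))
  co2 <- co
  for (cl in c("dens_TpMp", "dens_TpMm", "dens_TmMp", "dens_TmMm")) {
    co2[[cl]] <- co2[[cl]] * 7
  }
  m2 <- suppressMessages(fit_density_model(co2, family = "normal"))
  expect_equal(m1$anova$F, m2$anova$F, tolerance = 1e-6)
})

test_that("the relative-power model detects planted band-by-type structure", {
  pr <- simulate_spectral_profiles(60, seed = 25,
                                   effects = list("T+M-" = c(theta = 0.08),
                                                  "T-M+" = c(beta = 0.08)))
  m <- fit_relpower_model(pr)
  i3 <- m$anova$term == "t_status:m_status:band"
  expect_lt(m$anova$p[i3], 0.05)
  expect_true(all(c("contrast", "band") %in% names(m$contrasts)))
  # null profiles: the same design symmetry, no detectable interaction signal
  pr0 <- simulate_spectral_profiles(60, seed = 26)
  m0 <- fit_relpower_model(pr0)
  expect_gt(m0$anova$p[m0$anova$term == "t_status:m_status:band"], 0.001)
})

test_that("family selection prefers the generating distribution", {
  set.seed(27)
  # responses crossing zero admit only the normal candidate
  expect_equal(select_family(rnorm(400, 2, 2))$family, "normal")
  expect_equal(select_family(rlnorm(400, 0, 0.8))$family, "lognormal")
  expect_equal(select_family(rgamma(400, shape = 2, rate = 1))$family,
               "gamma")
})
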
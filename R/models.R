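#' Semipartial R-squared effect size for a fixed effect
#'
#' The standard semipartial formulation for mixed-model F tests:
#' `R2_beta = (q * F) / (q * F + df2)` with `q` the numerator degrees of
#' freedom of the term's F statistic and `df2` its denominator degrees of
#' freedom. `F = 0` gives 0; the value lies in `[0, 1)`.
#'
#' @param f F statistic (vectorized).
#' @param df1 numerator df.
#' @param df2 denominator df.
#' @return effect size in `[0, 1)`.
#' @examples
#' r2_beta(14.15, 1, 95)   # ~ 0.13
#' r2_beta(8.16, 1, 95)    # ~ 0.079
#' @export
r2_beta <- function(f, df1, df2) {
  stopifnot(all(df1 > 0), all(df2 > 0), all(f >= 0))
  (df1 * f) / (df1 * f + df2)
}

#' Cook's distance outlier scan
#'
#' Standard per-observation Cook's distances for a fixed-effects fit, with
#' the conventional flag threshold of 1.
#'
#' @param fit an `lm` fit (or any object with a [cooks.distance()]
#'   method).
#' @param threshold flag threshold (default 1).
#' @return list: `distances`, `flags`, `max`, `n_flagged`, `threshold`.
#' @export
cooks_outlier_scan <- function(fit, threshold = 1) {
  d <- stats::cooks.distance(fit)
  flags <- which(d > threshold)
  list(distances = d, flags = flags, max = max(d), n_flagged = length(flags),
       threshold = threshold)
}

#' Spearman rank correlation with midrank ties
#'
#' @param x,y equal-length numeric vectors, `n >= 3`, non-degenerate.
#' @return list: `r`, `p` (two-sided), `n`.
#' @export
spearman_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("spearman correlation undefined for zero-variance input")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Candidate response-distribution selection
#'
#' Scores a fixed candidate set (normal, log-normal, gamma) on the
#' response by AIC; the non-normal candidates are only eligible when the
#' response is strictly positive. An unbounded distribution scan is not
#' reproducible; this documented set covers the non-negative right-skewed
#' shapes arousal densities take.
#'
#' @param y numeric response.
#' @return list: `family` (name), `aic` (named vector).
#' @export
select_family <- function(y) {
  aics <- c(normal = tryCatch(
    fitdistrplus::fitdist(y, "norm")$aic, error = function(e) NA_real_))
  if (all(y > 0)) {
    aics["lognormal"] <- tryCatch(
      fitdistrplus::fitdist(y, "lnorm")$aic, error = function(e) NA_real_)
    aics["gamma"] <- tryCatch(
      fitdistrplus::fitdist(y, "gamma", lower = c(0, 0))$aic,
      error = function(e) NA_real_)
  }
  fam <- names(aics)[which.min(aics)]
  list(family = fam, aic = aics)
}

r2_from_anova <- function(tab) {
  tab$R2_beta <- r2_beta(tab$F, tab$NumDF, tab$DenDF)
  tab
}

# anova table of an lm as (term, NumDF, DenDF, F, p) with type-II F tests
lm_anova_table <- function(fit) {
  a <- car::Anova(fit, type = 2)
  res_df <- a["Residuals", "Df"]
  terms <- setdiff(rownames(a), "Residuals")
  tab <- data.frame(term = terms, NumDF = a[terms, "Df"], DenDF = res_df,
                    F = a[terms, "F value"], p = a[terms, "Pr(>F)"])
  rownames(tab) <- NULL
  r2_from_anova(tab)
}

new_arousal_model <- function(model_id, fit, family, ddf, anova, contrasts,
                              diagnostics, convergence = TRUE,
                              notes = character()) {
  structure(list(model_id = model_id, fit = fit, family = family, ddf = ddf,
                 anova = anova, contrasts = contrasts,
                 diagnostics = diagnostics, convergence = convergence,
                 notes = notes),
            class = "arousal_model")
}

#' @export
print.arousal_model <- function(x, ...) {
  cat("<arousal_model> ", x$model_id, " (family: ", x$family,
      ", ddf: ", x$ddf, ")\n", sep = "")
  tab <- x$anova
  tab$F <- round(tab$F, 2); tab$p <- signif(tab$p, 3)
  tab$R2_beta <- round(tab$R2_beta, 3)
  print(tab, row.names = FALSE)
  if (!is.null(x$contrasts) && nrow(x$contrasts)) {
    cat("contrasts:\n"); print(x$contrasts, row.names = FALSE)
  }
  if (!is.null(x$diagnostics$max_cook)) {
    cat(sprintf("max Cook's distance: %.3f (%d flagged > %g)\n",
                x$diagnostics$max_cook, x$diagnostics$n_flagged,
                x$diagnostics$threshold))
  }
  if (!x$convergence) cat("NOTE: model did not converge cleanly\n")
  if (length(x$notes)) cat(paste0("note: ", x$notes, "\n"))
  invisible(x)
}

check_cohort <- function(cohort, min_n = 10L, strict = FALSE) {
  if (anyDuplicated(cohort$subject_id)) {
    if (strict) stop("duplicate-id error: subject ids are not unique")
  }
  if (nrow(cohort) < min_n) {
    stop("need at least ", min_n, " subjects for model fitting")
  }
  invisible(TRUE)
}

#' Amyloid-burden association model
#'
#' Linear model of amyloid burden (Centiloid) on the T-M+ and T+M- arousal
#' densities, adjusting for age and sex (one observation per subject, so
#' the subject random intercept degenerates and a fixed-effects fit is
#' exact). Reports type-II F tests with semipartial R2, a contrast
#' comparing the two standardized arousal slopes, and a Cook's-distance
#' outlier scan. `all_types = TRUE` fits the supplementary variant with
#' all four density terms.
#'
#' @param cohort a `cohort_table` (needs `abeta_centiloid`, densities,
#'   `age`, `sex`).
#' @param all_types include all four arousal types (default `FALSE`).
#' @param strict error on duplicated subject ids (default `FALSE`).
#' @return an `arousal_model`.
#' @export
fit_abeta_model <- function(cohort, all_types = FALSE, strict = FALSE) {
  check_cohort(cohort, strict = strict)
  dens_terms <- if (all_types) {
    c("dens_TmMp", "dens_TpMm", "dens_TpMp", "dens_TmMm")
  } else c("dens_TmMp", "dens_TpMm")
  fml <- stats::as.formula(paste("abeta_centiloid ~",
                                 paste(c(dens_terms, "age", "sex"),
                                       collapse = " + ")))
  fit <- stats::lm(fml, data = cohort)

  X <- stats::model.matrix(fit)
  kappa_x <- kappa(X, exact = TRUE)
  notes <- character()
  if (kappa_x > 1e6) {
    notes <- c(notes, sprintf("collinearity warning: condition number %.3g",
                              kappa_x))
    warning("collinear predictors (condition number ", signif(kappa_x, 3), ")")
  }

  # standardized-slope contrast between the two headline density terms
  d <- cohort
  d$z_TmMp <- as.numeric(scale(d$dens_TmMp))
  d$z_TpMm <- as.numeric(scale(d$dens_TpMm))
  fml_z <- stats::as.formula(paste("abeta_centiloid ~ z_TmMp + z_TpMm +",
                                   paste(c(setdiff(dens_terms,
                                                   c("dens_TmMp", "dens_TpMm")),
                                           "age", "sex"), collapse = " + ")))
  fit_z <- stats::lm(fml_z, data = d)
  L <- rep(0, length(coef(fit_z)))
  L[match(c("z_TpMm", "z_TmMp"), names(coef(fit_z)))] <- c(1, -1)
  est <- sum(L * coef(fit_z))
  se <- sqrt(drop(t(L) %*% stats::vcov(fit_z) %*% L))
  df <- stats::df.residual(fit_z)
  tval <- est / se
  contrasts <- data.frame(
    contrast = "std slope: T+M- minus T-M+", estimate = est, se = se,
    t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))

  ck <- cooks_outlier_scan(fit)
  new_arousal_model("abeta ~ arousal densities + age + sex", fit, "normal",
                    "residual", lm_anova_table(fit), contrasts,
                    list(max_cook = ck$max, n_flagged = ck$n_flagged,
                         threshold = ck$threshold, cooks = ck$distances),
                    notes = notes)
}

#' Cognition association model
#'
#' Linear model of a standardized cognition composite on the T-M+ and
#' T+M- arousal densities, adjusting for age, sex and education.
#'
#' @param cohort a `cohort_table` with `cognition_*` columns.
#' @param response `"global"`, `"attention"`, `"executive"` or
#'   `"memory"`.
#' @param strict error on duplicated subject ids.
#' @return an `arousal_model`.
#' @export
fit_cognition_model <- function(cohort,
                                response = c("global", "attention",
                                             "executive", "memory"),
                                strict = FALSE) {
  response <- match.arg(response)
  check_cohort(cohort, strict = strict)
  col <- paste0("cognition_", response)
  stopifnot(col %in% names(cohort))
  fml <- stats::as.formula(paste(col,
                                 "~ dens_TmMp + dens_TpMm + age + sex + education"))
  fit <- stats::lm(fml, data = cohort)
  ck <- cooks_outlier_scan(fit)
  new_arousal_model(paste0("cognition_", response,
                           " ~ arousal densities + age + sex + education"),
                    fit, "normal", "residual", lm_anova_table(fit), NULL,
                    list(max_cook = ck$max, n_flagged = ck$n_flagged,
                         threshold = ck$threshold, cooks = ck$distances))
}

fit_lmm <- function(fml, data, family, ddf) {
  notes <- character(); convergence <- TRUE
  if (family == "lognormal") {
    data$.y <- log(data$.y)
    family <- "normal"
    notes <- c(notes, "log-normal family: LMM fitted on log response")
  }
  if (family == "gamma") {
    gfit <- withCallingHandlers(
      tryCatch(lme4::glmer(fml, data = data,
                           family = stats::Gamma(link = "log")),
               error = function(e) e),
      warning = function(w) invokeRestart("muffleWarning"))
    bad <- inherits(gfit, "error") ||
      length(unlist(gfit@optinfo$conv$lme4$messages)) > 0
    if (!bad) {
      a <- car::Anova(gfit, type = 3)
      terms <- setdiff(rownames(a), "(Intercept)")
      den <- stats::nobs(gfit) - length(lme4::fixef(gfit))
      tab <- data.frame(term = terms, NumDF = a[terms, "Df"], DenDF = den,
                        F = a[terms, "Chisq"] / a[terms, "Df"],
                        p = a[terms, "Pr(>Chisq)"])
      rownames(tab) <- NULL
      notes <- c(notes,
                 "gamma GLMM: Wald chi-square tests converted to F scale")
      return(list(fit = gfit, tab = r2_from_anova(tab), family = "gamma",
                  notes = notes, convergence = TRUE))
    }
    notes <- c(notes,
               "gamma GLMM failed to converge; fell back to LMM on log1p response")
    data$.y <- log1p(data$.y)
    family <- "normal"
  }
  fit <- lmerTest::lmer(fml, data = data)
  a <- stats::anova(fit, ddf = ddf)
  tab <- data.frame(term = rownames(a), NumDF = a$NumDF, DenDF = a$DenDF,
                    F = a[["F value"]], p = a[["Pr(>F)"]])
  rownames(tab) <- NULL
  list(fit = fit, tab = r2_from_anova(tab), family = family, notes = notes,
       convergence = convergence)
}

#' Arousal-density mixed model
#'
#' Mixed model of per-type arousal density (four rows per subject, subject
#' random intercept) on transition status, EMG status and standardized
#' amyloid burden with all their interactions, plus age and sex. The
#' response distribution is chosen from the documented candidate set by
#' AIC ([select_family()]); a gamma selection that fails to converge falls
#' back to a normal LMM on `log1p(density)` with a recorded note. F tests
#' use Satterthwaite (default) or Kenward-Roger denominator dfs, and Tukey
#' post hoc contrasts compare the four type cells.
#'
#' @param cohort a `cohort_table`.
#' @param ddf `"Satterthwaite"` (default) or `"Kenward-Roger"`.
#' @param family `"auto"` (default) or one of `"normal"`, `"lognormal"`,
#'   `"gamma"`.
#' @param strict error on duplicated subject ids.
#' @return an `arousal_model`.
#' @export
fit_density_model <- function(cohort, ddf = c("Satterthwaite",
                                              "Kenward-Roger"),
                              family = "auto", strict = FALSE) {
  ddf <- match.arg(ddf)
  check_cohort(cohort, strict = strict)
  long <- do.call(rbind, lapply(list(
    c("T+", "M+", "dens_TpMp"), c("T+", "M-", "dens_TpMm"),
    c("T-", "M+", "dens_TmMp"), c("T-", "M-", "dens_TmMm")),
    function(x) data.frame(subject_id = cohort$subject_id,
                           t_status = x[1], m_status = x[2],
                           .y = cohort[[x[3]]], age = cohort$age,
                           sex = cohort$sex,
                           abeta_z = as.numeric(scale(cohort$abeta_centiloid)))))
  long$t_status <- factor(long$t_status); long$m_status <- factor(long$m_status)
  if (family == "auto") family <- select_family(long$.y)$family
  fml <- .y ~ t_status * m_status * abeta_z + age + sex + (1 | subject_id)
  res <- fit_lmm(fml, long, family, ddf)
  em <- emmeans::emmeans(res$fit, ~ t_status:m_status)
  pairs_tab <- as.data.frame(emmeans::contrast(em, "pairwise",
                                               adjust = "tukey"))
  new_arousal_model("density ~ T * M * abeta + age + sex + (1|subject)",
                    res$fit, res$family, ddf, res$tab, pairs_tab,
                    list(), convergence = res$convergence,
                    notes = res$notes)
}

#' Arousal spectral-composition mixed model
#'
#' Mixed model of relative band power (long table from
#' [type_relative_power()] or [simulate_spectral_profiles()]) on
#' transition status, EMG status and frequency band with all interactions
#' and a subject random intercept; Tukey post hocs compare arousal types
#' within each band. Subjects missing a type are retained with the rows
#' they have; rows with missing power are dropped with a message.
#'
#' @param profiles long data frame: `subject_id`, `type` (or `t_status` +
#'   `m_status`), `band`, `rel_power`.
#' @param ddf `"Satterthwaite"` or `"Kenward-Roger"`.
#' @return an `arousal_model`.
#' @export
fit_relpower_model <- function(profiles, ddf = c("Satterthwaite",
                                                 "Kenward-Roger")) {
  ddf <- match.arg(ddf)
  d <- as.data.frame(profiles)
  if (!all(c("t_status", "m_status") %in% names(d))) {
    d$t_status <- substr(d$type, 1, 2)
    d$m_status <- substr(d$type, 3, 4)
  }
  drop <- !stats::complete.cases(d[, c("rel_power", "t_status", "m_status",
                                       "band")])
  if (any(drop)) {
    message("dropping ", sum(drop), " incomplete profile row(s)")
    d <- d[!drop, ]
  }
  if (length(unique(d$subject_id)) < 10L) stop("need >= 10 subjects")
  d$t_status <- factor(d$t_status); d$m_status <- factor(d$m_status)
  d$band <- factor(d$band)
  d$.y <- d$rel_power
  res <- fit_lmm(.y ~ t_status * m_status * band + (1 | subject_id), d,
                 "normal", ddf)
  em <- emmeans::emmeans(res$fit, ~ t_status:m_status | band)
  pairs_tab <- as.data.frame(emmeans::contrast(em, "pairwise",
                                               adjust = "tukey"))
  new_arousal_model("rel_power ~ T * M * band + (1|subject)", res$fit,
                    res$family, ddf, res$tab, pairs_tab, list(),
                    convergence = res$convergence, notes = res$notes)
}
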
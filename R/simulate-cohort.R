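#' Cohort simulation configuration
#'
#' Generates subject-level data with a configurable arousal-to-amyloid and
#' arousal-to-cognition effect structure: amyloid burden (Centiloid) falls
#' with T-M+ density and rises with T+M- density by default, and the T-M+
#' index improves attentional performance. Baseline densities make T-M+
#' the most prevalent type, with midlife demographics (age 59 +/- 5 y,
#' two-thirds women) and a low mean Centiloid typical of a healthy
#' late-midlife cohort.
#'
#' @param seed integer seed.
#' @param n_subjects number of subjects (>= 4 for model fitting; the
#'   generator itself accepts any n >= 2).
#' @param age_mean,age_sd,age_range age distribution (years; truncated
#'   normal).
#' @param sex_ratio_f proportion of women.
#' @param education_mean,education_sd years of education.
#' @param density_means,density_sds events/h per type, truncated > 0.
#' @param beta_abeta_TmMp Centiloid change per unit T-M+ density
#'   (default -2.3; with the default density and residual SDs this puts
#'   the semipartial R2 of the term near 0.13 at n = 100).
#' @param beta_abeta_TpMm Centiloid change per unit T+M- density
#'   (default +4.5, targeting a semipartial R2 near 0.08).
#' @param beta_age_abeta Centiloid per year of age (default 0.8).
#' @param abeta_intercept,abeta_sd Centiloid intercept and residual SD.
#' @param beta_cog named per-domain raw-score change per unit T-M+
#'   density; default concentrates the effect on attention.
#' @param beta_edu_cog raw-score change per year of education.
#' @param cog_sd residual SD of raw domain scores.
#' @param waso_meanlog,waso_sdlog log-normal WASO minutes.
#' @param awakening_rate mean awakenings per night (Poisson).
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(seed = 1L, n_subjects = 100L,
                          age_mean = 59, age_sd = 5, age_range = c(50, 70),
                          sex_ratio_f = 0.67,
                          education_mean = 14, education_sd = 3,
                          density_means = c("T+M+" = 2, "T+M-" = 1.5,
                                            "T-M+" = 5, "T-M-" = 1),
                          density_sds = c("T+M+" = 1, "T+M-" = 0.8,
                                          "T-M+" = 2, "T-M-" = 0.6),
                          beta_abeta_TmMp = -2.3, beta_abeta_TpMm = 4.5,
                          beta_age_abeta = 0.8,
                          abeta_intercept = 6, abeta_sd = 12,
                          beta_cog = c(attention = 0.2, executive = 0,
                                       memory = 0),
                          beta_edu_cog = 0.3, cog_sd = 2,
                          waso_meanlog = 3.4, waso_sdlog = 0.5,
                          awakening_rate = 4) {
  if (n_subjects < 2L) stop("n_subjects must be >= 2")
  structure(as.list(environment()), class = "cohort_config")
}

rtruncnorm_pos <- function(n, mean, sd, lower = 0) {
  lo <- stats::pnorm(lower, mean, sd)
  stats::qnorm(stats::runif(n, lo, 1), mean, sd)
}

#' Simulate a subject cohort
#'
#' Two modes. `"statistical"` (default, fast) draws per-subject arousal
#' densities directly around the configured baselines; `"psg"` (end to
#' end) simulates a short synthetic night per subject with
#' [simulate_psg()], runs [detect_arousals()] and [classify_events()] and
#' uses the measured densities. Amyloid burden, fragmentation metrics and
#' raw domain scores are then generated from the configured effect
#' structure, and standardized cognition composites are appended via
#' [build_composites()]. All generating parameters are stored in
#' `attr(x, "params")` for recovery tests.
#'
#' @param config a [cohort_config()].
#' @param mode `"statistical"` or `"psg"`.
#' @param psg_config a [sim_config()] template for `"psg"` mode (its seed
#'   is re-derived per subject); default a 1-h night with 2 events per
#'   type.
#' @return data frame of class `cohort_table`, one row per subject.
#' @export
simulate_cohort <- function(config = cohort_config(),
                            mode = c("statistical", "psg"),
                            psg_config = NULL) {
  mode <- match.arg(mode)
  set.seed(config$seed)
  n <- config$n_subjects
  age <- pmin(pmax(rnorm(n, config$age_mean, config$age_sd),
                   config$age_range[1]), config$age_range[2])
  sex <- factor(ifelse(runif(n) < config$sex_ratio_f, "F", "M"),
                levels = c("F", "M"))
  edu <- pmax(round(rnorm(n, config$education_mean, config$education_sd)), 6)

  if (mode == "statistical") {
    dens <- sapply(ASCAPE_TYPES, function(ty) {
      rtruncnorm_pos(n, config$density_means[[ty]], config$density_sds[[ty]])
    })
    waso_min <- stats::rlnorm(n, config$waso_meanlog, config$waso_sdlog)
    n_awake <- stats::rpois(n, config$awakening_rate)
  } else {
    psg_config <- psg_config %||%
      sim_config(duration_h = 1,
                 n_per_type = c("T+M+" = 2L, "T+M-" = 2L,
                                "T-M+" = 2L, "T-M-" = 2L))
    sub_seeds <- sample.int(.Machine$integer.max, n)
    rows <- lapply(seq_len(n), function(i) {
      cfg <- psg_config
      cfg$seed <- sub_seeds[i]
      sim <- simulate_psg(cfg, subject_id = sprintf("s%03d", i))
      ev <- detect_arousals(sim$recording, sim$hypnogram)
      bp_emg <- emg_tone_flags(emg_signal(sim$recording),
                               sim$recording$sampling_rate)
      ev <- classify_events(ev, sim$hypnogram, bp_emg)
      sleep_metrics(ev, sim$hypnogram)
    })
    m <- do.call(rbind, rows)
    dens <- as.matrix(m[, c("dens_TpMp", "dens_TpMm", "dens_TmMp",
                            "dens_TmMm")])
    colnames(dens) <- ASCAPE_TYPES
    waso_min <- m$waso_min
    n_awake <- m$n_awakenings
  }

  abeta <- config$abeta_intercept +
    config$beta_age_abeta * (age - config$age_mean) +
    config$beta_abeta_TmMp * dens[, "T-M+"] +
    config$beta_abeta_TpMm * dens[, "T+M-"] +
    rnorm(n, sd = config$abeta_sd)

  raw <- sapply(c("attention", "executive", "memory"), function(dom) {
    10 + config$beta_edu_cog * (edu - config$education_mean) +
      config$beta_cog[[dom]] * dens[, "T-M+"] +
      rnorm(n, sd = config$cog_sd)
  })

  out <- data.frame(
    subject_id = sprintf("s%03d", seq_len(n)),
    age = age, sex = sex, education = edu,
    dens_TpMp = dens[, "T+M+"], dens_TpMm = dens[, "T+M-"],
    dens_TmMp = dens[, "T-M+"], dens_TmMm = dens[, "T-M-"],
    abeta_centiloid = abeta,
    waso_min = waso_min, n_awakenings = n_awake,
    attention_raw = raw[, "attention"], executive_raw = raw[, "executive"],
    memory_raw = raw[, "memory"])
  comp <- build_composites(out, domain_map = list(
    attention = "attention_raw", executive = "executive_raw",
    memory = "memory_raw"))
  out <- cbind(out, comp)
  attr(out, "params") <- config
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Simulate per-subject spectral profiles of arousal types
#'
#' Fast statistical generator of the long relative-power table consumed by
#' [fit_relpower_model()]: per subject, type and band, a baseline band
#' share plus an optional type-by-band effect and subject-level noise,
#' clipped to the unit interval. Under `effects = NULL` all types share
#' one spectrum (the null generator for calibration work).
#'
#' @param n_subjects number of subjects.
#' @param seed integer seed.
#' @param base_shares named baseline shares for theta/alpha/beta.
#' @param effects optional list `type -> named band deltas`, e.g.
#'   `list("T+M-" = c(theta = 0.1), "T-M+" = c(beta = 0.1))`.
#' @param subject_sd,noise_sd random-intercept and residual SDs.
#' @return data frame: `subject_id`, `type`, `band`, `rel_power`.
#' @export
simulate_spectral_profiles <- function(n_subjects = 100L, seed = 1L,
                                       base_shares = c(theta = 0.25,
                                                       alpha = 0.2,
                                                       beta = 0.3),
                                       effects = NULL,
                                       subject_sd = 0.03, noise_sd = 0.05) {
  set.seed(seed)
  grid <- expand.grid(subject_id = sprintf("s%03d", seq_len(n_subjects)),
                      type = ASCAPE_TYPES, band = names(base_shares),
                      stringsAsFactors = FALSE)
  mu <- base_shares[grid$band]
  if (!is.null(effects)) {
    for (ty in names(effects)) {
      for (bd in names(effects[[ty]])) {
        sel <- grid$type == ty & grid$band == bd
        mu[sel] <- mu[sel] + effects[[ty]][[bd]]
      }
    }
  }
  u <- rnorm(n_subjects, sd = subject_sd)
  names(u) <- sprintf("s%03d", seq_len(n_subjects))
  grid$rel_power <- pmin(pmax(mu + u[grid$subject_id] +
                                rnorm(nrow(grid), sd = noise_sd), 0), 1)
  grid
}
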
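# Synthetic survival cohort with known proportional-hazards structure.

#' Default cancer-type mix of the simulated cohort
#'
#' Category counts of the emulated 526-patient anti-angiogenic cohort:
#' renal cell carcinoma 204, colorectal 93, hepatocellular 72, GIST 56,
#' melanoma 42, breast 27, others 32.
#' @return Named integer vector summing to 526.
#' @export
default_category_counts <- function() {
  c(renal = 204L, colorectal = 93L, hcc = 72L, gist = 56L,
    melanoma = 42L, breast = 27L, other = 32L)
}

# Marginal mean/SD targets for the lognormal body-composition covariates
# (kg/m2 for 3D masses, cm2/m2 for L3 areas) and the log-scale correlation
# between each 2D measure and its 3D counterpart.
.covariate_targets <- list(
  VFM3D = c(mean = 0.85, sd = 0.62),
  SFM3D = c(mean = 4.18, sd = 2.27),
  MBM3D = c(mean = 5.74, sd = 1.35),
  VFA2D = c(mean = 36.85, sd = 30.86),
  SFA2D = c(mean = 53.14, sd = 30.86),
  MBA2D = c(mean = 45.00, sd = 12.00))
.pair_correlations <- c(visceral = 0.96, subcutaneous = 0.86, muscle = 0.85)

#' Configure the cohort simulator
#'
#' The simulator draws body-composition covariates from sex-shifted
#' lognormals (males +20% muscle, -15% subcutaneous fat), generates event
#' times from an exponential proportional-hazards model
#' `hazard = baseline_hazard * exp(sum(log_hazard_ratios * covariate))`,
#' and censors with an independent exponential plus an administrative
#' horizon. Category and sex counts are met exactly (permutation of fixed
#' labels, not multinomial draws).
#'
#' @param n Number of patients.
#' @param category_counts Named integer vector of cancer-type counts; must
#'   sum to `n`.
#' @param sex_counts Named counts for `male` and `female`; must sum to `n`.
#' @param baseline_hazard Event hazard per month at covariate value zero.
#' @param log_hazard_ratios Named vector of log hazard ratios per unit of
#'   the matching covariate column. Defaults reflect a protective visceral
#'   fat/muscle effect.
#' @param censoring_rate Random right-censoring hazard per month (0 = none).
#' @param admin_censor_months Administrative censoring horizon (months;
#'   `Inf` to disable).
#' @param seed Integer seed.
#' @return A `cohort_sim_config` object.
#' @export
cohort_sim_config <- function(n = 526L,
                              category_counts = default_category_counts(),
                              sex_counts = c(male = 377L, female = 149L),
                              baseline_hazard = 0.10,
                              log_hazard_ratios = c(
                                VFM3D = log(0.55), SFM3D = log(0.98),
                                MBM3D = log(0.93),
                                line_of_treatment = log(0.88)),
                              censoring_rate = 0.01,
                              admin_censor_months = 60,
                              seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n <= 0 || n != round(n)) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  if (sum(category_counts) != n) {
    stop("`category_counts` must sum to n (", n, ")", call. = FALSE)
  }
  if (sum(sex_counts) != n || !all(c("male", "female") %in% names(sex_counts))) {
    stop("`sex_counts` must name male and female and sum to n", call. = FALSE)
  }
  stop_if_not_scalar_pos(baseline_hazard, "baseline_hazard")
  stop_if_not_scalar_pos(censoring_rate, "censoring_rate", strict = FALSE)
  if (!(is.numeric(admin_censor_months) && admin_censor_months > 0)) {
    stop("`admin_censor_months` must be > 0 (Inf allowed)", call. = FALSE)
  }
  structure(list(n = as.integer(n), category_counts = category_counts,
                 sex_counts = sex_counts, baseline_hazard = baseline_hazard,
                 log_hazard_ratios = log_hazard_ratios,
                 censoring_rate = censoring_rate,
                 admin_censor_months = admin_censor_months,
                 seed = as.integer(seed)),
            class = "cohort_sim_config")
}

# Lognormal parameters matching a target mean and SD.
lognormal_pars <- function(mean, sd) {
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  c(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a survival cohort
#'
#' @param config A [cohort_sim_config()].
#' @return A `cohort_table` data frame with one row per patient: `id`,
#'   `sex`, `cancer_type`, `age`, `line_of_treatment`, the eight
#'   body-composition covariates (`VFM3D`, `SFM3D`, `FBM3D`, `MBM3D`,
#'   `VFA2D`, `SFA2D`, `FBA2D`, `MBA2D`), `os_months` and `event`
#'   (1 = death). `FBM3D = VFM3D + SFM3D` and `FBA2D = VFA2D + SFA2D`
#'   hold by construction.
#' @export
generate_cohort <- function(config = cohort_sim_config()) {
  stopifnot(inherits(config, "cohort_sim_config"))
  n <- config$n
  with_seed(config$seed, {
    sex <- sample(rep(names(config$sex_counts), config$sex_counts))
    cancer <- sample(rep(names(config$category_counts),
                         config$category_counts))
    age <- pmin(83, pmax(19, round(rnorm(n, 57, 12))))
    line <- pmin(10L, 1L + rnbinom(n, size = 1.2, mu = 1.07))

    male <- sex == "male"
    p_male <- mean(male)
    # Sex multipliers normalized to preserve the population geometric mean.
    mult <- function(male_factor) {
      g <- exp(p_male * log(male_factor))
      ifelse(male, male_factor, 1) / g
    }
    mult_muscle <- mult(1.20)
    mult_subfat <- mult(0.85)

    draw_pair <- function(name3d, name2d, rho, sex_mult) {
      p3 <- lognormal_pars(.covariate_targets[[name3d]][["mean"]],
                           .covariate_targets[[name3d]][["sd"]])
      p2 <- lognormal_pars(.covariate_targets[[name2d]][["mean"]],
                           .covariate_targets[[name2d]][["sd"]])
      z3 <- rnorm(n)
      z2 <- rho * z3 + sqrt(1 - rho^2) * rnorm(n)
      list(v3 = exp(p3[["meanlog"]] + p3[["sdlog"]] * z3) * sex_mult,
           v2 = exp(p2[["meanlog"]] + p2[["sdlog"]] * z2) * sex_mult)
    }
    visc <- draw_pair("VFM3D", "VFA2D", .pair_correlations[["visceral"]], 1)
    subc <- draw_pair("SFM3D", "SFA2D", .pair_correlations[["subcutaneous"]],
                      mult_subfat)
    musc <- draw_pair("MBM3D", "MBA2D", .pair_correlations[["muscle"]],
                      mult_muscle)

    cohort <- data.frame(
      id = seq_len(n),
      sex = factor(sex, levels = c("male", "female")),
      cancer_type = factor(cancer, levels = names(config$category_counts)),
      age = age,
      line_of_treatment = as.integer(line),
      VFM3D = visc$v3, SFM3D = subc$v3, FBM3D = visc$v3 + subc$v3,
      MBM3D = musc$v3,
      VFA2D = visc$v2, SFA2D = subc$v2, FBA2D = visc$v2 + subc$v2,
      MBA2D = musc$v2)

    lhr <- config$log_hazard_ratios
    missing_cov <- setdiff(names(lhr), names(cohort))
    if (length(missing_cov)) {
      stop("log_hazard_ratios name unknown covariates: ",
           paste(missing_cov, collapse = ", "), call. = FALSE)
    }
    lp <- rep(0, n)
    for (nm in names(lhr)) lp <- lp + lhr[[nm]] * cohort[[nm]]
    hazard <- config$baseline_hazard * exp(lp)
    t_event <- rexp(n, rate = hazard)
    t_cens <- if (config$censoring_rate > 0) {
      rexp(n, rate = config$censoring_rate)
    } else rep(Inf, n)
    t_cens <- pmin(t_cens, config$admin_censor_months)
    cohort$os_months <- pmin(t_event, t_cens)
    cohort$event <- as.integer(t_event <= t_cens)
    class(cohort) <- c("cohort_table", "data.frame")
    cohort
  })
}

#' Names of the eight body-composition parameters
#'
#' Four height-normalized 3D masses (kg/m2) and four L3-level areas
#' (cm2/m2).
#' @return Character vector of column names.
#' @export
anthro_parameters <- function() {
  c("VFM3D", "SFM3D", "FBM3D", "MBM3D", "VFA2D", "SFA2D", "FBA2D", "MBA2D")
}
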
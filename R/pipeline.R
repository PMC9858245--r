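# End-to-end orchestration: simulate or ingest, segment, quantify, merge,
# run the statistical battery, emit the report bundle.

#' Configure a pipeline run
#'
#' Two modes: `"covariates_only"` analyses a cohort table directly (given
#' via `cohort` or simulated from `cohort_config`); `"synthetic_end_to_end"`
#' generates phantom patients, crops them to the acquisition field,
#' segments, quantifies with atlas-derived extrapolation factors, then
#' simulates survival from the measured covariates and runs the same
#' statistics.
#'
#' @param mode `"covariates_only"` or `"synthetic_end_to_end"`.
#' @param cohort Optional pre-built `cohort_table` (covariates_only mode).
#' @param cohort_config A [cohort_sim_config()]; also provides the hazard
#'   model used to simulate survival in end-to-end mode.
#' @param n_patients Number of phantom patients (end-to-end mode).
#' @param atlas_size Number of atlas phantoms behind the extrapolation
#'   factors (end-to-end mode).
#' @param field Acquisition field for the phantom patients.
#' @param phantom_base Base [phantom_spec()] for the phantom population;
#'   the pipeline default uses 4 x 4 x 6 mm voxels for phantom studies.
#' @param seg_params A [segmentation_params()].
#' @param output_dir Optional directory; when given, all report tables are
#'   written as CSV plus a JSON manifest.
#' @param seed Global seed; every stage derives its randomness from it.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(mode = c("covariates_only",
                                     "synthetic_end_to_end"),
                            cohort = NULL,
                            cohort_config = cohort_sim_config(),
                            n_patients = 20L,
                            atlas_size = 5L,
                            field = c("abdomen_pelvis",
                                      "thorax_abdomen_pelvis"),
                            phantom_base = phantom_spec(spacing = c(4, 4, 6)),
                            seg_params = segmentation_params(),
                            output_dir = NULL,
                            seed = 1L) {
  mode <- match.arg(mode)
  field <- match.arg(field)
  if (!is.null(cohort) && mode != "covariates_only") {
    stop("a pre-built cohort is only used in covariates_only mode",
         call. = FALSE)
  }
  stopifnot(inherits(cohort_config, "cohort_sim_config"),
            inherits(phantom_base, "phantom_spec"),
            inherits(seg_params, "segmentation_params"))
  stop_if_not_scalar_pos(n_patients, "n_patients")
  stop_if_not_scalar_pos(atlas_size, "atlas_size")
  structure(list(mode = mode, cohort = cohort, cohort_config = cohort_config,
                 n_patients = as.integer(n_patients),
                 atlas_size = as.integer(atlas_size), field = field,
                 phantom_base = phantom_base, seg_params = seg_params,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Describe a cohort
#'
#' Descriptive statistics: counts and percentages (one decimal) for
#' categorical fields, mean/median/SD/range for continuous fields (SD is
#' `NA` for a single observation).
#'
#' @param cohort A `cohort_table`.
#' @return List of data frames `categorical` and `continuous`.
#' @export
describe_cohort <- function(cohort) {
  if (!nrow(cohort)) stop("cohort is empty", call. = FALSE)
  cat_fields <- intersect(c("sex", "cancer_type"), names(cohort))
  cat_tab <- do.call(rbind, lapply(cat_fields, function(f) {
    tb <- table(cohort[[f]])
    data.frame(field = f, level = names(tb), n = as.integer(tb),
               pct = round(100 * as.integer(tb) / nrow(cohort), 1))
  }))
  cont_fields <- intersect(
    c("age", "line_of_treatment", anthro_parameters(), "os_months"),
    names(cohort))
  cont_tab <- do.call(rbind, lapply(cont_fields, function(f) {
    v <- cohort[[f]][!is.na(cohort[[f]])]
    data.frame(field = f, mean = mean(v), median = median(v),
               sd = if (length(v) > 1L) sd(v) else NA_real_,
               min = min(v), max = max(v))
  }))
  list(categorical = cat_tab, continuous = cont_tab)
}

# Quantify one phantom patient: crop, segment, measure.
quantify_phantom_patient <- function(spec, field, k, seg_params) {
  ph <- generate_phantom(spec)
  cr <- crop_field(ph$volume, ph$truth, field)
  masks <- segment_volume(cr$volume, seg_params)
  const <- mass_constants(cr$volume$spacing)
  masses <- compute_masses(masks, k, const, spec$height_m)
  l3 <- locate_L3(cr$volume, cr$truth)
  areas <- compute_l3_areas(masks, l3, cr$volume$spacing, spec$height_m)
  anthro_result(masses, areas)
}

build_imaging_cohort <- function(config) {
  base <- config$phantom_base
  atlas <- lapply(seq_len(config$atlas_size), function(i) {
    spec <- sample_phantom_spec(config$seed * 1000L + i, base)
    ph <- generate_phantom(spec)
    cr <- crop_field(ph$volume, ph$truth, config$field)
    atlas_entry(ph$truth, cr$truth)
  })
  k <- build_extrapolation_factors(atlas, config$field)
  rows <- lapply(seq_len(config$n_patients), function(j) {
    spec <- sample_phantom_spec(config$seed * 1000L + 500L + j, base)
    res <- tryCatch(
      quantify_phantom_patient(spec, config$field, k, config$seg_params),
      error = function(e) {
        stop("stage quantify failed for patient ", j, ": ",
             conditionMessage(e), call. = FALSE)
      })
    res$id <- j
    res
  })
  covs <- do.call(rbind, rows)
  cc <- config$cohort_config
  n <- nrow(covs)
  with_seed(config$seed + 77L, {
    cohort <- data.frame(
      id = covs$id,
      sex = factor(sample(rep(c("male", "female"),
                              c(ceiling(0.717 * n), n - ceiling(0.717 * n)))),
                   levels = c("male", "female")),
      cancer_type = factor(sample(names(cc$category_counts), n,
                                  replace = TRUE,
                                  prob = cc$category_counts),
                           levels = names(cc$category_counts)),
      age = pmin(83, pmax(19, round(rnorm(n, 57, 12)))),
      line_of_treatment = as.integer(pmin(10L, 1L +
                                            rnbinom(n, size = 1.2,
                                                    mu = 1.07))))
    cohort <- cbind(cohort, covs[anthro_parameters()])
    lhr <- cc$log_hazard_ratios
    lhr <- lhr[names(lhr) %in% names(cohort)]
    lp <- rep(0, n)
    for (nm in names(lhr)) lp <- lp + lhr[[nm]] * cohort[[nm]]
    hazard <- cc$baseline_hazard * exp(lp)
    t_event <- rexp(n, hazard)
    t_cens <- if (cc$censoring_rate > 0) rexp(n, cc$censoring_rate)
              else rep(Inf, n)
    t_cens <- pmin(t_cens, cc$admin_censor_months)
    cohort$os_months <- pmin(t_event, t_cens)
    cohort$event <- as.integer(t_event <= t_cens)
    class(cohort) <- c("cohort_table", "data.frame")
    attr(cohort, "extrapolation_factors") <- k
    cohort
  })
}

#' Run the full analysis pipeline
#'
#' Executes generate -> (crop, segment, quantify) -> merge -> statistics ->
#' report. Deterministic under the configuration's global seed: re-running
#' the same configuration reproduces every number.
#'
#' @param config A [pipeline_config()].
#' @return A `report_bundle`: `cohort`, `descriptive`, `roc_table` (ROC/
#'   cutoff table), `cox_table` (strata all/men/women), `forest` (per
#'   cancer type), `correlations`, `km` (curve data and log-rank tests for
#'   markers with significant AUC), `extrapolation_factors` (end-to-end
#'   mode), `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- switch(config$mode,
    covariates_only = config$cohort %||% generate_cohort(config$cohort_config),
    synthetic_end_to_end = build_imaging_cohort(config))

  params <- intersect(anthro_parameters(), names(cohort))
  markers <- c(intersect("line_of_treatment", names(cohort)), params)
  desc <- describe_cohort(cohort)
  corr <- spearman_matrix(cohort[params])
  s1 <- survival_at_1y(cohort)

  roc_rows <- lapply(markers, function(m) {
    r <- roc_with_youden(cohort[[m]][s1$included], s1$outcome[s1$included])
    data.frame(parameter = m, cutoff = r$cutoff, auc = r$auc,
               sensitivity = r$sensitivity, specificity = r$specificity,
               accuracy = r$accuracy, direction = r$direction,
               p_value = r$p_value)
  })
  roc_table <- do.call(rbind, roc_rows)

  km <- list()
  for (i in seq_len(nrow(roc_table))) {
    m <- roc_table$parameter[i]
    if (m == "line_of_treatment") next
    if (is.na(roc_table$p_value[i]) || roc_table$p_value[i] >= 0.05 ||
        is.na(roc_table$cutoff[i])) next
    grp <- ifelse(cohort[[m]] <= roc_table$cutoff[i], "low", "high")
    res <- km_logrank(cohort, grp)
    res$parameter <- m
    res$cutoff <- roc_table$cutoff[i]
    km[[m]] <- res
  }

  strata <- list(all = NULL, men = cohort$sex == "male",
                 women = cohort$sex == "female")
  cox_rows <- list()
  for (s in names(strata)) {
    for (m in c(intersect(c("age", "line_of_treatment"), names(cohort)),
                params)) {
      row <- tryCatch({
        r <- cox_univariate(cohort, m, strata[[s]], s)
        data.frame(stratum = s, parameter = m, hazard_ratio = r$hazard_ratio,
                   log_hr = r$log_hr, se = r$se, p_value = r$p_value,
                   n = r$n, n_events = r$n_events, converged = r$converged)
      }, error = function(e) NULL)
      cox_rows[[paste(s, m)]] <- row
    }
  }
  cox_table <- do.call(rbind, cox_rows)
  rownames(cox_table) <- NULL

  forest_rows <- list()
  if ("cancer_type" %in% names(cohort)) {
    for (ct in levels(droplevels(cohort$cancer_type))) {
      sel <- cohort$cancer_type == ct
      for (m in params) {
        row <- tryCatch({
          r <- cox_univariate(cohort, m, sel, ct)
          data.frame(cancer_type = ct, parameter = m, log_hr = r$log_hr,
                     lo95 = r$log_hr - 1.96 * r$se,
                     hi95 = r$log_hr + 1.96 * r$se,
                     p_value = r$p_value, n = r$n, converged = r$converged)
        }, error = function(e) NULL)
        forest_rows[[paste(ct, m)]] <- row
      }
    }
  }
  forest <- do.call(rbind, forest_rows)
  if (!is.null(forest)) rownames(forest) <- NULL

  manifest <- list(
    package = "ctanthro",
    version = as.character(packageVersion("ctanthro")),
    mode = config$mode, seed = config$seed, n = nrow(cohort),
    field = config$field,
    n_dead_1y = s1$n_dead, n_alive_1y = s1$n_alive,
    n_excluded_1y = s1$n_excluded,
    cohort_config = config$cohort_config[
      c("n", "baseline_hazard", "censoring_rate", "admin_censor_months",
        "seed")],
    log_hazard_ratios = as.list(config$cohort_config$log_hazard_ratios))

  bundle <- structure(list(
    cohort = cohort, descriptive = desc, roc_table = roc_table,
    cox_table = cox_table, forest = forest, correlations = corr,
    km = km,
    extrapolation_factors = attr(cohort, "extrapolation_factors"),
    manifest = manifest), class = "report_bundle")

  if (!is.null(config$output_dir)) write_report_bundle(bundle,
                                                       config$output_dir)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle> %s, n = %d (%d dead / %d alive at 1 y)\n",
              x$manifest$mode, x$manifest$n, x$manifest$n_dead_1y,
              x$manifest$n_alive_1y))
  cat("ROC / Youden cutoffs:\n")
  print(x$roc_table, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits plain CSV tables (descriptive, ROC/cutoffs, Cox strata, forest,
#' correlations, KM curves, cohort) and a JSON manifest.
#'
#' @param bundle A `report_bundle` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wr <- function(obj, name) {
    path <- file.path(dir, name)
    write.csv(obj, path, row.names = FALSE)
    files <<- c(files, path)
  }
  wr(bundle$cohort, "cohort.csv")
  wr(bundle$descriptive$categorical, "descriptive_categorical.csv")
  wr(bundle$descriptive$continuous, "descriptive_continuous.csv")
  wr(bundle$roc_table, "roc_cutoffs.csv")
  if (!is.null(bundle$cox_table)) wr(bundle$cox_table, "cox_strata.csv")
  if (!is.null(bundle$forest)) wr(bundle$forest, "forest.csv")
  rho <- as.data.frame(bundle$correlations$rho)
  rho <- cbind(parameter = rownames(rho), rho)
  wr(rho, "correlations.csv")
  if (length(bundle$km)) {
    km_curves <- do.call(rbind, lapply(bundle$km, function(r) {
      cbind(parameter = r$parameter, r$curves,
            logrank_p = r$logrank_p, cutoff = r$cutoff)
    }))
    rownames(km_curves) <- NULL
    wr(km_curves, "km_curves.csv")
  }
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(bundle$manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c(files, manifest_path)
  invisible(files)
}
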
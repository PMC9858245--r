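# Prognostic statistics: one-year-survival ROC with Youden cutoffs,
# Kaplan-Meier/log-rank, univariate Cox models, Spearman correlations.

#' Dichotomize survival at one year
#'
#' Patients dead within 12 months are cases; patients followed beyond 12
#' months (whatever their later status) are controls; patients censored
#' before 12 months are indeterminate and excluded.
#'
#' @param cohort A `cohort_table` (needs `os_months` and `event`).
#' @param months Landmark horizon, default 12 months.
#' @return List with `outcome` (1 = dead, 0 = alive, `NA` = excluded),
#'   `included` logical mask, and the class counts `n_dead`, `n_alive`,
#'   `n_excluded`.
#' @export
survival_at_1y <- function(cohort, months = 12) {
  stopifnot(all(c("os_months", "event") %in% names(cohort)))
  os <- cohort$os_months
  ev <- cohort$event
  outcome <- rep(NA_integer_, length(os))
  outcome[ev == 1L & os <= months] <- 1L
  outcome[os > months] <- 0L
  list(outcome = outcome, included = !is.na(outcome),
       n_dead = sum(outcome == 1L, na.rm = TRUE),
       n_alive = sum(outcome == 0L, na.rm = TRUE),
       n_excluded = sum(is.na(outcome)))
}

#' ROC analysis with Youden-optimal cutoff
#'
#' AUC via the rank (Mann-Whitney) formulation with midrank tie handling;
#' two-sided p-value for AUC != 0.5 from the normal approximation to the
#' Mann-Whitney statistic (tie-corrected). The marker orientation is fixed
#' so AUC >= 0.5 and recorded in `direction` (`"less"`: cases tend to lower
#' marker values, the "low marker = risk" pattern). Candidate cutoffs are
#' the midpoints between adjacent distinct observed values; the reported
#' cutoff maximizes Youden's index (sensitivity + specificity - 1), ties
#' broken toward the lower threshold.
#'
#' @param marker Numeric marker values.
#' @param outcome Binary outcome (1 = case/dead, 0 = control/alive); `NA`
#'   pairs are dropped.
#' @return A `roc_result`: `auc`, `p_value`, `cutoff`, `sensitivity`,
#'   `specificity`, `accuracy`, `youden`, `direction`, `n_dead_1y`,
#'   `n_alive_1y`.
#' @export
roc_with_youden <- function(marker, outcome) {
  keep <- !is.na(marker) & !is.na(outcome)
  marker <- marker[keep]
  outcome <- as.integer(outcome[keep])
  n1 <- sum(outcome == 1L)
  n0 <- sum(outcome == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("both outcome classes must be non-empty", call. = FALSE)
  }
  r <- rank(marker)
  auc_raw <- (sum(r[outcome == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  direction <- if (auc_raw >= 0.5) "greater" else "less"
  auc <- max(auc_raw, 1 - auc_raw)
  p <- suppressWarnings(
    wilcox.test(marker[outcome == 1L], marker[outcome == 0L],
                exact = FALSE, correct = FALSE)$p.value)
  v <- sort(unique(marker))
  if (length(v) < 2L) {
    res <- list(auc = 0.5, p_value = 1, cutoff = NA_real_,
                sensitivity = NA_real_, specificity = NA_real_,
                accuracy = NA_real_, youden = NA_real_,
                direction = direction, n_dead_1y = n1, n_alive_1y = n0)
    return(structure(res, class = "roc_result"))
  }
  cand <- (head(v, -1) + tail(v, -1)) / 2
  pos_at <- function(cut) {
    if (direction == "less") marker < cut else marker > cut
  }
  sens <- vapply(cand, function(cut) mean(pos_at(cut)[outcome == 1L]),
                 numeric(1))
  spec <- vapply(cand, function(cut) mean(!pos_at(cut)[outcome == 0L]),
                 numeric(1))
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)[1]  # ties -> lowest candidate cutoff
  pos <- pos_at(cand[best])
  structure(list(
    auc = auc, p_value = p, cutoff = cand[best],
    sensitivity = sens[best], specificity = spec[best],
    accuracy = mean(pos == (outcome == 1L)), youden = j[best],
    direction = direction, n_dead_1y = n1, n_alive_1y = n0),
    class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result> AUC %.3f (p = %.3g), cutoff %.4g (direction %s)\n",
    x$auc, x$p_value, x$cutoff, x$direction))
  cat(sprintf("sens %.3f / spec %.3f / acc %.3f; %d dead, %d alive at 1 y\n",
              x$sensitivity, x$specificity, x$accuracy,
              x$n_dead_1y, x$n_alive_1y))
  invisible(x)
}

#' Kaplan-Meier curves with log-rank test
#'
#' Product-limit survival estimates per group with the k-sample log-rank
#' test (hypergeometric variance summed over distinct event times,
#' chi-square with k - 1 degrees of freedom).
#'
#' @param cohort A `cohort_table`.
#' @param group Grouping vector (coerced to factor); every level must be
#'   non-empty.
#' @return A `km_result`: `curves` data frame (`group`, `time`, `n_risk`,
#'   `n_event`, `surv`), `logrank_chi2`, `df`, `logrank_p`, `n_groups`.
#' @export
km_logrank <- function(cohort, group) {
  g <- as.factor(group)  # declared-but-empty levels are an error, not dropped
  if (nlevels(g) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(table(g) == 0L)) stop("every group must be non-empty", call. = FALSE)
  keep <- !is.na(g)
  d <- data.frame(os = cohort$os_months[keep], ev = cohort$event[keep],
                  g = g[keep])
  fit <- survival::survfit(survival::Surv(os, ev) ~ g, data = d)
  strata <- rep(names(fit$strata) %||% "g=all",
                fit$strata %||% length(fit$time))
  curves <- data.frame(
    group = sub("^g=", "", strata), time = fit$time,
    n_risk = fit$n.risk, n_event = fit$n.event, surv = fit$surv)
  df <- nlevels(g) - 1L
  chi2 <- if (sum(d$ev) == 0L) 0 else {
    survival::survdiff(survival::Surv(os, ev) ~ g, data = d)$chisq
  }
  structure(list(curves = curves, logrank_chi2 = chi2, df = df,
                 logrank_p = pchisq(chi2, df, lower.tail = FALSE),
                 n_groups = nlevels(g)),
            class = "km_result")
}

#' @export
print.km_result <- function(x, ...) {
  cat(sprintf("<km_result> %d groups; log-rank chi2 %.4g (df %d), p = %.3g\n",
              x$n_groups, x$logrank_chi2, x$df, x$logrank_p))
  invisible(x)
}

#' Univariate Cox proportional-hazards model
#'
#' Maximizes the partial likelihood for one continuous covariate with Efron
#' handling of tied event times; reports the hazard ratio with Wald
#' standard error and two-sided p-value. Monotone-likelihood separation is
#' flagged (`converged = FALSE`) rather than reported as a finite hazard
#' ratio.
#'
#' @param cohort A `cohort_table`.
#' @param covariate Name of the covariate column.
#' @param stratum Optional logical mask selecting the analysis stratum.
#' @param stratum_label Label stored with the result (e.g. `"men"`).
#' @return A `cox_result`: `covariate`, `stratum`, `log_hr`, `se`,
#'   `hazard_ratio`, `z`, `p_value`, `n`, `n_events`, `converged`.
#' @export
cox_univariate <- function(cohort, covariate, stratum = NULL,
                           stratum_label = "all") {
  if (!covariate %in% names(cohort)) {
    stop("unknown covariate: ", covariate, call. = FALSE)
  }
  d <- if (is.null(stratum)) cohort else cohort[stratum, , drop = FALSE]
  d <- d[!is.na(d[[covariate]]), , drop = FALSE]
  if (sum(d$event) < 1L) {
    stop("stratum '", stratum_label, "' contains no events", call. = FALSE)
  }
  x <- d[[covariate]]
  if (length(unique(x)) < 2L) {
    stop("covariate '", covariate, "' is constant in stratum '",
         stratum_label, "'", call. = FALSE)
  }
  warn_inf <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(os_months, event) ~ x,
                    data = data.frame(os_months = d$os_months,
                                      event = d$event, x = x),
                    ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w))) {
        warn_inf <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  beta <- unname(fit$coefficients)
  se <- unname(sqrt(diag(fit$var)))
  converged <- !warn_inf && is.finite(beta) && is.finite(se) && se < 50
  structure(list(
    covariate = covariate, stratum = stratum_label,
    log_hr = beta, se = se,
    hazard_ratio = if (converged) exp(beta) else NA_real_,
    z = beta / se,
    p_value = 2 * pnorm(-abs(beta / se)),
    n = nrow(d), n_events = sum(d$event), converged = converged),
    class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf(
    "<cox_result> %s [%s]: HR %.4g (log HR %.4g +/- %.3g), p = %.3g%s\n",
    x$covariate, x$stratum, x$hazard_ratio, x$log_hr, x$se, x$p_value,
    if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Spearman correlation matrix
#'
#' Rank correlation with average ranks for ties, computed pairwise on
#' complete observations, with per-pair p-values. Constant columns yield
#' `NA` correlations (with a warning), as do pairs with fewer than three
#' complete observations.
#'
#' @param x Data frame or matrix of numeric columns.
#' @return A `spearman_result`: symmetric `rho` and `p` matrices and the
#'   pairwise sample-size matrix `n`.
#' @export
spearman_matrix <- function(x) {
  x <- as.data.frame(x)
  num <- vapply(x, is.numeric, logical(1))
  x <- x[num]
  p <- ncol(x)
  if (p < 2L) stop("need at least two numeric columns", call. = FALSE)
  nm <- names(x)
  rho <- matrix(NA_real_, p, p, dimnames = list(nm, nm))
  pv <- matrix(NA_real_, p, p, dimnames = list(nm, nm))
  nn <- matrix(0L, p, p, dimnames = list(nm, nm))
  const <- vapply(x, function(col) {
    v <- col[!is.na(col)]
    length(unique(v)) < 2L
  }, logical(1))
  if (any(const)) {
    warning("constant column(s): ", paste(nm[const], collapse = ", "),
            "; correlations reported as NA", call. = FALSE)
  }
  for (i in seq_len(p)) {
    rho[i, i] <- 1
    pv[i, i] <- 0
    nn[i, i] <- sum(!is.na(x[[i]]))
    for (j in seq_len(p)) {
      if (j <= i) next
      ok <- complete.cases(x[[i]], x[[j]])
      nn[i, j] <- nn[j, i] <- sum(ok)
      if (sum(ok) < 3L || const[i] || const[j]) next
      ct <- suppressWarnings(
        cor.test(x[[i]][ok], x[[j]][ok], method = "spearman"))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      pv[i, j] <- pv[j, i] <- ct$p.value
    }
  }
  structure(list(rho = rho, p = pv, n = nn), class = "spearman_result")
}

#' @export
print.spearman_result <- function(x, ...) {
  cat("<spearman_result> rho:\n")
  print(round(x$rho, 3))
  invisible(x)
}
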
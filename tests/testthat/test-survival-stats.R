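test_that("one-year landmark classification follows the censoring rule", {
  co <- data.frame(os_months = c(6, 30, 6, 12, 12.5),
                   event = c(1L, 0L, 0L, 1L, 0L))
  s <- survival_at_1y(co)
  expect_identical(s$outcome, c(1L, 0L, NA, 1L, 0L))
  expect_equal(s$n_dead, 2L)
  expect_equal(s$n_alive, 2L)
  expect_equal(s$n_excluded, 1L)
})

test_that("ROC degenerate cases: constant and perfectly separating markers", {
  outcome <- rep(c(1L, 0L), each = 10)
  flat <- roc_with_youden(rep(3.3, 20), outcome)
  expect_equal(flat$auc, 0.5)
  expect_true(is.na(flat$cutoff))
  perfect <- roc_with_youden(c(1:10, 21:30), outcome)
  expect_equal(perfect$auc, 1.0)
  expect_equal(perfect$sensitivity, 1.0)
  expect_equal(perfect$specificity, 1.0)
  expect_error(roc_with_youden(1:5, rep(1L, 5)), "both outcome classes")
})

test_that("AUC and Youden cutoff equal the brute-force oracle", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(40:300, 1)
    outcome <- rbinom(n, 1, 0.4)
    if (sum(outcome) == 0 || sum(outcome) == n) next
    # mixture with ties to exercise midrank handling
    marker <- round(rnorm(n, mean = 0.4 * outcome), 1)
    r <- roc_with_youden(marker, outcome)
    o <- roc_oracle(marker, outcome)
    expect_equal(r$auc, o$auc, tolerance = 1e-12, info = paste("seed", s))
    expect_equal(r$cutoff, o$cutoff, info = paste("seed", s))
    expect_equal(r$youden, o$youden, tolerance = 1e-12)
  }
})

test_that("tied Youden maxima resolve to the lowest candidate threshold", {
  # cases at {1, 4}, controls at {2, 5}: J is tied at several thresholds
  marker <- c(1, 4, 2, 5)
  outcome <- c(1L, 1L, 0L, 0L)
  r <- roc_with_youden(marker, outcome)
  o <- roc_oracle(marker, outcome)
  cand <- (sort(unique(marker))[-4] + sort(unique(marker))[-1]) / 2
  ties <- cand[abs(vapply(cand, function(cut) {
    pos <- marker < cut
    mean(pos[outcome == 1]) + mean(!pos[outcome == 0]) - 1
  }, numeric(1)) - r$youden) < 1e-12]
  expect_gt(length(ties), 1L)           # the tie actually occurs
  expect_equal(r$cutoff, min(ties))     # and resolves downward
  expect_equal(r$cutoff, o$cutoff)
})

test_that("log-rank matches direct O/E/V tabulation and is label-symmetric", {
  set.seed(7)
  for (i in 1:10) {
    n <- 100
    g <- rep(c("a", "b"), each = n / 2)
    time <- round(rexp(n, ifelse(g == "a", 0.08, 0.12)), 1)  # ties present
    event <- rbinom(n, 1, 0.8)
    co <- data.frame(os_months = time, event = event)
    r <- km_logrank(co, g)
    o <- logrank_oracle(time, event, g)
    expect_equal(r$logrank_chi2, o$chi2, tolerance = 1e-6)
    expect_equal(r$logrank_p, o$p, tolerance = 1e-6)
    swapped <- km_logrank(co, ifelse(g == "a", "b", "a"))
    expect_equal(swapped$logrank_p, r$logrank_p, tolerance = 1e-12)
  }
})

test_that("log-rank degenerate cases", {
  co <- data.frame(os_months = rep(c(3, 8, 15), 2), event = rep(c(1L, 0L, 1L), 2))
  g <- rep(c("a", "b"), each = 3)
  r <- km_logrank(co, g)  # identical patterns per group
  expect_equal(r$logrank_chi2, 0, tolerance = 1e-12)
  expect_equal(r$logrank_p, 1)
  no_events <- data.frame(os_months = c(2, 4, 6, 8), event = rep(0L, 4))
  r2 <- km_logrank(no_events, c("a", "a", "b", "b"))
  expect_equal(r2$logrank_chi2, 0)
  expect_error(km_logrank(co, rep("a", 6)), "two groups")
  expect_error(km_logrank(co, factor(g, levels = c("a", "b", "c"))),
               "non-empty")
})

test_that("KM estimate with no censoring equals the empirical survival", {
  set.seed(11)
  time <- sort(sample(1:40, 30, replace = TRUE))
  co <- data.frame(os_months = c(time, time + 2),
                   event = 1L)
  g <- rep(c("a", "b"), each = 30)
  r <- km_logrank(co, g)
  ca <- r$curves[r$curves$group == "a", ]
  emp <- vapply(ca$time, function(t) mean(time > t), numeric(1))
  expect_equal(ca$surv, emp, tolerance = 1e-12)
})

test_that("Cox model: null recovery and analytic score-root oracle", {
  set.seed(13)
  n <- 2000
  x <- rnorm(n)
  co <- data.frame(os_months = rexp(n, 0.1), event = rbinom(n, 1, 0.9),
                   x = x)
  r <- cox_univariate(co, "x")
  expect_lt(abs(r$log_hr), 3 * r$se)
  expect_equal(r$hazard_ratio, exp(r$log_hr))

  # three subjects, two events: root of the hand-derived score equation
  xx <- c(0.5, -0.2, 0.1)
  toy <- data.frame(os_months = c(1, 2, 3), event = c(1L, 1L, 0L), x = xx)
  beta_star <- uniroot(cox_score_3subject, c(-20, 20), x = xx,
                       tol = 1e-12)$root
  rt <- cox_univariate(toy, "x")
  expect_equal(rt$log_hr, beta_star, tolerance = 1e-6)
})

test_that("Cox recovers the generator's log hazard ratio", {
  cfg <- cohort_sim_config(
    n = 5000L, category_counts = c(renal = 5000L),
    sex_counts = c(male = 2500L, female = 2500L),
    baseline_hazard = 0.15, log_hazard_ratios = c(MBM3D = -0.5),
    censoring_rate = 0.005, admin_censor_months = 60, seed = 17L)
  co <- generate_cohort(cfg)
  r <- cox_univariate(co, "MBM3D")
  expect_lt(abs(r$log_hr - (-0.5)), 0.1)
})

test_that("monotone-likelihood separation is flagged, not reported as a HR", {
  sep <- data.frame(os_months = c(1, 2, 3, 4, 10, 11, 12, 13),
                    event = c(rep(1L, 4), rep(0L, 4)),
                    x = c(rep(1, 4), rep(0, 4)))
  r <- suppressWarnings(cox_univariate(sep, "x"))
  expect_false(r$converged)
  expect_true(is.na(r$hazard_ratio))
  expect_error(cox_univariate(data.frame(os_months = 1:3, event = 0L,
                                         x = rnorm(3)), "x"), "no events")
  expect_error(cox_univariate(data.frame(os_months = 1:3, event = 1L,
                                         x = 1), "x"), "constant")
})

test_that("Spearman matrix equals rank-then-Pearson and handles degeneracy", {
  set.seed(19)
  d <- data.frame(a = rnorm(100), b = rnorm(100),
                  c = sample(1:5, 100, TRUE))
  d$d <- -d$a
  sp <- spearman_matrix(d)
  expect_equal(unname(diag(sp$rho)), rep(1, 4))
  expect_equal(sp$rho["a", "d"], -1)
  for (i in c("a", "b", "c")) {
    for (j in c("b", "c", "d")) {
      if (i == j) next
      expect_equal(sp$rho[i, j], spearman_oracle(d[[i]], d[[j]]),
                   tolerance = 1e-12)
    }
  }
  expect_equal(sp$rho, t(sp$rho))
  d$e <- 1
  expect_warning(sp2 <- spearman_matrix(d), "constant")
  expect_true(all(is.na(sp2$rho["e", c("a", "b")])))
})
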
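# Shared fixtures and independent oracles.

# Phantom fixtures are expensive; cache them per test session.
.fixture_env <- new.env(parent = emptyenv())

coarse_spec <- function(seed = 1L, ...) {
  phantom_spec(spacing = c(4, 4, 6), seed = seed, ...)
}

tiny_spec <- function(seed = 1L, ...) {
  phantom_spec(spacing = c(6, 6, 10), seed = seed, ...)
}

cached <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

default_phantom <- function() cached("phantom", generate_phantom(coarse_spec()))

default_segmentation <- function() {
  cached("segmentation",
         suppressWarnings(segment_volume(default_phantom()$volume)))
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Station fractions of the phantom design (feet -> head), restated here so
# analytic geometry oracles do not read the implementation's internals.
.stations <- c(ischium = 0.48, iliac = 0.585, diaphragm = 0.72,
               shoulder = 0.87, neck_top = 0.905)

station_lengths_mm <- function(spec) {
  spec$body_length * diff(c(0, unname(.stations), 1))
}

# Closed-form subcutaneous shell volume: per-station elliptical ring area
# (outer minus inner cylinder) times station length.
analytic_subfat_volume_mm3 <- function(spec) {
  t <- spec$subcutaneous_thickness
  tr <- spec$torso_radii
  ring <- function(a, b = a) pi * (a * b - (a - t) * (b - t))
  areas <- c(2 * ring(tr$legs_r), ring(tr$pelvis[1], tr$pelvis[2]),
             ring(tr$abdomen[1], tr$abdomen[2]),
             ring(tr$thorax[1], tr$thorax[2]), ring(tr$neck_r),
             ring(tr$head[1], tr$head[2]))
  sum(areas * station_lengths_mm(spec))
}

# Closed-form muscle-ring cross-section at the L3 level (abdomen station).
analytic_l3_muscle_area_mm2 <- function(spec) {
  t <- spec$subcutaneous_thickness
  m <- spec$muscle_thickness
  a <- spec$torso_radii$abdomen[1]
  b <- spec$torso_radii$abdomen[2]
  pi * ((a - t) * (b - t) - (a - t - m) * (b - t - m))
}

# Brute-force ROC oracle: concordant-pair counting for the AUC and an
# exhaustive scan over midpoint thresholds for the Youden cutoff.
roc_oracle <- function(marker, outcome) {
  cases <- marker[outcome == 1]
  controls <- marker[outcome == 0]
  conc <- 0
  for (x in cases) {
    conc <- conc + sum(x > controls) + 0.5 * sum(x == controls)
  }
  auc_raw <- conc / (length(cases) * length(controls))
  dir <- if (auc_raw >= 0.5) "greater" else "less"
  v <- sort(unique(marker))
  cand <- (head(v, -1) + tail(v, -1)) / 2
  j <- numeric(length(cand))
  for (i in seq_along(cand)) {
    pos <- if (dir == "less") marker < cand[i] else marker > cand[i]
    j[i] <- mean(pos[outcome == 1]) + mean(!pos[outcome == 0]) - 1
  }
  best <- which(j >= max(j) - 1e-12)[1]
  list(auc = max(auc_raw, 1 - auc_raw), cutoff = cand[best],
       youden = j[best], direction = dir)
}

# Direct O/E/V log-rank tabulation over distinct event times (two groups).
logrank_oracle <- function(time, event, group) {
  g <- as.integer(factor(group)) == 1L
  o <- e <- v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & g)
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- (o - e)^2 / v
  list(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE))
}

# Spearman as rank-then-Pearson.
spearman_oracle <- function(x, y) cor(rank(x), rank(y))

# Analytic Cox partial-likelihood score for 3 subjects with events at the
# two earliest (distinct) times; root found numerically and compared with
# the fitter.
cox_score_3subject <- function(beta, x) {
  w1 <- exp(beta * x) / sum(exp(beta * x))
  w2 <- exp(beta * x[2:3]) / sum(exp(beta * x[2:3]))
  (x[1] - sum(w1 * x)) + (x[2] - sum(w2 * x[2:3]))
}
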
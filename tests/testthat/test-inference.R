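# OLS, PRESS/LOO, best-subset selection, t tests, regional deltas.

test_that("two_sample_t: identical groups give t = 0, p = 1", {
  ht <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ht$statistic, 0)
  expect_equal(ht$p_value, 1)
})

test_that("two_sample_t matches a numeric-integration reference for both variants", {
  a <- c(12.1, 13.4, 11.8, 14.2, 12.9, 13.7)
  b <- c(10.9, 11.5, 12.3, 10.2, 11.8)
  # Welch statistic and df from the textbook formulas
  va <- var(a) / length(a); vb <- var(b) / length(b)
  tw <- (mean(a) - mean(b)) / sqrt(va + vb)
  dfw <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  dens <- function(x, df) gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
    (1 + x^2 / df)^(-(df + 1) / 2)
  p_oracle <- 2 * integrate(dens, abs(tw), Inf, df = dfw)$value
  ht <- two_sample_t(a, b, "welch")
  expect_equal(ht$statistic, tw, tolerance = 1e-12)
  expect_equal(ht$df, dfw, tolerance = 1e-12)
  expect_equal(ht$p_value, p_oracle, tolerance = 1e-6)
  # Student: pooled variance
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  ts <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  hts <- two_sample_t(a, b, "student")
  expect_equal(hts$statistic, ts, tolerance = 1e-12)
  expect_equal(hts$df, length(a) + length(b) - 2)
})

test_that("shifting one group monotonically decreases the p-value", {
  set.seed(5)
  a <- rnorm(15); b <- rnorm(15)
  b <- b - mean(b) + mean(a)  # equal means at delta = 0
  ps <- sapply(seq(0, 2, by = 0.25), function(d)
    two_sample_t(a, b + d)$p_value)
  expect_true(all(diff(ps) < 0))
})

test_that("degenerate t-test inputs are flagged", {
  expect_error(two_sample_t(1, c(1, 2)), "degenerate")
  expect_error(two_sample_t(c(1, 1, 1), c(2, 2), "welch"), "degenerate")
})

test_that("fit_ols reproduces exact linear data and indicator closed forms", {
  x <- data.frame(x = seq(0, 9))
  fit <- fit_ols(2 + 3 * x$x, x)
  expect_equal(unname(coef(fit)), c(2, 3), tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  # indicator-only model: group coefficient = difference of group means
  g <- rep(c(0, 1), c(6, 5))
  y <- c(rnorm(6, 10), rnorm(5, 12))
  fit2 <- fit_ols(y, data.frame(group = g))
  expect_equal(unname(coef(fit2)["group"]),
               mean(y[g == 1]) - mean(y[g == 0]), tolerance = 1e-12)
})

test_that("fit_ols equals the SVD pseudoinverse oracle to 1e-10", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(15:40, 1)
    X <- cbind(rnorm(n), rnorm(n, 3, 2), rbinom(n, 1, 0.5))
    y <- 1 + X %*% c(0.5, -1.2, 2) + rnorm(n)
    fit <- fit_ols(y, as.data.frame(X))
    oracle <- pinv_ols(as.vector(y), cbind(1, X))
    expect_equal(unname(coef(fit)), oracle$beta, tolerance = 1e-10)
    expect_equal(unname(fit$se), oracle$se, tolerance = 1e-10)
    # adjusted R2 from its definition
    r2 <- fit$r_squared
    expect_equal(fit$adj_r_squared,
                 1 - (1 - r2) * (n - 1) / (n - ncol(X) - 1),
                 tolerance = 1e-12)
  }
})

test_that("rank-deficient designs are rejected naming a column", {
  x <- data.frame(a = 1:10, b = 2 * (1:10))
  expect_error(fit_ols(rnorm(10), x), "collinear.*b")
})

test_that("LOO leverage identity equals literal refits; perfect fit scores 1", {
  set.seed(77)
  for (rep in 1:6) {
    n <- sample(8:30, 1)
    x <- data.frame(u = rnorm(n), v = runif(n))
    y <- 0.3 + x$u - 2 * x$v + rnorm(n, 0, 0.5)
    fit <- fit_ols(y, x)
    expect_equal(loo_score(fit), literal_loo_press(y, x),
                 tolerance = 1e-10)
  }
  x <- data.frame(x = 1:12)
  expect_equal(loo_score(fit_ols(5 - 2 * x$x, x)), 1)
})

test_that("adding a pure-noise predictor does not raise predictive R2 on average", {
  set.seed(13)
  diffs <- replicate(200, {
    n <- 40
    x <- data.frame(x = rnorm(n))
    y <- 1 + 0.8 * x$x + rnorm(n)
    base <- loo_score(fit_ols(y, x))
    noisy <- loo_score(fit_ols(y, cbind(x, z = rnorm(n))))
    noisy - base
  })
  expect_lte(mean(diffs), 0)
})

test_that("select_model picks the generating predictor and reports all subsets", {
  set.seed(2)
  n <- 80
  cand <- data.frame(group = rbinom(n, 1, 0.5))
  y <- 9 + 1.5 * cand$group + rnorm(n, 0, 0.3)
  sel <- select_model(y, cand)
  expect_identical(sel$selected, "group")
  expect_equal(nrow(sel$table), 2)  # intercept-only + {group}
  sel2 <- select_model(y, cand, criterion = "loo_press")
  expect_identical(sel2$selected, "group")
})

test_that("strong group signal is recovered in at least 95% of seeded runs", {
  hits <- sapply(1:100, function(i) {
    set.seed(i)
    n <- 200
    cand <- data.frame(group = rbinom(n, 1, 0.5),
                       sex = rbinom(n, 1, 0.5), age = rnorm(n, 25, 3))
    y <- 9 + 1.5 * cand$group + rnorm(n, 0, 0.3)
    "group" %in% select_model(y, cand)$selected
  })
  expect_gte(mean(hits), 0.95)
})

test_that("with all-noise candidates the intercept-only model wins most runs", {
  # max-adjusted-R2 keeps a single noise predictor only when its F > 1
  # (probability ~ 0.32), so the intercept-only model wins the majority;
  # as the all-noise pool grows, maximizing over subsets increasingly
  # overfits — the motivation for the LOO-PRESS criterion, which stays
  # majority-correct with a larger pool
  wins_adj <- sapply(1:100, function(i) {
    set.seed(1000 + i)
    n <- 200
    length(select_model(rnorm(n), data.frame(a = rnorm(n)))$selected) == 0
  })
  expect_gt(mean(wins_adj), 0.5)
  wins_loo <- sapply(1:100, function(i) {
    set.seed(3000 + i)
    n <- 200
    cand <- data.frame(a = rnorm(n), b = rnorm(n))
    length(select_model(rnorm(n), cand, "loo_press")$selected) == 0
  })
  expect_gt(mean(wins_loo), 0.5)
})

test_that("selection ties break toward fewer predictors, then lexicographic", {
  n <- 30
  set.seed(9)
  a <- rnorm(n)
  y <- 2 + a + rnorm(n, 0, 0.1)
  # duplicate columns: {a} and {b} tie exactly, {a,b} is collinear and
  # drops out; the lexicographic tie-break picks "a"
  sel <- select_model(y, data.frame(b = a, a = a))
  expect_identical(sel$selected, "a")
  # exact duplicates of the winner at larger size never displace it
  expect_identical(sel$table$score[sel$table$subset == "a"],
                   sel$table$score[sel$table$subset == "b"])
})

test_that("regional deltas cancel common group shifts and flag distal-specific ones", {
  mdl_common <- list(intercept = 9, group_effect = 1.4, residual_sd = 0)
  p <- cohort_params(
    n_control = 10, n_skier = 10, n_female_control = 5, n_female_skier = 5,
    age = list(control = c(mean = 25, sd = 0), skier = c(mean = 24, sd = 0)),
    weight = list(control = c(mean = 66, sd = 0), skier = c(mean = 74, sd = 0)),
    height = list(control = c(mean = 172, sd = 0), skier = c(mean = 173, sd = 0)),
    tendon_length = c(mean = 46, sd = 0), csa = c(mean = 100, sd = 0),
    swv_model = list(proximal = mdl_common, mid = mdl_common,
                     distal = mdl_common), seed = 1L)
  co <- simulate_cohort(p)
  # common group shift: every subject's deltas are identically 0
  expect_true(all(co$swv_distal - co$swv_mid == 0))
  expect_true(all(co$swv_proximal - co$swv_mid == 0))
})

test_that("regional delta test holds its type-I error and detects distal offsets", {
  mk <- function(distal_offset) {
    mdl <- function(extra = 0) list(intercept = 9, group_effect = 1,
                                    residual_sd = 0.5)
    m <- list(proximal = mdl(), mid = mdl(), distal = mdl())
    m$distal$group_effect <- 1 + distal_offset
    cohort_params(
      n_control = 38, n_skier = 30, n_female_control = 20,
      n_female_skier = 14,
      age = list(control = c(mean = 25, sd = 2), skier = c(mean = 24, sd = 2)),
      weight = list(control = c(mean = 66, sd = 10), skier = c(mean = 74, sd = 10)),
      height = list(control = c(mean = 172, sd = 9), skier = c(mean = 173, sd = 9)),
      tendon_length = c(mean = 46, sd = 4), csa = c(mean = 100, sd = 15),
      swv_model = m, seed = 1L)
  }
  null_p <- mk(0)
  rej <- sapply(1:1000, function(i) {
    co <- simulate_cohort(null_p, seed = i)
    regional_delta_test(co)$distal_minus_mid$test$p_value < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 0.025)
  alt_p <- mk(0.8)
  power <- mean(sapply(1:500, function(i) {
    co <- simulate_cohort(alt_p, seed = i)
    regional_delta_test(co)$distal_minus_mid$test$p_value < 0.05
  }))
  expect_gt(power, 0.9)
})

test_that("cohort_inference drops group within a single study group", {
  co <- simulate_cohort(study_cohort_params(), seed = 3)
  ci <- cohort_inference(co, scope = "skier")
  expect_false("group" %in% unlist(lapply(ci$fits, `[[`, "selected")))
  tab <- tendonswe:::inference_table(ci)
  expect_true(all(c("region", "predictor", "estimate", "std_error",
                    "p_value") %in% names(tab)))
})
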
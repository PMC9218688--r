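# Inference layer: OLS with full summary statistics, PRESS-based
# leave-one-out predictive scoring, exhaustive best-subset model
# selection, Welch/Student two-sample t tests, and between-group tests on
# regional SWV deltas. No multiplicity correction is applied (results are
# reported as unadjusted p-values at alpha = 0.05, as is conventional for
# this analysis).

#' Ordinary least squares with full summary statistics
#'
#' Fits `y ~ 1 + x` by QR decomposition and reports coefficients, standard
#' errors, t statistics, two-sided p-values, R-squared and adjusted
#' R-squared. The intercept is always included.
#'
#' @param y numeric response vector.
#' @param x data frame (or matrix) of named numeric predictors; may have
#'   zero columns for the intercept-only model.
#' @return object of class `ols_fit` with fields `coefficients`, `se`,
#'   `t`, `p`, `r_squared`, `adj_r_squared`, `sigma`, `df_residual`, `n`,
#'   `fitted`, `residuals`, `leverage`, `predictors`.
#' @examples
#' set.seed(1)
#' x <- data.frame(dose = 1:10)
#' fit <- fit_ols(2 + 3 * x$dose + rnorm(10, 0, 0.1), x)
#' coef(fit)
#' @export
fit_ols <- function(y, x) {
  y <- as.numeric(y)
  x <- as.data.frame(x)
  n <- length(y)
  stopifnot(nrow(x) == n || ncol(x) == 0, all(is.finite(y)))
  k <- ncol(x)
  if (n <= k + 1) stop("need n > k + 1 observations")
  X <- cbind(`(Intercept)` = 1, as.matrix(x))
  if (!all(is.finite(X))) stop("non-finite predictor values")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("collinear design: column(s) ", paste(drop, collapse = ", "))
  }
  beta <- qr.coef(qx, y)
  fitted <- as.vector(X %*% beta)
  res <- y - fitted
  df <- n - (k + 1)
  rss <- sum(res^2)
  sigma2 <- rss / df
  XtXinv <- chol2inv(qr.R(qx))
  se <- sqrt(diag(XtXinv) * sigma2)
  names(se) <- names(beta)
  tval <- beta / se
  pval <- 2 * pt(abs(tval), df, lower.tail = FALSE)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - rss / sst else 1
  adj <- if (k == 0) 0 else 1 - (1 - r2) * (n - 1) / df
  h <- rowSums(qr.Q(qx)^2)
  structure(list(coefficients = beta, se = se, t = tval, p = pval,
                 r_squared = r2, adj_r_squared = adj,
                 sigma = sqrt(sigma2), df_residual = df, n = n,
                 fitted = fitted, residuals = res, leverage = h,
                 predictors = colnames(x)),
            class = "ols_fit")
}

#' @export
coef.ols_fit <- function(object, ...) object$coefficients

#' @export
residuals.ols_fit <- function(object, ...) object$residuals

#' @export
predict.ols_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  X <- cbind(1, as.matrix(as.data.frame(newdata)[, object$predictors,
                                                 drop = FALSE]))
  as.vector(X %*% object$coefficients)
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("OLS fit: n = %d, R² = %.4f, adj. R² = %.4f, sigma = %.4f\n",
              x$n, x$r_squared, x$adj_r_squared, x$sigma))
  tab <- data.frame(Estimate = x$coefficients, `Std.Error` = x$se,
                    t = x$t, `p.value` = x$p, check.names = FALSE)
  print(round(tab, 4))
  invisible(x)
}

#' @export
summary.ols_fit <- function(object, ...) {
  print(object)
  cat(sprintf("LOO predictive R² (PRESS): %.4f\n", loo_score(object)))
  invisible(object)
}

#' Leave-one-out predictive R-squared (PRESS)
#'
#' PRESS-based predictive R-squared, `1 - PRESS / SStot`, with PRESS
#' computed through the closed-form leverage identity
#' `e_(i) = e_i / (1 - h_i)` — exactly equal to refitting the model n
#' times with one point left out.
#'
#' @param fit an [fit_ols()] object.
#' @return predictive R-squared (can be negative; 1 = perfect).
#' @export
loo_score <- function(fit) {
  stopifnot(inherits(fit, "ols_fit"))
  h <- fit$leverage
  if (any(1 - h < 1e-10))
    stop("leverage of 1: leave-one-out prediction undefined for some point")
  press <- sum((fit$residuals / (1 - h))^2)
  sst <- sum((fit$fitted + fit$residuals -
                mean(fit$fitted + fit$residuals))^2)
  if (sst == 0) return(1)
  1 - press / sst
}

#' Exhaustive best-subset model selection
#'
#' Scores every subset of the candidate predictors (including the
#' intercept-only model) by the chosen criterion and returns the best
#' subset together with its full-data OLS fit. Mirrors the approach of
#' selecting the inference model as the predictor set with the best
#' predictive performance. Ties are broken toward fewer predictors, then
#' lexicographically by predictor names. Deterministic.
#'
#' @param y numeric response.
#' @param candidates data frame of named candidate predictors (at most 12
#'   for the exhaustive 2^k enumeration).
#' @param criterion `"adjusted_r2"` (default) or `"loo_press"`
#'   (leave-one-out predictive R-squared).
#' @return object of class `model_selection`: `table` (one row per subset
#'   with its score), `selected` (character vector of chosen predictors),
#'   `fit` (the final [fit_ols()] on full data), `criterion`.
#' @export
select_model <- function(y, candidates,
                         criterion = c("adjusted_r2", "loo_press")) {
  criterion <- match.arg(criterion)
  candidates <- as.data.frame(candidates)
  k <- ncol(candidates)
  if (k > 12) stop("at most 12 candidates (exhaustive enumeration)")
  nm <- sort(colnames(candidates))
  subsets <- list(character(0))
  for (m in seq_len(k))
    subsets <- c(subsets, combn(nm, m, simplify = FALSE))
  # collinear subsets (or leverage-1 LOO) score -Inf: they are excluded
  # from the search rather than aborting the whole enumeration
  score_one <- function(vars) {
    tryCatch({
      fit <- fit_ols(y, candidates[, vars, drop = FALSE])
      if (criterion == "adjusted_r2") fit$adj_r_squared else loo_score(fit)
    }, error = function(e) -Inf)
  }
  scores <- vapply(subsets, score_one, numeric(1))
  sizes <- lengths(subsets)
  keys <- vapply(subsets, paste, character(1), collapse = "+")
  ord <- order(-scores, sizes, keys)
  best <- subsets[[ord[1]]]
  structure(list(table = data.frame(subset = keys, size = sizes,
                                    score = scores,
                                    stringsAsFactors = FALSE),
                 selected = best, criterion = criterion,
                 fit = fit_ols(y, candidates[, best, drop = FALSE])),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat(sprintf("Best-subset selection (%s) over %d subsets\n",
              x$criterion, nrow(x$table)))
  cat("  selected:",
      if (length(x$selected)) paste(x$selected, collapse = " + ")
      else "(intercept only)", "\n")
  print(x$fit)
  invisible(x)
}

#' @export
summary.model_selection <- function(object, ...) {
  tab <- object$table[order(-object$table$score), ]
  cat("Top subsets:\n")
  print(utils::head(tab, 8), row.names = FALSE)
  print(object)
  invisible(object)
}

#' Independent two-sample t test
#'
#' Thin wrapper over the standard two-sample t test with a selectable
#' variant: Welch (unequal variances; default) or Student (pooled).
#'
#' @param a,b numeric group samples (each n >= 2, finite).
#' @param variant `"welch"` (default) or `"student"`.
#' @return object of class `swv_ttest`: `statistic`, `df`, `p_value`,
#'   `mean_difference` (mean(a) - mean(b)), `variant`, `n`.
#' @export
two_sample_t <- function(a, b, variant = c("welch", "student")) {
  variant <- match.arg(variant)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2 || !all(is.finite(c(a, b))))
    stop("degenerate input: each group needs >= 2 finite values")
  if (variant == "welch" && var(a) == 0 && var(b) == 0)
    stop("degenerate input: zero variance in both groups (welch)")
  ht <- stats::t.test(a, b, var.equal = (variant == "student"))
  structure(list(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value,
                 mean_difference = mean(a) - mean(b),
                 variant = variant, n = c(length(a), length(b))),
            class = "swv_ttest")
}

#' @export
print.swv_ttest <- function(x, ...) {
  cat(sprintf("%s two-sample t test: t = %.3f, df = %.2f, p = %.4g (diff = %.3f)\n",
              x$variant, x$statistic, x$df, x$p_value, x$mean_difference))
  invisible(x)
}

#' Between-group comparison of regional SWV deltas
#'
#' Computes per-subject regional deltas (distal - mid and proximal - mid)
#' and compares them between the skier and control groups with a
#' two-sample t test. A group effect common to all regions cancels in the
#' deltas, so this isolates regional-pattern differences. Subjects with an
#' undefined region are dropped (counts reported).
#'
#' @param cohort a cohort data frame (see [simulate_cohort()]) with
#'   columns `group`, `swv_proximal`, `swv_mid`, `swv_distal`.
#' @param variant t-test variant, default `"welch"`.
#' @return object of class `regional_delta_test`: one entry per delta with
#'   per-group means, the test, and the number of subjects dropped.
#' @export
regional_delta_test <- function(cohort, variant = "welch") {
  need <- c("group", "swv_proximal", "swv_mid", "swv_distal")
  stopifnot(all(need %in% names(cohort)))
  ok <- stats::complete.cases(cohort[, need])
  dropped <- sum(!ok)
  d <- cohort[ok, ]
  res <- lapply(list(distal_minus_mid = d$swv_distal - d$swv_mid,
                     proximal_minus_mid = d$swv_proximal - d$swv_mid),
                function(delta) {
    sk <- delta[d$group == "skier"]
    co <- delta[d$group == "control"]
    list(group_means = c(skier = mean(sk), control = mean(co)),
         test = two_sample_t(sk, co, variant))
  })
  structure(c(res, list(n_dropped = dropped)),
            class = "regional_delta_test")
}

#' @export
print.regional_delta_test <- function(x, ...) {
  cat("Regional SWV delta comparison (skier vs control)\n")
  for (nm in c("distal_minus_mid", "proximal_minus_mid")) {
    e <- x[[nm]]
    cat(sprintf("  %-19s skier %+.3f, control %+.3f, p = %.4g\n",
                nm, e$group_means["skier"], e$group_means["control"],
                e$test$p_value))
  }
  if (x$n_dropped > 0)
    cat(sprintf("  (%d subject(s) dropped for undefined regions)\n",
                x$n_dropped))
  invisible(x)
}

#' Full cohort inference mirroring the study's model tables
#'
#' Runs exhaustive best-subset selection per tendon region. For the whole
#' population the candidate pool is {group, sex, age, weight, height,
#' BMI, tendon length, CSA}; within a single group, `group` is dropped.
#' Predictors not selected get no effect estimates.
#'
#' @param cohort a cohort data frame (see [simulate_cohort()]).
#' @param scope `"population"`, `"skier"` or `"control"`.
#' @param criterion selection criterion, see [select_model()].
#' @param regions regions to model.
#' @return named list of [select_model()] results, class
#'   `cohort_inference`.
#' @export
cohort_inference <- function(cohort, scope = c("population", "skier",
                                               "control"),
                             criterion = c("adjusted_r2", "loo_press"),
                             regions = c("overall", "proximal", "mid",
                                         "distal")) {
  scope <- match.arg(scope)
  criterion <- match.arg(criterion)
  d <- if (scope == "population") cohort else cohort[cohort$group == scope, ]
  pool <- c("group", "sex", "age", "weight", "height", "bmi",
            "tendon_length", "csa")
  if (scope != "population") pool <- setdiff(pool, "group")
  X <- cohort_design(d, pool)
  fits <- lapply(regions, function(r)
    select_model(d[[paste0("swv_", r)]], X, criterion))
  names(fits) <- regions
  structure(list(fits = fits, scope = scope, criterion = criterion),
            class = "cohort_inference")
}

#' @export
print.cohort_inference <- function(x, ...) {
  cat(sprintf("Cohort inference (%s, criterion = %s)\n", x$scope,
              x$criterion))
  for (r in names(x$fits)) {
    sel <- x$fits[[r]]$selected
    cat(sprintf("  %-9s -> %s\n", r,
                if (length(sel)) paste(sel, collapse = " + ")
                else "(intercept only)"))
  }
  invisible(x)
}

# Serializable Table-2/3-style layout: predictor, estimate, SE, p per
# region (intercept omitted, mirroring the published tables).
inference_table <- function(ci) {
  rows <- do.call(rbind, lapply(names(ci$fits), function(r) {
    fit <- ci$fits[[r]]$fit
    sel <- ci$fits[[r]]$selected
    if (!length(sel)) return(NULL)
    data.frame(region = r, predictor = sel,
               estimate = unname(fit$coefficients[sel]),
               std_error = unname(fit$se[sel]),
               p_value = unname(fit$p[sel]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(region = character(0), predictor = character(0),
                       estimate = numeric(0), std_error = numeric(0),
                       p_value = numeric(0))
  rows
}
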
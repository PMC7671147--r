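#' Permutational two-sample T-test
#'
#' Tests for a difference between two groups by permuting group labels.
#' The default statistic is the difference of group means; a studentized
#' (Welch t) statistic is available, the two being permutationally
#' equivalent for equal-variance designs. The two-sided p-value uses the
#' add-one convention `p = (1 + #{|T_perm| >= |T_obs|}) / (1 + n_perm)`,
#' which includes the observed labelling and so can never be 0. With
#' `method = "exhaustive"` all `choose(n1 + n2, n1)` label assignments are
#' enumerated instead and the p-value is the exact fraction
#' `#{|T| >= |T_obs|} / n_assignments`.
#'
#' @param group_a,group_b numeric vectors (each of length >= 2).
#' @param n_perm number of random permutations (ignored for exhaustive).
#' @param seed integer seed making the Monte-Carlo draw reproducible.
#' @param statistic `"mean_diff"` (default) or `"t"`.
#' @param method `"montecarlo"` (default) or `"exhaustive"`.
#' @return an object of class `perm_test_result`: list with
#'   `observed_diff` (mean of a minus mean of b), `statistic_value`,
#'   `p_value`, `n_permutations`, `seed`, `group_sizes`, `method`.
#' @export
perm_t_test <- function(group_a, group_b, n_perm = 9999L, seed = 1L,
                        statistic = c("mean_diff", "t"),
                        method = c("montecarlo", "exhaustive")) {
  statistic <- match.arg(statistic)
  method <- match.arg(method)
  a <- as.numeric(group_a); b <- as.numeric(group_b)
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2 || n2 < 2)
    stopf("insufficient data: each group needs at least 2 values")
  x <- c(a, b)
  n <- n1 + n2
  total <- sum(x)
  stat_fun <- if (statistic == "mean_diff") {
    function(ia) {
      sa <- sum(x[ia])
      sa / n1 - (total - sa) / n2
    }
  } else {
    function(ia) {
      xa <- x[ia]; xb <- x[-ia]
      (mean(xa) - mean(xb)) /
        sqrt(stats::var(xa) / n1 + stats::var(xb) / n2)
    }
  }
  obs <- stat_fun(seq_len(n1))
  tol <- 1e-12 * (abs(obs) + 1)
  if (method == "exhaustive") {
    combos <- utils::combn(n, n1)
    perm_stats <- apply(combos, 2, stat_fun)
    p <- mean(abs(perm_stats) >= abs(obs) - tol)
    n_used <- ncol(combos)
  } else {
    set.seed(seed)
    perm_stats <- vapply(seq_len(n_perm),
                         function(i) stat_fun(sample.int(n, n1)), 0)
    p <- (1 + sum(abs(perm_stats) >= abs(obs) - tol)) / (1 + n_perm)
    n_used <- as.integer(n_perm)
  }
  structure(list(observed_diff = mean(a) - mean(b),
                 statistic_value = obs, statistic = statistic,
                 p_value = p, n_permutations = n_used,
                 seed = as.integer(seed), group_sizes = c(n1, n2),
                 method = method),
            class = "perm_test_result")
}

#' @export
print.perm_test_result <- function(x, ...) {
  cat(sprintf(
    "<perm_test_result> diff = %.4g, p = %.4g (%s, %d permutations, n = %d vs %d)\n",
    x$observed_diff, x$p_value, x$method, x$n_permutations,
    x$group_sizes[1], x$group_sizes[2]))
  invisible(x)
}

#' Power-law fit by log-log regression
#'
#' Fits `y = c * x^slope` by ordinary least squares of `ln y` on `ln x`;
#' the slope is the power. This is the regression behind
#' [attenuation_fit()], exposed for direct use.
#'
#' @param x,y positive numeric vectors, length >= 3.
#' @return list with `slope`, `intercept` (`ln c`), `r_squared`.
#' @export
power_law_fit <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stopf("need at least 3 paired observations")
  if (any(x <= 0) || any(y <= 0))
    stopf("power-law fitting requires strictly positive x and y")
  ly <- log(y)
  fit <- lm(ly ~ log(x))
  # r^2 computed directly so exact fits do not trip summary.lm warnings
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((ly - mean(ly))^2)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2)
}

#' Group summary table with permutation tests
#'
#' Builds a Table-1-style summary: per metric and group, mean and standard
#' error, plus a two-group permutational T-test and a significance flag at
#' p < 0.05. Metrics missing for every individual are dropped with a
#' warning; a group with a single usable value gets `NA` for its SE and
#' the test is skipped for that metric.
#'
#' @param results per-individual metrics: a `data.frame`/matrix with one
#'   row per individual, or a list of named numeric vectors (e.g. from
#'   [kinematics_metrics()]). Non-finite values (e.g. the `Inf` sentinel of
#'   an all-forward displacement ratio) are excluded from means and tests.
#' @param grouping vector of group labels, one per individual (exactly 2
#'   distinct groups).
#' @param cfg a [run_config()] supplying `n_permutations` and `rng_seed`.
#' @return `data.frame` with columns `metric`, `mean_<g>`, `se_<g>`,
#'   `n_<g>` for each group, `p_value`, `significant`.
#' @export
build_summary <- function(results, grouping, cfg = run_config()) {
  if (is.list(results) && !is.data.frame(results))
    results <- do.call(rbind, lapply(results, function(r) r[order(names(r))]))
  results <- as.matrix(results)
  grouping <- as.character(grouping)
  if (nrow(results) != length(grouping))
    stopf("grouping must supply one label per individual")
  groups <- unique(grouping)
  if (length(groups) != 2) stopf("exactly 2 groups are required")
  rows <- list()
  for (m in colnames(results)) {
    vals <- results[, m]
    vals[!is.finite(vals)] <- NA_real_
    if (all(is.na(vals))) {
      warnf("metric '%s' missing for all individuals; omitted", m)
      next
    }
    va <- vals[grouping == groups[1] & !is.na(vals)]
    vb <- vals[grouping == groups[2] & !is.na(vals)]
    se <- function(v) if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
    p <- if (length(va) >= 2 && length(vb) >= 2)
      perm_t_test(va, vb, n_perm = cfg$n_permutations,
                  seed = cfg$rng_seed)$p_value
    else NA_real_
    row <- data.frame(metric = m,
                      mean_a = mean(va), se_a = se(va), n_a = length(va),
                      mean_b = mean(vb), se_b = se(vb), n_b = length(vb),
                      p_value = p,
                      significant = !is.na(p) && p < 0.05)
    rows[[length(rows) + 1]] <- row
  }
  out <- do.call(rbind, rows)
  names(out) <- sub("_a$", paste0("_", groups[1]),
                    sub("_b$", paste0("_", groups[2]), names(out)))
  rownames(out) <- NULL
  out
}
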
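# Statistical primitives used throughout: Model II (standardized major axis)
# regression, OLS, Welch's t, Wilcoxon rank-sum, seeded bootstrap, and a
# one-way PERMANOVA with an explicit sums-of-squares decomposition.

#' Model II (standardized major axis) regression
#'
#' Symmetric regression for the case where both variables carry comparable
#' random error (e.g. DOC exudation vs. NPP, both incubation-derived). The
#' slope is the standardized major axis (SMA) estimator
#' \eqn{b = \mathrm{sign}(r)\, s_y / s_x}; the line passes through the
#' centroid. The p-value is the Pearson correlation test (the SMA slope is a
#' monotone function of r, so the tests coincide).
#'
#' @param x,y numeric vectors of equal length (n >= 3), finite, with nonzero
#'   variance in both.
#' @return an object of class `"model2_fit"`: a list with `slope`,
#'   `intercept`, `r`, `r_squared`, `n`, `p_value`.
#' @examples
#' fit <- model2_regression(c(0, 1, 2), c(1, 2, 3))
#' fit$slope      # 1
#' fit$intercept  # 1
#' @export
model2_regression <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("model2_regression requires at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("model2_regression requires nonzero variance in both variables")
  r <- stats::cor(x, y)
  slope <- sign(r) * stats::sd(y) / stats::sd(x)
  if (r == 0) slope <- stats::sd(y) / stats::sd(x)  # sign convention: undefined at r = 0
  intercept <- mean(y) - slope * mean(x)
  p <- stats::cor.test(x, y)$p.value
  structure(
    list(slope = slope, intercept = intercept, r = r, r_squared = r^2,
         n = n, p_value = p),
    class = "model2_fit"
  )
}

#' @export
print.model2_fit <- function(x, ...) {
  cat(sprintf("Model II (SMA) fit: y = %.4g x + %.4g  (R2 = %.3f, n = %d, p = %.3g)\n",
              x$slope, x$intercept, x$r_squared, x$n, x$p_value))
  invisible(x)
}

#' Ordinary least squares regression of y on x
#'
#' Used when one variable is controlled or measured without random error
#' (light level, blade age).
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
ols_regression <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("ols_regression requires at least 3 complete pairs")
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # exact lines trip a summary.lm warning
  co <- stats::coef(sm)
  p <- if (nrow(co) < 2L || stats::sd(x) == 0) NA_real_ else co["x", "Pr(>|t|)"]
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = sm$r.squared,
       p_value = p,
       n = length(x))
}

#' Welch's unequal-variance t test
#'
#' @param a,b numeric vectors, each with n >= 2 and nonzero variance in at
#'   least one group.
#' @return list with `t`, `df` (Welch-Satterthwaite), `p_value` (two-sided),
#'   and group means.
#' @export
welch_t <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("welch_t requires n >= 2 in each group")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    # degenerate: identical constants compare equal, otherwise no test possible
    if (mean(a) == mean(b))
      return(list(t = 0, df = length(a) + length(b) - 2, p_value = 1,
                  mean_a = mean(a), mean_b = mean(b)))
    stop("welch_t: both groups have zero variance")
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' Wilcoxon rank-sum test
#'
#' Midranks for ties; exact p for small tie-free samples, normal
#' approximation with continuity correction otherwise (the behaviour of
#' [stats::wilcox.test()]).
#'
#' @param a,b numeric vectors, non-empty.
#' @return list with `W` (rank-sum statistic of the first sample) and
#'   `p_value` (two-sided).
#' @export
wilcoxon_rank_sum <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) == 0L || length(b) == 0L)
    stop("wilcoxon_rank_sum requires non-empty groups")
  ht <- suppressWarnings(stats::wilcox.test(a, b))
  list(W = unname(ht$statistic), p_value = ht$p.value)
}

#' Seeded bootstrap of a sample statistic
#'
#' Resamples `values` with replacement `n_sim` times and summarizes the
#' bootstrap distribution of `statistic` by its median, standard deviation
#' (reported as the standard error) and 2.5/97.5 percentile confidence
#' interval. This is the uncertainty machinery used for the three DOC
#' exudation rate classes (default 100,000 simulations).
#'
#' @param values numeric vector, n >= 2.
#' @param statistic function of a numeric vector returning a scalar
#'   (default [stats::median()]; the mean is the common alternative).
#' @param n_sim number of bootstrap resamples.
#' @param seed integer seed (required: results are reproducible by contract).
#' @return an object of class `"bootstrap_result"`: list with `statistic`
#'   (name), `median`, `se`, `ci_low`, `ci_high`, `n_sim`, `seed`, `n`.
#' @export
bootstrap_stat <- function(values, statistic = stats::median,
                           n_sim = 100000L, seed) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop("bootstrap_stat requires n >= 2")
  if (missing(seed) || !is.numeric(seed)) stop("bootstrap_stat requires a seed")
  if (n_sim < 100L) warning("n_sim < 100: confidence interval will be unstable")
  stat_name <- deparse(substitute(statistic))
  n <- length(values)
  boot <- local_seed(seed, {
    idx <- matrix(sample.int(n, n * n_sim, replace = TRUE), nrow = n)
    apply(idx, 2L, function(i) statistic(values[i]))
  })
  qs <- unname(stats::quantile(boot, c(0.025, 0.5, 0.975), type = 7))
  structure(
    list(statistic = stat_name, median = qs[2L], se = stats::sd(boot),
         ci_low = qs[1L], ci_high = qs[3L], n_sim = n_sim, seed = seed, n = n),
    class = "bootstrap_result"
  )
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Bootstrap %s (n = %d, %d simulations): %.3g +/- %.3g (95%% CI %.3g-%.3g)\n",
              x$statistic, x$n, x$n_sim, x$median, x$se, x$ci_low, x$ci_high))
  invisible(x)
}

# Run an expression under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' One-way PERMANOVA
#'
#' Permutational multivariate analysis of variance on a distance matrix
#' (Anderson 2001). Sums of squares are computed directly from squared
#' inter-point distances:
#' \deqn{SS_{tot} = \frac{1}{n}\sum_{i<j} d_{ij}^2, \qquad
#'       SS_{w} = \sum_g \frac{1}{n_g}\sum_{i<j \in g} d_{ij}^2,}
#' with \eqn{F = (SS_b/(g-1)) / (SS_w/(n-g))}, \eqn{R^2 = SS_b/SS_{tot}},
#' and \eqn{p = (1 + \#\{F_{perm} \ge F_{obs}\})/(1 + n_{perm})} under random
#' permutation of the group labels.
#'
#' @param x numeric matrix/data.frame (samples x variables) or a
#'   [stats::dist] object.
#' @param groups factor or vector of group labels, >= 2 groups with >= 2
#'   samples each.
#' @param n_perm number of label permutations (default 999).
#' @param seed integer seed for the permutations (required).
#' @param method distance for matrix input: `"euclidean"` (default; on the
#'   caller's scaling) or `"bray"` (Bray-Curtis, for raw compositions).
#' @return list with `F`, `r_squared`, `p_value`, `ss_total`, `ss_within`,
#'   `ss_between`, `df_between`, `df_within`, `n_perm`.
#' @export
permanova <- function(x, groups, n_perm = 999L, seed, method = c("euclidean", "bray")) {
  method <- match.arg(method)
  if (inherits(x, "dist")) {
    d2 <- as.matrix(x)^2
  } else {
    x <- as.matrix(x)
    d2 <- if (method == "euclidean") as.matrix(stats::dist(x))^2
          else bray_curtis(x)^2
  }
  groups <- as.factor(groups)
  n <- nrow(d2)
  if (length(groups) != n) stop("length(groups) must match the number of samples")
  if (nlevels(droplevels(groups)) < 2L) stop("permanova requires >= 2 groups")
  if (any(table(groups) < 2L)) stop("permanova requires >= 2 samples per group")
  if (missing(seed)) stop("permanova requires a seed for the permutations")
  g <- nlevels(droplevels(groups))
  ss_total <- sum(d2[upper.tri(d2)]) / n

  ss_within_for <- function(lab) {
    sw <- 0
    for (lv in levels(lab)) {
      sel <- which(lab == lv)
      if (length(sel) > 1L) {
        sub <- d2[sel, sel, drop = FALSE]
        sw <- sw + sum(sub[upper.tri(sub)]) / length(sel)
      }
    }
    sw
  }
  f_for <- function(lab) {
    sw <- ss_within_for(lab)
    ((ss_total - sw) / (g - 1)) / (sw / (n - g))
  }

  f_obs <- f_for(groups)
  p <- local_seed(seed, {
    hits <- 0L
    for (k in seq_len(n_perm)) {
      if (f_for(groups[sample.int(n)]) >= f_obs - 1e-12) hits <- hits + 1L
    }
    (1 + hits) / (1 + n_perm)
  })
  sw <- ss_within_for(groups)
  list(F = f_obs, r_squared = (ss_total - sw) / ss_total, p_value = p,
       ss_total = ss_total, ss_within = sw, ss_between = ss_total - sw,
       df_between = g - 1L, df_within = n - g, n_perm = n_perm)
}

# Bray-Curtis dissimilarity matrix for nonnegative data (rows = samples).
bray_curtis <- function(x) {
  if (any(x < 0)) stop("Bray-Curtis requires nonnegative data")
  n <- nrow(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- sum(abs(x[i, ] - x[j, ]))
      t <- sum(x[i, ] + x[j, ])
      d[i, j] <- d[j, i] <- if (t == 0) 0 else s / t
    }
  }
  d
}
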
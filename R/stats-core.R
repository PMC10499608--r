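# Statistical primitives used throughout the pipeline: type II (ranged major
# axis) regression, saturating light-response fits, classical group tests and
# time-based rolling means.

#' Ranged-major-axis (type II) regression
#'
#' Fits a symmetric (model II) regression line by the ranged-major-axis (RMA)
#' procedure: both variables are range-transformed to \[0, 1\] by
#' `(v - min(v)) / (max(v) - min(v))`, the major-axis slope is computed on the
#' transformed data, and the slope is back-transformed by the ratio of the raw
#' ranges. The line passes through the bivariate means. RMA treats error in
#' `x` and `y` symmetrically, which is appropriate when both axes are measured
#' quantities (for example a fluorescence-yield anomaly against a sea surface
#' temperature anomaly), and unlike the plain major axis it is invariant to
#' the units in which either variable is expressed.
#'
#' The association p-value is, by default, the parametric two-tailed test of
#' the Pearson correlation (association significance does not depend on which
#' symmetric slope estimator is used). Setting `n_permutations > 0` replaces
#' it with a permutation p-value for `|r|`. Confidence limits on the slope
#' come from a seeded percentile bootstrap over pairs.
#'
#' @param x,y Numeric vectors of equal length (>= 3 complete pairs), each with
#'   nonzero range. Pairs with a missing value in either variable are dropped.
#' @param n_permutations Number of permutations for the permutation p-value;
#'   `0` (default) uses the parametric correlation test.
#' @param n_boot Number of bootstrap resamples for the slope confidence
#'   interval; `0` skips the bootstrap (CI set to the point estimate).
#' @param seed Integer seed controlling the bootstrap and permutation draws;
#'   `NULL` leaves the RNG state alone.
#' @param conf_level Confidence level for the slope interval.
#' @param method `"ranged_major_axis"` (default) or
#'   `"ordinary_least_squares"` for a conventional OLS fit with the same
#'   output contract.
#'
#' @return An object of class `"rma_fit"`: a list with `slope`, `intercept`,
#'   `r_squared`, `p_value`, `slope_ci_low`, `slope_ci_high`, `n`, `method`.
#' @examples
#' fit <- rma_regression(c(1, 2, 3, 4), c(3, 5, 7, 9), n_boot = 0)
#' fit$slope      # 2
#' fit$intercept  # 1
#' @export
rma_regression <- function(x, y, n_permutations = 0L, n_boot = 1999L,
                           seed = NULL, conf_level = 0.95,
                           method = c("ranged_major_axis",
                                      "ordinary_least_squares")) {
  method <- match.arg(method)
  if (length(x) != length(y)) {
    stop("`x` and `y` must have the same length", call. = FALSE)
  }
  keep <- is.finite(x) & is.finite(y)
  x <- as.numeric(x[keep])
  y <- as.numeric(y[keep])
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (diff(range(x)) == 0 || diff(range(y)) == 0) {
    stop("zero range in `x` or `y`: ranging transform undefined",
         call. = FALSE)
  }

  slope_fun <- if (method == "ranged_major_axis") .rma_slope else .ols_slope
  slope <- slope_fun(x, y)
  intercept <- mean(y) - slope * mean(x)

  r <- stats::cor(x, y)
  r_squared <- r^2

  p_value <- if (n_permutations > 0L) {
    .with_seed(seed, {
      r_obs <- abs(r)
      hits <- sum(vapply(seq_len(n_permutations), function(i) {
        abs(stats::cor(x, sample(y))) >= r_obs - 1e-15
      }, logical(1)))
      (1 + hits) / (n_permutations + 1)
    })
  } else {
    # two-tailed t-test of the Pearson correlation
    if (abs(r) >= 1) {
      .Machine$double.xmin
    } else {
      tt <- r * sqrt((n - 2) / (1 - r^2))
      2 * stats::pt(-abs(tt), df = n - 2)
    }
  }

  ci <- c(slope, slope)
  if (n_boot > 0L) {
    boot <- .with_seed(seed, {
      out <- numeric(n_boot)
      for (b in seq_len(n_boot)) {
        repeat {
          idx <- sample.int(n, n, replace = TRUE)
          if (diff(range(x[idx])) > 0 && diff(range(y[idx])) > 0) break
        }
        out[b] <- slope_fun(x[idx], y[idx])
      }
      out
    })
    alpha <- 1 - conf_level
    ci <- unname(stats::quantile(boot, c(alpha / 2, 1 - alpha / 2),
                                 na.rm = TRUE, type = 7))
    # the percentile interval is widened, if necessary, to contain the
    # point estimate (guaranteed contract of the result object)
    ci[1] <- min(ci[1], slope)
    ci[2] <- max(ci[2], slope)
  }

  structure(
    list(slope = slope, intercept = intercept, r_squared = r_squared,
         p_value = p_value, slope_ci_low = ci[1], slope_ci_high = ci[2],
         n = n, method = method),
    class = "rma_fit"
  )
}

# Ranged-MA slope: major-axis slope on range-transformed data, back-scaled
# by the ratio of raw ranges.
.rma_slope <- function(x, y) {
  rx <- diff(range(x))
  ry <- diff(range(y))
  u <- (x - min(x)) / rx
  v <- (y - min(y)) / ry
  suu <- stats::var(u)
  svv <- stats::var(v)
  suv <- stats::cov(u, v)
  if (suv == 0) {
    # degenerate: principal axis aligned with a coordinate axis
    b <- if (suu >= svv) 0 else Inf
  } else {
    b <- (svv - suu + sqrt((svv - suu)^2 + 4 * suv^2)) / (2 * suv)
  }
  b * ry / rx
}

.ols_slope <- function(x, y) {
  stats::cov(x, y) / stats::var(x)
}

#' @export
print.rma_fit <- function(x, ...) {
  cat(sprintf("%s regression (n = %d)\n",
              if (x$method == "ranged_major_axis") "Ranged major axis"
              else "Ordinary least squares", x$n))
  cat(sprintf("  slope     %.6g  [%.6g, %.6g]\n",
              x$slope, x$slope_ci_low, x$slope_ci_high))
  cat(sprintf("  intercept %.6g\n", x$intercept))
  cat(sprintf("  R2 = %.3f, p = %.3g\n", x$r_squared, x$p_value))
  invisible(x)
}

#' Saturating hyperbolic-tangent light-response fit
#'
#' Fits `yield = a * tanh(b * par / a)` by nonlinear least squares
#' (Levenberg-Marquardt). `a` is the light-saturated plateau in the units of
#' `yield`; `b` is the light-limited initial slope (yield per PAR unit):
#' the curve tends to `a` as PAR grows and has derivative `b` at PAR = 0.
#'
#' @param par Photosynthetically active radiation
#'   (\eqn{\mu}mol photons m\eqn{^{-2}} s\eqn{^{-1}}), >= 5 points spanning
#'   the light-limited and saturated regions.
#' @param yield Fluorescence yield (same length as `par`).
#' @param init Optional named starting values `c(a = , b = )`; a data-driven
#'   default is used otherwise.
#' @return An object of class `"tanh_fit"`: list with `a`, `b`,
#'   `residual_rms`, `converged`, `n`.
#' @seealso [tanh_response()] to evaluate the fitted curve.
#' @export
fit_tanh_response <- function(par, yield, init = NULL) {
  keep <- is.finite(par) & is.finite(yield)
  par <- as.numeric(par[keep])
  yield <- as.numeric(yield[keep])
  if (length(par) < 5L) stop("need at least 5 finite points", call. = FALSE)
  if (diff(range(par)) == 0) stop("PAR values are constant", call. = FALSE)
  if (stats::sd(yield) == 0) {
    # constant yield: informative only when every point sits on the
    # light-saturated plateau (all PAR > 0); the plateau is the value and
    # the initial slope is unidentifiable (set so saturation holds at the
    # lowest observed PAR)
    if (min(par) <= 0) {
      stop("constant yield with light-limited points: degenerate response",
           call. = FALSE)
    }
    a <- mean(yield)
    if (a <= 0) {
      stop("constant non-positive yield: degenerate response",
           call. = FALSE)
    }
    b <- a * atanh(1 - 1e-9) / min(par)
    return(structure(
      list(a = a, b = b,
           residual_rms = sqrt(mean((yield - tanh_response(par, a, b))^2)),
           converged = TRUE, n = length(par), plateau_only = TRUE),
      class = "tanh_fit"
    ))
  }
  if (is.null(init)) {
    a0 <- max(yield)
    if (a0 <= 0) a0 <- max(abs(yield)) + .Machine$double.eps
    # initial slope from the low-light third of the data
    lo <- par <= stats::quantile(par, 1 / 3)
    b0 <- if (sum(lo) >= 2 && diff(range(par[lo])) > 0) {
      abs(.ols_slope(par[lo], yield[lo]))
    } else {
      a0 / max(par)
    }
    if (!is.finite(b0) || b0 <= 0) b0 <- a0 / max(par)
    init <- c(a = a0, b = b0)
  }
  dat <- data.frame(par = par, yield = yield)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      yield ~ a * tanh(b * par / a),
      data = dat, start = as.list(init),
      lower = c(a = .Machine$double.eps, b = .Machine$double.eps),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    stop(structure(
      class = c("ferrolux_fit_error", "error", "condition"),
      list(message = paste0("tanh light-response fit failed: ",
                            conditionMessage(fit)),
           call = sys.call(-1), last_iterate = init)
    ))
  }
  est <- stats::coef(fit)
  res <- stats::resid(fit)
  structure(
    list(a = unname(est["a"]), b = unname(est["b"]),
         residual_rms = sqrt(mean(res^2)),
         converged = fit$convInfo$isConv, n = length(par)),
    class = "tanh_fit"
  )
}

#' Evaluate the saturating tanh light-response curve
#'
#' @param par PAR values at which to evaluate the curve.
#' @param a Light-saturated plateau.
#' @param b Light-limited initial slope.
#' @return `a * tanh(b * par / a)`.
#' @export
tanh_response <- function(par, a, b) {
  a * tanh(b * par / a)
}

#' @export
print.tanh_fit <- function(x, ...) {
  cat(sprintf("tanh light-response fit (n = %d%s)\n", x$n,
              if (isTRUE(x$converged)) "" else ", NOT converged"))
  cat(sprintf("  plateau a = %.6g, initial slope b = %.6g, rms = %.3g\n",
              x$a, x$b, x$residual_rms))
  invisible(x)
}

#' One-way ANOVA with Tukey's honestly-significant-difference test
#'
#' @param groups Named list of numeric vectors, one per treatment group
#'   (>= 2 groups, each with >= 2 replicates).
#' @param alpha Family-wise significance level for the Tukey flags.
#' @return List with `f_statistic`, `p_value`, `df`, `alpha`, and `table`, a
#'   tibble of pairwise comparisons (`pair`, `diff`, `ci_low`, `ci_high`,
#'   `p_adj`, `significant`).
#' @export
anova_tukey <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("`groups` must be a named list of >= 2 numeric vectors",
         call. = FALSE)
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("all groups must be named", call. = FALSE)
  }
  sizes <- lengths(groups)
  if (any(sizes < 2L)) {
    stop("every group needs >= 2 replicates", call. = FALSE)
  }
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), sizes), levels = names(groups))
  )
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  f_stat <- an[["F value"]][1]
  p_val <- an[["Pr(>F)"]][1]
  if (!is.finite(f_stat)) { # all residual variance zero, identical groups
    f_stat <- 0
    p_val <- 1
  }
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  tbl <- tibble::tibble(
    pair = rownames(tk),
    diff = tk[, "diff"],
    ci_low = tk[, "lwr"],
    ci_high = tk[, "upr"],
    p_adj = tk[, "p adj"],
    significant = tk[, "p adj"] < alpha
  )
  list(f_statistic = f_stat, p_value = p_val,
       df = unname(an[["Df"]]), alpha = alpha, table = tbl)
}

#' Two-sample unpaired t-test
#'
#' Welch's unequal-variance test by default; set `var_equal = TRUE` for the
#' pooled-variance form. Degenerate samples (zero variance in both groups)
#' follow the convention p = 1 for equal means and p = 0 otherwise.
#'
#' @param x,y Numeric vectors, each with >= 2 finite values.
#' @param var_equal Use the pooled-variance statistic.
#' @return List with `statistic`, `p_value`, `df`, `mean_x`, `mean_y`,
#'   `method`.
#' @export
ttest_unpaired <- function(x, y, var_equal = FALSE) {
  x <- as.numeric(x[is.finite(x)])
  y <- as.numeric(y[is.finite(y)])
  if (length(x) < 2L || length(y) < 2L) {
    stop("each sample needs >= 2 finite values", call. = FALSE)
  }
  method <- if (var_equal) "pooled" else "welch"
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    same <- isTRUE(all.equal(mean(x), mean(y)))
    return(list(statistic = if (same) 0 else sign(mean(x) - mean(y)) * Inf,
                p_value = if (same) 1 else 0,
                df = NA_real_, mean_x = mean(x), mean_y = mean(y),
                method = method))
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), mean_x = mean(x), mean_y = mean(y),
       method = method)
}

#' Centred time-window rolling mean
#'
#' Smooths an irregularly sampled series with a centred, time-based window:
#' the value at time `t` is the mean of all observations whose timestamps lie
#' in `[t - window/2, t + window/2]` (endpoints inclusive), ignoring missing
#' values. Windows are specified in minutes to match shipboard practice
#' (17-min smoothing of active-fluorometry series, 25-min smoothing of
#' radiometric yields).
#'
#' @param time Monotone non-decreasing timestamps (`POSIXct` or numeric
#'   minutes).
#' @param value Numeric series, same length as `time`.
#' @param window Full window width in minutes.
#' @return Numeric vector of smoothed values.
#' @export
rolling_mean <- function(time, value, window) {
  if (length(time) != length(value)) {
    stop("`time` and `value` must have the same length", call. = FALSE)
  }
  if (length(time) == 0L) return(numeric(0))
  t_num <- if (inherits(time, "POSIXct")) as.numeric(time) / 60 else
    as.numeric(time)
  if (is.unsorted(t_num)) {
    stop("timestamps must be non-decreasing", call. = FALSE)
  }
  half <- window / 2
  eps <- 1e-9
  lo <- findInterval(t_num - half - eps, t_num) + 1L
  hi <- findInterval(t_num + half + eps, t_num)
  out <- numeric(length(value))
  for (i in seq_along(value)) {
    w <- value[lo[i]:hi[i]]
    out[i] <- if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }
  out
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. NULL seed evaluates in place.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
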
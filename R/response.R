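#' Fit a Gaussian CDF to spontaneous-fluctuation statistics
#'
#' Least-squares fit of the error-function form of the Gaussian cumulative
#' distribution,
#' \deqn{F(x) = \tfrac12\left[1 + \mathrm{erf}\!\big((x-\mu)/\sqrt{2\sigma^2}\big)\right],}
#' to the empirical cumulative probability of the spontaneous dF_max/F0
#' values (plotting positions i/n at the i-th sorted value). The responder
#' threshold is `df_th = mu + 1.96 sigma`: a heated cell whose burst
#' statistic exceeds it is unlikely (p < 0.025 one-sided) to be a
#' spontaneous fluctuation.
#'
#' @param values Numeric vector of spontaneous dF_max/F0 values (n >= 10,
#'   finite).
#' @return An object of class `fluctuation_fit` with components `mu`,
#'   `sigma`, `df_th`, `n`, `rss` and the sorted `values`. Methods:
#'   `print`, `summary`, `coef`, `predict` (fitted CDF), `plot`.
#' @examples
#' set.seed(1)
#' fit <- fit_fluctuation(rnorm(200, 0.1, 0.05))
#' fit$df_th
#' @export
fit_fluctuation <- function(values) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("fluctuation values must be finite")
  n <- length(values)
  if (n < 10L) stop("need at least 10 fluctuation values")
  x <- sort(values)
  p_emp <- seq_len(n) / n
  mu0 <- mean(x)
  sd0 <- stats::sd(x)
  if (sd0 == 0) {
    warning("zero spread in fluctuation values; sigma = 0")
    return(new_fluctuation_fit(mu0, 0, n, 0, x))
  }
  obj <- function(par) {
    sum((stats::pnorm(x, par[1], exp(par[2])) - p_emp)^2)
  }
  opt <- stats::optim(c(mu0, log(sd0)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  new_fluctuation_fit(opt$par[1], exp(opt$par[2]), n, opt$value, x)
}

new_fluctuation_fit <- function(mu, sigma, n, rss, values) {
  structure(list(mu = mu, sigma = sigma, df_th = mu + 1.96 * sigma,
                 n = n, rss = rss, values = values),
            class = "fluctuation_fit")
}

#' Responder threshold of a fluctuation model
#'
#' @param model A `fluctuation_fit`.
#' @return `mu + 1.96 sigma`.
#' @export
threshold <- function(model) {
  stopifnot(inherits(model, "fluctuation_fit"))
  model$mu + 1.96 * model$sigma
}

#' @export
print.fluctuation_fit <- function(x, ...) {
  cat(sprintf("Gaussian CDF fit to %d spontaneous fluctuations\n", x$n))
  cat(sprintf("  mu = %.4g, sigma = %.4g, dF_th = mu + 1.96 sigma = %.4g\n",
              x$mu, x$sigma, x$df_th))
  invisible(x)
}

#' @export
summary.fluctuation_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  residual sum of squares: %.3g\n", object$rss))
  invisible(object)
}

#' @export
coef.fluctuation_fit <- function(object, ...) {
  c(mu = object$mu, sigma = object$sigma, df_th = object$df_th)
}

#' @export
predict.fluctuation_fit <- function(object, newdata = object$values, ...) {
  stats::pnorm(newdata, object$mu, object$sigma)
}

#' @export
plot.fluctuation_fit <- function(x, ...) {
  graphics::plot(x$values, seq_along(x$values) / x$n, pch = 16, cex = 0.5,
                 xlab = "spontaneous dFmax/F0", ylab = "cumulative probability",
                 main = "Fluctuation model", ...)
  xs <- seq(min(x$values), max(x$values), length.out = 200)
  graphics::lines(xs, stats::pnorm(xs, x$mu, x$sigma), col = 2)
  graphics::abline(v = x$df_th, lty = 2)
  invisible(x)
}

#' Classify responders
#'
#' A cell responded if its burst statistic strictly exceeds the fluctuation
#' threshold; a tie at the threshold is a non-responder.
#'
#' @param dfmax_values Numeric vector of dF_max/F0 values (or a list of
#'   `burst_metrics`).
#' @param df_th Threshold, from [threshold()] or supplied externally.
#' @return Logical vector.
#' @export
classify_responders <- function(dfmax_values, df_th) {
  stopifnot(is.finite(df_th))
  if (is.list(dfmax_values)) {
    dfmax_values <- vapply(dfmax_values, function(m) m$dfmax, numeric(1))
  }
  dfmax_values > df_th
}

#' Binned response-probability curve
#'
#' Bins cells by their temperature rise and reports per-bin counts and
#' responder fractions. The default scheme uses equal-count quantile bins
#' with at least `min_per_bin` cells per bin.
#'
#' @param deltaT Per-cell temperature rises, degC.
#' @param responder Logical per cell.
#' @param breaks Optional explicit bin breaks (degC).
#' @param min_per_bin Minimum cells per quantile bin (default 8).
#' @return Data frame of class `response_bins`: `deltaT_mid`, `n`, `k`, `p`.
#' @export
response_curve <- function(deltaT, responder, breaks = NULL, min_per_bin = 8) {
  stopifnot(length(deltaT) == length(responder))
  responder <- as.logical(responder)
  if (is.null(breaks)) {
    n_bins <- max(2L, min(12L, floor(length(deltaT) / min_per_bin)))
    breaks <- unique(stats::quantile(deltaT, probs = seq(0, 1, length.out = n_bins + 1)))
  }
  if (length(breaks) < 3L) stop("all cells fall in one bin; need more spread in deltaT")
  bin <- cut(deltaT, breaks = breaks, include.lowest = TRUE)
  keep <- !is.na(bin)
  tab_n <- tapply(responder[keep], bin[keep], length)
  tab_k <- tapply(responder[keep], bin[keep], sum)
  tab_m <- tapply(deltaT[keep], bin[keep], mean)
  ok <- !is.na(tab_n)
  if (sum(ok) < 2L) stop("all cells fall in one bin; need more spread in deltaT")
  out <- data.frame(deltaT_mid = as.numeric(tab_m[ok]),
                    n = as.integer(tab_n[ok]),
                    k = as.integer(tab_k[ok]))
  out$p <- out$k / out$n
  out <- out[order(out$deltaT_mid), ]
  rownames(out) <- NULL
  structure(out, class = c("response_bins", "data.frame"))
}

#' Estimate the heat-sensitivity threshold dT_th
#'
#' Fits a logistic response-probability curve with a spontaneous-response
#' floor, `p(dT) = g + (1 - g) / (1 + exp(-(dT - dT_th)/w))`, to per-cell
#' binary responder outcomes by maximum likelihood, and reports the midpoint
#' `dT_th` of the heat-induced component with a nonparametric bootstrap
#' confidence interval over cells. The floor `g` (bounded to [0, 0.2])
#' absorbs the small false-positive rate that the responder threshold admits
#' by construction (~2.5% of non-bursting cells exceed `mu + 1.96 sigma`,
#' plus spontaneous transients); without it the midpoint is biased low.
#' When the MLE is unavailable (complete separation, or a non-increasing
#' fit), the estimate falls back to isotonic regression with linear
#' interpolation of the 50% crossing and is flagged.
#'
#' @param deltaT Per-cell temperature rises, degC.
#' @param responder Logical per cell.
#' @param boot Number of bootstrap resamples for the 95% CI (0 to skip).
#' @param seed Seed for the bootstrap.
#' @param min_per_bin Passed to [response_curve()] for the binned summary.
#' @param floor Optional fixed spontaneous-response floor `g` (e.g. the
#'   observed fraction of unheated cells exceeding the threshold, as used by
#'   [run_pipeline()]); when NULL the floor is estimated by the MLE.
#' @return An object of class `dose_response` with `dtth` (degC),
#'   `logistic_width` (degC, NA on the fallback path), `ci_low`/`ci_high`,
#'   `method` ("mle" or "isotonic"), the binned `curve`, and the data.
#'   Methods: `print`, `summary`, `coef`, `predict`, `plot`, `simulate`,
#'   `residuals`.
#' @export
fit_dose_response <- function(deltaT, responder, boot = 1000, seed = 1,
                              min_per_bin = 8, floor = NULL) {
  stopifnot(length(deltaT) == length(responder))
  responder <- as.logical(responder)
  if (all(responder)) stop("all cells responded: dT_th outside sampled range")
  if (!any(responder)) stop("no cell responded: dT_th outside sampled range")
  est <- dtth_point_estimate(deltaT, responder, floor = floor)
  if (est$dtth < min(deltaT) || est$dtth > max(deltaT)) {
    stop("dT_th outside sampled range")
  }
  ci <- c(NA_real_, NA_real_)
  if (boot > 0) {
    set.seed(as.integer(seed))
    n <- length(deltaT)
    bb <- vapply(seq_len(boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(dtth_point_estimate(deltaT[idx], responder[idx],
                                   floor = floor)$dtth,
               error = function(e) NA_real_)
    }, numeric(1))
    ci <- unname(stats::quantile(bb, c(0.025, 0.975), na.rm = TRUE))
  }
  curve <- response_curve(deltaT, responder, min_per_bin = min_per_bin)
  structure(list(dtth = est$dtth, logistic_width = est$width,
                 spont_floor = est$floor,
                 ci_low = ci[1], ci_high = ci[2], method = est$method,
                 coef = est$coef, curve = curve,
                 data = data.frame(deltaT = deltaT, responder = responder),
                 n = length(deltaT), boot = boot),
            class = "dose_response")
}

# point estimate: logistic MLE with a spontaneous-response floor,
# isotonic-interpolation fallback on separation.
#
# The responder threshold df_th = mu + 1.96 sigma admits by construction a
# small false-positive rate among non-bursting cells (~2.5% from the
# Gaussian tail, plus any spontaneous transients). A plain two-parameter
# logistic absorbs that floor into its slope and is biased low; the model
# fitted here is p(dT) = g + (1 - g) * plogis((dT - m)/w) with the floor g
# estimated (0 <= g <= 0.2), and dtth = m, the midpoint of the heat-induced
# component.
dtth_point_estimate <- function(deltaT, responder, floor = NULL) {
  fit <- withCallingHandlers(
    tryCatch(stats::glm(responder ~ deltaT, family = stats::binomial()),
             error = function(e) NULL),
    warning = function(w) invokeRestart("muffleWarning"))
  if (!is.null(fit)) {
    b <- unname(stats::coef(fit))
    separated <- any(abs(b) > 1e3) ||
      all(abs(stats::fitted(fit) - 0.5) > 0.499)
    if (is.finite(b[2]) && b[2] > 0 && !separated) {
      m0 <- -b[1] / b[2]
      w0 <- 1 / b[2]
      y <- as.numeric(responder)
      fixed_g <- !is.null(floor)
      nll <- function(par) {
        g <- if (fixed_g) floor else 0.2 * stats::plogis(par[3])
        p <- g + (1 - g) * stats::plogis((deltaT - par[1]) / exp(par[2]))
        p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
        -sum(y * log(p) + (1 - y) * log(1 - p))
      }
      start <- if (fixed_g) c(m0, log(max(w0, 1e-3))) else
        c(m0, log(max(w0, 1e-3)), stats::qlogis(0.05))
      opt <- tryCatch(
        stats::optim(start, nll, method = "Nelder-Mead",
                     control = list(reltol = 1e-10, maxit = 2000)),
        error = function(e) NULL)
      if (!is.null(opt) && is.finite(opt$par[1]) &&
          opt$par[1] >= min(deltaT) - 5 && opt$par[1] <= max(deltaT) + 5) {
        g_hat <- if (fixed_g) floor else 0.2 * stats::plogis(opt$par[3])
        return(list(dtth = opt$par[1], width = exp(opt$par[2]),
                    floor = g_hat, method = "mle",
                    coef = c(midpoint = opt$par[1], width = exp(opt$par[2]),
                             floor = g_hat)))
      }
      return(list(dtth = m0, width = w0, floor = 0, method = "mle",
                  coef = c(midpoint = m0, width = w0, floor = 0)))
    }
  }
  # isotonic regression of responder on deltaT, interpolate the 0.5 crossing
  ord <- order(deltaT)
  iso <- stats::isoreg(deltaT[ord], as.numeric(responder[ord]))
  x <- iso$x
  p <- iso$yf
  above <- which(p >= 0.5)
  below <- which(p < 0.5)
  if (length(above) == 0L || length(below) == 0L) {
    stop("dT_th outside sampled range")
  }
  i2 <- min(above)
  i1 <- max(below[below < i2])
  dtth <- x[i1] + (0.5 - p[i1]) * (x[i2] - x[i1]) / (p[i2] - p[i1])
  list(dtth = dtth, width = NA_real_, floor = NA_real_, method = "isotonic",
       coef = NULL)
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf("Heat-sensitivity threshold (n = %d cells, %s)\n", x$n, x$method))
  cat(sprintf("  dT_th = %.3f degC", x$dtth))
  if (is.finite(x$ci_low)) {
    cat(sprintf("  [95%% CI %.3f, %.3f]", x$ci_low, x$ci_high))
  }
  cat("\n")
  if (is.finite(x$logistic_width)) {
    cat(sprintf("  logistic width = %.3f degC\n", x$logistic_width))
  }
  invisible(x)
}

#' @export
summary.dose_response <- function(object, ...) {
  print(object)
  cat(sprintf("  responders: %d / %d\n", sum(object$data$responder), object$n))
  print(as.data.frame(object$curve))
  invisible(object)
}

#' @export
coef.dose_response <- function(object, ...) {
  c(dtth = object$dtth, logistic_width = object$logistic_width)
}

#' Fitted response probability at given temperature rises
#' @param object A `dose_response`.
#' @param newdata Numeric temperature rises (degC); defaults to the data.
#' @param ... Unused.
#' @export
predict.dose_response <- function(object, newdata = object$data$deltaT, ...) {
  if (object$method == "mle") {
    g <- if (is.finite(object$spont_floor)) object$spont_floor else 0
    g + (1 - g) * stats::plogis((newdata - object$dtth) / object$logistic_width)
  } else {
    ord <- order(object$data$deltaT)
    iso <- stats::isoreg(object$data$deltaT[ord],
                         as.numeric(object$data$responder[ord]))
    stats::approx(iso$x, iso$yf, xout = newdata, rule = 2, ties = "ordered")$y
  }
}

#' @export
residuals.dose_response <- function(object, ...) {
  as.numeric(object$data$responder) - predict(object)
}

#' Simulate responder outcomes from a fitted dose-response curve
#' @param object A `dose_response`.
#' @param nsim Number of simulated cohorts.
#' @param seed Optional seed.
#' @param ... Unused.
#' @export
simulate.dose_response <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- predict(object)
  out <- replicate(nsim, stats::runif(length(p)) < p, simplify = FALSE)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.dose_response <- function(x, ...) {
  graphics::plot(x$curve$deltaT_mid, x$curve$p, ylim = c(0, 1), pch = 16,
                 xlab = "temperature rise dT (degC)",
                 ylab = "response probability",
                 main = "Heat-induced Ca2+ response", ...)
  xs <- seq(min(x$data$deltaT), max(x$data$deltaT), length.out = 200)
  graphics::lines(xs, predict(x, xs), col = 2)
  graphics::abline(h = 0.5, lty = 3)
  graphics::abline(v = x$dtth, lty = 2)
  invisible(x)
}

#' Two-sample rank comparison
#'
#' Two-sided Mann-Whitney U test between two groups of burst statistics.
#' With small, tie-free samples the exact null distribution is used;
#' otherwise the normal approximation with tie correction.
#'
#' @param a,b Numeric vectors (each n >= 3).
#' @return List with `U` (statistic for `a` vs `b`), `p.value`, `method`.
#' @export
compare_groups <- function(a, b) {
  if (length(a) < 3L || length(b) < 3L) stop("need at least 3 values per group")
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  list(U = unname(wt$statistic), p.value = wt$p.value, method = wt$method)
}
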
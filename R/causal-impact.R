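#' Fit a local-level structural time-series model by Gibbs/FFBS
#'
#' Model: `y_t = mu_t + eps_t`, `eps ~ N(0, sigma_obs^2)`;
#' `mu_{t+1} = mu_t + eta_t`, `eta ~ N(0, sigma_lvl^2)`. Inference
#' alternates a forward-filter backward-sampler for the level path with
#' conjugate inverse-gamma updates for the two variances, under
#' `IG(0.01, 0.01 * var(y))` priors scaled to the pre-period variance.
#' Deterministic per seed.
#'
#' @param y Numeric pre-period series (length >= 20).
#' @param draws Retained posterior draws (default 2000).
#' @param warmup Discarded burn-in iterations (default 500).
#' @param seed Integer seed.
#' @param prior_a,prior_b Inverse-gamma hyperparameters; `prior_b` defaults
#'   to `0.01 * var(y)` (floored for constant series, which are flagged).
#' @return A `local_level_fit`: list with `sigma_obs`, `sigma_lvl`
#'   (draw vectors), `level` (draws x length(y) matrix of sampled level
#'   paths), `y`, and `prior_floor` flag.
#' @export
fit_local_level <- function(y, draws = 2000, warmup = 500, seed = NULL,
                            prior_a = 0.01, prior_b = NULL) {
  n <- length(y)
  if (n < 20) stop("pre-period series must have length >= 20")
  v_y <- stats::var(y)
  prior_floor <- FALSE
  if (is.null(prior_b)) {
    if (!is.finite(v_y) || v_y <= 0) {
      prior_floor <- TRUE
      v_y <- 1e-12
    }
    prior_b <- 0.01 * v_y
  }
  with_seed(seed, {
    r <- max(v_y, 1e-12) * 0.5     # sigma_obs^2
    q <- max(v_y, 1e-12) * 0.1     # sigma_lvl^2
    m0 <- y[1]
    C0 <- 10 * max(v_y, 1e-12)
    total <- draws + warmup
    out_obs <- numeric(draws)
    out_lvl <- numeric(draws)
    out_path <- matrix(NA_real_, draws, n)
    m <- numeric(n)
    C <- numeric(n)
    mu <- numeric(n)
    for (it in seq_len(total)) {
      # forward filter
      a_t <- m0
      R_t <- C0 + q
      for (t in seq_len(n)) {
        K <- R_t / (R_t + r)
        m[t] <- a_t + K * (y[t] - a_t)
        C[t] <- (1 - K) * R_t
        if (t < n) {
          a_t <- m[t]
          R_t <- C[t] + q
        }
      }
      # backward sample
      mu[n] <- stats::rnorm(1, m[n], sqrt(C[n]))
      for (t in seq(n - 1L, 1L)) {
        Bt <- C[t] / (C[t] + q)
        mu[t] <- stats::rnorm(1, m[t] + Bt * (mu[t + 1] - m[t]),
                              sqrt(max((1 - Bt) * C[t], 0)))
      }
      # conjugate variance updates
      ss_obs <- sum((y - mu)^2)
      r <- 1 / stats::rgamma(1, prior_a + n / 2, prior_b + ss_obs / 2)
      ss_lvl <- sum(diff(mu)^2)
      q <- 1 / stats::rgamma(1, prior_a + (n - 1) / 2,
                             prior_b + ss_lvl / 2)
      if (it > warmup) {
        k <- it - warmup
        out_obs[k] <- sqrt(r)
        out_lvl[k] <- sqrt(q)
        out_path[k, ] <- mu
      }
    }
    structure(list(sigma_obs = out_obs, sigma_lvl = out_lvl,
                   level = out_path, y = y, prior_floor = prior_floor),
              class = "local_level_fit")
  })
}

#' Forecast a fitted local-level model
#'
#' For each retained posterior draw, propagates the sampled final level
#' forward with fresh level innovations and adds observation noise; the
#' predictive spread is non-decreasing in the horizon.
#'
#' @param fit A [fit_local_level()] result.
#' @param horizon Number of post-period steps (> 0).
#' @param seed Integer seed for the forecast innovations.
#' @return Matrix of predictive draws (draws x horizon).
#' @export
forecast_local_level <- function(fit, horizon, seed = NULL) {
  if (horizon <= 0) stop("`horizon` must be > 0")
  n_draw <- length(fit$sigma_obs)
  last <- fit$level[, ncol(fit$level)]
  with_seed(seed, {
    eta <- matrix(stats::rnorm(n_draw * horizon), n_draw, horizon) *
      fit$sigma_lvl
    lvl <- last + t(apply(eta, 1, cumsum))
    if (horizon == 1L) lvl <- matrix(lvl, n_draw, 1)
    lvl + matrix(stats::rnorm(n_draw * horizon), n_draw, horizon) *
      fit$sigma_obs
  })
}

#' Pointwise and cumulative counterfactual impact summary
#'
#' Differences `observed - predicted` are formed per posterior draw and
#' then summarised (median and 97% equal-tailed BCIs); the cumulative
#' difference is the running sum within each draw, summarised the same way.
#'
#' @param observed Observed post-period series.
#' @param pred_draws Predictive draws (draws x horizon) from
#'   [forecast_local_level()].
#' @param t_rel Optional time stamps for the post-period steps.
#' @param level Credible level (default 0.97).
#' @return A `playback_impact` data frame with columns `t_rel, observed,
#'   pred_median, pred_lo97, pred_hi97, diff_median, diff_lo97, diff_hi97,
#'   cum_median, cum_lo97, cum_hi97`.
#' @export
impact_summary <- function(observed, pred_draws, t_rel = NULL,
                           level = 0.97) {
  h <- length(observed)
  if (ncol(pred_draws) != h)
    stop("observed length and forecast horizon differ")
  t_rel <- t_rel %||% (seq_len(h) - 1)
  diff_draws <- matrix(observed, nrow(pred_draws), h, byrow = TRUE) -
    pred_draws
  cum_draws <- t(apply(diff_draws, 1, cumsum))
  if (h == 1L) cum_draws <- matrix(cum_draws, ncol = 1)
  q <- function(m, p) apply(m, 2, stats::quantile, probs = p,
                            names = FALSE, type = 5)
  a <- (1 - level) / 2
  tag <- round(level * 100)
  out <- data.frame(t_rel = t_rel, observed = observed,
                    pred_median = q(pred_draws, 0.5),
                    pred_lo = q(pred_draws, a), pred_hi = q(pred_draws, 1 - a),
                    diff_median = q(diff_draws, 0.5),
                    diff_lo = q(diff_draws, a), diff_hi = q(diff_draws, 1 - a),
                    cum_median = q(cum_draws, 0.5),
                    cum_lo = q(cum_draws, a), cum_hi = q(cum_draws, 1 - a))
  names(out) <- sub("_lo$", paste0("_lo", tag),
                    sub("_hi$", paste0("_hi", tag), names(out)))
  class(out) <- c("playback_impact", "data.frame")
  out
}

# Mean-aggregate a (t, value) series to 1 Hz bins [k, k+1).
aggregate_1hz <- function(t, value) {
  sec <- floor(t)
  agg <- rowsum(value, sec) / as.vector(table(sec))
  data.frame(t = as.numeric(rownames(agg)), value = agg[, 1])
}

#' Counterfactual impact of playback on one indicator series
#'
#' End-to-end analogue of a covariate-free structural time-series impact
#' analysis: the onset-aligned indicator series is mean-aggregated to 1 Hz
#' (S-VeDBA and AD-MPR arrive at 25 and 30 samples/s), the local-level
#' model is fitted to the `pre_len` seconds before onset, the post-period
#' is forecast, and pointwise plus cumulative differences are reported with
#' 97% BCIs.
#'
#' @param series An [align_to_onset()] `indicator_series` (`t_rel, value`).
#' @param pre_len,post_len Pre/post spans in seconds (default 60 each).
#' @param draws,warmup Passed to [fit_local_level()].
#' @param seed Integer seed (spawns fit and forecast seeds).
#' @param level Credible level (default 0.97).
#' @return List with `fit`, `impact` (a `playback_impact`), `pre`, `post`.
#' @export
causal_impact <- function(series, pre_len = 60, post_len = 60,
                          draws = 2000, warmup = 500, seed = NULL,
                          level = 0.97) {
  agg <- aggregate_1hz(series$t_rel, series$value)
  pre <- agg[agg$t >= -pre_len & agg$t < 0, ]
  post <- agg[agg$t >= 0 & agg$t < post_len, ]
  if (nrow(pre) < 20) stop("pre-period too short after aggregation")
  if (nrow(post) < 1) stop("empty post-period")
  seeds <- spawn_seeds(seed, 2)
  fit <- fit_local_level(pre$value, draws = draws, warmup = warmup,
                         seed = seeds[[1]])
  pred <- forecast_local_level(fit, nrow(post), seed = seeds[[2]])
  list(fit = fit,
       impact = impact_summary(post$value, pred, t_rel = post$t,
                               level = level),
       pre = pre, post = post)
}

#' @export
print.playback_impact <- function(x, ...) {
  h <- nrow(x)
  lo <- x[[grep("^cum_lo", names(x))]][h]
  hi <- x[[grep("^cum_hi", names(x))]][h]
  cat("<playback_impact> ", h, " post-period steps\n",
      sprintf(" cumulative difference at end: %.4g [%.4g, %.4g]\n",
              x$cum_median[h], lo, hi), sep = "")
  invisible(x)
}

#' Plot pointwise and cumulative impact panels
#'
#' Base-graphics three-panel display: observed vs. predicted, pointwise
#' difference, cumulative difference, each with its credible ribbon.
#'
#' @param x A `playback_impact`.
#' @param ... Passed to `plot`.
#' @export
plot.playback_impact <- function(x, ...) {
  lo <- function(p) x[[grep(paste0("^", p, "_lo"), names(x))]]
  hi <- function(p) x[[grep(paste0("^", p, "_hi"), names(x))]]
  old <- graphics::par(mfrow = c(3, 1), mar = c(3, 4, 1, 1))
  on.exit(graphics::par(old))
  ribbon <- function(l, h) graphics::polygon(c(x$t_rel, rev(x$t_rel)),
                                             c(l, rev(h)), border = NA,
                                             col = grDevices::grey(0.85))
  plot(x$t_rel, x$observed, type = "n", ylab = "series",
       ylim = range(x$observed, lo("pred"), hi("pred")), ...)
  ribbon(lo("pred"), hi("pred"))
  graphics::lines(x$t_rel, x$observed)
  graphics::lines(x$t_rel, x$pred_median, lty = 2)
  plot(x$t_rel, x$diff_median, type = "n", ylab = "pointwise diff",
       ylim = range(lo("diff"), hi("diff")))
  ribbon(lo("diff"), hi("diff"))
  graphics::lines(x$t_rel, x$diff_median, lty = 2)
  graphics::abline(h = 0, col = "grey40")
  plot(x$t_rel, x$cum_median, type = "n", ylab = "cumulative diff",
       ylim = range(lo("cum"), hi("cum")))
  ribbon(lo("cum"), hi("cum"))
  graphics::lines(x$t_rel, x$cum_median, lty = 2)
  graphics::abline(h = 0, col = "grey40")
  invisible(x)
}
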
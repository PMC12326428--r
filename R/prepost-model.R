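#' Pre/post window means and their difference for one session
#'
#' Means of an onset-aligned indicator series over the `(-pre_window_s, 0]`
#' window (pre) and the `(0, post_window_s]` window (post), and the
#' response variable `diff = post_mean - pre_mean`. `offset` shifts both
#' windows jointly (windows adjacent to onset by default).
#'
#' @param series An [align_to_onset()] `indicator_series` (`t_rel, value`).
#' @param pre_window_s,post_window_s Window lengths in seconds (default 5).
#' @param offset Shift applied to both windows in seconds (default 0).
#' @return One-row data frame `pre_mean, post_mean, diff`.
#' @export
window_means <- function(series, pre_window_s = 5, post_window_s = 5,
                         offset = 0) {
  t <- series$t_rel
  if (min(t) > offset - pre_window_s || max(t) < offset + post_window_s)
    stop("series does not cover [-", pre_window_s, ", ", post_window_s,
         "] around onset; session excluded")
  pre <- series$value[t > offset - pre_window_s & t <= offset]
  post <- series$value[t > offset & t <= offset + post_window_s]
  data.frame(pre_mean = mean(pre), post_mean = mean(post),
             diff = mean(post) - mean(pre))
}

#' Build the response vector and design matrix for the hierarchical model
#'
#' Covariate coding follows the analysis convention: audio type (0 = noise,
#' 1 = predator), location (0 = non-offshore, 1 = offshore), standardised
#' body mass, and the standardised within-bird playback count, counted
#' separately per audio type (the session's ordinal index among that bird's
#' sessions with the same stimulus). Standardisation uses the analysis-set
#' mean and sample (n-1) SD; a zero-variance covariate is dropped with a
#' warning.
#'
#' @param sessions Data frame with columns `session`, `bird`, `audio`
#'   (`"predator"`/`"noise"` or 0/1), `offshore` (logical or 0/1) and
#'   `diff` (the response), ordered by session time within bird.
#' @param deployments Data frame with columns `bird` and `body_mass` (g);
#'   every session's bird must appear.
#' @return List with `y`, `X` (columns among `audio`, `location`,
#'   `mass_std`, `count_std`), `bird` (factor) and `table` (the assembled
#'   per-session rows).
#' @export
build_design <- function(sessions, deployments) {
  if (!all(sessions$bird %in% deployments$bird))
    stop("every session must map to a deployment bird")
  audio <- if (is.numeric(sessions$audio)) sessions$audio
           else as.numeric(sessions$audio == "predator")
  if (!all(audio %in% c(0, 1))) stop("audio must code to {0, 1}")
  location <- as.numeric(sessions$offshore)
  if (!all(location %in% c(0, 1))) stop("offshore must code to {0, 1}")
  mass <- deployments$body_mass[match(sessions$bird, deployments$bird)]
  count <- stats::ave(seq_len(nrow(sessions)),
                      sessions$bird, audio, FUN = seq_along)
  std <- function(x, name) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      warning("zero-variance covariate `", name, "` dropped")
      return(NULL)
    }
    (x - mean(x)) / s
  }
  cols <- list(audio = audio, location = location,
               mass_std = std(mass, "body_mass"),
               count_std = std(count, "playback_count"))
  cols <- Filter(Negate(is.null), cols)
  X <- do.call(cbind, cols)
  list(y = sessions$diff, X = X, bird = factor(sessions$bird),
       table = data.frame(session = sessions$session, bird = sessions$bird,
                          audio = audio, location = location,
                          count = count, mass = mass))
}

#' MCMC configuration for the hierarchical model
#'
#' Defaults follow the published analysis settings: 4 chains of 8000
#' iterations with 6000 warm-up, thinning 1 and a 0.99 target-acceptance
#' setting. The location/variance sampler used here is Gibbs plus slice
#' steps, which have no step size to adapt, so `target_accept` is carried
#' as configuration metadata only.
#'
#' @param chains Number of chains (>= 2 for split-R-hat).
#' @param iterations Iterations per chain including warm-up.
#' @param warmup Warm-up iterations discarded per chain.
#' @param thin Thinning interval.
#' @param target_accept Nominal target acceptance (metadata).
#' @param seed Integer seed; per-chain seeds are spawned from it.
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(chains = 4, iterations = 8000, warmup = 6000,
                        thin = 1, target_accept = 0.99, seed = NULL) {
  if (warmup >= iterations) stop("`warmup` must be < `iterations`")
  if (chains < 2) stop("need >= 2 chains")
  structure(list(chains = chains, iterations = iterations, warmup = warmup,
                 thin = thin, target_accept = target_accept, seed = seed),
            class = "mcmc_config")
}

# One update of a univariate slice sampler (Neal 2003, stepping out +
# shrinkage) on target log-density `logf`.
slice_update <- function(x0, logf, w = 1, max_steps = 50L) {
  y <- logf(x0) - stats::rexp(1)
  u <- stats::runif(1)
  L <- x0 - w * u
  R <- L + w
  k <- max_steps
  while (k > 0L && logf(L) > y) { L <- L - w; k <- k - 1L }
  k <- max_steps
  while (k > 0L && logf(R) > y) { R <- R + w; k <- k - 1L }
  repeat {
    x1 <- stats::runif(1, L, R)
    if (logf(x1) >= y) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
}

#' Fit the Bayesian hierarchical random-intercept model
#'
#' Model: `y_i ~ Normal(alpha + a_bird[i] + X beta, sigma)` with
#' `a_b ~ Normal(0, sigma_b)`. Priors: Normal(0, 10^2) on `alpha` and
#' `beta`; half-Normal(0, 5 * SD(y)) on `sigma` and `sigma_b`. Sampling is
#' a self-contained MCMC: one joint conjugate Gibbs update of all location
#' parameters (fixed effects and random intercepts drawn together, which
#' removes the intercept/random-intercept random-walk behaviour a blocked
#' update would suffer) and univariate slice updates on the log standard
#' deviations.
#' Chains are initialised with jitter and run sequentially from seeds
#' spawned off `config$seed`; post-warm-up draws are pooled across chains.
#' Split-chain R-hat and effective sample size are reported per parameter;
#' any R-hat above 1.05 sets the `converged` flag to `FALSE` (with a
#' warning, never silently).
#'
#' @param y Numeric response vector (post-mean minus pre-mean differences).
#' @param X Fixed-effect design matrix (no intercept column).
#' @param bird Factor (or coercible) of bird identities, one per session.
#' @param config An [mcmc_config()].
#' @param priors Optional list overriding `theta_sd` (fixed-effect prior
#'   SD), `sigma_scale`, `sigma_b_scale` (half-Normal scales).
#' @return A `prepost_fit`: list with `draws` (array kept-iterations x
#'   chains x parameters), `summary` (a [summarize_draws()] data frame),
#'   `converged`, `config`, `priors`.
#' @export
fit_hierarchical <- function(y, X, bird, config = mcmc_config(),
                             priors = NULL) {
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n) stop("X and y lengths differ")
  if (n < ncol(X) + 2) stop("need n >= number of fixed effects + 2")
  bird <- factor(bird)
  B <- nlevels(bird)
  if (B < 2) warning("fewer than 2 birds: sigma_b is weakly identified")
  bi <- as.integer(bird)
  sd_y <- stats::sd(y)
  if (!is.finite(sd_y) || sd_y == 0) sd_y <- 1
  pri <- list(theta_sd = 10, sigma_scale = 5 * sd_y,
              sigma_b_scale = 5 * sd_y)
  pri[names(priors)] <- priors

  Z <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Z)
  M <- matrix(0, n, B)
  M[cbind(seq_len(n), bi)] <- 1
  W <- cbind(Z, M)
  WtW <- crossprod(W)
  Wty <- crossprod(W, y)
  keep_idx <- seq(config$warmup + 1L, config$iterations, by = config$thin)
  n_keep <- length(keep_idx)
  par_names <- c("alpha", colnames(X), "sigma", "sigma_b",
                 paste0("a[", levels(bird), "]"))
  draws <- array(NA_real_, c(n_keep, config$chains, length(par_names)),
                 dimnames = list(NULL, NULL, par_names))
  seeds <- spawn_seeds(config$seed, config$chains)

  for (ch in seq_len(config$chains)) {
    with_seed(seeds[[ch]], {
      sigma <- sd_y * stats::runif(1, 0.5, 2)
      sigma_b <- sd_y * stats::runif(1, 0.25, 1)
      row <- 0L
      for (it in seq_len(config$iterations)) {
        # (theta, a) | sigma, sigma_b  (one joint conjugate normal draw)
        prec <- WtW / sigma^2 +
          diag(c(rep(1 / pri$theta_sd^2, p), rep(1 / sigma_b^2, B)))
        ch_u <- chol(prec)
        mu <- backsolve(ch_u, forwardsolve(t(ch_u), Wty / sigma^2))
        gam <- drop(mu + backsolve(ch_u, stats::rnorm(p + B)))
        theta <- gam[seq_len(p)]
        a <- gam[p + seq_len(B)]
        # sigma | rest  (slice on log sigma, half-Normal prior)
        ss <- sum((y - drop(W %*% gam))^2)
        lf_s <- function(ls) {
          s <- exp(ls)
          -n * ls - ss / (2 * s^2) - s^2 / (2 * pri$sigma_scale^2) + ls
        }
        sigma <- exp(slice_update(log(sigma), lf_s))
        # sigma_b | a  (slice on log sigma_b, half-Normal prior)
        ssa <- sum(a^2)
        lf_b <- function(ls) {
          s <- exp(ls)
          -B * ls - ssa / (2 * s^2) - s^2 / (2 * pri$sigma_b_scale^2) + ls
        }
        sigma_b <- exp(slice_update(log(sigma_b), lf_b))
        if (it > config$warmup &&
            (it - config$warmup - 1L) %% config$thin == 0L) {
          row <- row + 1L
          draws[row, ch, ] <- c(theta, sigma, sigma_b, a)
        }
      }
    })
  }
  summary <- summarize_draws(draws)
  converged <- all(summary$rhat < 1.05, na.rm = TRUE)
  if (!converged)
    warning("R-hat > 1.05 for: ",
            paste(summary$param[summary$rhat >= 1.05], collapse = ", "))
  structure(list(draws = draws, summary = summary, converged = converged,
                 config = config, priors = pri, par_names = par_names),
            class = "prepost_fit")
}

#' @export
print.prepost_fit <- function(x, ...) {
  cat("<prepost_fit> ", dim(x$draws)[1] * dim(x$draws)[2], " pooled draws (",
      dim(x$draws)[2], " chains); converged: ", x$converged, "\n", sep = "")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

# Split-chain R-hat (each chain halved, then the classic potential
# scale-reduction formula over the 2m half-chains).
split_rhat <- function(mat) {
  n <- nrow(mat)
  half <- floor(n / 2)
  sub <- cbind(mat[seq_len(half), , drop = FALSE],
               mat[seq(n - half + 1, n), , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, stats::var)
  W <- mean(vars)
  Bv <- half * stats::var(means)
  if (W == 0) return(NA_real_)
  sqrt(((half - 1) / half * W + Bv / half) / W)
}

# Effective sample size over split chains: combined autocorrelation with
# Geyer's initial-monotone truncation.
ess_basic <- function(mat) {
  n <- nrow(mat)
  half <- floor(n / 2)
  sub <- cbind(mat[seq_len(half), , drop = FALSE],
               mat[seq(n - half + 1, n), , drop = FALSE])
  m <- ncol(sub)
  vars <- apply(sub, 2, stats::var)
  W <- mean(vars)
  Bv <- half * stats::var(colMeans(sub))
  var_plus <- (half - 1) / half * W + Bv / half
  if (var_plus == 0) return(NA_real_)
  max_lag <- min(half - 1L, 500L)
  acov <- sapply(seq_len(m), function(j) {
    x <- sub[, j] - mean(sub[, j])
    stats::acf(x, lag.max = max_lag, type = "covariance", plot = FALSE,
               demean = FALSE)$acf[, 1, 1]
  })
  rho <- 1 - (W - rowMeans(acov[-1L, , drop = FALSE])) / var_plus
  tau <- 1
  t <- 1L
  while (t + 1L <= length(rho)) {
    pair <- rho[t] + rho[t + 1L]
    if (pair < 0) break
    tau <- tau + 2 * pair
    t <- t + 2L
  }
  max(m * half / tau, 1)
}

#' Summarise posterior draws: median, nested BCIs, R-hat, ESS
#'
#' Equal-tailed Bayesian credible intervals at the requested levels (89%
#' and 97% by default) from midpoint-interpolation (type-5) quantiles, with
#' split-chain R-hat and effective sample size when the draws carry a chain
#' dimension.
#'
#' @param draws Array (iterations x chains x parameters), matrix
#'   (iterations x parameters, treated as one chain) or numeric vector.
#' @param levels Credible-interval levels.
#' @return Data frame `param, median, lo89, hi89, lo97, hi97, rhat, ess`
#'   (columns named after the requested levels).
#' @export
summarize_draws <- function(draws, levels = c(0.89, 0.97)) {
  if (is.numeric(draws) && is.null(dim(draws)))
    draws <- array(draws, c(length(draws), 1, 1),
                   dimnames = list(NULL, NULL, "value"))
  if (is.matrix(draws))
    draws <- array(draws, c(nrow(draws), 1, ncol(draws)),
                   dimnames = list(NULL, NULL,
                                   colnames(draws) %||%
                                     paste0("par", seq_len(ncol(draws)))))
  if (dim(draws)[1] * dim(draws)[2] < 100) stop("need >= 100 draws")
  params <- dimnames(draws)[[3]] %||% paste0("par", seq_len(dim(draws)[3]))
  multi <- dim(draws)[2] >= 2
  rows <- lapply(seq_along(params), function(k) {
    mat <- draws[, , k, drop = FALSE]
    dim(mat) <- dim(draws)[1:2]
    pooled <- as.vector(mat)
    out <- data.frame(param = params[k],
                      median = stats::quantile(pooled, 0.5, names = FALSE,
                                               type = 5))
    for (lv in sort(levels)) {
      ci <- eqtail_interval(pooled, lv)
      out[[sprintf("lo%d", round(lv * 100))]] <- ci[1]
      out[[sprintf("hi%d", round(lv * 100))]] <- ci[2]
    }
    out$rhat <- if (multi) split_rhat(mat) else NA_real_
    out$ess <- ess_basic(mat)
    out
  })
  do.call(rbind, rows)
}

#' Simulate a pre/post session dataset with known coefficients
#'
#' Generates a session table and design for sampler calibration and
#' recovery studies: random 0/1 audio and location, per-bird body masses,
#' within-bird per-audio playback counts, bird random intercepts of SD
#' `sigma_b` and Normal residuals of SD `sigma`.
#'
#' @param n_sessions,n_birds Dataset size (defaults 200 sessions, 8 birds).
#' @param beta Named true coefficients on the standardised design columns
#'   (`audio`, `location`, `mass_std`, `count_std`).
#' @param alpha True intercept.
#' @param sigma,sigma_b Residual and random-intercept SDs.
#' @param seed Integer seed.
#' @return List `y`, `X`, `bird`, plus the `truth` parameter list.
#' @export
simulate_prepost_data <- function(n_sessions = 200, n_birds = 8,
                                  beta = c(audio = 0, location = 0,
                                           mass_std = 0, count_std = 0),
                                  alpha = 0, sigma = 0.1, sigma_b = 0.1,
                                  seed = NULL) {
  with_seed(seed, {
    bird <- factor(sample(sprintf("LBP%02d", seq_len(n_birds) - 1),
                          n_sessions, replace = TRUE))
    mass <- stats::rnorm(n_birds, 650, 35)[as.integer(bird)]
    audio <- stats::rbinom(n_sessions, 1, 0.5)
    location <- stats::rbinom(n_sessions, 1, 0.5)
    count <- stats::ave(seq_len(n_sessions), bird, audio, FUN = seq_along)
    X <- cbind(audio = audio, location = location,
               mass_std = (mass - mean(mass)) / stats::sd(mass),
               count_std = (count - mean(count)) / stats::sd(count))
    a <- stats::rnorm(n_birds, 0, sigma_b)
    y <- alpha + a[as.integer(bird)] + drop(X %*% beta[colnames(X)]) +
      stats::rnorm(n_sessions, 0, sigma)
    list(y = y, X = X, bird = bird,
         truth = list(alpha = alpha, beta = beta, sigma = sigma,
                      sigma_b = sigma_b, a = a))
  })
}
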
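# Mismatch-distribution analysis under the sudden-expansion model:
# observed histogram, model expectation, least-squares fit with parametric
# bootstrap (SSD and Harpending's raggedness), and expansion-time dating.

#' Observed mismatch distribution
#'
#' Histogram of raw pairwise difference counts over all sample pairs,
#' normalised to relative frequencies.
#'
#' @param dm_raw `haplo_dist` of raw differences over *samples* (expand a
#'   haplotype-level matrix with the haplotype counts first if needed).
#' @return list `freq` (relative frequencies for classes `0..d`), `counts`,
#'   `mean` (plain mean pairwise differences).
#' @export
mismatch_observed <- function(dm_raw) {
  stopifnot(is.matrix(dm_raw), nrow(dm_raw) >= 2)
  v <- round(dm_raw[upper.tri(dm_raw)])
  counts <- tabulate(v + 1L, nbins = max(v) + 1L)
  list(freq = counts / length(v), counts = counts, mean = mean(v))
}

#' Expected mismatch distribution under sudden expansion
#'
#' The pairwise coalescence age `x` has the two-phase exponential density
#' `f(x) = e^{-x/theta1}/theta1` for `x < tau` and
#' `f(x) = e^{-tau/theta1} e^{-(x-tau)/theta0}/theta0` beyond, and the
#' difference count is Poisson(`x`). The resulting class probabilities have
#' the closed form of a Poisson-geometric convolution:
#' `F_i = G1_i P(aux) + w * sum_k Pois(i-k; tau) Geom(k; theta0)` (see the
#' source). Mass beyond `i_max` is folded into the last class.
#'
#' @param i_max largest difference class.
#' @param tau expansion age in mutational time units.
#' @param theta0 pre-expansion scaled population size.
#' @param theta1 post-expansion (current) scaled size.
#' @return Numeric vector `F_0..F_{i_max}` summing to 1.
#' @export
mismatch_expected <- function(i_max, tau, theta0, theta1) {
  stopifnot(i_max >= 1, tau >= 0, theta0 >= 0, theta1 >= 0)
  mismatch_expected_core(i_max, tau, theta0, theta1)
}

# Check-free workhorse behind mismatch_expected (also the least-squares
# objective, where it is called tens of thousands of times during the
# parametric bootstrap). Everything is built from two cumulative products
# (geometric and Poisson pmfs) and a cumulative sum (the regularised
# gamma over consecutive integer shapes is a Poisson upper tail):
# pgamma(x, i+1) = 1 - cumsum(dpois(0:i, x)) shifted by one.
mismatch_expected_core <- function(i_max, tau, theta0, theta1) {
  i <- 0:i_max
  geom_pmf <- function(theta) {
    p <- 1 / (1 + theta)
    p * c(1, cumprod(rep.int(theta * p, i_max)))
  }
  pois_pmf <- function(lambda) {
    if (lambda == 0) return(as.numeric(i == 0L))
    if (lambda > 100) return(stats::dpois(i, lambda))  # cumprod overflows
    exp(-lambda) * c(1, cumprod(lambda / seq_len(i_max)))
  }
  if (theta0 == 0 && theta1 == 0) {
    f <- pois_pmf(tau)
  } else if (theta1 == 0) {
    # current size zero: every pair coalesces immediately
    f <- as.numeric(i == 0L)
  } else {
    # phase 1 (x < tau): Geom(theta1) damped by the truncated gamma mass
    a <- 1 + 1 / theta1
    pg <- 1 - cumsum(pois_pmf(a * tau))   # pgamma(a*tau, shape = i+1)
    f1 <- geom_pmf(theta1) * pmax(pg, 0)
    # phase 2 (x >= tau): Poisson(tau) convolved with Geom(theta0),
    # weighted by the probability w of surviving phase 1; the geometric
    # convolution is the linear recursion c_i = p*Pois_i + (1-p)*c_{i-1}
    w <- exp(-tau / theta1)
    pois <- pois_pmf(tau)
    if (theta0 == 0) {
      f2 <- pois
    } else {
      f2 <- geom_convolve(pois, 1 / (1 + theta0))
    }
    f <- f1 + w * f2
  }
  f[length(f)] <- max(1 - sum(f[-length(f)]), 0)   # fold the tail
  f
}

# Convolution with a Geometric(p) kernel via its linear recursion
# c_i = (1-p) c_{i-1} + p x_i; a bare loop beats stats::filter for the
# short vectors used here.
geom_convolve <- function(x, p) {
  q <- 1 - p
  out <- numeric(length(x))
  acc <- 0
  for (k in seq_along(x)) {
    acc <- acc * q + p * x[k]
    out[k] <- acc
  }
  out
}

#' Harpending's raggedness index
#'
#' `r = sum_{i=1}^{d+1} (x_i - x_{i-1})^2` with `x_{d+1} = 0`; low values
#' indicate the smooth unimodal shape expected after a sudden expansion.
#'
#' @param freq relative mismatch frequencies `x_0..x_d`.
#' @return Raggedness index.
#' @export
raggedness <- function(freq) {
  x <- c(freq, 0)
  sum(diff(x)^2)
}

# SSD between an observed mismatch vector and the model expectation at
# (tau, theta0, theta1), classes 0..d with tail folding.
mismatch_ssd <- function(freq, par) {
  f <- mismatch_expected_core(length(freq) - 1L, par[1], par[2], par[3])
  sum((freq - f)^2)
}

# Analytic gradient of mismatch_ssd in (tau, theta0, theta1), derived from
# the closed form: F = g1 * P + w * conv(pois, geom0) with
# g1 = Geom(theta1) pmf, P = pgamma(a*tau, i+1), a = 1 + 1/theta1,
# w = exp(-tau/theta1). Geometric-kernel convolutions reduce to the linear
# recursion via stats::filter; the theta0 derivative uses
# d conv(pois, geom0)/d theta0 = (p0/q0) * (conv(f2, geom0) - f2).
# Parameters are floored away from 0 (the objective is continuous there;
# nlminb only needs a consistent subgradient at the boundary).
mismatch_ssd_grad <- function(freq, par) {
  d <- length(freq) - 1L
  i <- 0:d
  tau <- par[1]
  th0 <- max(par[2], 1e-9)
  th1 <- max(par[3], 1e-9)
  p0 <- 1 / (1 + th0); q0 <- 1 - p0
  p1 <- 1 / (1 + th1); q1 <- 1 - p1
  a <- 1 + 1 / th1
  pois_pmf <- function(lambda) {
    if (lambda <= 0) return(as.numeric(i == 0L))
    if (lambda > 100) return(stats::dpois(i, lambda))
    exp(-lambda) * c(1, cumprod(lambda / seq_len(d)))
  }
  geo_conv <- geom_convolve
  g1 <- p1 * c(1, cumprod(rep.int(q1, d)))
  pois_at <- pois_pmf(a * tau)
  P <- pmax(1 - cumsum(pois_at), 0)
  w <- exp(-tau / th1)
  pois <- pois_pmf(tau)
  f2 <- geo_conv(pois, p0)
  F_ <- g1 * P + w * f2

  # tau
  dpois_dtau <- c(0, pois[-length(pois)]) - pois
  dF_tau <- g1 * (a * pois_at) + (-w / th1) * f2 +
    w * geo_conv(dpois_dtau, p0)
  # theta0
  dF_th0 <- w * (p0 / q0) * (geo_conv(f2, p0) - f2)
  # theta1
  dg1 <- g1 * (-p1 + i * p1^2 / q1)
  dP_th1 <- -(tau / th1^2) * pois_at
  dF_th1 <- dg1 * P + g1 * dP_th1 + (w * tau / th1^2) * f2

  # fold the tail: the last class absorbs 1 - sum(previous)
  fold <- function(f, df) {
    f[d + 1] <- max(1 - sum(f[-(d + 1)]), 0)
    df[d + 1] <- -sum(df[-(d + 1)])
    list(f = f, df = df)
  }
  r <- freq
  out <- numeric(3)
  for (k in 1:3) {
    df <- switch(k, dF_tau, dF_th0, dF_th1)
    fd <- fold(F_, df)
    out[k] <- -2 * sum((r - fd$f) * fd$df)
  }
  out
}

# Least-squares fit of (tau, theta0, theta1): four deterministic starts,
# best kept. The same protocol is used for the observed data and for every
# bootstrap refit (the bootstrap must apply the identical estimator).
fit_mismatch_params <- function(freq) {
  d <- length(freq) - 1L
  mu <- sum((0:d) * freq)
  tau_hi <- max(2 * d, 1)
  starts <- list(c(max(mu, 0.1), 0.1, 100),
                 c(max(mu / 2, 0.1), 0.5, 10),
                 c(min(2 * mu + 0.1, tau_hi), 0.01, 1000),
                 c(0.1, max(mu, 0.1), max(mu, 0.1)))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, function(p) mismatch_ssd(freq, p),
                   gr = function(p) mismatch_ssd_grad(freq, p),
                   method = "L-BFGS-B",
                   lower = c(0, 1e-6, 1e-6), upper = c(tau_hi, 1e5, 1e5),
                   control = list(factr = 1e7)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("mismatch fit failed to converge from all starts", call. = FALSE)
  list(par = best$par, ssd = best$value, convergence = best$convergence)
}

#' Fit the sudden-expansion model to a mismatch distribution
#'
#' Estimates `(tau, theta0, theta1)` by bounded least squares on the
#' mismatch class frequencies (objective: sum of squared deviations, SSD),
#' then assesses goodness of fit by parametric bootstrap: `B` coalescent
#' samples of size `n` are simulated under the fitted model, each is
#' refitted, and `p_SSD` (`p_r`) is the fraction of simulated SSD
#' (raggedness) at least as large as observed. The bootstrap `tau` values
#' give a 95% percentile confidence interval.
#'
#' @param x_obs observed relative mismatch frequencies `x_0..x_d` (or the
#'   list from [mismatch_observed()]).
#' @param n number of sampled sequences behind the histogram.
#' @param B bootstrap replicates (default 10000; reduce for exploratory
#'   runs).
#' @param seed integer seed.
#' @return A `mismatch_fit` list: `tau`, `theta0`, `theta1`, `SSD`,
#'   `raggedness`, `p_SSD`, `p_r`, `tau_ci` (2.5/97.5 percentiles), `B`,
#'   `freq`.
#' @export
fit_sudden_expansion <- function(x_obs, n, B = 10000, seed = NULL) {
  if (is.list(x_obs)) x_obs <- x_obs$freq
  if (length(x_obs) < 2)
    stop("need at least 2 mismatch classes (pad a flat histogram)",
         call. = FALSE)
  stopifnot(abs(sum(x_obs) - 1) < 1e-8)
  fit <- fit_mismatch_params(x_obs)
  r_obs <- raggedness(x_obs)
  tau <- fit$par[1]; th0 <- fit$par[2]; th1 <- fit$par[3]
  p_ssd <- p_r <- NA_real_
  tau_ci <- c(NA_real_, NA_real_)
  if (B > 0) {
    if (!is.null(seed)) set.seed(seed)
    model <- demographic_model("step_expansion", theta0 = th0,
                               theta1 = th1, tau = tau)
    ssd_b <- r_b <- tau_b <- numeric(B)
    for (b in seq_len(B)) {
      gen <- sim_genealogy(n, model)
      n_mut <- drop_mutations(branch_lengths(gen))
      dmat <- genealogy_pairdiff(gen, n_mut)
      obs_b <- mismatch_observed(dmat)
      freq_b <- obs_b$freq
      if (length(freq_b) < 2) freq_b <- c(freq_b, 0)
      fb <- tryCatch(fit_mismatch_params(freq_b), error = function(e) NULL)
      if (is.null(fb)) { ssd_b[b] <- NA; r_b[b] <- NA; tau_b[b] <- NA; next }
      ssd_b[b] <- fb$ssd
      r_b[b] <- raggedness(freq_b)
      tau_b[b] <- fb$par[1]
    }
    ok <- !is.na(ssd_b)
    p_ssd <- (sum(ssd_b[ok] >= fit$ssd - 1e-15) + 1) / (sum(ok) + 1)
    p_r <- (sum(r_b[ok] >= r_obs - 1e-15) + 1) / (sum(ok) + 1)
    tau_ci <- stats::quantile(tau_b[ok], c(0.025, 0.975), names = FALSE)
  }
  structure(list(tau = tau, theta0 = th0, theta1 = th1, SSD = fit$ssd,
                 raggedness = r_obs, p_SSD = p_ssd, p_r = p_r,
                 tau_ci = tau_ci, B = B, freq = x_obs, n = n),
            class = "mismatch_fit")
}

#' @export
print.mismatch_fit <- function(x, ...) {
  cat(sprintf(
    "Sudden-expansion fit: tau = %.3f (%.3f-%.3f), theta0 = %.3g, theta1 = %.3g\n",
    x$tau, x$tau_ci[1], x$tau_ci[2], x$theta0, x$theta1))
  cat(sprintf("SSD = %.4g (p = %.3g), raggedness = %.4g (p = %.3g), B = %d\n",
              x$SSD, x$p_SSD, x$raggedness, x$p_r, x$B))
  invisible(x)
}

#' Convert an expansion age to calendar time
#'
#' `t = tau / (2 * rate * L)` years, with `rate` the divergence rate per
#' site per year (2.3% per Myr = 2.3e-8). Confidence-interval endpoints are
#' transformed identically.
#'
#' @param tau expansion age in mutational time units.
#' @param L sequence length in base pairs.
#' @param rate divergence rate per site per year.
#' @param tau_ci optional `c(lo, hi)` for `tau`.
#' @return list `t_years`, `t_ka`, `ci_years`, `ci_ka`, `rate`, `L`.
#' @export
expansion_time <- function(tau, L, rate, tau_ci = NULL) {
  stopifnot(L > 0, rate > 0, tau >= 0)
  conv <- function(x) x / (2 * rate * L)
  t <- conv(tau)
  ci <- if (is.null(tau_ci)) c(NA_real_, NA_real_) else conv(tau_ci)
  list(t_years = t, t_ka = t / 1000, ci_years = ci, ci_ka = ci / 1000,
       rate = rate, L = L)
}

#' Unimodality of a mismatch histogram
#'
#' A histogram is called unimodal when, after 3-bin moving-average
#' smoothing (edges padded), its sequence of non-zero first differences is
#' all rising, all falling, or rising then falling exactly once.
#'
#' @param freq relative mismatch frequencies.
#' @return `TRUE` if unimodal.
#' @export
mismatch_unimodal <- function(freq) {
  if (length(freq) < 3) return(TRUE)
  padded <- c(freq[1], freq, freq[length(freq)])
  sm <- as.numeric(stats::filter(padded, rep(1 / 3, 3), sides = 2))
  sm <- sm[!is.na(sm)]
  d <- diff(sm)
  d <- d[d != 0]
  if (length(d) < 2) return(TRUE)
  s <- rle(sign(d))$values
  length(s) == 1 || (length(s) == 2 && s[1] == 1 && s[2] == -1)
}
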
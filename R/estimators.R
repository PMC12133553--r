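# Causal-effect estimators for two-sample MR on summary statistics.
#
# All methods consume a HarmonizedSet (or its pairs data.frame) carrying
# per-SNP exposure effects beta_exp (SE se_exp) and outcome effects
# beta_out (SE se_out) on a shared effect allele. Estimates are on the
# log-OR scale; presentation layers exponentiate.

ratio_parts <- function(pairs, weighting = c("first", "second")) {
  weighting <- match.arg(weighting)
  b <- pairs$beta_out / pairs$beta_exp
  if (weighting == "first") {
    se <- pairs$se_out / abs(pairs$beta_exp)
  } else {
    se <- sqrt(pairs$se_out^2 / pairs$beta_exp^2 +
                 pairs$beta_out^2 * pairs$se_exp^2 / pairs$beta_exp^4)
  }
  list(b = b, se = se, w = 1 / se^2)
}

#' Wald ratio for a single instrument
#'
#' The per-SNP causal estimate: outcome effect divided by exposure effect,
#' with the first-order delta-method SE se_out/|beta_exp| (or the
#' second-order form adding the exposure-uncertainty term).
#'
#' @param pair one-row data.frame (or \linkS4class{HarmonizedSet} with a
#'   single instrument).
#' @param weighting "first" (default) or "second" order delta method.
#' @return an \linkS4class{MREstimate} with method "wald".
#' @export
waldRatio <- function(pair, weighting = c("first", "second")) {
  pair <- as_pairs(pair)
  stopifnot(nrow(pair) == 1L)
  if (pair$beta_exp == 0)
    stop("Wald ratio undefined: exposure effect is zero")
  rp <- ratio_parts(pair, match.arg(weighting))
  new_estimate("wald", rp$b, rp$se, 1L)
}

#' Inverse-variance-weighted estimate
#'
#' Weighted mean of the per-SNP Wald ratios with inverse-variance weights.
#' Fixed-effect SE is (sum w)^(-1/2); the random-effects (multiplicative)
#' SE inflates it by max(1, sqrt(Q/(k-1))) where Q is Cochran's Q at the
#' pooled estimate, so it can never shrink below the fixed-effect SE. A
#' single instrument delegates to \code{waldRatio}.
#'
#' @param x \linkS4class{HarmonizedSet} or pairs data.frame.
#' @param model "fixed" or "random".
#' @param weighting delta-method order for the ratio SEs.
#' @return an \linkS4class{MREstimate} (extras carry Q, Q_df, Q_pval).
#' @export
mrIvw <- function(x, model = c("random", "fixed"),
                  weighting = c("first", "second")) {
  pairs <- as_pairs(x)
  model <- match.arg(model)
  k <- nrow(pairs)
  if (k == 0L) stop("no instruments: use waldRatio for a single SNP")
  if (k == 1L) return(waldRatio(pairs, weighting))
  rp <- ratio_parts(pairs, match.arg(weighting))
  beta <- sum(rp$w * rp$b) / sum(rp$w)
  se_fixed <- sqrt(1 / sum(rp$w))
  Q <- sum(rp$w * (rp$b - beta)^2)
  q_pval <- pchisq(Q, df = k - 1, lower.tail = FALSE)
  se <- if (model == "random") se_fixed * max(1, sqrt(Q / (k - 1))) else se_fixed
  new_estimate(paste0("ivw_", model), beta, se, k,
               extras = list(Q = Q, Q_df = k - 1, Q_pval = q_pval,
                             se_fixed = se_fixed))
}

#' Cochran's Q heterogeneity test
#'
#' Q = sum w_j (b_j - beta)^2 over the per-SNP ratios with first-order
#' inverse-variance weights, referred to chi-square with k - 1 df.
#'
#' @param x \linkS4class{HarmonizedSet} or pairs data.frame.
#' @param beta pooled estimate to test against; defaults to the IVW
#'   fixed-effect estimate.
#' @return list(Q, df, pval).
#' @export
cochranQ <- function(x, beta = NULL) {
  pairs <- as_pairs(x)
  k <- nrow(pairs)
  stopifnot(k >= 2L)
  rp <- ratio_parts(pairs)
  if (is.null(beta)) beta <- sum(rp$w * rp$b) / sum(rp$w)
  Q <- sum(rp$w * (rp$b - beta)^2)
  list(Q = Q, df = k - 1, pval = pchisq(Q, df = k - 1, lower.tail = FALSE))
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome effects on the exposure effects
#' with an unconstrained intercept (the average directional pleiotropic
#' effect), weights 1/se_out^2. Exposure effects are sign-oriented to be
#' non-negative first (flipping the matching outcome effects), the
#' identifiability convention for the intercept. Coefficient SEs are the
#' WLS SEs scaled by max(1, sqrt(RSS_w/(k-2))). Also returns I2_GX, the
#' NOME diagnostic: I2_GX = (Q_GX - (k-1))/Q_GX with Q_GX the weighted
#' heterogeneity of the exposure effects; values below 0.9 trigger a
#' regression-dilution warning.
#'
#' @param x \linkS4class{HarmonizedSet} or pairs data.frame (k >= 3).
#' @return an \linkS4class{MREggerResult}.
#' @export
mrEgger <- function(x) {
  pairs <- as_pairs(x)
  k <- nrow(pairs)
  if (k < 3L) stop("MR-Egger needs at least 3 instruments")
  s <- sign(pairs$beta_exp)
  s[s == 0] <- 1
  gx <- abs(pairs$beta_exp)
  gy <- pairs$beta_out * s
  w <- 1 / pairs$se_out^2
  wx <- 1 / pairs$se_exp^2
  gxbar <- sum(wx * gx) / sum(wx)
  q_gx <- sum((gx - gxbar)^2 / pairs$se_exp^2)
  i2gx <- if (q_gx > 0) max(0, (q_gx - (k - 1)) / q_gx) else 0
  if (i2gx < 0.9)
    warning(sprintf(
      "I2_GX = %.3f < 0.9: the NOME assumption is violated and the ",
      i2gx), "Egger slope is attenuated; interpret with caution")

  X <- cbind(intercept = 1, slope = gx)
  XtWX <- crossprod(X, w * X)
  if (q_gx == 0 || abs(det(XtWX)) < 1e-300) {
    warning("exposure effects show no spread: Egger slope and intercept ",
            "are not separately identifiable")
    na <- new_estimate("egger", NA_real_, NA_real_, k)
    nai <- new_estimate("egger_intercept", NA_real_, NA_real_, k)
    return(new("MREggerResult", slope = na, intercept = nai, i2gx = i2gx))
  }
  coef <- drop(solve(XtWX, crossprod(X, w * gy)))
  resid <- gy - drop(X %*% coef)
  rss_w <- sum(w * resid^2)
  scale <- max(1, sqrt(rss_w / (k - 2)))
  se <- sqrt(diag(solve(XtWX))) * scale

  slope <- new_estimate("egger", coef[["slope"]], se[["slope"]], k,
                        extras = list(rss_w = rss_w, scale = scale))
  intercept <- new_estimate("egger_intercept", coef[["intercept"]],
                            se[["intercept"]], k)
  new("MREggerResult", slope = slope, intercept = intercept, i2gx = i2gx)
}

wm_point <- function(b, w) {
  ord <- order(b)
  b <- b[ord]
  w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(b[1])
  if (s[length(s)] < 0.5) return(b[length(b)])
  j <- which(s >= 0.5)[1]
  b[j - 1] + (b[j] - b[j - 1]) * (0.5 - s[j - 1]) / (s[j] - s[j - 1])
}

boot_se <- function(pairs, n_boot, seed, statistic) {
  set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(i) {
    bx <- rnorm(nrow(pairs), pairs$beta_exp, pairs$se_exp)
    by <- rnorm(nrow(pairs), pairs$beta_out, pairs$se_out)
    statistic(bx, by)
  }, numeric(1))
  sd(reps)
}

#' Weighted median estimate
#'
#' Orders the per-SNP ratios and takes the value at which the cumulative
#' normalized inverse-variance weight crosses one half, interpolating
#' linearly between the bracketing ratios. Consistent as long as at least
#' half the weight comes from valid instruments. SE by seeded parametric
#' bootstrap (perturbing both exposure and outcome effects by their SEs).
#'
#' @param x \linkS4class{HarmonizedSet} or pairs data.frame (k >= 3).
#' @param n_boot bootstrap resamples for the SE.
#' @param seed RNG seed (bootstrap is bit-reproducible under it).
#' @return an \linkS4class{MREstimate} with method "weighted_median".
#' @export
weightedMedian <- function(x, n_boot = 1000, seed = 1) {
  pairs <- as_pairs(x)
  k <- nrow(pairs)
  if (k < 3L) stop("weighted median needs at least 3 instruments")
  rp <- ratio_parts(pairs)
  beta <- wm_point(rp$b, rp$w)
  se <- boot_se(pairs, n_boot, seed, function(bx, by) {
    wm_point(by / bx, bx^2 / pairs$se_out^2)
  })
  new_estimate("weighted_median", beta, se, k)
}

mode_point <- function(b, w, phi, grid_n = 512) {
  k <- length(b)
  spread <- min(sd(b), mad(b, constant = 1) / 0.6745)
  h <- phi * 0.9 * spread * k^(-1 / 5)
  if (!is.finite(h) || h <= 0) return(list(beta = b[1], h = 0, step = 0))
  grid <- seq(min(b) - 3 * h, max(b) + 3 * h, length.out = grid_n)
  dens <- vapply(grid, function(g) sum(w * dnorm(g, b, h)), numeric(1))
  list(beta = grid[which.max(dens)], h = h, step = diff(grid[1:2]))
}

#' Mode-based estimate
#'
#' Gaussian-kernel smoothed density over the per-SNP ratios (modified
#' Silverman bandwidth h = phi * 0.9 * min(sd, MAD/0.6745) * k^(-1/5)),
#' maximized on a 512-point grid spanning the ratio range +/- 3h. The
#' weighted variant weights each kernel by the ratio's inverse variance;
#' the simple variant weights equally. Robust to a majority of invalid
#' instruments (the estimate tracks the largest cluster of ratios). If all
#' ratios coincide the common value is returned with the IVW SE. Bootstrap
#' SE, seeded.
#'
#' @param x \linkS4class{HarmonizedSet} or pairs data.frame (k >= 3).
#' @param weighted weight kernels by inverse ratio variance.
#' @param phi bandwidth multiplier (default 1).
#' @param n_boot,seed bootstrap settings.
#' @param grid_n density grid resolution.
#' @return an \linkS4class{MREstimate} with method "weighted_mode" or
#'   "simple_mode" (extras carry the bandwidth and grid step).
#' @export
modeEstimate <- function(x, weighted = TRUE, phi = 1, n_boot = 1000,
                         seed = 1, grid_n = 512) {
  pairs <- as_pairs(x)
  k <- nrow(pairs)
  if (k < 3L) stop("mode estimate needs at least 3 instruments")
  rp <- ratio_parts(pairs)
  w <- if (weighted) rp$w else rep(1, k)
  mp <- mode_point(rp$b, w, phi, grid_n)
  method <- if (weighted) "weighted_mode" else "simple_mode"
  if (mp$h == 0) {
    ivw <- mrIvw(pairs, model = "fixed")
    return(new_estimate(method, rp$b[1], ivw@se, k,
                        extras = list(bandwidth = 0, grid_step = 0)))
  }
  se <- boot_se(pairs, n_boot, seed, function(bx, by) {
    b <- by / bx
    wb <- if (weighted) bx^2 / pairs$se_out^2 else rep(1, k)
    mode_point(b, wb, phi, grid_n)$beta
  })
  new_estimate(method, mp$beta, se, k,
               extras = list(bandwidth = mp$h, grid_step = mp$step))
}

# Huber psi and its reference moments under a standard normal
huber_psi <- function(t, c) pmin(pmax(t, -c), c)
huber_delta <- function(c) 2 * pnorm(c) - 1              # E[psi(Z) Z]
huber_epsi2 <- function(c) {                             # E[psi(Z)^2]
  (2 * pnorm(c) - 1) - 2 * c * dnorm(c) + 2 * c^2 * pnorm(c, lower.tail = FALSE)
}
tukey_psi <- function(t, c) ifelse(abs(t) <= c, t * (1 - (t / c)^2)^2, 0)
tukey_moment <- function(f, c) { # numeric E[f(Z)] on a fine grid
  z <- seq(-8, 8, length.out = 4001)
  sum(f(z) * dnorm(z)) * diff(z[1:2])
}

#' Robust adjusted profile score estimate
#'
#' Models per-SNP pleiotropy as a mean-zero random effect with variance
#' tau2 and solves the robust profile estimating equations for the causal
#' slope and tau2 jointly: with standardized residuals
#' t_j = (beta_out - beta * beta_exp) / sqrt(se_out^2 + beta^2 se_exp^2 + tau2),
#' the slope solves sum psi_c(t_j) d t_j / d beta = 0 and tau2 solves
#' sum psi_c(t_j) t_j = (k - 1) * delta_c, where delta_c = E[psi_c(Z) Z]
#' under normality makes the equation unbiased (the k - 1 multiplier is a
#' small-sample df adjustment for the estimated slope) and tau2 is floored
#' at 0. The solver is deterministic: the profile root in beta is bracketed
#' around the IVW estimate and refined by bisection; tau2 is profiled by
#' bisection at each beta. SE from the expectation-form sandwich.
#'
#' @param x \linkS4class{HarmonizedSet} or pairs data.frame (k >= 3).
#' @param overdispersion estimate tau2 (FALSE fixes tau2 = 0).
#' @param loss "huber" (default) or "tukey".
#' @param c_tuning robustness tuning constant (1.345 for Huber).
#' @param max_expand bracket-expansion limit before declaring
#'   non-convergence.
#' @return an \linkS4class{MREstimate} with method "raps" (extras carry
#'   tau2).
#' @export
mrRaps <- function(x, overdispersion = TRUE, loss = c("huber", "tukey"),
                   c_tuning = NULL, max_expand = 60) {
  pairs <- as_pairs(x)
  k <- nrow(pairs)
  if (k < 3L) stop("mrRaps needs at least 3 instruments")
  loss <- match.arg(loss)
  if (is.null(c_tuning)) c_tuning <- if (loss == "huber") 1.345 else 4.685
  psi <- if (loss == "huber") function(t) huber_psi(t, c_tuning)
         else function(t) tukey_psi(t, c_tuning)
  delta <- if (loss == "huber") huber_delta(c_tuning)
           else tukey_moment(function(z) tukey_psi(z, c_tuning) * z, c_tuning)
  epsi2 <- if (loss == "huber") huber_epsi2(c_tuning)
           else tukey_moment(function(z) tukey_psi(z, c_tuning)^2, c_tuning)
  epsi_d <- if (loss == "huber") 2 * pnorm(c_tuning) - 1
            else tukey_moment(function(z)
              ifelse(abs(z) <= c_tuning,
                     (1 - (z / c_tuning)^2) * (1 - 5 * (z / c_tuning)^2), 0),
              c_tuning)

  bx <- pairs$beta_exp; sx <- pairs$se_exp
  by <- pairs$beta_out; sy <- pairs$se_out

  tau2_profile <- function(beta) {
    if (!overdispersion) return(0)
    g <- function(tau2) {
      t <- (by - beta * bx) / sqrt(sy^2 + beta^2 * sx^2 + tau2)
      sum(psi(t) * t) - (k - 1) * delta
    }
    if (g(0) <= 0) return(0)
    hi <- max(sy^2) # expand until the equation changes sign
    it <- 0
    while (g(hi) > 0 && it < max_expand) { hi <- hi * 4; it <- it + 1 }
    if (g(hi) > 0) stop("mrRaps: tau2 profiling failed to bracket a root")
    uniroot(g, c(0, hi), tol = 1e-12)$root
  }
  score <- function(beta) {
    tau2 <- tau2_profile(beta)
    v <- sy^2 + beta^2 * sx^2 + tau2
    t <- (by - beta * bx) / sqrt(v)
    dt <- -(bx * v + (by - beta * bx) * beta * sx^2) / v^1.5
    sum(psi(t) * dt)
  }
  b0 <- mrIvw(pairs, model = "fixed")@beta
  half <- max(1, 10 * mrIvw(pairs, model = "fixed")@se, abs(b0))
  lo <- b0 - half; hi <- b0 + half
  it <- 0
  while (score(lo) * score(hi) > 0 && it < max_expand) {
    lo <- lo - half; hi <- hi + half; it <- it + 1
  }
  if (score(lo) * score(hi) > 0)
    stop("mrRaps did not converge: no sign change in the profile score ",
         "on [", format(lo), ", ", format(hi), "]")
  beta <- uniroot(score, c(lo, hi), tol = 1e-10)$root
  tau2 <- tau2_profile(beta)
  v <- sy^2 + beta^2 * sx^2 + tau2
  dt <- -(bx * v + (by - beta * bx) * beta * sx^2) / v^1.5
  se <- sqrt(epsi2 / (epsi_d^2 * sum(dt^2)))
  new_estimate("raps", beta, se, k,
               extras = list(tau2 = tau2, loss = loss, c = c_tuning))
}
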
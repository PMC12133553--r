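# Sensitivity analyses: MR-PRESSO, Steiger directionality, leave-one-out,
# funnel data, statistical power.

ivw_slope <- function(bx, by, sy) {
  sum(bx * by / sy^2) / sum(bx^2 / sy^2)
}

loo_slopes <- function(bx, by, sy) {
  w <- bx^2 / sy^2
  wb <- bx * by / sy^2
  (sum(wb) - wb) / (sum(w) - w)
}

#' MR-PRESSO: pleiotropy residual sum of squares and outlier test
#'
#' Global test: the observed residual sum of squares around the
#' leave-one-out IVW predictions is compared with a simulated null in
#' which outcome effects are drawn from Normal(beta_(-j) * beta_exp_j,
#' se_out_j) and exposure effects from Normal(beta_exp_j, se_exp_j), the
#' leave-one-out slopes being recomputed on each simulated dataset.
#' global_pval = (1 + #{RSS* >= RSS_obs}) / (n_sim + 1) — the add-one
#' pseudo-count keeps p strictly positive and the rank construction makes
#' the null p super-uniform at resolution 1/(n_sim + 1). Per-SNP outlier
#' p-values compare each observed squared residual to its simulated
#' distribution, Bonferroni-adjusted by the number of instruments. The
#' distortion test bootstraps the outlier-free set and locates the
#' all-SNP estimate in that distribution (two-sided).
#'
#' @param x \linkS4class{HarmonizedSet} or pairs data.frame (k >= 4).
#' @param n_sim simulated null datasets (must be >= 1).
#' @param seed RNG seed.
#' @param outlier_alpha level for the Bonferroni-adjusted outlier call.
#' @param n_boot bootstrap resamples for the distortion test.
#' @return a \linkS4class{PressoResult}.
#' @export
mrPresso <- function(x, n_sim = 1000, seed = 1, outlier_alpha = 0.05,
                     n_boot = 1000) {
  pairs <- as_pairs(x)
  k <- nrow(pairs)
  if (k < 4L) stop("MR-PRESSO needs at least 4 instruments")
  if (n_sim < 1L) stop("n_sim must be at least 1 (degenerate null)")
  bx <- pairs$beta_exp; sx <- pairs$se_exp
  by <- pairs$beta_out; sy <- pairs$se_out

  loo <- loo_slopes(bx, by, sy)
  resid2_obs <- (by - loo * bx)^2
  rss_obs <- sum(resid2_obs)

  set.seed(seed)
  bx_star <- matrix(rnorm(k * n_sim, bx, sx), nrow = k)
  by_star <- matrix(rnorm(k * n_sim, loo * bx, sy), nrow = k)
  w_star <- bx_star^2 / sy^2
  wb_star <- bx_star * by_star / sy^2
  loo_star <- sweep(-wb_star, 2, colSums(wb_star), `+`) /
    sweep(-w_star, 2, colSums(w_star), `+`)
  resid2_star <- (by_star - loo_star * bx_star)^2
  rss_star <- colSums(resid2_star)

  global_pval <- (1 + sum(rss_star >= rss_obs)) / (n_sim + 1)
  p_raw <- (1 + rowSums(resid2_star >= resid2_obs)) / (n_sim + 1)
  p_adj <- pmin(1, p_raw * k)
  outlier <- p_adj < outlier_alpha
  outliers <- data.frame(snp = pairs$snp, pval_raw = p_raw,
                         pval_adj = p_adj, outlier = outlier,
                         stringsAsFactors = FALSE)

  beta_before <- ivw_slope(bx, by, sy)
  distortion_pval <- NA_real_
  beta_after <- beta_before
  free <- which(!outlier)
  if (any(outlier) && length(free) >= 2L) {
    beta_after <- ivw_slope(bx[free], by[free], sy[free])
    boot <- vapply(seq_len(n_boot), function(i) {
      idx <- sample(free, length(free), replace = TRUE)
      ivw_slope(bx[idx], by[idx], sy[idx])
    }, numeric(1))
    lo <- (1 + sum(boot <= beta_before)) / (n_boot + 1)
    hi <- (1 + sum(boot >= beta_before)) / (n_boot + 1)
    distortion_pval <- min(1, 2 * min(lo, hi))
  }
  new("PressoResult", rss_obs = rss_obs, global_pval = global_pval,
      outliers = outliers, distortion_pval = distortion_pval,
      beta_before = beta_before, beta_after = beta_after)
}

steiger_r2 <- function(beta, se, n, eaf = NULL, binary = FALSE,
                       case_fraction = NULL) {
  if (binary) {
    if (is.null(eaf) || any(is.na(eaf))) {
      warning("binary-outcome Steiger requested without eaf; ",
              "falling back to z-based r2")
    } else {
      r <- beta * sqrt(2 * eaf * (1 - eaf)) *
        sqrt(case_fraction * (1 - case_fraction))
      return(pmin(r^2, 0.999))
    }
  }
  z <- beta / se
  z^2 / (z^2 + n - 2)
}

#' Steiger directionality test
#'
#' Per SNP, the variance explained in exposure and outcome is computed
#' from the z statistic, r2 = z^2 / (z^2 + n - 2); for binary outcomes the
#' correlation is first formed on the observed scale from the log OR,
#' effect-allele frequency and case fraction (r = beta * sqrt(2 eaf (1 -
#' eaf)) * sqrt(cf (1 - cf))), then squared. Totals are summed over the
#' instruments; the causal direction is called correct when the
#' instruments explain more variance in the exposure. The p-value is the
#' two-sided z test on the difference of the Fisher-transformed total
#' correlations.
#'
#' @param x \linkS4class{HarmonizedSet} or pairs data.frame.
#' @param n_exp,n_out sample sizes; default to the per-SNP n columns.
#' @param outcome_type "binary" or "continuous".
#' @param case_fraction outcome case fraction (binary only).
#' @return a \linkS4class{SteigerResult}.
#' @export
mrSteiger <- function(x, n_exp = NULL, n_out = NULL,
                      outcome_type = c("binary", "continuous"),
                      case_fraction = NULL) {
  pairs <- as_pairs(x)
  outcome_type <- match.arg(outcome_type)
  if (is.null(n_exp)) n_exp <- stats::median(pairs$n_exp)
  if (is.null(n_out)) n_out <- stats::median(pairs$n_out)
  stopifnot(n_exp > 2, n_out > 2)
  binary <- outcome_type == "binary"
  if (binary && is.null(case_fraction))
    stop("case_fraction is required for a binary outcome")
  r2_exp <- steiger_r2(pairs$beta_exp, pairs$se_exp, n_exp)
  r2_out <- steiger_r2(pairs$beta_out, pairs$se_out, n_out,
                       eaf = pairs$eaf_out, binary = binary,
                       case_fraction = case_fraction)
  R2e <- min(sum(r2_exp), 0.999)
  R2o <- min(sum(r2_out), 0.999)
  z <- (atanh(sqrt(R2e)) - atanh(sqrt(R2o))) /
    sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  pval <- 2 * pnorm(-abs(z))
  new("SteigerResult", r2_exposure = R2e, r2_outcome = R2o,
      direction_correct = R2e > R2o, steiger_pval = pval,
      per_snp = data.frame(snp = pairs$snp, r2_exp = r2_exp,
                           r2_out = r2_out, stringsAsFactors = FALSE))
}

#' Steiger per-SNP direction filter
#'
#' Drops instruments that individually explain strictly more variance in
#' the outcome than in the exposure (r2_out > r2_exp); when outcome
#' effects are all zero nothing is ever removed.
#'
#' @inheritParams mrSteiger
#' @return filtered \linkS4class{HarmonizedSet} (ledger gains a
#'   "steiger_direction" step) or data.frame if a data.frame was given.
#' @export
steigerFilter <- function(x, n_exp = NULL, n_out = NULL,
                          outcome_type = c("binary", "continuous"),
                          case_fraction = NULL) {
  st <- mrSteiger(x, n_exp, n_out, outcome_type, case_fraction)
  drop <- st@per_snp$r2_out > st@per_snp$r2_exp
  if (is(x, "HarmonizedSet"))
    new("HarmonizedSet", pairs = x@pairs[!drop, , drop = FALSE],
        ledger = ledger_add(x@ledger, "steiger_direction",
                            nrow(x@pairs), sum(drop)))
  else x[!drop, , drop = FALSE]
}

#' Leave-one-out IVW
#'
#' Recomputes the IVW estimate excluding each instrument in turn and flags
#' exclusions that flip the p < 0.05 significance call of the full
#' estimate.
#'
#' @param x \linkS4class{HarmonizedSet} or pairs data.frame (k >= 3).
#' @param model IVW model passed through.
#' @param alpha significance level for the flip flag.
#' @return data.frame (snp, beta, se, pval, sig_flip) with one row per
#'   excluded SNP; attribute "full" carries the all-SNP estimate.
#' @export
leaveOneOut <- function(x, model = "random", alpha = 0.05) {
  pairs <- as_pairs(x)
  k <- nrow(pairs)
  if (k < 3L) stop("leave-one-out needs at least 3 instruments")
  full <- mrIvw(pairs, model = model)
  full_sig <- full@pval < alpha
  rows <- lapply(seq_len(k), function(j) {
    est <- mrIvw(pairs[-j, , drop = FALSE], model = model)
    data.frame(snp = pairs$snp[j], beta = est@beta, se = est@se,
               pval = est@pval,
               sig_flip = (est@pval < alpha) != full_sig,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "full") <- full
  out
}

#' Funnel-plot data
#'
#' Per-SNP Wald ratio against its precision (1/SE); a plotting-ready
#' table, no inference. Asymmetry around the pooled estimate suggests
#' directional pleiotropy.
#'
#' @param x \linkS4class{HarmonizedSet} or pairs data.frame.
#' @return data.frame (snp, ratio, precision); empty input gives an empty
#'   table.
#' @export
funnelData <- function(x) {
  pairs <- as_pairs(x)
  if (nrow(pairs) == 0L)
    return(data.frame(snp = character(0), ratio = numeric(0),
                      precision = numeric(0), stringsAsFactors = FALSE))
  rp <- ratio_parts(pairs)
  data.frame(snp = pairs$snp, ratio = rp$b, precision = 1 / rp$se,
             stringsAsFactors = FALSE)
}

#' Statistical power for binary-outcome two-sample MR
#'
#' Normal-approximation power to detect an odds ratio \code{or_alt} at
#' two-sided level alpha, given the outcome GWAS size and case fraction
#' and the variance in the exposure explained by the instruments:
#' power = Phi(|ln or_alt| * sqrt(n * R2 * cf * (1 - cf)) - z_{1-alpha/2}).
#'
#' @param n_total outcome GWAS total sample size.
#' @param case_fraction fraction of cases.
#' @param r2_instrument variance in the exposure explained by the
#'   instruments, in (0, 1).
#' @param or_alt odds ratio under the alternative.
#' @param alpha two-sided test level.
#' @return power in (0, 1).
#' @export
powerBinary <- function(n_total, case_fraction, r2_instrument, or_alt,
                        alpha = 0.05) {
  if (r2_instrument <= 0 || r2_instrument >= 1)
    stop("r2_instrument must lie in (0, 1)")
  stopifnot(case_fraction > 0, case_fraction < 1, n_total > 0)
  ncp <- abs(log(or_alt)) *
    sqrt(n_total * r2_instrument * case_fraction * (1 - case_fraction))
  pnorm(ncp - qnorm(1 - alpha / 2))
}
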
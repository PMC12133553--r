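# Synthetic GWAS summary-statistic generator with a known two-step
# mediation structure: exposure instruments gamma feed the exposure; each
# mediator k receives beta1[k] * gamma from the exposure plus its own
# independent cis instruments delta; the outcome receives theta_direct *
# gamma, beta2[k] times each mediator signal, and any configured
# pleiotropic offsets. theta_total = theta_direct + sum(beta1 * beta2)
# holds by construction.

#' Build a simulation configuration
#'
#' The direct effect is always derived from \code{theta_total} and the
#' mediator products, so the conservation identity theta_total =
#' theta_direct + sum(beta1 * beta2) holds exactly. Defaults are
#' desk-scale (100 exposure instruments, 5 mediators with 30 cis
#' instruments each) but carry the three study cohort sizes: a 110,347
#' continuous exposure GWAS, 3,301-sample mediator (plasma protein)
#' GWAS, and a binary outcome GWAS of 1,030,836 with case fraction
#' 60620/1030836.
#'
#' @param m_snps exposure-instrument SNPs.
#' @param m_med_snps cis-instrument SNPs per mediator.
#' @param n_exp,n_med,n_out GWAS sample sizes.
#' @param case_fraction outcome case fraction.
#' @param theta_total total exposure -> outcome log OR.
#' @param beta1,beta2 per-mediator step-1/step-2 effects (optionally
#'   named; names become mediator trait ids).
#' @param gamma_sd SD of exposure-instrument effects.
#' @param delta_sd SD of mediator cis-instrument effects.
#' @param med_noise_sd mediator-specific noise on exposure instruments.
#' @param pleiotropy list(type = "none"/"balanced"/"directional", mean,
#'   sd, fraction) of direct instrument -> outcome paths.
#' @param maf_range uniform minor-allele-frequency range.
#' @param frac_palindromic fraction of SNPs given A/T or C/G alleles.
#' @param ld_blocks list(n_blocks, block_size, r2) duplicating exposure
#'   signals in tight LD blocks.
#' @param seed RNG seed.
#' @return a \linkS4class{SimulationConfig}.
#' @export
simConfig <- function(m_snps = 100, m_med_snps = 30,
                      n_exp = 110347, n_med = 3301, n_out = 1030836,
                      case_fraction = 60620 / 1030836,
                      theta_total = 0.044,
                      beta1 = c(PROT1 = 0.143, PROT2 = 0.20, PROT3 = 0.15,
                                PROT4 = 0, PROT5 = 0),
                      beta2 = c(0.046, 0.08, 0, 0.05, 0),
                      gamma_sd = 0.1, delta_sd = 0.3, med_noise_sd = 0,
                      pleiotropy = list(type = "none", mean = 0, sd = 0,
                                        fraction = 0),
                      maf_range = c(0.05, 0.5),
                      frac_palindromic = 0.05,
                      ld_blocks = list(n_blocks = 0, block_size = 0, r2 = 0),
                      seed = 1) {
  if (length(beta1) && is.null(names(beta1)))
    names(beta1) <- paste0("PROT", seq_along(beta1))
  if (!length(beta1)) names(beta1) <- character(0)
  pleiotropy <- utils::modifyList(
    list(type = "none", mean = 0, sd = 0, fraction = 0), pleiotropy)
  ld_blocks <- utils::modifyList(
    list(n_blocks = 0, block_size = 0, r2 = 0), ld_blocks)
  new("SimulationConfig",
      m_snps = as.integer(m_snps), m_med_snps = as.integer(m_med_snps),
      n_exp = n_exp, n_med = n_med, n_out = n_out,
      case_fraction = case_fraction,
      theta_total = theta_total,
      theta_direct = theta_total - sum(beta1 * beta2),
      beta1 = beta1, beta2 = beta2,
      gamma_sd = gamma_sd, delta_sd = delta_sd,
      med_noise_sd = med_noise_sd,
      pleiotropy = pleiotropy, maf_range = maf_range,
      frac_palindromic = frac_palindromic, ld_blocks = ld_blocks,
      seed = as.integer(seed))
}

PALINDROMIC_PAIRS <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
NONPAL_PAIRS <- list(c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
                     c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))

gwas_from_truth <- function(snp, chrom, pos, ea, oa, maf, beta_true, se,
                            n, trait, block_id, block_r) {
  m <- length(snp)
  eps <- rnorm(m)
  if (any(block_id > 0)) {
    for (b in unique(block_id[block_id > 0])) {
      idx <- which(block_id == b)
      shared <- rnorm(1)
      eps[idx] <- sqrt(block_r^2) * shared + sqrt(1 - block_r^2) * eps[idx]
    }
  }
  beta <- beta_true + se * eps
  pval <- pmax(z_pval(beta, se), P_FLOOR)
  new("GwasSummary",
      data = data.frame(snp = snp, chrom = chrom, pos = pos,
                        ea = ea, oa = oa, eaf = maf,
                        beta = beta, se = se, pval = pval, n = n,
                        stringsAsFactors = FALSE),
      trait = trait,
      qc = c(bad_allele = 0L, nonpositive_se = 0L, bad_pval = 0L,
             nonpositive_n = 0L, missing_beta = 0L, bad_eaf = 0L))
}

#' Simulate a mediation GWAS triple
#'
#' Generates exposure, per-mediator and outcome summary tables plus the
#' realized truth. Observed effect estimates are the true effects plus
#' normal noise with SE = 1 / sqrt(2 maf (1 - maf) n) per trait; the
#' binary outcome uses the log-OR approximation with effective n =
#' n_out * cf * (1 - cf). Alleles carry the configured palindromic
#' fraction; LD blocks duplicate exposure-instrument signals at nearby
#' positions with correlated noise. Fully reproducible under the seed.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list(exposure, mediators = named list, outcome — all
#'   \linkS4class{GwasSummary} — and truth, a
#'   \linkS4class{SyntheticTruth}).
#' @export
simulateMediationGwas <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(config@seed)
  K <- length(config@beta1)
  med_ids <- names(config@beta1)
  m_exp <- config@m_snps
  m_med <- config@m_med_snps
  m <- m_exp + K * m_med
  role <- c(rep("exposure", m_exp), rep(med_ids, each = m_med))

  snp <- sprintf("rs%06d", seq_len(m))
  maf <- runif(m, config@maf_range[1], config@maf_range[2])

  # positions: far apart by default; LD-block members packed within 5 kb
  chrom <- as.character(((seq_len(m) - 1) %% 22) + 1)
  pos <- 1e6 + ((seq_len(m) - 1) %/% 22) * 2e7
  block_id <- integer(m)
  lb <- config@ld_blocks
  if (lb$n_blocks > 0 && lb$block_size > 1) {
    stopifnot(lb$n_blocks * lb$block_size <= m_exp)
    for (b in seq_len(lb$n_blocks)) {
      idx <- ((b - 1) * lb$block_size + 1):(b * lb$block_size)
      block_id[idx] <- b
      chrom[idx] <- chrom[idx[1]]
      pos[idx] <- pos[idx[1]] + (seq_along(idx) - 1) * 1000
    }
  }

  is_pal <- runif(m) < config@frac_palindromic
  pick <- function(pairs, n) {
    sel <- sample(length(pairs), n, replace = TRUE)
    do.call(rbind, pairs[sel])
  }
  alleles <- matrix("", m, 2)
  if (any(is_pal)) alleles[is_pal, ] <- pick(PALINDROMIC_PAIRS, sum(is_pal))
  if (any(!is_pal)) alleles[!is_pal, ] <- pick(NONPAL_PAIRS, sum(!is_pal))

  gamma <- numeric(m)
  gamma[role == "exposure"] <- rnorm(m_exp, 0, config@gamma_sd)
  if (lb$n_blocks > 0 && lb$block_size > 1)
    for (b in seq_len(lb$n_blocks))
      gamma[block_id == b] <- gamma[which(block_id == b)[1]]

  delta <- matrix(0, m, K, dimnames = list(snp, med_ids))
  for (k in seq_len(K))
    delta[role == med_ids[k], k] <- rnorm(m_med, 0, config@delta_sd)

  pl <- config@pleiotropy
  pleio <- numeric(m)
  if (pl$type != "none" && pl$fraction > 0) {
    affected <- which(role == "exposure" &
                        runif(m) < pl$fraction)
    mu <- if (pl$type == "directional") pl$mean else 0
    pleio[affected] <- rnorm(length(affected), mu, pl$sd)
  }

  med_true <- matrix(0, m, K)
  for (k in seq_len(K)) {
    med_true[, k] <- config@beta1[k] * gamma + delta[, k]
    if (config@med_noise_sd > 0) {
      exp_idx <- role == "exposure"
      med_true[exp_idx, k] <- med_true[exp_idx, k] +
        rnorm(sum(exp_idx), 0, config@med_noise_sd)
    }
  }
  # pleiotropic offsets are defined relative to the exposure-increasing
  # allele (the MR-Egger orientation), so they enter the outcome with the
  # sign of the instrument's exposure effect
  sg <- ifelse(gamma >= 0, 1, -1)
  out_true <- config@theta_direct * gamma +
    drop(med_true %*% config@beta2) + pleio * sg

  het <- 2 * maf * (1 - maf)
  se_exp <- 1 / sqrt(het * config@n_exp)
  se_med <- 1 / sqrt(het * config@n_med)
  n_eff_out <- config@n_out * config@case_fraction * (1 - config@case_fraction)
  se_out <- 1 / sqrt(het * n_eff_out)
  block_r <- sqrt(lb$r2)

  exposure <- gwas_from_truth(snp, chrom, pos, alleles[, 1], alleles[, 2],
                              maf, gamma, se_exp, config@n_exp,
                              "exposure", block_id, block_r)
  mediators <- setNames(lapply(seq_len(K), function(k)
    gwas_from_truth(snp, chrom, pos, alleles[, 1], alleles[, 2], maf,
                    med_true[, k], se_med, config@n_med, med_ids[k],
                    block_id, block_r)), med_ids)
  outcome <- gwas_from_truth(snp, chrom, pos, alleles[, 1], alleles[, 2],
                             maf, out_true, se_out, config@n_out,
                             "outcome", block_id, block_r)
  truth <- new("SyntheticTruth", config = config, snp = snp,
               gamma = gamma, delta = delta, pleio = pleio,
               valid_instrument = pleio == 0)
  list(exposure = exposure, mediators = mediators, outcome = outcome,
       truth = truth)
}

#' Implant pleiotropic outliers into a simulated dataset
#'
#' Adds the stated offsets to the observed outcome effects at the stated
#' SNP indices and updates the truth ledger (the SNPs stop being valid
#' instruments). An empty implant list is the identity.
#'
#' @param sim list as returned by \code{simulateMediationGwas}.
#' @param implants data.frame (index, offset) or list of c(index, offset).
#' @return the modified sim list.
#' @export
implantOutliers <- function(sim, implants) {
  if (is.list(implants) && !is.data.frame(implants))
    implants <- do.call(rbind, lapply(implants, function(x)
      data.frame(index = x[[1]], offset = x[[2]])))
  if (is.null(implants) || nrow(implants) == 0L) return(sim)
  m <- nrow(sim$outcome@data)
  if (any(implants$index < 1 | implants$index > m))
    stop("implant index out of range 1..", m)
  d <- sim$outcome@data
  d$beta[implants$index] <- d$beta[implants$index] + implants$offset
  d$pval <- pmax(z_pval(d$beta, d$se), P_FLOOR)
  sim$outcome@data <- d
  sim$truth@pleio[implants$index] <- sim$truth@pleio[implants$index] +
    implants$offset
  sim$truth@valid_instrument[implants$index] <- FALSE
  sim
}
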
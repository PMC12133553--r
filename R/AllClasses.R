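#' @import methods
#' @importFrom stats pnorm qnorm pchisq phyper p.adjust dnorm sd mad
#'   median rnorm runif uniroot setNames
#' @importFrom utils read.delim write.table head
NULL

GWAS_COLUMNS <- c("snp", "chrom", "pos", "ea", "oa", "eaf",
                  "beta", "se", "pval", "n")

#' GWAS summary-statistic table
#'
#' One row per SNP association with a single trait: identifiers, alleles,
#' effect-allele frequency, effect estimate (log odds ratio for binary
#' traits), its standard error, p-value and sample size. Rows failing the
#' record invariants at read time are dropped and tallied in \code{qc}.
#'
#' @slot data data.frame with columns snp, chrom, pos, ea, oa, eaf, beta,
#'   se, pval, n.
#' @slot trait single trait identifier shared by all rows.
#' @slot qc named integer vector counting rows dropped per reason.
#' @export
setClass("GwasSummary",
  representation(data = "data.frame", trait = "character", qc = "integer"),
  validity = function(object) {
    d <- object@data
    msg <- character(0)
    if (!all(GWAS_COLUMNS %in% names(d)))
      msg <- c(msg, paste("missing columns:",
                          paste(setdiff(GWAS_COLUMNS, names(d)), collapse = ", ")))
    else {
      if (nrow(d)) {
        if (any(d$se <= 0)) msg <- c(msg, "all se must be > 0")
        if (any(d$pval <= 0 | d$pval > 1)) msg <- c(msg, "pval must lie in (0, 1]")
        if (any(d$ea == d$oa)) msg <- c(msg, "effect allele must differ from other allele")
        if (!all(d$ea %in% c("A", "C", "G", "T")) ||
            !all(d$oa %in% c("A", "C", "G", "T")))
          msg <- c(msg, "alleles must be single nucleotides A/C/G/T")
        bad_eaf <- !is.na(d$eaf) & (d$eaf < 0 | d$eaf > 1)
        if (any(bad_eaf)) msg <- c(msg, "eaf must lie in [0, 1] or be NA")
      }
    }
    if (length(object@trait) != 1L) msg <- c(msg, "trait must be a single string")
    if (length(msg)) msg else TRUE
  })

#' Filter ledger
#'
#' Ordered record of an instrument-selection chain: for every filter the
#' number of SNPs entering, removed, and surviving. Counts telescope: the
#' survivors of step k are the input of step k + 1.
#'
#' @slot steps data.frame with columns step, n_in, n_removed, n_out.
#' @export
setClass("FilterLedger",
  representation(steps = "data.frame"),
  validity = function(object) {
    s <- object@steps
    need <- c("step", "n_in", "n_removed", "n_out")
    if (!all(need %in% names(s))) return("ledger needs step/n_in/n_removed/n_out")
    if (nrow(s)) {
      if (any(s$n_out != s$n_in - s$n_removed))
        return("n_out must equal n_in - n_removed")
      if (nrow(s) > 1 && any(s$n_out[-nrow(s)] != s$n_in[-1]))
        return("ledger does not telescope: n_out of step k must equal n_in of step k+1")
      if (any(s$n_removed < 0)) return("n_removed must be non-negative")
    }
    TRUE
  })

#' Harmonized exposure/outcome instrument set
#'
#' Exposure and outcome effects for each instrument expressed on a shared
#' effect allele, plus the per-SNP instrument-strength F statistic, together
#' with the ledger of the filters that produced the set.
#'
#' @slot pairs data.frame with columns snp, chrom, pos, ea, oa,
#'   beta_exp, se_exp, pval_exp, eaf_exp, beta_out, se_out, pval_out,
#'   eaf_out, f_stat.
#' @slot ledger a \linkS4class{FilterLedger}.
#' @export
setClass("HarmonizedSet",
  representation(pairs = "data.frame", ledger = "FilterLedger"),
  validity = function(object) {
    p <- object@pairs
    need <- c("snp", "ea", "beta_exp", "se_exp", "pval_exp",
              "beta_out", "se_out", "pval_out", "f_stat")
    if (!all(need %in% names(p)))
      return(paste("pairs missing columns:",
                   paste(setdiff(need, names(p)), collapse = ", ")))
    if (nrow(p) && (any(p$se_exp <= 0) || any(p$se_out <= 0)))
      return("all standard errors must be > 0")
    if (anyDuplicated(p$snp)) return("duplicate snp ids in harmonized set")
    TRUE
  })

#' Causal-effect estimate from one MR method
#'
#' @slot method method tag, one of wald, ivw_fixed, ivw_random, egger,
#'   egger_intercept, weighted_median, simple_mode, weighted_mode, raps.
#' @slot beta causal log odds ratio per unit of exposure.
#' @slot se standard error of beta.
#' @slot ci_low,ci_high 95\% confidence limits on the beta scale.
#' @slot pval two-sided p-value.
#' @slot nsnp number of instruments used.
#' @slot extras list of method-specific quantities (e.g. Q, I2_GX, tau2).
#' @export
setClass("MREstimate",
  representation(method = "character", beta = "numeric", se = "numeric",
                 ci_low = "numeric", ci_high = "numeric", pval = "numeric",
                 nsnp = "integer", extras = "list"),
  validity = function(object) {
    if (length(object@beta) != 1L || length(object@se) != 1L)
      return("beta and se must be scalars")
    if (is.finite(object@ci_low) && is.finite(object@ci_high) &&
        (object@ci_low > object@beta || object@beta > object@ci_high))
      return("beta must lie inside [ci_low, ci_high]")
    TRUE
  })

#' MR-Egger fit: slope, intercept and the NOME I-squared
#'
#' @slot slope \linkS4class{MREstimate} for the causal slope.
#' @slot intercept \linkS4class{MREstimate} for the average pleiotropic effect.
#' @slot i2gx I-squared for the exposure associations (NOME diagnostic);
#'   values below 0.9 indicate regression-dilution bias in the slope.
#' @export
setClass("MREggerResult",
  representation(slope = "MREstimate", intercept = "MREstimate",
                 i2gx = "numeric"))

#' MR-PRESSO result
#'
#' @slot rss_obs observed residual sum of squares.
#' @slot global_pval simulation p-value for the global pleiotropy test.
#' @slot outliers data.frame (snp, pval_raw, pval_adj, outlier).
#' @slot distortion_pval bootstrap p-value comparing estimates before and
#'   after outlier removal (NA when no outlier is flagged).
#' @slot beta_before,beta_after IVW estimates with and without outliers.
#' @export
setClass("PressoResult",
  representation(rss_obs = "numeric", global_pval = "numeric",
                 outliers = "data.frame", distortion_pval = "numeric",
                 beta_before = "numeric", beta_after = "numeric"))

#' Steiger directionality result
#'
#' @slot r2_exposure,r2_outcome total variance explained by the instruments
#'   in exposure and outcome.
#' @slot direction_correct TRUE when the instruments explain more variance
#'   in the exposure than in the outcome.
#' @slot steiger_pval two-sided p-value of the correlation-difference z test.
#' @slot per_snp data.frame (snp, r2_exp, r2_out).
#' @export
setClass("SteigerResult",
  representation(r2_exposure = "numeric", r2_outcome = "numeric",
                 direction_correct = "logical", steiger_pval = "numeric",
                 per_snp = "data.frame"),
  validity = function(object) {
    if (object@r2_exposure < 0 || object@r2_exposure >= 1 ||
        object@r2_outcome < 0 || object@r2_outcome >= 1)
      return("r2 values must lie in [0, 1)")
    TRUE
  })

#' Effects of the two mediation legs plus the total effect
#'
#' beta_total is the exposure-to-outcome log OR, beta1 the exposure-to-
#' mediator effect (step 1), beta2 the mediator-to-outcome log OR per
#' mediator unit (step 2).
#'
#' @slot mediator_id mediator (protein) name.
#' @slot beta_total,se_total,p_total total-effect estimate.
#' @slot beta1,se1,p1 step-1 estimate.
#' @slot beta2,se2,p2 step-2 estimate.
#' @export
setClass("TwoStepEffects",
  representation(mediator_id = "character",
                 beta_total = "numeric", se_total = "numeric", p_total = "numeric",
                 beta1 = "numeric", se1 = "numeric", p1 = "numeric",
                 beta2 = "numeric", se2 = "numeric", p2 = "numeric"),
  validity = function(object) {
    ses <- c(object@se_total, object@se1, object@se2)
    if (any(!is.na(ses) & ses <= 0)) return("standard errors must be > 0")
    TRUE
  })

#' Mediation decomposition for one mediator
#'
#' indirect = beta1 * beta2; direct = total - indirect (so direct +
#' indirect reproduces the total exactly); proportion = indirect / total on
#' the log-odds scale.
#'
#' @slot effects the underlying \linkS4class{TwoStepEffects}.
#' @slot indirect,se_indirect product-of-coefficients indirect effect and
#'   its delta-method standard error.
#' @slot direct total minus indirect.
#' @slot proportion indirect / total (raw fraction).
#' @slot classification one of partial, complete, none.
#' @export
setClass("MediationResult",
  representation(effects = "TwoStepEffects", indirect = "numeric",
                 se_indirect = "numeric", direct = "numeric",
                 proportion = "numeric", classification = "character"),
  validity = function(object) {
    tot <- object@effects@beta_total
    gap <- object@direct + object@indirect - tot
    if (is.finite(tot) && is.finite(gap) &&
        abs(gap) > 1e-12 * max(1, abs(tot)))
      return("direct + indirect must equal the total effect")
    if (!object@classification %in% c("partial", "complete", "none"))
      return("classification must be partial/complete/none")
    TRUE
  })

#' Linkage-disequilibrium matrix
#'
#' Symmetric matrix of squared correlations between SNPs, unit diagonal.
#'
#' @slot r2 numeric matrix with SNP ids as dimnames.
#' @export
setClass("LDMatrix",
  representation(r2 = "matrix"),
  validity = function(object) {
    m <- object@r2
    if (nrow(m) != ncol(m)) return("r2 must be square")
    if (is.null(rownames(m)) || is.null(colnames(m)) ||
        !identical(rownames(m), colnames(m)))
      return("r2 must carry identical row/column SNP ids")
    if (any(m < 0 | m > 1)) return("r2 values must lie in [0, 1]")
    if (any(abs(diag(m) - 1) > 1e-8)) return("r2 diagonal must be 1")
    if (any(abs(m - t(m)) > 1e-6)) return("r2 must be symmetric (tolerance 1e-6)")
    TRUE
  })

#' Gene-set collection
#'
#' @slot sets named list of character vectors of member symbols
#'   (upper-cased, deduplicated, non-empty).
#' @slot descriptions character vector parallel to \code{sets}.
#' @export
setClass("GeneSetCollection",
  representation(sets = "list", descriptions = "character"),
  validity = function(object) {
    if (length(object@sets) != length(object@descriptions))
      return("one description per set required")
    if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
      return("sets must be uniquely named")
    for (s in object@sets) {
      if (!length(s)) return("member lists must be non-empty")
      if (anyDuplicated(s)) return("member lists must be deduplicated")
      if (!identical(s, toupper(s))) return("member symbols must be case-normalized")
    }
    TRUE
  })

#' Configuration of the synthetic summary-statistic generator
#'
#' Encodes the causal diagram of the two-step design: exposure instruments
#' with effects gamma, K mediators each with a step-1 effect beta1[k], a
#' step-2 effect beta2[k] and its own independent cis instruments, and a
#' total exposure-to-outcome effect theta_total that is partitioned as
#' theta_total = theta_direct + sum(beta1 * beta2) at construction (the
#' direct effect is derived, never set).
#'
#' @slot m_snps number of exposure-instrument SNPs.
#' @slot m_med_snps cis-instrument SNPs per mediator.
#' @slot n_exp,n_med,n_out GWAS sample sizes for the three legs.
#' @slot case_fraction outcome case fraction (binary outcome).
#' @slot theta_total total exposure-to-outcome log OR per exposure unit.
#' @slot theta_direct derived direct effect.
#' @slot beta1,beta2 per-mediator step-1 / step-2 effects.
#' @slot gamma_sd SD of the exposure-instrument effect sizes.
#' @slot delta_sd SD of the mediator cis-instrument effect sizes.
#' @slot med_noise_sd SD of mediator-specific (non-exposure) signal on
#'   exposure instruments.
#' @slot pleiotropy list(type, mean, sd, fraction) for direct instrument-
#'   to-outcome paths; type none/balanced/directional.
#' @slot maf_range uniform range for minor-allele frequencies.
#' @slot frac_palindromic fraction of SNPs given A/T or C/G alleles.
#' @slot ld_blocks list(n_blocks, block_size, r2) of duplicated-signal
#'   LD blocks among the exposure instruments.
#' @slot seed RNG seed making the generated tables fully reproducible.
#' @export
setClass("SimulationConfig",
  representation(m_snps = "integer", m_med_snps = "integer",
                 n_exp = "numeric", n_med = "numeric", n_out = "numeric",
                 case_fraction = "numeric",
                 theta_total = "numeric", theta_direct = "numeric",
                 beta1 = "numeric", beta2 = "numeric",
                 gamma_sd = "numeric", delta_sd = "numeric",
                 med_noise_sd = "numeric",
                 pleiotropy = "list", maf_range = "numeric",
                 frac_palindromic = "numeric", ld_blocks = "list",
                 seed = "integer"),
  validity = function(object) {
    if (length(object@beta1) != length(object@beta2))
      return("beta1 and beta2 must have one entry per mediator")
    tot <- object@theta_direct + sum(object@beta1 * object@beta2)
    if (abs(tot - object@theta_total) > 1e-12 * max(1, abs(object@theta_total)))
      return("theta_total must equal theta_direct + sum(beta1*beta2)")
    if (object@maf_range[1] <= 0 || object@maf_range[2] >= 1 ||
        object@maf_range[1] > object@maf_range[2])
      return("maf_range must lie inside (0, 1)")
    if (object@case_fraction <= 0 || object@case_fraction >= 1)
      return("case_fraction must lie in (0, 1)")
    if (!object@pleiotropy$type %in% c("none", "balanced", "directional"))
      return("pleiotropy type must be none/balanced/directional")
    if (object@frac_palindromic < 0 || object@frac_palindromic > 1)
      return("frac_palindromic must lie in [0, 1]")
    TRUE
  })

#' Realized truth of a synthetic dataset
#'
#' The generating parameters plus the per-SNP true effects, serialized
#' alongside every generated dataset so recovery can be scored.
#'
#' @slot config the \linkS4class{SimulationConfig} used.
#' @slot snp SNP ids in table order.
#' @slot gamma true exposure effects (0 for mediator cis instruments).
#' @slot delta matrix of true mediator cis effects (SNP x mediator).
#' @slot pleio true direct instrument-to-outcome offsets.
#' @slot valid_instrument TRUE for SNPs with no pleiotropic path.
#' @export
setClass("SyntheticTruth",
  representation(config = "SimulationConfig", snp = "character",
                 gamma = "numeric", delta = "matrix", pleio = "numeric",
                 valid_instrument = "logical"))
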
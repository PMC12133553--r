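#' Filter associations by p-value threshold
#'
#' Keeps exactly the records with p strictly below the threshold (the
#' genome-wide 5e-8 convention for the exposure; 1e-5 for mediator legs,
#' where the weaker threshold trades heterogeneity against explained
#' variance), preserving input order.
#'
#' @param x a \linkS4class{GwasSummary} or its data.frame.
#' @param threshold p-value threshold in (0, 1).
#' @return object of the same kind as the input, filtered.
#' @export
filterByPvalue <- function(x, threshold = 5e-8) {
  stopifnot(threshold > 0, threshold < 1)
  if (is(x, "GwasSummary")) {
    keep <- x@data$pval < threshold
    if (!any(keep)) message("filterByPvalue: no records below ", threshold)
    return(new("GwasSummary", data = x@data[keep, , drop = FALSE],
               trait = x@trait, qc = x@qc))
  }
  x[x$pval < threshold, , drop = FALSE]
}

#' Greedy distance/LD clumping
#'
#' Sorts records ascending by p-value (ties by SNP id) and accepts a SNP
#' iff no previously accepted SNP on the same chromosome lies within
#' \code{window_kb} with squared correlation at or above \code{r2_max}.
#' Without an LD matrix the rule degrades to pure distance pruning (any
#' accepted SNP within the window rejects the candidate), which is logged
#' loudly since no LD reference ships with the package. SNP pairs absent
#' from the supplied matrix are treated as uncorrelated. The result is
#' independent of the input row order.
#'
#' @param x a \linkS4class{GwasSummary} or its data.frame (needs chrom/pos).
#' @param ld optional \linkS4class{LDMatrix}.
#' @param r2_max squared-correlation threshold (default 0.001).
#' @param window_kb window size in kilobases (default 10000).
#' @return filtered object of the same kind, rows ordered by (pval, snp).
#' @export
clumpInstruments <- function(x, ld = NULL, r2_max = 0.001,
                             window_kb = 10000) {
  d <- if (is(x, "GwasSummary")) x@data else x
  if (nrow(d) == 0L) return(x)
  if (any(is.na(d$chrom)) || any(is.na(d$pos)))
    stop("clumping requires chrom and pos on every record")
  if (is.null(ld))
    message("clumpInstruments: no LD matrix supplied; ",
            "falling back to distance-only pruning")
  ord <- order(d$pval, d$snp)
  d <- d[ord, , drop = FALSE]
  r2m <- if (!is.null(ld)) ld@r2 else NULL
  accepted <- integer(0)
  for (i in seq_len(nrow(d))) {
    near <- accepted[d$chrom[accepted] == d$chrom[i] &
                     abs(d$pos[accepted] - d$pos[i]) <= window_kb * 1000]
    reject <- FALSE
    if (length(near)) {
      if (is.null(r2m)) {
        reject <- TRUE
      } else {
        ids <- intersect(d$snp[near], rownames(r2m))
        if (d$snp[i] %in% colnames(r2m) && length(ids))
          reject <- any(r2m[ids, d$snp[i]] >= r2_max)
      }
    }
    if (!reject) accepted <- c(accepted, i)
  }
  out <- d[accepted, , drop = FALSE]
  row.names(out) <- NULL
  if (is(x, "GwasSummary"))
    new("GwasSummary", data = out, trait = x@trait, qc = x@qc)
  else out
}

#' Instrument-strength F statistic
#'
#' Per-SNP approximation F = (beta/se)^2. When effect-allele frequency and
#' sample size are available the exact form (n - 2) * R2 / (1 - R2) with
#' R2 = 2 * eaf * (1 - eaf) * beta^2 (standardized trait) can be requested.
#'
#' @param beta,se exposure effect and standard error.
#' @param eaf,n frequency and sample size (only for \code{exact = TRUE}).
#' @param exact use the R2-based form.
#' @return numeric F statistic(s).
#' @export
fStatistic <- function(beta, se, eaf = NULL, n = NULL, exact = FALSE) {
  if (exact) {
    if (is.null(eaf) || is.null(n))
      stop("exact F statistic needs eaf and n")
    r2 <- 2 * eaf * (1 - eaf) * beta^2
    return((n - 2) * r2 / (1 - r2))
  }
  (beta / se)^2
}

#' Remove weak instruments
#'
#' Keeps instruments with F at or above \code{f_min} (removal is for F
#' strictly below the cutoff, so F = 10 survives).
#'
#' @param x a \linkS4class{HarmonizedSet}.
#' @param f_min minimum F (default 10).
#' @return filtered \linkS4class{HarmonizedSet}; the ledger gains a
#'   "weak_instrument" step.
#' @export
filterWeak <- function(x, f_min = 10) {
  stopifnot(is(x, "HarmonizedSet"))
  keep <- x@pairs$f_stat >= f_min
  new("HarmonizedSet",
      pairs = x@pairs[keep, , drop = FALSE],
      ledger = ledger_add(x@ledger, "weak_instrument",
                          nrow(x@pairs), sum(!keep)))
}

#' Harmonize exposure and outcome effects onto a shared effect allele
#'
#' Intersects the two tables by SNP id, removes palindromic (A/T or C/G)
#' pairs unconditionally, removes pairs whose allele sets cannot be matched
#' even after strand complementing (ambiguous), and flips the outcome beta
#' sign (and replaces eaf by 1 - eaf) where the outcome's effect allele is
#' the exposure's other allele. The ledger records missing_in_outcome,
#' palindromic and ambiguous removals plus the (non-removing) flipped
#' count. An opt-in frequency rescue keeps palindromic SNPs whose eaf is
#' far from 0.5 on both sides (|eaf - 0.5| > \code{pal_rescue_eaf}) and
#' strand-resolvable; it defaults off, matching the unconditional-removal
#' rule.
#'
#' @param exposure,outcome \linkS4class{GwasSummary} objects (or their
#'   data.frames).
#' @param pal_rescue_eaf NULL (default: drop all palindromes) or the
#'   minimum |eaf - 0.5| for rescue.
#' @return a \linkS4class{HarmonizedSet}.
#' @export
harmonizeEffects <- function(exposure, outcome, pal_rescue_eaf = NULL) {
  ex <- if (is(exposure, "GwasSummary")) exposure@data else exposure
  ou <- if (is(outcome, "GwasSummary")) outcome@data else outcome
  for (tab in list(ex, ou)) {
    dup <- tab$snp[duplicated(tab$snp)]
    if (length(dup))
      stop("duplicate snp id within one table: ", dup[[1]])
  }
  ledger <- new_ledger()
  n0 <- nrow(ex)
  idx <- match(ex$snp, ou$snp)
  present <- !is.na(idx)
  ledger <- ledger_add(ledger, "missing_in_outcome", n0, sum(!present))
  ex <- ex[present, , drop = FALSE]
  ou <- ou[idx[present], , drop = FALSE]

  pal <- is_palindromic(ex$ea, ex$oa) | is_palindromic(ou$ea, ou$oa)
  if (!is.null(pal_rescue_eaf)) {
    resolvable <- pal & !is.na(ex$eaf) & !is.na(ou$eaf) &
      abs(ex$eaf - 0.5) > pal_rescue_eaf & abs(ou$eaf - 0.5) > pal_rescue_eaf
    pal <- pal & !resolvable
  }
  ledger <- ledger_add(ledger, "palindromic", nrow(ex), sum(pal))
  ex <- ex[!pal, , drop = FALSE]
  ou <- ou[!pal, , drop = FALSE]

  same <- ou$ea == ex$ea & ou$oa == ex$oa
  flip <- ou$ea == ex$oa & ou$oa == ex$ea
  comp_ea <- unname(COMPLEMENT[ou$ea])
  comp_oa <- unname(COMPLEMENT[ou$oa])
  same_c <- !same & !flip & comp_ea == ex$ea & comp_oa == ex$oa
  flip_c <- !same & !flip & comp_ea == ex$oa & comp_oa == ex$ea
  ambiguous <- !(same | flip | same_c | flip_c)
  ledger <- ledger_add(ledger, "ambiguous", nrow(ex), sum(ambiguous))
  keep <- !ambiguous
  ex <- ex[keep, , drop = FALSE]
  ou <- ou[keep, , drop = FALSE]
  do_flip <- (flip | flip_c)[keep]
  beta_out <- ifelse(do_flip, -ou$beta, ou$beta)
  eaf_out <- ifelse(do_flip, 1 - ou$eaf, ou$eaf)
  ledger <- ledger_add(ledger, "flipped", nrow(ex), 0L)

  pairs <- data.frame(
    snp = ex$snp, chrom = ex$chrom, pos = ex$pos,
    ea = ex$ea, oa = ex$oa,
    beta_exp = ex$beta, se_exp = ex$se, pval_exp = ex$pval,
    eaf_exp = ex$eaf, n_exp = ex$n,
    beta_out = beta_out, se_out = ou$se, pval_out = ou$pval,
    eaf_out = eaf_out, n_out = ou$n,
    f_stat = (ex$beta / ex$se)^2,
    stringsAsFactors = FALSE)
  row.names(pairs) <- NULL
  attr(pairs, "n_flipped") <- sum(do_flip)
  new("HarmonizedSet", pairs = pairs, ledger = ledger)
}

#' Remove instruments annotated to confounder traits
#'
#' Case-insensitive substring match of each pattern against the blacklist
#' annotations of each SNP (local surrogate for a phenome-wide confounder
#' look-up).
#'
#' @param x a \linkS4class{HarmonizedSet}.
#' @param blacklist data.frame (snp, trait) as from \code{readBlacklist}.
#' @param patterns character vector of confounder trait substrings.
#' @return filtered \linkS4class{HarmonizedSet} with a
#'   "confounder_blacklist" ledger step.
#' @export
removeBlacklisted <- function(x, blacklist, patterns) {
  stopifnot(is(x, "HarmonizedSet"))
  hit <- rep(FALSE, nrow(x@pairs))
  if (!is.null(blacklist) && nrow(blacklist) && length(patterns)) {
    matched <- rep(FALSE, nrow(blacklist))
    for (p in patterns)
      matched <- matched | grepl(p, blacklist$trait, ignore.case = TRUE,
                                 fixed = FALSE)
    bad_snps <- unique(blacklist$snp[matched])
    hit <- x@pairs$snp %in% bad_snps
  }
  new("HarmonizedSet",
      pairs = x@pairs[!hit, , drop = FALSE],
      ledger = ledger_add(x@ledger, "confounder_blacklist",
                          nrow(x@pairs), sum(hit)))
}

#' Remove instruments directly associated with the outcome
#'
#' Bonferroni screen: with k pairs under test, removes those with outcome
#' p-value below alpha / k (such SNPs plausibly violate the exclusion
#' restriction).
#'
#' @param x a \linkS4class{HarmonizedSet}.
#' @param alpha family-wise level (default 0.05).
#' @return filtered \linkS4class{HarmonizedSet} with an
#'   "outcome_associated" ledger step.
#' @export
removeOutcomeAssociated <- function(x, alpha = 0.05) {
  stopifnot(is(x, "HarmonizedSet"))
  k <- nrow(x@pairs)
  hit <- if (k) x@pairs$pval_out < alpha / k else logical(0)
  new("HarmonizedSet",
      pairs = x@pairs[!hit, , drop = FALSE],
      ledger = ledger_add(x@ledger, "outcome_associated", k, sum(hit)))
}
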
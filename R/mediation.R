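# Two-step mediation MR: product-of-coefficients decomposition of the
# total exposure->outcome effect into a mediator-borne indirect part and
# the remaining direct part, all on the log-OR scale.

#' Parse an "OR(low~high)" string
#'
#' @param s character like "1.045(1.007~1.083)".
#' @return numeric c(or, low, high).
#' @export
parseOrCi <- function(s) {
  m <- regmatches(s, regexec(
    "^\\s*([0-9.]+)\\s*\\(\\s*([0-9.]+)\\s*~\\s*([0-9.]+)\\s*\\)\\s*$", s))[[1]]
  if (length(m) != 4L) stop("cannot parse OR(low~high): '", s, "'")
  as.numeric(m[2:4])
}

#' Format an estimate as "OR(low~high)"
#'
#' @param or,low,high numeric values on the OR scale.
#' @param digits decimals (default 3, the reporting convention).
#' @return character string.
#' @export
formatOrCi <- function(or, low, high, digits = 3) {
  fmt <- paste0("%.", digits, "f")
  sprintf(paste0(fmt, "(", fmt, "~", fmt, ")"), or, low, high)
}

# "<0.001" style censored p-values parse to their bound
parse_pval <- function(s) {
  as.numeric(sub("^<\\s*", "", trimws(as.character(s))))
}

#' Product-of-coefficients indirect effect
#'
#' indirect = beta1 * beta2 with the delta-method SE
#' sqrt(beta1^2 se2^2 + beta2^2 se1^2); \code{exact_variance} adds the
#' second-order term se1^2 se2^2.
#'
#' @param beta1,se1 step-1 (exposure -> mediator) effect and SE.
#' @param beta2,se2 step-2 (mediator -> outcome) effect and SE.
#' @param exact_variance include the product-of-variances term.
#' @return list(indirect, se).
#' @export
indirectEffect <- function(beta1, se1, beta2, se2, exact_variance = FALSE) {
  v <- beta1^2 * se2^2 + beta2^2 * se1^2
  if (exact_variance) v <- v + se1^2 * se2^2
  list(indirect = beta1 * beta2, se = sqrt(v))
}

#' Mediation proportion
#'
#' indirect / total on the log-odds scale. The reported headline numeral
#' is this raw fraction rounded to two decimals; the percent-formatted
#' string appends a percent sign to that same numeral (the field's
#' reporting convention prints the fraction with a percent sign — the
#' discrepancy is surfaced by returning both forms, never resolved
#' silently).
#'
#' @param total total effect (log OR), must be non-zero.
#' @param indirect indirect effect (log OR).
#' @return list(proportion = raw fraction, rounded = two-decimal value,
#'   label = formatted string).
#' @export
mediationProportion <- function(total, indirect) {
  if (total == 0) stop("mediation proportion undefined: total effect is 0")
  p <- indirect / total
  r <- round(p, 2)
  list(proportion = p, rounded = r, label = sprintf("%.2f%%", r))
}

#' Classify a mediation result
#'
#' partial: both steps and the total effect significant; complete: both
#' steps significant but the total is not; none: otherwise.
#'
#' @param p_total,p1,p2 p-values of the total, step-1 and step-2 effects.
#' @param alpha significance level (default 0.05).
#' @return "partial", "complete" or "none".
#' @export
classifyMediation <- function(p_total, p1, p2, alpha = 0.05) {
  steps <- p1 < alpha & p2 < alpha
  ifelse(steps & p_total < alpha, "partial",
         ifelse(steps, "complete", "none"))
}

mediate_result <- function(effects, alpha = 0.05, exact_variance = FALSE) {
  ind <- indirectEffect(effects@beta1, effects@se1,
                        effects@beta2, effects@se2,
                        exact_variance = exact_variance)
  prop <- if (effects@beta_total != 0)
    ind$indirect / effects@beta_total else NA_real_
  new("MediationResult", effects = effects,
      indirect = ind$indirect, se_indirect = ind$se,
      direct = effects@beta_total - ind$indirect,
      proportion = prop,
      classification = classifyMediation(effects@p_total, effects@p1,
                                         effects@p2, alpha))
}

#' Bootstrap confidence interval for the mediation proportion
#'
#' Parametric bootstrap on (beta1, beta2, total) from their normal
#' sampling distributions; percentile interval. Seeded.
#'
#' @param effects a \linkS4class{TwoStepEffects}.
#' @param n_boot resamples.
#' @param seed RNG seed.
#' @param level interval level.
#' @return numeric c(low, high).
#' @export
proportionCI <- function(effects, n_boot = 2000, seed = 1, level = 0.95) {
  set.seed(seed)
  b1 <- rnorm(n_boot, effects@beta1, effects@se1)
  b2 <- rnorm(n_boot, effects@beta2, effects@se2)
  tot <- rnorm(n_boot, effects@beta_total, effects@se_total)
  props <- (b1 * b2) / tot
  unname(stats::quantile(props, c((1 - level) / 2, 1 - (1 - level) / 2)))
}

run_mr_leg <- function(exposure, outcome, p_threshold, ld = NULL,
                       f_min = 10, leg_name = "leg", clump = TRUE,
                       window_kb = 10000, r2_max = 0.001) {
  sel <- filterByPvalue(exposure, p_threshold)
  if (clump)
    sel <- suppressMessages(clumpInstruments(sel, ld = ld,
                                             r2_max = r2_max,
                                             window_kb = window_kb))
  hs <- harmonizeEffects(sel, outcome)
  hs <- filterWeak(hs, f_min)
  if (nrow(hs@pairs) == 0L)
    stop("leg failure [", leg_name, "]: no instruments survive selection")
  hs
}

#' Run the two-step mediation MR for one mediator
#'
#' Three full univariable MR legs: total (exposure -> outcome), step 1
#' (exposure -> mediator) and step 2 (mediator -> outcome). Instruments
#' for the exposure legs are selected at \code{p_exposure} (genome-wide),
#' for the mediator leg at \code{p_mediator}; each leg clumps, harmonizes
#' and drops weak instruments, then IVW is the primary estimator.
#'
#' @param exposure,mediator,outcome \linkS4class{GwasSummary} tables.
#' @param p_exposure,p_mediator instrument p thresholds (5e-8 / 1e-5).
#' @param ld optional \linkS4class{LDMatrix}.
#' @param f_min weak-instrument cutoff.
#' @param ivw_model IVW model for all three legs.
#' @return a \linkS4class{TwoStepEffects}.
#' @export
runTwoStep <- function(exposure, mediator, outcome,
                       p_exposure = 5e-8, p_mediator = 1e-5,
                       ld = NULL, f_min = 10, ivw_model = "random") {
  if (missing(mediator) || is.null(mediator))
    stop("mediator table is required for two-step mediation")
  leg_tot <- run_mr_leg(exposure, outcome, p_exposure, ld, f_min, "total")
  leg_1 <- run_mr_leg(exposure, mediator, p_exposure, ld, f_min, "step1")
  leg_2 <- run_mr_leg(mediator, outcome, p_mediator, ld, f_min, "step2")
  est_tot <- mrIvw(leg_tot, model = ivw_model)
  est_1 <- mrIvw(leg_1, model = ivw_model)
  est_2 <- mrIvw(leg_2, model = ivw_model)
  new("TwoStepEffects",
      mediator_id = if (is(mediator, "GwasSummary")) mediator@trait else "mediator",
      beta_total = est_tot@beta, se_total = est_tot@se, p_total = est_tot@pval,
      beta1 = est_1@beta, se1 = est_1@se, p1 = est_1@pval,
      beta2 = est_2@beta, se2 = est_2@se, p2 = est_2@pval)
}

#' Mediation report table
#'
#' One row per mediator with OR-scale "OR(low~high)" strings for the
#' total, step-1 and step-2 effects, p-values, the Steiger direction flag,
#' the classification and the percent-formatted mediation proportion,
#' sorted by mediator name. \code{significant_only} restricts to rows
#' classified partial or complete.
#'
#' @param results list of \linkS4class{MediationResult} objects.
#' @param direction optional named logical vector of Steiger direction
#'   flags per mediator (defaults to TRUE).
#' @param significant_only keep only rows with classification != "none".
#' @return data.frame mirroring the reporting layout (mediator, total,
#'   p_total, step1, p1, step2, p2, direction, classification,
#'   proportion, ratio_label).
#' @export
mediationTable <- function(results, direction = NULL,
                           significant_only = FALSE) {
  rows <- lapply(results, function(r) {
    e <- r@effects
    or_str <- function(b, s) formatOrCi(exp(b), exp(b - Z95 * s),
                                        exp(b + Z95 * s))
    dirflag <- if (!is.null(direction) && e@mediator_id %in% names(direction))
      direction[[e@mediator_id]] else TRUE
    data.frame(
      mediator = e@mediator_id,
      total = or_str(e@beta_total, e@se_total), p_total = e@p_total,
      step1 = or_str(e@beta1, e@se1), p1 = e@p1,
      step2 = or_str(e@beta2, e@se2), p2 = e@p2,
      direction = dirflag,
      classification = r@classification,
      proportion = r@proportion,
      ratio_label = sprintf("%.2f%%", round(r@proportion, 2)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mediator), , drop = FALSE]
  if (significant_only)
    out <- out[out$classification != "none", , drop = FALSE]
  row.names(out) <- NULL
  out
}
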
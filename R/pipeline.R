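# Orchestration: the full primary MR analysis and the mediator scan,
# driven by one configuration list, with deterministic text outputs.

#' Assemble a run configuration
#'
#' Central bag of thresholds used by the orchestration functions; every
#' value has the analysis default: genome-wide instrument threshold 5e-8
#' for the exposure, 1e-5 for mediator legs, clumping at r2 < 0.001 in a
#' 10,000 kb window, weak-instrument cutoff F >= 10, significance level
#' 0.05.
#'
#' @param p_exposure,p_mediator instrument p-value thresholds.
#' @param r2_max,window_kb clumping parameters.
#' @param f_min weak-instrument F cutoff.
#' @param alpha significance level.
#' @param presso_n_sim MR-PRESSO simulated null size.
#' @param n_boot bootstrap resamples for SE/distortion estimation.
#' @param seed RNG seed; mandatory since several components are
#'   stochastic.
#' @param confounder_patterns trait substrings for the blacklist screen.
#' @param fdr use BH-FDR instead of raw alpha in the mediator scan.
#' @return a plain list.
#' @export
runConfig <- function(p_exposure = 5e-8, p_mediator = 1e-5,
                      r2_max = 0.001, window_kb = 10000, f_min = 10,
                      alpha = 0.05, presso_n_sim = 1000, n_boot = 1000,
                      seed = 1, confounder_patterns = character(0),
                      fdr = FALSE) {
  stopifnot(p_exposure > 0, p_mediator > 0, r2_max > 0, window_kb > 0,
            f_min > 0, alpha > 0, length(seed) == 1L)
  list(p_exposure = p_exposure, p_mediator = p_mediator,
       r2_max = r2_max, window_kb = window_kb, f_min = f_min,
       alpha = alpha, presso_n_sim = presso_n_sim, n_boot = n_boot,
       seed = as.integer(seed),
       confounder_patterns = confounder_patterns, fdr = fdr)
}

write_tsv <- function(d, path) {
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], function(x) sprintf("%.10g", x))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

select_instruments <- function(exposure, outcome, config, ld = NULL,
                               blacklist = NULL, case_fraction = NULL,
                               p_threshold = config$p_exposure,
                               presso = TRUE) {
  sel <- filterByPvalue(exposure, p_threshold)
  n_raw <- nrow(gwasData(exposure))
  n_sig <- nrow(gwasData(sel))
  sel <- suppressMessages(clumpInstruments(sel, ld = ld,
                                           r2_max = config$r2_max,
                                           window_kb = config$window_kb))
  n_clump <- nrow(gwasData(sel))
  hs <- harmonizeEffects(sel, outcome)
  pre <- data.frame(step = c("pvalue_threshold", "ld_clump"),
                    n_in = c(n_raw, n_sig),
                    n_removed = c(n_raw - n_sig, n_sig - n_clump),
                    n_out = c(n_sig, n_clump))
  hs@ledger <- new("FilterLedger", steps = rbind(pre, hs@ledger@steps))
  hs <- filterWeak(hs, config$f_min)
  presso_res <- NULL
  if (presso && nrow(hs@pairs) >= 4L) {
    presso_res <- mrPresso(hs, n_sim = config$presso_n_sim,
                           seed = config$seed,
                           outlier_alpha = config$alpha,
                           n_boot = config$n_boot)
    bad <- presso_res@outliers$outlier
    hs <- new("HarmonizedSet",
              pairs = hs@pairs[!bad, , drop = FALSE],
              ledger = ledger_add(hs@ledger, "presso_outlier",
                                  nrow(hs@pairs), sum(bad)))
  } else {
    hs@ledger <- ledger_add(hs@ledger, "presso_outlier",
                            nrow(hs@pairs), 0L)
  }
  hs <- steigerFilter(hs, outcome_type = if (is.null(case_fraction))
    "continuous" else "binary", case_fraction = case_fraction)
  hs <- removeBlacklisted(hs, blacklist, config$confounder_patterns)
  hs <- removeOutcomeAssociated(hs, config$alpha)
  list(hs = hs, presso = presso_res)
}

#' Primary two-sample MR analysis
#'
#' Runs the full instrument-selection chain in the canonical order
#' (p-value threshold, clumping, harmonization, weak-instrument filter,
#' MR-PRESSO outlier removal, Steiger direction filter, confounder
#' blacklist, outcome-association Bonferroni screen), then the complete
#' estimator battery and sensitivity diagnostics, and applies the
#' decision rules: MR-Egger becomes the principal estimate when its
#' intercept is significant (directional pleiotropy); otherwise
#' random-effects IVW, with the weighted median emphasized when
#' Cochran's Q signals heterogeneity.
#'
#' @param exposure,outcome \linkS4class{GwasSummary} tables.
#' @param config list from \code{runConfig()}.
#' @param ld optional \linkS4class{LDMatrix}.
#' @param blacklist optional confounder blacklist data.frame.
#' @param case_fraction outcome case fraction (binary outcome); NULL for
#'   a continuous outcome.
#' @param out_dir optional directory; when given, estimates, ledger,
#'   leave-one-out, funnel tables and a manifest are written as
#'   deterministic text files.
#' @return list with elements instruments (HarmonizedSet), estimates
#'   (named list of MREstimate), egger (MREggerResult), presso, steiger,
#'   loo, funnel, q (Cochran's Q list), power, principal (method tag),
#'   emphasis (character notes), ledger (data.frame).
#' @export
runPrimary <- function(exposure, outcome, config = runConfig(),
                       ld = NULL, blacklist = NULL, case_fraction = NULL,
                       out_dir = NULL) {
  if (missing(outcome) || is.null(outcome))
    stop("configuration error: outcome table is required")
  sel <- select_instruments(exposure, outcome, config, ld, blacklist,
                            case_fraction)
  hs <- sel$hs
  k <- nrow(hs@pairs)
  if (k == 0L) {
    err <- simpleError("leg failure [primary]: no instruments survive")
    err$ledger <- ledgerSteps(hs)
    stop(err)
  }
  estimates <- list()
  if (k == 1L) {
    estimates$wald <- waldRatio(hs)
  } else {
    estimates$ivw_fixed <- mrIvw(hs, model = "fixed")
    estimates$ivw_random <- mrIvw(hs, model = "random")
  }
  egger <- NULL
  if (k >= 3L) {
    egger <- suppressWarnings(mrEgger(hs))
    estimates$egger <- egger@slope
    estimates$egger_intercept <- egger@intercept
    estimates$weighted_median <- weightedMedian(hs, n_boot = config$n_boot,
                                                seed = config$seed)
    estimates$weighted_mode <- modeEstimate(hs, weighted = TRUE,
                                            n_boot = config$n_boot,
                                            seed = config$seed)
    estimates$simple_mode <- modeEstimate(hs, weighted = FALSE,
                                          n_boot = config$n_boot,
                                          seed = config$seed)
    estimates$raps <- mrRaps(hs)
  }
  q <- if (k >= 2L) cochranQ(hs) else NULL
  steiger <- mrSteiger(hs, outcome_type = if (is.null(case_fraction))
    "continuous" else "binary", case_fraction = case_fraction)
  loo <- if (k >= 3L) leaveOneOut(hs, alpha = config$alpha) else NULL
  funnel <- funnelData(hs)
  power <- if (!is.null(case_fraction) && steiger@r2_exposure > 0 &&
               steiger@r2_exposure < 1)
    powerBinary(stats::median(hs@pairs$n_out), case_fraction,
                steiger@r2_exposure,
                exp(if (k == 1L) estimates$wald@beta else
                  estimates$ivw_random@beta),
                config$alpha)
  else NA_real_

  emphasis <- character(0)
  principal <- if (k == 1L) "wald" else "ivw_random"
  if (!is.null(egger) && egger@intercept@pval < config$alpha) {
    principal <- "egger"
    emphasis <- c(emphasis,
                  "Egger intercept significant: directional pleiotropy; MR-Egger is principal")
  } else if (!is.null(q) && q$pval < config$alpha) {
    principal <- "ivw_random"
    emphasis <- c(emphasis,
                  "Cochran Q significant: random-effects IVW with weighted median emphasized")
  }
  res <- list(instruments = hs, estimates = estimates, egger = egger,
              presso = sel$presso, steiger = steiger, loo = loo,
              funnel = funnel, q = q, power = power,
              principal = principal, emphasis = emphasis,
              ledger = ledgerSteps(hs))
  if (!is.null(out_dir)) write_primary(res, config, out_dir)
  invisible(res)
}

estimates_frame <- function(estimates) {
  rows <- lapply(names(estimates), function(nm) {
    e <- estimates[[nm]]
    data.frame(method = e@method, beta = e@beta, se = e@se,
               or = exp(e@beta), ci_low = exp(e@ci_low),
               ci_high = exp(e@ci_high), pval = e@pval, nsnp = e@nsnp,
               extras = as.character(jsonlite::toJSON(e@extras,
                                                      auto_unbox = TRUE,
                                                      digits = 10)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

write_primary <- function(res, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(estimates_frame(res$estimates),
            file.path(out_dir, "estimates.tsv"))
  write_tsv(res$ledger, file.path(out_dir, "ledger.tsv"))
  if (!is.null(res$loo)) write_tsv(res$loo, file.path(out_dir, "leave_one_out.tsv"))
  write_tsv(res$funnel, file.path(out_dir, "funnel.tsv"))
  manifest <- list(seed = config$seed, config = config,
                   principal = res$principal, emphasis = res$emphasis,
                   package_version = as.character(utils::packageVersion("mrMediate")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10)
  invisible(out_dir)
}

#' Mediator scan with two-step mediation and enrichment
#'
#' Step-1 MR (exposure -> mediator, exposure instruments) for every
#' mediator; step-2 MR (mediator -> outcome, mediator instruments at the
#' relaxed threshold) for the step-1-significant mediators; product-of-
#' coefficients decomposition and classification against the total
#' effect; then gene-set overrepresentation of the significant-mediator
#' list. Mediators whose step 2 is not run are classified "none".
#'
#' @param exposure,outcome \linkS4class{GwasSummary} tables.
#' @param mediators named list of \linkS4class{GwasSummary} tables.
#' @param config list from \code{runConfig()}.
#' @param gmt optional \linkS4class{GeneSetCollection}; NULL or empty
#'   skips enrichment with a warning.
#' @param ld optional \linkS4class{LDMatrix}.
#' @param universe optional enrichment universe.
#' @param out_dir optional output directory for TSV reports.
#' @return list(results = MediationResult list, table = full report,
#'   significant = significant view, enrichment = data.frame or NULL,
#'   total = MREstimate of the total effect).
#' @export
runMediationScan <- function(exposure, mediators, outcome,
                             config = runConfig(), gmt = NULL, ld = NULL,
                             universe = NULL, out_dir = NULL) {
  stopifnot(length(mediators) > 0, !is.null(names(mediators)))
  leg_tot <- run_mr_leg(exposure, outcome, config$p_exposure, ld,
                        config$f_min, "total",
                        window_kb = config$window_kb,
                        r2_max = config$r2_max)
  est_tot <- mrIvw(leg_tot)
  results <- list()
  for (nm in names(mediators)) {
    leg1 <- run_mr_leg(exposure, mediators[[nm]], config$p_exposure, ld,
                       config$f_min, paste0("step1:", nm),
                       window_kb = config$window_kb,
                       r2_max = config$r2_max)
    est1 <- mrIvw(leg1)
    run2 <- est1@pval < config$alpha
    if (run2) {
      leg2 <- run_mr_leg(mediators[[nm]], outcome, config$p_mediator, ld,
                         config$f_min, paste0("step2:", nm),
                         window_kb = config$window_kb,
                         r2_max = config$r2_max)
      est2 <- mrIvw(leg2)
      eff <- new("TwoStepEffects", mediator_id = nm,
                 beta_total = est_tot@beta, se_total = est_tot@se,
                 p_total = est_tot@pval,
                 beta1 = est1@beta, se1 = est1@se, p1 = est1@pval,
                 beta2 = est2@beta, se2 = est2@se, p2 = est2@pval)
      results[[nm]] <- mediate_result(eff, alpha = config$alpha)
    } else {
      eff <- new("TwoStepEffects", mediator_id = nm,
                 beta_total = est_tot@beta, se_total = est_tot@se,
                 p_total = est_tot@pval,
                 beta1 = est1@beta, se1 = est1@se, p1 = est1@pval,
                 beta2 = NA_real_, se2 = NA_real_, p2 = NA_real_)
      results[[nm]] <- new("MediationResult", effects = eff,
                           indirect = NA_real_, se_indirect = NA_real_,
                           direct = NA_real_, proportion = NA_real_,
                           classification = "none")
    }
  }
  if (config$fdr) {
    p1s <- vapply(results, function(r) r@effects@p1, numeric(1))
    adj <- bhFdr(p1s)
    for (i in seq_along(results))
      if (results[[i]]@classification != "none" && adj[i] >= config$alpha)
        results[[i]]@classification <- "none"
  }
  tab <- mediationTable(results)
  sig <- mediationTable(results, significant_only = TRUE)
  enrichment <- NULL
  if (is.null(gmt) || length(geneSets(gmt)) == 0L) {
    warning("no gene sets supplied: enrichment skipped")
  } else if (nrow(sig)) {
    enrichment <- hypergeomEnrich(sig$mediator, gmt, universe = universe)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(tab, file.path(out_dir, "mediation_full.tsv"))
    write_tsv(sig, file.path(out_dir, "mediation_significant.tsv"))
    if (!is.null(enrichment))
      write_tsv(enrichment, file.path(out_dir, "enrichment.tsv"))
  }
  invisible(list(results = results, table = tab, significant = sig,
                 enrichment = enrichment, total = est_tot))
}

#' Run the whole study on a simulated dataset
#'
#' Generates a synthetic dataset from the configuration, runs the primary
#' MR (exposure -> outcome) and the mediator scan, and writes every report
#' under \code{out_dir}. Identical configuration and seed produce a
#' byte-identical output directory.
#'
#' @param sim_config a \linkS4class{SimulationConfig}.
#' @param config list from \code{runConfig()}.
#' @param gmt optional \linkS4class{GeneSetCollection}.
#' @param out_dir output directory (required).
#' @return invisibly, list(primary, scan, sim).
#' @export
runAll <- function(sim_config = simConfig(), config = runConfig(),
                   gmt = NULL, out_dir) {
  sim <- simulateMediationGwas(sim_config)
  cf <- sim_config@case_fraction
  primary <- runPrimary(sim$exposure, sim$outcome, config,
                        case_fraction = cf,
                        out_dir = file.path(out_dir, "primary"))
  scan <- suppressWarnings(
    runMediationScan(sim$exposure, sim$mediators, sim$outcome, config,
                     gmt = gmt, out_dir = file.path(out_dir, "mediation")))
  invisible(list(primary = primary, scan = scan, sim = sim))
}
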
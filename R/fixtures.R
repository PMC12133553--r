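#' Published two-step mediation worked example
#'
#' The 17 plasma-protein rows of the published serum urate -> plasma
#' protein -> atrial fibrillation mediation report, shipped as a
#' plain-text fixture: total, step-1 and step-2 odds ratios with 95\%
#' confidence intervals and p-values, plus the printed mediation direction,
#' classification and ratio strings. Odds ratios are converted to
#' log-scale effects; standard errors are back-derived from the confidence
#' limits (se = (ln high - ln low) / (2 z_0.975)); censored p-values such
#' as "<0.001" parse to their bound.
#'
#' This is the golden input for the mediation worked-example checks: the
#' printed mediation ratios are recomputable from the printed odds ratios
#' alone.
#'
#' @return list of \linkS4class{TwoStepEffects}, one per mediator, with
#'   attribute "table" holding the parsed fixture data.frame (including
#'   the printed ratio strings).
#' @export
workedExampleEffects <- function() {
  path <- system.file("extdata", "mediation_worked_example.tsv",
                      package = "mrMediate", mustWork = TRUE)
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(nrow(d) == 17L)
  parse_leg <- function(orci, p) {
    v <- parseOrCi(orci)
    list(beta = log(v[1]), se = (log(v[3]) - log(v[2])) / (2 * Z95),
         p = parse_pval(p))
  }
  effects <- lapply(seq_len(nrow(d)), function(i) {
    tot <- parse_leg(d$total[i], d$p_total[i])
    s1 <- parse_leg(d$step1[i], d$p1[i])
    s2 <- parse_leg(d$step2[i], d$p2[i])
    new("TwoStepEffects", mediator_id = d$mediator[i],
        beta_total = tot$beta, se_total = tot$se, p_total = tot$p,
        beta1 = s1$beta, se1 = s1$se, p1 = s1$p,
        beta2 = s2$beta, se2 = s2$se, p2 = s2$p)
  })
  attr(effects, "table") <- d
  effects
}
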
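# Internal numeric helpers shared across modules.

Z95 <- qnorm(0.975)

# two-sided normal p from an estimate and its SE
z_pval <- function(beta, se) {
  out <- rep(NA_real_, length(beta))
  ok <- !is.na(se) & !is.na(beta) & se > 0
  out[ok] <- 2 * pnorm(-abs(beta[ok] / se[ok]))
  out
}

new_estimate <- function(method, beta, se, nsnp, extras = list(),
                         pval = NULL) {
  if (is.null(pval)) pval <- z_pval(beta, se)
  new("MREstimate", method = method, beta = beta, se = se,
      ci_low = beta - Z95 * se, ci_high = beta + Z95 * se,
      pval = pval, nsnp = as.integer(nsnp), extras = extras)
}

new_ledger <- function(steps = NULL) {
  if (is.null(steps))
    steps <- data.frame(step = character(0), n_in = integer(0),
                        n_removed = integer(0), n_out = integer(0),
                        stringsAsFactors = FALSE)
  new("FilterLedger", steps = steps)
}

ledger_add <- function(ledger, step, n_in, n_removed) {
  row <- data.frame(step = step, n_in = as.integer(n_in),
                    n_removed = as.integer(n_removed),
                    n_out = as.integer(n_in - n_removed),
                    stringsAsFactors = FALSE)
  new("FilterLedger", steps = rbind(ledger@steps, row))
}

as_pairs <- function(x) {
  if (is(x, "HarmonizedSet")) return(x@pairs)
  stopifnot(is.data.frame(x))
  x
}

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

# smallest positive double, used to clamp p = 0 inputs
P_FLOOR <- .Machine$double.xmin
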
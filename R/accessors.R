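#' Accessors for mrMediate classes
#'
#' Small accessor layer so user code never touches slots directly.
#'
#' @param x an mrMediate object.
#' @name accessors
NULL

#' @describeIn accessors data.frame of associations in a
#'   \linkS4class{GwasSummary}.
#' @export
gwasData <- function(x) {
  stopifnot(is(x, "GwasSummary"))
  x@data
}

#' @describeIn accessors QC tally of rows dropped at read time.
#' @export
qcTally <- function(x) {
  stopifnot(is(x, "GwasSummary"))
  x@qc
}

#' @describeIn accessors trait identifier of a \linkS4class{GwasSummary}.
#' @export
traitId <- function(x) {
  stopifnot(is(x, "GwasSummary"))
  x@trait
}

#' @describeIn accessors harmonized pairs data.frame of a
#'   \linkS4class{HarmonizedSet}.
#' @export
harmonizedPairs <- function(x) {
  stopifnot(is(x, "HarmonizedSet"))
  x@pairs
}

#' @describeIn accessors filter ledger steps as a data.frame (works for
#'   \linkS4class{FilterLedger} and \linkS4class{HarmonizedSet}).
#' @export
ledgerSteps <- function(x) {
  if (is(x, "HarmonizedSet")) x <- x@ledger
  stopifnot(is(x, "FilterLedger"))
  x@steps
}

#' @describeIn accessors point estimate of an \linkS4class{MREstimate}.
#' @export
mrBeta <- function(x) {
  stopifnot(is(x, "MREstimate"))
  x@beta
}

#' @describeIn accessors standard error of an \linkS4class{MREstimate}.
#' @export
mrSE <- function(x) {
  stopifnot(is(x, "MREstimate"))
  x@se
}

#' @describeIn accessors two-sided p-value of an \linkS4class{MREstimate}.
#' @export
mrPval <- function(x) {
  stopifnot(is(x, "MREstimate"))
  x@pval
}

#' @describeIn accessors 95\% confidence interval c(low, high) of an
#'   \linkS4class{MREstimate}.
#' @export
confInt <- function(x) {
  stopifnot(is(x, "MREstimate"))
  c(x@ci_low, x@ci_high)
}

#' @describeIn accessors number of instruments behind an estimate.
#' @export
nSnp <- function(x) {
  stopifnot(is(x, "MREstimate"))
  x@nsnp
}

#' @describeIn accessors method-specific extras list.
#' @export
mrExtras <- function(x) {
  stopifnot(is(x, "MREstimate"))
  x@extras
}

#' @describeIn accessors named list of member vectors of a
#'   \linkS4class{GeneSetCollection}.
#' @export
geneSets <- function(x) {
  stopifnot(is(x, "GeneSetCollection"))
  x@sets
}

#' @describeIn accessors squared-correlation matrix of an
#'   \linkS4class{LDMatrix}.
#' @export
ldR2 <- function(x) {
  stopifnot(is(x, "LDMatrix"))
  x@r2
}

setMethod("show", "GwasSummary", function(object) {
  cat("GwasSummary for trait '", object@trait, "': ",
      nrow(object@data), " SNPs", sep = "")
  dropped <- sum(object@qc)
  if (dropped) cat(" (", dropped, " rows dropped at QC)", sep = "")
  cat("\n")
})

setMethod("show", "FilterLedger", function(object) {
  cat("FilterLedger with", nrow(object@steps), "steps\n")
  if (nrow(object@steps)) print(object@steps, row.names = FALSE)
})

setMethod("show", "HarmonizedSet", function(object) {
  cat("HarmonizedSet:", nrow(object@pairs), "instruments\n")
})

setMethod("show", "MREstimate", function(object) {
  cat(sprintf("%s: beta = %.4f (SE %.4f), OR %.3f (%.3f ~ %.3f), p = %.3g, nsnp = %d\n",
              object@method, object@beta, object@se, exp(object@beta),
              exp(object@ci_low), exp(object@ci_high), object@pval,
              object@nsnp))
})

setMethod("show", "MREggerResult", function(object) {
  cat("MR-Egger (I2_GX = ", sprintf("%.3f", object@i2gx), ")\n  slope     ",
      sep = "")
  show(object@slope)
  cat("  intercept ")
  show(object@intercept)
})

setMethod("show", "PressoResult", function(object) {
  n_out <- sum(object@outliers$outlier)
  cat(sprintf(
    "MR-PRESSO: global p = %.4g, %d outlier(s); beta %.4f -> %.4f\n",
    object@global_pval, n_out, object@beta_before, object@beta_after))
})

setMethod("show", "SteigerResult", function(object) {
  cat(sprintf(
    "Steiger: R2(exposure) = %.4g, R2(outcome) = %.4g, direction %s (p = %.3g)\n",
    object@r2_exposure, object@r2_outcome,
    if (object@direction_correct) "correct" else "NOT correct",
    object@steiger_pval))
})

setMethod("show", "TwoStepEffects", function(object) {
  cat(sprintf(
    "TwoStepEffects [%s]\n  total  %.4f (p = %.3g)\n  step 1 %.4f (p = %.3g)\n  step 2 %.4f (p = %.3g)\n",
    object@mediator_id, object@beta_total, object@p_total,
    object@beta1, object@p1, object@beta2, object@p2))
})

setMethod("show", "MediationResult", function(object) {
  cat(sprintf(
    "MediationResult [%s]: indirect = %.5f, direct = %.5f, proportion = %.4f, %s\n",
    object@effects@mediator_id, object@indirect, object@direct,
    object@proportion, object@classification))
})

setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection:", length(object@sets), "sets,",
      length(unique(unlist(object@sets))), "distinct genes\n")
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf(
    "SyntheticTruth: %d SNPs, %d mediator(s), theta_total = %.4f (direct %.4f), seed %d\n",
    length(object@snp), length(object@config@beta1),
    object@config@theta_total, object@config@theta_direct,
    object@config@seed))
})
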
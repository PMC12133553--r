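test_that("the indirect effect is the product of coefficients with delta-method SE", {
  z <- indirectEffect(0, 0.1, 0.5, 0.2)
  expect_equal(z$indirect, 0)
  expect_equal(z$se, abs(0.5) * 0.1)

  # worked-example arithmetic oracle: direct multiplication of the log ORs
  ind <- indirectEffect(log(1.154), 0.05, log(1.047), 0.02)
  expect_equal(ind$indirect, log(1.154) * log(1.047))
  expect_equal(ind$indirect, 0.006578, tolerance = 1e-4)

  # both step effects below 1 still give positive mediation
  gk <- indirectEffect(log(0.868), 0.05, log(0.929), 0.03)
  expect_gt(gk$indirect, 0)

  # exact-variance option adds the product term
  a <- indirectEffect(0.1, 0.2, 0.3, 0.4)
  b <- indirectEffect(0.1, 0.2, 0.3, 0.4, exact_variance = TRUE)
  expect_equal(b$se^2 - a$se^2, 0.2^2 * 0.4^2)
})

test_that("the mediation proportion reproduces the printed two-decimal ratios", {
  expect_equal(mediationProportion(1, 1)$rounded, 1)
  expect_error(mediationProportion(0, 0.1), "undefined")

  total <- log(1.045)
  hnf <- mediationProportion(total, log(1.154) * log(1.047))
  expect_equal(hnf$rounded, 0.15)
  expect_equal(hnf$label, "0.15%")
  cpb <- mediationProportion(total, log(1.221) * log(1.082))
  expect_equal(cpb$rounded, 0.36)
  expect_equal(cpb$proportion, 0.015737 / 0.044017, tolerance = 1e-3)
})

test_that("classification follows the two-step significance rule", {
  expect_equal(classifyMediation(0.019, 0.012, 0.012), "partial")
  expect_equal(classifyMediation(0.2, 0.01, 0.01), "complete")
  expect_equal(classifyMediation(0.019, 0.3, 0.01), "none")
  expect_equal(classifyMediation(0.019, 0.01, 0.3), "none")
  expect_equal(classifyMediation(0.2, 0.3, 0.3), "none")
  # boundary: p exactly alpha is not significant
  expect_equal(classifyMediation(0.05, 0.01, 0.01), "complete")
})

test_that("the two-step run recovers the generating effects within 3 SE", {
  cfg <- simConfig(seed = 5)
  sim <- simulateMediationGwas(cfg)
  ts <- runTwoStep(sim$exposure, sim$mediators$PROT1, sim$outcome)
  expect_lt(abs(ts@beta_total - 0.044), 3 * ts@se_total)
  expect_lt(abs(ts@beta1 - 0.143), 3 * ts@se1)
  expect_lt(abs(ts@beta2 - 0.046), 3 * ts@se2)
  expect_error(runTwoStep(sim$exposure, NULL, sim$outcome), "mediator")
})

test_that("a null step-2 mediator rarely reaches significance", {
  hits <- vapply(1:20, function(s) {
    sim <- simulateMediationGwas(simConfig(seed = 300 + s))
    ts <- runTwoStep(sim$exposure, sim$mediators$PROT3, sim$outcome)
    ts@p2 < 0.05
  }, logical(1))
  expect_lte(mean(hits), 0.10)  # beta2 = 0 in truth for PROT3
})

test_that("direct + indirect reproduces the total exactly and the proportion is scale-invariant", {
  eff <- new("TwoStepEffects", mediator_id = "m",
             beta_total = 0.044, se_total = 0.01, p_total = 0.01,
             beta1 = 0.143, se1 = 0.05, p1 = 0.01,
             beta2 = 0.046, se2 = 0.02, p2 = 0.01)
  res <- mrMediate:::mediate_result(eff)
  expect_identical(res@direct + res@indirect, eff@beta_total)
  expect_equal(res@classification, "partial")

  # rescaling the mediator's units leaves the proportion unchanged
  scaled <- new("TwoStepEffects", mediator_id = "m",
                beta_total = 0.044, se_total = 0.01, p_total = 0.01,
                beta1 = 0.143 * 10, se1 = 0.5, p1 = 0.01,
                beta2 = 0.046 / 10, se2 = 0.002, p2 = 0.01)
  res2 <- mrMediate:::mediate_result(scaled)
  expect_equal(res2@proportion, res@proportion, tolerance = 1e-12)
})

test_that("the proportion bootstrap interval is seeded and brackets the estimate", {
  eff <- new("TwoStepEffects", mediator_id = "m",
             beta_total = 0.044, se_total = 0.005, p_total = 0.001,
             beta1 = 0.143, se1 = 0.02, p1 = 0.001,
             beta2 = 0.046, se2 = 0.005, p2 = 0.001)
  ci <- proportionCI(eff, n_boot = 500, seed = 4)
  expect_identical(ci, proportionCI(eff, n_boot = 500, seed = 4))
  prop <- (0.143 * 0.046) / 0.044
  expect_true(ci[1] < prop && prop < ci[2])
})

test_that("OR formatting round-trips and the report table filters and sorts", {
  v <- parseOrCi("1.045(1.007~1.083)")
  expect_equal(v, c(1.045, 1.007, 1.083))
  expect_equal(parseOrCi(formatOrCi(1.045, 1.007, 1.083)), v)
  expect_error(parseOrCi("garbage"), "cannot parse")

  mk <- function(id, p2) {
    eff <- new("TwoStepEffects", mediator_id = id,
               beta_total = 0.044, se_total = 0.01, p_total = 0.019,
               beta1 = 0.143, se1 = 0.05, p1 = 0.012,
               beta2 = 0.046, se2 = 0.02, p2 = p2)
    mrMediate:::mediate_result(eff)
  }
  results <- list(mk("B_PROT", 0.012), mk("A_PROT", 0.5))
  tab <- mediationTable(results)
  expect_equal(tab$mediator, c("A_PROT", "B_PROT"))  # sorted by name
  sig <- mediationTable(results, significant_only = TRUE)
  expect_equal(sig$mediator, "B_PROT")
  expect_equal(sig$classification, "partial")
  expect_match(sig$ratio_label, "^0\\.1[0-9]%$")
})

test_that("the published worked example parses to 17 rows with the printed ORs", {
  we <- workedExampleEffects()
  expect_length(we, 17L)
  ids <- vapply(we, function(e) e@mediator_id, character(1))
  hnf <- we[[which(ids == "Hepatocyte nuclear factor 4-alpha")]]
  expect_equal(exp(hnf@beta_total), 1.045, tolerance = 1e-6)
  gk <- we[[which(ids == "Granzyme K")]]
  expect_equal(exp(gk@beta1), 0.868, tolerance = 1e-6)
  # every printed row is classified partial from its printed p-values
  cls <- vapply(we, function(e)
    classifyMediation(e@p_total, e@p1, e@p2), character(1))
  expect_true(all(cls == "partial"))
})
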
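test_that("the Wald ratio follows the delta method at both orders", {
  p <- make_pairs(bx = 0.1, by = 0.05, sx = 0.02, sy = 0.01)
  e <- waldRatio(p)
  expect_equal(mrBeta(e), 0.5)
  expect_equal(mrSE(e), 0.1)
  # second-order oracle evaluated symbolically: sy^2/bx^2 + by^2 sx^2 / bx^4
  e2 <- waldRatio(p, weighting = "second")
  expect_equal(mrSE(e2), sqrt(0.01^2 / 0.1^2 + 0.05^2 * 0.02^2 / 0.1^4))
  # null outcome effect
  p0 <- make_pairs(bx = 0.1, by = 0, sx = 0.02, sy = 0.01)
  e0 <- waldRatio(p0)
  expect_equal(mrBeta(e0), 0)
  expect_equal(mrPval(e0), 1)
  pz <- make_pairs(bx = 0, by = 0.05)
  expect_error(waldRatio(pz), "zero")
})

test_that("IVW equals the hand-summed weighted mean and delegates at one SNP", {
  # identical ratios: Q = 0, random equals fixed
  same <- make_ratio_pairs(c(0.5, 0.5), c(0.1, 0.1))
  ef <- mrIvw(same, model = "fixed")
  er <- mrIvw(same, model = "random")
  expect_equal(mrBeta(ef), 0.5)
  expect_equal(mrSE(er), mrSE(ef))
  expect_equal(mrExtras(ef)$Q, 0)

  # hand-summed oracle: ratios {0.4, 0.6}, weights {100, 100}
  two <- make_ratio_pairs(c(0.4, 0.6), c(0.1, 0.1))
  e <- mrIvw(two, model = "fixed")
  expect_equal(mrBeta(e), (100 * 0.4 + 100 * 0.6) / 200)
  expect_equal(mrExtras(e)$Q, 100 * 0.01 + 100 * 0.01)  # = 2, brute-force sum
  expect_equal(mrSE(e), sqrt(1 / 200))

  one <- make_pairs(bx = 0.1, by = 0.05, sx = 0.02, sy = 0.01)
  expect_equal(mrBeta(mrIvw(one)), mrBeta(waldRatio(one)))
  expect_equal(mrSE(mrIvw(one)), mrSE(waldRatio(one)))
})

test_that("IVW recovers the generating effect within 3 SE on clean data", {
  cfg <- simConfig(m_snps = 50, beta1 = numeric(0), beta2 = numeric(0),
                   frac_palindromic = 0, seed = 1)
  sim <- simulateMediationGwas(cfg)
  e <- mrIvw(harmonizeEffects(sim$exposure, sim$outcome))
  expect_lt(abs(mrBeta(e) - 0.044), 3 * mrSE(e))
})

test_that("Cochran's Q matches the chi-square oracle", {
  same <- make_ratio_pairs(c(0.5, 0.5, 0.5), c(0.1, 0.1, 0.1))
  q0 <- cochranQ(same)
  expect_equal(q0$Q, 0)
  expect_equal(q0$pval, 1)
  two <- make_ratio_pairs(c(0.4, 0.6), c(0.1, 0.1))
  q <- cochranQ(two)
  expect_equal(q$Q, 2)
  expect_equal(q$df, 1)
  expect_equal(q$pval, pchisq(2, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(q$pval, 0.1573, tolerance = 1e-3)
})

test_that("MR-Egger reproduces an exact linear configuration and floors I2_GX", {
  gx <- c(0.05, 0.1, 0.15, 0.2)
  gy <- 0.01 + 0.5 * gx
  p <- make_pairs(bx = gx, by = gy, sx = rep(0.001, 4), sy = rep(0.01, 4))
  eg <- suppressWarnings(mrEgger(p))
  expect_equal(mrBeta(eg@slope), 0.5, tolerance = 1e-9)
  expect_equal(mrBeta(eg@intercept), 0.01, tolerance = 1e-9)
  expect_equal(mrExtras(eg@slope)$scale, 1)  # exact fit: residual scale floored

  # all exposure effects equal: Q_GX = 0, I2 floored at 0, NOME warning
  pe <- make_pairs(bx = rep(0.1, 4), by = c(0.05, 0.06, 0.05, 0.04),
                   sx = rep(0.001, 4), sy = rep(0.01, 4))
  msgs <- capture_warnings(ege <- mrEgger(pe))
  expect_true(any(grepl("NOME", msgs)))
  expect_equal(ege@i2gx, 0)
  expect_error(mrEgger(make_ratio_pairs(c(0.5, 0.5), c(0.1, 0.1))),
               "at least 3")
})

test_that("Egger recovers implanted directional pleiotropy within 3 SE", {
  cfg <- simConfig(m_snps = 100, beta1 = numeric(0), beta2 = numeric(0),
                   frac_palindromic = 0,
                   pleiotropy = list(type = "directional", mean = 0.02,
                                     sd = 0.005, fraction = 1),
                   seed = 7)
  sim <- simulateMediationGwas(cfg)
  eg <- suppressWarnings(mrEgger(harmonizeEffects(sim$exposure, sim$outcome)))
  expect_lt(abs(mrBeta(eg@intercept) - 0.02), 3 * mrSE(eg@intercept))
})

test_that("the weighted median interpolates the cumulative-weight crossing", {
  eq <- make_ratio_pairs(c(0.1, 0.5, 0.9), c(0.1, 0.1, 0.1))
  expect_equal(mrBeta(weightedMedian(eq, n_boot = 50, seed = 1)), 0.5)

  # brute-force cumulative-weight walk oracle
  walk_oracle <- function(b, w) {
    o <- order(b); b <- b[o]; w <- w[o] / sum(w)
    s <- cumsum(w) - w / 2
    if (s[1] >= 0.5) return(b[1])
    j <- which(s >= 0.5)[1]
    b[j - 1] + (b[j] - b[j - 1]) * (0.5 - s[j - 1]) / (s[j] - s[j - 1])
  }
  ratios <- c(0.5, 5, 5)
  w <- c(0.6, 0.2, 0.2)
  p <- make_ratio_pairs(ratios, 1 / sqrt(w))
  est <- mrBeta(weightedMedian(p, n_boot = 50, seed = 1))
  expect_equal(est, walk_oracle(ratios, w))
  expect_lte(est, 5)  # never beyond the first crossing ratio

  # bootstrap SE is bit-reproducible under a fixed seed
  a <- weightedMedian(p, n_boot = 100, seed = 9)
  b <- weightedMedian(p, n_boot = 100, seed = 9)
  expect_identical(mrSE(a), mrSE(b))
})

test_that("the weighted median resists 49% invalid weight", {
  set.seed(11)
  k <- 51
  bx <- rep(0.1, k); sy <- rep(0.01, k)
  by <- 0.5 * bx
  by[1:25] <- by[1:25] + 0.1 * bx[1:25] * 10  # +1 on the ratio scale
  by <- by + rnorm(k, 0, sy)
  p <- make_pairs(bx, by, sx = rep(0.002, k), sy = sy)
  wm <- weightedMedian(p, n_boot = 500, seed = 11)
  expect_lt(abs(mrBeta(wm) - 0.5), 3 * mrSE(wm))
})

test_that("the mode estimator tracks the majority cluster and degenerates cleanly", {
  p <- make_ratio_pairs(c(0.5, 0.5, 0.5, 5), rep(0.1, 4))
  m <- modeEstimate(p, weighted = FALSE, n_boot = 50, seed = 1)
  expect_lt(abs(mrBeta(m) - 0.5), 0.1)

  pid <- make_ratio_pairs(rep(0.3, 4), rep(0.1, 4))
  mid <- modeEstimate(pid, n_boot = 10, seed = 1)
  expect_equal(mrBeta(mid), 0.3)  # degenerate branch, exact
  expect_equal(mrSE(mid), mrSE(mrIvw(pid, model = "fixed")))

  # bimodal: 70% of weight at 0, 30% at 0.5 -> within one grid step of 0
  set.seed(12)
  k <- 100
  bx <- rep(0.1, k)
  ratios <- c(rep(0, 70), rep(0.5, 30)) + rnorm(k, 0, 0.02)
  pb <- make_pairs(bx, ratios * bx, sx = rep(1e-4, k), sy = rep(0.01, k))
  mb <- modeEstimate(pb, weighted = TRUE, n_boot = 50, seed = 12)
  expect_lt(abs(mrBeta(mb) - 0), mrExtras(mb)$grid_step + 1e-12)
})

test_that("RAPS hits the exact fixed point on clean linear data", {
  gx <- c(0.05, 0.1, 0.15, 0.2, 0.25)
  p <- make_pairs(bx = gx, by = 0.5 * gx, sx = rep(1e-4, 5),
                  sy = rep(0.01, 5))
  e <- mrRaps(p)
  expect_equal(mrBeta(e), 0.5, tolerance = 1e-7)
  expect_equal(mrExtras(e)$tau2, 0)
})

test_that("RAPS outperforms IVW under a gross outlier", {
  set.seed(11)
  k <- 21
  bx <- rnorm(k, 0.1, 0.02); sy <- rep(0.01, k)
  by <- 0.5 * bx + rnorm(k, 0, sy)
  by[1] <- by[1] + 0.5  # gross pleiotropic outlier
  p <- make_pairs(bx, by, sx = rep(1e-4, k), sy = sy)
  err_raps <- abs(mrBeta(mrRaps(p)) - 0.5)
  err_ivw <- abs(mrBeta(mrIvw(p, model = "fixed")) - 0.5)
  expect_lt(err_raps, err_ivw)
})

test_that("all estimators are sign-equivariant in the outcome", {
  set.seed(31)
  k <- 20
  bx <- rnorm(k, 0.1, 0.03)
  by <- 0.3 * bx + rnorm(k, 0, 0.01)
  p <- make_pairs(bx, by, sx = rep(0.002, k), sy = rep(0.01, k))
  pf <- p; pf$beta_out <- -pf$beta_out
  # analytic SEs are identical, point estimates flip exactly
  for (fn in list(function(x) mrIvw(x, model = "fixed"),
                  function(x) mrIvw(x, model = "random"),
                  mrRaps)) {
    a <- fn(p); b <- fn(pf)
    expect_equal(mrBeta(b), -mrBeta(a), tolerance = 1e-8)
    expect_equal(mrSE(b), mrSE(a), tolerance = 1e-8)
  }
  ea <- suppressWarnings(mrEgger(p))
  eb <- suppressWarnings(mrEgger(pf))
  expect_equal(mrBeta(eb@slope), -mrBeta(ea@slope))
  expect_equal(mrBeta(eb@intercept), -mrBeta(ea@intercept))
  expect_equal(mrSE(eb@slope), mrSE(ea@slope))
  # bootstrap-based estimators flip their point estimates exactly
  expect_equal(mrBeta(weightedMedian(pf, n_boot = 10, seed = 1)),
               -mrBeta(weightedMedian(p, n_boot = 10, seed = 1)))
})

test_that("the multi-SNP estimators agree on pleiotropy-free data", {
  cfg <- simConfig(m_snps = 80, beta1 = numeric(0), beta2 = numeric(0),
                   frac_palindromic = 0, seed = 13)
  sim <- simulateMediationGwas(cfg)
  hs <- harmonizeEffects(sim$exposure, sim$outcome)
  ests <- list(mrIvw(hs, model = "random"),
               suppressWarnings(mrEgger(hs))@slope,
               weightedMedian(hs, n_boot = 200, seed = 13),
               modeEstimate(hs, n_boot = 200, seed = 13),
               mrRaps(hs))
  for (i in 1:4) for (j in (i + 1):5) {
    a <- ests[[i]]; b <- ests[[j]]
    expect_lt(abs(mrBeta(a) - mrBeta(b)),
              3 * sqrt(mrSE(a)^2 + mrSE(b)^2))
  }
})
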
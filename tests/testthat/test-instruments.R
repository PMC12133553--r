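test_that("p-value filtering is strict and order-preserving", {
  df <- gwas_df(2, pval = c(1e-9, 1e-7))
  gs <- readGwasTable(write_gwas_file(df), trait_id = "x")
  kept <- gwasData(filterByPvalue(gs, 5e-8))
  expect_equal(kept$snp, "rs1")
  df2 <- gwas_df(1, pval = 4.9e-8)
  gs2 <- readGwasTable(write_gwas_file(df2), trait_id = "x")
  expect_equal(nrow(gwasData(filterByPvalue(gs2, 5e-8))), 1L)

  set.seed(7)
  p <- runif(1000)
  d <- gwas_df(1000, pval = p)
  gs3 <- readGwasTable(write_gwas_file(d), trait_id = "x")
  # oracle: direct enumeration over the simulated vector
  expect_equal(nrow(gwasData(filterByPvalue(gs3, 1e-5))), sum(p < 1e-5))
})

test_that("greedy clumping keeps the best SNP per window and is order-invariant", {
  d <- gwas_df(2, pos = c(1e6, 1e6 + 5000), pval = c(1e-10, 1e-9))
  ld <- new("LDMatrix",
            r2 = matrix(c(1, 0.9, 0.9, 1), 2,
                        dimnames = list(c("rs1", "rs2"), c("rs1", "rs2"))))
  gs <- readGwasTable(write_gwas_file(d), trait_id = "x")
  out <- clumpInstruments(gs, ld = ld)
  expect_equal(gwasData(out)$snp, "rs1")

  # different chromosomes, no r2 entry: both kept
  d2 <- gwas_df(2, chr = c("1", "2"), pos = c(1e6, 1e6), pval = c(1e-10, 1e-9))
  gs2 <- readGwasTable(write_gwas_file(d2), trait_id = "x")
  empty_ld <- new("LDMatrix", r2 = matrix(1, 1, 1, dimnames = list("rsX", "rsX")))
  expect_equal(nrow(gwasData(clumpInstruments(gs2, ld = empty_ld))), 2L)

  # 10 SNPs, all pairwise r2 = 1, one window: exactly the minimum-p SNP
  set.seed(5)
  p10 <- runif(10, 1e-12, 1e-8)
  d10 <- gwas_df(10, pos = 1e6 + (0:9) * 1000, pval = p10)
  ids <- d10$SNP
  ld10 <- new("LDMatrix",
              r2 = matrix(1, 10, 10, dimnames = list(ids, ids)))
  gs10 <- readGwasTable(write_gwas_file(d10), trait_id = "x")
  out10 <- clumpInstruments(gs10, ld = ld10)
  expect_equal(gwasData(out10)$snp, ids[which.min(p10)])

  # order invariance: shuffled input gives the identical result
  shuf <- d10[sample(10), ]
  gs_s <- readGwasTable(write_gwas_file(shuf), trait_id = "x")
  expect_identical(gwasData(clumpInstruments(gs_s, ld = ld10)),
                   gwasData(out10))

  # distance-only fallback messages and prunes within the window
  expect_message(out_d <- clumpInstruments(gs10), "distance-only")
  expect_equal(nrow(gwasData(out_d)), 1L)
})

test_that("the F statistic and the weak-instrument filter follow (beta/se)^2 with inclusive cutoff", {
  expect_equal(fStatistic(0.1, 0.02), 25)
  expect_equal(fStatistic(0.02, 0.01), 4)
  hs <- new("HarmonizedSet",
            pairs = make_pairs(bx = c(0.1, 0.02, 0.1 * sqrt(10) / 5),
                               by = c(0.05, 0.01, 0.05),
                               sx = c(0.02, 0.01, 0.02)),
            ledger = new("FilterLedger",
                         steps = data.frame(step = "in", n_in = 3L,
                                            n_removed = 0L, n_out = 3L)))
  hs@pairs$f_stat <- (hs@pairs$beta_exp / hs@pairs$se_exp)^2
  expect_equal(hs@pairs$f_stat, c(25, 4, 10))
  out <- filterWeak(hs, 10)
  expect_equal(harmonizedPairs(out)$f_stat, c(25, 10))  # F = 10 kept
  # exact form when eaf and n are present
  expect_equal(fStatistic(0.1, NA, eaf = 0.3, n = 1000, exact = TRUE),
               998 * (2 * 0.3 * 0.7 * 0.01) / (1 - 2 * 0.3 * 0.7 * 0.01))
})

test_that("harmonization flips strands and signs, removes palindromes and ambiguities", {
  exp_df <- gwas_df(4, ea = c("A", "A", "A", "A"), oa = c("G", "T", "G", "G"),
                    beta = 0.1)
  out_df <- gwas_df(4, ea = c("G", "A", "A", "A"), oa = c("A", "T", "C", "G"),
                    beta = 0.05)
  ex <- readGwasTable(write_gwas_file(exp_df), trait_id = "e")
  ou <- readGwasTable(write_gwas_file(out_df), trait_id = "o")
  hs <- harmonizeEffects(ex, ou)
  p <- harmonizedPairs(hs)
  # rs1: EA/OA swapped -> sign flip; rs2 palindromic; rs3 ambiguous; rs4 aligned
  expect_equal(p$snp, c("rs1", "rs4"))
  expect_equal(p$beta_out, c(-0.05, 0.05))
  steps <- ledgerSteps(hs)
  expect_equal(steps$n_removed[steps$step == "palindromic"], 1L)
  expect_equal(steps$n_removed[steps$step == "ambiguous"], 1L)
  # ledger telescopes
  expect_equal(steps$n_out[-nrow(steps)], steps$n_in[-1])
})

test_that("strand-complement alleles harmonize without loss", {
  exp_df <- gwas_df(1, ea = "A", oa = "G", beta = 0.1)
  out_df <- gwas_df(1, ea = "T", oa = "C", beta = 0.05)  # complement, aligned
  hs <- harmonizeEffects(readGwasTable(write_gwas_file(exp_df), trait_id = "e"),
                         readGwasTable(write_gwas_file(out_df), trait_id = "o"))
  expect_equal(harmonizedPairs(hs)$beta_out, 0.05)
})

test_that("harmonization is idempotent and rejects duplicate ids", {
  sim <- simulateMediationGwas(simConfig(m_snps = 40, seed = 21))
  hs <- harmonizeEffects(sim$exposure, sim$outcome)
  p <- harmonizedPairs(hs)
  back_exp <- data.frame(snp = p$snp, chrom = p$chrom, pos = p$pos,
                         ea = p$ea, oa = p$oa, eaf = p$eaf_exp,
                         beta = p$beta_exp, se = p$se_exp,
                         pval = p$pval_exp, n = p$n_exp)
  back_out <- transform(back_exp, beta = p$beta_out, se = p$se_out,
                        pval = p$pval_out, eaf = p$eaf_out, n = p$n_out)
  hs2 <- harmonizeEffects(back_exp, back_out)
  expect_equal(harmonizedPairs(hs2)$beta_out, p$beta_out)
  expect_equal(harmonizedPairs(hs2)$beta_exp, p$beta_exp)
  expect_equal(sum(ledgerSteps(hs2)$n_removed), 0L)

  dup <- rbind(back_exp, back_exp[1, ])
  expect_error(harmonizeEffects(dup, back_out), back_exp$snp[1])
})

test_that("the confounder blacklist removes matching SNPs with a ledger entry", {
  sim <- simulateMediationGwas(simConfig(m_snps = 30, frac_palindromic = 0,
                                         seed = 8))
  hs <- harmonizeEffects(sim$exposure, sim$outcome)
  ids <- harmonizedPairs(hs)$snp
  k <- length(ids)
  bl <- data.frame(snp = ids[1:3],
                   trait = c("Body Mass Index", "smoking status", "BMI adj"),
                   stringsAsFactors = FALSE)
  out <- removeBlacklisted(hs, bl, c("body mass", "smoking"))
  expect_equal(nrow(harmonizedPairs(out)), k - 2L)
  steps <- ledgerSteps(out)
  expect_equal(steps$n_removed[steps$step == "confounder_blacklist"], 2L)
  # empty blacklist is the identity
  out2 <- removeBlacklisted(hs, NULL, c("body mass"))
  expect_equal(nrow(harmonizedPairs(out2)), k)
})

test_that("the outcome Bonferroni screen removes exactly the implanted associations", {
  # threshold arithmetic: k = 10, alpha 0.05 -> cut at 0.005
  hs <- new("HarmonizedSet",
            pairs = local({
              p <- make_pairs(bx = rep(0.1, 10), by = rep(0.05, 10))
              p$pval_out <- c(0.004, 0.006, rep(0.5, 8))
              p
            }),
            ledger = new_ledger_for_test(10))
  out <- removeOutcomeAssociated(hs, 0.05)
  expect_false("rs001" %in% harmonizedPairs(out)$snp)
  expect_true("rs002" %in% harmonizedPairs(out)$snp)

  # 100 pairs, 5 implanted at p = 1e-6, Bonferroni keeps the rest
  pr <- make_pairs(bx = rep(0.1, 100), by = rep(0.05, 100))
  pr$pval_out <- 0.5
  implanted <- c(3, 17, 42, 77, 98)
  pr$pval_out[implanted] <- 1e-6
  hs2 <- new("HarmonizedSet", pairs = pr, ledger = new_ledger_for_test(100))
  out2 <- removeOutcomeAssociated(hs2, 0.05)
  expect_equal(setdiff(pr$snp, harmonizedPairs(out2)$snp),
               pr$snp[implanted])
})
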
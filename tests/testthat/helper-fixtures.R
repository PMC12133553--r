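# Shared fixture builders: everything is generated in code, no files.

# minimal harmonized-pairs data.frame for estimator/diagnostic tests
make_pairs <- function(bx, by, sx = rep(0.001, length(bx)),
                       sy = rep(0.01, length(bx))) {
  k <- length(bx)
  data.frame(snp = sprintf("rs%03d", seq_len(k)),
             chrom = rep("1", k), pos = seq_len(k) * 1e6,
             ea = rep("A", k), oa = rep("G", k),
             beta_exp = bx, se_exp = sx, pval_exp = z_p(bx, sx),
             eaf_exp = rep(0.3, k), n_exp = rep(1e5, k),
             beta_out = by, se_out = sy, pval_out = z_p(by, sy),
             eaf_out = rep(0.3, k), n_out = rep(1e5, k),
             f_stat = (bx / sx)^2,
             stringsAsFactors = FALSE)
}

z_p <- function(beta, se) pmin(1, pmax(2 * pnorm(-abs(beta / se)),
                                       .Machine$double.xmin))

new_ledger_for_test <- function(n) {
  new("FilterLedger",
      steps = data.frame(step = "input", n_in = as.integer(n),
                         n_removed = 0L, n_out = as.integer(n)))
}

# pairs yielding exactly the requested ratio estimates and weights:
# beta_exp = 1 makes ratio = beta_out and ratio SE = se_out
make_ratio_pairs <- function(ratios, ratio_se) {
  make_pairs(bx = rep(1, length(ratios)), by = ratios,
             sx = rep(1e-6, length(ratios)), sy = ratio_se)
}

# write a small GWAS table file in the package dialect
write_gwas_file <- function(df, path = tempfile(fileext = ".tsv")) {
  names(df) <- toupper(names(df))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

gwas_df <- function(n = 3, snp = sprintf("rs%d", seq_len(n)),
                    chr = "1", pos = seq_len(n) * 1e6,
                    ea = "A", oa = "G", eaf = 0.3,
                    beta = NULL, se = 0.02, pval = NULL, nsamp = 1e5) {
  # keep beta/se and pval z-consistent whichever is supplied
  if (is.null(beta) && is.null(pval)) beta <- 0.1
  if (is.null(pval)) pval <- z_p(beta, se)
  if (is.null(beta)) beta <- -qnorm(pmax(pval, 1e-320) / 2) * se
  data.frame(SNP = snp, CHR = chr, POS = pos, EA = ea, OA = oa,
             EAF = eaf, BETA = beta, SE = se, PVAL = pval, N = nsamp,
             stringsAsFactors = FALSE)
}
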
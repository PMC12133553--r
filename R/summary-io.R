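#' Default column mapping for GWAS summary tables
#'
#' Maps the internal field names to the header names of the package's own
#' tab-separated dialect (SNP/CHR/POS/EA/OA/EAF/BETA/SE/PVAL/N). Column
#' mapping is explicit configuration, never sniffed from the file.
#'
#' @return named character vector: internal name -> file header name.
#' @export
defaultColumnMap <- function() {
  c(snp = "SNP", chrom = "CHR", pos = "POS", ea = "EA", oa = "OA",
    eaf = "EAF", beta = "BETA", se = "SE", pval = "PVAL", n = "N")
}

#' Read a GWAS summary-statistic table
#'
#' Reads a delimited summary-statistic file (gzip-transparent), upper-cases
#' alleles, imputes missing p-values from the normal approximation of the
#' z statistic, clamps p = 0 to the smallest positive double (with a
#' warning), drops rows violating the record invariants and tallies each
#' drop reason. The input rows always partition into retained rows plus the
#' QC tallies.
#'
#' @param path file path (plain or .gz).
#' @param column_map named character vector mapping internal field names
#'   (snp, chrom, pos, ea, oa, eaf, beta, se, pval, n) to file headers;
#'   defaults to \code{defaultColumnMap()}. eaf may be omitted from the map.
#' @param trait_id trait identifier attached to every record.
#' @param z_p_tol tolerance for the warning-level consistency check between
#'   |beta/se| and the stated p-value (on the z scale).
#' @return a \linkS4class{GwasSummary}.
#' @export
readGwasTable <- function(path, column_map = defaultColumnMap(),
                          trait_id, z_p_tol = 0.5) {
  if (!file.exists(path)) stop("file not found: ", path)
  # read as character so allele columns of all T are not parsed as logical
  raw <- read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character")
  if (nrow(raw) == 0L) stop("empty input: ", path, " contains no data rows")
  mandatory <- c("snp", "ea", "oa", "beta", "se", "n")
  for (field in mandatory) {
    if (!field %in% names(column_map))
      stop("column_map lacks mandatory field '", field, "'")
    if (!column_map[[field]] %in% names(raw))
      stop("missing mandatory column '", column_map[[field]],
           "' (field ", field, ") in ", path)
  }
  pull <- function(field, default = NA) {
    if (field %in% names(column_map) && column_map[[field]] %in% names(raw))
      raw[[column_map[[field]]]]
    else rep(default, nrow(raw))
  }
  d <- data.frame(
    snp = as.character(pull("snp")),
    chrom = as.character(pull("chrom", NA_character_)),
    pos = suppressWarnings(as.integer(pull("pos", NA_integer_))),
    ea = toupper(as.character(pull("ea"))),
    oa = toupper(as.character(pull("oa"))),
    eaf = suppressWarnings(as.numeric(pull("eaf", NA_real_))),
    beta = suppressWarnings(as.numeric(pull("beta"))),
    se = suppressWarnings(as.numeric(pull("se"))),
    pval = suppressWarnings(as.numeric(pull("pval", NA_real_))),
    n = suppressWarnings(as.numeric(pull("n"))),
    stringsAsFactors = FALSE)

  qc <- c(bad_allele = 0L, nonpositive_se = 0L, bad_pval = 0L,
          nonpositive_n = 0L, missing_beta = 0L, bad_eaf = 0L)
  drop <- rep(FALSE, nrow(d))
  mark <- function(bad, reason) {
    bad <- bad & !drop
    qc[[reason]] <<- qc[[reason]] + sum(bad)
    drop <<- drop | bad
  }
  valid_allele <- d$ea %in% names(COMPLEMENT) & d$oa %in% names(COMPLEMENT)
  mark(!valid_allele | d$ea == d$oa, "bad_allele")
  mark(is.na(d$beta) | is.na(d$se), "missing_beta")
  mark(!is.na(d$se) & d$se <= 0, "nonpositive_se")
  mark(is.na(d$n) | d$n <= 0, "nonpositive_n")
  mark(!is.na(d$eaf) & (d$eaf < 0 | d$eaf > 1), "bad_eaf")

  # p-value repair before the validity check: clamp 0, impute missing
  zero_p <- !drop & !is.na(d$pval) & d$pval == 0
  if (any(zero_p)) {
    warning(sum(zero_p), " p-value(s) of 0 clamped to the smallest ",
            "positive double")
    d$pval[zero_p] <- P_FLOOR
  }
  imp <- !drop & is.na(d$pval)
  d$pval[imp] <- z_pval(d$beta[imp], d$se[imp])
  mark(!is.na(d$pval) & (d$pval <= 0 | d$pval > 1), "bad_pval")

  keep <- d[!drop, , drop = FALSE]
  row.names(keep) <- NULL
  if (nrow(keep)) {
    z_stated <- abs(qnorm(pmax(keep$pval, P_FLOOR) / 2))
    z_obs <- abs(keep$beta / keep$se)
    incons <- is.finite(z_stated) & abs(z_obs - z_stated) > z_p_tol &
      keep$pval > 1e-300
    if (any(incons))
      warning(sum(incons), " row(s) have |beta/se| inconsistent with the ",
              "stated p-value beyond tolerance ", z_p_tol)
  }
  new("GwasSummary", data = keep, trait = trait_id, qc = qc)
}

#' Write a GWAS summary table in the package dialect
#'
#' Tab-separated with the \code{defaultColumnMap()} headers; reading the
#' result back reproduces all retained fields.
#'
#' @param x a \linkS4class{GwasSummary}.
#' @param path output path; a ".gz" suffix writes gzip.
#' @return invisibly, the path.
#' @export
writeGwasTable <- function(x, path) {
  stopifnot(is(x, "GwasSummary"))
  d <- x@data
  out <- d[, GWAS_COLUMNS]
  names(out) <- defaultColumnMap()[GWAS_COLUMNS]
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(format(out, digits = 17, trim = TRUE, scientific = NA),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square LD matrix with SNP-id headers
#'
#' Whitespace-delimited square matrix of squared correlations with SNP ids
#' as the first row and first column (compatible with common LD-calculator
#' square outputs).
#'
#' @param path file path.
#' @return an \linkS4class{LDMatrix}.
#' @export
readLdMatrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.table(path, header = TRUE, row.names = 1,
                    check.names = FALSE)
  m <- as.matrix(raw)
  if (nrow(m) != ncol(m))
    stop("LD matrix must be square, got ", nrow(m), " x ", ncol(m))
  if (!identical(rownames(m), colnames(m)))
    stop("LD matrix row and column SNP ids disagree")
  if (any(m < 0 | m > 1)) stop("LD r2 values outside [0, 1]")
  if (any(abs(diag(m) - 1) > 1e-8))
    stop("LD matrix diagonal must be exactly 1")
  if (any(abs(m - t(m)) > 1e-6))
    stop("LD matrix asymmetric beyond tolerance 1e-6")
  new("LDMatrix", r2 = m)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated fields name, description,
#' then member symbols. Members are upper-cased and deduplicated.
#'
#' @param path file path.
#' @return a \linkS4class{GeneSetCollection}.
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  descs <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop("GMT format error at line ", i,
           ": expected name, description and at least one member")
    members <- unique(toupper(trimws(fields[-(1:2)])))
    members <- members[nzchar(members)]
    if (!length(members))
      stop("GMT format error at line ", i, ": no non-empty members")
    sets[[fields[[1]]]] <- members
    descs <- c(descs, fields[[2]])
  }
  new("GeneSetCollection", sets = sets, descriptions = descs)
}

#' Read a confounder-annotation blacklist
#'
#' Two-column TSV (SNP id, annotated trait string), one annotation per
#' line; a SNP may appear on several lines. Serves as the local surrogate
#' for look-ups of instrument associations with confounding traits.
#'
#' @param path file path.
#' @return data.frame with columns snp, trait.
#' @export
readBlacklist <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- read.delim(path, header = FALSE, sep = "\t",
                  stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop("blacklist must have two tab-separated columns")
  data.frame(snp = as.character(d[[1]]), trait = as.character(d[[2]]),
             stringsAsFactors = FALSE)
}
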
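# File interfaces. All tabular formats are plain text: weight panels and LD
# as TSV, dosage matrices as TSV (NA = missing), phenotypes and results as
# CSV, genotypes alternatively as VCF with hard GT calls (via vcfR).

stop_schema <- function(path, missing_cols) {
  stop(basename(path), " is missing required column(s): ",
       paste(missing_cols, collapse = ", "), call. = FALSE)
}

#' Read a SNP weight panel from TSV
#'
#' Expects a tab-separated file with header columns `rsid`, `chrom`, `pos`,
#' `effect_allele`, `other_allele`, `weight`, `trait`.
#'
#' @param path file path.
#' @return A [snp_panel()].
#' @export
read_weight_panel <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
            "weight", "trait")
  if (length(setdiff(need, names(x)))) stop_schema(path, setdiff(need, names(x)))
  bad <- which(!is.finite(suppressWarnings(as.numeric(x$weight))))
  if (length(bad))
    stop(basename(path), ": non-numeric weight at line(s) ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  snp_panel(x$rsid, x$chrom, x$pos, x$effect_allele, x$other_allele,
            as.numeric(x$weight), trait = x$trait[1L])
}

#' @rdname read_weight_panel
#' @param panel a `snp_panel` to write.
#' @export
write_weight_panel <- function(panel, path) {
  utils::write.table(as.data.frame(panel), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a genotype dosage matrix from TSV
#'
#' Expects individuals in rows (first column `id`) and SNPs in columns
#' (header = rsids), with hard-call dosages 0/1/2 and `NA` for missing.
#' Because this dialect carries no allele labels, a weight panel must be
#' supplied; the counts are taken to be of the panel's effect alleles.
#'
#' @param path file path.
#' @param panel `snp_panel` providing the allele labels per rsid.
#' @return A [dosage_matrix()].
#' @export
read_dosage_tsv <- function(path, panel) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"id" %in% names(x)) stop_schema(path, "id")
  ids <- as.character(x$id)
  m <- as.matrix(x[setdiff(names(x), "id")])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  i <- match(colnames(m), panel$rsid)
  if (anyNA(i))
    stop(basename(path), ": rsid(s) not in panel: ",
         paste(colnames(m)[is.na(i)], collapse = ", "), call. = FALSE)
  dosage_matrix(m, panel$effect_allele[i], panel$other_allele[i])
}

#' @rdname read_dosage_tsv
#' @param x a `dosage_matrix` to write.
#' @export
write_dosage_tsv <- function(x, path) {
  out <- data.frame(id = rownames(x$dosage), x$dosage, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read hard-called genotype dosages from a VCF
#'
#' Parses the GT field of a VCF (hard calls only; any fractional or
#' half-missing call is rejected) into a dosage matrix counting the ALT
#' allele, with REF/ALT as the allele labels. Use [align_dosages()] to
#' orient the counts to a panel's effect alleles.
#'
#' @param path VCF file path (uncompressed or bgzipped).
#' @return A [dosage_matrix()] counting ALT alleles.
#' @export
read_vcf_dosages <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  rsid <- fix[, "ID"]
  rsid[is.na(rsid) | rsid == "."] <- paste0(fix[, "CHROM"], ":",
                                            fix[, "POS"])[is.na(rsid) | rsid == "."]
  count_alt <- function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
    al <- strsplit(g, "[/|]")[[1L]]
    if (any(al == ".")) return(NA_real_)
    sum(al != "0")
  }
  d <- matrix(vapply(gt, count_alt, numeric(1)), nrow(gt), ncol(gt))
  d <- t(d)                                  # individuals x SNPs
  dimnames(d) <- list(colnames(gt), rsid)
  if (any(!is.na(d) & d > 2))
    stop(basename(path), ": multi-allelic genotypes are not supported",
         call. = FALSE)
  dosage_matrix(d, counted_allele = fix[, "ALT"], other_allele = fix[, "REF"])
}

#' Read a cohort phenotype table from CSV
#'
#' Validates the presence and basic sanity of the phenotype columns used by
#' the endpoint and association stack: `id`, `sex`, `age_b`, `cac_b`,
#' `cac_5y`, `t_years` are required; risk-factor columns are optional.
#'
#' @param path file path.
#' @return Data frame of phenotypes.
#' @export
read_phenotypes <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "sex", "age_b", "cac_b", "cac_5y", "t_years")
  if (length(setdiff(need, names(x)))) stop_schema(path, setdiff(need, names(x)))
  bad <- which(!x$sex %in% c("female", "male") & !is.na(x$sex))
  if (length(bad))
    stop(basename(path), ": sex must be 'female'/'male'; offending line(s) ",
         paste(utils::head(bad + 1L, 5L), collapse = ", "), call. = FALSE)
  for (col in c("cac_b", "cac_5y"))
    if (any(x[[col]] < 0, na.rm = TRUE))
      stop(basename(path), ": negative ", col, " value(s)", call. = FALSE)
  if (any(x$t_years <= 0, na.rm = TRUE))
    stop(basename(path), ": non-positive inter-scan time(s)", call. = FALSE)
  if ("smoking" %in% names(x))
    x$smoking <- factor(x$smoking, levels = c("never", "past", "current"))
  x
}

#' @rdname read_phenotypes
#' @param cohort phenotype data frame to write.
#' @export
write_phenotypes <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a long-format LD table
#'
#' Expects TSV columns `rsid_a`, `rsid_b`, `r2`, `d_prime`; pairs may appear
#' in either order. Pairs not listed are unknown (`NA`) and raise an error
#' if LD pruning needs them.
#'
#' @param path file path.
#' @param rsids optional rsids fixing the matrix order (defaults to the
#'   rsids appearing in the file).
#' @return An [ld_matrix()].
#' @export
read_ld <- function(path, rsids = NULL) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("rsid_a", "rsid_b", "r2", "d_prime")
  if (length(setdiff(need, names(x)))) stop_schema(path, setdiff(need, names(x)))
  if (is.null(rsids)) rsids <- unique(c(x$rsid_a, x$rsid_b))
  n <- length(rsids)
  r2 <- dp <- matrix(NA_real_, n, n, dimnames = list(rsids, rsids))
  diag(r2) <- diag(dp) <- 1
  ia <- match(x$rsid_a, rsids); ib <- match(x$rsid_b, rsids)
  if (anyNA(ia) || anyNA(ib))
    stop(basename(path), ": rsid(s) outside the requested set", call. = FALSE)
  r2[cbind(ia, ib)] <- r2[cbind(ib, ia)] <- x$r2
  dp[cbind(ia, ib)] <- dp[cbind(ib, ia)] <- x$d_prime
  ld_matrix(rsids, r2, dp)
}

#' @rdname read_ld
#' @param ld an `ld_matrix` to write (upper triangle, long format).
#' @export
write_ld <- function(ld, path) {
  n <- length(ld$rsids)
  idx <- which(upper.tri(ld$r2) & !is.na(ld$r2), arr.ind = TRUE)
  out <- data.frame(rsid_a = ld$rsids[idx[, 1]], rsid_b = ld$rsids[idx[, 2]],
                    r2 = ld$r2[idx], d_prime = ld$d_prime[idx])
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write genetic risk scores to CSV
#'
#' @param grs a `grs` object.
#' @param path file path.
#' @export
write_grs <- function(grs, path) {
  utils::write.csv(as.data.frame(grs), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write endpoint results to CSV
#'
#' @param endpoints output of [cac_endpoints()].
#' @param path file path.
#' @export
write_endpoints <- function(endpoints, path) {
  utils::write.csv(as.data.frame(endpoints), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Tabulate association fits in the layout of a results table
#'
#' Renders one or more fitted models as a results table: one row per model
#' term with the percent-scale effect, 95% interval, p-value, and the
#' incremental explained variance (delta R-squared, present only for the
#' exposure terms). Exposure rows with p below the Bonferroni threshold for
#' `m_tests` primary tests are marked significant.
#'
#' @param fits a named list of `cac_assoc` fits (names become model labels),
#'   or a single fit.
#' @param m_tests number of primary tests for the Bonferroni threshold
#'   (default 11).
#' @param alpha family-wise level (default 0.05).
#' @param file optional path; when given, the table is also written as CSV
#'   (`file`) and Markdown (`file` with extension `.md`).
#' @return Data frame with columns `model`, `term`, `pct_effect`,
#'   `pct_ci_low`, `pct_ci_high`, `p`, `delta_r2`, `bonferroni_significant`.
#' @export
assoc_report <- function(fits, m_tests = 11, alpha = 0.05, file = NULL) {
  if (inherits(fits, "cac_assoc")) fits <- list(model = fits)
  thr <- bonferroni_threshold(alpha, m_tests)$threshold
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    tab <- f$terms[f$terms$term != "(Intercept)", , drop = FALSE]
    data.frame(model = nm, term = tab$term,
               pct_effect = round(tab$pct_effect, 1),
               pct_ci_low = round(tab$pct_ci_low, 1),
               pct_ci_high = round(tab$pct_ci_high, 1),
               p = signif(tab$p, 2),
               delta_r2 = round(tab$delta_r2, 1),
               bonferroni_significant = tab$term %in% f$exposure_cols &
                 tab$p < thr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(file)) {
    utils::write.csv(out, file, row.names = FALSE, quote = FALSE, na = "")
    md <- c(paste("|", paste(names(out), collapse = " | "), "|"),
            paste("|", paste(rep("---", ncol(out)), collapse = " | "), "|"),
            apply(out, 1L, function(r)
              paste("|", paste(ifelse(is.na(r), "", r), collapse = " | "), "|")))
    writeLines(md, sub("\\.[^.]*$", ".md", file))
  }
  out
}

#' Build a run manifest for reproducibility
#'
#' Records the seed, input-file digests and per-stage row counts of a
#' pipeline run; re-running with an identical manifest reproduces identical
#' outputs because all randomness is funnelled through the recorded seed.
#'
#' @param seed the run seed.
#' @param inputs character vector of input file paths (digested with MD5).
#' @param counts named list/vector of per-stage row counts or an exclusion
#'   log.
#' @return List of class `run_manifest`.
#' @export
run_manifest <- function(seed, inputs = character(0), counts = list()) {
  structure(list(seed = seed,
                 version = as.character(utils::packageVersion("cacprog")),
                 inputs = if (length(inputs))
                   data.frame(path = inputs,
                              md5 = unname(tools::md5sum(inputs)),
                              stringsAsFactors = FALSE)
                 else data.frame(path = character(0), md5 = character(0)),
                 counts = counts),
            class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Run manifest: seed", x$seed, "- cacprog", x$version, "\n")
  if (nrow(x$inputs)) {
    cat("inputs:\n")
    for (i in seq_len(nrow(x$inputs)))
      cat(" ", x$inputs$path[i], x$inputs$md5[i], "\n")
  }
  if (length(x$counts)) utils::str(x$counts, give.attr = FALSE)
  invisible(x)
}
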
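#' Genotype dosage matrices
#'
#' A dosage matrix holds hard-called counts of a counted allele (0, 1, 2, or
#' `NA` for missing) for individuals (rows) by SNPs (columns), together with
#' the allele labels the counts refer to. Fractional dosages are rejected at
#' construction: upstream hard-calling is assumed, and the only fractional
#' values ever present are those created by [impute_missing()].
#'
#' @param dosage numeric matrix (individuals x SNPs) with values in
#'   \{0, 1, 2\} or `NA`; rownames are individual ids, colnames are rsids.
#' @param counted_allele per-SNP allele whose copies `dosage` counts.
#' @param other_allele per-SNP other allele.
#' @param imputed logical; `TRUE` only for matrices produced by
#'   [impute_missing()], which may contain fractional expected dosages.
#' @return An object of class `dosage_matrix`.
#' @export
dosage_matrix <- function(dosage, counted_allele, other_allele,
                          imputed = FALSE) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("ind", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage)))
    stop("dosage matrix must carry rsids as column names", call. = FALSE)
  stopifnot(length(counted_allele) == ncol(dosage),
            length(other_allele) == ncol(dosage))
  v <- dosage[!is.na(dosage)]
  if (any(v < 0 | v > 2))
    stop("dosages must lie in [0, 2]", call. = FALSE)
  if (!imputed && any(v != round(v)))
    stop("fractional dosages found; only hard calls (0/1/2) are accepted ",
         "at ingest", call. = FALSE)
  structure(list(dosage = dosage,
                 counted_allele = toupper(as.character(counted_allele)),
                 other_allele = toupper(as.character(other_allele)),
                 imputed = isTRUE(imputed)),
            class = "dosage_matrix")
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat(sprintf("Genotype dosage matrix: %d individual(s) x %d SNP(s); %d missing entr%s%s\n",
              nrow(x$dosage), ncol(x$dosage), sum(is.na(x$dosage)),
              if (sum(is.na(x$dosage)) == 1L) "y" else "ies",
              if (x$imputed) " (missing entries imputed)" else ""))
  invisible(x)
}

#' @export
dim.dosage_matrix <- function(x) dim(x$dosage)

#' Per-SNP counted-allele frequency
#'
#' The sample frequency of the counted allele at each SNP, computed from
#' non-missing entries: sum of dosages over twice the number of non-missing
#' individuals.
#'
#' @param x a `dosage_matrix`.
#' @return Named numeric vector of frequencies in \[0, 1\]; `NaN` for a SNP
#'   with no non-missing entries.
#' @export
effect_allele_freq <- function(x) {
  stopifnot(inherits(x, "dosage_matrix"))
  colSums(x$dosage, na.rm = TRUE) / (2 * colSums(!is.na(x$dosage)))
}

is_strand_ambiguous <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
  (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

complement_allele <- function(a) {
  chartr("ACGT", "TGCA", a)
}

#' Orient genotype dosages to a panel's effect alleles
#'
#' Restricts a genotype matrix to the SNPs of a weight panel and re-orients
#' each dosage column so that it counts the panel's effect allele. Columns
#' whose counted allele is the panel's other allele are flipped (dosage
#' becomes 2 minus the stored count). SNPs whose allele labels match only
#' after strand complementation are flipped to the complementary strand
#' first, except strand-ambiguous A/T and C/G SNPs, which are dropped with a
#' warning whenever their labels do not match directly (a strand flip cannot
#' be verified for them). SNPs absent from the genotypes, or with
#' irreconcilable allele labels, are dropped with a warning.
#'
#' @param genotypes a `dosage_matrix` with allele labels per SNP.
#' @param panel a `snp_panel`.
#' @return A `dosage_matrix` whose columns are the usable intersection of
#'   panel and genotype SNPs, counting the panel effect allele.
#' @export
align_dosages <- function(genotypes, panel) {
  stopifnot(inherits(genotypes, "dosage_matrix"), inherits(panel, "snp_panel"))
  g_rsid <- colnames(genotypes$dosage)
  shared <- intersect(panel$rsid, g_rsid)
  absent <- setdiff(panel$rsid, g_rsid)
  if (length(absent))
    warning("panel SNP(s) absent from genotypes: ",
            paste(absent, collapse = ", "), call. = FALSE)
  keep <- character(0)
  flip <- logical(0)
  dropped <- character(0)
  for (rs in shared) {
    j <- match(rs, g_rsid)
    i <- match(rs, panel$rsid)
    ga1 <- genotypes$counted_allele[j]; ga2 <- genotypes$other_allele[j]
    pe <- panel$effect_allele[i]; po <- panel$other_allele[i]
    if (ga1 == pe && ga2 == po) {            # identical orientation
      keep <- c(keep, rs); flip <- c(flip, FALSE)
    } else if (ga1 == po && ga2 == pe) {     # counted the other allele
      keep <- c(keep, rs); flip <- c(flip, TRUE)
    } else if (is_strand_ambiguous(ga1, ga2) || is_strand_ambiguous(pe, po)) {
      dropped <- c(dropped, rs)              # unverifiable strand flip
    } else if (complement_allele(ga1) == pe && complement_allele(ga2) == po) {
      keep <- c(keep, rs); flip <- c(flip, FALSE)
    } else if (complement_allele(ga1) == po && complement_allele(ga2) == pe) {
      keep <- c(keep, rs); flip <- c(flip, TRUE)
    } else {
      dropped <- c(dropped, rs)
    }
  }
  if (length(dropped))
    warning("dropping SNP(s) with unmatchable allele labels: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  if (!length(keep))
    stop("no usable SNPs shared between panel '", attr(panel, "trait"),
         "' and the genotype matrix", call. = FALSE)
  d <- genotypes$dosage[, keep, drop = FALSE]
  if (any(flip)) d[, flip] <- 2 - d[, flip, drop = FALSE]
  i <- match(keep, panel$rsid)
  dosage_matrix(d, counted_allele = panel$effect_allele[i],
                other_allele = panel$other_allele[i],
                imputed = genotypes$imputed)
}

#' Impute missing dosages from the sample allele frequency
#'
#' Every missing entry at a SNP is replaced by its expected dosage,
#' 2p, where p is the sample effect-allele frequency computed from the
#' non-missing entries of that SNP. Non-missing entries are unchanged.
#'
#' @param x a `dosage_matrix`.
#' @return A `dosage_matrix` with no missing entries (`imputed = TRUE`).
#' @export
impute_missing <- function(x) {
  stopifnot(inherits(x, "dosage_matrix"))
  p <- effect_allele_freq(x)
  if (any(!is.finite(p)))
    stop("cannot impute: SNP(s) with no observed genotypes: ",
         paste(names(p)[!is.finite(p)], collapse = ", "), call. = FALSE)
  d <- x$dosage
  for (j in seq_len(ncol(d))) {
    nas <- is.na(d[, j])
    if (any(nas)) d[nas, j] <- 2 * p[j]
  }
  dosage_matrix(d, x$counted_allele, x$other_allele, imputed = TRUE)
}
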
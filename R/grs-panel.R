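#' SNP weight panels
#'
#' A weight panel is the trait-specific list of SNPs that enter a genetic risk
#' score: one row per SNP with its effect (risk) allele, the other allele, and
#' the published per-allele effect estimate (log odds ratio for binary traits,
#' beta for quantitative traits).
#'
#' @param rsid character vector of SNP identifiers (unique within a panel).
#' @param chrom chromosome labels.
#' @param pos integer 1-based base positions.
#' @param effect_allele,other_allele single-character alleles; must differ
#'   within each row.
#' @param weight numeric per-allele effect estimates (finite).
#' @param trait single trait label for the panel.
#' @param ld_pruned logical; whether the panel has already been LD-pruned.
#'
#' @return An object of class `snp_panel`: a data frame with columns
#'   `rsid`, `chrom`, `pos`, `effect_allele`, `other_allele`, `weight`,
#'   `trait` and attributes `trait` and `ld_pruned`.
#' @examples
#' snp_panel(rsid = c("rs1", "rs2"), chrom = c("1", "2"), pos = c(100L, 200L),
#'           effect_allele = c("A", "C"), other_allele = c("G", "T"),
#'           weight = c(0.10, -0.05), trait = "CAD")
#' @export
snp_panel <- function(rsid, chrom, pos, effect_allele, other_allele, weight,
                      trait, ld_pruned = FALSE) {
  x <- data.frame(rsid = as.character(rsid),
                  chrom = as.character(chrom),
                  pos = as.integer(pos),
                  effect_allele = toupper(as.character(effect_allele)),
                  other_allele = toupper(as.character(other_allele)),
                  weight = as.numeric(weight),
                  trait = as.character(trait),
                  stringsAsFactors = FALSE)
  validate_snp_panel(x)
  structure(x, trait = trait[1L], ld_pruned = isTRUE(ld_pruned),
            class = c("snp_panel", "data.frame"))
}

validate_snp_panel <- function(x) {
  need <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
            "weight", "trait")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("weight panel is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(x) == 0L) stop("weight panel has no SNPs", call. = FALSE)
  if (anyDuplicated(x$rsid))
    stop("duplicated rsid(s) in weight panel: ",
         paste(unique(x$rsid[duplicated(x$rsid)]), collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(x$weight)))
    stop("non-finite weight(s) in panel for rsid(s): ",
         paste(x$rsid[!is.finite(x$weight)], collapse = ", "), call. = FALSE)
  bad <- x$effect_allele == x$other_allele
  if (any(bad))
    stop("effect allele equals other allele for rsid(s): ",
         paste(x$rsid[bad], collapse = ", "), call. = FALSE)
  ok <- c("A", "C", "G", "T")
  if (any(!x$effect_allele %in% ok) || any(!x$other_allele %in% ok))
    stop("alleles must be single bases A/C/G/T", call. = FALSE)
  invisible(x)
}

#' @export
print.snp_panel <- function(x, ...) {
  cat(sprintf("SNP weight panel: trait %s, %d SNP(s), %sLD-pruned\n",
              attr(x, "trait"), nrow(x),
              if (isTRUE(attr(x, "ld_pruned"))) "" else "not "))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more SNP(s)\n")
  invisible(x)
}

#' Merge weight panels into one score panel
#'
#' Combines panels row-wise, keeping a single entry for any rsid present in
#' more than one panel (the first occurrence wins, with a warning). Used to
#' build combined scores such as a joint coronary-artery-disease +
#' coronary-artery-calcification panel from partially overlapping SNP sets.
#'
#' @param ... `snp_panel` objects.
#' @param trait trait label for the merged panel.
#' @return A `snp_panel` containing the union of the input SNPs.
#' @export
combine_panels <- function(..., trait = "combined") {
  panels <- list(...)
  if (!length(panels)) stop("no panels supplied", call. = FALSE)
  x <- do.call(rbind, lapply(panels, as.data.frame))
  dup <- duplicated(x$rsid)
  if (any(dup)) {
    warning("dropping ", sum(dup), " duplicated rsid(s) shared between panels: ",
            paste(unique(x$rsid[dup]), collapse = ", "), call. = FALSE)
    x <- x[!dup, , drop = FALSE]
  }
  snp_panel(x$rsid, x$chrom, x$pos, x$effect_allele, x$other_allele,
            x$weight, trait = trait, ld_pruned = FALSE)
}

#' Prune a weight panel for linkage disequilibrium
#'
#' Applies the panel-construction rule that when two SNPs are in high LD
#' (D' = 1 and R-squared >= 0.80) only one of the pair enters the score.
#' The retained member is chosen deterministically: the SNP with the larger
#' absolute weight, ties broken by lexicographically smaller rsid.
#'
#' @param panel a `snp_panel`.
#' @param ld an `ld_matrix` (see [ld_matrix()]) covering every panel rsid.
#' @param r2_threshold R-squared threshold for the high-LD rule (default 0.80).
#' @param dprime_tol numeric tolerance when testing D' = 1 (default 1e-9).
#' @return The pruned `snp_panel` with `ld_pruned = TRUE`.
#' @export
prune_ld <- function(panel, ld, r2_threshold = 0.80, dprime_tol = 1e-9) {
  stopifnot(inherits(panel, "snp_panel"), inherits(ld, "ld_matrix"))
  miss <- setdiff(panel$rsid, ld$rsids)
  if (length(miss))
    stop("LD matrix lacks entries for panel rsid(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  # order candidates by |weight| desc then rsid asc; greedily keep a SNP
  # unless it is in high LD with an already-kept SNP
  ord <- order(-abs(panel$weight), panel$rsid)
  idx <- match(panel$rsid, ld$rsids)
  kept <- integer(0)
  for (i in ord) {
    high_ld <- FALSE
    for (k in kept) {
      r2 <- ld$r2[idx[i], idx[k]]
      dp <- ld$d_prime[idx[i], idx[k]]
      if (is.na(r2) || is.na(dp))
        stop("missing LD entry for panel pair ", panel$rsid[i], " / ",
             panel$rsid[k], call. = FALSE)
      if (abs(dp - 1) <= dprime_tol && r2 >= r2_threshold) { high_ld <- TRUE; break }
    }
    if (!high_ld) kept <- c(kept, i)
  }
  kept <- sort(kept)
  out <- as.data.frame(panel)[kept, , drop = FALSE]
  if (nrow(out) == 0L) stop("LD pruning removed every SNP", call. = FALSE)
  snp_panel(out$rsid, out$chrom, out$pos, out$effect_allele, out$other_allele,
            out$weight, trait = attr(panel, "trait"), ld_pruned = TRUE)
}

#' Pairwise linkage-disequilibrium matrix
#'
#' @param rsids SNP identifiers.
#' @param r2 symmetric matrix of pairwise R-squared values in \[0, 1\].
#' @param d_prime symmetric matrix of pairwise D' values in \[0, 1\].
#' @return An object of class `ld_matrix` (a list with `rsids`, `r2`,
#'   `d_prime`).
#' @export
ld_matrix <- function(rsids, r2, d_prime) {
  rsids <- as.character(rsids)
  r2 <- as.matrix(r2); d_prime <- as.matrix(d_prime)
  n <- length(rsids)
  stopifnot(nrow(r2) == n, ncol(r2) == n, nrow(d_prime) == n, ncol(d_prime) == n)
  for (m in list(r2, d_prime)) {
    if (max(abs(m - t(m)), na.rm = TRUE) > 1e-12 ||
        any(is.na(m) != is.na(t(m))))
      stop("LD matrix is not symmetric", call. = FALSE)
    if (any(m < 0 | m > 1, na.rm = TRUE))
      stop("LD values must lie in [0, 1]", call. = FALSE)
    if (any(abs(diag(m) - 1) > 1e-12, na.rm = TRUE) || anyNA(diag(m)))
      stop("LD matrix diagonal must equal 1", call. = FALSE)
  }
  dimnames(r2) <- dimnames(d_prime) <- list(rsids, rsids)
  structure(list(rsids = rsids, r2 = r2, d_prime = d_prime),
            class = "ld_matrix")
}
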
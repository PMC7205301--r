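#' Average weighted genetic risk score
#'
#' For each individual the per-SNP effect-allele dosage is multiplied by the
#' published per-allele effect estimate, the products are summed, and the sum
#' is divided by the number of SNPs in the panel. Missing dosages must have
#' been imputed first (see [impute_missing()]) so the divisor is the same for
#' every individual.
#'
#' @param x a `dosage_matrix` whose columns are exactly the panel SNPs,
#'   oriented to the panel effect alleles and free of missing entries.
#' @param panel a `snp_panel`.
#' @return An object of class `grs`: a data frame with columns `id` and
#'   `raw_score` (and `z_score` after [standardize()]), with attributes
#'   `trait` and `weighted`.
#' @seealso [unweighted_grs()], [standardize()], [quartile_groups()]
#' @export
weighted_grs <- function(x, panel) {
  grs_compute(x, panel, weights = panel$weight, weighted = TRUE)
}

#' Unweighted genetic risk score
#'
#' As [weighted_grs()] but ignoring the published effect sizes: every SNP
#' receives weight 1, so the score is the mean effect-allele dosage.
#'
#' @inheritParams weighted_grs
#' @return A `grs` object with `weighted = FALSE`.
#' @export
unweighted_grs <- function(x, panel) {
  grs_compute(x, panel, weights = rep(1, nrow(panel)), weighted = FALSE)
}

grs_compute <- function(x, panel, weights, weighted) {
  stopifnot(inherits(x, "dosage_matrix"), inherits(panel, "snp_panel"))
  m <- nrow(panel)
  if (m == 0L) stop("panel contains no SNPs", call. = FALSE)
  if (!setequal(colnames(x$dosage), panel$rsid))
    stop("dosage matrix columns must be exactly the panel SNPs; ",
         "run align_dosages() first", call. = FALSE)
  if (anyNA(x$dosage))
    stop("dosage matrix has missing entries; run impute_missing() first",
         call. = FALSE)
  d <- x$dosage[, panel$rsid, drop = FALSE]
  raw <- as.numeric(d %*% weights) / m
  structure(data.frame(id = rownames(x$dosage), raw_score = raw,
                       stringsAsFactors = FALSE),
            trait = attr(panel, "trait"), weighted = weighted,
            class = c("grs", "data.frame"))
}

#' Standardize a genetic risk score to zero mean and unit variance
#'
#' Centers and scales the raw score with the study-population mean and sample
#' standard deviation (denominator n - 1), so association effects can be
#' reported per standard deviation of the score.
#'
#' @param grs a `grs` object with at least 2 individuals and non-degenerate
#'   raw scores.
#' @return The `grs` with an added `z_score` column.
#' @export
standardize <- function(grs) {
  stopifnot(inherits(grs, "grs"))
  if (nrow(grs) < 2L)
    stop("need at least 2 individuals to standardize", call. = FALSE)
  s <- stats::sd(grs$raw_score)
  if (!is.finite(s) || s == 0)
    stop("raw score is degenerate (zero standard deviation); ",
         "cannot standardize", call. = FALSE)
  grs$z_score <- (grs$raw_score - mean(grs$raw_score)) / s
  grs
}

#' @export
print.grs <- function(x, ...) {
  cat(sprintf("%s genetic risk score (%s): n = %d; raw mean %.4g, sd %.4g%s\n",
              attr(x, "trait"),
              if (isTRUE(attr(x, "weighted"))) "weighted" else "unweighted",
              nrow(x), mean(x$raw_score), stats::sd(x$raw_score),
              if ("z_score" %in% names(x)) "; standardized" else ""))
  invisible(x)
}

#' Quartile risk groups of a genetic risk score
#'
#' Splits individuals into three groups by the quartiles of the score:
#' `low` (at or below the first quartile, Q1), `high` (above the third
#' quartile, Q4), and `medium` (the middle two quartiles, Q2 + Q3). Quartiles
#' are type-7 sample quantiles; individuals exactly on a boundary go to the
#' lower group.
#'
#' @param grs a `grs` object (or numeric vector of scores) with at least 4
#'   individuals.
#' @param use column to split on when `grs` is a `grs` object: `"z_score"`
#'   if present, else `"raw_score"`.
#' @return Factor with levels `low`, `medium`, `high`, one per individual.
#' @export
quartile_groups <- function(grs, use = NULL) {
  score <- if (is.numeric(grs)) grs else {
    stopifnot(inherits(grs, "grs"))
    if (is.null(use)) use <- if ("z_score" %in% names(grs)) "z_score" else "raw_score"
    grs[[use]]
  }
  if (length(score) < 4L)
    stop("need at least 4 individuals for quartile groups", call. = FALSE)
  q <- stats::quantile(score, c(0.25, 0.75), type = 7, names = FALSE)
  if (q[1] == q[2])
    stop("degenerate quartiles: first and third quartile coincide",
         call. = FALSE)
  factor(ifelse(score <= q[1], "low", ifelse(score > q[2], "high", "medium")),
         levels = c("low", "medium", "high"))
}
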
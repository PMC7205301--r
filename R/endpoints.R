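#' Log transform of a CAC score
#'
#' The Agatston CAC distribution is heavily right-skewed with a mass at zero;
#' all modelling is done on loge(CAC + 1), which maps 0 to 0.
#'
#' @param x CAC score(s), non-negative.
#' @return loge(x + 1).
#' @export
log_cac <- function(x) {
  if (any(x < 0, na.rm = TRUE))
    stop("CAC scores must be non-negative", call. = FALSE)
  log1p(x)
}

#' Quality-control flag for extreme scan-pair progression
#'
#' Flags scan pairs whose apparent progression or regression is extreme
#' enough to trigger a second reading: a jump from CAC_b <= 10 to
#' CAC_5y > 50, a drop from CAC_b > 20 to CAC_5y <= 10, or otherwise an
#' annualized relative change in (CAC + 1) above +30% or below -7%. The
#' annualized change is r = ((cac_5y + 1) / (cac_b + 1))^(1/t) - 1, which is
#' well defined for zero-baseline individuals. Flags mark records for
#' re-reading; they do not exclude.
#'
#' @param cac_b,cac_5y baseline and follow-up CAC scores (non-negative).
#' @param t_years inter-scan time in years (> 0).
#' @param upper,lower annual-change trigger bounds (defaults +0.30, -0.07).
#' @return Factor with levels `none`, `rule_low_to_high`, `rule_high_to_low`,
#'   `rule_annual_change`.
#' @export
qc_flag_extreme <- function(cac_b, cac_5y, t_years,
                            upper = 0.30, lower = -0.07) {
  n <- max(length(cac_b), length(cac_5y), length(t_years))
  cac_b <- rep_len(cac_b, n); cac_5y <- rep_len(cac_5y, n)
  t_years <- rep_len(t_years, n)
  stopifnot(all(cac_b >= 0), all(cac_5y >= 0), all(t_years > 0))
  r <- ((cac_5y + 1) / (cac_b + 1))^(1 / t_years) - 1
  flag <- rep("none", n)
  flag[r > upper | r < lower] <- "rule_annual_change"
  flag[cac_b > 20 & cac_5y <= 10] <- "rule_high_to_low"
  flag[cac_b <= 10 & cac_5y > 50] <- "rule_low_to_high"
  factor(flag, levels = c("none", "rule_low_to_high", "rule_high_to_low",
                          "rule_annual_change"))
}

#' Deviation of observed from expected follow-up CAC (endpoint 1)
#'
#' The difference between the observed loge(CAC_5y + 1) and the value
#' expected from carrying the baseline CAC percentile forward in age,
#' "log(obs) - log(exp)". Positive values indicate accelerated progression
#' relative to percentile tracking.
#'
#' @param log_cac_5y observed loge(CAC_5y + 1).
#' @param expected_log_cac_5y expected loge(CAC_5y + 1) from
#'   [expected_log_cac_5y()].
#' @return dev = log_cac_5y - expected_log_cac_5y.
#' @export
endpoint_dev <- function(log_cac_5y, expected_log_cac_5y) {
  stopifnot(all(is.finite(log_cac_5y)), all(is.finite(expected_log_cac_5y)))
  log_cac_5y - expected_log_cac_5y
}

#' Five-year normalized CAC progression (endpoint 2)
#'
#' The change in loge(CAC + 1) between the scans, normalized to a common
#' 5-year interval: 5 * (loge(CAC_5y + 1) - loge(CAC_b + 1)) / T, where T is
#' the individual inter-scan time in years.
#'
#' @param cac_b,cac_5y baseline and follow-up CAC scores (non-negative).
#' @param t_years inter-scan time in years (> 0).
#' @return prog5 in loge units.
#' @export
endpoint_prog5 <- function(cac_b, cac_5y, t_years) {
  stopifnot(all(t_years > 0))
  5 * (log_cac(cac_5y) - log_cac(cac_b)) / t_years
}

#' Compute both progression endpoints for a cohort
#'
#' End-to-end endpoint derivation: log-transforms both scans, fits (or
#' reuses) the age/sex percentile surface of baseline CAC, locates each
#' individual's baseline percentile, projects it to the attained age for the
#' expected follow-up value, and returns both endpoints together with the
#' scan-pair QC flag.
#'
#' @param cohort data frame with columns `id`, `sex`, `age_b`, `cac_b`,
#'   `cac_5y`, `t_years`.
#' @param model optional pre-fitted [cac_percentile_fit()] model; fitted from
#'   `cohort` when `NULL`.
#' @param exclude_flagged drop QC-flagged records from the output
#'   (default `FALSE`: flags mark records for re-reading, they are not
#'   exclusions).
#' @param ... passed to [cac_percentile_fit()] when `model` is `NULL`.
#' @return Data frame with columns `id`, `log_cac_b`, `log_cac_5y`,
#'   `baseline_percentile`, `expected_log_cac_5y`, `dev`, `prog5`, `qc_flag`;
#'   the fitted percentile model is attached as attribute `model`.
#' @export
cac_endpoints <- function(cohort, model = NULL, exclude_flagged = FALSE, ...) {
  need <- c("id", "sex", "age_b", "cac_b", "cac_5y", "t_years")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(model)) model <- cac_percentile_fit(cohort, ...)
  lb <- log_cac(cohort$cac_b)
  l5 <- log_cac(cohort$cac_5y)
  pb <- baseline_percentile(model, cohort$sex, cohort$age_b, lb)
  ex <- expected_log_cac_5y(model, cohort$sex, cohort$age_b, pb,
                            cohort$t_years)
  out <- data.frame(id = cohort$id,
                    log_cac_b = lb,
                    log_cac_5y = l5,
                    baseline_percentile = pb,
                    expected_log_cac_5y = ex,
                    dev = endpoint_dev(l5, ex),
                    prog5 = endpoint_prog5(cohort$cac_b, cohort$cac_5y,
                                           cohort$t_years),
                    qc_flag = qc_flag_extreme(cohort$cac_b, cohort$cac_5y,
                                              cohort$t_years),
                    stringsAsFactors = FALSE)
  if (exclude_flagged) out <- out[out$qc_flag == "none", , drop = FALSE]
  attr(out, "model") <- model
  out
}
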
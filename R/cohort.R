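#' Derive analysis phenotypes from raw examination fields
#'
#' Standard risk-factor derivations for a CAC-progression analysis:
#' \itemize{
#'   \item Blood pressure: the mean of the second and third of three seated
#'     measurements (the first is discarded as an accommodation reading). If
#'     one of the two is missing the other is used; if all are missing the
#'     value is `NA`.
#'   \item Diabetes: any of (1) self-reported physician-diagnosed diabetes,
#'     (2) use of glucose-lowering drugs, (3) fasting glucose > 125 mg/dL,
#'     (4) non-fasting glucose >= 200 mg/dL.
#'   \item Socio-economic status: total years of formal education,
#'     dichotomized at <= 13 versus >= 14 years (`ses_high`).
#'   \item Smoking: mapped to `never` / `past` / `current`.
#' }
#'
#' @param raw data frame with (any of) columns `sbp1`, `sbp2`, `sbp3`,
#'   `dbp1`, `dbp2`, `dbp3`, `diabetes_history`, `glucose_lowering_med`,
#'   `fasting_glucose`, `nonfasting_glucose`, `education_years`, `smoking`.
#' @return `raw` with derived columns `sbp`, `dbp`, `diabetes`, `ses_high`,
#'   and a normalized `smoking` factor added (where the inputs permit).
#' @export
derive_phenotypes <- function(raw) {
  stopifnot(is.data.frame(raw))
  out <- raw
  mean23 <- function(v2, v3) {
    m <- rowMeans(cbind(v2, v3), na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    m
  }
  if (all(c("sbp2", "sbp3") %in% names(raw)))
    out$sbp <- mean23(raw$sbp2, raw$sbp3)
  if (all(c("dbp2", "dbp3") %in% names(raw)))
    out$dbp <- mean23(raw$dbp2, raw$dbp3)
  gl_cols <- c("diabetes_history", "glucose_lowering_med", "fasting_glucose",
               "nonfasting_glucose")
  if (any(gl_cols %in% names(raw))) {
    n <- nrow(raw)
    pick <- function(col, default) if (col %in% names(raw)) raw[[col]] else rep(default, n)
    hist <- pick("diabetes_history", FALSE)
    med  <- pick("glucose_lowering_med", FALSE)
    fg   <- pick("fasting_glucose", NA_real_)
    nfg  <- pick("nonfasting_glucose", NA_real_)
    out$diabetes <- (hist %in% TRUE) | (med %in% TRUE) |
      (!is.na(fg) & fg > 125) | (!is.na(nfg) & nfg >= 200)
  }
  if ("education_years" %in% names(raw))
    out$ses_high <- raw$education_years >= 14
  if ("smoking" %in% names(raw)) {
    sm <- tolower(as.character(raw$smoking))
    map <- c(never = "never", non = "never", nonsmoker = "never",
             past = "past", former = "past", ex = "past",
             current = "current", smoker = "current")
    bad <- !is.na(sm) & !sm %in% names(map)
    if (any(bad))
      stop("unrecognized smoking value(s): ",
           paste(unique(sm[bad]), collapse = ", "), call. = FALSE)
    out$smoking <- factor(unname(map[sm]),
                          levels = c("never", "past", "current"))
  }
  out
}

#' Apply the cohort inclusion and exclusion rules
#'
#' Filters a raw longitudinal cohort down to the analysis population,
#' applying the exclusion rules in a fixed order and recording the count
#' removed at each step:
#' \enumerate{
#'   \item prior coronary artery disease at baseline (bypass surgery,
#'     revascularization, or prior myocardial infarction);
#'   \item missing either CAC scan;
#'   \item stent implantation, bypass, balloon dilatation or myocardial
#'     infarction during follow-up (revascularization disturbs the CAC
#'     measurement);
#'   \item baseline or follow-up age outside the study range (defaults
#'     45-74 at baseline, 50-79 at 5 years);
#'   \item missing Framingham risk-factor information.
#' }
#'
#' @param raw data frame with columns `prior_cad`, `cac_b`, `cac_5y`,
#'   `event_during_followup`, `age_b`, `t_years`, plus the risk-factor
#'   columns named in `risk_factor_cols`.
#' @param age_min_b,age_max_b baseline age range (default 45-74).
#' @param age_min_5y,age_max_5y follow-up age range (default 50-79).
#' @param risk_factor_cols columns whose missingness excludes a record
#'   (default the Framingham set present in `raw` among `age_b`, `sex`,
#'   `sbp`, `smoking`, `diabetes`, `ldl`, `hdl`).
#' @return The retained rows, with attribute `exclusion_log`: a data frame
#'   of rule labels and counts excluded, in application order.
#' @export
apply_cohort_filters <- function(raw, age_min_b = 45, age_max_b = 74,
                                 age_min_5y = 50, age_max_5y = 79,
                                 risk_factor_cols = NULL) {
  stopifnot(is.data.frame(raw))
  if (is.null(risk_factor_cols))
    risk_factor_cols <- intersect(c("age_b", "sex", "sbp", "smoking",
                                    "diabetes", "ldl", "hdl"), names(raw))
  x <- raw
  log <- data.frame(rule = character(0), excluded = integer(0),
                    stringsAsFactors = FALSE)
  drop_rule <- function(x, keep, label) {
    keep[is.na(keep)] <- FALSE
    log <<- rbind(log, data.frame(rule = label, excluded = sum(!keep),
                                  stringsAsFactors = FALSE))
    x[keep, , drop = FALSE]
  }
  if ("prior_cad" %in% names(x))
    x <- drop_rule(x, !(x$prior_cad %in% TRUE), "prior_cad_at_baseline")
  x <- drop_rule(x, !is.na(x$cac_b) & !is.na(x$cac_5y), "missing_cac_scan")
  if ("event_during_followup" %in% names(x))
    x <- drop_rule(x, !(x$event_during_followup %in% TRUE),
                   "event_during_followup")
  age_5y <- x$age_b + x$t_years
  x <- drop_rule(x, x$age_b >= age_min_b & x$age_b <= age_max_b &
                    age_5y >= age_min_5y & age_5y <= age_max_5y,
                 "outside_age_range")
  if (length(risk_factor_cols)) {
    complete <- !Reduce(`|`, lapply(x[risk_factor_cols], is.na))
    x <- drop_rule(x, complete, "missing_risk_factors")
  }
  if (nrow(x) == 0L)
    stop("no individuals remain after cohort filtering", call. = FALSE)
  attr(x, "exclusion_log") <- log
  x
}
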
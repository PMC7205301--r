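#' Covariate-adjusted association between a risk score and CAC progression
#'
#' Fits the association between one or more exposures (standardized genetic
#' risk scores, quartile groups, or single-SNP dosages) and a continuous
#' progression endpoint, adjusted for a covariate set, on the loge scale.
#' Effects are additionally reported on the percent scale,
#' (e^beta - 1) * 100, i.e. the percent deviation from the expected
#' (CAC_5y + 1) for the `dev` endpoint or the percent change in (CAC + 1)
#' for `prog5`. For OLS-based estimators the incremental explained variance
#' of the exposure block over the covariate-only base model (delta R-squared,
#' percent points, identical rows) is attached.
#'
#' Estimators: `"ols"` (ordinary least squares, t-based confidence
#' intervals), `"robust"` (identical point estimates with
#' heteroscedasticity-consistent HC3 standard errors and normal-approximation
#' intervals), `"quantile"` (check-loss regression at level `tau`, bootstrap
#' percentile intervals).
#'
#' Missing covariate or exposure values are handled by listwise deletion; the
#' number of dropped rows is recorded. A rank-deficient design is a hard
#' error naming the collinear columns.
#'
#' @param data analysis table (one row per individual) containing the
#'   outcome, exposure and covariate columns. Column `sex` may be a factor or
#'   `"female"`/`"male"` character; `smoking` must be a factor with levels
#'   `never`, `past`, `current` when used.
#' @param outcome outcome column name, typically `"dev"` or `"prog5"`.
#' @param exposure character vector of exposure column names; a factor
#'   exposure (e.g. quartile groups) enters as indicator contrasts against
#'   its first level.
#' @param covariates `"base"` (age, sex, log(CAC_b+1)), `"full"` (base +
#'   diabetes, BMI, systolic blood pressure, smoking, antihypertensive and
#'   lipid-lowering medication, socio-economic status, LDL and HDL
#'   cholesterol), `"base_fh"` (base + family history of CHD), or an explicit
#'   character vector of column names. `NULL` or `character(0)` fits the
#'   exposure alone (with intercept).
#' @param estimator `"ols"`, `"robust"`, or `"quantile"`.
#' @param tau quantile level for `estimator = "quantile"` (default 0.75).
#' @param boot bootstrap resamples for quantile-regression intervals
#'   (default 500).
#' @param seed seed for the bootstrap resampling.
#' @param conf_level confidence level (default 0.95).
#' @return An object of class `cac_assoc` with `print`, `summary`, `coef`,
#'   `confint` and `residuals` methods. `summary()` returns one row per model
#'   term with loge-scale and percent-scale estimates, intervals, p-values,
#'   and delta R-squared for the exposure terms.
#' @examples
#' set.seed(1)
#' d <- data.frame(dev = rnorm(200), z = rnorm(200), age_b = runif(200, 45, 75),
#'                 sex = sample(c("female", "male"), 200, TRUE),
#'                 log_cac_b = rexp(200))
#' d$dev <- d$dev + 0.09 * d$z
#' fit <- cac_assoc(d, outcome = "dev", exposure = "z", covariates = "base")
#' summary(fit)
#' @export
cac_assoc <- function(data, outcome, exposure, covariates = "base",
                      estimator = c("ols", "robust", "quantile"),
                      tau = 0.75, boot = 500L, seed = NULL,
                      conf_level = 0.95) {
  estimator <- match.arg(estimator)
  stopifnot(is.data.frame(data), length(outcome) == 1L)
  covariates <- resolve_covariates(covariates)
  cols <- unique(c(outcome, exposure, covariates))
  miss <- setdiff(cols, names(data))
  if (length(miss))
    stop("analysis table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(c(exposure, covariates)))
    stop("duplicated model term(s): ",
         paste(unique(c(exposure, covariates)[
           duplicated(c(exposure, covariates))]), collapse = ", "),
         call. = FALSE)
  df <- normalize_model_columns(data[cols])
  cc <- stats::complete.cases(df)
  n_dropped <- sum(!cc)
  df <- df[cc, , drop = FALSE]
  X <- build_design(df, c(exposure, covariates))
  y <- df[[outcome]]
  if (nrow(X) < ncol(X) + 2L)
    stop("too few complete rows (", nrow(X), ") for ", ncol(X),
         " parameters", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  exposure_cols <- attr(X, "term_cols")[exposure]
  res <- switch(estimator,
    ols = fit_ols_terms(X, y, conf_level, robust = FALSE),
    robust = fit_ols_terms(X, y, conf_level, robust = TRUE),
    quantile = fit_rq_terms(X, y, tau, boot, seed, conf_level))
  tab <- res$table
  pct <- percent_scale(tab$beta_log, tab$ci_low, tab$ci_high)
  tab$pct_effect <- pct$pct
  tab$pct_ci_low <- pct$pct_low
  tab$pct_ci_high <- pct$pct_high
  r2 <- r2_base <- dr2 <- NA_real_
  if (estimator %in% c("ols", "robust")) {
    r2 <- res$r2
    keep <- !colnames(X) %in% unlist(exposure_cols)
    Xb <- X[, keep, drop = FALSE]
    r2_base <- ols_r2(Xb, y)
    dr2 <- (r2 - r2_base) * 100
  }
  tab$delta_r2 <- ifelse(tab$term %in% unlist(exposure_cols), dr2, NA_real_)
  structure(list(terms = tab, outcome = outcome, exposure = exposure,
                 exposure_cols = unlist(exposure_cols),
                 covariates = covariates, estimator = estimator, tau = tau,
                 n = nrow(X), n_dropped = n_dropped, r2 = r2,
                 r2_base = r2_base, delta_r2 = dr2,
                 conf_level = conf_level, residuals = res$residuals,
                 fitted = y - res$residuals,
                 objective = res$objective),
            class = "cac_assoc")
}

resolve_covariates <- function(covariates) {
  if (is.null(covariates)) return(character(0))
  if (length(covariates) == 1L && covariates %in% c("base", "full", "base_fh"))
    switch(covariates,
           base = c("age_b", "sex", "log_cac_b"),
           full = c("age_b", "sex", "log_cac_b", "diabetes", "bmi", "sbp",
                    "smoking", "antihypertensive_med", "lipid_med",
                    "ses_high", "ldl", "hdl"),
           base_fh = c("age_b", "sex", "log_cac_b", "family_history_chd"))
  else covariates
}

normalize_model_columns <- function(df) {
  for (nm in names(df)) {
    v <- df[[nm]]
    if (nm == "sex" && !is.numeric(v))
      df[[nm]] <- factor(as.character(v), levels = c("female", "male"))
    else if (is.logical(v)) df[[nm]] <- as.numeric(v)
    else if (is.character(v)) df[[nm]] <- factor(v)
  }
  df
}

# expand terms to a design matrix with intercept; factors become treatment
# contrasts against their first level; records which columns belong to which
# term in attr "term_cols"
build_design <- function(df, terms) {
  n <- nrow(df)
  cols <- list(`(Intercept)` = rep(1, n))
  term_cols <- list()
  for (tm in terms) {
    v <- df[[tm]]
    if (is.factor(v)) {
      v <- droplevels(v)
      lev <- levels(v)
      if (length(lev) < 2L)
        stop("factor term '", tm, "' has a single level", call. = FALSE)
      nms <- paste0(tm, lev[-1L])
      for (k in seq_along(nms)) cols[[nms[k]]] <- as.numeric(v == lev[k + 1L])
      term_cols[[tm]] <- nms
    } else {
      cols[[tm]] <- as.numeric(v)
      term_cols[[tm]] <- tm
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  attr(X, "term_cols") <- term_cols
  X
}

ols_r2 <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

fit_ols_terms <- function(X, y, conf_level, robust = FALSE) {
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  rdf <- nrow(X) - ncol(X)
  if (robust) {
    lmfit <- stats::lm(y ~ X - 1)
    V <- sandwich::vcovHC(lmfit, type = "HC3")
    se <- sqrt(diag(V))
    crit <- stats::qnorm(1 - (1 - conf_level) / 2)
    stat <- beta / se
    p <- 2 * stats::pnorm(-abs(stat))
  } else {
    XtXinv <- chol2inv(chol(crossprod(X)))
    sigma2 <- sum(fit$residuals^2) / rdf
    se <- sqrt(diag(XtXinv) * sigma2)
    crit <- stats::qt(1 - (1 - conf_level) / 2, rdf)
    stat <- beta / se
    p <- 2 * stats::pt(-abs(stat), rdf)
  }
  list(table = data.frame(term = colnames(X), beta_log = unname(beta),
                          se = unname(se),
                          ci_low = unname(beta - crit * se),
                          ci_high = unname(beta + crit * se),
                          p = unname(p), stringsAsFactors = FALSE),
       residuals = fit$residuals,
       r2 = 1 - sum(fit$residuals^2) / sum((y - mean(y))^2),
       objective = NULL)
}

fit_rq_terms <- function(X, y, tau, boot, seed, conf_level) {
  fit <- rq_fit(X, y, tau)
  bs <- rq_boot_ci(X, y, tau, fit$coefficients, B = boot, level = conf_level,
                   seed = seed)
  z <- fit$coefficients / bs$se
  list(table = data.frame(term = colnames(X),
                          beta_log = unname(fit$coefficients),
                          se = unname(bs$se),
                          ci_low = bs$ci[, 1], ci_high = bs$ci[, 2],
                          p = unname(2 * stats::pnorm(-abs(z))),
                          stringsAsFactors = FALSE),
       residuals = fit$residuals, r2 = NA_real_, objective = fit$objective)
}

#' @export
print.cac_assoc <- function(x, digits = 3, ...) {
  cat(sprintf("CAC-progression association model (%s%s)\n", x$estimator,
              if (x$estimator == "quantile") sprintf(", tau = %.2f", x$tau) else ""))
  cat(sprintf("  outcome: %s; exposure: %s; covariates: %s\n", x$outcome,
              paste(x$exposure, collapse = " + "),
              if (length(x$covariates)) paste(x$covariates, collapse = " + ")
              else "(none)"))
  cat(sprintf("  n = %d (%d dropped for missingness)\n", x$n, x$n_dropped))
  tab <- x$terms[x$terms$term %in% x$exposure_cols, , drop = FALSE]
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %s: %+.*f%% (%.*f%%; %.*f%%), p = %.2g\n", tab$term[i],
                digits - 2, tab$pct_effect[i], digits - 2, tab$pct_ci_low[i],
                digits - 2, tab$pct_ci_high[i], tab$p[i]))
  if (is.finite(x$delta_r2))
    cat(sprintf("  delta R-squared (exposure over base): %.1f%%\n",
                x$delta_r2))
  invisible(x)
}

#' @export
summary.cac_assoc <- function(object, ...) {
  tab <- object$terms
  tab$n <- object$n
  tab$r2 <- object$r2
  attr(tab, "estimator") <- object$estimator
  attr(tab, "outcome") <- object$outcome
  tab
}

#' @export
coef.cac_assoc <- function(object, ...) {
  stats::setNames(object$terms$beta_log, object$terms$term)
}

#' @export
confint.cac_assoc <- function(object, parm, ...) {
  m <- cbind(object$terms$ci_low, object$terms$ci_high)
  rownames(m) <- object$terms$term
  a <- (1 - object$conf_level) / 2
  colnames(m) <- paste0(format(100 * c(a, 1 - a), trim = TRUE), " %")
  if (!missing(parm)) m <- m[parm, , drop = FALSE]
  m
}

#' @export
residuals.cac_assoc <- function(object, ...) object$residuals

#' Transform loge-scale effects to the percent scale
#'
#' Maps a loge-scale coefficient and its confidence bounds through
#' (e^x - 1) * 100, the percent deviation/change in (CAC + 1) per unit of
#' the predictor. The mapping is monotone, so interval ordering is
#' preserved; `percent_to_log()` is the exact inverse.
#'
#' @param beta_log,ci_low,ci_high loge-scale estimate and bounds.
#' @return A list with elements `pct`, `pct_low`, `pct_high`.
#' @export
percent_scale <- function(beta_log, ci_low = NULL, ci_high = NULL) {
  to_pct <- function(x) (exp(x) - 1) * 100
  list(pct = to_pct(beta_log),
       pct_low = if (is.null(ci_low)) NULL else to_pct(ci_low),
       pct_high = if (is.null(ci_high)) NULL else to_pct(ci_high))
}

#' @rdname percent_scale
#' @param pct percent-scale effect.
#' @export
percent_to_log <- function(pct) log1p(pct / 100)

#' Incremental explained variance of nested linear models
#'
#' The difference in (unadjusted) R-squared between a full model and a nested
#' base model fitted on identical rows, in percent points. Used to report how
#' much observed phenotypic variance a genetic risk score explains over the
#' age + sex + log(CAC_b + 1) base model.
#'
#' @param full_fit,base_fit fitted `lm` objects (or `cac_assoc` objects with
#'   an OLS estimator), base nested in full, identical rows.
#' @return R-squared difference in percent points.
#' @export
delta_r2 <- function(full_fit, base_fit) {
  get_r2n <- function(f) {
    if (inherits(f, "cac_assoc")) {
      if (!is.finite(f$r2)) stop("delta_r2 needs an OLS-based fit",
                                 call. = FALSE)
      c(f$r2, f$n)
    } else if (inherits(f, "lm")) {
      c(summary(f)$r.squared, stats::nobs(f))
    } else stop("expected an lm or cac_assoc fit", call. = FALSE)
  }
  fu <- get_r2n(full_fit); ba <- get_r2n(base_fit)
  if (fu[2] != ba[2])
    stop("models were fitted on different rows (n = ", fu[2], " vs ",
         ba[2], ")", call. = FALSE)
  (fu[1] - ba[1]) * 100
}

#' Bonferroni threshold for a family of tests
#'
#' @param alpha family-wise error rate, in (0, 1).
#' @param m number of tests (>= 1).
#' @return List with `threshold` (alpha / m, exact) and `display` (rounded
#'   to one significant figure, the conventional reporting form).
#' @examples
#' bonferroni_threshold(0.05, 11)  # threshold 0.004545..., display 0.005
#' @export
bonferroni_threshold <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  thr <- alpha / m
  list(threshold = thr, display = signif(thr, 1))
}

#' Quartile-contrast association model
#'
#' Recodes a risk-score quartile grouping (see [quartile_groups()]) as
#' indicator contrasts — medium (Q2 + Q3) and high (Q4) against the low
#' quartile (Q1) as reference — and fits the adjusted association model.
#'
#' @param data analysis table.
#' @param outcome outcome column name.
#' @param groups factor of quartile groups (levels `low`, `medium`, `high`)
#'   aligned with `data` rows, or the name of such a column in `data`.
#' @param ... passed to [cac_assoc()] (covariates, estimator, ...).
#' @return A `cac_assoc` fit with terms `grs_group medium` and
#'   `grs_group high`.
#' @export
fit_quartile_contrast <- function(data, outcome, groups, ...) {
  if (is.character(groups) && length(groups) == 1L) groups <- data[[groups]]
  groups <- factor(groups, levels = c("low", "medium", "high"))
  if (any(table(groups) == 0L))
    stop("empty quartile group(s): ",
         paste(names(which(table(groups) == 0L)), collapse = ", "),
         call. = FALSE)
  data$grs_group <- groups
  cac_assoc(data, outcome = outcome, exposure = "grs_group", ...)
}

#' Per-SNP association scan
#'
#' Fits the covariate-adjusted per-allele association of each SNP dosage with
#' a progression endpoint (no multiplicity adjustment; a nominal two-sided
#' 0.05 level, as a descriptive scan). Monomorphic SNPs are skipped with a
#' warning and excluded from the summary denominator.
#'
#' @param dosages a `dosage_matrix` (individuals aligned with `data` rows and
#'   oriented so each column counts the risk allele), or a plain numeric
#'   matrix with rsid column names.
#' @param data analysis table.
#' @param outcome outcome column name.
#' @param covariates covariate specification as in [cac_assoc()].
#' @param alpha nominal significance level for the summary (default 0.05).
#' @return Data frame with one row per tested SNP (`rsid`, `beta_log`, `se`,
#'   `ci_low`, `ci_high`, `p`, `pct_effect`, ...), with attributes
#'   `fraction_positive_significant` (share of tested SNPs with p < `alpha`
#'   and a positive risk-allele effect) and `n_skipped`.
#' @export
per_snp_scan <- function(dosages, data, outcome, covariates = "base",
                         alpha = 0.05) {
  d <- if (inherits(dosages, "dosage_matrix")) dosages$dosage else as.matrix(dosages)
  if (nrow(d) != nrow(data))
    stop("dosage rows (", nrow(d), ") do not match analysis-table rows (",
         nrow(data), ")", call. = FALSE)
  rows <- list()
  skipped <- character(0)
  for (rs in colnames(d)) {
    v <- d[, rs]
    if (stats::var(v, na.rm = TRUE) == 0) {
      skipped <- c(skipped, rs)
      next
    }
    data$.snp <- v
    fit <- cac_assoc(data, outcome = outcome, exposure = ".snp",
                     covariates = covariates)
    row <- fit$terms[fit$terms$term == ".snp", , drop = FALSE]
    row$term <- rs
    rows[[rs]] <- row
  }
  if (length(skipped))
    warning("skipping monomorphic SNP(s): ",
            paste(skipped, collapse = ", "), call. = FALSE)
  if (!length(rows)) stop("no polymorphic SNPs to test", call. = FALSE)
  out <- do.call(rbind, rows)
  names(out)[names(out) == "term"] <- "rsid"
  rownames(out) <- NULL
  attr(out, "fraction_positive_significant") <-
    mean(out$p < alpha & out$beta_log > 0)
  attr(out, "n_skipped") <- length(skipped)
  out
}
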
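#' Fit the age- and sex-conditional percentile surface of baseline CAC
#'
#' Estimates, separately for women and men, the quantile surface of
#' log(CAC + 1) as a function of age: for every center of a sliding age
#' window, the empirical (type-7) quantiles of log(CAC_b + 1) at a grid of
#' percentile levels. The surface underlies percentile tracking: an
#' individual's expected follow-up CAC is the surface value at their baseline
#' percentile and their attained age. Quantiles are non-decreasing in the
#' percentile level by construction, and the surface is evaluated anywhere in
#' the observed age range by bilinear interpolation.
#'
#' Age windows with fewer than `min_window` observations are widened
#' symmetrically (half-width doubled, repeatedly) until they reach
#' `min_window`, so edge-of-range windows remain estimable.
#'
#' @param cohort data frame with columns `sex` (`"female"`/`"male"`), `age_b`
#'   (years), and `cac_b` (Agatston units) or `log_cac_b` (loge(CAC+1),
#'   used directly when present).
#' @param half_width half-width of the sliding age window in years
#'   (default 2.5).
#' @param step spacing of window centers in years (default 1).
#' @param plevels percentile levels (percent) of the quantile grid.
#' @param min_stratum minimum individuals required per sex (default 100).
#' @param min_window minimum individuals per age window before widening
#'   (default 20).
#' @param method `"empirical"` for sliding-window quantiles (default) or
#'   `"linear"` for a parametric alternative in which each percentile level's
#'   quantile is a linear function of age (fitted by least squares through
#'   the window quantiles).
#' @return An object of class `cac_percentile_model`.
#' @seealso [baseline_percentile()], [expected_log_cac_5y()],
#'   [quantile.cac_percentile_model()]
#' @export
cac_percentile_fit <- function(cohort, half_width = 2.5, step = 1,
                               plevels = c(0.5, 1:99, 99.5),
                               min_stratum = 100, min_window = 20,
                               method = c("empirical", "linear")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(cohort), all(c("sex", "age_b") %in% names(cohort)))
  y <- if ("log_cac_b" %in% names(cohort)) cohort$log_cac_b else log_cac(cohort$cac_b)
  sex <- as.character(cohort$sex)
  if (!all(sex %in% c("female", "male")))
    stop("sex must be 'female' or 'male'", call. = FALSE)
  stopifnot(all(is.finite(y)), all(is.finite(cohort$age_b)))
  plevels <- sort(unique(plevels))
  strata <- lapply(c(female = "female", male = "male"), function(s) {
    keep <- sex == s
    n <- sum(keep)
    if (n < min_stratum)
      stop("only ", n, " individuals in the ", s, " stratum (minimum ",
           min_stratum, "); widen the windows or pool sexes upstream",
           call. = FALSE)
    age <- cohort$age_b[keep]; ys <- y[keep]
    centers <- seq(floor(min(age)), ceiling(max(age)), by = step)
    qmat <- matrix(NA_real_, length(centers), length(plevels))
    for (i in seq_along(centers)) {
      hw <- half_width
      idx <- abs(age - centers[i]) <= hw
      while (sum(idx) < min(min_window, n)) {
        hw <- hw * 2
        idx <- abs(age - centers[i]) <= hw
      }
      qmat[i, ] <- stats::quantile(ys[idx], plevels / 100, type = 7,
                                   names = FALSE)
    }
    if (method == "linear") {
      # replace each percentile level's column by its least-squares line in age
      X <- cbind(1, centers)
      coefs <- qr.solve(X, qmat)            # 2 x length(plevels)
      qmat <- X %*% coefs
    }
    list(centers = centers, qmat = qmat, n = n,
         age_range = range(age))
  })
  structure(list(strata = strata, plevels = plevels, half_width = half_width,
                 step = step, method = method, monotonized = TRUE),
            class = "cac_percentile_model")
}

#' @export
print.cac_percentile_model <- function(x, ...) {
  cat("Age/sex percentile surface of log(CAC_b + 1)\n")
  cat(sprintf("  method: %s; window half-width %.3g y, step %.3g y; %d percentile levels\n",
              x$method, x$half_width, x$step, length(x$plevels)))
  for (s in names(x$strata))
    cat(sprintf("  %s: n = %d, ages %.1f-%.1f\n", s, x$strata[[s]]$n,
                x$strata[[s]]$age_range[1], x$strata[[s]]$age_range[2]))
  invisible(x)
}

# quantile vector q(plevels) at a given sex and age, linear in age between
# window centers, clamped to the fitted center range; monotone in p
surface_at_age <- function(model, sex, age) {
  st <- model$strata[[sex]]
  if (is.null(st)) stop("unknown sex '", sex, "'", call. = FALSE)
  cn <- st$centers
  age <- min(max(age, cn[1]), cn[length(cn)])
  i <- findInterval(age, cn, rightmost.closed = TRUE)
  i <- max(1L, min(i, length(cn) - 1L))
  if (length(cn) == 1L) return(cummax(st$qmat[1, ]))
  w <- (age - cn[i]) / (cn[i + 1] - cn[i])
  cummax((1 - w) * st$qmat[i, ] + w * st$qmat[i + 1, ])
}

#' Evaluate the fitted quantile surface
#'
#' @param x a `cac_percentile_model`.
#' @param sex `"female"` or `"male"` (recycled against `age` and `percentile`).
#' @param age age in years; clamped to the fitted range.
#' @param percentile percentile level in percent; clamped to the fitted grid.
#' @param ... unused.
#' @return loge(CAC + 1) quantile value(s).
#' @export
quantile.cac_percentile_model <- function(x, sex, age, percentile, ...) {
  n <- max(length(sex), length(age), length(percentile))
  sex <- rep_len(as.character(sex), n)
  age <- rep_len(age, n); percentile <- rep_len(percentile, n)
  pl <- x$plevels
  vapply(seq_len(n), function(k) {
    q <- surface_at_age(x, sex[k], age[k])
    p <- min(max(percentile[k], pl[1]), pl[length(pl)])
    stats::approx(pl, q, xout = p, rule = 2)$y
  }, numeric(1))
}

#' Baseline CAC percentile of an individual
#'
#' Inverts the fitted quantile surface at the individual's sex and baseline
#' age: the percentile level whose quantile equals the observed
#' log(CAC_b + 1). Values outside the fitted surface clamp to
#' \[0.5, 99.5\]. Individuals with CAC_b = 0 sit on the zero mass point; they
#' are assigned the midpoint of the zero-mass probability interval for their
#' sex and age (deterministic, since any point of the interval is
#' consistent). Ties at positive values likewise resolve to the midpoint of
#' the flat stretch of the quantile function.
#'
#' @param model a `cac_percentile_model`.
#' @param sex,age_b,log_cac_b vectors (recycled) of sex, baseline age and
#'   observed loge(CAC_b + 1).
#' @return Percentile level(s) in percent.
#' @export
baseline_percentile <- function(model, sex, age_b, log_cac_b) {
  n <- max(length(sex), length(age_b), length(log_cac_b))
  sex <- rep_len(as.character(sex), n)
  age_b <- rep_len(age_b, n); log_cac_b <- rep_len(log_cac_b, n)
  pl <- model$plevels
  vapply(seq_len(n), function(k) {
    q <- surface_at_age(model, sex[k], age_b[k])
    v <- log_cac_b[k]
    if (v <= 0) {                      # zero mass point
      if (q[1] > 1e-9) return(0.5)     # no zero mass in this window
      j <- max(which(q <= 1e-9))
      p_hi <- if (j == length(q)) pl[j] else {
        # interpolate the right edge of the zero-mass interval
        pl[j] + (pl[j + 1] - pl[j]) * (0 - q[j]) / (q[j + 1] - q[j])
      }
      return(max(p_hi / 2, 0))         # midpoint of [0, p_hi]
    }
    if (v <= q[1]) return(pl[1])
    if (v >= q[length(q)]) return(pl[length(pl)])
    eq <- abs(q - v) < 1e-12
    if (any(eq)) return((pl[min(which(eq))] + pl[max(which(eq))]) / 2)
    j <- max(which(q < v))
    pl[j] + (pl[j + 1] - pl[j]) * (v - q[j]) / (q[j + 1] - q[j])
  }, numeric(1))
}

#' Expected log(CAC + 1) at follow-up under percentile tracking
#'
#' Carries an individual's baseline CAC percentile forward in age for the
#' time between scans and reads the fitted quantile surface at the attained
#' age: the CAC a person is expected to have if they stay on their
#' age-conditional percentile. Attained ages beyond the fitted range clamp
#' to the range edge.
#'
#' @param model a `cac_percentile_model`.
#' @param sex,age_b,percentile_b,t_years vectors (recycled) of sex, baseline
#'   age, baseline percentile (percent) and inter-scan time (years).
#' @return Expected loge(CAC_5y + 1) value(s).
#' @export
expected_log_cac_5y <- function(model, sex, age_b, percentile_b, t_years) {
  quantile(model, sex = sex, age = age_b + t_years, percentile = percentile_b)
}
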
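# Check-loss (pinball) linear quantile regression, fitted by a
# majorize-minimize sequence of weighted least-squares solves with a
# shrinking smoothing parameter. Small designs only (the association models
# here have at most ~15 columns), where this route is simple, dependency-free
# and accurate to the stated objective tolerance.

check_loss <- function(r, tau) sum(r * (tau - (r < 0)))

rq_fit <- function(X, y, tau = 0.75, tol = 1e-8, max_iter = 2000L) {
  y <- as.numeric(y)
  stopifnot(tau > 0, tau < 1, nrow(X) == length(y))
  X <- as.matrix(X)
  beta <- qr.coef(qr(X), y)                       # OLS start
  beta[is.na(beta)] <- 0
  r <- y - as.numeric(X %*% beta)
  scale <- max(stats::sd(y), 1e-6)
  # stationarity of the smoothed surrogate: X'W(y - Xb) = (2 tau - 1) X'1
  shift <- (2 * tau - 1) * colSums(X)
  iter <- 0L
  eps_seq <- scale * 10^seq(-2, -8, by = -2)
  converged <- FALSE
  for (eps in eps_seq) {
    stage_iter <- 0L
    repeat {
      iter <- iter + 1L; stage_iter <- stage_iter + 1L
      w <- 1 / (abs(r) + eps)
      XtW <- t(X * w)
      beta_new <- tryCatch(
        as.numeric(solve(XtW %*% X, XtW %*% y + shift)),
        error = function(e)
          stop("quantile regression failed: singular weighted system at ",
               "iteration ", iter, " (eps = ", signif(eps, 3), ")",
               call. = FALSE))
      step <- max(abs(beta_new - beta))
      beta <- beta_new
      r <- y - as.numeric(X %*% beta)
      if (step < 1e-9 * (1 + max(abs(beta)))) { converged <- TRUE; break }
      converged <- FALSE
      if (stage_iter >= max_iter) break      # shrink eps and keep going
    }
  }
  obj <- check_loss(r, tau)
  # polish: the exact minimizer interpolates p observations, which the
  # smoothed solution approaches; snap to the p smallest-|residual| points
  p <- ncol(X)
  idx <- order(abs(r))[seq_len(p)]
  snap <- tryCatch(solve(X[idx, , drop = FALSE], y[idx]),
                   error = function(e) NULL)
  if (!is.null(snap) && all(is.finite(snap))) {
    r_snap <- y - as.numeric(X %*% snap)
    if (check_loss(r_snap, tau) <= obj) {
      beta <- as.numeric(snap); r <- r_snap; obj <- check_loss(r_snap, tau)
    }
  }
  # optimality certificate: at a minimizer the share of strictly negative
  # residuals lies in [tau - p/n, tau]
  frac_neg <- mean(r < 0)
  cert <- frac_neg >= tau - p / length(y) - 1e-10 && frac_neg <= tau + 1e-10
  if (!converged && !cert)
    stop("quantile regression did not converge (objective ",
         signif(obj, 6), ", negative-residual share ", signif(frac_neg, 4),
         " outside [", signif(tau - p / length(y), 4), ", ", tau,
         "]); the design may be ill-conditioned", call. = FALSE)
  names(beta) <- colnames(X)
  list(coefficients = beta, residuals = r, objective = obj, tau = tau,
       iterations = iter)
}

rq_boot_ci <- function(X, y, tau, coef_hat, B = 500L, level = 0.95,
                       seed = NULL) {
  n <- nrow(X)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  draws <- matrix(NA_real_, B, length(coef_hat))
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    fit <- tryCatch(rq_fit(X[idx, , drop = FALSE], y[idx], tau),
                    error = function(e) NULL)
    if (!is.null(fit)) draws[b, ] <- fit$coefficients
  }
  ok <- stats::complete.cases(draws)
  if (sum(ok) < B * 0.5)
    stop("quantile-regression bootstrap failed in more than half of the ",
         "resamples", call. = FALSE)
  a <- (1 - level) / 2
  list(ci = t(apply(draws[ok, , drop = FALSE], 2, stats::quantile,
                    probs = c(a, 1 - a), type = 7, names = FALSE)),
       se = apply(draws[ok, , drop = FALSE], 2, stats::sd),
       n_boot = sum(ok))
}
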
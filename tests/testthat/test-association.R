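test_that("OLS coefficients match a normal-equations brute-force solve", {
  set.seed(2)
  for (rep in 1:5) {
    n <- sample(20:50, 1)
    p <- sample(2:5, 1)
    X <- cbind(matrix(rnorm(n * (p - 1)), n), sample(0:1, n, TRUE))
    colnames(X) <- paste0("x", seq_len(p))
    y <- rnorm(n)
    d <- data.frame(y = y, X)
    fit <- cac_assoc(d, outcome = "y", exposure = "x1",
                     covariates = colnames(X)[-1])
    Xd <- cbind(1, X)
    beta_oracle <- solve(t(Xd) %*% Xd, t(Xd) %*% y)
    expect_equal(unname(coef(fit)), as.numeric(beta_oracle),
                 tolerance = 1e-8)
  }
})

test_that("percent transformation round-trips and preserves ordering", {
  expect_equal(percent_scale(0)$pct, 0)
  expect_equal(percent_scale(log(1.097))$pct, 9.7, tolerance = 1e-12)
  expect_equal(percent_scale(-0.1)$pct, -9.516258, tolerance = 1e-6)
  b <- c(-0.4, -0.01, 0, 0.0926, 1.2)
  expect_equal(percent_to_log(percent_scale(b)$pct), b, tolerance = 1e-12)
  p <- percent_scale(0.0926, 0.0507, 0.1354)
  expect_true(p$pct_low < p$pct && p$pct < p$pct_high)
})

test_that("delta R-squared is non-negative for nested models, zero on self", {
  set.seed(14)
  d <- simulate_analysis_table(1500, beta_per_sd = 0.05)
  full <- cac_assoc(d, outcome = "dev", exposure = "z", covariates = "base")
  expect_gte(full$delta_r2, -1e-10)
  base_lm <- lm(dev ~ age_b + sex + log_cac_b, data = d)
  full_lm <- lm(dev ~ z + age_b + sex + log_cac_b, data = d)
  expect_equal(full$delta_r2, delta_r2(full_lm, base_lm), tolerance = 1e-10)
  expect_equal(delta_r2(base_lm, base_lm), 0)
  # pure-noise additions stay tiny
  d$junk <- rnorm(nrow(d))
  noise_fit <- cac_assoc(d, outcome = "dev", exposure = "junk",
                         covariates = "base")
  expect_gte(noise_fit$delta_r2, 0)
  expect_lt(noise_fit$delta_r2, 0.5)
  # different rows are refused
  expect_error(delta_r2(full_lm, lm(dev ~ age_b, data = d[-1, ])),
               "different rows")
})

test_that("a planted 0.6%-variance exposure is recovered as delta R2 ~ 0.6", {
  set.seed(26)
  dr2 <- replicate(60, {
    d <- simulate_analysis_table(3097, beta_per_sd = log(1.097))
    cac_assoc(d, outcome = "dev", exposure = "z",
              covariates = "base")$delta_r2
  })
  expect_equal(mean(dr2), 0.6, tolerance = 0.3 / 0.6)
})

test_that("Bonferroni threshold is alpha/m with a one-significant-figure display", {
  bf <- bonferroni_threshold(0.05, 11)
  expect_equal(bf$threshold, 0.05 / 11)
  expect_equal(bf$display, 0.005)
  expect_equal(bonferroni_threshold(0.05, 1)$threshold, 0.05)
  expect_equal(bonferroni_threshold(0.05, 10)$threshold, 0.005)
})

test_that("rank-deficient designs and duplicate terms are hard errors", {
  set.seed(3)
  d <- data.frame(y = rnorm(30), a = rnorm(30))
  d$b <- d$a
  expect_error(cac_assoc(d, outcome = "y", exposure = "a",
                         covariates = "b"), "collinear")
  expect_error(cac_assoc(d, outcome = "y", exposure = "a",
                         covariates = c("a", "b")), "duplicated")
})

test_that("listwise deletion drops incomplete rows and records the count", {
  set.seed(6)
  d <- simulate_analysis_table(200, beta_per_sd = 0)
  d$z[c(3, 10)] <- NA
  fit <- cac_assoc(d, outcome = "dev", exposure = "z", covariates = "base")
  expect_equal(fit$n, 198L)
  expect_equal(fit$n_dropped, 2L)
})

test_that("the planted per-SD effect is recovered with nominal CI coverage", {
  set.seed(18)
  beta <- log(1.097)
  reps <- 250
  out <- vapply(seq_len(reps), function(i) {
    d <- simulate_analysis_table(3097, beta_per_sd = beta)
    f <- cac_assoc(d, outcome = "dev", exposure = "z", covariates = "base")
    r <- f$terms[f$terms$term == "z", ]
    c(r$pct_effect, r$ci_low <= beta && beta <= r$ci_high)
  }, numeric(2))
  expect_equal(mean(out[1, ]), 9.7, tolerance = 0.5 / 9.7)
  expect_gte(mean(out[2, ]), 0.92)
  expect_lte(mean(out[2, ]), 0.98)
})

test_that("null-exposure p-values are uniform", {
  set.seed(19)
  ps <- replicate(200, {
    d <- simulate_analysis_table(250, beta_per_sd = 0)
    f <- cac_assoc(d, outcome = "dev", exposure = "z", covariates = "base")
    f$terms$p[f$terms$term == "z"]
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("robust HC3 errors match classical ones under homoscedasticity", {
  set.seed(23)
  d <- simulate_analysis_table(3000, beta_per_sd = 0.05)
  ols <- cac_assoc(d, outcome = "dev", exposure = "z", covariates = "base")
  rob <- cac_assoc(d, outcome = "dev", exposure = "z", covariates = "base",
                   estimator = "robust")
  # identical point estimates, standard errors within 10%
  expect_equal(coef(rob), coef(ols))
  i <- match("z", ols$terms$term)
  expect_lt(abs(rob$terms$se[i] / ols$terms$se[i] - 1), 0.10)
})

test_that("robust intervals keep coverage under strong heteroscedasticity", {
  set.seed(24)
  reps <- 250
  cover <- vapply(seq_len(reps), function(i) {
    n <- 400
    x <- runif(n, 0, 3)
    y <- 0.5 * x + rnorm(n, 0, 0.3 + x^2)   # variance grows with x
    d <- data.frame(y = y, x = x)
    cl <- cac_assoc(d, outcome = "y", exposure = "x", covariates = NULL)
    rb <- cac_assoc(d, outcome = "y", exposure = "x", covariates = NULL,
                    estimator = "robust")
    ic <- match("x", cl$terms$term)
    c(classical = cl$terms$ci_low[ic] <= 0.5 & 0.5 <= cl$terms$ci_high[ic],
      robust = rb$terms$ci_low[ic] <= 0.5 & 0.5 <= rb$terms$ci_high[ic])
  }, logical(2))
  expect_gte(mean(cover["robust", ]), 0.92)
  expect_gt(mean(cover["robust", ]), mean(cover["classical", ]))
})

test_that("quantile regression solves the check-loss problem", {
  set.seed(33)
  # intercept-only fit at tau = 0.75 is the sample 75th percentile
  y <- rnorm(101)
  X <- matrix(1, 101, 1, dimnames = list(NULL, "(Intercept)"))
  fit <- cacprog:::rq_fit(X, y, tau = 0.75)
  expect_equal(unname(fit$coefficients),
               unname(quantile(y, 0.75, type = 1)), tolerance = 1e-6)
  # objective at the optimum is no worse than the OLS solution's check loss
  n <- 80
  X2 <- cbind(1, rnorm(n), runif(n)); colnames(X2) <- c("i", "a", "b")
  y2 <- X2 %*% c(1, 0.5, -0.2) + rt(n, 3)
  f2 <- cacprog:::rq_fit(X2, y2, tau = 0.75)
  ols <- qr.coef(qr(X2), y2)
  expect_lte(f2$objective,
             cacprog:::check_loss(y2 - X2 %*% ols, 0.75) + 1e-8)
  # subgradient condition: share of negative residuals in [tau - k/n, tau]
  frac_neg <- mean(f2$residuals < 0)
  expect_gte(frac_neg, 0.75 - ncol(X2) / n - 1e-8)
  expect_lte(frac_neg, 0.75 + 1e-8)
})

test_that("quantile regression matches brute-force enumeration on small fits", {
  # the exact minimizer interpolates p observations; enumerate all of them
  set.seed(34)
  for (rep in 1:3) {
    n <- 25
    x <- rnorm(n); y <- 1 + 0.8 * x + rt(n, 2)
    X <- cbind(1, x)
    best <- Inf
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (abs(x[i] - x[j]) < 1e-12) next
      sl <- (y[i] - y[j]) / (x[i] - x[j]); ic <- y[i] - sl * x[i]
      best <- min(best, cacprog:::check_loss(y - ic - sl * x, 0.75))
    }
    fit <- cacprog:::rq_fit(X, y, tau = 0.75)
    expect_equal(fit$objective, best, tolerance = 1e-6)
  }
})

test_that("median regression agrees with OLS under symmetric noise", {
  set.seed(35)
  d <- simulate_analysis_table(1200, beta_per_sd = 0.3, noise_sd = 0.8)
  q <- cac_assoc(d, outcome = "dev", exposure = "z", covariates = "base",
                 estimator = "quantile", tau = 0.5, boot = 200, seed = 9)
  o <- cac_assoc(d, outcome = "dev", exposure = "z", covariates = "base")
  i <- match("z", q$terms$term)
  expect_lt(abs(q$terms$beta_log[i] - o$terms$beta_log[i]),
            2 * q$terms$se[i])
  # bootstrap intervals are seeded and reproducible
  q2 <- cac_assoc(d, outcome = "dev", exposure = "z", covariates = "base",
                  estimator = "quantile", tau = 0.5, boot = 200, seed = 9)
  expect_equal(q$terms, q2$terms)
})

test_that("quartile contrasts code medium and high against the low quartile", {
  set.seed(41)
  n <- 2000
  z <- rnorm(n)
  grp <- quartile_groups(z)
  d <- simulate_analysis_table(n, beta_per_sd = 0, grs_z = z)
  d$dev <- d$dev + 0.15 * (grp == "medium") + log(1.263) * (grp == "high")
  fit <- fit_quartile_contrast(d, outcome = "dev", groups = grp,
                               covariates = "base")
  tab <- fit$terms
  expect_setequal(setdiff(tab$term, "(Intercept)")[1:2],
                  c("grs_groupmedium", "grs_grouphigh"))
  hi <- tab[tab$term == "grs_grouphigh", ]
  expect_lt(abs(hi$beta_log - log(1.263)), 2.5 * hi$se)
  expect_gt(tab$pct_effect[tab$term == "grs_grouphigh"],
            tab$pct_effect[tab$term == "grs_groupmedium"])
  grp_bad <- factor(rep("low", n), levels = c("low", "medium", "high"))
  expect_error(fit_quartile_contrast(d, outcome = "dev", groups = grp_bad),
               "empty quartile")
})

test_that("a monotone planted dose effect orders the quartile contrasts", {
  set.seed(43)
  hits <- replicate(40, {
    n <- 800
    z <- rnorm(n)
    d <- simulate_analysis_table(n, beta_per_sd = 0.25, grs_z = z,
                                 noise_sd = 0.6)
    fit <- fit_quartile_contrast(d, outcome = "dev",
                                 groups = quartile_groups(z),
                                 covariates = "base")
    tab <- fit$terms
    hi <- tab$pct_effect[tab$term == "grs_grouphigh"]
    me <- tab$pct_effect[tab$term == "grs_groupmedium"]
    hi > me && me > 0
  })
  expect_gte(mean(hits), 0.9)
})

test_that("per-SNP scans reduce to single-exposure fits and flag monomorphs", {
  set.seed(51)
  n <- 500
  freq <- c(rsA = 0.3, rsB = 0.5)
  g <- simulate_genotypes(n, freq)
  d <- simulate_analysis_table(n, beta_per_sd = 0)
  d$dev <- d$dev + 0.2 * g$dosage[, "rsA"]
  scan <- per_snp_scan(g, d, outcome = "dev")
  expect_equal(nrow(scan), 2L)
  d$.snp <- g$dosage[, "rsA"]
  single <- cac_assoc(d, outcome = "dev", exposure = ".snp",
                      covariates = "base")
  expect_equal(scan$beta_log[scan$rsid == "rsA"],
               single$terms$beta_log[single$terms$term == ".snp"])
  # monomorphic SNP skipped and excluded from the denominator
  g2 <- g; g2$dosage[, "rsB"] <- 0
  expect_warning(scan2 <- per_snp_scan(g2, d, outcome = "dev"),
                 "monomorphic")
  expect_equal(nrow(scan2), 1L)
  expect_equal(attr(scan2, "fraction_positive_significant"), 1)
})

test_that("null per-SNP scans are calibrated near the one-sided nominal rate", {
  set.seed(52)
  hits <- unlist(lapply(1:30, function(i) {
    g <- simulate_genotypes(400, setNames(runif(20, 0.2, 0.8),
                                          paste0("rs", 1:20)))
    d <- simulate_analysis_table(400, beta_per_sd = 0)
    scan <- per_snp_scan(g, d, outcome = "dev")
    scan$p < 0.05 & scan$beta_log > 0
  }))
  rate <- mean(hits)   # expect ~2.5% (two-sided 5% halved by direction)
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.055)
})
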
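# Synthetic study generator. Defaults emulate a population-based cardiac-CT
# cohort: ~3,000 participants aged 45-75, 52.6% women, zero-inflated
# right-skewed baseline Agatston scores (median ~7.2, Q1 0, Q3 ~91.8),
# inter-scan time 5.1 +/- 0.3 years, Hardy-Weinberg genotypes for trait
# panels of 3-70 SNPs, and loge-scale planted per-SD score effects on the
# progression endpoints.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate a SNP weight panel
#'
#' Draws a synthetic trait panel: rsids, alleles (strand-ambiguous A/T and
#' C/G pairs avoided unless requested), zero-mean weights scaled by
#' `weight_scale`, and true effect-allele frequencies.
#'
#' @param trait trait label.
#' @param m_snps number of SNPs (>= 1).
#' @param maf_range range the true effect-allele frequencies are drawn from.
#' @param weight_scale standard deviation of the per-SNP weights; 0 gives an
#'   all-zero (null) panel.
#' @param allow_ambiguous also draw strand-ambiguous allele pairs
#'   (default `FALSE`).
#' @param rsid_prefix prefix for the synthetic rsids.
#' @param seed optional seed (the caller's RNG state is restored).
#' @return List with `panel` (a [snp_panel()]) and `freq` (true frequencies).
#' @export
simulate_panel <- function(trait, m_snps, maf_range = c(0.10, 0.90),
                           weight_scale = 0.1, allow_ambiguous = FALSE,
                           rsid_prefix = paste0("rs", trait), seed = NULL) {
  stopifnot(m_snps >= 1)
  with_seed(seed, {
    pairs <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                  c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
    if (allow_ambiguous)
      pairs <- c(pairs, list(c("A", "T"), c("C", "G")))
    al <- pairs[sample.int(length(pairs), m_snps, replace = TRUE)]
    panel <- snp_panel(
      rsid = sprintf("%s_%03d", rsid_prefix, seq_len(m_snps)),
      chrom = as.character(sample.int(22, m_snps, replace = TRUE)),
      pos = sample.int(2.5e8, m_snps),
      effect_allele = vapply(al, `[`, "", 1L),
      other_allele = vapply(al, `[`, "", 2L),
      weight = if (weight_scale == 0) rep(0, m_snps)
               else stats::rnorm(m_snps, 0, weight_scale),
      trait = trait)
    list(panel = panel,
         freq = stats::setNames(stats::runif(m_snps, maf_range[1],
                                             maf_range[2]), panel$rsid))
  })
}

#' Simulate hard-called genotype dosages under Hardy-Weinberg equilibrium
#'
#' Dosages are drawn binomial(2, p) per SNP, independently across SNPs
#' (no linkage disequilibrium), with completely-at-random missingness.
#'
#' @param n number of individuals.
#' @param freq named vector of effect-allele frequencies in (0, 1); names
#'   become the rsids.
#' @param panel optional `snp_panel` supplying allele labels for the columns
#'   (by rsid); defaults to A (counted) / G.
#' @param missing_rate fraction of entries set missing (default 0).
#' @param seed optional seed.
#' @return A [dosage_matrix()] counting the panel effect allele.
#' @export
simulate_genotypes <- function(n, freq, panel = NULL, missing_rate = 0,
                               seed = NULL) {
  stopifnot(all(freq > 0), all(freq < 1), missing_rate >= 0, missing_rate < 1)
  with_seed(seed, {
    m <- length(freq)
    d <- vapply(freq, function(p) stats::rbinom(n, 2L, p), numeric(n))
    if (n == 1L) d <- matrix(d, nrow = 1L)
    colnames(d) <- names(freq)
    rownames(d) <- sprintf("ind%05d", seq_len(n))
    if (missing_rate > 0)
      d[matrix(stats::runif(n * m) < missing_rate, n, m)] <- NA_real_
    if (!is.null(panel)) {
      i <- match(colnames(d), panel$rsid)
      if (anyNA(i)) stop("freq names not all present in panel", call. = FALSE)
      dosage_matrix(d, panel$effect_allele[i], panel$other_allele[i])
    } else {
      dosage_matrix(d, rep("A", m), rep("G", m))
    }
  })
}

default_cac_params <- function() {
  # zero-inflation probability pi(age, sex) on the logit scale and the
  # conditional normal law of log(CAC + 1) given CAC > 0; calibrated so the
  # marginal baseline distribution has median ~7.2, Q1 = 0, Q3 ~91.8
  list(zero_logit0 = -0.155,   # logit of P(CAC_b = 0) at age 60, female
       zero_age = 0.05,        # decrease per year of age (logit scale)
       zero_male = 0.90,       # male offset (logit scale)
       mu0 = 3.45,             # location of log(CAC+1) | CAC>0, age 60 female
       mu_age = 0.055,         # age drift per year (loge units)
       mu_male = 0.80,         # male offset (loge units)
       sigma = 2.17)           # scale of log(CAC+1) | CAC>0
}

cac_zero_prob <- function(age, male, pars) {
  stats::plogis(pars$zero_logit0 - pars$zero_age * (age - 60) -
                  pars$zero_male * male)
}

cac_surface_mu <- function(age, male, pars) {
  pars$mu0 + pars$mu_age * (age - 60) + pars$mu_male * male
}

# generating quantile surface: log(CAC+1) quantile at probability u; the
# conditional normal is floored at 0 (its negative tail joins the zero mass,
# so the surface is a valid non-negative, non-decreasing quantile function)
cac_surface_quantile <- function(u, age, male, pars) {
  pi0 <- cac_zero_prob(age, male, pars)
  pmax(0, ifelse(u <= pi0, 0,
                 cac_surface_mu(age, male, pars) +
                   pars$sigma * stats::qnorm(pmax((u - pi0) / (1 - pi0), 0))))
}

#' Simulate a longitudinal CAC cohort with known planted effects
#'
#' Generates demographics, risk factors and a pair of CAC scans. Baseline
#' CAC comes from a zero-inflated lognormal surface whose zero probability
#' falls, and whose location rises, with age and male sex. Follow-up CAC is
#' generated by exact percentile tracking on that generating surface (each
#' individual keeps their latent baseline percentile at the attained age)
#' and then perturbed on the loge scale by `beta_dev_per_sd * z` +
#' `(t/5) * beta_prog_per_sd * z` + Gaussian noise; negative latent values
#' are floored at CAC = 0, so the follow-up distribution keeps its zero
#' spike. The truth record stores every planted parameter and each
#' individual's latent percentile and noise-free expected value.
#'
#' @param n number of individuals (default 3097).
#' @param grs_z standardized score vector of length `n` used to plant the
#'   genetic effect (default all zero; see [standardize()]).
#' @param beta_dev_per_sd planted loge-scale effect per SD of `grs_z` on the
#'   deviation endpoint (default 0).
#' @param beta_prog_per_sd planted loge-scale effect per SD on the 5-year
#'   progression endpoint (default 0).
#' @param noise_sd loge-scale residual noise of the follow-up scan
#'   (default 1.15; see the package vignette for the calibration).
#' @param age_range,frac_female,t_mean,t_sd demographic margins (defaults:
#'   ages uniform on 45-75, 52.6% women, inter-scan time normal 5.1 +/- 0.3
#'   years truncated positive).
#' @param cac_params parameter list for the generating CAC surface; see
#'   `default_cac_params()` in the package source.
#' @param seed optional seed.
#' @return List with `cohort` (a data frame of phenotypes, one row per
#'   individual) and `truth` (planted parameters and per-individual latent
#'   quantities).
#' @export
simulate_cohort <- function(n = 3097, grs_z = NULL, beta_dev_per_sd = 0,
                            beta_prog_per_sd = 0, noise_sd = 1.15,
                            age_range = c(45, 75), frac_female = 0.526,
                            t_mean = 5.1, t_sd = 0.3,
                            cac_params = default_cac_params(), seed = NULL) {
  if (is.null(grs_z)) grs_z <- rep(0, n)
  stopifnot(length(grs_z) == n, t_mean > 0, frac_female >= 0, frac_female <= 1)
  with_seed(seed, {
    age <- stats::runif(n, age_range[1], age_range[2])
    male <- as.numeric(stats::runif(n) >= frac_female)
    t_years <- stats::rnorm(n, t_mean, t_sd)
    while (any(t_years <= 0))
      t_years[t_years <= 0] <- stats::rnorm(sum(t_years <= 0), t_mean, t_sd)
    u <- stats::runif(n)                       # latent lifetime percentile
    y_b <- cac_surface_quantile(u, age, male, cac_params)
    y_exp <- cac_surface_quantile(u, age + t_years, male, cac_params)
    noise <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
    y_5y <- pmax(0, y_exp + beta_dev_per_sd * grs_z +
                   (t_years / 5) * beta_prog_per_sd * grs_z + noise)
    smoking <- sample(c("never", "past", "current"), n, replace = TRUE,
                      prob = c(0.438, 0.332, 0.230))
    fh_known <- stats::runif(n) < 0.919
    cohort <- data.frame(
      id = sprintf("ind%05d", seq_len(n)),
      sex = ifelse(male == 1, "male", "female"),
      age_b = age,
      cac_b = expm1(y_b),
      cac_5y = expm1(y_5y),
      t_years = t_years,
      diabetes = stats::runif(n) < 0.112,
      bmi = stats::rnorm(n, 27.6, 4.3),
      sbp = stats::rnorm(n, 132.0, 20.0),
      dbp = stats::rnorm(n, 81.5, 10.6),
      ldl = stats::rnorm(n, 146.1, 36.0),
      hdl = stats::rnorm(n, 59.5, 17.3),
      smoking = factor(smoking, levels = c("never", "past", "current")),
      antihypertensive_med = stats::runif(n) < 0.304,
      lipid_med = stats::runif(n) < 0.095,
      ses_high = stats::runif(n) < 0.339,
      family_history_chd = ifelse(fh_known, stats::runif(n) < 0.20, NA),
      stringsAsFactors = FALSE)
    list(cohort = cohort,
         truth = list(beta_dev_per_sd = beta_dev_per_sd,
                      beta_prog_per_sd = beta_prog_per_sd,
                      noise_sd = noise_sd, cac_params = cac_params,
                      grs_z = grs_z, latent_percentile = u,
                      expected_log_cac_5y = y_exp, log_cac_b = y_b))
  })
}

#' Simulate an analysis table with a planted exposure effect
#'
#' Builds the covariate block of a cohort (age, sex, baseline log CAC from
#' the generating surface) plus a standardized exposure, and generates the
#' endpoint directly on the loge scale as a linear model:
#' `dev = intercept + gamma_age * age + gamma_male * male + gamma_lcb *
#' log_cac_b + beta_per_sd * z + N(0, noise_sd)`. This is the
#' regression-calibration companion of [simulate_cohort()]: the endpoint is
#' linear in the exposure by construction, so ordinary least squares is
#' unbiased for `beta_per_sd` and coverage can be audited exactly.
#'
#' @param n number of individuals.
#' @param beta_per_sd planted loge-scale effect per SD of the exposure.
#' @param noise_sd residual noise (loge units, default 1.15).
#' @param gamma covariate coefficients (intercept, per-year age, male,
#'   per-unit log(CAC_b + 1)).
#' @param grs_z optional standardized exposure (default standard normal).
#' @param seed optional seed.
#' @return Data frame with columns `dev`, `z`, `age_b`, `sex`, `log_cac_b`,
#'   with the planted parameters in attribute `truth`.
#' @export
simulate_analysis_table <- function(n, beta_per_sd, noise_sd = 1.15,
                                    gamma = c(intercept = -1.0,
                                              age = 0.0266, male = -0.185,
                                              log_cac_b = -0.093),
                                    grs_z = NULL, seed = NULL) {
  with_seed(seed, {
    age <- stats::runif(n, 45, 75)
    male <- as.numeric(stats::runif(n) >= 0.526)
    u <- stats::runif(n)
    lcb <- cac_surface_quantile(u, age, male, default_cac_params())
    z <- if (is.null(grs_z)) stats::rnorm(n) else grs_z
    dev <- gamma[["intercept"]] + gamma[["age"]] * age +
      gamma[["male"]] * male + gamma[["log_cac_b"]] * lcb +
      beta_per_sd * z + stats::rnorm(n, 0, noise_sd)
    structure(data.frame(dev = dev, z = z, age_b = age,
                         sex = ifelse(male == 1, "male", "female"),
                         log_cac_b = lcb, stringsAsFactors = FALSE),
              truth = list(beta_per_sd = beta_per_sd, noise_sd = noise_sd,
                           gamma = gamma))
  })
}

#' Panel sizes of the default 11-trait score family
#'
#' The default trait family used by [simulate_study()]: coronary artery
#' disease (70 SNPs), coronary artery calcification (3 SNPs, one shared with
#' the CAD panel), type 2 diabetes, body mass index, systolic/diastolic/pulse
#' blood pressure, and four lipid traits.
#'
#' @return Named integer vector of panel sizes.
#' @export
default_panel_sizes <- function() {
  c(CAD = 70L, CAC = 3L, T2D = 65L, BMI = 97L, SBP = 29L, DBP = 29L,
    PP = 29L, LDL = 57L, HDL = 71L, TG = 39L, TC = 74L)
}

#' Simulate a complete genetic study
#'
#' End-to-end generator: draws the trait weight panels (the CAC panel shares
#' its first SNP with the CAD panel, mirroring the known overlap between CAC
#' and CAD loci), Hardy-Weinberg genotypes, computes the standardized
#' weighted score for each trait, and generates the cohort with the planted
#' effect attached to the exposure score.
#'
#' @param n number of individuals (default 3097).
#' @param panel_sizes named vector of panel sizes
#'   (default [default_panel_sizes()]).
#' @param exposure_trait the trait whose score carries the planted effect
#'   (default `"CAD"`).
#' @param beta_dev_per_sd,beta_prog_per_sd,noise_sd planted effect and noise,
#'   as in [simulate_cohort()].
#' @param missing_rate genotype missingness (default 0.02).
#' @param seed optional seed.
#' @return List with `panels`, `genotypes` (per trait), `scores`
#'   (standardized `grs` per trait), `cohort`, and `truth`.
#' @export
simulate_study <- function(n = 3097, panel_sizes = default_panel_sizes(),
                           exposure_trait = "CAD", beta_dev_per_sd = 0,
                           beta_prog_per_sd = 0, noise_sd = 1.15,
                           missing_rate = 0.02, seed = NULL) {
  stopifnot(exposure_trait %in% names(panel_sizes))
  with_seed(seed, {
    panels <- list(); freqs <- list()
    for (tr in names(panel_sizes)) {
      sim <- simulate_panel(tr, panel_sizes[[tr]])
      panels[[tr]] <- sim$panel; freqs[[tr]] <- sim$freq
    }
    if (all(c("CAD", "CAC") %in% names(panels)) && nrow(panels$CAC) >= 1) {
      # share one locus between the CAC and CAD panels (same SNP, trait-
      # specific weight), like the 9p21 locus present in both score lists
      shared <- as.data.frame(panels$CAD)[1L, ]
      cac <- as.data.frame(panels$CAC)
      cac[1L, c("rsid", "chrom", "pos", "effect_allele", "other_allele")] <-
        shared[c("rsid", "chrom", "pos", "effect_allele", "other_allele")]
      panels$CAC <- snp_panel(cac$rsid, cac$chrom, cac$pos, cac$effect_allele,
                              cac$other_allele, cac$weight, trait = "CAC")
      freqs$CAC[1L] <- freqs$CAD[[shared$rsid]]
      names(freqs$CAC)[1L] <- shared$rsid
    }
    genotypes <- list(); scores <- list()
    for (tr in names(panels)) {
      g <- simulate_genotypes(n, freqs[[tr]], panel = panels[[tr]],
                              missing_rate = missing_rate)
      genotypes[[tr]] <- g
      scores[[tr]] <- standardize(weighted_grs(impute_missing(g),
                                               panels[[tr]]))
    }
    z <- scores[[exposure_trait]]$z_score
    sim <- simulate_cohort(n = n, grs_z = z,
                           beta_dev_per_sd = beta_dev_per_sd,
                           beta_prog_per_sd = beta_prog_per_sd,
                           noise_sd = noise_sd)
    sim$truth$exposure_trait <- exposure_trait
    list(panels = panels, genotypes = genotypes, scores = scores,
         cohort = sim$cohort, truth = sim$truth)
  })
}
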
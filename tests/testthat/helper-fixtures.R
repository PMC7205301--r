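# Small in-code fixtures shared across the test files.

make_panel <- function(weights = c(0.2, -0.1, 0.05), trait = "CAD",
                       effect = c("A", "C", "G"), other = c("G", "T", "A")) {
  m <- length(weights)
  snp_panel(rsid = paste0("rs", seq_len(m)),
            chrom = as.character(seq_len(m)),
            pos = 100L * seq_len(m),
            effect_allele = rep_len(effect, m),
            other_allele = rep_len(other, m),
            weight = weights, trait = trait)
}

make_dosages <- function(d, panel, ids = NULL) {
  d <- as.matrix(d)
  colnames(d) <- panel$rsid
  if (!is.null(ids)) rownames(d) <- ids
  dosage_matrix(d, panel$effect_allele, panel$other_allele)
}

# cohort whose log(CAC_b + 1) has exactly linear quantiles in age:
# y = a + b * age + s * qnorm(p); used as a closed-form oracle for the
# percentile surface
linear_surface_cohort <- function(n_per_sex = 4000, a = 0.5, b = 0.04,
                                  s = 0.8, seed = 42) {
  set.seed(seed)
  out <- do.call(rbind, lapply(c("female", "male"), function(sx) {
    age <- runif(n_per_sex, 45, 75)
    p <- runif(n_per_sex)
    data.frame(id = paste0(sx, seq_len(n_per_sex)), sex = sx, age_b = age,
               log_cac_b = a + b * age + s * qnorm(p), true_p = p,
               stringsAsFactors = FALSE)
  }))
  attr(out, "surface") <- function(age, p) a + b * age + s * qnorm(p)
  out
}
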
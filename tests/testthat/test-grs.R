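test_that("panel construction enforces its invariants", {
  expect_error(make_panel(effect = c("A", "C", "G"), other = c("A", "T", "A")),
               "effect allele equals other")
  expect_error(snp_panel("rs1", "1", 1L, "A", "G", NaN, "CAD"), "non-finite")
  expect_error(
    snp_panel(c("rs1", "rs1"), c("1", "1"), c(1L, 2L), c("A", "A"),
              c("G", "G"), c(0.1, 0.2), "CAD"),
    "duplicated")
})

test_that("dosage orientation counts the panel effect allele", {
  # genotype stores ref = A / alt = G and counts the ALT allele
  g_panel <- make_panel(weights = c(0, 0, 0), effect = c("G", "G", "G"),
                        other = c("A", "A", "A"))
  d <- make_dosages(rbind(c(1, 2, 0)), g_panel)

  # panel effect allele G: identity orientation
  p_same <- make_panel(weights = c(0.1, 0.1, 0.1), effect = c("G", "G", "G"),
                       other = c("A", "A", "A"))
  expect_equal(unname(align_dosages(d, p_same)$dosage[1, ]), c(1, 2, 0))

  # panel effect allele A: flipped, dosage becomes 2 - alt count
  p_flip <- make_panel(weights = c(0.1, 0.1, 0.1), effect = c("A", "A", "A"),
                       other = c("G", "G", "G"))
  expect_equal(unname(align_dosages(d, p_flip)$dosage[1, ]), c(1, 0, 2))

  # complementary-strand labels (T/C vs A/G) are matched via complement
  p_comp <- make_panel(weights = c(0.1, 0.1, 0.1), effect = c("C", "C", "C"),
                       other = c("T", "T", "T"))
  expect_equal(unname(align_dosages(d, p_comp)$dosage[1, ]), c(1, 2, 0))
})

test_that("unmatched, ambiguous and absent SNPs are dropped with warnings", {
  g_panel <- snp_panel(c("rs1", "rs2", "rs3"), c("1", "1", "1"),
                       c(1L, 2L, 3L), c("A", "A", "C"), c("G", "T", "G"),
                       c(0, 0, 0), "x")
  d <- make_dosages(rbind(c(2, 1, 0), c(0, 1, 2)), g_panel)
  # rs2 (A/T) and rs3 (C/G) are strand-ambiguous: kept only on exact label
  # match; rs4 is absent from the genotypes entirely
  p <- snp_panel(c("rs1", "rs2", "rs3", "rs4"), c("1", "1", "1", "1"),
                 1:4, c("A", "T", "C", "A"), c("G", "A", "G", "G"),
                 c(0.1, 0.1, 0.1, 0.1), "x")
  expect_warning(out <- align_dosages(d, p), "absent")
  expect_setequal(colnames(out$dosage), c("rs1", "rs2", "rs3"))
  # ambiguous rs2 with panel alleles T/A matches by direct flip
  expect_equal(unname(out$dosage[, "rs2"]), c(1, 1))
  # fully unmatchable ambiguous labels are dropped
  p_bad <- snp_panel("rs2", "1", 2L, "C", "G", 0.1, "x")
  expect_warning(expect_error(align_dosages(d, p_bad), "no usable"),
                 "unmatchable|absent")
})

test_that("LD pruning keeps one SNP per high-LD pair, deterministically", {
  p <- make_panel(weights = c(0.10, 0.05, 0.2))
  full_ld <- function(pairs) {
    r2 <- dp <- diag(3); dimnames(r2) <- dimnames(dp) <- NULL
    for (pr in pairs) {
      r2[pr$i, pr$j] <- r2[pr$j, pr$i] <- pr$r2
      dp[pr$i, pr$j] <- dp[pr$j, pr$i] <- pr$dp
    }
    r2[r2 == 0] <- 0.01; dp[dp == 0] <- 0.2; diag(r2) <- diag(dp) <- 1
    ld_matrix(p$rsid, r2, dp)
  }
  # d' = 1 and r2 = 0.95: keep the larger-|weight| member (rs1, 0.10 > 0.05)
  ld <- full_ld(list(list(i = 1, j = 2, r2 = 0.95, dp = 1)))
  pruned <- prune_ld(p, ld)
  expect_setequal(pruned$rsid, c("rs1", "rs3"))
  expect_true(attr(pruned, "ld_pruned"))
  # r2 = 0.32 at d' = 1: both kept (below the 0.80 threshold)
  expect_equal(nrow(prune_ld(p, full_ld(list(list(i = 1, j = 2, r2 = 0.32,
                                                  dp = 1))))), 3L)
  # r2 = 0.85 but d' = 0.9: both kept (rule requires d' = 1)
  expect_equal(nrow(prune_ld(p, full_ld(list(list(i = 1, j = 2, r2 = 0.85,
                                                  dp = 0.9))))), 3L)
  # idempotence: pruning a pruned panel changes nothing
  expect_equal(as.data.frame(prune_ld(pruned, ld)), as.data.frame(pruned))
  # missing LD entry for a needed pair is a hard error
  r2 <- dp <- diag(3); r2[1, 2] <- r2[2, 1] <- NA; dp[1, 2] <- dp[2, 1] <- NA
  r2[r2 == 0] <- 0.1; dp[dp == 0] <- 0.1; diag(r2) <- diag(dp) <- 1
  expect_error(prune_ld(p, ld_matrix(p$rsid, r2, dp)), "missing LD entry")
})

test_that("missing dosages are imputed with the expected value 2p", {
  p <- make_panel(weights = c(0.1, 0.1), effect = c("A", "C"),
                  other = c("G", "T"))
  d <- rbind(c(1, 0), c(NA, 0), c(2, 0), c(NA, 0))
  colnames(d) <- p$rsid
  x <- dosage_matrix(d, p$effect_allele, p$other_allele)
  # column 1 frequency from non-missing entries: (1 + 2) / (2 * 2) = 0.75
  expect_equal(unname(effect_allele_freq(x)), c(0.75, 0))
  imp <- impute_missing(x)
  expect_equal(unname(imp$dosage[c(2, 4), 1]), c(1.5, 1.5))
  # monomorphic zero-frequency column imputes to 0; observed entries untouched
  expect_equal(unname(imp$dosage[, 2]), c(0, 0, 0, 0))
  expect_equal(imp$dosage[c(1, 3), 1], x$dosage[c(1, 3), 1])
  # no missing entries: identity
  full <- make_dosages(rbind(c(1, 0), c(2, 2)), p)
  expect_equal(impute_missing(full)$dosage, full$dosage)
  # a column with no observed genotypes cannot be imputed
  allna <- rbind(c(NA, 1), c(NA, 0)); colnames(allna) <- p$rsid
  expect_error(impute_missing(dosage_matrix(allna, p$effect_allele,
                                            p$other_allele)),
               "no observed genotypes")
})

test_that("imputation is unbiased for the true allele frequency", {
  set.seed(101)
  n <- 4000; p_true <- 0.3
  g <- simulate_genotypes(n, c(rsX = p_true), missing_rate = 0.3)
  imp <- impute_missing(g)
  was_missing <- is.na(g$dosage[, 1])
  se <- sqrt(2 * p_true * (1 - p_true) / sum(!was_missing))
  expect_lt(abs(mean(imp$dosage[was_missing, 1]) - 2 * p_true), 3 * se)
})

test_that("weighted scores are the weight-dosage products averaged over SNPs", {
  p <- make_panel(weights = c(0.2, -0.1, 0.05))
  d <- make_dosages(rbind(c(2, 1, 0), c(0, 0, 0), c(2, 2, 2)), p)
  g <- weighted_grs(d, p)
  expect_equal(g$raw_score, c((0.4 - 0.1) / 3, 0, 2 * 0.15 / 3))
  # single SNP, dosage 2 -> 2w
  p1 <- make_panel(weights = 0.07)
  expect_equal(weighted_grs(make_dosages(matrix(2), p1), p1)$raw_score, 0.14)
  # linearity in the weights
  p2 <- make_panel(weights = 3 * c(0.2, -0.1, 0.05))
  expect_equal(weighted_grs(d, p2)$raw_score, 3 * g$raw_score)
  # unimputed matrices are rejected
  dm <- rbind(c(2, 1, NA)); colnames(dm) <- p$rsid
  expect_error(weighted_grs(dosage_matrix(dm, p$effect_allele,
                                          p$other_allele), p),
               "impute_missing")
})

test_that("unweighted scores are mean dosages and match unit-weight scores", {
  p <- make_panel(weights = c(0.2, -0.1, 0.05))
  d <- make_dosages(rbind(c(2, 1, 0), c(2, 2, 2)), p)
  u <- unweighted_grs(d, p)
  expect_equal(u$raw_score, c(1, 2))
  expect_false(attr(u, "weighted"))
  p_ones <- make_panel(weights = c(1, 1, 1))
  expect_equal(weighted_grs(d, p_ones)$raw_score, u$raw_score)
})

test_that("combining disjoint panels averages scores by panel size", {
  set.seed(7)
  p1 <- make_panel(weights = rnorm(5, 0, 0.1), trait = "A")
  p2 <- snp_panel(paste0("rsB", 1:3), "2", 1:3, "C", "T",
                  rnorm(3, 0, 0.1), "B")
  comb <- combine_panels(p1, p2, trait = "AB")
  expect_equal(nrow(comb), 8L)
  freqs <- setNames(runif(8, 0.2, 0.8), comb$rsid)
  g <- simulate_genotypes(50, freqs, panel = comb)
  s1 <- weighted_grs(align_dosages(g, p1), p1)$raw_score
  s2 <- weighted_grs(align_dosages(g, p2), p2)$raw_score
  sc <- weighted_grs(g, comb)$raw_score
  expect_equal(sc, (5 * s1 + 3 * s2) / 8)
})

test_that("standardization gives mean zero, unit variance, and is affine-invariant", {
  g <- structure(data.frame(id = c("a", "b", "c"), raw_score = c(1, 2, 3)),
                 trait = "x", weighted = TRUE, class = c("grs", "data.frame"))
  z <- standardize(g)
  expect_equal(z$z_score, c(-1, 0, 1))
  set.seed(5)
  g$raw_score <- rnorm(3)
  z <- standardize(g)$z_score
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(sd(z), 1, tolerance = 1e-10)
  g2 <- g; g2$raw_score <- 3 * g$raw_score + 10   # location-scale invariance
  expect_equal(standardize(g2)$z_score, z)
  g$raw_score <- rep(1, 3)
  expect_error(standardize(g), "degenerate")
})

test_that("quartile groups split low / medium (Q2+Q3) / high", {
  gr <- quartile_groups(1:8)
  expect_equal(as.character(gr),
               c("low", "low", "medium", "medium", "medium", "medium",
                 "high", "high"))
  gr4 <- quartile_groups(c(10, 20, 30, 40))
  expect_equal(table(gr4)[["medium"]], 2L)
  expect_equal(table(gr4)[["low"]], 1L)
  expect_error(quartile_groups(rep(2, 10)), "degenerate")
  # group sizes near n/4, n/2, n/4 for continuous scores
  set.seed(9)
  tab <- table(quartile_groups(rnorm(400)))
  expect_equal(unname(tab[["low"]]), 100, tolerance = 0.011)
  expect_equal(unname(tab[["medium"]]), 200, tolerance = 0.006)
})
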
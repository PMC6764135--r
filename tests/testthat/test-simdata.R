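test_that("sim_config validates variances and allele-frequency range", {
  expect_error(sim_config(sigma2_A = -1), "non-negative")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.6, 0.7)), "maf_range")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("founder genotypes are Hardy-Weinberg binomial draws", {
  # fixed p = 0.5: expected heterozygosity 0.5
  cfg <- sim_config(n_boars = 500, n_sows = 1500, m_snps = 50,
                    maf_range = c(0.5, 0.5), seed = 2)
  g <- simulate_founder_genotypes(cfg)
  expect_equal(mean(g$counts == 1), 0.5, tolerance = 0.02)

  # per-SNP sample frequency within 4 binomial SE of its drawn p for >= 99%
  cfg <- sim_config(n_boars = 500, n_sows = 1500, m_snps = 1000, seed = 3)
  g <- simulate_founder_genotypes(cfg)
  p_true <- attr(g, "true_p")
  p_obs <- allele_freq(g)
  se <- sqrt(p_true * (1 - p_true) / (2 * 2000))
  expect_gte(mean(abs(p_obs - p_true) <= 4 * se), 0.99)
})

test_that("simulation is fully deterministic under a fixed seed", {
  cfg <- sim_config(n_boars = 5, n_sows = 10, m_snps = 50, seed = 77)
  a <- simulate_population(cfg)
  b <- simulate_population(cfg)
  expect_identical(a$geno$counts, b$geno$counts)
  expect_identical(a$pheno, b$pheno)
  expect_identical(a$truth$true_a, b$truth$true_a)
})

test_that("offspring genotypes follow Mendelian gamete sampling", {
  # forced heterozygote: AA sire x aa dam
  par <- tiny_geno(rbind(B0001 = 2, S0001 = 0), ids = c("B0001", "S0001"))
  attr(par, "boar_ids") <- "B0001"
  attr(par, "sow_ids") <- "S0001"
  cfg <- sim_config(n_boars = 1, n_sows = 1, litters_per_sow = 1,
                    piglets_per_litter = 50, m_snps = 1, seed = 1)
  off <- simulate_matings_and_offspring(par, cfg)
  expect_true(all(off$geno$counts == 1))

  # Aa x Aa: genotype proportions converge to the Mendelian probabilities
  par2 <- tiny_geno(rbind(B0001 = 1, S0001 = 1), ids = c("B0001", "S0001"))
  attr(par2, "boar_ids") <- "B0001"
  attr(par2, "sow_ids") <- "S0001"
  cfg2 <- sim_config(n_boars = 1, n_sows = 1, litters_per_sow = 1,
                     piglets_per_litter = 1e5, m_snps = 1, seed = 4)
  off2 <- simulate_matings_and_offspring(par2, cfg2)
  pr <- progeny_genotype_probs(1, 1)
  obs <- c(mean(off2$geno$counts == 2), mean(off2$geno$counts == 1),
           mean(off2$geno$counts == 0))
  se <- sqrt(c(0.25, 0.5, 0.25) * c(0.75, 0.5, 0.75) / 1e5)
  expect_true(all(abs(obs - c(pr$P_AA, pr$P_Aa, pr$P_aa)) <= 3 * se))

  # full sibs share both parents in the pedigree
  cfg3 <- sim_config(n_boars = 3, n_sows = 4, litters_per_sow = 1,
                     piglets_per_litter = 6, m_snps = 10, seed = 5)
  pop3 <- simulate_matings_and_offspring(simulate_founder_genotypes(cfg3), cfg3)
  off_ped <- pop3$ped[grepl("^P", pop3$ped$animal), ]
  litters <- split(off_ped, paste(off_ped$sire, off_ped$dam))
  expect_true(all(vapply(litters, nrow, integer(1)) %% 6 == 0))
})

test_that("true genetic values realise the configured variances", {
  cfg <- sim_config(n_boars = 1000, n_sows = 1000, m_snps = 800, seed = 6)
  founders <- freeze_freq(simulate_founder_genotypes(cfg))
  sim <- simulate_effects_and_phenotypes(founders, cfg)
  # Table-2-like values: empirical Var of breeding values within 15% of 16.26
  expect_equal(stats::var(sim$truth$true_u), 16.26, tolerance = 0.15)
  expect_equal(stats::var(sim$truth$true_v), 3.31, tolerance = 0.40)
})

test_that("no dominance means zero dominance effects and deviations", {
  cfg <- sim_config(n_boars = 20, n_sows = 30, m_snps = 50, sigma2_D = 0,
                    inb_depression_b = 0, seed = 8)
  founders <- freeze_freq(simulate_founder_genotypes(cfg))
  sim <- simulate_effects_and_phenotypes(founders, cfg)
  expect_true(all(sim$truth$true_d == 0))
  expect_true(all(abs(sim$truth$true_v) < 1e-12))
})

test_that("directional dominance induces a linear effect of homozygosity", {
  cfg <- sim_config(n_boars = 1000, n_sows = 1500, m_snps = 600, seed = 9)
  founders <- freeze_freq(simulate_founder_genotypes(cfg))
  sim <- simulate_effects_and_phenotypes(founders, cfg)
  f <- genomic_inbreeding(founders)
  reg <- stats::lm(sim$truth$true_g ~ f$f)
  slope <- summary(reg)$coefficients[2, ]
  expect_lt(abs(slope["Estimate"] - cfg$inb_depression_b), 3 * slope["Std. Error"])
})

test_that("repeated records show the expected repeatability", {
  cfg <- sim_config(n_boars = 400, n_sows = 600, m_snps = 300,
                    sigma2_pe = 5, repeated_records = TRUE, n_records = 2,
                    inb_depression_b = 0, seed = 10)
  founders <- freeze_freq(simulate_founder_genotypes(cfg))
  sim <- simulate_effects_and_phenotypes(founders, cfg)
  wide <- tidyr::pivot_wider(sim$pheno[, c("animal", "record", "y")],
                             names_from = "record", values_from = "y")
  # between-record correlation approximates (sA2 + sD2 + spe2) / sP2;
  # each record draws its own batch, so the fixed-effect variance enters
  # the denominator only
  r_obs <- stats::cor(wide$`1`, wide$`2`)
  rep_expected <- (16.26 + 3.31 + 5) /
    (16.26 + 3.31 + 5 + 42.8 + cfg$fixed_sd^2)
  expect_lt(abs(r_obs - rep_expected), 0.06)
})

test_that("qc fixture plants exactly the advertised violations", {
  fx <- make_qc_fixture(seed = 21, k1 = 5, k2 = 4, k3 = 3, k4 = 2, k5 = 3)
  fa <- filter_animals(fx$geno)
  expect_setequal(fa$removed, fx$planted$lowcall_animals)
  fs <- filter_snps(fa$geno)
  rem <- fs$removed
  expect_setequal(rem$snp[rem$criterion == "callrate"], fx$planted$lowcall_snps)
  expect_setequal(rem$snp[rem$criterion == "maf"], fx$planted$lowmaf_snps)
  expect_setequal(rem$snp[rem$criterion == "hwe"], fx$planted$hwe_snps)
  mc <- mendelian_check(fx$geno, fx$ped)
  expect_setequal(mc$flagged, fx$planted$conflicted_offspring)

  # zero-violation fixture: nothing removed
  fx0 <- make_qc_fixture(seed = 22, k1 = 0, k2 = 0, k3 = 0, k4 = 0, k5 = 0)
  expect_length(filter_animals(fx0$geno)$removed, 0)
  fs0 <- filter_snps(fx0$geno)
  expect_equal(fs0$report$n_snps_out, fs0$report$n_snps_in)
  expect_length(mendelian_check(fx0$geno, fx0$ped)$flagged, 0)
})
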
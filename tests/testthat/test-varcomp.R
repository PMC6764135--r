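test_that("mixed-model equations reduce to ridge regression when K = I", {
  set.seed(41)
  n <- 40
  q <- 8
  Z <- matrix(0, n, q, dimnames = list(NULL, paste0("u", 1:q)))
  Z[cbind(1:n, rep(1:q, length.out = n))] <- 1
  y <- rnorm(n)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  lambda <- 2.5
  mme <- build_mme(y, X, list(list(name = "u", Z = Z, lambda = lambda)))
  # direct ridge solve of the same augmented system
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + diag(lambda, q)))
  sol <- solve(C, c(crossprod(X, y), crossprod(Z, y)))
  expect_equal(unname(mme$solutions$fixed), unname(sol[1]), tolerance = 1e-10)
  expect_equal(unname(mme$solutions$random$u), unname(sol[-1]),
               tolerance = 1e-10)

  # shrinkage limit: enormous lambda drives all random solutions to 0
  mme_inf <- build_mme(y, X, list(list(name = "u", Z = Z, lambda = 1e12)))
  expect_true(all(abs(mme_inf$solutions$random$u) < 1e-8))
})

test_that("MME solutions equal the direct-V GLS oracle on a 5-animal toy", {
  set.seed(42)
  n <- 5
  K <- crossprod(matrix(rnorm(25), 5)) / 5 + diag(0.5, 5)
  dimnames(K) <- list(paste0("a", 1:5), paste0("a", 1:5))
  Z <- diag(n)
  colnames(Z) <- rownames(K)
  X <- cbind(`(Intercept)` = 1, x = rnorm(n))
  y <- rnorm(n, 10)
  s2u <- 2
  s2e <- 3
  mme <- build_mme(y, X, list(list(name = "u", Z = Z, K = K,
                                   lambda = s2e / s2u)))
  V <- Z %*% K %*% t(Z) * s2u + diag(s2e, n)
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  u <- s2u * K %*% t(Z) %*% Vi %*% (y - X %*% beta)
  expect_equal(unname(mme$solutions$fixed), unname(drop(beta)), tolerance = 1e-8)
  expect_equal(unname(mme$solutions$random$u), unname(drop(u)), tolerance = 1e-8)

  # a singular covariance raises an actionable error
  Ks <- matrix(1, 5, 5, dimnames = dimnames(K))
  expect_error(build_mme(y, X, list(list(name = "u", Z = Z, K = Ks,
                                         lambda = 1))), "blend")
})

test_that("EM-REML equals ANOVA-REML on a balanced sire design", {
  set.seed(43)
  s <- 12
  np <- 15
  sire <- rep(sprintf("s%02d", 1:s), each = np)
  y <- 10 + rnorm(s, 0, 2)[as.integer(factor(sire))] + rnorm(s * np, 0, 4)
  ph <- tibble::tibble(animal = paste0("a", seq_along(y)), sire = sire, y = y)
  fit <- em_reml(ph, random = list(sire = list(K = NULL, group = "sire")),
                 tol = 1e-12, max_iter = 20000, method = "em")
  MSB <- np * stats::var(tapply(y, sire, mean))
  MSW <- sum((y - stats::ave(y, sire))^2) / (s * (np - 1))
  expect_equal(fit$theta[["sire"]], (MSB - MSW) / np, tolerance = 1e-6)
  expect_equal(fit$theta[["residual"]], MSW, tolerance = 1e-6)
  expect_true(fit$converged)

  # restricted logL never decreases (asserted internally; checked here too)
  expect_true(all(diff(fit$logL_trace) > -1e-8 * abs(fit$logL)))
})

test_that("AI acceleration reaches the same optimum as plain EM", {
  set.seed(44)
  cfg <- sim_config(n_boars = 10, n_sows = 40, litters_per_sow = 1,
                    piglets_per_litter = 4, m_snps = 150,
                    sigma2_D = 0, inb_depression_b = 0, seed = 45)
  pop <- simulate_population(cfg)
  geno <- freeze_freq(subset_geno(pop$geno, animals = pop$offspring_ids))
  G <- blend(build_G(geno), 0.95)
  fit_em <- em_reml(pop$pheno, list(additive = G), fixed = "batch",
                    tol = 1e-10, max_iter = 20000, method = "em")
  fit_ai <- em_reml(pop$pheno, list(additive = G), fixed = "batch",
                    tol = 1e-10, max_iter = 500, method = "ai")
  expect_equal(fit_em$theta, fit_ai$theta, tolerance = 1e-4)
  expect_lt(fit_ai$n_iter, fit_em$n_iter)
})

test_that("a null dominance component is estimated near zero", {
  cfg <- sim_config(n_boars = 20, n_sows = 60, litters_per_sow = 1,
                    piglets_per_litter = 8, m_snps = 300, sigma2_D = 0,
                    inb_depression_b = 0, seed = 46)
  pop <- simulate_population(cfg)
  geno <- freeze_freq(subset_geno(pop$geno, animals = pop$offspring_ids))
  fit <- em_reml(pop$pheno,
                 list(additive = blend(build_G(geno), 0.95),
                      dominance = blend(build_D(geno), 0.95)),
                 fixed = "batch", tol = 1e-6, max_iter = 300, method = "ai")
  expect_lt(fit$theta[["dominance"]], 0.25 * fit$theta[["additive"]])
})

test_that("estimates are continuous in the blending weight near w = 1", {
  cfg <- sim_config(n_boars = 12, n_sows = 50, litters_per_sow = 1,
                    piglets_per_litter = 5, m_snps = 200, sigma2_D = 0,
                    inb_depression_b = 0, seed = 47)
  pop <- simulate_population(cfg)
  geno <- freeze_freq(subset_geno(pop$geno, animals = pop$offspring_ids))
  G <- build_G(geno)
  ests <- vapply(c(0.95, 0.99, 1 - 1e-6), function(w) {
    em_reml(pop$pheno, list(additive = blend(G, w)), fixed = "batch",
            tol = 1e-8, max_iter = 400, method = "ai")$theta[["additive"]]
  }, numeric(1))
  expect_lt(abs(ests[2] - ests[3]) / ests[3], 0.05)
  expect_lt(abs(ests[1] - ests[3]) / ests[3], 0.15)
})

test_that("AIC bookkeeping counts variance components only", {
  expect_equal(compute_aic(0, 2), 4)
  # one extra component with identical logL costs exactly 2 AIC points
  expect_equal(compute_aic(-100, 3) - compute_aic(-100, 2), 2)
})

test_that("asymptotic SEs follow the inverse information and delta method", {
  expect_equal(asymptotic_se(diag(4, 2)), c(0.5, 0.5))
  # ratio r = x / y with variance only in x: SE(r) = SE(x) / y
  info <- diag(c(1 / 0.04, 1e12))   # SE(x) = 0.2, SE(y) ~ 0
  x <- 3
  y <- 2
  grad <- c(1 / y, -x / y^2)
  expect_equal(asymptotic_se(info, grad), 0.2 / y, tolerance = 1e-4)
})

test_that("standard errors shrink roughly as 1/sqrt(n)", {
  ses <- vapply(c(6, 24), function(np) {
    set.seed(48)
    s <- 20
    sire <- rep(sprintf("s%02d", 1:s), each = np)
    y <- rnorm(s, 0, 2)[as.integer(factor(sire))] + rnorm(s * np, 0, 3)
    ph <- tibble::tibble(animal = paste0("a", seq_along(y)),
                         sire = sire, y = y)
    fit <- em_reml(ph, random = list(sire = list(K = NULL, group = "sire")),
                   tol = 1e-8, max_iter = 5000, method = "ai")
    fit$varcomp$se[fit$varcomp$component == "residual"]
  }, numeric(1))
  expect_lt(ses[2], ses[1])
})

test_that("tidy and glance summarise a fit in broom style", {
  set.seed(49)
  s <- 8
  np <- 6
  sire <- rep(paste0("s", 1:s), each = np)
  ph <- tibble::tibble(animal = paste0("a", 1:(s * np)), sire = sire,
                       y = rnorm(s * np))
  fit <- em_reml(ph, random = list(sire = list(K = NULL, group = "sire")),
                 tol = 1e-8, max_iter = 2000)
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error") %in% names(td)))
  expect_true("sigma2_e" %in% td$term)
  gl <- glance(fit)
  expect_equal(gl$nobs, s * np)
  expect_equal(gl$AIC, compute_aic(fit))
})

test_that("model_spec enforces the model-family invariants", {
  spec_a <- model_spec("A", trait = "AGE")
  expect_false(spec_a$include_f)   # pedigree model has no inbreeding covariate
  expect_false(spec_a$dominance)
  spec_g <- model_spec("G")
  expect_true(spec_g$include_f)
  expect_false(spec_g$dominance)
  spec_gd <- model_spec("GD", use_pe = TRUE, direction = "higher_better")
  expect_true(spec_gd$dominance)
  expect_true(spec_gd$use_pe)
  expect_error(model_spec("Z"))
})
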
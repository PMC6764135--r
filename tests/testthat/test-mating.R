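test_that("progeny genotype probabilities match gamete enumeration", {
  # independent oracle: enumerate the four parental gametes explicitly
  enumerate <- function(gs, gd) {
    alleles <- function(g) c(rep(1, g), rep(0, 2 - g))
    out <- c(AA = 0, Aa = 0, aa = 0)
    for (x in alleles(gs)) {
      for (z in alleles(gd)) {
        gt <- x + z
        out[c("aa", "Aa", "AA")[gt + 1]] <- out[c("aa", "Aa", "AA")[gt + 1]] + 0.25
      }
    }
    out
  }
  for (gs in 0:2) {
    for (gd in 0:2) {
      pr <- progeny_genotype_probs(gs, gd)
      expect_equal(c(pr$P_AA, pr$P_Aa, pr$P_aa),
                   unname(enumerate(gs, gd)[c("AA", "Aa", "aa")]),
                   tolerance = 1e-12,
                   label = sprintf("pair %d x %d", gs, gd))
    }
  }
  # missing parents flag the locus as skipped
  pr_na <- progeny_genotype_probs(c(NA, 1), c(2, NA))
  expect_true(all(pr_na$skipped))
})

make_fx <- function(m, p, a, d, b_hat = 0) {
  tibble::new_tibble(
    tibble::tibble(snp_id = paste0("s", seq_len(m)), p = p, a = a,
                   d_star = d + b_hat / m, d = d,
                   alpha = a + d * (1 - 2 * p)),
    b_hat = b_hat, sigma2_a = 1, sigma2_d = 1, m = m,
    class = "marker_effects", nrow = m)
}

test_that("mating prediction handles degenerate and missing genotypes", {
  m <- 5
  fx <- make_fx(m, p = rep(0.3, m), a = 1:5 / 10, d = rep(0.2, m))
  # both parents AA everywhere: g = sum(a), u = sum((2 - 2p) alpha)
  pm <- predict_mating(rep(2, m), rep(2, m), fx)
  expect_equal(pm$g_hat, sum(fx$a))
  expect_equal(pm$u_hat, sum((2 - 2 * fx$p) * fx$alpha))
  # a missing locus contributes nothing
  gs <- rep(2, m)
  gs[3] <- NA
  pm2 <- predict_mating(gs, rep(2, m), fx)
  expect_equal(pm2$g_hat, sum(fx$a[-3]))
  expect_error(predict_mating(rep(NA_real_, m), rep(2, m), fx), "co-typed")
})

test_that("grid prediction equals the single-pair function with missingness", {
  set.seed(61)
  m <- 40
  counts <- matrix(sample(c(0, 1, 2, NA), 12 * m, replace = TRUE,
                          prob = c(0.3, 0.4, 0.25, 0.05)), 12, m)
  g <- tiny_geno(counts, p = runif(m, 0.1, 0.9))
  fx <- make_fx(m, p = g$p, a = rnorm(m, 0, 0.1), d = rnorm(m, 0, 0.05),
                b_hat = 0.5)
  boars <- animal_ids(g)[1:5]
  sows <- animal_ids(g)[6:12]
  grid <- build_mating_grid(g, fx, boars, sows)
  for (i in c(1, 3, 5)) {
    for (j in c(2, 7)) {
      pm <- predict_mating(g$counts[boars[i], ], g$counts[sows[j], ], fx)
      expect_equal(grid$g_hat[i, j], pm$g_hat, tolerance = 1e-10)
      expect_equal(grid$u_hat[i, j], pm$u_hat, tolerance = 1e-10)
    }
  }
})

test_that("expected mating value equals the mean over simulated offspring", {
  set.seed(62)
  m <- 60
  n_off <- 2e4
  counts <- matrix(sample(0:2, 2 * m, replace = TRUE), 2, m)
  g <- tiny_geno(counts, p = runif(m, 0.2, 0.8))
  fx <- make_fx(m, p = g$p, a = rnorm(m, 0, 0.3), d = rnorm(m, -0.05, 0.1))
  pm <- predict_mating(counts[1, ], counts[2, ], fx)
  # gamete-sampling oracle
  hs <- counts[1, ] / 2
  hd <- counts[2, ] / 2
  off <- matrix(rbinom(n_off * m, 1, rep(hs, each = n_off)) +
                  rbinom(n_off * m, 1, rep(hd, each = n_off)), n_off, m)
  gval <- off
  K <- off - 1
  Tm <- 1 * (off == 1)
  gsim <- drop(K %*% fx$a + Tm %*% fx$d)
  mc_se <- stats::sd(gsim) / sqrt(n_off)
  expect_lt(abs(pm$g_hat - mean(gsim)), 3 * mc_se)
})

test_that("parental-average identity holds for complete genotypes", {
  set.seed(63)
  m <- 50
  counts <- matrix(sample(0:2, 10 * m, replace = TRUE), 10, m)
  g <- freeze_freq(tiny_geno(counts))
  fx <- make_fx(m, p = g$p, a = rnorm(m), d = rnorm(m))
  boars <- animal_ids(g)[1:4]
  sows <- animal_ids(g)[5:10]
  grid <- build_mating_grid(g, fx, boars, sows)
  gb <- gebv(g, fx)
  gv <- stats::setNames(gb$gebv, gb$animal)
  pa <- outer(gv[boars], gv[sows], function(x, z) (x + z) / 2)
  expect_lt(max(abs(grid$u_hat - unclass(pa))), 1e-10)
})

test_that("boar preselection truncates on GEBV in the right direction", {
  tbl <- tibble::tibble(animal = paste0("b", 1:6),
                        gebv = c(3, -2, 0, -5, 1, -5))
  expect_setequal(preselect_boars(tbl, 6), tbl$animal)
  expect_equal(preselect_boars(tbl, 2, "lower_better"), c("b4", "b6"))
  expect_equal(preselect_boars(tbl, 2, "higher_better"), c("b1", "b5"))
  r1 <- preselect_boars(tbl, 3, method = "random", seed = 9)
  expect_identical(r1, preselect_boars(tbl, 3, method = "random", seed = 9))
})

test_that("allocation equals brute-force enumeration on small grids", {
  # worked toy: 2 boars x 3 sows, capacity 1, 2 matings
  vals <- matrix(c(3, 2, 2, 4, 1, 1), 2, 3,
                 dimnames = list(c("b1", "b2"), c("s1", "s2", "s3")))
  grid <- structure(list(boar_ids = rownames(vals), sow_ids = colnames(vals),
                         u_hat = vals, g_hat = vals), class = "mating_grid")
  plan <- allocate_matings(grid, "u", n_matings = 2, boar_capacity = 1,
                           direction = "higher_better")
  expect_equal(attr(plan, "objective_value"), 7)
  expect_setequal(paste(plan$boar, plan$sow), c("b1 s1", "b2 s2"))

  set.seed(64)
  for (rep in 1:12) {
    nb <- sample(2:4, 1)
    ns <- sample(2:6, 1)
    cap <- sample(1:3, 1)
    n_mat <- sample(seq_len(min(ns, nb * cap)), 1)
    v <- matrix(round(rnorm(nb * ns), 2), nb, ns,
                dimnames = list(paste0("b", 1:nb), paste0("s", 1:ns)))
    gr <- structure(list(boar_ids = rownames(v), sow_ids = colnames(v),
                         u_hat = v, g_hat = v), class = "mating_grid")
    for (dir in c("higher_better", "lower_better")) {
      pl <- allocate_matings(gr, "u", n_mat, cap, dir)
      oracle <- allocation_oracle(v, cap, n_mat,
                                  maximize = dir == "higher_better")
      expect_equal(attr(pl, "objective_value"), oracle, tolerance = 1e-9)
      # constraint audit
      expect_true(all(table(pl$boar) <= cap))
      expect_true(all(table(pl$sow) <= 1))
      expect_equal(nrow(pl), n_mat)
    }
  }
})

test_that("degenerate allocations behave sensibly", {
  v <- matrix(1, 3, 4, dimnames = list(paste0("b", 1:3), paste0("s", 1:4)))
  gr <- structure(list(boar_ids = rownames(v), sow_ids = colnames(v),
                       u_hat = v, g_hat = v), class = "mating_grid")
  # all-equal values: any feasible plan is optimal
  pl <- allocate_matings(gr, "u", 3, 2, "higher_better")
  expect_equal(attr(pl, "objective_value"), 3)
  # single boar with ample capacity picks the best sows
  v2 <- matrix(c(5, 1, 3, 2), 1, 4,
               dimnames = list("b1", paste0("s", 1:4)))
  gr2 <- structure(list(boar_ids = "b1", sow_ids = colnames(v2),
                        u_hat = v2, g_hat = v2), class = "mating_grid")
  pl2 <- allocate_matings(gr2, "u", 2, 10, "higher_better")
  expect_setequal(pl2$sow, c("s1", "s3"))
  # infeasible request names the binding bound
  expect_error(allocate_matings(gr, "u", 5, 1, "higher_better"), "infeasible")
})

test_that("gains compare selected matings with all candidate matings", {
  vals_u <- matrix(c(3, 2, 2, 4, 1, 1), 2, 3,
                   dimnames = list(c("b1", "b2"), c("s1", "s2", "s3")))
  vals_g <- vals_u + 0.5
  gr <- structure(list(boar_ids = rownames(vals_u), sow_ids = colnames(vals_u),
                       u_hat = vals_u, g_hat = vals_g), class = "mating_grid")
  pl <- allocate_matings(gr, "u", 2, 1, "higher_better")
  gains <- mating_gains(pl, gr, sigma2_A = 4)
  expect_equal(gains$delta_U, mean(c(3, 4)) - mean(vals_u))
  expect_equal(gains$delta_G, mean(c(3.5, 4.5)) - mean(vals_g))
  expect_equal(gains$delta_U_sd, gains$delta_U / 2)

  # the full grid as a plan has zero gain
  all_plan <- structure(as_tibble(gr), objective = "u",
                        objective_value = sum(vals_u),
                        class = c("mating_plan", class(as_tibble(gr))))
  g0 <- mating_gains(all_plan, gr)
  expect_equal(g0$delta_U, 0)
  expect_equal(g0$delta_G, 0)
})

test_that("cross-optimality of the two objectives always holds", {
  set.seed(65)
  for (rep in 1:5) {
    nb <- 4
    ns <- 8
    u <- matrix(rnorm(nb * ns), nb, ns,
                dimnames = list(paste0("b", 1:nb), paste0("s", 1:ns)))
    g <- u + matrix(rnorm(nb * ns, 0, 0.5), nb, ns)
    gr <- structure(list(boar_ids = rownames(u), sow_ids = colnames(u),
                         u_hat = u, g_hat = g), class = "mating_grid")
    pu <- allocate_matings(gr, "u", 5, 3, "higher_better")
    pg <- allocate_matings(gr, "g", 5, 3, "higher_better")
    expect_gte(sum(pg$g_hat), sum(pu$g_hat) - 1e-9)
    expect_gte(sum(pu$u_hat), sum(pg$u_hat) - 1e-9)
  }
})
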
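#' Convert genetic variances to marker-effect variances
#'
#' Marker-level variances for the SNP-BLUP model are obtained from the
#' animal-level additive and dominance variances (estimated under the
#' breeding-value / dominance-deviation parameterisation) as
#' `sigma2_d = sigma2_D / sum((2 p_k q_k)^2)` and
#' `sigma2_a = (sigma2_A - sum(2 p_k q_k (q_k - p_k)^2) * sigma2_d) / sum(2 p_k q_k)`.
#'
#' @param sigma2_A,sigma2_D animal-level additive and dominance variances
#' @param p per-SNP allele-A frequencies (the frozen, post-QC frequencies)
#' @return list with `sigma2_a` and `sigma2_d`.
#' @seealso [marker_to_genetic_variance()] for the inverse map, used by the
#'   simulator.
#' @export
genetic_to_marker_variance <- function(sigma2_A, sigma2_D, p) {
  q <- 1 - p
  s2pq <- sum(2 * p * q)
  s4p2q2 <- sum((2 * p * q)^2)
  if (s2pq <= 0) stop("sum(2pq) is zero: no polymorphic SNPs", call. = FALSE)
  sigma2_d <- if (sigma2_D == 0) 0 else sigma2_D / s4p2q2
  num <- sigma2_A - sum(2 * p * q * (q - p)^2) * sigma2_d
  if (num < 0) {
    stop(sprintf(paste0(
      "sigma2_a would be negative: sigma2_A (%.4g) < sum(2pq (q-p)^2) * ",
      "sigma2_d (%.4g); dominance variance too large relative to additive"),
      sigma2_A, sum(2 * p * q * (q - p)^2) * sigma2_d), call. = FALSE)
  }
  list(sigma2_a = num / s2pq, sigma2_d = sigma2_d)
}

#' @rdname genetic_to_marker_variance
#' @param sigma2_a,sigma2_d marker-level variances
#' @export
marker_to_genetic_variance <- function(sigma2_a, sigma2_d, p) {
  q <- 1 - p
  list(
    sigma2_A = sum(2 * p * q) * sigma2_a + sum(2 * p * q * (q - p)^2) * sigma2_d,
    sigma2_D = sum((2 * p * q)^2) * sigma2_d
  )
}

#' Solve the SNP-BLUP model for additive and dominance marker effects
#'
#' Fits `y = X beta + f b + K a + T d* + Z pe + e` by Henderson's mixed-model
#' equations, where `K` codes genotypes AA/Aa/aa as 1/0/-1 and `T` as 0/1/0,
#' `a ~ N(0, I sigma2_a)`, `d* ~ N(0, I sigma2_d)` and `f` is the genomic
#' inbreeding covariate (proportion of homozygous calls). The variances are
#' treated as known, normally converted from REML estimates with
#' [genetic_to_marker_variance()]. Missing genotypes are coded at their
#' population mean (`p - q` in `K`, `2pq` in `T`), consistent with the
#' mean-substitution used in the relationship matrices.
#'
#' Dominance effects on the original scale are recovered as
#' `d = d* - b/m` and substitution effects as `alpha = a + d (q - p)`.
#'
#' @param pheno tibble with columns `animal`, `y`, plus any fixed-effect
#'   factors and covariates named in `fixed`/`covariates`.
#' @param geno a [genotype_matrix()] with frozen frequencies covering all
#'   phenotyped animals.
#' @param sigma2_a,sigma2_d,sigma2_pe,sigma2_e known variance components;
#'   `sigma2_d = 0` drops the dominance term, `sigma2_pe = 0` the
#'   permanent-environmental term.
#' @param fixed character vector of factor columns in `pheno`.
#' @param covariates character vector of numeric covariate columns.
#' @param include_f include the genomic-inbreeding covariate (default TRUE).
#' @return a `marker_effects` object: tibble `snp_id`, `p`, `a`, `d_star`,
#'   `d`, `alpha`, with attributes `b_hat`, `sigma2_a`, `sigma2_d`, `m`,
#'   `beta` (fixed-effect solutions) and `pe` (when fitted).
#' @export
solve_snp_blup <- function(pheno, geno, sigma2_a, sigma2_d = 0,
                           sigma2_pe = 0, sigma2_e,
                           fixed = character(), covariates = character(),
                           include_f = TRUE) {
  stopifnot(inherits(geno, "genotype_matrix"))
  m <- n_snps(geno)
  if (m == 0) stop("no SNPs", call. = FALSE)
  pheno <- tibble::as_tibble(pheno)
  ids <- animal_ids(geno)
  if (!all(pheno$animal %in% ids)) stop("phenotyped animals missing genotypes", call. = FALSE)
  p <- geno_freq(geno)
  q <- 1 - p

  K <- geno$counts - 1
  K <- sweep_na(K, p - q)
  Tm <- 1 * (geno$counts == 1)
  Tm <- sweep_na(Tm, 2 * p * q)

  X <- fixed_design(pheno, fixed, covariates)
  if (include_f) {
    f <- genomic_inbreeding(geno)
    X <- cbind(X, f = f$f[match(pheno$animal, f$animal)])
  }
  ridx <- match(pheno$animal, ids)
  y <- pheno$y

  designs <- list(list(name = "a", Z = K[ridx, , drop = FALSE],
                       lambda = sigma2_e / sigma2_a))
  if (sigma2_d > 0) {
    designs <- c(designs, list(list(name = "d_star", Z = Tm[ridx, , drop = FALSE],
                                    lambda = sigma2_e / sigma2_d)))
  }
  if (sigma2_pe > 0) {
    Zpe <- stats::model.matrix(~ 0 + factor(pheno$animal, levels = unique(pheno$animal)))
    colnames(Zpe) <- unique(pheno$animal)
    designs <- c(designs, list(list(name = "pe", Z = Zpe,
                                    lambda = sigma2_e / sigma2_pe)))
  }
  mme <- build_mme(y, X, designs)
  beta <- mme$solutions$fixed
  a <- mme$solutions$random$a
  d_star <- if (sigma2_d > 0) mme$solutions$random$d_star else rep(0, m)
  b_hat <- if (include_f) unname(beta["f"]) else 0
  d <- recover_dominance(d_star, b_hat, m)
  out <- tibble::tibble(
    snp_id = snp_ids(geno), p = unname(p),
    a = unname(a), d_star = unname(d_star), d = d,
    alpha = substitution_effects(a, d, p)
  )
  structure(out,
            b_hat = b_hat, sigma2_a = sigma2_a, sigma2_d = sigma2_d, m = m,
            beta = beta,
            pe = if (sigma2_pe > 0) mme$solutions$random$pe else NULL,
            class = c("marker_effects", class(out)))
}

sweep_na <- function(M, fill) {
  if (anyNA(M)) {
    na <- which(is.na(M), arr.ind = TRUE)
    M[na] <- fill[na[, 2]]
  }
  M
}

# design matrix for categorical fixed effects (reference level dropped) and
# numeric covariates, with an intercept
fixed_design <- function(pheno, fixed = character(), covariates = character()) {
  X <- matrix(1, nrow(pheno), 1, dimnames = list(NULL, "(Intercept)"))
  for (fct in fixed) {
    fval <- factor(pheno[[fct]])
    if (nlevels(fval) > 1) {
      Xi <- stats::model.matrix(~fval)[, -1, drop = FALSE]
      colnames(Xi) <- paste0(fct, levels(fval)[-1])
      X <- cbind(X, Xi)
    }
  }
  for (cv in covariates) {
    Xi <- matrix(pheno[[cv]], ncol = 1, dimnames = list(NULL, cv))
    X <- cbind(X, Xi)
  }
  colnames(X) <- make.unique(colnames(X))
  X
}

#' Recover directional dominance effects
#'
#' The SNP-BLUP model estimates centered dominance effects `d*`; the
#' original-scale effects are `d = d* - b/m`, where `b` is the estimated
#' inbreeding-depression coefficient and `m` the number of SNPs.
#'
#' @param d_star centered dominance effects
#' @param b_hat inbreeding-depression coefficient (per unit homozygosity)
#' @param m number of SNPs
#' @return numeric vector `d`.
#' @export
recover_dominance <- function(d_star, b_hat, m) {
  d_star - b_hat / m
}

#' Allele substitution effects
#'
#' `alpha_k = a_k + d_k (q_k - p_k)`.
#'
#' @param a,d additive and dominance marker effects
#' @param p allele-A frequencies
#' @return numeric vector `alpha`.
#' @export
substitution_effects <- function(a, d, p) {
  a + d * (1 - 2 * p)
}

#' Genomic estimated breeding values
#'
#' `GEBV_i = sum_k (count_ik - 2 p_k) alpha_k`; the centered coding makes
#' GEBVs deviations from the population mean (an uncentered coding would
#' shift every GEBV by the same constant and cannot change rankings or
#' allocations). Missing genotypes contribute 0 (mean substitution).
#'
#' @param geno a [genotype_matrix()]
#' @param fx a `marker_effects` object from [solve_snp_blup()], or a vector
#'   of substitution effects.
#' @return tibble `animal`, `gebv`.
#' @export
gebv <- function(geno, fx) {
  alpha <- if (inherits(fx, "marker_effects")) fx$alpha else fx
  p <- if (inherits(fx, "marker_effects")) fx$p else geno_freq(geno)
  stopifnot(length(alpha) == n_snps(geno))
  M <- sweep(geno$counts, 2, 2 * p)
  M[is.na(M)] <- 0
  tibble::tibble(animal = animal_ids(geno), gebv = unname(drop(M %*% alpha)))
}

#' Write marker effects to CSV
#' @param fx a `marker_effects` object
#' @param path CSV path; a sidecar JSON with `b_hat`, `sigma2_a`,
#'   `sigma2_d`, `m` is written next to it.
#' @export
write_marker_effects <- function(fx, path) {
  utils::write.csv(as.data.frame(fx), path, row.names = FALSE)
  meta <- list(b_hat = attr(fx, "b_hat"), sigma2_a = attr(fx, "sigma2_a"),
               sigma2_d = attr(fx, "sigma2_d"), m = attr(fx, "m"))
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path), auto_unbox = TRUE,
                       digits = NA)
  invisible(fx)
}
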
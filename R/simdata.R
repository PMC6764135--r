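#' Simulation configuration
#'
#' Describes a family-structured pig-breeding simulation: founder boars and
#' sows, full-sib litters from boar x sow matings, SNP genotypes without
#' linkage disequilibrium, and phenotypes generated under an additive +
#' dominance model with directional dominance (inbreeding depression).
#'
#' Default variance components are the additive/dominance/residual estimates
#' for age at 100 kg in a Landrace population (trait units days^2):
#' `sigma2_A = 16.26`, `sigma2_D = 3.31`, `sigma2_e = 42.80`, with an
#' inbreeding-depression coefficient of 42.9 days per unit increase in
#' genomic homozygosity (i.e. 4.29 days per 10%). Defaults for the herd
#' structure give ~2400 genotyped offspring in full-sib litters, a desk-scale
#' analogue of a purebred nucleus population.
#'
#' @param n_boars,n_sows numbers of founder boars and sows.
#' @param litters_per_sow,piglets_per_litter litter structure; each litter is
#'   a full-sib family from one boar x sow mating.
#' @param m_snps number of (independent) SNPs.
#' @param maf_range range of founder allele frequencies, drawn uniformly;
#'   must lie in (0, 0.5] on the minor-allele scale (upper bound 0.5 means
#'   allele A can be minor or major after drift).
#' @param sigma2_A,sigma2_D,sigma2_pe,sigma2_e additive, dominance,
#'   permanent-environmental and residual variances (trait units squared).
#' @param inb_depression_b change in phenotype per unit increase in genomic
#'   homozygosity (trait units); induced through the mean of the per-SNP
#'   dominance effects, `mean(d) = -b/m`, not through an explicit covariate,
#'   so that recovery of `b` by the model is a genuine test.
#' @param n_fixed_levels number of levels of the single categorical fixed
#'   effect (a stand-in for farm-year-sex / farrowing batch).
#' @param fixed_sd standard deviation of the fixed-effect level values.
#' @param repeated_records if `TRUE`, each phenotyped animal gets
#'   `n_records` records and a permanent-environmental effect.
#' @param n_records records per animal when `repeated_records` is `TRUE`.
#' @param seed master seed; all sub-draws derive from named substreams so
#'   the output of each stage is stable when other stages change.
#'
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_boars = 30, n_sows = 150, litters_per_sow = 2,
                       piglets_per_litter = 8, m_snps = 1000,
                       maf_range = c(0.05, 0.5),
                       sigma2_A = 16.26, sigma2_D = 3.31,
                       sigma2_pe = 0, sigma2_e = 42.80,
                       inb_depression_b = 42.9,
                       n_fixed_levels = 20, fixed_sd = 3,
                       repeated_records = FALSE, n_records = 3,
                       seed = 1L) {
  cfg <- list(
    n_boars = as.integer(n_boars), n_sows = as.integer(n_sows),
    litters_per_sow = as.integer(litters_per_sow),
    piglets_per_litter = as.integer(piglets_per_litter),
    m_snps = as.integer(m_snps), maf_range = as.numeric(maf_range),
    sigma2_A = sigma2_A, sigma2_D = sigma2_D,
    sigma2_pe = sigma2_pe, sigma2_e = sigma2_e,
    inb_depression_b = inb_depression_b,
    n_fixed_levels = as.integer(n_fixed_levels), fixed_sd = fixed_sd,
    repeated_records = isTRUE(repeated_records),
    n_records = as.integer(n_records),
    seed = as.integer(seed)
  )
  if (any(c(cfg$sigma2_A, cfg$sigma2_D, cfg$sigma2_pe, cfg$sigma2_e) < 0)) {
    stop("variances must be non-negative", call. = FALSE)
  }
  if (length(cfg$maf_range) != 2 || any(cfg$maf_range <= 0) ||
      any(cfg$maf_range > 0.5) || cfg$maf_range[1] > cfg$maf_range[2]) {
    stop("maf_range must satisfy 0 < lower <= upper <= 0.5", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# deterministic substream seed from a master seed and a stream name;
# stays below 2^31 - 1 so it is a valid R integer seed
substream_seed <- function(master, name) {
  h <- sum(utf8ToInt(name) * (seq_along(utf8ToInt(name)) + 7L))
  as.integer((as.numeric(master) * 69621 + h * 1013) %% 2147483629)
}

with_substream <- function(master, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(master, name))
  expr
}

#' Simulate founder genotypes
#'
#' Per-SNP founder frequencies `p_k` are drawn uniformly in `maf_range`;
#' founder genotypes are binomial(2, p_k) draws, so Hardy-Weinberg holds in
#' expectation. No missing calls. Boars get ids `B...`, sows `S...`.
#'
#' @param cfg a [sim_config()]
#' @return a [genotype_matrix()] with attribute `true_p` (the drawn
#'   frequencies) and attributes `boar_ids`/`sow_ids`.
#' @export
simulate_founder_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_boars + cfg$n_sows
  m <- cfg$m_snps
  p <- with_substream(cfg$seed, "founder_freq",
                      stats::runif(m, cfg$maf_range[1], cfg$maf_range[2]))
  counts <- with_substream(cfg$seed, "founder_geno", {
    matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), nrow = n, ncol = m)
  })
  ids <- c(sprintf("B%04d", seq_len(cfg$n_boars)),
           sprintf("S%04d", seq_len(cfg$n_sows)))
  dimnames(counts) <- list(ids, sprintf("snp%05d", seq_len(m)))
  g <- genotype_matrix(counts)
  attr(g, "true_p") <- stats::setNames(p, colnames(counts))
  attr(g, "boar_ids") <- ids[seq_len(cfg$n_boars)]
  attr(g, "sow_ids") <- ids[-seq_len(cfg$n_boars)]
  g
}

#' Simulate one generation of matings and offspring
#'
#' Each sow produces `litters_per_sow` litters, each sired by a boar drawn at
#' random; every litter is a full-sib family of `piglets_per_litter`
#' offspring. Each offspring genotype at each SNP is the sum of one gamete
#' per parent, each gamete allele drawn uniformly from the parent's two
#' alleles; loci segregate independently.
#'
#' @param parents a [genotype_matrix()] of founder genotypes (no missing
#'   calls), with boar/sow ids taken from attributes set by
#'   [simulate_founder_genotypes()] or inferred from the `B`/`S` id prefix.
#' @param cfg a [sim_config()]
#' @return list with `geno` (offspring [genotype_matrix()]) and `ped`
#'   (tibble `animal`, `sire`, `dam`; founders included with unknown
#'   parents coded "0").
#' @export
simulate_matings_and_offspring <- function(parents, cfg) {
  stopifnot(inherits(parents, "genotype_matrix"))
  if (n_animals(parents) == 0) stop("no parents supplied", call. = FALSE)
  boars <- attr(parents, "boar_ids") %||% grep("^B", animal_ids(parents), value = TRUE)
  sows <- attr(parents, "sow_ids") %||% grep("^S", animal_ids(parents), value = TRUE)
  if (!length(boars) || !length(sows)) stop("need at least one boar and one sow", call. = FALSE)

  n_lit <- length(sows) * cfg$litters_per_sow
  litter_sow <- rep(sows, each = cfg$litters_per_sow)
  litter_boar <- with_substream(cfg$seed, "mating",
                                sample(boars, n_lit, replace = TRUE))
  sire <- rep(litter_boar, each = cfg$piglets_per_litter)
  dam <- rep(litter_sow, each = cfg$piglets_per_litter)
  n_off <- length(sire)
  m <- n_snps(parents)

  ps <- parents$counts[sire, , drop = FALSE] / 2
  pd <- parents$counts[dam, , drop = FALSE] / 2
  counts <- with_substream(cfg$seed, "gametes", {
    matrix(stats::rbinom(n_off * m, 1L, ps) + stats::rbinom(n_off * m, 1L, pd),
           nrow = n_off, ncol = m)
  })
  off_ids <- sprintf("P%05d", seq_len(n_off))
  dimnames(counts) <- list(off_ids, snp_ids(parents))
  off_sex <- with_substream(cfg$seed, "sex",
                            sample(c("male", "female"), n_off, replace = TRUE))
  founder_sex <- ifelse(animal_ids(parents) %in% boars, "male", "female")
  ped <- tibble::tibble(
    animal = c(animal_ids(parents), off_ids),
    sire = c(rep("0", n_animals(parents)), sire),
    dam = c(rep("0", n_animals(parents)), dam),
    sex = c(founder_sex, off_sex)
  )
  list(geno = genotype_matrix(counts), ped = ped)
}

#' Simulate SNP effects and phenotypes
#'
#' Per-SNP additive effects are `a_k ~ N(0, sigma2_a)` and dominance effects
#' `d_k ~ N(-b/m, sigma2_d)`, where the marker-level variances are obtained
#' from the configured genetic variances `sigma2_A`, `sigma2_D` by inverting
#' the marker-variance conversion (see [marker_to_genetic_variance()]) at
#' the observed allele frequencies. The genotypic value of an animal is
#' `sum_k [a_k, d_k, -a_k]` picked by its genotype (AA, Aa, aa); the
#' phenotype adds a categorical fixed effect, a permanent-environmental
#' effect (for repeated records) and a residual. Directional dominance
#' (`mean(d) = -b/m`) makes the genotypic mean rise linearly in genomic
#' homozygosity with slope `b`; no explicit inbreeding covariate is added.
#'
#' @param geno a complete (no missing calls) [genotype_matrix()]
#' @param cfg a [sim_config()]
#' @return list with `pheno` (tibble `animal`, `record`, `batch`, `y`) and
#'   `truth` (list: `true_a`, `true_d`, `true_u`, `true_v`, `true_g`,
#'   `true_components`, `p`).
#' @export
simulate_effects_and_phenotypes <- function(geno, cfg) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (anyNA(geno$counts)) stop("genotypes must be complete", call. = FALSE)
  m <- n_snps(geno)
  if (m == 0 && cfg$sigma2_D > 0) {
    stop("sigma2_D > 0 requires at least one SNP", call. = FALSE)
  }
  p <- geno_freq(geno)
  mv <- genetic_to_marker_variance(cfg$sigma2_A, cfg$sigma2_D, p)
  b <- cfg$inb_depression_b
  eff <- with_substream(cfg$seed, "effects", {
    list(a = stats::rnorm(m, 0, sqrt(mv$sigma2_a)),
         d = stats::rnorm(m, -b / m, sqrt(mv$sigma2_d)))
  })
  if (cfg$sigma2_D == 0 && b == 0) eff$d[] <- 0

  counts <- geno$counts
  K <- counts - 1                      # 1 / 0 / -1 for AA / Aa / aa
  Tm <- 1 * (counts == 1)              # 0 / 1 / 0
  g_val <- drop(K %*% eff$a + Tm %*% eff$d)
  q <- 1 - p
  alpha <- eff$a + eff$d * (q - p)
  u <- drop(sweep(counts, 2, 2 * p) %*% alpha)
  W <- dominance_coding(counts, p)
  v <- drop(W %*% eff$d)

  n <- n_animals(geno)
  nrec <- if (cfg$repeated_records) cfg$n_records else 1L
  level_vals <- with_substream(cfg$seed, "fixed_levels",
                               stats::rnorm(cfg$n_fixed_levels, 0, cfg$fixed_sd))
  batch <- with_substream(cfg$seed, "fixed_assign",
                          sample.int(cfg$n_fixed_levels, n * nrec, replace = TRUE))
  pe <- with_substream(cfg$seed, "pe",
                       stats::rnorm(n, 0, sqrt(cfg$sigma2_pe)))
  e <- with_substream(cfg$seed, "residual",
                      stats::rnorm(n * nrec, 0, sqrt(cfg$sigma2_e)))
  idx <- rep(seq_len(n), times = nrec)
  pheno <- tibble::tibble(
    animal = animal_ids(geno)[idx],
    record = rep(seq_len(nrec), each = n),
    batch = factor(batch),
    y = level_vals[batch] + g_val[idx] + (if (cfg$repeated_records) pe[idx] else 0) + e
  )
  truth <- list(
    true_a = eff$a, true_d = eff$d,
    true_u = stats::setNames(u, animal_ids(geno)),
    true_v = stats::setNames(v, animal_ids(geno)),
    true_g = stats::setNames(g_val, animal_ids(geno)),
    true_components = list(sigma2_A = cfg$sigma2_A, sigma2_D = cfg$sigma2_D,
                           sigma2_pe = cfg$sigma2_pe, sigma2_e = cfg$sigma2_e,
                           b = b),
    p = p
  )
  list(pheno = pheno, truth = truth)
}

#' Simulate a complete two-generation population
#'
#' Convenience wrapper: founders, one generation of litters, and phenotypes
#' on the offspring.
#'
#' @param cfg a [sim_config()]
#' @param phenotype_on which animals get phenotypes: `"offspring"` (default)
#'   or `"all"`.
#' @return list with `founders`, `geno` (all animals), `offspring_ids`,
#'   `ped`, `pheno`, `truth`.
#' @export
simulate_population <- function(cfg, phenotype_on = c("offspring", "all")) {
  phenotype_on <- match.arg(phenotype_on)
  founders <- simulate_founder_genotypes(cfg)
  off <- simulate_matings_and_offspring(founders, cfg)
  all_counts <- rbind(founders$counts, off$geno$counts)
  geno <- genotype_matrix(all_counts)
  attr(geno, "boar_ids") <- attr(founders, "boar_ids")
  attr(geno, "sow_ids") <- attr(founders, "sow_ids")
  target <- if (phenotype_on == "offspring") {
    subset_geno(geno, animals = animal_ids(off$geno))
  } else {
    geno
  }
  sim <- simulate_effects_and_phenotypes(freeze_freq(target), cfg)
  list(founders = founders, geno = geno,
       offspring_ids = animal_ids(off$geno), ped = off$ped,
       pheno = sim$pheno, truth = sim$truth)
}

#' Quality-control fixture with planted violations
#'
#' Builds a genotype set with a known number of planted QC violations so the
#' filters can be tested against exact truth: `k1` SNPs with call rate below
#' 0.98, `k2` SNPs with minor allele frequency below 0.05, `k3` SNPs
#' deviating grossly from Hardy-Weinberg equilibrium (all-heterozygous),
#' `k4` animals with call rate below 0.98, and `k5` offspring with planted
#' opposite-homozygote Mendelian conflicts against a genotyped parent.
#'
#' @param seed integer seed
#' @param k1,k2,k3,k4,k5 planted violation counts
#' @param n_animals,m_snps base panel size (clean part)
#' @return list with `geno`, `ped` and `planted` (ids per category).
#' @export
make_qc_fixture <- function(seed = 1L, k1 = 5L, k2 = 4L, k3 = 3L,
                            k4 = 2L, k5 = 3L, n_animals = 100L,
                            m_snps = 60L) {
  set.seed(as.integer(seed))
  n <- n_animals
  m_extra <- k1 + k2 + k3
  m <- m_snps + m_extra
  # clean base: MAF ~ 0.3, HWE, full call rate; regenerate any column that
  # drifts near a threshold so planted counts are exact
  draw_clean <- function() {
    repeat {
      x <- stats::rbinom(n, 2L, 0.35)
      pf <- mean(x) / 2
      if (min(pf, 1 - pf) < 0.15) next
      if (hwe_pvalue(sum(x == 2), sum(x == 1), sum(x == 0)) > 0.2) return(x)
    }
  }
  counts <- vapply(seq_len(m_snps), function(k) draw_clean(), numeric(n))

  lowcall <- lowmaf <- badhwe <- NULL
  if (k1 > 0) {
    # each planted low-call-rate SNP misses a disjoint block of animals
    # (excluding the planted low-call-rate animals), so no clean animal
    # accumulates enough missing calls to fail the animal filter itself
    miss_per <- ceiling(0.05 * n)
    pool <- setdiff(seq_len(n), seq_len(k4))
    if (k1 * miss_per > length(pool)) {
      stop("too many low-call-rate SNPs for the panel size", call. = FALSE)
    }
    lowcall <- vapply(seq_len(k1), function(k) {
      x <- draw_clean()
      x[pool[(k - 1) * miss_per + seq_len(miss_per)]] <- NA
      x
    }, numeric(n))
  }
  if (k2 > 0) {
    lowmaf <- vapply(seq_len(k2), function(k) {
      x <- numeric(n)
      x[sample.int(n, max(1L, round(0.04 * n)))] <- 1   # MAF ~ 0.02
      x
    }, numeric(n))
  }
  if (k3 > 0) {
    badhwe <- vapply(seq_len(k3), function(k) rep(1, n), numeric(n))
  }
  counts <- cbind(counts, lowcall, lowmaf, badhwe)
  colnames(counts) <- sprintf("snp%03d", seq_len(ncol(counts)))
  rownames(counts) <- sprintf("A%03d", seq_len(n))
  snp_names <- colnames(counts)
  planted <- list(
    lowcall_snps = if (k1) snp_names[m_snps + seq_len(k1)] else character(),
    lowmaf_snps = if (k2) snp_names[m_snps + k1 + seq_len(k2)] else character(),
    hwe_snps = if (k3) snp_names[m_snps + k1 + k2 + seq_len(k3)] else character()
  )

  # low-call-rate animals: missing spread over clean SNPs, at most 1 extra
  # missing call per SNP so no SNP drops below the 0.98 call-rate threshold
  bad_animals <- character()
  if (k4 > 0) {
    bad_animals <- rownames(counts)[seq_len(k4)]
    need <- ceiling((1 - 0.98) * ncol(counts)) + 1L
    for (i in seq_len(k4)) {
      cols <- ((i - 1) * need + seq_len(need) - 1L) %% m_snps + 1L
      counts[i, cols] <- NA
    }
  }
  planted$lowcall_animals <- bad_animals

  # Mendelian conflicts: trios appended; conflicted offspring are opposite
  # homozygotes to their sire at ~8% of loci (above the 2% default rate)
  sires <- rownames(counts)[n - seq_len(max(1, k5))]
  off_ids <- conflicted <- character()
  ped <- tibble::tibble(animal = rownames(counts), sire = "0", dam = "0")
  if (k5 > 0) {
    n_conf_loci <- max(2L, ceiling(0.08 * ncol(counts)))
    off <- vapply(seq_len(k5), function(j) {
      s <- counts[sires[j], ]
      x <- vapply(s, function(cs) {
        if (is.na(cs)) return(stats::rbinom(1, 2, 0.35))
        if (cs == 2) sample(c(2, 1), 1) else if (cs == 0) sample(c(0, 1), 1) else stats::rbinom(1, 1, 0.5) + stats::rbinom(1, 1, 0.5)
      }, numeric(1))
      hom <- which(!is.na(s) & s != 1)
      conf <- hom[seq_len(min(n_conf_loci, length(hom)))]
      x[conf] <- 2 - s[conf]           # opposite homozygote
      x
    }, numeric(ncol(counts)))
    off_ids <- sprintf("O%03d", seq_len(k5))
    conflicted <- off_ids
    off <- t(off)
    rownames(off) <- off_ids
    counts <- rbind(counts, off)
    ped <- dplyr::bind_rows(ped, tibble::tibble(animal = off_ids,
                                                sire = sires[seq_len(k5)],
                                                dam = "0"))
  }
  planted$conflicted_offspring <- conflicted
  list(geno = genotype_matrix(counts), ped = ped, planted = planted)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
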
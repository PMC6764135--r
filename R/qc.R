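#' @keywords internal
#' Pearson chi-square HWE p-value (1 df) from genotype counts
#' @noRd
hwe_pvalue <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  if (n == 0) return(NaN)
  p <- (2 * nAA + nAa) / (2 * n)
  q <- 1 - p
  expc <- n * c(p^2, 2 * p * q, q^2)
  obs <- c(nAA, nAa, naa)
  if (any(expc == 0)) {
    # monomorphic: observed equals expected exactly, no deviation testable
    if (all(obs[expc == 0] == 0)) return(1)
    return(0)
  }
  x2 <- sum((obs - expc)^2 / expc)
  stats::pchisq(x2, df = 1, lower.tail = FALSE)
}

#' SNP quality control
#'
#' Removes SNPs failing, in order: call rate below `callrate_min`, minor
#' allele frequency below `maf_min`, and Hardy-Weinberg equilibrium (Pearson
#' chi-square with 1 df on observed vs HWE-expected genotype counts among
#' non-missing calls, p-value below `hwe_alpha`). Each SNP is attributed to
#' the first criterion it fails, so the per-criterion counts in the report
#' sum to the total number removed. Monomorphic SNPs fall under the MAF rule
#' (frequency 0), never a crash.
#'
#' @param geno a [genotype_matrix()]
#' @param callrate_min,maf_min,hwe_alpha thresholds; defaults are the usual
#'   0.98 / 0.05 / 0.05.
#' @return list with `geno` (filtered, frequencies re-frozen from the
#'   retained calls) and `report` (a `qc_report` tibble row: `n_snps_in`,
#'   `n_removed_callrate`, `n_removed_maf`, `n_removed_hwe`, `n_snps_out`),
#'   plus `removed` (tibble `snp`, `criterion`).
#' @export
filter_snps <- function(geno, callrate_min = 0.98, maf_min = 0.05,
                        hwe_alpha = 0.05) {
  stopifnot(inherits(geno, "genotype_matrix"))
  counts <- geno$counts
  if (ncol(counts) == 0) stop("empty genotype matrix", call. = FALSE)
  n <- nrow(counts)
  callrate <- colMeans(!is.na(counts))
  p <- colMeans(counts, na.rm = TRUE) / 2
  p[is.nan(p)] <- 0
  maf <- pmin(p, 1 - p)
  hwe_p <- vapply(seq_len(ncol(counts)), function(k) {
    x <- counts[, k]
    hwe_pvalue(sum(x == 2, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
               sum(x == 0, na.rm = TRUE))
  }, numeric(1))
  fail_cr <- callrate < callrate_min
  fail_maf <- !fail_cr & maf < maf_min
  fail_hwe <- !fail_cr & !fail_maf & !is.nan(hwe_p) & hwe_p < hwe_alpha
  keep <- !(fail_cr | fail_maf | fail_hwe)
  removed <- tibble::tibble(
    snp = colnames(counts)[!keep],
    criterion = c("callrate", "maf", "hwe")[
      max.col(cbind(fail_cr, fail_maf, fail_hwe)[!keep, , drop = FALSE],
              ties.method = "first")]
  )
  out <- freeze_freq(subset_geno(geno, snps = keep))
  report <- tibble::tibble(
    n_snps_in = ncol(counts),
    n_removed_callrate = sum(fail_cr),
    n_removed_maf = sum(fail_maf),
    n_removed_hwe = sum(fail_hwe),
    n_snps_out = sum(keep)
  )
  class(report) <- c("qc_report", class(report))
  list(geno = out, report = report, removed = removed)
}

#' Animal call-rate filter
#'
#' Discards animals whose genotype call rate is below `callrate_min`.
#'
#' @inheritParams filter_snps
#' @return list with `geno` and `removed` (character vector of animal ids).
#' @export
filter_animals <- function(geno, callrate_min = 0.98) {
  stopifnot(inherits(geno, "genotype_matrix"))
  callrate <- rowMeans(!is.na(geno$counts))
  keep <- callrate >= callrate_min
  list(geno = subset_geno(geno, animals = keep),
       removed = animal_ids(geno)[!keep])
}

#' Mendelian-consistency check
#'
#' For each offspring with at least one genotyped parent, a conflict is a
#' locus where the offspring and a genotyped parent are opposite homozygotes,
#' or where the offspring is homozygous for an allele absent in both
#' genotyped parents. Offspring whose conflict rate among co-typed loci
#' exceeds `conflict_rate_max` are flagged (whole-animal removal tolerates
#' isolated genotyping errors). Offspring with no genotyped parent are
#' skipped and listed in `skipped`.
#'
#' @param geno a [genotype_matrix()]
#' @param ped pedigree tibble (`animal`, `sire`, `dam`; "0"/`NA` = unknown)
#' @param conflict_rate_max maximum tolerated conflict rate (default 0.02)
#' @return list with `flagged` (animal ids), `rates` (tibble `animal`,
#'   `n_checked`, `n_conflict`, `rate`) and `skipped`.
#' @export
mendelian_check <- function(geno, ped, conflict_rate_max = 0.02) {
  counts <- geno$counts
  ids <- rownames(counts)
  res <- list()
  skipped <- character()
  for (i in seq_len(nrow(ped))) {
    an <- as.character(ped$animal[i])
    if (!an %in% ids) next
    par <- as.character(c(ped$sire[i], ped$dam[i]))
    par <- par[!is.na(par) & par != "0" & par %in% ids]
    if (!length(par)) {
      if (!is.na(ped$sire[i]) && ped$sire[i] != "0" ||
          !is.na(ped$dam[i]) && ped$dam[i] != "0") {
        skipped <- c(skipped, an)
      }
      next
    }
    o <- counts[an, ]
    conf <- rep(FALSE, length(o))
    checked <- rep(FALSE, length(o))
    for (pp in par) {
      g <- counts[pp, ]
      ok <- !is.na(o) & !is.na(g)
      checked <- checked | ok
      conf <- conf | (ok & abs(o - g) == 2)   # opposite homozygotes
    }
    if (length(par) == 2) {
      s <- counts[par[1], ]; d <- counts[par[2], ]
      ok <- !is.na(o) & !is.na(s) & !is.na(d)
      # offspring homozygous for an allele carried by neither parent
      conf <- conf | (ok & o == 2 & s == 0 & d == 0) |
        (ok & o == 0 & s == 2 & d == 2)
    }
    res[[an]] <- c(n_checked = sum(checked), n_conflict = sum(conf & checked))
  }
  rates <- tibble::tibble(
    animal = as.character(names(res)),
    n_checked = unname(vapply(res, `[[`, numeric(1), "n_checked")),
    n_conflict = unname(vapply(res, `[[`, numeric(1), "n_conflict"))
  )
  rates$rate <- ifelse(rates$n_checked > 0, rates$n_conflict / rates$n_checked, 0)
  list(flagged = rates$animal[rates$rate > conflict_rate_max],
       rates = rates, skipped = unique(skipped))
}

#' Intersect two genotyping panels
#'
#' Keeps SNPs present on both panels (by SNP id) and concatenates the
#' animals, emulating the merge of two chip panels.
#'
#' @param geno_panel1,geno_panel2 [genotype_matrix()] objects
#' @return a [genotype_matrix()] on the common SNPs.
#' @export
intersect_panels <- function(geno_panel1, geno_panel2) {
  common <- intersect(snp_ids(geno_panel1), snp_ids(geno_panel2))
  if (!length(common)) stop("panels share no SNPs", call. = FALSE)
  g1 <- geno_panel1$counts[, common, drop = FALSE]
  g2 <- geno_panel2$counts[, common, drop = FALSE]
  genotype_matrix(rbind(g1, g2))
}

#' Adjust age to 100 kg live weight
#'
#' `AGE = age_test + (r - 0.0077 * w_batch + 0.0047 * age_batch) * (100 - w_test)`
#' with coefficient r of 1.05 for males and 1.125 for females.
#'
#' @param rec data frame with columns `sex` ("male"/"female"), `age_test`
#'   (days), `w_test`, `w_batch` (kg) and `age_batch` (days). Extra columns
#'   pass through.
#' @return the input tibble with an `AGE` column (days); records with
#'   missing fields get `NA` and a warning rather than aborting the run.
#' @export
adjust_age <- function(rec) {
  rec <- tibble::as_tibble(rec)
  need <- c("sex", "age_test", "w_test", "w_batch", "age_batch")
  miss <- setdiff(need, names(rec))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  r <- ifelse(rec$sex == "male", 1.05,
              ifelse(rec$sex == "female", 1.125, NA_real_))
  age <- rec$age_test +
    (r - 0.0077 * rec$w_batch + 0.0047 * rec$age_batch) * (100 - rec$w_test)
  bad <- is.na(age)
  if (any(bad)) warning(sum(bad), " record(s) with missing fields: AGE set to NA")
  dplyr::mutate(rec, AGE = age)
}

#' Adjust backfat depth to 100 kg live weight
#'
#' The six ultrasonic depth measurements are averaged per animal, then
#' `BD = averageBD + r * (100 - w_test)` with coefficient r of 0.1 for
#' males and 0.12 for females.
#'
#' @param rec data frame with columns `sex`, `w_test` and either `bd1`..`bd6`
#'   (six depths, mm) or a precomputed `averageBD`.
#' @return the input tibble with `averageBD` and `BD` columns (mm).
#' @export
adjust_bd <- function(rec) {
  rec <- tibble::as_tibble(rec)
  if (!"averageBD" %in% names(rec)) {
    bdcols <- paste0("bd", 1:6)
    if (!all(bdcols %in% names(rec))) {
      stop("need bd1..bd6 or averageBD", call. = FALSE)
    }
    rec$averageBD <- rowMeans(rec[bdcols])
  }
  r <- ifelse(rec$sex == "male", 0.1,
              ifelse(rec$sex == "female", 0.12, NA_real_))
  bd <- rec$averageBD + r * (100 - rec$w_test)
  bad <- is.na(bd)
  if (any(bad)) warning(sum(bad), " record(s) with missing fields: BD set to NA")
  dplyr::mutate(rec, BD = bd)
}

#' Average piglet weight at birth within litter
#'
#' One record per farrowing: the mean of the individual piglet birth
#' weights. A maternal trait with repeated records across parities.
#'
#' @param litters tibble with columns `sow`, `parity` (or any litter key)
#'   and `piglet_weight` (g), one row per piglet.
#' @return tibble with one row per sow x parity and column `APWL` (g).
#' @export
compute_apwl <- function(litters) {
  litters <- tibble::as_tibble(litters)
  if (nrow(litters) == 0) stop("no piglet weights supplied", call. = FALSE)
  if (anyNA(litters$piglet_weight)) stop("missing piglet weights", call. = FALSE)
  dplyr::summarise(dplyr::group_by(litters, dplyr::across(dplyr::any_of(c("sow", "parity")))),
                   APWL = mean(piglet_weight), n_piglets = dplyr::n(),
                   .groups = "drop")
}
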
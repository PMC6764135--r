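#' Mendelian progeny genotype probabilities
#'
#' Single-locus genotype probabilities of the progeny of two unphased
#' parental genotypes under random gamete transmission and no mutation: a
#' parent with allele-A count `c` transmits A with probability `c/2`.
#' Loci where either parent is missing are flagged `skipped` and contribute
#' nothing to mating predictions.
#'
#' @param g_sire,g_dam allele-A counts (0, 1, 2 or `NA`), vectorised over
#'   loci.
#' @return tibble with columns `P_AA`, `P_Aa`, `P_aa`, `skipped`.
#' @examples
#' progeny_genotype_probs(1, 1)   # Punnett square: 0.25 / 0.5 / 0.25
#' @export
progeny_genotype_probs <- function(g_sire, g_dam) {
  hs <- g_sire / 2
  hd <- g_dam / 2
  skipped <- is.na(hs) | is.na(hd)
  P_AA <- hs * hd
  P_aa <- (1 - hs) * (1 - hd)
  P_Aa <- 1 - P_AA - P_aa
  out <- tibble::tibble(P_AA = P_AA, P_Aa = P_Aa, P_aa = P_aa,
                        skipped = skipped)
  out[skipped, c("P_AA", "P_Aa", "P_aa")] <- 0
  out
}

#' Predict progeny total genetic and breeding value of one mating
#'
#' Expected total genetic value of the progeny of a sire x dam pair,
#' `g_hat = sum_k [P_k(AA) a_k + P_k(Aa) d_k + P_k(aa) (-a_k)]`, and
#' expected breeding value
#' `u_hat = sum_k [P_k(AA)(2-2p_k) + P_k(Aa)(1-2p_k) + P_k(aa)(-2p_k)] alpha_k`.
#' Loci with a missing parental genotype are skipped.
#'
#' @param geno_sire,geno_dam allele-A count vectors over the SNPs of `fx`.
#' @param fx a `marker_effects` object (see [solve_snp_blup()]).
#' @return list with `g_hat` and `u_hat`.
#' @export
predict_mating <- function(geno_sire, geno_dam, fx) {
  m <- nrow(fx)
  stopifnot(length(geno_sire) == m, length(geno_dam) == m)
  pr <- progeny_genotype_probs(geno_sire, geno_dam)
  keep <- !pr$skipped
  if (!any(keep)) stop("no co-typed loci between the parents", call. = FALSE)
  p <- fx$p
  g_hat <- sum((pr$P_AA - pr$P_aa) * fx$a + pr$P_Aa * fx$d)
  u_hat <- sum((pr$P_AA * (2 - 2 * p) + pr$P_Aa * (1 - 2 * p) +
                  pr$P_aa * (-2 * p)) * fx$alpha)
  list(g_hat = g_hat, u_hat = u_hat)
}

#' Expected progeny values for all boar x sow pairs
#'
#' Vectorised version of [predict_mating()] over the full grid of candidate
#' matings. Missing parental genotypes are skipped per pair, matching the
#' single-pair function exactly.
#'
#' @param geno a [genotype_matrix()] containing all candidate parents.
#' @param fx a `marker_effects` object on the same SNPs.
#' @param boar_ids,sow_ids candidate parents (rows of `geno`).
#' @return a `mating_grid`: list with `boar_ids`, `sow_ids`, and matrices
#'   `u_hat`, `g_hat` (boars x sows).
#' @export
build_mating_grid <- function(geno, fx, boar_ids, sow_ids) {
  stopifnot(inherits(fx, "marker_effects"))
  stopifnot(all(c(boar_ids, sow_ids) %in% animal_ids(geno)))
  if (!identical(snp_ids(geno), fx$snp_id)) {
    common <- intersect(snp_ids(geno), fx$snp_id)
    if (!length(common)) stop("genotypes and marker effects share no SNPs", call. = FALSE)
    geno <- subset_geno(geno, snps = common)
    fx <- fx[match(common, fx$snp_id), ]
  }
  a <- fx$a; d <- fx$d; alpha <- fx$alpha; p <- fx$p
  Hs <- geno$counts[boar_ids, , drop = FALSE] / 2
  Hd <- geno$counts[sow_ids, , drop = FALSE] / 2
  Ms <- 1 * !is.na(Hs); Md <- 1 * !is.na(Hd)
  Hs0 <- ifelse(is.na(Hs), 0, Hs); Hd0 <- ifelse(is.na(Hd), 0, Hd)

  cw <- function(M, wts) sweep(M, 2, wts, `*`)
  # g_hat = sum over co-typed k of (hs + hd - 1) a_k + (hs + hd - 2 hs hd) d_k
  g_hat <- cw(Hs0, a + d) %*% t(Md) + Ms %*% t(cw(Hd0, a + d)) -
    cw(Ms, a) %*% t(Md) - 2 * (cw(Hs0, d) %*% t(Hd0))
  # u_hat = sum over co-typed k of (hs + hd - 2 p_k) alpha_k
  u_hat <- cw(Hs0, alpha) %*% t(Md) + Ms %*% t(cw(Hd0, alpha)) -
    cw(Ms, 2 * p * alpha) %*% t(Md)
  dimnames(u_hat) <- dimnames(g_hat) <- list(boar_ids, sow_ids)
  structure(list(boar_ids = boar_ids, sow_ids = sow_ids,
                 u_hat = u_hat, g_hat = g_hat),
            class = "mating_grid")
}

#' @export
print.mating_grid <- function(x, ...) {
  cat(sprintf("<mating_grid> %d boars x %d sows (%d candidate matings)\n",
              length(x$boar_ids), length(x$sow_ids),
              length(x$boar_ids) * length(x$sow_ids)))
  invisible(x)
}

#' @export
as_tibble.mating_grid <- function(x, ...) {
  tibble::tibble(
    boar = rep(x$boar_ids, times = length(x$sow_ids)),
    sow = rep(x$sow_ids, each = length(x$boar_ids)),
    u_hat = as.vector(x$u_hat),
    g_hat = as.vector(x$g_hat)
  )
}

#' Preselect boars on GEBV
#'
#' Keeps the `n_keep` best boars by genomic estimated breeding value in the
#' favourable direction (ties broken deterministically by animal id), or a
#' random subset for the robustness scenario.
#'
#' @param gebv_tbl tibble (`animal`, `gebv`) as returned by [gebv()].
#' @param n_keep number of boars to keep (default 120, a typical annual
#'   boar intake).
#' @param direction `"lower_better"` (e.g. age at 100 kg, backfat) or
#'   `"higher_better"` (e.g. litter birth weight).
#' @param method `"gebv"` (truncation on GEBV) or `"random"`.
#' @param seed seed for `method = "random"`.
#' @return character vector of selected boar ids.
#' @export
preselect_boars <- function(gebv_tbl, n_keep = 120,
                            direction = c("lower_better", "higher_better"),
                            method = c("gebv", "random"), seed = 1L) {
  direction <- match.arg(direction)
  method <- match.arg(method)
  n_keep <- min(n_keep, nrow(gebv_tbl))
  if (method == "random") {
    ids <- with_substream(seed, "boar_preselect",
                          sample(gebv_tbl$animal, n_keep))
    return(sort(ids))
  }
  key <- if (direction == "lower_better") gebv_tbl$gebv else -gebv_tbl$gebv
  ord <- order(key, gebv_tbl$animal)
  gebv_tbl$animal[ord[seq_len(n_keep)]]
}

#' Allocate matings by exact linear programming
#'
#' Selects `n_matings` boar x sow pairs maximising (or minimising, for
#' traits where lower is better) the summed expected progeny value, subject
#' to at most `boar_capacity` sows per boar and at most one boar per sow.
#' The constraint matrix is a transportation polytope, so the linear-program
#' optimum is integral; it is found exactly by a successive-shortest-path
#' min-cost-flow solver and is deterministic for a fixed input ordering.
#'
#' @param grid a `mating_grid` from [build_mating_grid()].
#' @param objective optimise on expected breeding value (`"u"`) or expected
#'   total genetic value (`"g"`).
#' @param n_matings total number of matings (equality constraint).
#' @param boar_capacity maximum sows per boar.
#' @param direction trait direction; `"lower_better"` minimises.
#' @return a `mating_plan`: tibble (`boar`, `sow`, `u_hat`, `g_hat`) with
#'   attributes `objective`, `objective_value`, `n_matings`,
#'   `boar_capacity`, `direction`.
#' @export
allocate_matings <- function(grid, objective = c("u", "g"), n_matings = 600,
                             boar_capacity = 15,
                             direction = c("lower_better", "higher_better")) {
  objective <- match.arg(objective)
  direction <- match.arg(direction)
  nb <- length(grid$boar_ids); ns <- length(grid$sow_ids)
  bound <- min(ns, nb * boar_capacity)
  if (n_matings > bound) {
    stop(sprintf(paste0("infeasible: n_matings = %d exceeds the binding ",
                        "bound min(n_sows = %d, n_boars x capacity = %d)"),
                 n_matings, ns, nb * boar_capacity), call. = FALSE)
  }
  values <- if (objective == "u") grid$u_hat else grid$g_hat
  if (any(!is.finite(values))) stop("non-finite mating values", call. = FALSE)
  sign <- if (direction == "lower_better") -1 else 1
  sel <- .mcf_allocate(sign * values, as.integer(boar_capacity),
                       as.integer(n_matings))
  if (attr(sel, "flow") < n_matings) {
    stop("solver could not route all matings (infeasible)", call. = FALSE)
  }
  plan <- tibble::tibble(
    boar = grid$boar_ids[sel[, 1]],
    sow = grid$sow_ids[sel[, 2]],
    u_hat = grid$u_hat[sel],
    g_hat = grid$g_hat[sel]
  )
  plan <- dplyr::arrange(plan, boar, sow)
  structure(plan,
            objective = objective,
            objective_value = sum(if (objective == "u") plan$u_hat else plan$g_hat),
            n_matings = n_matings, boar_capacity = boar_capacity,
            direction = direction,
            class = c("mating_plan", class(plan)))
}

#' Expected genetic gains of a mating plan
#'
#' `Delta_U` is the mean expected progeny breeding value of the selected
#' matings minus the mean over all candidate matings; `Delta_G` the same on
#' total genetic values. Both are also expressed in genetic standard
#' deviations by dividing by `sqrt(sigma2_A)`.
#'
#' @param plan a `mating_plan`.
#' @param grid the `mating_grid` it was selected from.
#' @param sigma2_A additive genetic variance used for the SD scale
#'   (optional; SD-scale columns are `NA` when absent).
#' @return one-row tibble: `objective`, `delta_U`, `delta_G`,
#'   `delta_U_sd`, `delta_G_sd`, `objective_value`, `n_matings`,
#'   `n_boars_used`.
#' @export
mating_gains <- function(plan, grid, sigma2_A = NULL) {
  dU <- mean(plan$u_hat) - mean(grid$u_hat)
  dG <- mean(plan$g_hat) - mean(grid$g_hat)
  sdA <- if (is.null(sigma2_A)) NA_real_ else sqrt(sigma2_A)
  tibble::tibble(
    objective = attr(plan, "objective"),
    delta_U = dU, delta_G = dG,
    delta_U_sd = dU / sdA, delta_G_sd = dG / sdA,
    objective_value = attr(plan, "objective_value"),
    n_matings = nrow(plan),
    n_boars_used = dplyr::n_distinct(plan$boar)
  )
}
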
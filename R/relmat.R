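#' Centered additive marker design M
#'
#' VanRaden's centered coding: `2 - 2p_k`, `1 - 2p_k`, `-2p_k` for genotypes
#' AA, Aa, aa of SNP `k`. Missing calls are set to the population average of
#' the coding, i.e. 0.
#'
#' @param geno a [genotype_matrix()]; frozen frequencies are used when
#'   present, else the observed ones.
#' @return numeric n x m matrix.
#' @export
build_M <- function(geno) {
  p <- geno_freq(geno)
  if (anyNA(p)) stop("allele frequency undefined for some SNPs", call. = FALSE)
  M <- sweep(geno$counts, 2, 2 * p)
  M[is.na(M)] <- 0
  M
}

#' Dominance-deviation design W
#'
#' Coding `-2q_k^2`, `2p_k q_k`, `-2p_k^2` for AA, Aa, aa; the classical
#' dominance-deviation parameterisation whose per-SNP population mean is 0
#' under Hardy-Weinberg. Missing calls are set to the population average of
#' the coding, i.e. 0.
#'
#' @inheritParams build_M
#' @return numeric n x m matrix.
#' @export
build_W <- function(geno) {
  p <- geno_freq(geno)
  if (anyNA(p)) stop("allele frequency undefined for some SNPs", call. = FALSE)
  W <- dominance_coding(geno$counts, p)
  W[is.na(W)] <- 0
  W
}

# raw W coding, NA preserved
dominance_coding <- function(counts, p) {
  q <- 1 - p
  n <- nrow(counts)
  pA <- matrix(p, n, length(p), byrow = TRUE)
  qA <- 1 - pA
  W <- counts
  W[] <- NA_real_
  i2 <- which(counts == 2)
  i1 <- which(counts == 1)
  i0 <- which(counts == 0)
  W[i2] <- (-2 * qA^2)[i2]
  W[i1] <- (2 * pA * qA)[i1]
  W[i0] <- (-2 * pA^2)[i0]
  W
}

#' Additive genomic relationship matrix G (VanRaden)
#'
#' `G = M M' / (2 * sum(p_k q_k))` with `M` from [build_M()]. The
#' denominator uses the frozen allele frequencies, so monomorphic SNPs
#' contribute zero to both numerator and denominator.
#'
#' @inheritParams build_M
#' @return a `relationship_matrix` (symmetric n x n, `kind = "G"`).
#' @export
build_G <- function(geno) {
  p <- geno_freq(geno)
  denom <- 2 * sum(p * (1 - p))
  if (denom == 0) stop("all SNPs monomorphic: G denominator is zero", call. = FALSE)
  M <- build_M(geno)
  new_relmat(tcrossprod(M) / denom, "G")
}

#' Dominance genomic relationship matrix D
#'
#' `D = W W' / sum((2 p_k q_k)^2)` with `W` from [build_W()].
#'
#' @inheritParams build_M
#' @return a `relationship_matrix` (`kind = "D"`).
#' @export
build_D <- function(geno) {
  p <- geno_freq(geno)
  denom <- sum((2 * p * (1 - p))^2)
  if (denom == 0) stop("all SNPs monomorphic: D denominator is zero", call. = FALSE)
  W <- build_W(geno)
  new_relmat(tcrossprod(W) / denom, "D")
}

new_relmat <- function(values, kind, blend_weight = 1) {
  structure(values, kind = kind, blend_weight = blend_weight,
            class = c("relationship_matrix", "matrix", "array"))
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat(sprintf("<relationship_matrix %s> %d x %d (blend weight %.3g)\n",
              attr(x, "kind"), nrow(x), ncol(x), attr(x, "blend_weight")))
  invisible(x)
}

#' Blend a relationship matrix with the identity
#'
#' `K* = w K + (1 - w) I`, the standard numerical-stability scaling (default
#' `w = 0.95`) that guarantees positive definiteness before REML.
#'
#' @param K a `relationship_matrix` (or plain symmetric matrix)
#' @param w blend weight in (0, 1]; `w = 1` returns `K` unchanged.
#' @return a `relationship_matrix` with `kind` suffixed `_blend` when
#'   `w < 1`.
#' @export
blend <- function(K, w = 0.95) {
  stopifnot(w >= 0, w <= 1)
  kind <- attr(K, "kind") %||% "K"
  out <- w * unclass(K) + diag(1 - w, nrow(K))
  dimnames(out) <- dimnames(K)
  new_relmat(out, if (w < 1) paste0(kind, "_blend") else kind, blend_weight = w)
}

#' Genomic inbreeding: proportion of homozygous genotypes
#'
#' `f_i` is the number of homozygous non-missing calls divided by the number
#' of non-missing calls of animal `i`.
#'
#' @param geno a [genotype_matrix()]
#' @return tibble with columns `animal` and `f`.
#' @export
genomic_inbreeding <- function(geno) {
  counts <- geno$counts
  n_called <- rowSums(!is.na(counts))
  if (any(n_called == 0)) {
    stop("animal(s) with zero non-missing calls: ",
         paste(rownames(counts)[n_called == 0], collapse = ", "), call. = FALSE)
  }
  f <- unname(rowSums(counts != 1, na.rm = TRUE) / n_called)
  tibble::tibble(animal = rownames(counts), f = f)
}

#' Pedigree numerator relationship matrix A (tabular method)
#'
#' Classical tabular construction: animals are sorted so parents precede
#' offspring, unknown parents are treated as unrelated non-inbred founders,
#' and `a_ij = (a_{j,sire(i)} + a_{j,dam(i)})/2`,
#' `a_ii = 1 + a_{sire(i),dam(i)}/2`.
#'
#' @param ped tibble with columns `animal`, `sire`, `dam`; "0" or `NA`
#'   marks an unknown parent. A pedigree cycle raises an error naming the
#'   animals involved.
#' @return a `relationship_matrix` (`kind = "A"`) over all pedigree animals,
#'   in the original row order of `ped`.
#' @export
build_A <- function(ped) {
  ped <- tibble::as_tibble(ped)
  ids <- as.character(ped$animal)
  if (anyDuplicated(ids)) stop("duplicated animals in pedigree", call. = FALSE)
  clean <- function(x) {
    x <- as.character(x)
    x[is.na(x) | x == "0" | x == ""] <- NA
    x
  }
  sire <- clean(ped$sire); dam <- clean(ped$dam)
  unknown_parents <- setdiff(stats::na.omit(c(sire, dam)), ids)
  if (length(unknown_parents)) {
    # parents never listed as animals become founders
    ids <- c(unknown_parents, ids)
    sire <- c(rep(NA, length(unknown_parents)), sire)
    dam <- c(rep(NA, length(unknown_parents)), dam)
  }
  n <- length(ids)
  si <- match(sire, ids); di <- match(dam, ids)

  # topological sort (Kahn); a leftover set means a cycle
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (pp in c(si[i], di[i])) {
      if (!is.na(pp)) {
        indeg[i] <- indeg[i] + 1L
        children[[pp]] <- c(children[[pp]], i)
      }
    }
  }
  order <- integer(0)
  queue <- which(indeg == 0)
  indeg2 <- indeg
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    for (ch in children[[v]]) {
      indeg2[ch] <- indeg2[ch] - 1L
      if (indeg2[ch] == 0) queue <- c(queue, ch)
    }
  }
  if (length(order) < n) {
    stop("pedigree contains a cycle involving: ",
         paste(ids[setdiff(seq_len(n), order)], collapse = " -> "),
         call. = FALSE)
  }

  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in order) {
    s <- si[i]; d <- di[i]
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) A[s, d] / 2 else 0
    for (j in order) {
      if (j == i) break
      a <- 0
      if (!is.na(s)) a <- a + A[j, s]
      if (!is.na(d)) a <- a + A[j, d]
      A[i, j] <- A[j, i] <- a / 2
    }
  }
  keep <- as.character(ped$animal)
  new_relmat(A[keep, keep, drop = FALSE], "A")
}

#' Write / read a relationship matrix as dense CSV
#'
#' Animal ids form the header row and first column.
#' @param K a `relationship_matrix`
#' @param path file path
#' @export
write_relmat_csv <- function(K, path) {
  df <- data.frame(animal = rownames(K), unclass(K), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(K)
}

#' @rdname write_relmat_csv
#' @param kind matrix kind label to attach on read
#' @export
read_relmat_csv <- function(path, kind = "K") {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  new_relmat(m, kind)
}
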
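# small deterministic fixtures shared across tests

tiny_geno <- function(counts, p = NULL, ids = NULL, snps = NULL) {
  counts <- as.matrix(counts)
  rownames(counts) <- ids %||% paste0("a", seq_len(nrow(counts)))
  colnames(counts) <- snps %||% paste0("s", seq_len(ncol(counts)))
  matealloc::genotype_matrix(counts, p = p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force kinship by recursive Malecot coancestry (oracle for build_A)
kinship_oracle <- function(ped) {
  ids <- as.character(ped$animal)
  sire <- as.character(ped$sire)
  dam <- as.character(ped$dam)
  sire[sire == "0"] <- NA
  dam[dam == "0"] <- NA
  phi <- function(x, y) {
    if (is.na(x) || is.na(y)) return(0)
    ix <- match(x, ids)
    iy <- match(y, ids)
    if (ix == iy) {
      return(0.5 * (1 + phi(sire[ix], dam[ix])))
    }
    # recurse on the later-listed animal (parents precede offspring)
    if (ix < iy) {
      tmp <- ix
      ix <- iy
      iy <- tmp
    }
    0.5 * (phi(sire[ix], ids[iy]) + phi(dam[ix], ids[iy]))
  }
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(i)) {
      A[i, j] <- A[j, i] <- 2 * phi(ids[i], ids[j])
    }
  }
  A
}

# brute-force optimum of the allocation problem by enumeration
allocation_oracle <- function(values, capacity, n_matings, maximize = TRUE) {
  nb <- nrow(values)
  ns <- ncol(values)
  cells <- expand.grid(i = seq_len(nb), j = seq_len(ns))
  best <- if (maximize) -Inf else Inf
  combs <- utils::combn(nrow(cells), n_matings)
  for (k in seq_len(ncol(combs))) {
    sel <- cells[combs[, k], ]
    if (any(table(sel$j) > 1) || any(table(sel$i) > capacity)) next
    v <- sum(values[cbind(sel$i, sel$j)])
    best <- if (maximize) max(best, v) else min(best, v)
  }
  best
}
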
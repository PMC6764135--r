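#' Genotype matrix container
#'
#' A light S3 container around an animals x SNPs matrix of allele-A counts
#' (0, 1, 2, or `NA` for missing calls), together with the per-SNP frequency
#' of allele A. Frequencies are "frozen" once computed (normally right after
#' quality control) and reused by every downstream consumer — relationship
#' matrices, marker-effect models and GEBVs must all see the same `p`.
#'
#' @param counts integer or numeric matrix, animals in rows (rownames are
#'   animal ids) and SNPs in columns (colnames are SNP ids); values in
#'   `{0, 1, 2, NA}` counting copies of allele A.
#' @param p optional numeric vector of allele-A frequencies, one per SNP.
#'   When `NULL` the frequencies are left unset; call [freeze_freq()] to
#'   compute and store the observed frequencies.
#'
#' @return An object of class `genotype_matrix` with elements `counts` and
#'   `p`.
#' @examples
#' g <- genotype_matrix(matrix(c(0, 1, 2, 1), 2, 2,
#'   dimnames = list(c("a1", "a2"), c("s1", "s2"))))
#' g <- freeze_freq(g)
#' g$p
#' @export
genotype_matrix <- function(counts, p = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("id", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("snp", seq_len(ncol(counts)))
  }
  bad <- !(counts %in% c(0L, 1L, 2L) | is.na(counts))
  if (any(bad)) {
    stop("genotype counts must be 0, 1, 2 or NA", call. = FALSE)
  }
  storage.mode(counts) <- "double"
  if (!is.null(p)) {
    if (length(p) != ncol(counts)) {
      stop("length(p) must equal the number of SNPs", call. = FALSE)
    }
    if (any(p < 0 | p > 1)) stop("allele frequencies must lie in [0, 1]", call. = FALSE)
    p <- stats::setNames(as.numeric(p), colnames(counts))
  }
  structure(list(counts = counts, p = p), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d animals x %d SNPs (%.2f%% missing), frequencies %s\n",
    nrow(x$counts), ncol(x$counts),
    100 * mean(is.na(x$counts)),
    if (is.null(x$p)) "unset" else "frozen"
  ))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param x a `genotype_matrix`
#' @export
n_animals <- function(x) nrow(x$counts)

#' @rdname genotype_matrix
#' @export
n_snps <- function(x) ncol(x$counts)

#' @rdname genotype_matrix
#' @export
animal_ids <- function(x) rownames(x$counts)

#' @rdname genotype_matrix
#' @export
snp_ids <- function(x) colnames(x$counts)

#' Observed allele-A frequencies
#'
#' Computed from non-missing calls only; a SNP with zero non-missing calls
#' gets frequency `NaN` (it would be removed by the call-rate filter anyway).
#'
#' @param geno a [genotype_matrix()]
#' @return numeric vector of allele-A frequencies, one per SNP.
#' @export
allele_freq <- function(geno) {
  colMeans(geno$counts, na.rm = TRUE) / 2
}

#' Freeze allele frequencies into the container
#'
#' Stores the observed post-QC allele frequencies so every consumer (G, D,
#' marker models, GEBVs, mating predictions) uses the same `p`.
#'
#' @inheritParams allele_freq
#' @param p optional frequencies to store; defaults to [allele_freq()].
#' @return the `genotype_matrix` with `p` set.
#' @export
freeze_freq <- function(geno, p = NULL) {
  if (is.null(p)) p <- allele_freq(geno)
  genotype_matrix(geno$counts, p = p)
}

#' Frozen frequencies, or observed ones with a warning
#' @noRd
geno_freq <- function(geno) {
  if (!is.null(geno$p)) {
    return(geno$p)
  }
  allele_freq(geno)
}

#' Subset a genotype matrix
#'
#' @param geno a [genotype_matrix()]
#' @param animals,snps index vectors (names, integers or logicals) applied to
#'   rows and columns. Frozen frequencies are carried along for kept SNPs.
#' @return a `genotype_matrix`
#' @export
subset_geno <- function(geno, animals = NULL, snps = NULL) {
  counts <- geno$counts
  if (!is.null(animals)) counts <- counts[animals, , drop = FALSE]
  if (!is.null(snps)) counts <- counts[, snps, drop = FALSE]
  p <- geno$p
  if (!is.null(p)) p <- p[colnames(counts)]
  genotype_matrix(counts, p = p)
}

#' Read and write genotypes
#'
#' `write_plink_raw()`/`read_plink_raw()` use the PLINK `--recode A` dialect:
#' a header line `FID IID PAT MAT SEX PHENOTYPE <snp> ...` followed by one
#' whitespace-separated row per animal with allele counts 0/1/2 or `NA`.
#' `write_geno_csv()`/`read_geno_csv()` use plain CSV with animal ids in the
#' first column.
#'
#' @param geno a [genotype_matrix()]
#' @param path file path
#' @param ped optional pedigree tibble (`animal`, `sire`, `dam`) used to fill
#'   the PAT/MAT columns; unknown parents are written as 0.
#' @return the input (write) or a `genotype_matrix` (read). Frequencies are
#'   not stored in either format and come back unset.
#' @export
write_plink_raw <- function(geno, path, ped = NULL) {
  ids <- animal_ids(geno)
  pat <- mat <- rep("0", length(ids))
  if (!is.null(ped)) {
    idx <- match(ids, ped$animal)
    pat <- ifelse(is.na(idx), "0", as.character(ped$sire[idx]))
    mat <- ifelse(is.na(idx), "0", as.character(ped$dam[idx]))
    pat[is.na(pat) | pat == "NA"] <- "0"
    mat[is.na(mat) | mat == "NA"] <- "0"
  }
  header <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE", snp_ids(geno))
  body <- cbind(
    "0", ids, pat, mat, "0", "-9",
    ifelse(is.na(geno$counts), "NA", format(geno$counts, trim = TRUE, scientific = FALSE))
  )
  writeLines(
    c(paste(header, collapse = " "), apply(body, 1, paste, collapse = " ")),
    path
  )
  invisible(geno)
}

#' @rdname write_plink_raw
#' @export
read_plink_raw <- function(path) {
  tab <- utils::read.table(path, header = TRUE, check.names = FALSE,
                           na.strings = c("NA", "-9."))
  meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(meta %in% names(tab)[seq_along(meta)])) {
    stop("not a PLINK RAW file: expected header FID IID PAT MAT SEX PHENOTYPE ...",
         call. = FALSE)
  }
  counts <- as.matrix(tab[, setdiff(names(tab), meta), drop = FALSE])
  rownames(counts) <- as.character(tab$IID)
  genotype_matrix(counts)
}

#' @rdname write_plink_raw
#' @export
write_geno_csv <- function(geno, path) {
  df <- data.frame(animal = animal_ids(geno), geno$counts, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(geno)
}

#' @rdname write_plink_raw
#' @export
read_geno_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- as.character(df[[1]])
  genotype_matrix(counts)
}
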
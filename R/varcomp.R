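#' Model specification for variance-component estimation
#'
#' Encodes the three model families used for genetic evaluation: `"A"`
#' (pedigree additive model, no genomic-inbreeding covariate), `"G"`
#' (genomic additive model with inbreeding depression) and `"GD"` (genomic
#' additive + dominance model with inbreeding depression). The permanent
#' environmental term is only meaningful for repeated-record traits.
#'
#' @param name one of `"A"`, `"G"`, `"GD"`.
#' @param trait trait name (bookkeeping only).
#' @param fixed character vector of categorical fixed-effect columns.
#' @param covariates character vector of numeric covariate columns (trait
#'   covariates such as birth weight or litter size; the genomic-inbreeding
#'   covariate is handled by `name`, never listed here).
#' @param use_pe include a permanent-environmental random term.
#' @param direction which direction of the trait is favourable (used
#'   downstream by the mate-allocation step).
#' @return a `model_spec` list.
#' @export
model_spec <- function(name = c("GD", "G", "A"), trait = "trait",
                       fixed = character(), covariates = character(),
                       use_pe = FALSE,
                       direction = c("lower_better", "higher_better")) {
  name <- match.arg(name)
  structure(list(
    name = name, trait = trait, fixed = fixed, covariates = covariates,
    use_pe = isTRUE(use_pe),
    include_f = name != "A",          # model A has no inbreeding covariate
    dominance = name == "GD",
    direction = match.arg(direction)
  ), class = "model_spec")
}

#' Henderson mixed-model equations
#'
#' Builds and solves the MME for `y = X beta + sum_j Z_j u_j + e` with
#' `u_j ~ N(0, K_j sigma2_j)` and `e ~ N(0, I sigma2_e)`:
#' the coefficient matrix has blocks `X'X`, `X'Z_j`, and
#' `Z_j'Z_j + K_j^{-1} lambda_j` with variance ratio
#' `lambda_j = sigma2_e / sigma2_j`. With `K = I` and a single term the
#' system reduces to ridge regression with penalty `lambda`.
#'
#' @param y numeric response vector.
#' @param X fixed-effect design matrix (full column rank).
#' @param random list of terms, each a list with elements `name`, `Z`
#'   (n x q design), `lambda` (variance ratio) and optionally `K` (q x q
#'   covariance; identity when absent). `K` is inverted by Cholesky; a
#'   singular `K` raises an error advising blending.
#' @return list with `C` (coefficient matrix), `rhs`, and `solutions`
#'   (`fixed` named vector, `random` named list of vectors).
#' @export
build_mme <- function(y, X, random = list()) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n)
  blocks <- list(X)
  pen <- list(matrix(0, ncol(X), ncol(X)))
  for (term in random) {
    Z <- as.matrix(term$Z)
    stopifnot(nrow(Z) == n)
    q <- ncol(Z)
    Kinv <- if (is.null(term$K)) {
      diag(q)
    } else {
      ch <- tryCatch(chol(unclass(term$K)), error = function(e) {
        stop("covariance for term '", term$name, "' is not positive ",
             "definite; blend it with the identity (see blend())",
             call. = FALSE)
      })
      chol2inv(ch)
    }
    blocks <- c(blocks, list(Z))
    pen <- c(pen, list(Kinv * term$lambda))
  }
  Wmat <- do.call(cbind, blocks)
  C <- crossprod(Wmat)
  off <- 0
  for (j in seq_along(pen)) {
    idx <- off + seq_len(ncol(blocks[[j]]))
    C[idx, idx] <- C[idx, idx] + pen[[j]]
    off <- off + ncol(blocks[[j]])
  }
  rhs <- crossprod(Wmat, y)
  sol <- tryCatch(solve(C, rhs), error = function(e) {
    stop("mixed-model equations are singular: ", conditionMessage(e),
         call. = FALSE)
  })
  off <- ncol(X)
  fixed <- stats::setNames(sol[seq_len(ncol(X)), 1], colnames(X))
  rand <- list()
  for (term in random) {
    q <- ncol(term$Z)
    rand[[term$name]] <- stats::setNames(sol[off + seq_len(q), 1],
                                         colnames(term$Z))
    off <- off + q
  }
  list(C = C, rhs = rhs, solutions = list(fixed = fixed, random = rand))
}

#' REML estimation of variance components by EM (with optional AI steps)
#'
#' Restricted maximum likelihood for
#' `y = X beta + sum_j Z_j u_j + e`, `u_j ~ N(0, K_j sigma2_j)`,
#' `e ~ N(0, I sigma2_e)`, parameterised through the phenotypic covariance
#' `V = sum_j Z_j K_j Z_j' sigma2_j + I sigma2_e`. The default update is the
#' classical EM-REML fixed point, whose restricted log-likelihood never
#' decreases; `method = "ai"` tries an average-information (quasi-Newton)
#' step first and falls back to the EM step whenever the AI step would leave
#' the parameter space or decrease the restricted log-likelihood, so
#' monotonicity holds for both methods and is asserted every iteration.
#'
#' @param pheno tibble with columns `y`, a grouping column per random term
#'   (usually `animal`), plus fixed-effect factors/covariates.
#' @param random named list of random terms. Each element is either a
#'   relationship matrix (rows/columns named by level, grouping column
#'   `"animal"`), `NULL`/`"identity"` for an i.i.d. term on `animal`
#'   (permanent environment), or a list with elements `K` (or `NULL`) and
#'   `group` (column of `pheno` holding the level ids).
#' @param fixed,covariates fixed-effect factor and covariate column names.
#' @param f optional tibble (`animal`, `f`) of genomic inbreeding
#'   coefficients, entered as a covariate whose coefficient is the
#'   inbreeding-depression parameter `b`.
#' @param init optional named initial variances (defaults to an equal split
#'   of `var(y)` across all components).
#' @param tol convergence tolerance on the maximum relative parameter
#'   change (default `1e-8`).
#' @param max_iter iteration cap; non-convergence returns
#'   `converged = FALSE` rather than an error.
#' @param method `"em"` (default) or `"ai"` (AI acceleration with EM
#'   fallback).
#' @param verbose print the per-iteration restricted log-likelihood.
#' @return a `reml_fit` object; see [tidy.reml_fit()] and
#'   [glance.reml_fit()]. Key elements: `varcomp` (tibble with estimates and
#'   asymptotic SEs), `b_hat`/`b_se`, `beta`, `h2`, `ratios`, `logL`,
#'   `aic`, `blup` (per-level random-effect solutions), `logL_trace`,
#'   `converged`, `boundary`.
#' @export
em_reml <- function(pheno, random, fixed = character(),
                    covariates = character(), f = NULL, init = NULL,
                    tol = 1e-8, max_iter = 5000,
                    method = c("em", "ai"), verbose = FALSE) {
  method <- match.arg(method)
  pheno <- tibble::as_tibble(pheno)
  y <- pheno$y
  n <- length(y)
  X <- fixed_design(pheno, fixed, covariates)
  if (!is.null(f)) {
    fv <- f$f[match(pheno$animal, f$animal)]
    if (anyNA(fv)) stop("inbreeding coefficient missing for some animals", call. = FALSE)
    X <- cbind(X, f = fv)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("fixed-effect design is rank-deficient (rank ", qrX$rank, " < ",
         ncol(X), " columns)", call. = FALSE)
  }
  p_rank <- ncol(X)

  terms <- normalize_random(random, pheno)
  J <- length(terms)
  Q <- lapply(terms, function(tm) {
    Zt <- tm$Z
    if (is.null(tm$K)) tcrossprod(Zt) else Zt %*% unclass(tm$K) %*% t(Zt)
  })
  qlev <- vapply(terms, function(tm) ncol(tm$Z), numeric(1))

  vary <- stats::var(y)
  theta <- if (is.null(init)) {
    rep(vary / (J + 1), J + 1)
  } else {
    as.numeric(c(unlist(init[names(terms)]), init[["sigma2_e"]]))
  }
  if (any(theta <= 0)) stop("initial variances must be positive", call. = FALSE)
  names(theta) <- c(names(terms), "residual")
  floor_val <- 1e-8 * vary
  floor_hits <- integer(J + 1)

  # restricted logL (and optionally the full workspace) at theta
  eval_theta <- function(theta, full = TRUE) {
    V <- diag(theta[J + 1], n)
    for (j in seq_len(J)) V <- V + theta[j] * Q[[j]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    logdetV <- 2 * sum(log(diag(ch)))
    Vinv <- chol2inv(ch)
    VX <- Vinv %*% X
    XtVX <- crossprod(X, VX)
    XtVXi <- solve(XtVX)
    Py <- Vinv %*% y - VX %*% (XtVXi %*% crossprod(VX, y))
    ld2 <- determinant(XtVX, logarithm = TRUE)
    logL <- -0.5 * ((n - p_rank) * log(2 * pi) + logdetV +
                      as.numeric(ld2$modulus) + sum(y * Py))
    out <- list(logL = logL, Py = Py, XtVXi = XtVXi)
    if (full) {
      P <- Vinv - VX %*% tcrossprod(XtVXi, VX)
      out$P <- P
    }
    out
  }

  ws <- eval_theta(theta)
  if (is.null(ws)) stop("initial covariance not positive definite", call. = FALSE)
  logL_trace <- ws$logL
  converged <- FALSE
  iter <- 0

  reml_derivs <- function(ws) {
    Py <- ws$Py
    w <- vector("list", J + 1)
    trPQ <- yPQPy <- numeric(J + 1)
    for (j in seq_len(J)) {
      w[[j]] <- Q[[j]] %*% Py
      trPQ[j] <- sum(ws$P * Q[[j]])
      yPQPy[j] <- sum(Py * w[[j]])
    }
    w[[J + 1]] <- Py
    trPQ[J + 1] <- sum(diag(ws$P))
    yPQPy[J + 1] <- sum(Py * Py)
    grad <- -0.5 * (trPQ - yPQPy)
    AI <- matrix(0, J + 1, J + 1)
    for (j in seq_len(J + 1)) {
      Pwj <- ws$P %*% w[[j]]
      for (k in j:(J + 1)) {
        AI[j, k] <- AI[k, j] <- 0.5 * sum(w[[k]] * Pwj)
      }
    }
    list(grad = grad, AI = AI, trPQ = trPQ, yPQPy = yPQPy)
  }

  dv <- reml_derivs(ws)
  while (iter < max_iter) {
    iter <- iter + 1
    qall <- c(qlev, n)
    em_step <- theta + theta^2 / qall * (dv$yPQPy - dv$trPQ)
    em_step <- pmax(em_step, floor_val)
    cand <- NULL
    if (method == "ai") {
      ai_step <- tryCatch(theta + solve(dv$AI, dv$grad), error = function(e) NULL)
      if (!is.null(ai_step) && all(ai_step > floor_val)) {
        trial <- eval_theta(ai_step, full = FALSE)
        if (!is.null(trial) && trial$logL >= ws$logL - 1e-10 * abs(ws$logL)) {
          cand <- ai_step
        }
      }
    }
    if (is.null(cand)) cand <- em_step
    ws_new <- eval_theta(cand)
    if (is.null(ws_new)) { cand <- em_step; ws_new <- eval_theta(cand) }
    if (ws_new$logL < ws$logL - 1e-6 * max(1, abs(ws$logL))) {
      stop(sprintf("restricted logL decreased (%.8f -> %.8f) at iteration %d",
                   ws$logL, ws_new$logL, iter), call. = FALSE)
    }
    rel <- max(abs(cand - theta) / pmax(abs(theta), floor_val))
    floor_hits <- floor_hits + (cand <= floor_val)
    theta <- cand
    ws <- ws_new
    logL_trace <- c(logL_trace, ws$logL)
    if (verbose) message(sprintf("iter %4d  logL %.6f", iter, ws$logL))
    dv <- reml_derivs(ws)
    if (rel < tol) { converged <- TRUE; break }
  }

  # asymptotic covariance of the variance components from the AI matrix
  cov_theta <- tryCatch(solve(dv$AI), error = function(e) {
    matrix(NA_real_, J + 1, J + 1)
  })
  se_theta <- sqrt(pmax(diag(cov_theta), 0))

  # GLS fixed effects at convergence
  V <- diag(theta[J + 1], n)
  for (j in seq_len(J)) V <- V + theta[j] * Q[[j]]
  Vinv <- chol2inv(chol(V))
  VX <- Vinv %*% X
  XtVXi <- solve(crossprod(X, VX))
  beta <- drop(XtVXi %*% crossprod(VX, y))
  names(beta) <- colnames(X)
  beta_se <- sqrt(diag(XtVXi))
  names(beta_se) <- colnames(X)

  blup <- list()
  Py <- ws$Py
  for (j in seq_len(J)) {
    tm <- terms[[j]]
    ZPy <- crossprod(tm$Z, Py)
    u <- if (is.null(tm$K)) theta[j] * ZPy else theta[j] * (unclass(tm$K) %*% ZPy)
    blup[[names(terms)[j]]] <- tibble::tibble(level = colnames(tm$Z),
                                              blup = drop(u))
  }

  sigma2_P <- sum(theta)
  h2 <- unname(theta["additive"] %||% NA_real_) / sigma2_P
  idxA <- match("additive", names(theta))
  idxD <- match("dominance", names(theta))
  ratio_grad <- function(num_idx, den_idx) {
    # delta method for theta[num]/sum(theta[den]); den_idx = all -> sigma2_P
    g <- rep(0, J + 1)
    den <- sum(theta[den_idx])
    g[den_idx] <- -theta[num_idx] / den^2
    g[num_idx] <- g[num_idx] + 1 / den
    sqrt(max(0, drop(t(g) %*% cov_theta %*% g)))
  }
  h2_se <- if (!is.na(idxA)) ratio_grad(idxA, seq_len(J + 1)) else NA_real_
  ratios <- list()
  if (!is.na(idxD) && !is.na(idxA)) {
    ratios$D_A <- theta[[idxD]] / theta[[idxA]]
    ratios$D_A_se <- ratio_grad(idxD, idxA)
    ratios$D_P <- theta[[idxD]] / sigma2_P
    ratios$D_P_se <- ratio_grad(idxD, seq_len(J + 1))
  }

  n_params <- J + 1
  logL <- ws$logL
  fit <- structure(list(
    varcomp = tibble::tibble(component = names(theta),
                             estimate = unname(theta),
                             se = se_theta),
    theta = theta, cov_theta = cov_theta,
    beta = beta, beta_se = beta_se,
    b_hat = if ("f" %in% names(beta)) unname(beta["f"]) else NA_real_,
    b_se = if ("f" %in% names(beta)) unname(beta_se["f"]) else NA_real_,
    h2 = h2, h2_se = h2_se, ratios = ratios, sigma2_P = sigma2_P,
    logL = logL, aic = compute_aic(logL, n_params),
    n_var_params = n_params,
    blup = blup, logL_trace = logL_trace,
    n_iter = iter, converged = converged,
    boundary = names(theta)[floor_hits >= 50],
    n_obs = n, method = method
  ), class = "reml_fit")
  fit
}

# normalise the `random =` argument of em_reml into a list of
# list(K = <matrix or NULL>, Z = <indicator design>) entries
normalize_random <- function(random, pheno) {
  if (is.null(names(random)) || any(names(random) == "")) {
    stop("random terms must be named", call. = FALSE)
  }
  lapply(random, function(term) {
    K <- NULL
    group <- "animal"
    if (is.matrix(term) || inherits(term, "relationship_matrix")) {
      K <- term
    } else if (is.list(term)) {
      K <- term$K
      group <- term$group %||% "animal"
    } else if (!is.null(term) && !identical(term, "identity")) {
      stop("unrecognised random term specification", call. = FALSE)
    }
    gvals <- as.character(pheno[[group]])
    if (is.null(K)) {
      levels <- unique(gvals)
    } else {
      levels <- rownames(K)
      if (!all(gvals %in% levels)) {
        stop("levels of '", group, "' missing from the covariance matrix: ",
             paste(utils::head(setdiff(gvals, levels), 5), collapse = ", "),
             call. = FALSE)
      }
      used <- levels[levels %in% gvals]
      K <- K[used, used, drop = FALSE]
      levels <- used
    }
    Z <- matrix(0, nrow(pheno), length(levels),
                dimnames = list(NULL, levels))
    Z[cbind(seq_len(nrow(pheno)), match(gvals, levels))] <- 1
    list(K = K, Z = Z, group = group)
  })
}

#' Akaike information criterion for a REML fit
#'
#' `AIC = -2 logL_restricted + 2 k`, where `k` counts the estimated
#' variance components only (fixed effects are identical across the genomic
#' models for a trait).
#'
#' @param logL restricted log-likelihood, or a `reml_fit`.
#' @param n_var_params number of estimated variance components (ignored if
#'   a fit is supplied).
#' @return numeric AIC.
#' @export
compute_aic <- function(logL, n_var_params) {
  if (inherits(logL, "reml_fit")) {
    n_var_params <- logL$n_var_params
    logL <- logL$logL
  }
  -2 * logL + 2 * n_var_params
}

#' Asymptotic standard errors from an information matrix
#'
#' `SE(theta_i)` is the square root of the i-th diagonal element of the
#' inverse information matrix; for a smooth function `g(theta)` (a ratio,
#' a heritability) the first-order delta method gives
#' `SE(g) = sqrt(grad' I^{-1} grad)`.
#'
#' @param information information matrix (e.g. the average-information
#'   matrix at convergence).
#' @param grad optional gradient vector (or matrix with one column per
#'   function) for delta-method SEs of functions of the parameters.
#' @return numeric vector of standard errors.
#' @export
asymptotic_se <- function(information, grad = NULL) {
  covm <- solve(information)
  if (is.null(grad)) return(sqrt(pmax(diag(covm), 0)))
  grad <- as.matrix(grad)
  sqrt(pmax(colSums(grad * (covm %*% grad)), 0))
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("REML fit (%s): logL = %.3f, AIC = %.2f, %d iterations%s\n",
              x$method, x$logL, x$aic, x$n_iter,
              if (x$converged) "" else " (NOT converged)"))
  print(x$varcomp)
  if (!is.na(x$b_hat)) {
    cat(sprintf("inbreeding depression b = %.4f (SE %.4f) per unit f\n",
                x$b_hat, x$b_se))
  }
  if (!is.na(x$h2)) cat(sprintf("h2 = %.4f (SE %.4f)\n", x$h2, x$h2_se))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a REML fit
#'
#' One row per estimated parameter: variance components, derived ratios
#' (heritability, dominance/additive, dominance/phenotypic) and the
#' inbreeding-depression coefficient, with asymptotic standard errors.
#'
#' @param x a `reml_fit`
#' @param ... unused
#' @return a tibble with columns `term`, `estimate`, `std.error`.
#' @export
tidy.reml_fit <- function(x, ...) {
  out <- tibble::tibble(
    term = paste0("sigma2_", sub("additive", "A",
                  sub("dominance", "D", sub("residual", "e", x$varcomp$component)))),
    estimate = x$varcomp$estimate,
    std.error = x$varcomp$se
  )
  extra <- tibble::tibble(term = character(), estimate = numeric(),
                          std.error = numeric())
  if (!is.na(x$h2)) {
    extra <- dplyr::bind_rows(extra, tibble::tibble(
      term = "h2", estimate = x$h2, std.error = x$h2_se))
  }
  if (length(x$ratios)) {
    extra <- dplyr::bind_rows(extra, tibble::tibble(
      term = c("ratio_D_A", "ratio_D_P"),
      estimate = c(x$ratios$D_A, x$ratios$D_P),
      std.error = c(x$ratios$D_A_se, x$ratios$D_P_se)))
  }
  if (!is.na(x$b_hat)) {
    extra <- dplyr::bind_rows(extra, tibble::tibble(
      term = "b", estimate = x$b_hat, std.error = x$b_se))
  }
  dplyr::bind_rows(out, extra)
}

#' Glance at a REML fit
#'
#' @inheritParams tidy.reml_fit
#' @return a one-row tibble: `logLik`, `AIC`, `nobs`, `n_iter`,
#'   `converged`.
#' @export
glance.reml_fit <- function(x, ...) {
  tibble::tibble(logLik = x$logL, AIC = x$aic, nobs = x$n_obs,
                 n_iter = x$n_iter, converged = x$converged)
}

#' @export
logLik.reml_fit <- function(object, ...) {
  structure(object$logL, df = object$n_var_params, class = "logLik")
}

#' Animal-level BLUP at known variance components
#'
#' Solves the animal-level mixed model
#' `y = X beta + (f b) + sum_j Z_j u_j + e` for fixed effects and BLUPs with
#' the variance components treated as known, through the phenotypic
#' covariance `V` (so a singular relationship matrix — e.g. an unblended G
#' centered at the observed allele frequencies — is handled exactly).
#'
#' @inheritParams em_reml
#' @param theta named variances: one per random term plus `residual`.
#' @return list with `beta` and `blup` (named list of tibbles
#'   `level`, `blup`).
#' @export
gblup <- function(pheno, random, theta, fixed = character(),
                  covariates = character(), f = NULL) {
  pheno <- tibble::as_tibble(pheno)
  y <- pheno$y
  n <- length(y)
  X <- fixed_design(pheno, fixed, covariates)
  if (!is.null(f)) X <- cbind(X, f = f$f[match(pheno$animal, f$animal)])
  terms <- normalize_random(random, pheno)
  V <- diag(theta[["residual"]], n)
  for (j in seq_along(terms)) {
    tm <- terms[[j]]
    Qj <- if (is.null(tm$K)) tcrossprod(tm$Z) else tm$Z %*% unclass(tm$K) %*% t(tm$Z)
    V <- V + theta[[names(terms)[j]]] * Qj
  }
  Vinv <- chol2inv(chol(V))
  VX <- Vinv %*% X
  XtVXi <- solve(crossprod(X, VX))
  beta <- drop(XtVXi %*% crossprod(VX, y))
  names(beta) <- colnames(X)
  Py <- Vinv %*% y - VX %*% (XtVXi %*% crossprod(VX, y))
  blup <- list()
  for (j in seq_along(terms)) {
    tm <- terms[[j]]
    ZPy <- crossprod(tm$Z, Py)
    u <- if (is.null(tm$K)) theta[[names(terms)[j]]] * ZPy else
      theta[[names(terms)[j]]] * (unclass(tm$K) %*% ZPy)
    blup[[names(terms)[j]]] <- tibble::tibble(level = colnames(tm$Z),
                                              blup = drop(u))
  }
  list(beta = beta, blup = blup)
}
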
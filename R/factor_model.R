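#' Exploratory five-factor modelling with target rotation
#'
#' The measurement model is an exploratory factor model on the cluster
#' indicators, rotated toward a partially specified target: every cell
#' outside an indicator's intended domain is targeted at zero, intended
#' cells are left free. With an oblique rotation this approximates the
#' exploratory-structural-equation-modelling solutions reported for this
#' item design (point estimates only; robust standard errors are out of
#' scope). Extraction is by maximum likelihood, minimum residual, or
#' principal components; rotation uses a gradient projection algorithm on
#' the orthogonal or oblique rotation manifold.
#'
#' @name factor-model
NULL

#' Correlation matrix of an indicator matrix
#'
#' @param ind numeric matrix (respondents x indicators), missing allowed.
#' @param use `"complete"` (listwise, the default) or `"pairwise"`.
#' @return list with `R` (unit-diagonal symmetric correlation matrix) and
#'   `n_used` (rows entering the computation; for pairwise, the minimum
#'   pairwise n).
#' @export
correlation_matrix <- function(ind, use = c("complete", "pairwise")) {
  use <- match.arg(use)
  if (ncol(ind) < 2L) stop("need at least two indicators")
  cc <- stats::complete.cases(ind)
  n_used <- if (use == "complete") sum(cc) else {
    present <- !is.na(ind)
    min(crossprod(present))
  }
  if (sum(cc) < 2L && use == "complete") stop("fewer than 2 complete rows")
  sds <- apply(ind, 2, stats::sd, na.rm = TRUE)
  zero <- colnames(ind)[!is.finite(sds) | sds == 0]
  if (length(zero))
    stop("zero-variance indicator(s): ", paste(zero, collapse = ", "))
  R <- stats::cor(ind, use = if (use == "complete") "complete.obs"
                             else "pairwise.complete.obs")
  R <- (R + t(R)) / 2
  diag(R) <- 1
  list(R = R, n_used = as.integer(n_used))
}

# Repair a slightly indefinite correlation matrix by ridging, with warning.
.repair_psd <- function(R) {
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 0) {
    # warn only for genuinely indefinite input; numerical dust is fixed quietly
    if (min(ev) < -1e-8)
      warning("correlation matrix not positive semi-definite (min eigenvalue ",
              signif(min(ev), 3), "); ridge-repaired", call. = FALSE)
    ridge <- abs(min(ev)) + 1e-8
    R <- (R + ridge * diag(nrow(R))) / (1 + ridge)
    diag(R) <- 1
  }
  R
}

# Squared multiple correlations; ipsatized indicator sets make R exactly
# singular (centering introduces one linear dependency), so invert with a
# small ridge when needed.
.smc <- function(R) {
  inv <- tryCatch(solve(R), error = function(e) solve(R + diag(1e-4, nrow(R))))
  1 - 1 / diag(inv)
}

# Loadings from a reduced correlation matrix with communalities 1 - psi on
# the diagonal: first m principal axes.
.principal_axes <- function(R, psi, m) {
  S <- R
  diag(S) <- 1 - psi
  e <- eigen(S, symmetric = TRUE)
  L <- e$vectors[, seq_len(m), drop = FALSE] %*%
    diag(sqrt(pmax(e$values[seq_len(m)], 0)), m)
  rownames(L) <- rownames(R)
  L
}

#' Extract an unrotated factor (or component) solution
#'
#' `minres` minimizes the sum of squared off-diagonal residuals over the
#' uniquenesses; `ml` minimizes the normal-theory maximum-likelihood
#' discrepancy (via [stats::factanal()]); `pca` returns eigenvector
#' loadings scaled by the root eigenvalues. Uniquenesses below 0.005
#' (Heywood cases) are clamped and flagged.
#'
#' @param R correlation matrix (k x k).
#' @param m number of factors, `1 <= m < k` (for pca, `m <= k`).
#' @param method `"ml"`, `"minres"` or `"pca"`.
#' @return object of class `factor_solution`: list with `loadings`
#'   (k x m), `uniquenesses`, `phi` (identity until an oblique rotation),
#'   `rotation = "none"`, `method`, `criterion_value` (extraction
#'   discrepancy) and `heywood` (logical vector of clamped rows).
#' @export
extract_factors <- function(R, m, method = c("minres", "ml", "pca")) {
  method <- match.arg(method)
  k <- ncol(R)
  if (m < 1 || (method != "pca" && m >= k) || m > k)
    stop("invalid number of factors for k = ", k)
  R <- .repair_psd(R)
  # Within-person centering makes indicator sets exactly collinear (one
  # dependency among the oriented identity indicators), so R can be
  # singular; a minimal ridge keeps the ML discrepancy finite while
  # perturbing correlations by < 1e-6.
  ev_min <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (method != "pca" && ev_min < 1e-7) {
    R <- (R + 1e-6 * diag(k)) / (1 + 1e-6)
    diag(R) <- 1
  }

  if (method == "pca") {
    e <- eigen(R, symmetric = TRUE)
    L <- e$vectors[, seq_len(m), drop = FALSE] %*%
      diag(sqrt(pmax(e$values[seq_len(m)], 0)), m)
    psi <- 1 - rowSums(L^2)
    crit <- 0
  } else if (method == "ml") {
    # factanal's default start occasionally fails on large well-conditioned
    # matrices; retry from an SMC-based start, then from flat uniquenesses
    smc_start <- pmin(pmax(1 - .smc(R), 0.01), 0.95)
    fa <- tryCatch(
      stats::factanal(covmat = R, factors = m, rotation = "none", lower = 0.005),
      error = function(e) tryCatch(
        stats::factanal(covmat = R, factors = m, rotation = "none",
                        lower = 0.005, start = smc_start),
        error = function(e2)
          stats::factanal(covmat = R, factors = m, rotation = "none",
                          lower = 0.005, start = rep(0.5, k))))
    L <- matrix(fa$loadings, k, m)
    psi <- fa$uniquenesses
    crit <- unname(fa$criteria["objective"])
  } else {
    start <- pmin(pmax(1 - .smc(R), 0.05), 1)
    low <- lower.tri(R)
    obj <- function(psi) {
      L <- .principal_axes(R, psi, m)
      res <- R - tcrossprod(L)
      sum(res[low]^2)
    }
    opt <- stats::optim(start, obj, method = "L-BFGS-B",
                        lower = 0.005, upper = 1,
                        control = list(maxit = 1000, factr = 1e4))
    psi <- opt$par
    L <- .principal_axes(R, psi, m)
    # report uniqueness consistent with the fitted loadings
    psi <- pmax(1 - rowSums(L^2), 0)
    crit <- opt$value
  }

  # Heywood screening applies to common-factor methods; pca communalities
  # may legitimately reach 1
  heywood <- if (method == "pca") rep(FALSE, k) else psi < 0.005
  if (any(heywood)) {
    warning(sum(heywood), " Heywood case(s): uniqueness clamped to 0.005",
            call. = FALSE)
    psi[heywood] <- 0.005
  }
  rownames(L) <- rownames(R)
  colnames(L) <- paste0("F", seq_len(m))
  structure(list(loadings = L, uniquenesses = stats::setNames(psi, rownames(R)),
                 phi = diag(m), rotation = "none", method = method,
                 criterion_value = crit, heywood = heywood,
                 convergence = TRUE),
            class = "factor_solution")
}

#' @export
print.factor_solution <- function(x, ...) {
  cat(sprintf("factor_solution: %d indicators, %d factors, method = %s, rotation = %s\n",
              nrow(x$loadings), ncol(x$loadings), x$method, x$rotation))
  if (!is.null(x$criterion_value))
    cat(sprintf("  criterion value: %.6g\n", x$criterion_value))
  invisible(x)
}

# Partially specified target criterion: sum of squared loadings over the
# cells designated zero. W is 1 on zero-targeted cells, 0 on free cells.
.vgQ_target <- function(L, W) {
  list(f = sum((W * L)^2), Gq = 2 * W * L)
}

# Gradient projection on the orthogonal rotation manifold
# (Jennrich-style; criterion minimized).
.gp_orth <- function(A, W, Tmat, max_iter = 1000, tol = 1e-6) {
  L <- A %*% Tmat
  v <- .vgQ_target(L, W)
  G <- crossprod(A, v$Gq)
  al <- 1
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    M <- crossprod(Tmat, G)
    S <- (M + t(M)) / 2
    Gp <- G - Tmat %*% S
    s <- sqrt(sum(Gp^2))
    if (s < tol) { converged <- TRUE; break }
    al <- 2 * al
    for (half in 1:20) {
      X <- Tmat - al * Gp
      sv <- La.svd(X)
      Tt <- sv$u %*% sv$vt
      Lt <- A %*% Tt
      vt <- .vgQ_target(Lt, W)
      if (vt$f < v$f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    Tmat <- Tt
    v <- vt
    G <- crossprod(A, vt$Gq)
  }
  list(loadings = A %*% Tmat, phi = diag(ncol(A)), Tmat = Tmat,
       f = v$f, converged = converged)
}

# Gradient projection on the oblique rotation manifold (unit-length
# columns of Tmat; pattern loadings A %*% t(solve(Tmat))).
.gp_oblq <- function(A, W, Tmat, max_iter = 1000, tol = 1e-6) {
  Ti <- solve(Tmat)
  L <- A %*% t(Ti)
  v <- .vgQ_target(L, W)
  G <- -t(t(L) %*% v$Gq %*% Ti)
  al <- 1
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    Gp <- G - Tmat %*% diag(diag(crossprod(Tmat, G)), ncol(Tmat))
    s <- sqrt(sum(Gp^2))
    if (s < tol) { converged <- TRUE; break }
    al <- 2 * al
    for (half in 1:20) {
      X <- Tmat - al * Gp
      Tt <- X %*% diag(1 / sqrt(colSums(X^2)), ncol(X))
      Ti <- solve(Tt)
      Lt <- A %*% t(Ti)
      vt <- .vgQ_target(Lt, W)
      if (vt$f < v$f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    Tmat <- Tt
    v <- vt
    G <- -t(t(Lt) %*% vt$Gq %*% Ti)
  }
  Ti <- solve(Tmat)
  list(loadings = A %*% t(Ti), phi = crossprod(Tmat), Tmat = Tmat,
       f = v$f, converged = converged)
}

# random orthonormal m x m matrix
.random_orth <- function(m) {
  qr.Q(qr(matrix(stats::rnorm(m * m), m)))
}

#' Rotate loadings toward a partially specified target
#'
#' Minimizes the sum of squared loadings over the target-zero cells by
#' gradient projection on the orthogonal or oblique rotation manifold.
#' Several random orthonormal starts (plus the identity start) guard
#' against local minima; the best criterion is kept.
#'
#' @param solution a `factor_solution` (or a bare loading matrix) holding
#'   the unrotated loadings.
#' @param target_mask k x m matrix: `0` marks cells targeted at zero, `NA`
#'   marks free cells. Each column needs at least one free cell.
#' @param oblique logical; oblique rotation (default) or orthogonal.
#' @param n_starts number of random starts in addition to the identity.
#' @param seed optional seed for the random starts.
#' @param max_iter,tol gradient projection iteration cap and gradient norm
#'   tolerance (non-convergence is a warning, not an error).
#' @return a `factor_solution` with rotated `loadings`, factor correlation
#'   `phi` (identity if orthogonal), `criterion_value`, and `rotation` set
#'   to `"target-oblique"` or `"target-orthogonal"`.
#' @export
rotate_to_target <- function(solution, target_mask, oblique = TRUE,
                             n_starts = 10, seed = NULL,
                             max_iter = 1000, tol = 1e-6) {
  A <- if (inherits(solution, "factor_solution")) solution$loadings
       else as.matrix(solution)
  k <- nrow(A); m <- ncol(A)
  if (!all(dim(target_mask) == c(k, m)))
    stop("target mask must be ", k, " x ", m)
  W <- ifelse(is.na(target_mask), 0, 1)
  if (any(colSums(W) == k))
    stop("each target column needs at least one free (NA) cell")
  if (qr(A)$rank < m) stop("unrotated loadings are rank deficient")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  }
  engine <- if (oblique) .gp_oblq else .gp_orth
  starts <- c(list(diag(m)), replicate(n_starts, .random_orth(m),
                                       simplify = FALSE))
  best <- NULL
  for (s in starts) {
    res <- engine(A, W, s, max_iter = max_iter, tol = tol)
    if (is.null(best) || res$f < best$f) best <- res
  }
  if (!best$converged)
    warning("target rotation did not reach gradient tolerance ", tol,
            " within ", max_iter, " iterations", call. = FALSE)
  L <- best$loadings
  dimnames(L) <- dimnames(A)
  out <- if (inherits(solution, "factor_solution")) solution
         else list(uniquenesses = NULL, method = "unknown", heywood = NULL)
  out$loadings <- L
  out$phi <- best$phi
  out$rotation <- if (oblique) "target-oblique" else "target-orthogonal"
  out$criterion_value <- best$f
  out$convergence <- best$converged
  class(out) <- "factor_solution"
  out
}

#' Build a target mask from a one-hot target matrix
#'
#' Cells outside an indicator's intended domain are targeted at zero;
#' intended cells are free (NA) - the standard partially specified target
#' convention.
#'
#' @param target one-hot matrix as returned by [ideal_target()].
#' @return matrix of `0` / `NA` suitable for [rotate_to_target()].
#' @export
target_mask_from_ideal <- function(target) {
  mask <- matrix(0, nrow(target), ncol(target), dimnames = dimnames(target))
  mask[target == 1] <- NA
  mask
}

#' Degrees of freedom of an exploratory factor model
#'
#' `df = k(k+1)/2 - (k m + k - m(m-1)/2)`: correlation moments minus free
#' loadings and uniquenesses, plus the m(m-1)/2 rotational indeterminacies.
#'
#' @param k number of indicators; @param m number of factors.
#' @return integer degrees of freedom.
#' @export
efa_df <- function(k, m) {
  as.integer(k * (k + 1) / 2 - (k * m + k - m * (m - 1) / 2))
}

#' Fit statistics for a maximum-likelihood factor solution
#'
#' Computes the ML discrepancy of the model-implied correlation matrix
#' `Sigma = L Phi L' + Psi` and the usual derived indices. Conventions:
#' `chi^2 = (n - 1) F_ML` (no Bartlett correction),
#' `RMSEA = sqrt(max(chi^2 - df, 0) / (df (n - 1)))`, CFI/TLI against the
#' independence baseline, SRMR as the root mean square residual over the
#' lower triangle including the diagonal, and the chi-square-based
#' `BIC = chi^2 - df ln(n)` (program conventions for BIC differ; this one
#' is labelled as such and not comparable to -2logL-based values).
#'
#' @param R observed correlation matrix.
#' @param solution a `factor_solution` from `ml` (or `minres`) extraction,
#'   rotated or not (the implied matrix is rotation invariant).
#' @param n number of observations behind `R`.
#' @return data frame of class `fit_stats` with columns `chi_square`,
#'   `df`, `cfi`, `tli`, `rmsea`, `srmr`, `bic`, `n_used`. When `df <= 0`
#'   the model is saturated and all indices are NA.
#' @export
fit_statistics <- function(R, solution, n) {
  stopifnot(inherits(solution, "factor_solution"))
  if (solution$method == "pca")
    stop("fit statistics are defined for ml/minres factor solutions, not pca")
  k <- nrow(solution$loadings)
  m <- ncol(solution$loadings)
  if (n <= k) stop("n must exceed the number of indicators")
  df <- efa_df(k, m)
  Sigma <- solution$loadings %*% solution$phi %*% t(solution$loadings) +
    diag(solution$uniquenesses, k)
  if (df <= 0) {
    out <- data.frame(chi_square = NA_real_, df = df, cfi = NA_real_,
                      tli = NA_real_, rmsea = NA_real_, srmr = NA_real_,
                      bic = NA_real_, n_used = n)
    class(out) <- c("fit_stats", "data.frame")
    return(out)
  }
  logdet <- function(M) as.numeric(determinant(M, logarithm = TRUE)$modulus)
  f_ml <- logdet(Sigma) - logdet(R) + sum(diag(R %*% solve(Sigma))) - k
  f_ml <- max(f_ml, 0)
  chi2 <- (n - 1) * f_ml
  # independence baseline: Sigma0 = I, so F0 = -log det(R)
  f0 <- -logdet(R)
  chi2_0 <- (n - 1) * f0
  df0 <- k * (k - 1) / 2
  cfi <- 1 - max(chi2 - df, 0) / max(chi2_0 - df0, chi2 - df, 0)
  tli <- (chi2_0 / df0 - chi2 / df) / (chi2_0 / df0 - 1)
  rmsea <- sqrt(max(chi2 - df, 0) / (df * (n - 1)))
  res <- R - Sigma
  lt <- lower.tri(res, diag = TRUE)
  srmr <- sqrt(sum(res[lt]^2) / sum(lt))
  bic <- chi2 - df * log(n)
  out <- data.frame(chi_square = chi2, df = df, cfi = cfi, tli = tli,
                    rmsea = rmsea, srmr = srmr, bic = bic, n_used = n)
  class(out) <- c("fit_stats", "data.frame")
  out
}

# all permutations of 1..m (m small)
.permutations <- function(m) {
  if (m == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(m)) {
    for (p in .permutations(m - 1L)) {
      rest <- seq_len(m)[-i]
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

#' Align a solution's factors to the blueprint domains
#'
#' Empirical factor order and sign are arbitrary; this chooses the column
#' permutation and sign pattern maximizing the sum of diagonal congruence
#' coefficients against the idealized one-hot target (exhaustive search
#' over all m! permutations x 2^m sign patterns), and transforms the
#' factor correlation matrix consistently. Factor columns are renamed to
#' the domain codes.
#'
#' @param solution a `factor_solution` whose loading rows are indicator
#'   labels resolvable against `bp`.
#' @param bp a `blueprint`.
#' @param method congruence method used for the matching criterion
#'   (default Tucker).
#' @return the aligned `factor_solution`.
#' @export
align_to_blueprint <- function(solution, bp, method = "tucker") {
  stopifnot(inherits(solution, "factor_solution"))
  L <- solution$loadings
  m <- ncol(L)
  if (m != nrow(bp$domains))
    stop("number of factors must equal the number of domains")
  if (m > 6) stop("exhaustive alignment supported for up to 6 factors")
  target <- ideal_target(bp, rownames(L))
  signs_grid <- as.matrix(expand.grid(rep(list(c(1, -1)), m)))
  best <- list(score = -Inf)
  base_C <- .congruence_values(L, target, method) # m x m, rows empirical
  for (p in .permutations(m)) {
    # diag of congruence after permuting columns of L by p: C[p[d], d]
    d_vals <- base_C[cbind(p, seq_len(m))]
    for (si in seq_len(nrow(signs_grid))) {
      s <- signs_grid[si, ]
      score <- sum(s * d_vals)
      if (score > best$score) best <- list(score = score, perm = p, signs = s)
    }
  }
  p <- best$perm; s <- best$signs
  solution$loadings <- sweep(L[, p, drop = FALSE], 2, s, `*`)
  colnames(solution$loadings) <- colnames(target)
  D <- diag(s, m)
  solution$phi <- D %*% solution$phi[p, p, drop = FALSE] %*% D
  dimnames(solution$phi) <- list(colnames(target), colnames(target))
  solution$alignment <- list(perm = p, signs = s)
  solution
}
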
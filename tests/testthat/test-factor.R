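test_that("correlation_matrix returns a unit-diagonal matrix and n_used", {
  set.seed(1)
  x <- matrix(rnorm(600), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
  x[, 2] <- x[, 1] # perfectly correlated pair
  cm <- correlation_matrix(x)
  expect_equal(cm$n_used, 200L)
  expect_equal(unname(diag(cm$R)), rep(1, 3))
  expect_equal(cm$R["a", "b"], 1.0)
  x[1, 3] <- NA
  expect_equal(correlation_matrix(x)$n_used, 199L)
  expect_equal(correlation_matrix(x, use = "pairwise")$n_used, 199L)
})

test_that("independent columns have near-zero sample correlations", {
  set.seed(2)
  x <- matrix(rnorm(10000 * 4), 10000, 4, dimnames = list(NULL, letters[1:4]))
  cm <- correlation_matrix(x)
  expect_lt(max(abs(cm$R[lower.tri(cm$R)])), 0.03)
})

test_that("constant columns are rejected by name", {
  x <- cbind(a = rnorm(50), b = rep(2, 50))
  expect_error(correlation_matrix(x), "b")
})

test_that("pca on the identity preserves the trace", {
  k <- 6
  sol <- extract_factors(diag(k), k, "pca")
  expect_equal(sum(sol$loadings^2), k) # eigenvalue sum = trace
  expect_equal(crossprod(sol$loadings), diag(k), ignore_attr = TRUE)
})

test_that("minres solves the one-factor equicorrelation case in closed form", {
  R <- matrix(0.49, 6, 6); diag(R) <- 1
  dimnames(R) <- list(paste0("v", 1:6), paste0("v", 1:6))
  sol <- extract_factors(R, 1, "minres")
  expect_equal(unname(abs(sol$loadings[, 1])), rep(0.7, 6), tolerance = 1e-6)
  expect_lt(sol$criterion_value, 1e-10)
})

test_that("ml and minres agree on a clean five-factor population matrix", {
  bp <- build_default_blueprint()
  cfg <- sim_config(n = 10, seed = 1)
  pop <- population_correlation(cfg, bp)
  for (method in c("ml", "minres")) {
    sol <- extract_factors(pop$R, 5, method)
    aligned <- procrustes_align(sol$loadings, pop$pattern)
    expect_lt(max(abs(aligned - pop$pattern)), 0.02)
  }
})

test_that("target rotation reaches the grid-search optimum on a 2-factor toy", {
  simple <- rbind(c(0.8, 0), c(0.7, 0), c(0.6, 0),
                  c(0, 0.8), c(0, 0.7), c(0, 0.6))
  rot <- function(a) matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2)
  L0 <- simple %*% rot(30 * pi / 180)
  mask <- ifelse(simple == 0, 0, NA)
  sol <- rotate_to_target(L0, mask, oblique = FALSE, n_starts = 5, seed = 3)
  # oracle: brute force over a 0.05-degree grid of angles and reflections
  angles <- seq(0, 2 * pi, by = 0.05 * pi / 180)
  crit <- function(a, refl) {
    L <- L0 %*% rot(a)
    if (refl) L[, 2] <- -L[, 2]
    target_criterion(L, mask)
  }
  grid_min <- min(vapply(angles, crit, numeric(1), refl = FALSE),
                  vapply(angles, crit, numeric(1), refl = TRUE))
  expect_lt(abs(sol$criterion_value - grid_min), 1e-5)
})

test_that("a loading matrix already satisfying the target has criterion zero", {
  simple <- rbind(c(0.8, 0), c(0.7, 0), c(0, 0.8), c(0, 0.6))
  mask <- ifelse(simple == 0, 0, NA)
  sol <- rotate_to_target(simple, mask, oblique = TRUE, n_starts = 3, seed = 4)
  expect_lt(sol$criterion_value, 1e-10)
  # rotation is identity up to column sign/permutation
  recovered <- abs(sol$loadings)
  expect_equal(sort(round(colSums(recovered^2), 6)),
               sort(round(colSums(simple^2), 6)))
})

test_that("the orthogonal criterion is never below the oblique one", {
  set.seed(5)
  for (i in 1:5) {
    L0 <- matrix(rnorm(8 * 2), 8, 2)
    mask <- matrix(NA, 8, 2)
    mask[1:4, 2] <- 0; mask[5:8, 1] <- 0
    f_orth <- rotate_to_target(L0, mask, oblique = FALSE, n_starts = 5,
                               seed = i)$criterion_value
    f_obl <- rotate_to_target(L0, mask, oblique = TRUE, n_starts = 5,
                              seed = i)$criterion_value
    expect_gte(f_orth + 1e-8, f_obl) # nested feasible sets
  }
})

test_that("rotation preserves the model-implied correlation matrix", {
  bp <- build_default_blueprint()
  sim <- cached_sim(n = 1000, seed = 101)
  acq <- compute_acq(sim$responses, bp)
  ori <- key_orient(center_responses(sim$responses, acq, bp), bp)
  ind <- cluster_scores(ori, bp, "triplet54")
  cm <- correlation_matrix(ind)
  sol0 <- extract_factors(cm$R, 5, "minres")
  implied0 <- tcrossprod(sol0$loadings)
  mask <- target_mask_from_ideal(ideal_target(bp, colnames(ind)))
  for (oblique in c(TRUE, FALSE)) {
    sol <- rotate_to_target(sol0, mask, oblique = oblique, n_starts = 3, seed = 6)
    implied <- sol$loadings %*% sol$phi %*% t(sol$loadings)
    expect_lt(max(abs(implied - implied0)), 1e-8)
  }
})

test_that("model df matches the published value and a Jacobian-rank oracle", {
  expect_equal(efa_df(54, 5), 1171L)
  expect_equal(efa_df(6, 1), 9L)
  for (km in list(c(6, 1), c(6, 2), c(8, 2), c(10, 3))) {
    expect_equal(efa_df(km[1], km[2]), df_by_jacobian(km[1], km[2]),
                 info = paste(km, collapse = "x"))
  }
})

test_that("fit statistics are exact for a perfectly reproduced matrix", {
  set.seed(7)
  L <- matrix(c(runif(6, 0.5, 0.8), rep(0, 6)), 6, 2)
  L[4:6, ] <- L[4:6, 2:1]
  psi <- 1 - rowSums(L^2)
  R <- tcrossprod(L) + diag(psi)
  sol <- structure(list(loadings = L, uniquenesses = psi, phi = diag(2),
                        rotation = "none", method = "ml"),
                   class = "factor_solution")
  fs <- fit_statistics(R, sol, n = 500)
  expect_equal(fs$chi_square, 0, tolerance = 1e-8)
  expect_equal(fs$cfi, 1)
  expect_equal(fs$rmsea, 0)
  expect_lt(fs$srmr, 1e-8)
  expect_equal(fs$df, efa_df(6, 2))
})

test_that("saturated models report undefined indices explicitly", {
  R <- diag(3); dimnames(R) <- list(letters[1:3], letters[1:3])
  fs <- suppressWarnings(fit_statistics(R, structure(
    list(loadings = matrix(0.1, 3, 2), uniquenesses = rep(0.9, 3),
         phi = diag(2), method = "ml"), class = "factor_solution"), n = 100))
  expect_lte(fs$df, 0)
  expect_true(is.na(fs$cfi))
  expect_error(fit_statistics(R, extract_factors(R, 1, "pca"), 100), "pca")
})

test_that("blueprint alignment undoes a known permutation and sign scramble", {
  bp <- build_default_blueprint()
  ref <- reference_loadings("corrected")
  sol <- structure(list(loadings = ref$loadings, phi = diag(5),
                        uniquenesses = rep(0.5, 54), rotation = "target-oblique",
                        method = "ml"), class = "factor_solution")
  aligned0 <- align_to_blueprint(sol, bp)
  expect_equal(aligned0$loadings, ref$loadings, ignore_attr = TRUE) # already aligned

  perm <- c(3, 1, 5, 2, 4); signs <- c(-1, 1, -1, 1, 1)
  scr <- sol
  scr$loadings <- sweep(ref$loadings[, perm], 2, signs, `*`)
  back <- align_to_blueprint(scr, bp)
  expect_equal(unname(back$loadings), unname(ref$loadings))

  neg1 <- sol; neg1$loadings[, 2] <- -neg1$loadings[, 2]
  expect_equal(unname(align_to_blueprint(neg1, bp)$loadings),
               unname(ref$loadings))
})
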
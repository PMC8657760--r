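test_that("the one-hot target has the blueprint's column sums", {
  bp <- build_default_blueprint()
  t54 <- ideal_target(bp, indicator_table(bp, "triplet54")$indicator)
  expect_equal(unname(colSums(t54)), c(9, 15, 9, 12, 9)) # 3 indicators x facets
  expect_equal(unname(rowSums(t54)), rep(1, 54))
  t18 <- ideal_target(bp, indicator_table(bp, "identity18")$indicator)
  expect_equal(unname(colSums(t18)), c(3, 5, 3, 4, 3))
  expect_error(ideal_target(bp, "Z9_id"), "unknown facet")
})

test_that("congruence of a matrix with itself is exactly one on the diagonal", {
  bp <- build_default_blueprint()
  t54 <- ideal_target(bp, indicator_table(bp, "triplet54")$indicator)
  for (method in c("tucker", "pearson")) {
    rep_ <- congruence_matrix(t54, t54, method = method)
    expect_equal(unname(diag(rep_$C)), rep(1, 5))
  }
})

test_that("a hand-computed toy reproduces both coefficient definitions", {
  L <- cbind(f1 = c(0.8, 0.7, 0.1, 0.0), f2 = c(0.0, 0.1, 0.6, 0.9))
  Tm <- cbind(d1 = c(1, 1, 0, 0), d2 = c(0, 0, 1, 1))
  cp <- congruence_matrix(L, Tm, method = "pearson")
  # direct correlation-formula oracle
  pear <- function(x, y) {
    xc <- x - mean(x); yc <- y - mean(y)
    sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
  }
  ct <- congruence_matrix(L, Tm, method = "tucker")
  for (i in 1:2) for (j in 1:2) {
    expect_equal(cp$C[i, j], pear(L[, i], Tm[, j]))
    expect_equal(ct$C[i, j], tucker_phi(L[, i], Tm[, j]))
  }
  expect_equal(cp$diag_mean, mean(c(pear(L[, 1], Tm[, 1]), pear(L[, 2], Tm[, 2]))))
})

test_that("summary extracts diagonal and off-diagonal structure", {
  s <- congruence_summary(diag(5))
  expect_equal(s$diag_mean, 1)
  expect_equal(s$diag_min, 1)
  expect_equal(s$off_diag_max_abs, 0)
})

test_that("pearson congruence is affine invariant, tucker only scale invariant", {
  set.seed(9)
  L <- matrix(rnorm(40), 20, 2)
  Tm <- matrix(rbinom(40, 1, 0.5), 20, 2)
  Tm[1, ] <- c(1, 0); Tm[2, ] <- c(0, 1) # avoid zero columns
  base_p <- congruence_matrix(L, Tm, "pearson")$C
  base_t <- congruence_matrix(L, Tm, "tucker")$C
  L2 <- L; L2[, 1] <- 3 * L2[, 1] + 5
  expect_equal(congruence_matrix(L2, Tm, "pearson")$C, base_p)
  expect_false(isTRUE(all.equal(congruence_matrix(L2, Tm, "tucker")$C, base_t)))
  L3 <- L; L3[, 1] <- 3 * L3[, 1] # positive scaling
  expect_equal(congruence_matrix(L3, Tm, "tucker")$C, base_t)
})

test_that("published corrected loadings reproduce the reported congruence", {
  bp <- build_default_blueprint()
  ref <- reference_loadings("corrected")
  target <- ideal_target(bp, rownames(ref$loadings))
  rep_ <- congruence_matrix(ref$loadings, target, method = "tucker")
  expect_lt(abs(rep_$diag_mean - 0.85), 0.02)
  expect_lt(abs(rep_$diag_min - 0.78), 0.02)
  # off-diagonals are small for the corrected solution
  expect_lt(congruence_summary(rep_)$off_diag_max_abs, 0.25)
})

test_that("published raw loadings show the reported loss of the Amity factor", {
  bp <- build_default_blueprint()
  ref <- reference_loadings("raw")
  target <- ideal_target(bp, rownames(ref$loadings))
  # columns used exactly as printed: no re-alignment
  rep_ <- congruence_matrix(ref$loadings, target, method = "tucker")
  expect_lt(abs(rep_$diag_mean - 0.62), 0.02)
  expect_lt(abs(rep_$C["A", "A"] - (-0.06)), 0.03)
  # the theoretical A column correlates weakly with other empirical factors
  expect_lt(abs(rep_$C["C", "A"] - 0.34), 0.02)
  expect_lt(abs(rep_$C["E", "A"] - 0.27), 0.02)
  expect_lt(abs(rep_$C["N", "A"] - 0.25), 0.02)
})

test_that("blueprint alignment maximizes the congruence diagonal", {
  bp <- build_default_blueprint()
  ref <- reference_loadings("corrected")
  target <- ideal_target(bp, rownames(ref$loadings))
  perm <- c(2, 4, 1, 5, 3)
  sol <- structure(list(loadings = ref$loadings[, perm], phi = diag(5),
                        uniquenesses = rep(0.5, 54), method = "ml"),
                   class = "factor_solution")
  aligned <- align_to_blueprint(sol, bp)
  got <- sum(diag(congruence_matrix(aligned$loadings, target)$C))
  # exhaustive check over all column permutations of the scrambled loadings
  best <- -Inf
  for (p in combinat_perms(5)) {
    Ck <- congruence_matrix(sol$loadings[, p], target)$C
    best <- max(best, sum(abs(diag(Ck))))
  }
  expect_equal(got, best, tolerance = 1e-12)
})
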
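# Shared test fixtures and independent oracles.

# tiny two-facet blueprint (18 items, 6 pairs) for fast structural tests
tiny_blueprint <- function() {
  build_blueprint(data.frame(facet_id = c("O1", "C1"),
                             domain = c("O", "C"),
                             stringsAsFactors = FALSE))
}

# a small simulated data set reused across tests (cached per session)
.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(n = 1000, seed = 101, ...) {
  key <- paste(n, seed, ..., sep = "|")
  if (is.null(.sim_cache[[key]])) {
    cfg <- sim_config(n = n, seed = seed, ...)
    .sim_cache[[key]] <- simulate_responses(cfg, build_default_blueprint())
  }
  .sim_cache[[key]]
}

# oracle: unconstrained least-squares alignment of loadings L onto a
# reference matrix (absorbs any rotation/oblique transform), then the
# aligned loadings themselves
procrustes_align <- function(L, ref) {
  Tm <- solve(crossprod(L), crossprod(L, ref))
  L %*% Tm
}

# oracle: Tucker congruence by direct formula
tucker_phi <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))

# oracle: target criterion value by direct summation
target_criterion <- function(L, mask) sum(L[!is.na(mask) & mask == 0]^2)

# all permutations of 1..m (independent of the package's internal helper)
combinat_perms <- function(m) {
  if (m == 1L) return(list(1L))
  unlist(lapply(seq_len(m), function(i) {
    lapply(combinat_perms(m - 1L), function(p) c(i, seq_len(m)[-i][p]))
  }), recursive = FALSE)
}

# oracle: brute-force model df via the rank of the Jacobian of the
# model-implied covariance wrt the free parameters (loadings + uniquenesses)
df_by_jacobian <- function(k, m, seed = 1) {
  set.seed(seed)
  L <- matrix(rnorm(k * m, sd = 0.5), k, m)
  psi <- runif(k, 0.3, 0.8)
  theta <- c(as.vector(L), psi)
  vech <- function(M) M[lower.tri(M, diag = TRUE)]
  sigma_of <- function(th) {
    Lm <- matrix(th[seq_len(k * m)], k, m)
    vech(tcrossprod(Lm) + diag(th[k * m + seq_len(k)], k))
  }
  eps <- 1e-5
  J <- vapply(seq_along(theta), function(i) {
    up <- theta; up[i] <- up[i] + eps
    dn <- theta; dn[i] <- dn[i] - eps
    (sigma_of(up) - sigma_of(dn)) / (2 * eps)
  }, numeric(k * (k + 1) / 2))
  sv <- svd(J, nu = 0, nv = 0)$d
  rank <- sum(sv > max(sv) * 1e-6)
  k * (k + 1) / 2 - rank
}
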
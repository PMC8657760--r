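#' Simulation of balanced Likert inventory responses
#'
#' The generator draws correlated domain scores, facet scores nested under
#' them, and latent item values, adds a per-respondent acquiescence shift
#' *before* thresholding, and discretizes onto the 1-5 response scale. A
#' configurable fraction of respondents answer uniformly at random
#' (insufficient-effort responding) and responses can be set missing
#' completely at random. The true latent quantities are returned alongside
#' the responses so every downstream estimator can be validated against
#' known truth.
#'
#' @name synthetic-data
NULL

#' Simulation configuration
#'
#' @param n number of respondents.
#' @param seed integer seed driving the single generator stream.
#' @param factor_correlations 5x5 (or d x d) unit-diagonal positive
#'   semi-definite matrix of domain intercorrelations. Default: 0.25
#'   off-diagonal, a typical magnitude for Big Five domain overlap.
#' @param gamma facet-on-domain loading in (0, 1]; scalar or per-facet
#'   vector named by facet id. Default 0.8.
#' @param lambda item-on-facet loading in (0, 1]; scalar or per-item vector
#'   named by item id. Default 0.7.
#' @param secondary_loadings sparse cross-loading table, a data frame with
#'   columns `facet`, `domain`, `value`: every item of `facet` also loads
#'   `value` on the score of `domain`. The default mimics cross-loadings
#'   repeatedly observed in large-sample studies of this item design
#'   (Responsibility on Amity, Self-confidence on Engaging-with-others,
#'   Frustration tolerance on Amity, and the Enthusiasm and Respect
#'   self-efficacy clusters on Negative-emotion regulation), all at 0.25.
#' @param acq_mean,acq_sd mean and standard deviation of the true
#'   acquiescence level on the response scale (midpoint 3). Defaults 2.95
#'   and 0.37, the values observed in the motivating large-sample study.
#' @param thresholds four strictly increasing cut-points on the response
#'   scale; default `c(1.5, 2.5, 3.5, 4.5)` (equally spaced around the
#'   midpoint).
#' @param ier_rate fraction in \[0, 1) of insufficient-effort responders
#'   whose answers are uniform on 1..5. Default 0.05.
#' @param missing_rate fraction in \[0, 1) of responses set missing
#'   completely at random. Default 0.
#' @return An object of class `sim_config` (a list of the above).
#' @export
sim_config <- function(n = 5000, seed = 1,
                       factor_correlations = NULL,
                       gamma = 0.8, lambda = 0.7,
                       secondary_loadings = NULL,
                       acq_mean = 2.95, acq_sd = 0.37,
                       thresholds = c(1.5, 2.5, 3.5, 4.5),
                       ier_rate = 0.05, missing_rate = 0) {
  if (is.null(factor_correlations)) {
    factor_correlations <- matrix(0.25, 5, 5,
                                  dimnames = list(c("O","C","E","A","N"),
                                                  c("O","C","E","A","N")))
    diag(factor_correlations) <- 1
  }
  if (is.null(secondary_loadings)) {
    secondary_loadings <- data.frame(
      facet = c("C5", "N2", "N3", "E3", "A2"),
      domain = c("A", "E", "A", "N", "N"),
      value = 0.25,
      stringsAsFactors = FALSE
    )
  }
  cfg <- list(n = n, seed = seed, factor_correlations = factor_correlations,
              gamma = gamma, lambda = lambda,
              secondary_loadings = secondary_loadings,
              acq_mean = acq_mean, acq_sd = acq_sd, thresholds = thresholds,
              ier_rate = ier_rate, missing_rate = missing_rate)
  class(cfg) <- "sim_config"
  .validate_sim_config(cfg)
  cfg
}

.validate_sim_config <- function(cfg) {
  if (!is.numeric(cfg$n) || length(cfg$n) != 1L || cfg$n <= 0 ||
      cfg$n != round(cfg$n))
    stop("n must be a positive integer")
  P <- cfg$factor_correlations
  if (!isSymmetric(unname(P)) || any(abs(diag(P) - 1) > 1e-12))
    stop("factor_correlations must be symmetric with unit diagonal")
  if (min(eigen(P, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop("factor_correlations is not positive semi-definite")
  if (length(cfg$thresholds) != 4L || any(diff(cfg$thresholds) <= 0))
    stop("thresholds must be 4 strictly increasing cut-points")
  if (cfg$ier_rate < 0 || cfg$ier_rate >= 1) stop("ier_rate must be in [0, 1)")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (any(cfg$gamma <= 0 | cfg$gamma > 1)) stop("gamma must be in (0, 1]")
  if (any(cfg$lambda <= 0 | cfg$lambda > 1)) stop("lambda must be in (0, 1]")
  invisible(cfg)
}

#' Discretize a latent response onto the 1-5 scale
#'
#' Half-open convention: a value exactly equal to a cut-point falls in the
#' upper category. Monotone non-decreasing in `z`.
#'
#' @param z numeric vector (or matrix) of latent response values.
#' @param thresholds four strictly increasing cut-points.
#' @return integer values in 1..5, same shape as `z`.
#' @export
discretize <- function(z, thresholds) {
  if (any(diff(thresholds) <= 0)) stop("thresholds must be strictly increasing")
  out <- findInterval(z, thresholds) + 1L
  if (is.matrix(z)) dim(out) <- dim(z)
  out
}

# Per-item generative parameters for a blueprint under a config:
# lambda (item-facet loading), secondary loadings onto domains, and the
# implied population pattern matrix on the domain factors.
.item_params <- function(cfg, bp) {
  items <- bp$items
  k <- nrow(items)
  doms <- bp$domains$code
  gam <- if (length(cfg$gamma) == 1L) stats::setNames(rep(cfg$gamma, nrow(bp$facets)),
                                                     bp$facets$facet_id)
         else cfg$gamma[bp$facets$facet_id]
  lam <- if (length(cfg$lambda) == 1L) stats::setNames(rep(cfg$lambda, k), items$item_id)
         else cfg$lambda[items$item_id]
  sec <- matrix(0, k, length(doms), dimnames = list(items$item_id, doms))
  sl <- cfg$secondary_loadings
  if (!is.null(sl) && nrow(sl)) {
    for (r in seq_len(nrow(sl))) {
      idx <- items$facet == sl$facet[r]
      if (any(idx)) sec[idx, sl$domain[r]] <- sl$value[r]
    }
  }
  # pattern matrix on domain factors: key * (lambda * gamma) on the own
  # domain plus key * secondary value elsewhere
  Lam <- sec
  for (j in seq_len(k)) {
    Lam[j, items$domain[j]] <- Lam[j, items$domain[j]] +
      lam[j] * gam[items$facet[j]]
  }
  Lam <- Lam * items$key
  list(gamma = gam, lambda = lam, secondary = sec, pattern = Lam)
}

#' Population item correlation matrix implied by a configuration
#'
#' The correlation matrix of the latent item values under the five-factor
#' approximation `R = Lambda Phi Lambda' + Psi` built from the population
#' pattern matrix. Facet-specific shared variance and the discretization
#' onto 1..5 are deliberately not included: this is the factor-model-implied
#' target that extraction should recover exactly.
#'
#' @param cfg a `sim_config`.
#' @param bp a `blueprint`.
#' @return list with `R` (k x k correlation matrix), `pattern` (k x d
#'   population loadings) and `phi` (domain correlations).
#' @export
population_correlation <- function(cfg, bp) {
  p <- .item_params(cfg, bp)
  Phi <- cfg$factor_correlations
  S <- p$pattern %*% Phi %*% t(p$pattern)
  if (any(diag(S) >= 1)) stop("communalities at or above 1; reduce loadings")
  diag(S) <- 1
  list(R = S, pattern = p$pattern, phi = Phi)
}

#' Simulate a response matrix with known structure
#'
#' Generative model, content part first: domain scores `theta ~ MVN(0, Phi)`;
#' facet score `f = gamma * theta_domain + sqrt(1 - gamma^2) * u` with `u`
#' standard normal (shared by the facet's items); latent item value
#' `y = key * (lambda * f + secondary terms) + eps`, with `eps` scaled so
#' `var(y) = 1`. The acquiescence shift enters pre-reversal and
#' content-blind: `z = y + (a - 3)` with `a ~ N(acq_mean, acq_sd)` on the
#' response scale, and the response is `discretize(z + 3, thresholds)`.
#' Insufficient-effort responders then overwrite all their responses with
#' uniform draws on 1..5; missingness is completely at random.
#'
#' @param cfg a `sim_config`.
#' @param bp a `blueprint`; default the canonical 162-item design.
#' @return list of class `sim_result` with elements
#'   `responses` (n x k integer matrix, respondent ids as rownames) and
#'   `truth` (list: `theta`, `facet_scores`, `acq_true`, `ier_flags`,
#'   `pattern`, `phi`, `config`).
#' @export
simulate_responses <- function(cfg, bp = build_default_blueprint()) {
  .validate_sim_config(cfg)
  set.seed(cfg$seed)
  n <- cfg$n
  items <- bp$items
  k <- nrow(items)
  doms <- bp$domains$code
  p <- .item_params(cfg, bp)
  Phi <- cfg$factor_correlations

  theta <- matrix(stats::rnorm(n * length(doms)), n) %*% chol(Phi)
  colnames(theta) <- doms

  fid <- bp$facets$facet_id
  facet_scores <- sapply(fid, function(f) {
    d <- bp$facets$domain[bp$facets$facet_id == f]
    g <- p$gamma[f]
    g * theta[, d] + sqrt(1 - g^2) * stats::rnorm(n)
  })
  if (n == 1L) facet_scores <- matrix(facet_scores, nrow = 1,
                                      dimnames = list(NULL, fid))

  # content variance per item (for scaling eps so var(y) = 1):
  # content = lambda * f + s' theta_sec, var(f) = 1, cov(f, theta_s) =
  # gamma * Phi[d, s]
  content <- facet_scores[, items$facet, drop = FALSE] *
    rep(p$lambda, each = n) + theta %*% t(p$secondary)
  var_c <- vapply(seq_len(k), function(j) {
    lamj <- p$lambda[j]; g <- p$gamma[items$facet[j]]; d <- items$domain[j]
    s <- p$secondary[j, ]
    lamj^2 + drop(s %*% Phi %*% s) + 2 * lamj * g * drop(Phi[d, ] %*% s)
  }, numeric(1))
  if (any(var_c >= 1)) stop("item content variance >= 1; reduce loadings")

  eps <- matrix(stats::rnorm(n * k), n, k) * rep(sqrt(1 - var_c), each = n)
  y <- sweep(content, 2, items$key, `*`) + eps

  acq_true <- stats::rnorm(n, cfg$acq_mean, cfg$acq_sd)
  z <- y + (acq_true - 3)
  resp <- discretize(z + 3, cfg$thresholds)

  ier <- stats::runif(n) < cfg$ier_rate
  if (any(ier)) {
    resp[ier, ] <- sample(1:5, sum(ier) * k, replace = TRUE)
  }
  if (cfg$missing_rate > 0) {
    resp[matrix(stats::runif(n * k) < cfg$missing_rate, n, k)] <- NA_integer_
  }
  storage.mode(resp) <- "integer"
  dimnames(resp) <- list(paste0("r", seq_len(n)), items$item_id)

  truth <- list(theta = theta, facet_scores = facet_scores,
                acq_true = acq_true, ier_flags = ier,
                pattern = p$pattern, phi = Phi, config = cfg)
  structure(list(responses = resp, truth = truth), class = "sim_result")
}

#' Write a simulated data set to CSV
#'
#' Writes the wide response matrix (`respondent_id` plus one column per
#' item) and, beside it, the truth file (`respondent_id`, domain scores,
#' true acquiescence, insufficient-effort flag).
#'
#' @param sim a `sim_result`.
#' @param responses_path,truth_path output CSV paths.
#' @return invisibly, the two paths.
#' @export
write_simulation <- function(sim, responses_path, truth_path) {
  stopifnot(inherits(sim, "sim_result"))
  rd <- data.frame(respondent_id = rownames(sim$responses),
                   sim$responses, check.names = FALSE)
  utils::write.csv(rd, responses_path, row.names = FALSE, quote = FALSE)
  th <- sim$truth
  td <- data.frame(respondent_id = rownames(sim$responses),
                   theta = th$theta,
                   acq_true = th$acq_true, ier = th$ier_flags,
                   check.names = FALSE)
  utils::write.csv(td, truth_path, row.names = FALSE, quote = FALSE)
  invisible(c(responses_path, truth_path))
}

#' Read a wide response CSV into a response matrix
#'
#' @param path CSV with a `respondent_id` column and one column per item.
#' @return integer matrix with respondent ids as rownames.
#' @export
read_responses <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"respondent_id" %in% names(d)) stop("no respondent_id column")
  m <- as.matrix(d[, setdiff(names(d), "respondent_id"), drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(d$respondent_id)
  m
}
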
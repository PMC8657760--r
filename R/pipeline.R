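#' End-to-end internal-structure analysis
#'
#' Orchestrates the full pipeline on a response matrix: acquiescence
#' estimation, within-person correction, cluster scoring, five-factor
#' target-rotated modelling, blueprint alignment and idealized-target
#' congruence - on both the corrected branch (center, then key-orient) and
#' the raw branch (reverse on the 1-5 scale, no correction) - plus separate
#' and joint component solutions for the identity and self-efficacy scales.
#'
#' @name pipeline
NULL

#' Analysis configuration
#'
#' @param method extraction method for the triplet analyses (`"ml"`
#'   default, `"minres"` available).
#' @param factors number of factors (default 5).
#' @param oblique logical, oblique target rotation (default TRUE).
#' @param congruence_method `"tucker"` (default) or `"pearson"`.
#' @param seed seed for the rotation's random starts.
#' @param n_starts random rotation starts in addition to identity.
#' @param schemes indicator schemes to analyse beyond `triplet54`:
#'   any of `"identity18"`, `"se18"`, `"joint36"` (fitted by principal
#'   components with the same target rotation, on the corrected branch).
#' @param use correlation handling, `"complete"` or `"pairwise"`.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(method = "ml", factors = 5, oblique = TRUE,
                            congruence_method = "tucker", seed = 1,
                            n_starts = 10,
                            schemes = c("identity18", "se18", "joint36"),
                            use = "complete") {
  structure(list(method = method, factors = factors, oblique = oblique,
                 congruence_method = congruence_method, seed = seed,
                 n_starts = n_starts, schemes = schemes, use = use),
            class = "analysis_config")
}

# one branch at indicator level: correlation -> extract -> rotate -> align
# -> congruence (+ ml fit statistics)
.fit_branch <- function(ind, bp, cfg, method = cfg$method) {
  cm <- correlation_matrix(ind, use = cfg$use)
  sol0 <- extract_factors(cm$R, cfg$factors, method = method)
  target <- ideal_target(bp, colnames(ind))
  mask <- target_mask_from_ideal(target)
  sol <- rotate_to_target(sol0, mask, oblique = cfg$oblique,
                          n_starts = cfg$n_starts, seed = cfg$seed)
  sol <- align_to_blueprint(sol, bp, method = cfg$congruence_method)
  cong <- congruence_matrix(sol$loadings, target,
                            method = cfg$congruence_method)
  fit <- if (method %in% c("ml", "minres"))
    fit_statistics(cm$R, sol, cm$n_used) else NULL
  list(solution = sol, congruence = cong, fit = fit, n_used = cm$n_used)
}

#' Run the full internal-structure analysis
#'
#' @param responses integer response matrix (respondents x items, 1-5 or
#'   NA) with item ids as colnames.
#' @param bp a `blueprint`.
#' @param cfg an [analysis_config()].
#' @return list of class `analysis_report` with elements `acq_summary`,
#'   `acq`, `corrected` and `raw` (each: `solution`, `congruence`, `fit`,
#'   `n_used` on the 54 triplet indicators), `schemes` (per-scheme
#'   corrected-branch component solutions), and `provenance`.
#' @export
run_full_analysis <- function(responses, bp = build_default_blueprint(),
                              cfg = analysis_config()) {
  .check_responses(responses, bp)

  acq <- compute_acq(responses, bp)
  acq_summary <- list(mean = mean(acq$acq, na.rm = TRUE),
                      sd = stats::sd(acq$acq, na.rm = TRUE),
                      pct_flagged = 100 * mean(!acq$balanced_flag))
  message(sprintf("stage acq: n = %d, mean = %.3f, sd = %.3f, flagged = %.1f%%",
                  nrow(acq), acq_summary$mean, acq_summary$sd,
                  acq_summary$pct_flagged))

  corrected <- center_responses(responses, acq, bp)
  oriented <- key_orient(corrected, bp)
  ind_corr <- cluster_scores(oriented, bp, "triplet54")
  message("stage corrected indicators: ", nrow(ind_corr), " x ", ncol(ind_corr))
  branch_corr <- .fit_branch(ind_corr, bp, cfg)

  reversed <- reverse_raw(responses, bp)
  ind_raw <- cluster_scores(reversed, bp, "triplet54")
  branch_raw <- .fit_branch(ind_raw, bp, cfg)
  message(sprintf("stage congruence: corrected diag mean %.3f, raw %.3f",
                  branch_corr$congruence$diag_mean,
                  branch_raw$congruence$diag_mean))

  schemes <- list()
  for (sc in cfg$schemes) {
    ind <- cluster_scores(oriented, bp, sc)
    schemes[[sc]] <- .fit_branch(ind, bp, cfg, method = "pca")
  }

  provenance <- list(
    package_version = as.character(utils::packageVersion("acqstruct")),
    config = unclass(cfg),
    n_respondents = nrow(responses),
    n_items = ncol(responses),
    input_hash = .hash_object(responses),
    timestamp_free = TRUE # reports are content-addressed, not timestamped
  )
  structure(list(acq_summary = acq_summary, acq = acq,
                 corrected = branch_corr, raw = branch_raw,
                 schemes = schemes, provenance = provenance),
            class = "analysis_report")
}

.hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("analysis_report\n")
  cat(sprintf("  acquiescence: mean %.3f, sd %.3f, %.1f%% flagged\n",
              x$acq_summary$mean, x$acq_summary$sd, x$acq_summary$pct_flagged))
  cat(sprintf("  corrected branch: congruence diag mean %.3f (min %.3f)\n",
              x$corrected$congruence$diag_mean, x$corrected$congruence$diag_min))
  cat(sprintf("  raw branch:       congruence diag mean %.3f (min %.3f)\n",
              x$raw$congruence$diag_mean, x$raw$congruence$diag_min))
  invisible(x)
}

#' Write an analysis report to a directory
#'
#' Writes a deterministic file set: per-branch loading, congruence and fit
#' CSVs, the acquiescence table, per-scheme loading CSVs, and a plain-text
#' provenance block. Identical inputs produce byte-identical files.
#'
#' @param report an `analysis_report`.
#' @param out_dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  put <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    written <<- c(written, p)
  }
  loadings_df <- function(sol) {
    data.frame(indicator = rownames(sol$loadings),
               round(sol$loadings, 6),
               uniqueness = round(unname(sol$uniquenesses), 6),
               check.names = FALSE)
  }
  for (br in c("corrected", "raw")) {
    b <- report[[br]]
    if (is.null(b)) next
    put(loadings_df(b$solution), sprintf("loadings_%s_triplet54.csv", br))
    C <- b$congruence$C
    put(data.frame(empirical = rownames(C), round(C, 6), check.names = FALSE),
        sprintf("congruence_%s.csv", br))
    if (!is.null(b$fit)) put(as.data.frame(b$fit), sprintf("fit_%s.csv", br))
  }
  for (sc in names(report$schemes)) {
    put(loadings_df(report$schemes[[sc]]$solution),
        sprintf("loadings_corrected_%s.csv", sc))
  }
  put(report$acq, "acq.csv")
  pv <- report$provenance
  lines <- c(paste0("package_version=", pv$package_version),
             paste0("n_respondents=", pv$n_respondents),
             paste0("n_items=", pv$n_items),
             paste0("input_hash=", pv$input_hash),
             paste0("config_", names(pv$config), "=",
                    vapply(pv$config, function(v) paste(v, collapse = ","),
                           character(1))))
  p <- file.path(out_dir, "provenance.txt")
  writeLines(lines, p)
  written <- c(written, p)
  invisible(written)
}
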
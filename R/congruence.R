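#' Idealized-target congruence analysis
#'
#' Structure recovery is summarized by comparing each empirical factor's
#' loading vector with an idealized target: one vector per domain holding
#' 1.0 on indicators intended for that domain and 0 elsewhere (deliberately
#' ignoring known secondary loadings). Congruence is computed for all
#' empirical-by-theoretical pairs; with identical structures the diagonal
#' would be 1 and the off-diagonal 0. Tucker's congruence coefficient (the
#' normalized inner product) is the default - it reproduces published
#' coefficient tables for this design - with the Pearson correlation over
#' indicator rows available as an alternative.
#'
#' @name congruence
NULL

# facet id encoded as the prefix of an indicator label ("A2_idneg" -> "A2")
.label_facet <- function(labels) sub("_[^_]*$", "", labels)

#' Idealized one-hot target matrix for a set of indicators
#'
#' @param bp a `blueprint`.
#' @param indicator_labels character vector of indicator labels
#'   (`<facet>_<suffix>`), e.g. rownames of a loading matrix.
#' @return k x d matrix of 0/1 with one 1 per row (the indicator's
#'   intended domain); columns are the blueprint domain codes.
#' @export
ideal_target <- function(bp, indicator_labels) {
  fac <- .label_facet(indicator_labels)
  unknown <- setdiff(fac, bp$facets$facet_id)
  if (length(unknown))
    stop("indicator label(s) with unknown facet: ",
         paste(unique(unknown), collapse = ", "))
  dom <- bp$facets$domain[match(fac, bp$facets$facet_id)]
  codes <- bp$domains$code
  out <- vapply(codes, function(d) as.numeric(dom == d),
                numeric(length(indicator_labels)))
  if (length(indicator_labels) == 1L)
    out <- matrix(out, 1, dimnames = list(indicator_labels, codes))
  else rownames(out) <- indicator_labels
  out
}

# m x m matrix of congruence values, rows = empirical columns of L,
# columns = target columns.
.congruence_values <- function(L, target, method = c("tucker", "pearson")) {
  method <- match.arg(method)
  if (nrow(L) != nrow(target))
    stop("empirical loadings and target must share rows")
  if (method == "pearson") {
    if (any(apply(L, 2, stats::sd) == 0))
      stop("zero-variance empirical loading column")
    C <- stats::cor(L, target)
  } else {
    nl <- sqrt(colSums(L^2)); nt <- sqrt(colSums(target^2))
    if (any(nl == 0)) stop("zero empirical loading column")
    C <- crossprod(L, target) / outer(nl, nt)
  }
  dimnames(C) <- list(colnames(L), colnames(target))
  C
}

#' Congruence of empirical loadings with a target matrix
#'
#' @param L k x m empirical loading matrix (columns in blueprint-aligned
#'   order if diagonal summaries are to be read as matched pairs).
#' @param target k x m target matrix (typically [ideal_target()] output).
#' @param method `"tucker"` (default) or `"pearson"`.
#' @return object of class `congruence_report`: list with `C` (m x m,
#'   rows = empirical factors, columns = theoretical domains),
#'   `diag_mean`, `diag_min`, `method`.
#' @export
congruence_matrix <- function(L, target, method = c("tucker", "pearson")) {
  method <- match.arg(method)
  C <- .congruence_values(as.matrix(L), as.matrix(target), method)
  structure(list(C = C, diag_mean = mean(diag(C)), diag_min = min(diag(C)),
                 method = method),
            class = "congruence_report")
}

#' @export
print.congruence_report <- function(x, digits = 2, ...) {
  cat(sprintf("congruence_report (%s): diagonal mean %.3f, min %.3f\n",
              x$method, x$diag_mean, x$diag_min))
  print(round(x$C, digits))
  invisible(x)
}

#' Summarize a congruence report
#'
#' @param report a `congruence_report` (or a bare square matrix).
#' @return list with `diag_mean`, `diag_min`, `off_diag_max_abs`.
#' @export
congruence_summary <- function(report) {
  C <- if (inherits(report, "congruence_report")) report$C else as.matrix(report)
  off <- C[row(C) != col(C)]
  list(diag_mean = mean(diag(C)), diag_min = min(diag(C)),
       off_diag_max_abs = max(abs(off)))
}

#' Published reference loading matrices
#'
#' The 54-indicator five-factor loading matrices reported by a large-scale
#' administration (N = 50,209) of the canonical 162-item design, as printed:
#' one solution on acquiescence-corrected scores and one on raw scores. Row
#' order follows the canonical blueprint; the raw solution's columns are
#' kept exactly as published (its fourth factor carries acquiescence
#' variance with a reversed orientation, and the published congruence
#' summaries were evidently computed without re-alignment).
#'
#' @param branch `"corrected"` or `"raw"`.
#' @return list with `loadings` (54 x 5 matrix, indicator labels as
#'   rownames) and `info` (data frame: `indicator`, `facet`, `framing`).
#' @export
reference_loadings <- function(branch = c("corrected", "raw")) {
  branch <- match.arg(branch)
  path <- system.file("extdata", paste0("ref_loadings_", branch, ".csv"),
                      package = "acqstruct", mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  L <- as.matrix(d[, c("O", "C", "E", "A", "N")])
  rownames(L) <- d$indicator
  list(loadings = L, info = d[, c("indicator", "facet", "framing")])
}
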
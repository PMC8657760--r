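#' Cluster indicator scales
#'
#' The factor analyses operate on short cluster scales rather than single
#' items: per facet, the mean of the three positively keyed identity items,
#' of the three (reversed) negatively keyed identity items, and of the
#' three self-efficacy items - 54 triplet indicators in the default design.
#' Alternative schemes collapse the six identity items into one scale per
#' facet (18 indicators), take the self-efficacy triplets alone (18), or
#' join both (36).
#'
#' @name scoring
NULL

.schemes <- c("triplet54", "identity18", "se18", "joint36")

#' Indicator membership table for a scoring scheme
#'
#' @param bp a `blueprint`.
#' @param scheme one of `"triplet54"`, `"identity18"`, `"se18"`, `"joint36"`.
#' @return data frame with columns `indicator`, `facet`, `domain`,
#'   `framing` (`identity_pos`/`identity_neg`/`self_efficacy` for triplets,
#'   `identity`/`self_efficacy` for collapsed schemes), `pole` (-1 for the
#'   negatively keyed identity triplet, +1 otherwise) and `items` (list
#'   column of member item ids), in canonical blueprint order.
#' @export
indicator_table <- function(bp, scheme = "triplet54") {
  scheme <- match.arg(scheme, .schemes)
  it <- bp$items
  fac <- bp$facets
  one <- function(fid, framing, suffix, pole) {
    members <- if (identical(framing, "identity"))
      it$item_id[it$facet == fid & it$framing != "self_efficacy"]
    else it$item_id[it$facet == fid & it$framing == framing]
    data.frame(indicator = paste0(fid, "_", suffix), facet = fid,
               domain = fac$domain[fac$facet_id == fid],
               framing = if (identical(framing, "identity")) "identity" else framing,
               pole = pole, items = I(list(members)),
               stringsAsFactors = FALSE)
  }
  rows <- switch(scheme,
    triplet54 = lapply(fac$facet_id, function(f)
      rbind(one(f, "identity_pos", "idpos", 1L),
            one(f, "identity_neg", "idneg", -1L),
            one(f, "self_efficacy", "se", 1L))),
    identity18 = lapply(fac$facet_id, function(f) one(f, "identity", "id", 1L)),
    se18 = lapply(fac$facet_id, function(f) one(f, "self_efficacy", "se", 1L)),
    joint36 = lapply(fac$facet_id, function(f)
      rbind(one(f, "identity", "id", 1L),
            one(f, "self_efficacy", "se", 1L)))
  )
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reverse negatively keyed items on the raw 1-5 scale
#'
#' Maps `x -> 6 - x` on negatively keyed identity items and leaves all
#' other items unchanged. This is the reversal for *uncorrected* (raw)
#' pipelines; corrected pipelines must orient by key multiplication after
#' centering instead (see [key_orient()]).
#'
#' @param responses integer response matrix (values 1-5 or NA).
#' @param bp a `blueprint`.
#' @return numeric matrix with negatively keyed columns reversed.
#' @export
reverse_raw <- function(responses, bp) {
  .check_responses(responses, bp)
  out <- responses * 1.0
  neg <- colnames(out) %in% bp$items$item_id[bp$items$key == -1L]
  out[, neg] <- 6 - out[, neg, drop = FALSE]
  out
}

#' Compute cluster indicator scores
#'
#' Each indicator is the mean of its member items, on an input matrix
#' already oriented so that high scores mean high skill (either
#' [key_orient()] output on the corrected branch or [reverse_raw()] output
#' on the raw branch). A cluster mean is set missing when fewer than
#' `min_frac` of its member items were answered (default two-thirds: 2 of
#' 3 items, 4 of 6).
#'
#' @param matrix numeric matrix of oriented scores.
#' @param bp a `blueprint`.
#' @param scheme scoring scheme, see [indicator_table()].
#' @param min_frac minimum answered fraction per cluster.
#' @return numeric matrix (respondents x indicators) of class
#'   `indicator_matrix` with the scheme stored in attribute `scheme`.
#' @export
cluster_scores <- function(matrix, bp, scheme = "triplet54", min_frac = 2 / 3) {
  scheme <- match.arg(scheme, .schemes)
  info <- indicator_table(bp, scheme)
  missing_items <- setdiff(unlist(info$items), colnames(matrix))
  if (length(missing_items))
    stop("matrix lacks blueprint items: ",
         paste(utils::head(missing_items, 5), collapse = ", "))
  out <- vapply(seq_len(nrow(info)), function(i) {
    m <- matrix[, info$items[[i]], drop = FALSE]
    mu <- rowMeans(m, na.rm = TRUE)
    mu[rowMeans(!is.na(m)) < min_frac - 1e-12] <- NA_real_
    mu
  }, numeric(nrow(matrix)))
  if (nrow(matrix) == 1L) out <- t(as.matrix(out))
  dimnames(out) <- list(rownames(matrix), info$indicator)
  structure(out, scheme = scheme, class = c("indicator_matrix", "matrix", "array"))
}
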
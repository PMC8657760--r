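#' Acquiescence estimation and within-person correction
#'
#' On a balanced identity item set (equal numbers of positively and
#' negatively keyed items per facet, arranged as antonym pairs), a
#' respondent's mean over the *un-reversed* identity items estimates their
#' content-blind agreement tendency: symmetric answering of every antonym
#' pair (profiles such as 1-5, 2-4, 3-3) gives exactly the scale midpoint 3,
#' while yea-saying pushes the mean above 3 and nay-saying below.
#' Subtracting this index from every item response - identity and
#' self-efficacy alike - removes acquiescence variance while preserving
#' content; content reversal of negatively keyed items must happen *after*
#' this centering (by key multiplication), never before.
#'
#' @name acquiescence
NULL

#' Compute the per-respondent acquiescence index
#'
#' The index is the mean of the raw (un-reversed) identity-item responses.
#' Self-efficacy items are excluded: being all positively keyed they cannot
#' separate content from agreement tendency.
#'
#' @param responses integer matrix (respondents x items, values 1-5 or NA)
#'   with item ids as colnames; ids must belong to `bp`.
#' @param bp a `blueprint` containing antonym pairs.
#' @param min_items minimum number of answered identity items for
#'   `balanced_flag` to remain TRUE (default half the identity items).
#' @param max_incomplete_pairs maximum tolerated fraction of antonym pairs
#'   with exactly one member answered (default 0.25).
#' @return data frame with columns `respondent_id`, `acq` (NA when no
#'   identity item was answered), `n_items_used`, `balanced_flag`.
#' @export
compute_acq <- function(responses, bp, min_items = NULL,
                        max_incomplete_pairs = 0.25) {
  .check_responses(responses, bp)
  pairs <- antonym_pairs(bp) # errors on a pair-free or broken blueprint
  id_items <- intersect(colnames(responses), .identity_items(bp))
  if (!length(id_items)) stop("no identity items present in the responses")
  if (is.null(min_items)) min_items <- ceiling(length(.identity_items(bp)) / 2)

  m <- responses[, id_items, drop = FALSE]
  n_used <- rowSums(!is.na(m))
  acq <- rowMeans(m, na.rm = TRUE)
  acq[n_used == 0L] <- NA_real_

  # a pair is incomplete when exactly one member was answered
  pairs <- pairs[pairs$item_pos %in% id_items & pairs$item_neg %in% id_items, ,
                 drop = FALSE]
  pos_na <- is.na(responses[, pairs$item_pos, drop = FALSE])
  neg_na <- is.na(responses[, pairs$item_neg, drop = FALSE])
  incomplete <- rowSums(pos_na != neg_na)
  frac_incomplete <- incomplete / nrow(pairs)

  # balanced: every used item sits in a complete pair, and enough items used
  balanced <- n_used >= min_items & incomplete == 0L
  n_warn <- sum(n_used < min_items | frac_incomplete > max_incomplete_pairs)
  if (n_warn) {
    warning(n_warn, " respondent(s) have fewer than ", min_items,
            " answered identity items or more than ",
            round(100 * max_incomplete_pairs), "% incomplete antonym pairs",
            call. = FALSE)
  }
  data.frame(respondent_id = rownames(responses), acq = acq,
             n_items_used = n_used, balanced_flag = balanced,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Remove acquiescence by within-person centering
#'
#' Subtracts each respondent's acquiescence index from all of their item
#' responses, including the self-efficacy items (whose all-positive keying
#' precludes estimating acquiescence from them directly). Missing responses
#' stay missing; respondents without an index are dropped with a message.
#'
#' @param responses integer response matrix (see [compute_acq()]).
#' @param acq data frame as returned by [compute_acq()].
#' @param bp a `blueprint`.
#' @return numeric matrix of centered (possibly negative) scores with
#'   attribute `acq_used` (the rows of `acq` actually applied).
#' @export
center_responses <- function(responses, acq, bp) {
  .check_responses(responses, bp)
  if (!all(rownames(responses) %in% acq$respondent_id))
    stop("acquiescence index missing for some respondents in the matrix")
  a <- acq$acq[match(rownames(responses), acq$respondent_id)]
  keep <- !is.na(a)
  if (any(!keep)) {
    message("dropping ", sum(!keep), " respondent(s) without an acquiescence index")
  }
  out <- responses[keep, , drop = FALSE] - a[keep]
  attr(out, "acq_used") <- acq[match(rownames(out), acq$respondent_id), ,
                               drop = FALSE]
  out
}

#' Orient centered scores so that high always means high skill
#'
#' Multiplies each column by its keying sign: negatively keyed identity
#' content is flipped *after* centering; positively keyed items (including
#' all self-efficacy items) are unchanged. On centered scores this is the
#' correct reversal; applying the raw-scale reversal 6 - x before
#' centering would double the acquiescence in negatively keyed items
#' instead of removing it.
#'
#' @param corrected numeric matrix of centered scores.
#' @param bp a `blueprint`.
#' @return numeric matrix of oriented scores.
#' @export
key_orient <- function(corrected, bp) {
  .check_responses(corrected, bp, integer_scale = FALSE)
  key <- .item_key_vector(bp)[colnames(corrected)]
  out <- sweep(corrected, 2, key, `*`)
  attr(out, "acq_used") <- attr(corrected, "acq_used")
  out
}

.check_responses <- function(responses, bp, integer_scale = TRUE) {
  if (!is.matrix(responses) || nrow(responses) == 0L || ncol(responses) == 0L)
    stop("responses must be a non-empty matrix with item ids as colnames")
  if (is.null(colnames(responses)) || is.null(rownames(responses)))
    stop("responses must carry respondent ids (rownames) and item ids (colnames)")
  unknown <- setdiff(colnames(responses), bp$items$item_id)
  if (length(unknown))
    stop("responses reference items absent from the blueprint: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  if (integer_scale) {
    v <- responses[!is.na(responses)]
    if (length(v) && (any(v < 1) || any(v > 5)))
      stop("response values must be integers in 1..5 (or NA)")
  }
  invisible(TRUE)
}
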
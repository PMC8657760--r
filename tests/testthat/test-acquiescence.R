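# build a one-row response matrix for a blueprint from a named vector
resp_row <- function(bp, values, id = "r1") {
  m <- matrix(NA_integer_, 1, nrow(bp$items),
              dimnames = list(id, bp$items$item_id))
  m[1, names(values)] <- as.integer(values)
  m
}

test_that("fully symmetric antonym profiles give an index of exactly 3", {
  bp <- build_default_blueprint()
  ap <- antonym_pairs(bp)
  # cycle through the symmetric profiles 1-5, 2-4, 3-3, 4-2, 5-1
  pos_vals <- rep_len(c(1L, 2L, 3L, 4L, 5L), nrow(ap))
  vals <- setNames(c(pos_vals, 6L - pos_vals), c(ap$item_pos, ap$item_neg))
  se <- bp$items$item_id[bp$items$framing == "self_efficacy"]
  vals[se] <- 4L # self-efficacy answers must not affect the index
  acq <- compute_acq(resp_row(bp, vals), bp)
  expect_equal(acq$acq, 3)
  expect_true(acq$balanced_flag)
  expect_equal(acq$n_items_used, 108L)
})

test_that("uniform extreme responding yields the scale maximum", {
  bp <- build_default_blueprint()
  vals <- setNames(rep(5L, 162), bp$items$item_id)
  acq <- compute_acq(resp_row(bp, vals), bp)
  expect_equal(acq$acq, 5)
})

test_that("the index is the arithmetic mean of un-reversed identity items", {
  bp <- tiny_blueprint()
  id_items <- bp$items$item_id[bp$items$framing != "self_efficacy"]
  vals <- setNames(rep(3L, 18), bp$items$item_id)
  vals[id_items[1:6]] <- c(5L, 4L, 3L, 2L, 1L, 5L)
  vals[id_items[7:12]] <- 3L
  m <- resp_row(bp, vals)
  acq <- compute_acq(m, bp)
  expect_equal(acq$acq, mean(m[1, id_items])) # direct arithmetic oracle
  expect_equal(acq$acq, (5 + 4 + 3 + 2 + 1 + 5 + 6 * 3) / 12)
})

test_that("missing identity data is flagged and the empty case gives NA", {
  bp <- tiny_blueprint()
  vals <- setNames(rep(4L, 18), bp$items$item_id)
  m <- rbind(resp_row(bp, vals, "full"),
             resp_row(bp, vals[1:2], "sparse")) # only two identity items
  rownames(m) <- c("full", "sparse")
  expect_warning(acq <- compute_acq(m, bp), "identity items")
  expect_true(acq$balanced_flag[acq$respondent_id == "full"])
  expect_false(acq$balanced_flag[acq$respondent_id == "sparse"])

  se_only <- bp$items$item_id[bp$items$framing == "self_efficacy"]
  m2 <- resp_row(bp, setNames(rep(2L, 6), se_only))
  expect_warning(acq2 <- compute_acq(m2, bp))
  expect_true(is.na(acq2$acq))
  expect_equal(acq2$n_items_used, 0L)
})

test_that("centering subtracts the index from every item including self-efficacy", {
  bp <- tiny_blueprint()
  vals <- setNames(rep(4L, 18), bp$items$item_id)
  m <- resp_row(bp, vals)
  acq <- compute_acq(m, bp) # index 4
  cc <- center_responses(m, acq, bp)
  expect_equal(unname(cc[1, ]), rep(0, 18))

  vals2 <- vals; vals2[1] <- 5L # one raw 5 against index ~4
  m2 <- resp_row(bp, vals2)
  a2 <- compute_acq(m2, bp)
  cc2 <- center_responses(m2, a2, bp)
  expect_equal(unname(cc2[1, 1]), 5 - a2$acq)
})

test_that("corrected identity items have exactly zero mean per respondent", {
  bp <- build_default_blueprint()
  sim <- cached_sim(n = 300, seed = 71)
  acq <- compute_acq(sim$responses, bp)
  cc <- center_responses(sim$responses, acq, bp)
  id_items <- bp$items$item_id[bp$items$framing != "self_efficacy"]
  expect_lt(max(abs(rowMeans(cc[, id_items]))), 1e-10)
})

test_that("a constant shift in raw responses leaves corrected values unchanged", {
  bp <- tiny_blueprint()
  sim <- simulate_responses(sim_config(n = 50, seed = 81), bp)
  m <- sim$responses
  acq <- compute_acq(m, bp)
  cc <- center_responses(m, acq, bp)
  # shift on an unbounded numeric copy; the index absorbs the constant
  shifted <- m + 1L
  id_items <- bp$items$item_id[bp$items$framing != "self_efficacy"]
  acq_s <- data.frame(respondent_id = rownames(m),
                      acq = rowMeans(shifted[, id_items]))
  cc_s <- shifted - acq_s$acq
  expect_equal(cc_s, cc, ignore_attr = TRUE)
})

test_that("key orientation flips negatively keyed content after centering", {
  bp <- tiny_blueprint()
  cc <- matrix(c(-0.8, 0.3), 1, 2,
               dimnames = list("r1", c("O1_idneg_1", "O1_idpos_1")))
  out <- key_orient(cc, bp)
  expect_equal(unname(out[1, "O1_idneg_1"]), 0.8)
  expect_equal(unname(out[1, "O1_idpos_1"]), 0.3)
})

test_that("reversing before centering doubles acquiescence instead of removing it", {
  bp <- build_default_blueprint()
  sim <- cached_sim(n = 300, seed = 71)
  m <- sim$responses
  acq <- compute_acq(m, bp)
  correct <- key_orient(center_responses(m, acq, bp), bp)
  # wrong order: reverse on the raw scale first, then subtract the index
  wrong <- reverse_raw(m, bp) - acq$acq
  neg <- bp$items$item_id[bp$items$key == -1L]
  delta <- wrong[, neg] - correct[, neg]
  # each negatively keyed item now carries -2 * (acq - 3) of bias
  expect_equal(unname(delta), unname(outer(-2 * (acq$acq - 3), rep(1, length(neg)))),
               tolerance = 1e-10)
  # and the zero-mean invariant over identity items fails for acquiescent respondents
  id_items <- bp$items$item_id[bp$items$framing != "self_efficacy"]
  expect_gt(max(abs(rowMeans(wrong[, id_items]))), 0.05)
})

test_that("oriented triplet means track true facet scores for all framings", {
  bp <- build_default_blueprint()
  sim <- cached_sim(n = 1000, seed = 101)
  acq <- compute_acq(sim$responses, bp)
  ori <- key_orient(center_responses(sim$responses, acq, bp), bp)
  info <- indicator_table(bp, "triplet54")
  for (i in c(1, 2, 3)) { # idpos, idneg, se of the first facet
    mu <- rowMeans(ori[, info$items[[i]]])
    expect_gt(cor(mu, sim$truth$facet_scores[, info$facet[i]]), 0.3)
  }
})

test_that("id mismatches between responses and index are rejected", {
  bp <- tiny_blueprint()
  vals <- setNames(rep(4L, 18), bp$items$item_id)
  m <- resp_row(bp, vals)
  acq <- compute_acq(m, bp)
  acq$respondent_id <- "someone_else"
  expect_error(center_responses(m, acq, bp), "missing")
})
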
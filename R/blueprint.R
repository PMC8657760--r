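#' Instrument blueprints for balanced socio-emotional skill inventories
#'
#' A blueprint records the design of a hierarchical, balanced inventory:
#' broad domains (the socio-emotional Big Five), narrow facets nested under
#' them, and items nested under facets. Each facet carries three item
#' framings: positively keyed trait-identity items, negatively keyed
#' trait-identity items (each matched to a positive item as an antonym
#' pair), and positively keyed self-efficacy items. Every downstream stage
#' (acquiescence estimation, cluster scoring, target construction) indexes
#' against a blueprint.
#'
#' @name blueprint
NULL

# Canonical domain table. Labels follow the socio-emotional reading of the
# Big Five rather than the classic trait labels.
.domain_table <- function() {
  data.frame(
    code = c("O", "C", "E", "A", "N"),
    label = c("Open-mindedness", "Self-management", "Engaging with others",
              "Amity", "Negative-emotion regulation"),
    stringsAsFactors = FALSE
  )
}

# Canonical facet allocation: 3/5/3/4/3 facets over O/C/E/A/N.
.facet_table <- function() {
  data.frame(
    facet_id = c("O1", "O2", "O3",
                 "C1", "C2", "C3", "C4", "C5",
                 "E1", "E2", "E3",
                 "A1", "A2", "A3", "A4",
                 "N1", "N2", "N3"),
    label = c("Curiosity to learn", "Creative imagination", "Artistic interest",
              "Organization", "Determination", "Focus", "Persistence",
              "Responsibility",
              "Social initiative", "Assertiveness", "Enthusiasm",
              "Empathy", "Respect", "Trust", "Gratitude",
              "Stress modulation", "Self-confidence", "Frustration tolerance"),
    domain = c("O", "O", "O", "C", "C", "C", "C", "C", "E", "E", "E",
               "A", "A", "A", "A", "N", "N", "N"),
    stringsAsFactors = FALSE
  )
}

.framings <- c("identity_pos", "identity_neg", "self_efficacy")

#' Build an instrument blueprint from a facet table
#'
#' Generates the full item design for a set of facets: per facet, three
#' positively keyed identity items, three negatively keyed identity items
#' (paired one-to-one with the positive items as antonym pairs), and three
#' positively keyed self-efficacy items. Item order is canonical
#' (domain, facet, framing, index) so loading tables are comparable across
#' runs.
#'
#' @param facets data frame with columns `facet_id`, `domain`, and
#'   optionally `label`.
#' @param domains data frame with columns `code` and `label`; defaults to
#'   the five socio-emotional domains.
#' @return An object of class `blueprint`: a list with data frames
#'   `domains`, `facets` and `items` (columns `item_id`, `facet`, `domain`,
#'   `framing`, `key`, `pair_id`).
#' @export
build_blueprint <- function(facets, domains = .domain_table()) {
  stopifnot(is.data.frame(facets), all(c("facet_id", "domain") %in% names(facets)))
  if (anyDuplicated(domains$code)) stop("duplicate domain codes")
  if (anyDuplicated(facets$facet_id)) stop("duplicate facet ids")
  if (!all(facets$domain %in% domains$code)) {
    stop("facet(s) reference unknown domain: ",
         paste(setdiff(facets$domain, domains$code), collapse = ", "))
  }
  if (is.null(facets$label)) facets$label <- facets$facet_id
  # canonical facet order: domain order as given in `domains`, then input order
  facets <- facets[order(match(facets$domain, domains$code)), , drop = FALSE]

  items <- do.call(rbind, lapply(seq_len(nrow(facets)), function(i) {
    fid <- facets$facet_id[i]
    dom <- facets$domain[i]
    data.frame(
      item_id = c(paste0(fid, "_idpos_", 1:3),
                  paste0(fid, "_idneg_", 1:3),
                  paste0(fid, "_se_", 1:3)),
      facet = fid,
      domain = dom,
      framing = rep(.framings, each = 3),
      key = rep(c(1L, -1L, 1L), each = 3),
      pair_id = c(paste0(fid, "_p", 1:3), paste0(fid, "_p", 1:3), rep(NA, 3)),
      stringsAsFactors = FALSE
    )
  }))
  rownames(items) <- NULL
  structure(list(domains = domains, facets = facets, items = items),
            class = "blueprint")
}

#' Build the canonical 5-domain / 18-facet / 162-item blueprint
#'
#' The default design: 18 facets allocated 3/5/3/4/3 over the domains
#' O, C, E, A, N, nine items per facet (3 identity-positive, 3
#' identity-negative, 3 self-efficacy), giving 162 items, 108 identity
#' items and 54 antonym pairs.
#'
#' @return A `blueprint` object.
#' @export
build_default_blueprint <- function() {
  build_blueprint(.facet_table())
}

#' @export
print.blueprint <- function(x, ...) {
  cat(sprintf("Instrument blueprint: %d domains, %d facets, %d items (%d identity, %d pairs)\n",
              nrow(x$domains), nrow(x$facets), nrow(x$items),
              sum(x$items$framing != "self_efficacy"),
              length(unique(stats::na.omit(x$items$pair_id)))))
  invisible(x)
}

#' Extract the antonym pairs of a blueprint
#'
#' @param bp a `blueprint`.
#' @return data frame with one row per pair: `pair_id`, `facet`,
#'   `item_pos`, `item_neg`.
#' @export
antonym_pairs <- function(bp) {
  stopifnot(inherits(bp, "blueprint"))
  it <- bp$items[!is.na(bp$items$pair_id), , drop = FALSE]
  out <- lapply(split(it, it$pair_id), function(g) {
    pos <- g[g$framing == "identity_pos", , drop = FALSE]
    neg <- g[g$framing == "identity_neg", , drop = FALSE]
    if (nrow(pos) != 1L || nrow(neg) != 1L)
      stop("blueprint integrity: pair '", g$pair_id[1],
           "' does not have exactly one identity_pos and one identity_neg member")
    if (pos$facet != neg$facet)
      stop("blueprint integrity: pair '", g$pair_id[1],
           "' spans facets ", pos$facet, " and ", neg$facet)
    data.frame(pair_id = g$pair_id[1], facet = pos$facet,
               item_pos = pos$item_id, item_neg = neg$item_id,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  # report in canonical item order
  out <- out[order(match(out$item_pos, bp$items$item_id)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Validate an item-key table and return a blueprint
#'
#' Checks a long-format item key (one row per item) against the structural
#' invariants of a balanced design and returns a validated `blueprint`.
#' All violations are collected and reported together.
#'
#' @param table data frame with columns `item_id`, `domain`, `facet`,
#'   `framing`, `key`, `pair_id` (`pair_id` empty/NA for self-efficacy
#'   items). Alternatively a path to a CSV file with that header.
#' @param domains optional domain table (`code`, `label`).
#' @return A validated `blueprint` whose item order follows the table.
#' @export
validate_itemkey <- function(table, domains = NULL) {
  if (is.character(table) && length(table) == 1L) {
    table <- utils::read.csv(table, stringsAsFactors = FALSE)
  }
  need <- c("item_id", "domain", "facet", "framing", "key", "pair_id")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("item key lacks column(s): ", paste(miss, collapse = ", "))
  table$pair_id[!is.na(table$pair_id) & table$pair_id == ""] <- NA
  table$key <- as.integer(table$key)

  errs <- character(0)
  bad <- function(...) errs <<- c(errs, sprintf(...))

  dup <- unique(table$item_id[duplicated(table$item_id)])
  if (length(dup)) bad("duplicate item_id: %s", paste(dup, collapse = ", "))
  unk <- setdiff(table$framing, .framings)
  if (length(unk)) bad("unknown framing value(s): %s", paste(unk, collapse = ", "))

  # keying must follow framing: -1 iff identity_neg
  wrong_key <- table$item_id[(table$framing == "identity_neg") != (table$key == -1L)]
  for (id in wrong_key) bad("item '%s': key does not match framing", id)
  se_pair <- table$item_id[table$framing == "self_efficacy" & !is.na(table$pair_id)]
  for (id in se_pair) bad("item '%s': self_efficacy item carries a pair_id", id)
  id_nopair <- table$item_id[table$framing != "self_efficacy" & is.na(table$pair_id)]
  for (id in id_nopair) bad("item '%s': identity item lacks a pair_id", id)

  # per facet: exactly 3 items of each framing
  for (f in unique(table$facet)) {
    sub <- table[table$facet == f, , drop = FALSE]
    cnt <- table(factor(sub$framing, levels = .framings))
    if (any(cnt != 3L))
      bad("facet '%s': item counts per framing are %s (need 3/3/3)", f,
          paste(cnt, collapse = "/"))
    if (length(unique(sub$domain)) != 1L)
      bad("facet '%s': assigned to multiple domains", f)
  }

  # pairs: each pair_id on exactly one identity_pos and one identity_neg of
  # the same facet
  pr <- table[!is.na(table$pair_id), , drop = FALSE]
  for (p in unique(pr$pair_id)) {
    g <- pr[pr$pair_id == p, , drop = FALSE]
    if (nrow(g) != 2L || sort(g$framing)[1] != "identity_neg" ||
        sort(g$framing)[2] != "identity_pos")
      bad("pair '%s': members are not exactly one identity_pos and one identity_neg", p)
    else if (g$facet[1] != g$facet[2])
      bad("pair '%s': members on different facets", p)
  }

  if (length(errs)) stop("invalid item key:\n  ", paste(errs, collapse = "\n  "))

  fc <- unique(table[, c("facet", "domain")])
  names(fc) <- c("facet_id", "domain")
  if (is.null(domains)) {
    dt <- .domain_table()
    domains <- if (all(fc$domain %in% dt$code)) dt[dt$code %in% fc$domain, , drop = FALSE]
               else data.frame(code = unique(fc$domain), label = unique(fc$domain),
                               stringsAsFactors = FALSE)
  }
  fc$label <- fc$facet_id
  fc <- fc[order(match(fc$domain, domains$code)), , drop = FALSE]
  rownames(fc) <- NULL
  items <- table[, need]
  rownames(items) <- NULL
  structure(list(domains = domains, facets = fc,
                 items = items[, c("item_id", "facet", "domain", "framing",
                                   "key", "pair_id")]),
            class = "blueprint")
}

#' Serialize a blueprint's item key to CSV
#'
#' @param bp a `blueprint`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_itemkey <- function(bp, path) {
  stopifnot(inherits(bp, "blueprint"))
  it <- bp$items[, c("item_id", "domain", "facet", "framing", "key", "pair_id")]
  it$pair_id[is.na(it$pair_id)] <- ""
  utils::write.csv(it, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Internal helpers -----------------------------------------------------------

.identity_items <- function(bp) {
  bp$items$item_id[bp$items$framing != "self_efficacy"]
}

.item_key_vector <- function(bp) {
  stats::setNames(bp$items$key, bp$items$item_id)
}
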
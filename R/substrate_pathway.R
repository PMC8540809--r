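#' Canonical substrates of a set of enzymes
#'
#' Matches EC numbers of expressed gene products against a local reaction
#' database, fetches the compound ids (CIDs) of the reaction substrates,
#' retrieves their molecular formulas from the compound database and
#' classifies them into heteroatom classes. Only complete four-field ECs are
#' looked up; partial ECs are dropped with a warning since they have no
#' unambiguous reaction. ECs with no reaction in the database are returned
#' in a side list rather than silently dropped.
#'
#' @param ecs Character vector of EC numbers.
#' @param rxdb Reaction table with columns `rxn_id`, `ec`, `cid` (one row
#'   per reaction substrate).
#' @param cmpdb Compound table with columns `cid`, `cmpdname`, `mf`.
#' @return A list with `substrates` — a tibble with one row per distinct
#'   (cid, ec) pair carrying `cid`, `ec`, `cmpdname`, `mf`, element counts,
#'   `dbe`, `class`, `species` — and `unmatched_ecs`, the ECs with no
#'   reaction.
#' @export
substrates_for_ecs <- function(ecs, rxdb, cmpdb) {
  ecs <- unique(ecs)
  partial <- ecs[!is_complete_ec(ecs)]
  if (length(partial) > 0) {
    warn(paste0("dropping ", length(partial),
                " partial/malformed EC(s) with no unambiguous reaction: ",
                paste(utils::head(partial, 5), collapse = ", ")))
    ecs <- setdiff(ecs, partial)
  }
  hits <- as_tibble(rxdb) |>
    dplyr::filter(.data$ec %in% ecs) |>
    dplyr::distinct(.data$cid, .data$ec)
  unmatched <- sort(setdiff(ecs, hits$ec))
  if (nrow(hits) == 0) {
    empty <- annotate_formulas(tibble(cid = character(), ec = character(),
                                      cmpdname = character(), mf = character()))
    return(list(substrates = empty, unmatched_ecs = unmatched))
  }
  missing_cid <- setdiff(hits$cid, cmpdb$cid)
  if (length(missing_cid) > 0) {
    abort(paste0("compound(s) referenced by reactions but missing from the ",
                 "compound table: ", paste(utils::head(missing_cid, 5),
                                           collapse = ", ")))
  }
  sub <- dplyr::inner_join(hits,
                           dplyr::distinct(as_tibble(cmpdb)[c("cid", "cmpdname", "mf")]),
                           by = "cid")
  list(substrates = annotate_formulas(sub), unmatched_ecs = unmatched)
}

#' Filter candidate substrates on molecular descriptors
#'
#' Optional descriptor-based filter hook for substrate tables: carbon-number
#' range, DBE range, and required heteroatoms. All filters default to off so
#' the unfiltered table is the baseline; filtering criteria are reported via
#' attributes for audit.
#'
#' @param substrates Substrate table from [substrates_for_ecs()].
#' @param carbon_range,dbe_range Optional length-2 numeric ranges
#'   (inclusive).
#' @param require_heteroatoms Optional character vector among
#'   `c("N", "O", "S")`; compounds must contain all of them.
#' @return The filtered substrate tibble.
#' @export
filter_substrates <- function(substrates, carbon_range = NULL,
                              dbe_range = NULL, require_heteroatoms = NULL) {
  keep <- rep(TRUE, nrow(substrates))
  if (!is.null(carbon_range)) {
    keep <- keep & substrates$c >= carbon_range[1] & substrates$c <= carbon_range[2]
  }
  if (!is.null(dbe_range)) {
    keep <- keep & substrates$dbe >= dbe_range[1] & substrates$dbe <= dbe_range[2]
  }
  for (el in require_heteroatoms) {
    col <- c(N = "n", O = "o", S = "s")[[el]]
    keep <- keep & substrates[[col]] > 0
  }
  substrates[keep, , drop = FALSE]
}

#' Heteroatom class distribution of a substrate table
#'
#' Counts distinct compounds per heteroatom class. A compound reached
#' through several ECs is counted once, so multi-enzyme substrates do not
#' inflate their class.
#'
#' @param substrates Substrate table with columns `cid` and `class`.
#' @return A tibble `class` (all eight classes, zero-filled), `count`.
#' @export
class_distribution <- function(substrates) {
  if (nrow(substrates) == 0) abort("substrate table is empty")
  x <- dplyr::distinct(as_tibble(substrates)[c("cid", "class")])
  tb <- table(factor(as.character(x$class), levels = NAFC_CLASSES))
  tibble(class = factor(NAFC_CLASSES, levels = NAFC_CLASSES),
         count = as.integer(tb))
}

#' Chi-square comparison of two class distributions
#'
#' Pearson's chi-square test for count data on the 2 x k contingency table
#' formed by two heteroatom-class distributions, without continuity
#' correction. Classes with zero combined count are dropped before testing
#' (they contribute no information and would break the expected counts), so
#' the degrees of freedom are `k - 1` over the retained classes. Small
#' expected counts trigger the usual approximation warning but not a
#' failure.
#'
#' @param d1,d2 Class distributions as returned by [class_distribution()]
#'   (tibbles with `class`, `count`) or named count vectors.
#' @return A list with `statistic`, `df`, `p_value` and the tested `table`.
#' @export
compare_distributions <- function(d1, d2) {
  as_counts <- function(d) {
    if (is.data.frame(d)) stats::setNames(as.numeric(d$count), as.character(d$class))
    else stats::setNames(as.numeric(d), names(d))
  }
  x1 <- as_counts(d1)
  x2 <- as_counts(d2)
  labs <- union(names(x1), names(x2))
  m <- rbind(x1[labs], x2[labs])
  m[is.na(m)] <- 0
  colnames(m) <- labs
  m <- m[, colSums(m) > 0, drop = FALSE]
  if (ncol(m) < 2) {
    abort("need at least two classes with nonzero combined count")
  }
  ht <- stats::chisq.test(m, correct = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, table = m)
}

#' Match substrate-enzyme pairs to pathways
#'
#' Interrogates every (cid, ec) combination against a pathway database: a
#' pair supports a pathway exactly when it appears among that pathway's
#' steps. Two tables are returned — pairs *with* pathway information (one
#' row per pair-pathway hit, so a pair in two pathways yields two rows) and
#' pairs *without* any pathway. Every input pair lands in exactly one of the
#' two outputs.
#'
#' @param pairs A data frame with columns `cid`, `ec` (extra columns such as
#'   `class` are carried through).
#' @param pwdb Pathway step table with columns `pathway_id`, `name`, `cid`,
#'   `ec` (one row per step), as from [read_pathway_db()].
#' @return A list with tibbles `with_pathway` and `without_pathway`.
#' @export
match_cid_ec_to_pathways <- function(pairs, pwdb) {
  p <- dplyr::distinct(as_tibble(pairs))
  steps <- dplyr::distinct(as_tibble(pwdb))
  hits <- dplyr::inner_join(p, steps, by = c("cid", "ec"),
                            relationship = "many-to-many")
  misses <- dplyr::anti_join(p, steps, by = c("cid", "ec"))
  list(with_pathway = hits, without_pathway = misses)
}

#' Heteroatom group panels used for pathway presence
#'
#' The presence matrix is reported over four heteroatom panels — N and NO,
#' O, NOS, S and SO — with the remaining classes (CH, NS) routed to a
#' residual `other` panel rather than dropped.
#'
#' @param class Character or factor vector of heteroatom classes.
#' @return Character vector of panel names.
#' @export
nafc_group <- function(class) {
  cls <- as.character(class)
  dplyr::case_when(cls %in% c("N", "NO") ~ "N+NO",
                   cls == "O" ~ "O",
                   cls == "NOS" ~ "NOS",
                   cls %in% c("S", "SO") ~ "S+SO",
                   TRUE ~ "other")
}

NAFC_GROUPS <- c("N+NO", "O", "NOS", "S+SO", "other")

#' Pathway presence matrix by culture and heteroatom group
#'
#' Collapses pathway hits into the presence/absence matrix behind the
#' green/grey pathway panels: a pathway is present for a (culture, group)
#' cell when at least `min_hits` supporting (cid, ec) pairs whose substrate
#' class belongs to the group were found in that culture. Presence is
#' monotone — adding hits can only turn cells on.
#'
#' @param with_pathway Hit table from [match_cid_ec_to_pathways()], with
#'   columns `culture`, `class`, `pathway_id` (and optionally `name`).
#' @param min_hits Minimum number of supporting pairs (default 1).
#' @param pathways Optional character vector fixing the pathway universe of
#'   the matrix (defaults to the pathways observed in `with_pathway`).
#' @param cultures Optional character vector fixing the culture axis.
#' @return A long tibble `culture`, `group`, `pathway_id`, `n_hits`,
#'   `present`, completed over all cultures, the five groups and all
#'   pathways.
#' @export
presence_matrix <- function(with_pathway, min_hits = 1, pathways = NULL,
                            cultures = NULL) {
  miss <- setdiff(c("culture", "class", "pathway_id"), names(with_pathway))
  if (length(miss) > 0) {
    abort(paste0("hit table missing column(s): ", paste(miss, collapse = ", ")))
  }
  h <- as_tibble(with_pathway)
  h$group <- nafc_group(h$class)
  counted <- h |>
    dplyr::distinct(.data$culture, .data$group, .data$pathway_id, .data$cid,
                    .data$ec) |>
    dplyr::count(.data$culture, .data$group, .data$pathway_id, name = "n_hits")
  skel <- tidyr::expand_grid(culture = cultures %||% unique(h$culture),
                             group = NAFC_GROUPS,
                             pathway_id = sort(pathways %||% unique(h$pathway_id)))
  skel |>
    dplyr::left_join(counted, by = c("culture", "group", "pathway_id")) |>
    dplyr::mutate(n_hits = dplyr::coalesce(.data$n_hits, 0L),
                  present = .data$n_hits >= min_hits)
}
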
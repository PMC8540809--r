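#' Merge term annotations across sources
#'
#' Takes per-gene term annotations (GO terms and/or EC numbers) from several
#' sources and returns the per-gene union, keeping per-term provenance so
#' that cross-source agreement can be audited. The merge is commutative,
#' associative and idempotent over sources.
#'
#' @param records A data frame with columns `gene_id`, `source`, `term`.
#' @return A tibble `gene_id`, `term`, `sources` (comma-separated, sorted),
#'   `n_sources`.
#' @export
merge_term_sets <- function(records) {
  miss <- setdiff(c("gene_id", "source", "term"), names(records))
  if (length(miss) > 0) {
    abort(paste0("records missing column(s): ", paste(miss, collapse = ", ")))
  }
  as_tibble(records) |>
    dplyr::distinct(.data$gene_id, .data$source, .data$term) |>
    dplyr::group_by(.data$gene_id, .data$term) |>
    dplyr::summarise(sources = paste(sort(unique(.data$source)), collapse = ","),
                     n_sources = dplyr::n_distinct(.data$source),
                     .groups = "drop") |>
    dplyr::arrange(.data$gene_id, .data$term)
}

#' Validate Enzyme Commission numbers
#'
#' An EC number has four dot-separated fields with a top-level class digit
#' in 1..7 (oxidoreductases through translocases). Partial ECs use `-` for
#' unresolved fields (e.g. `"1.1.-.-"`); they still carry a top-level class
#' but cannot be matched to reactions.
#'
#' @param x Character vector of EC strings.
#' @return `is_valid_ec`/`is_complete_ec`: logical vectors. `ec_top_class`:
#'   integer vector of top-level classes (`NA` for malformed input).
#' @export
is_valid_ec <- function(x) {
  stringr::str_detect(x, "^[1-7]\\.([0-9]+|-)\\.([0-9]+|-)\\.([0-9]+|-)$")
}

#' @rdname is_valid_ec
#' @export
is_complete_ec <- function(x) {
  stringr::str_detect(x, "^[1-7]\\.[0-9]+\\.[0-9]+\\.[0-9]+$")
}

#' @rdname is_valid_ec
#' @export
ec_top_class <- function(x) {
  out <- rep(NA_integer_, length(x))
  ok <- is_valid_ec(x)
  out[ok] <- as.integer(stringr::str_sub(x[ok], 1, 1))
  out
}

EC_CLASS_NAMES <- c("1" = "Oxidoreductases", "2" = "Transferases",
                    "3" = "Hydrolases", "4" = "Lyases", "5" = "Isomerases",
                    "6" = "Ligases", "7" = "Translocases")

#' Consolidate EC annotations from two sources
#'
#' Cross-references per-gene EC assignments from two annotation routes
#' (e.g. a homology-based EC mapping and curated database annotations). The
#' default is the union with a per-record agreement flag — `"both"` when the
#' two sources concur, otherwise the name of the single supporting source —
#' which keeps recall while preserving the evidence trail. `mode =
#' "intersection"` keeps only concordant assignments.
#'
#' @param source_a,source_b Data frames with columns `gene_id`, `ec`.
#' @param mode `"union"` (default) or `"intersection"`.
#' @param source_names Length-2 character vector naming the sources, used in
#'   the agreement flag.
#' @return A tibble `gene_id`, `ec`, `agreement`.
#' @export
consolidate_ec <- function(source_a, source_b, mode = c("union", "intersection"),
                           source_names = c("source_a", "source_b")) {
  mode <- match.arg(mode)
  check_ec_table <- function(tb, nm) {
    miss <- setdiff(c("gene_id", "ec"), names(tb))
    if (length(miss) > 0) abort(paste0(nm, " missing column(s): ",
                                       paste(miss, collapse = ", ")))
    bad <- !is_valid_ec(tb$ec)
    if (any(bad)) {
      i <- which(bad)[1]
      abort(paste0("malformed EC number in ", nm, ": gene '", tb$gene_id[i],
                   "', ec '", tb$ec[i], "'"))
    }
    dplyr::distinct(as_tibble(tb[c("gene_id", "ec")]))
  }
  a <- check_ec_table(source_a, source_names[1])
  b <- check_ec_table(source_b, source_names[2])
  a$.a <- TRUE
  b$.b <- TRUE
  m <- dplyr::full_join(a, b, by = c("gene_id", "ec"))
  m$.a[is.na(m$.a)] <- FALSE
  m$.b[is.na(m$.b)] <- FALSE
  m$agreement <- dplyr::case_when(m$.a & m$.b ~ "both",
                                  m$.a ~ source_names[1],
                                  TRUE ~ source_names[2])
  if (mode == "intersection") m <- m[m$agreement == "both", , drop = FALSE]
  dplyr::arrange(m[c("gene_id", "ec", "agreement")], .data$gene_id, .data$ec)
}

#' Gene counts by top-level enzyme class and culture
#'
#' Tabulates EC-annotated genes into the seven top-level Enzyme Commission
#' classes per culture. A gene contributes at most once per top-level class
#' even when it carries several ECs within that class, but can contribute to
#' several classes. Partial ECs still count toward their top-level class.
#'
#' @param annotations A data frame with columns `gene_id`, `ec`, `culture`.
#' @return A tibble with one row per enzyme class (`ec_class`, `class_name`)
#'   and one count column per culture, zero-filled.
#' @export
enzyme_class_table <- function(annotations) {
  miss <- setdiff(c("gene_id", "ec", "culture"), names(annotations))
  if (length(miss) > 0) {
    abort(paste0("annotations missing column(s): ", paste(miss, collapse = ", ")))
  }
  x <- as_tibble(annotations)
  x$ec_class <- ec_top_class(x$ec)
  if (any(is.na(x$ec_class))) {
    i <- which(is.na(x$ec_class))[1]
    abort(paste0("malformed EC number: gene '", x$gene_id[i], "', ec '",
                 x$ec[i], "'"))
  }
  skel <- tidyr::expand_grid(ec_class = 1:7,
                             culture = unique(x$culture))
  x |>
    dplyr::distinct(.data$culture, .data$gene_id, .data$ec_class) |>
    dplyr::count(.data$ec_class, .data$culture) |>
    dplyr::right_join(skel, by = c("ec_class", "culture")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  class_name = unname(EC_CLASS_NAMES[as.character(.data$ec_class)])) |>
    tidyr::pivot_wider(id_cols = c("ec_class", "class_name"),
                       names_from = "culture", values_from = "n") |>
    dplyr::arrange(.data$ec_class)
}

#' Hypergeometric over-representation of annotation terms
#'
#' For each term, tests whether the up-regulated gene set contains more
#' genes with that term than expected by chance, using the upper-tail
#' hypergeometric test `P(X >= k)` with parameters (`N` genome genes, `K`
#' genes with the term, `n` up-regulated genes). P-values are adjusted by
#' Benjamini-Hochberg across all tested terms (within each ontology class
#' when the universe table carries an `ontology` column, mirroring per-class
#' BP/MF reporting).
#'
#' The reported `gene_ratio` is `k / K` — the number of over-expressed genes
#' with the term relative to the number of genes with the same term in the
#' whole genome. The more common `k / n` convention is emitted alongside as
#' `gene_ratio_de`.
#'
#' @param universe A data frame with columns `term`, `gene_id` (one row per
#'   gene-term assignment over the whole genome) and optionally `ontology`.
#' @param de_genes Character vector of up-regulated ("differentially
#'   expressed") gene ids; must be a subset of the gene universe.
#' @param alpha Significance threshold on the adjusted p-value (default
#'   0.05).
#' @param universe_genes Optional full genome gene set; defaults to all
#'   genes appearing in `universe` (genes with no terms can be supplied
#'   here).
#' @return A tibble `term` (+ `ontology` if present), `k`, `K`, `n`, `N`,
#'   `gene_ratio`, `gene_ratio_de`, `p_value`, `p_adjusted`, `significant`,
#'   sorted by p-value.
#' @export
overrepresentation <- function(universe, de_genes, alpha = 0.05,
                               universe_genes = NULL) {
  miss <- setdiff(c("term", "gene_id"), names(universe))
  if (length(miss) > 0) {
    abort(paste0("universe missing column(s): ", paste(miss, collapse = ", ")))
  }
  u <- dplyr::distinct(as_tibble(universe))
  if (is.null(universe_genes)) universe_genes <- unique(u$gene_id)
  de_genes <- unique(de_genes)
  if (!all(de_genes %in% universe_genes)) {
    abort("`de_genes` must be a subset of the gene universe")
  }
  N <- length(universe_genes)
  n <- length(de_genes)
  grp <- intersect(c("ontology", "term"), names(u))
  res <- u |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(K = dplyr::n_distinct(.data$gene_id),
                     k = dplyr::n_distinct(intersect(.data$gene_id, de_genes)),
                     .groups = "drop")
  if (any(res$K == 0)) {
    warn("terms with no genome genes were skipped")
    res <- res[res$K > 0, , drop = FALSE]
  }
  res$n <- n
  res$N <- N
  res$gene_ratio <- res$k / res$K
  res$gene_ratio_de <- ifelse(n > 0, res$k / n, NA_real_)
  res$p_value <- stats::phyper(res$k - 1, res$K, res$N - res$K, res$n,
                               lower.tail = FALSE)
  if ("ontology" %in% names(res)) {
    res <- res |>
      dplyr::group_by(.data$ontology) |>
      dplyr::mutate(p_adjusted = stats::p.adjust(.data$p_value, method = "BH")) |>
      dplyr::ungroup()
  } else {
    res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  }
  res$significant <- res$p_adjusted < alpha
  dplyr::arrange(res, .data$p_value, .data$term)
}
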
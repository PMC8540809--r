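#' Relative class-abundance profile of one sample
#'
#' Summarises an NAFC feature table into the relative abundance of each
#' heteroatom species within a sample, the quantity displayed by
#' before/after degradation bar charts. Abundance is concentration-weighted
#' by default; `weight = "count"` weights every compound equally instead
#' (the two conventions coincide only for equal concentrations).
#'
#' @param features A data frame with columns `mf`, `sample_id`,
#'   `concentration` (non-negative).
#' @param sample Optional sample id to select; required when `features`
#'   contains more than one sample.
#' @param weight `"concentration"` (default) or `"count"`.
#' @return A tibble with columns `species`, `class`, `abundance`; abundances
#'   sum to 1 within the sample.
#' @export
class_abundance <- function(features, sample = NULL,
                            weight = c("concentration", "count")) {
  weight <- match.arg(weight)
  f <- check_features(features)
  if (!is.null(sample)) f <- f[f$sample_id == sample, , drop = FALSE]
  ids <- unique(f$sample_id)
  if (length(ids) == 0 || nrow(f) == 0) abort("no features for the requested sample")
  if (length(ids) > 1) {
    abort("`features` spans several samples; pass `sample` to pick one")
  }
  ann <- annotate_formulas(f)
  w <- if (weight == "concentration") ann$concentration else rep(1, nrow(ann))
  tot <- sum(w)
  if (tot <= 0) abort("sample has zero total concentration")
  ann |>
    dplyr::mutate(.w = w) |>
    dplyr::group_by(.data$species, .data$class) |>
    dplyr::summarise(abundance = sum(.data$.w) / tot, .groups = "drop") |>
    dplyr::arrange(.data$class, .data$species)
}

#' Per-compound concentration change across microbial treatment
#'
#' Joins before- and after-treatment feature tables on the canonical formula
#' and reports the per-compound delta \eqn{C_{io} - C_i}. A compound missing
#' from one table is treated as concentration zero there, so degradation
#' products that only appear after treatment show up with negative deltas.
#' Class, carbon number and DBE are carried along for heat-map aggregation.
#'
#' @param before,after Feature tables (columns `mf`, `sample_id`,
#'   `concentration`), each covering a single sample.
#' @return A tibble with one row per formula present in either table:
#'   `formula`, `class`, `species`, `carbon`, `dbe`, `before`, `after`,
#'   `delta` (`before - after`).
#' @export
delta_concentration <- function(before, after) {
  b <- sum_by_formula(before, "before")
  a <- sum_by_formula(after, "after")
  out <- dplyr::full_join(b, a,
                          by = c("formula", "class", "species", "carbon", "dbe"))
  out$before[is.na(out$before)] <- 0
  out$after[is.na(out$after)] <- 0
  out$delta <- out$before - out$after
  dplyr::arrange(out, .data$class, .data$species, .data$carbon, .data$dbe)
}

#' Species completely removed or newly produced by treatment
#'
#' A species is *removed* when it has positive total concentration before
#' treatment and zero (or no features) after; it is *produced* when it is
#' absent before but present after — the signature of degradation products
#' generated by microbial metabolism.
#'
#' @inheritParams delta_concentration
#' @return A list with character vectors `removed` and `produced` (disjoint
#'   by construction).
#' @export
removed_and_produced_classes <- function(before, after) {
  d <- delta_concentration(before, after)
  tot <- d |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(before = sum(.data$before), after = sum(.data$after),
                     .groups = "drop")
  list(removed = sort(tot$species[tot$before > 0 & tot$after == 0]),
       produced = sort(tot$species[tot$before == 0 & tot$after > 0]))
}

#' Summary of the classic naphthenic acids in one sample
#'
#' Restricts a feature table to classic NAs (CcHhO2) and reports the number
#' of unique compounds, their cumulative concentration, and the fractions of
#' the classic-NA population by carbon number and by DBE (count-weighted, as
#' population shares).
#'
#' @param features A feature table for a single sample.
#' @return A list with `n_compounds`, `total_concentration`, `carbon_hist`
#'   (tibble `carbon`, `fraction`) and `dbe_hist` (tibble `dbe`, `fraction`).
#' @export
classic_na_summary <- function(features) {
  f <- check_features(features)
  ann <- annotate_formulas(f)
  cl <- ann[ann$classic_na, , drop = FALSE]
  cl <- cl |>
    dplyr::group_by(.data$formula, .data$c, .data$dbe) |>
    dplyr::summarise(concentration = sum(.data$concentration), .groups = "drop")
  n <- nrow(cl)
  hist_of <- function(v, name) {
    if (n == 0) {
      return(tibble(!!name := numeric(), fraction = numeric()))
    }
    tb <- table(v)
    tibble(!!name := as.numeric(names(tb)), fraction = as.numeric(tb) / n)
  }
  list(n_compounds = n,
       total_concentration = sum(cl$concentration),
       carbon_hist = hist_of(cl$c, "carbon"),
       dbe_hist = hist_of(cl$dbe, "dbe"))
}

#' Percent removal of NAFCs by treatment
#'
#' \eqn{100 (T_{before} - T_{after}) / T_{before}} over the selected compound
#' set, optionally restricted to classic NAs (the paper-style "% of NAs
#' removed" figure). Negative values indicate net production. The value is
#' returned unrounded.
#'
#' @inheritParams delta_concentration
#' @param classic_only If `TRUE`, only classic NAs enter the totals.
#' @return A single numeric percentage.
#' @export
percent_removal <- function(before, after, classic_only = FALSE) {
  d <- delta_concentration(before, after)
  if (classic_only) {
    keep <- is_classic_na(parse_formula(d$formula))
    d <- d[keep, , drop = FALSE]
  }
  tb <- sum(d$before)
  if (tb <= 0) abort("total concentration before treatment must be positive")
  100 * (tb - sum(d$after)) / tb
}

#' Carbon-number by DBE heat-map matrix of concentration deltas
#'
#' Aggregates a [delta_concentration()] table into the matrix behind the
#' per-class degradation heat maps: rows are carbon numbers, columns DBE
#' values, cells the summed delta (positive = net removal).
#'
#' @param delta A table from [delta_concentration()].
#' @param class Optional single heteroatom class to restrict to.
#' @return A numeric matrix with carbon numbers as rownames and DBE values as
#'   colnames.
#' @export
delta_heatmap <- function(delta, class = NULL) {
  d <- delta
  if (!is.null(class)) d <- d[as.character(d$class) == class, , drop = FALSE]
  if (nrow(d) == 0) return(matrix(numeric(0), 0, 0))
  carbons <- sort(unique(d$carbon))
  dbes <- sort(unique(d$dbe))
  m <- matrix(0, length(carbons), length(dbes),
              dimnames = list(carbons, dbes))
  for (i in seq_len(nrow(d))) {
    m[as.character(d$carbon[i]), as.character(d$dbe[i])] <-
      m[as.character(d$carbon[i]), as.character(d$dbe[i])] + d$delta[i]
  }
  m
}

sum_by_formula <- function(features, value_name) {
  f <- check_features(features)
  ann <- annotate_formulas(f)
  ann |>
    dplyr::group_by(.data$formula, .data$class, .data$species,
                    carbon = .data$c, dbe = .data$dbe) |>
    dplyr::summarise(!!value_name := sum(.data$concentration), .groups = "drop")
}

check_features <- function(features) {
  if (!is.data.frame(features)) abort("feature table must be a data frame")
  miss <- setdiff(c("mf", "sample_id", "concentration"), names(features))
  if (length(miss) > 0) {
    abort(paste0("feature table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (any(is.na(features$concentration) | features$concentration < 0)) {
    abort("concentrations must be non-negative")
  }
  as_tibble(features)
}
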
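# Readers/writers for the flat-file formats consumed and produced by the
# workflow. All are thin readr/jsonlite wrappers with column checks; the
# pathway database is the only nested format (JSON) and is flattened to one
# row per step at the reader boundary.

read_checked <- function(path, reader, cols, what) {
  x <- reader(path)
  miss <- setdiff(cols, names(x))
  if (length(miss) > 0) {
    abort(paste0(what, " file '", path, "' is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  x
}

tsv <- function(path) readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
csv <- function(path) readr::read_csv(path, show_col_types = FALSE, progress = FALSE)

#' Read workflow input tables
#'
#' Column-checked readers for the flat files the pipeline consumes:
#' * `read_ms_table()`: CSV of MS features — `mf`, `sample_id`, `concentration`.
#' * `read_gene_catalog()`: TSV — `gene_id`, `strain`, `length`.
#' * `read_coverage()`: TSV — `gene_id`, `library`, `covered_bases`.
#' * `read_counts()`: TSV — `gene_id`, `library`, `count`.
#' * `read_annotations()`: TSV of term annotations — `gene_id`, `source`, `term`.
#' * `read_ec_annotations()`: TSV — `gene_id`, `ec`.
#' * `read_reaction_db()`: TSV — `rxn_id`, `ec`, `cid` (one row per substrate).
#' * `read_compound_db()`: CSV — `cid`, `cmpdname`, `mf`.
#' * `read_gene_pathways()`: TSV — `gene_id`, `pathway_id`, `pathway_name`.
#'
#' @param path File path.
#' @return A tibble with the documented columns.
#' @name readers
NULL

#' @rdname readers
#' @export
read_ms_table <- function(path) {
  read_checked(path, csv, c("mf", "sample_id", "concentration"), "MS feature")
}

#' @rdname readers
#' @export
read_gene_catalog <- function(path) {
  read_checked(path, tsv, c("gene_id", "strain", "length"), "gene catalog")
}

#' @rdname readers
#' @export
read_coverage <- function(path) {
  read_checked(path, tsv, c("gene_id", "library", "covered_bases"), "coverage")
}

#' @rdname readers
#' @export
read_counts <- function(path) {
  read_checked(path, tsv, c("gene_id", "library", "count"), "count")
}

#' @rdname readers
#' @export
read_annotations <- function(path) {
  read_checked(path, tsv, c("gene_id", "source", "term"), "annotation")
}

#' @rdname readers
#' @export
read_ec_annotations <- function(path) {
  read_checked(path, tsv, c("gene_id", "ec"), "EC annotation")
}

#' @rdname readers
#' @export
read_reaction_db <- function(path) {
  read_checked(path, tsv, c("rxn_id", "ec", "cid"), "reaction database")
}

#' @rdname readers
#' @export
read_compound_db <- function(path) {
  read_checked(path, csv, c("cid", "cmpdname", "mf"), "compound database")
}

#' @rdname readers
#' @export
read_gene_pathways <- function(path) {
  read_checked(path, tsv, c("gene_id", "pathway_id", "pathway_name"),
               "gene-pathway map")
}

#' Read or write a pathway database
#'
#' The pathway database is stored as JSON: an array of objects with
#' `pathway_id`, `name` and `steps`, each step a `{cid, ec}` pair. The
#' reader flattens it into the step table (`pathway_id`, `name`, `cid`,
#' `ec`) used by [match_cid_ec_to_pathways()]; the writer performs the
#' inverse.
#'
#' @param path File path.
#' @param pwdb A step table with columns `pathway_id`, `name`, `cid`, `ec`.
#' @return `read_pathway_db()` returns the step tibble;
#'   `write_pathway_db()` returns `path` invisibly.
#' @export
read_pathway_db <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(raw) == 0 || is.null(raw$pathway_id)) {
    return(tibble(pathway_id = character(), name = character(),
                  cid = character(), ec = character()))
  }
  purrr::pmap_dfr(list(raw$pathway_id, raw$name, raw$steps),
                  function(pid, nm, st) {
                    st <- as_tibble(st)
                    tibble(pathway_id = pid, name = nm,
                           cid = as.character(st$cid), ec = st$ec)
                  })
}

#' @rdname read_pathway_db
#' @export
write_pathway_db <- function(pwdb, path) {
  split_steps <- as_tibble(pwdb) |>
    dplyr::group_by(.data$pathway_id, .data$name) |>
    dplyr::summarise(steps = list(data.frame(cid = cid, ec = ec)),
                     .groups = "drop")
  jsonlite::write_json(split_steps, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
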
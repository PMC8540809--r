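#' Gene-coverage retention rule
#'
#' A gene is retained for expression analysis when sequencing reads cover at
#' least `min_bases` of it **or** at least `min_frac` of its length — a
#' disjunction, so short genes can qualify through the fractional clause
#' alone. The rule is monotone in `covered_bases`.
#'
#' @param covered_bases Integer vector of covered bases per gene.
#' @param length Integer vector of gene lengths (recycled).
#' @param min_bases Absolute coverage threshold in bases (default 150).
#' @param min_frac Fractional coverage threshold (default 0.90).
#' @return Logical vector, `TRUE` for retained genes.
#' @examples
#' coverage_filter(c(150, 90, 149), c(1000, 100, 1000))
#' @export
coverage_filter <- function(covered_bases, length, min_bases = 150,
                            min_frac = 0.90) {
  if (any(covered_bases < 0) || any(length < 1)) {
    abort("covered_bases must be >= 0 and length >= 1")
  }
  if (any(covered_bases > length)) {
    abort("covered_bases cannot exceed gene length")
  }
  covered_bases >= min_bases | covered_bases / length >= min_frac
}

#' Covered bases per gene from read and gene intervals
#'
#' Computes, for every gene, the number of bases covered by at least one
#' read: the size of the union of the read intervals intersected with the
#' gene interval. All coordinates are 0-based half-open (BED convention) on
#' named contigs. Overlapping and abutting reads are never double-counted.
#'
#' @param reads A data frame with columns `contig`, `start`, `end`.
#' @param genes A data frame with columns `gene_id`, `contig`, `start`,
#'   `end`.
#' @return A tibble with columns `gene_id`, `covered_bases`, in the row
#'   order of `genes`.
#' @export
compute_gene_coverage <- function(reads, genes) {
  for (tb in list(reads, genes)) {
    if (any(tb$end < tb$start)) abort("interval end < start")
  }
  covered <- integer(nrow(genes))
  for (ctg in unique(genes$contig)) {
    gi <- which(genes$contig == ctg)
    r <- reads[reads$contig == ctg, , drop = FALSE]
    g <- genes[gi, , drop = FALSE]
    if (nrow(r) == 0) next
    # half-open [start, end) -> 1-based closed [start + 1, end]
    rr <- IRanges::IRanges(start = r$start + 1L, end = r$end)
    rr <- rr[IRanges::width(rr) > 0]
    if (length(rr) == 0) next
    hit <- IRanges::coverage(rr) > 0L
    gr <- IRanges::IRanges(start = g$start + 1L, end = g$end)
    gr <- IRanges::restrict(gr, start = 1L, end = length(hit),
                            keep.all.ranges = TRUE)
    ok <- IRanges::width(gr) > 0
    if (any(ok)) {
      v <- IRanges::Views(hit, gr[ok])
      covered[gi[ok]] <- as.integer(sum(v))
    }
  }
  tibble(gene_id = genes$gene_id, covered_bases = covered)
}

#' Transcripts per million
#'
#' Length-normalised TPM: per gene, `rate = count / length`; per
#' normalisation group, `tpm = 1e6 * rate / sum(rate)`, so TPM sums to one
#' million within each group. By default normalisation is performed within
#' each (library, strain) pair, which keeps per-organism expression
#' comparable between a pure-culture library and the same organism's share
#' of a composite (co-culture) library; `by_strain = FALSE` normalises each
#' library jointly over the composite gene set instead.
#'
#' @param counts A data frame with columns `gene_id`, `library`, `count`
#'   (non-negative).
#' @param genes Gene catalog with columns `gene_id`, `strain`, `length`.
#' @param by_strain Normalise within (library, strain) (default) or per
#'   library only.
#' @return A tibble `gene_id`, `library`, `strain`, `tpm`.
#' @export
tpm <- function(counts, genes, by_strain = TRUE) {
  if (any(counts$count < 0)) abort("counts must be non-negative")
  x <- dplyr::inner_join(as_tibble(counts), as_tibble(genes)[c("gene_id", "strain", "length")],
                         by = "gene_id")
  if (nrow(x) < nrow(counts)) {
    abort("some counted genes are missing from the gene catalog")
  }
  grp <- if (by_strain) c("library", "strain") else "library"
  x <- x |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::mutate(.rate = .data$count / .data$length,
                  .tot = sum(.data$.rate)) |>
    dplyr::ungroup()
  if (any(x$.tot <= 0)) {
    abort("a normalisation group has zero total count")
  }
  tibble(gene_id = x$gene_id, library = x$library, strain = x$strain,
         tpm = 1e6 * x$.rate / x$.tot)
}

#' MA statistics for consortium vs pure-culture expression
#'
#' For each gene, `M = log2((tpm_consortium + pseudocount) /
#' (tpm_individual + pseudocount))` and `A = 0.5 * log2((tpm_consortium +
#' pseudocount) * (tpm_individual + pseudocount))`. A positive M means the
#' gene is more highly expressed in the co-culture (fold-change > 1). The
#' pseudocount guards against zeros — subtractive libraries routinely
#' contain genes absent in one condition — and the identity
#' `log2(tpm_consortium + pseudocount) = A + M/2` holds exactly.
#'
#' @param tpm_consortium,tpm_individual Non-negative numeric vectors of TPM
#'   values (recycled to a common length).
#' @param pseudocount Positive value added to both sides (default 0.5 TPM).
#' @return A tibble with columns `M` and `A`.
#' @export
ma_stats <- function(tpm_consortium, tpm_individual, pseudocount = 0.5) {
  if (pseudocount <= 0) abort("pseudocount must be positive")
  if (any(tpm_consortium < 0) || any(tpm_individual < 0)) {
    abort("TPM values must be non-negative")
  }
  a <- tpm_consortium + pseudocount
  b <- tpm_individual + pseudocount
  tibble(M = log2(a / b), A = 0.5 * log2(a * b))
}

#' Rank pathways by count of fold-changed member enzymes
#'
#' Mirrors the KEGG-style ranking of pathways whose constituent enzymes show
#' fold-changes greater than 1 (`direction = "up"`, i.e. `M > 0`) or lower
#' than 1 (`direction = "down"`, `M < 0`) between co-culture and pure
#' culture. Pathways are ranked by the number of qualifying member genes,
#' descending, with ties broken lexicographically on pathway id so output is
#' deterministic.
#'
#' @param ma A data frame with columns `gene_id` and `M`.
#' @param gene_pathways Map with columns `gene_id`, `pathway_id` and
#'   optionally `pathway_name`.
#' @param direction `"up"` or `"down"`.
#' @param top_k Number of top pathways to keep (default all).
#' @return A tibble `pathway_name` (if available), `pathway_id`,
#'   `enzyme_count`, `genes` (comma-separated member genes).
#' @export
rank_pathways_by_fc <- function(ma, gene_pathways, direction = c("up", "down"),
                                top_k = Inf) {
  direction <- match.arg(direction)
  qual <- if (direction == "up") ma$gene_id[ma$M > 0] else ma$gene_id[ma$M < 0]
  gp <- dplyr::distinct(as_tibble(gene_pathways))
  hit <- gp[gp$gene_id %in% qual, , drop = FALSE]
  if (nrow(hit) == 0) {
    out <- tibble(pathway_id = character(), enzyme_count = integer(),
                  genes = character())
    if ("pathway_name" %in% names(gp)) {
      out <- dplyr::bind_cols(tibble(pathway_name = character()), out)
    }
    return(out)
  }
  grp <- intersect(c("pathway_name", "pathway_id"), names(hit))
  out <- hit |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(enzyme_count = dplyr::n_distinct(.data$gene_id),
                     genes = paste(sort(unique(.data$gene_id)), collapse = ","),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$enzyme_count), .data$pathway_id)
  utils::head(out, top_k)
}
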
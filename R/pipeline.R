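#' Run the full workflow on a fixture bundle
#'
#' Convenience driver that chains every stage of the workflow over an
#' in-memory input bundle (as produced by [generate_fixture()] or
#' [read_fixture()]): coverage filtering, TPM, EC consolidation,
#' substrate retrieval and classing per culture, chi-square comparison of
#' each pure culture against the co-culture, pathway matching and the
#' presence matrix, MS removal summaries, per-strain MA statistics with
#' pathway ranking, the enzyme-class table and GO over-representation.
#'
#' @param fx Input bundle: a named list with elements `genes`, `coverage`,
#'   `counts`, `go_annotations`, `ec_blast2go`, `ec_uniprot`, `reactions`,
#'   `compounds`, `pathway_db`, `gene_pathways`, `ms_before`, `ms_after`.
#' @param alpha Significance threshold for enrichment (default 0.05).
#' @return A named list of stage outputs; see Details in the vignette.
#' @export
analyze_fixture <- function(fx, alpha = 0.05) {
  cultures <- unique(fx$coverage$library)
  strains <- unique(fx$genes$strain)

  ## coverage filter -> retained gene sets per library
  cov <- dplyr::inner_join(fx$coverage, fx$genes[c("gene_id", "length")],
                           by = "gene_id")
  cov$retained <- coverage_filter(cov$covered_bases, cov$length)
  retained <- lapply(stats::setNames(cultures, cultures), function(cu) {
    sort(cov$gene_id[cov$library == cu & cov$retained])
  })

  ## expression
  tpm_tbl <- tpm(fx$counts, fx$genes)

  ## annotations
  ec_cons <- consolidate_ec(fx$ec_blast2go, fx$ec_uniprot,
                            source_names = c("blast2go", "uniprot"))
  ec_annotations <- purrr::map_dfr(cultures, function(cu) {
    x <- ec_cons[ec_cons$gene_id %in% retained[[cu]], c("gene_id", "ec")]
    dplyr::mutate(x, culture = cu)
  })
  enzyme_classes <- enzyme_class_table(ec_annotations)
  go_universe <- dplyr::distinct(fx$go_annotations[c("term", "gene_id", "ontology")])
  enrichment <- lapply(stats::setNames(cultures, cultures), function(cu) {
    overrepresentation(go_universe, retained[[cu]], alpha = alpha,
                       universe_genes = unique(fx$genes$gene_id))
  })

  ## substrates and class distributions per culture
  ec_by_culture <- lapply(stats::setNames(cultures, cultures), function(cu) {
    sort(unique(ec_annotations$ec[ec_annotations$culture == cu]))
  })
  substrates <- lapply(ec_by_culture, function(ecs) {
    substrates_for_ecs(ecs, fx$reactions, fx$compounds)
  })
  distributions <- lapply(substrates, function(s) class_distribution(s$substrates))
  pure <- setdiff(cultures, "coculture")
  chisq <- if ("coculture" %in% cultures) {
    lapply(stats::setNames(pure, pure), function(cu) {
      compare_distributions(distributions[[cu]], distributions$coculture)
    })
  }

  ## pathway matching and presence
  pairs <- purrr::map_dfr(cultures, function(cu) {
    s <- substrates[[cu]]$substrates
    tibble(culture = cu, cid = s$cid, ec = s$ec, class = s$class)
  })
  matched <- match_cid_ec_to_pathways(pairs, fx$pathway_db)
  presence <- presence_matrix(matched$with_pathway, cultures = cultures)

  ## MS profiles
  ms <- lapply(stats::setNames(names(fx$ms_after), names(fx$ms_after)),
               function(cu) {
    after <- fx$ms_after[[cu]]
    list(percent_removal = percent_removal(fx$ms_before, after),
         percent_removal_classic = percent_removal(fx$ms_before, after,
                                                   classic_only = TRUE),
         removed_produced = removed_and_produced_classes(fx$ms_before, after))
  })
  classic <- classic_na_summary(fx$ms_before)

  ## MA and fold-change pathway ranking per strain
  ma <- list()
  rankings <- list()
  if ("coculture" %in% cultures) {
    for (st in intersect(strains, cultures)) {
      t_pure <- tpm_tbl[tpm_tbl$library == st, c("gene_id", "tpm")]
      t_co <- tpm_tbl[tpm_tbl$library == "coculture" & tpm_tbl$strain == st,
                      c("gene_id", "tpm")]
      m <- dplyr::full_join(t_pure, t_co, by = "gene_id",
                            suffix = c("_pure", "_co"))
      m[is.na(m)] <- 0
      ma[[st]] <- dplyr::bind_cols(tibble(gene_id = m$gene_id),
                                   ma_stats(m$tpm_co, m$tpm_pure))
      gp <- fx$gene_pathways[fx$gene_pathways$gene_id %in%
                               fx$genes$gene_id[fx$genes$strain == st], ]
      rankings[[st]] <- list(
        up = rank_pathways_by_fc(ma[[st]], gp, direction = "up"),
        down = rank_pathways_by_fc(ma[[st]], gp, direction = "down"))
    }
  }

  list(retained = retained, tpm = tpm_tbl, ec_consolidated = ec_cons,
       ec_by_culture = ec_by_culture, enzyme_classes = enzyme_classes,
       enrichment = enrichment, substrates = substrates,
       distributions = distributions, chisq = chisq,
       pathway_hits = matched, presence = presence,
       ms = ms, classic_na = classic, ma = ma, pathway_rankings = rankings)
}
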
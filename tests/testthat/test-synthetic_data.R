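norm_df <- function(d) {
  as.data.frame(lapply(d, function(x) {
    if (is.factor(x)) as.character(x) else if (is.numeric(x)) as.numeric(x) else x
  }))
}

test_that("the same seed reproduces the fixture byte for byte", {
  cfg <- fixture_config(seed = 11)
  fx1 <- generate_fixture(cfg)
  fx2 <- generate_fixture(cfg)
  for (el in setdiff(names(fx1), c("ms_after", "manifest"))) {
    expect_identical(fx1[[el]], fx2[[el]], label = el)
  }
  expect_identical(fx1$ms_after, fx2$ms_after)

  d1 <- file.path(tempdir(), "fxa"); d2 <- file.path(tempdir(), "fxb")
  write_fixture(fx1, d1); write_fixture(fx2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE), label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)

  fx3 <- generate_fixture(fixture_config(seed = 12))
  expect_false(identical(fx1$counts, fx3$counts))
})

test_that("infeasible configurations fail before any file is written", {
  expect_error(fixture_config(fraction_upregulated = 1.2), "fractions")
  expect_error(fixture_config(n_terms = 0), "positive")
  expect_error(fixture_config(n_fold_genes = 50), "fold")
  expect_error(fixture_config(class_probs_pure = c(O = 1)), "eight NAFC classes")
  # planted removal of a species absent from the untreated water
  expect_error(generate_fixture(fixture_config(removed_species = "N9S9")),
               "removed_species")
  # planted production of a species already present
  expect_error(generate_fixture(fixture_config(produced_species = "O3")),
               "produced_species")
  expect_error(fixture_config(n_classic_na = 1000) |> generate_fixture(),
               "classic NAs")
})

test_that("fixture files round-trip through the module readers", {
  fx <- generate_fixture(fixture_config(seed = 13))
  dir <- file.path(tempdir(), "fx_rt")
  write_fixture(fx, dir)
  back <- read_fixture(dir)
  for (el in c("genes", "coverage", "counts", "go_annotations", "ec_blast2go",
               "ec_uniprot", "reactions", "compounds", "gene_pathways",
               "ms_before")) {
    expect_equal(norm_df(back[[el]]), norm_df(fx[[el]]), label = el,
                 tolerance = 1e-12)
  }
  expect_equal(norm_df(back$pathway_db[order(back$pathway_db$pathway_id,
                                             back$pathway_db$cid,
                                             back$pathway_db$ec), ]),
               norm_df(fx$pathway_db[order(fx$pathway_db$pathway_id,
                                           fx$pathway_db$cid,
                                           fx$pathway_db$ec), ]),
               tolerance = 1e-12)
  for (cu in names(fx$ms_after)) {
    expect_equal(norm_df(back$ms_after[[cu]]), norm_df(fx$ms_after[[cu]]),
                 tolerance = 1e-12)
  }
  expect_equal(unname(unlist(back$manifest$percent_removal_classic)),
               unname(fx$manifest$percent_removal_classic))
  unlink(dir, recursive = TRUE)
})

test_that("null fixtures plant no effects", {
  fx <- null_fixture(fixture_config(seed = 14))
  expect_length(fx$manifest$removed_species, 0)
  expect_length(fx$manifest$produced_species, 0)
  for (cu in fx$manifest$cultures) {
    rp <- removed_and_produced_classes(fx$ms_before, fx$ms_after[[cu]])
    expect_length(rp$removed, 0)
    expect_length(rp$produced, 0)
    expect_lt(abs(percent_removal(fx$ms_before, fx$ms_after[[cu]],
                                  classic_only = TRUE)), 5)
  }
  # all cultures share one substrate-class generating process
  expect_equal(fx$manifest$class_probs$coculture, fx$manifest$class_probs$P_putida)
})

test_that("enrichment p-values on a null fixture are near-uniform", {
  fx <- null_fixture(fixture_config(seed = 15))
  uni <- dplyr::distinct(fx$go_annotations[c("term", "gene_id")])
  set.seed(151)
  de <- sample(unique(fx$genes$gene_id), 60)
  res <- overrepresentation(uni, de, universe_genes = unique(fx$genes$gene_id))
  ks <- suppressWarnings(stats::ks.test(res$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("planted class-abundance structure is recovered from the manifest", {
  fx <- generate_fixture(fixture_config(seed = 16))
  # classic NA truth
  cs <- classic_na_summary(fx$ms_before)
  expect_equal(cs$n_compounds, fx$manifest$classic_na_count)
  expect_equal(cs$total_concentration, fx$manifest$classic_total,
               tolerance = 1e-9)
  expect_equal(norm_df(cs$carbon_hist),
               norm_df(dplyr::arrange(fx$manifest$classic_carbon_hist, carbon)),
               tolerance = 1e-12)
  expect_equal(norm_df(cs$dbe_hist),
               norm_df(dplyr::arrange(fx$manifest$classic_dbe_hist, dbe)),
               tolerance = 1e-12)
  # abundance profile sums to one and covers the planted species
  ab <- class_abundance(fx$ms_before)
  expect_equal(sum(ab$abundance), 1, tolerance = 1e-9)
  expect_true(all(c("O2", "S", "N2S3") %in% ab$species))
})
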
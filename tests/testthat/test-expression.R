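test_that("coverage retention is the disjunction of the 150-base and 90% rules", {
  # exactly 150 bases on a long gene; 90% of a short gene; both clauses failing
  expect_true(coverage_filter(150, 1000))
  expect_true(coverage_filter(90, 100))
  expect_false(coverage_filter(149, 1000))
  expect_false(coverage_filter(89, 100))
  expect_true(coverage_filter(900, 1000))
  expect_error(coverage_filter(101, 100), "exceed")
})

test_that("coverage retention is monotone in covered bases", {
  set.seed(21)
  for (i in 1:50) {
    len <- sample(50:2000, 1)
    covs <- sort(sample(0:len, 10))
    kept <- coverage_filter(covs, len)
    expect_true(all(diff(kept) >= 0))  # never flips retained -> dropped
  }
})

test_that("gene coverage is the union of read overlaps, never double counted", {
  genes <- tibble::tibble(gene_id = "g1", contig = "c1", start = 100, end = 600)
  inside <- tibble::tibble(contig = "c1", start = 200, end = 350)
  expect_equal(compute_gene_coverage(inside, genes)$covered_bases, 150)

  abutting <- tibble::tibble(contig = "c1", start = c(100, 200), end = c(200, 300))
  expect_equal(compute_gene_coverage(abutting, genes)$covered_bases, 200)

  overlapping <- tibble::tibble(contig = "c1", start = c(0, 50), end = c(100, 150))
  g0 <- tibble::tibble(gene_id = "g0", contig = "c1", start = 0, end = 500)
  expect_equal(compute_gene_coverage(overlapping, g0)$covered_bases, 150)

  bad <- tibble::tibble(contig = "c1", start = 10, end = 5)
  expect_error(compute_gene_coverage(bad, genes), "end < start")
})

test_that("gene coverage equals a per-base marking oracle on random instances", {
  set.seed(22)
  for (i in 1:200) {
    glen <- sample(100:1000, 1)
    gstart <- sample(0:500, 1)
    genes <- tibble::tibble(gene_id = "g", contig = "c",
                            start = gstart, end = gstart + glen)
    nr <- sample(1:50, 1)
    rs <- sample(0:1500, nr, replace = TRUE)
    reads <- tibble::tibble(contig = "c", start = rs,
                            end = rs + sample(20:200, nr, replace = TRUE))
    expect_equal(compute_gene_coverage(reads, genes)$covered_bases,
                 perbase_coverage_oracle(reads, gstart, gstart + glen))
  }
})

test_that("TPM is the length-normalised rate scaled to one million", {
  genes <- tibble::tibble(gene_id = c("g1", "g2"), strain = "st",
                          length = c(1000, 2000))
  single <- tibble::tibble(gene_id = "g1", library = "L1", count = 7)
  expect_equal(tpm(single, genes)$tpm, 1e6)

  counts <- tibble::tibble(gene_id = c("g1", "g2"), library = "L1",
                           count = c(10, 40))
  tt <- tpm(counts, genes)
  expect_equal(tt$tpm, c(1e6 / 3, 2e6 / 3), tolerance = 1e-9)

  doubled <- dplyr::mutate(counts, count = count * 2)
  expect_equal(tpm(doubled, genes)$tpm, tt$tpm)

  zero <- tibble::tibble(gene_id = c("g1", "g2"), library = "L1", count = 0)
  expect_error(tpm(zero, genes), "zero total")
})

test_that("TPM sums to one million per normalisation group", {
  fx <- generate_fixture(fixture_config(seed = 3))
  tt <- tpm(fx$counts, fx$genes)
  sums <- tapply(tt$tpm, paste(tt$library, tt$strain), sum)
  expect_true(all(abs(sums - 1e6) < 1e-3))
  joint <- tpm(fx$counts, fx$genes, by_strain = FALSE)
  sums2 <- tapply(joint$tpm, joint$library, sum)
  expect_true(all(abs(sums2 - 1e6) < 1e-3))
})

test_that("MA statistics obey their defining identities", {
  expect_equal(ma_stats(120, 120)$M, 0)
  near_zero <- ma_stats(200, 50, pseudocount = 1e-9)
  expect_equal(near_zero$M, 2, tolerance = 1e-6)
  expect_equal(near_zero$A, 0.5 * log2(1e4), tolerance = 1e-6)
  swapped <- ma_stats(50, 200, pseudocount = 1e-9)
  expect_equal(swapped$M, -near_zero$M, tolerance = 1e-12)
  expect_equal(swapped$A, near_zero$A, tolerance = 1e-12)

  set.seed(23)
  tc <- runif(1000, 0, 1e5)
  ti <- runif(1000, 0, 1e5)
  st <- ma_stats(tc, ti, pseudocount = 0.5)
  expect_true(all(abs(log2(tc + 0.5) - (st$A + st$M / 2)) < 1e-9))
})

test_that("pathway ranking counts qualifying enzymes with deterministic ties", {
  ma <- tibble::tibble(gene_id = paste0("g", 1:6),
                       M = c(2, 1, 0.5, -1, 0, 3))
  gp <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g1", "g2", "g4", "g6"),
    pathway_id = c("pwB", "pwB", "pwB", "pwA", "pwA", "pwA", "pwC"),
    pathway_name = paste0("map ", c("B", "B", "B", "A", "A", "A", "C")))
  up <- rank_pathways_by_fc(ma, gp, "up")
  expect_equal(up$pathway_id, c("pwB", "pwA", "pwC"))  # 3 > 2 = 1... pwA ties pwC
  expect_equal(up$enzyme_count, c(3, 2, 1))
  expect_equal(up$genes[1], "g1,g2,g3")

  down <- rank_pathways_by_fc(ma, gp, "down")
  expect_equal(down$pathway_id, "pwA")
  expect_equal(down$enzyme_count, 1)

  none <- rank_pathways_by_fc(dplyr::mutate(ma, M = -1), gp, "up")
  expect_equal(nrow(none), 0)

  # lexicographic tie-break on pathway id
  tie <- rank_pathways_by_fc(ma, dplyr::bind_rows(gp,
    tibble::tibble(gene_id = "g6", pathway_id = "pwZ", pathway_name = "map Z"),
    tibble::tibble(gene_id = "g6", pathway_id = "pwAA", pathway_name = "map AA")),
    "up")
  k1 <- tie$pathway_id[tie$enzyme_count == 1]
  expect_equal(k1, sort(k1))
  expect_equal(rank_pathways_by_fc(ma, gp, "up", top_k = 1)$pathway_id, "pwB")
})
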
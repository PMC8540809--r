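tiny_db <- function() {
  list(rxdb = tibble::tibble(rxn_id = c("R1", "R1", "R2"),
                             ec = c("1.1.1.1", "1.1.1.1", "2.2.2.2"),
                             cid = c("C01", "C02", "C01")),
       cmpdb = tibble::tibble(cid = c("C01", "C02"),
                              cmpdname = c("alpha", "beta"),
                              mf = c("C16H28O2", "C14H23NO2")))
}

test_that("substrate lookup returns one row per (cid, ec) and reports misses", {
  db <- tiny_db()
  res <- substrates_for_ecs("1.1.1.1", db$rxdb, db$cmpdb)
  expect_equal(nrow(res$substrates), 2)
  expect_setequal(res$substrates$cid, c("C01", "C02"))
  expect_equal(as.character(res$substrates$class[res$substrates$cid == "C02"]), "NO")
  expect_length(res$unmatched_ecs, 0)

  miss <- substrates_for_ecs("5.5.5.5", db$rxdb, db$cmpdb)
  expect_equal(nrow(miss$substrates), 0)
  expect_equal(miss$unmatched_ecs, "5.5.5.5")

  expect_warning(substrates_for_ecs(c("1.1.1.1", "1.1.-.-"), db$rxdb, db$cmpdb),
                 "partial")
  broken <- db$rxdb
  broken$cid[1] <- "C99"
  expect_error(substrates_for_ecs("1.1.1.1", broken, db$cmpdb), "C99")
})

test_that("class distribution counts distinct compounds once per class", {
  db <- tiny_db()
  res <- substrates_for_ecs(c("1.1.1.1", "2.2.2.2"), db$rxdb, db$cmpdb)
  d <- class_distribution(res$substrates)
  expect_equal(sum(d$count), 2)            # C01 via two ECs counted once
  expect_equal(d$count[d$class == "O"], 1)
  expect_equal(d$count[d$class == "NO"], 1)
  expect_equal(nrow(d), 8)
  expect_error(class_distribution(res$substrates[0, ]), "empty")
})

test_that("descriptor filters restrict substrates only when switched on", {
  db <- tiny_db()
  s <- substrates_for_ecs("1.1.1.1", db$rxdb, db$cmpdb)$substrates
  expect_equal(nrow(filter_substrates(s)), 2)
  expect_equal(filter_substrates(s, carbon_range = c(15, 20))$cid, "C01")
  expect_equal(filter_substrates(s, require_heteroatoms = "N")$cid, "C02")
  expect_equal(nrow(filter_substrates(s, dbe_range = c(99, 100))), 0)
})

test_that("chi-square comparison reproduces the Pearson statistic without correction", {
  d <- compare_distributions(c(a = 10, b = 10), c(a = 10, b = 30))
  expect_equal(d$statistic, 3.75, tolerance = 1e-12)
  expect_equal(d$df, 1)

  same <- suppressWarnings(compare_distributions(c(a = 5, b = 5), c(a = 5, b = 5)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  x <- c(CH = 0, O = 12, NO = 7, S = 3)
  y <- c(CH = 0, O = 9, NO = 11, S = 2)
  perm <- sample(names(x))
  expect_equal(suppressWarnings(compare_distributions(x, y))$statistic,
               suppressWarnings(compare_distributions(x[perm], y[perm]))$statistic)
  # zero-total classes dropped before computing df
  expect_equal(suppressWarnings(compare_distributions(x, y))$df, 2)
  expect_error(compare_distributions(c(a = 1, b = 0), c(a = 2, b = 0)), "two classes")
})

test_that("chi-square agrees with a textbook implementation on random tables", {
  set.seed(41)
  for (i in 1:50) {
    k <- sample(2:8, 1)
    m <- matrix(rpois(2 * k, 8) + 1, nrow = 2)
    colnames(m) <- paste0("c", 1:k)
    res <- suppressWarnings(compare_distributions(m[1, ], m[2, ]))
    ora <- pearson_oracle(m)
    expect_equal(res$statistic, ora$statistic, tolerance = 1e-9)
    expect_equal(res$df, ora$df)
  }
})

test_that("pathway matching splits pairs into with/without without loss", {
  pwdb <- tibble::tibble(pathway_id = c("P1", "P2", "P2"),
                         name = c("one", "two", "two"),
                         cid = c("C01", "C01", "C02"),
                         ec = c("1.1.1.1", "1.1.1.1", "2.2.2.2"))
  pairs <- tibble::tibble(cid = c("C01", "C02", "C03"),
                          ec = c("1.1.1.1", "2.2.2.2", "3.3.3.3"))
  m <- match_cid_ec_to_pathways(pairs, pwdb)
  # C01/1.1.1.1 sits in two pathways -> two hit rows
  expect_equal(sum(m$with_pathway$cid == "C01"), 2)
  expect_equal(sum(m$with_pathway$cid == "C02"), 1)
  expect_equal(m$without_pathway$cid, "C03")
  recovered <- dplyr::bind_rows(m$with_pathway[c("cid", "ec")],
                                m$without_pathway[c("cid", "ec")])
  expect_setequal(paste(recovered$cid, recovered$ec),
                  paste(pairs$cid, pairs$ec))
})

test_that("presence requires a supporting hit in the right heteroatom panel", {
  hit <- tibble::tibble(culture = "co", class = "O", pathway_id = "P1",
                        cid = "C01", ec = "1.1.1.1")
  pm <- presence_matrix(hit)
  expect_true(pm$present[pm$group == "O" & pm$pathway_id == "P1"])
  expect_false(any(pm$present[pm$group != "O"]))

  empty <- presence_matrix(hit[0, ])
  expect_equal(nrow(empty), 0)

  # CH and NS are routed to the residual panel, not dropped
  resid <- presence_matrix(tibble::tibble(culture = "co", class = c("CH", "NS"),
                                          pathway_id = "P1",
                                          cid = c("C01", "C02"), ec = "1.1.1.1"))
  expect_true(all(resid$present[resid$group == "other"]))

  # threshold: two supporting pairs needed
  two <- dplyr::bind_rows(hit, dplyr::mutate(hit, cid = "C02"))
  strict <- presence_matrix(hit, min_hits = 2)
  expect_false(any(strict$present))
  expect_true(any(presence_matrix(two, min_hits = 2)$present))
})

test_that("presence is monotone under added hits", {
  set.seed(42)
  base <- tibble::tibble(culture = sample(c("a", "b"), 6, TRUE),
                         class = sample(c("O", "NO", "S"), 6, TRUE),
                         pathway_id = sample(c("P1", "P2"), 6, TRUE),
                         cid = paste0("C", 1:6), ec = "1.1.1.1")
  more <- dplyr::bind_rows(base,
                           tibble::tibble(culture = "a", class = "NOS",
                                          pathway_id = "P1", cid = "C9",
                                          ec = "2.2.2.2"))
  p1 <- presence_matrix(base, pathways = c("P1", "P2"), cultures = c("a", "b"))
  p2 <- presence_matrix(more, pathways = c("P1", "P2"), cultures = c("a", "b"))
  j <- dplyr::left_join(p1, p2, by = c("culture", "group", "pathway_id"))
  expect_true(all(!j$present.x | j$present.y))
})
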
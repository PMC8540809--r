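# Seeded synthetic-fixture generator. Every pipeline stage can be exercised
# offline against these bundles; the manifest records all planted truth so
# tests can derive expected outputs independently of the pipeline code.

#' Configuration for the synthetic fixture generator
#'
#' Bundles and validates all knobs of [generate_fixture()]. The defaults
#' define the reference study conditions emulated by the package: two
#' strains grown as pure cultures and a 1:1 co-culture, subtractive
#' (up-regulated-only) expression libraries, per-culture enzyme complements
#' whose substrate class distributions differ between pure and co-culture
#' (the co-culture loses the S and SO classes), classic-NA removal of
#' 11%/12%/31% by culture, four completely removed species and four newly
#' produced species. See the methods vignette for the rationale behind each
#' default.
#'
#' @param seed Integer root seed; the same seed reproduces the fixture
#'   byte-for-byte. Per-section sub-seeds are derived from it so adding a
#'   section never perturbs the others.
#' @param n_genes_per_strain Genes per strain genome.
#' @param gene_length_range Inclusive range of gene lengths in bases.
#' @param fraction_upregulated Fraction of each strain's genes planted as
#'   up-regulated per culture.
#' @param coculture_overlap Fraction of a strain's pure-culture up-set that
#'   is also up-regulated in the co-culture.
#' @param n_fold_genes Number of planted strong fold-change genes per strain
#'   and direction (used for MA and pathway-ranking recovery).
#' @param planted_fold Fold-change planted on those genes.
#' @param count_noise_sd Log-normal noise sd on read counts.
#' @param n_terms Number of GO-style annotation terms.
#' @param n_ecs_per_culture Enzymes (complete ECs) per culture; per-culture
#'   EC sets are disjoint so between-culture comparisons are independent.
#' @param substrates_per_ec Integer vector sampled for the number of
#'   substrates per reaction.
#' @param class_probs_pure,class_probs_coculture Heteroatom-class sampling
#'   probabilities for substrates of pure-culture and co-culture enzymes.
#' @param n_extra_compounds_per_class Unreferenced compounds added to the
#'   compound database per class.
#' @param n_pathways Number of pathways in the pathway database.
#' @param pathway_miss_fraction Fraction of substrate-enzyme pairs reserved
#'   as belonging to no pathway.
#' @param n_kegg_maps Decoy gene-pathway maps per strain (besides the two
#'   planted ones).
#' @param n_classic_na Number of unique classic NAs in the untreated water.
#' @param classic_total Cumulative classic-NA concentration (mg/L).
#' @param classic_removal Named fractions of classic-NA concentration
#'   removed by each culture.
#' @param removed_species Species completely removed by every culture.
#' @param produced_species Species absent before treatment but produced by
#'   every culture.
#' @param concentration_noise_sd Log-normal noise sd on per-compound
#'   retention.
#' @return A validated config list of class `nafc_fixture_config`.
#' @export
fixture_config <- function(seed = 1L,
                           n_genes_per_strain = 200L,
                           gene_length_range = c(300L, 3000L),
                           fraction_upregulated = 0.25,
                           coculture_overlap = 0.5,
                           n_fold_genes = 6L,
                           planted_fold = 4,
                           count_noise_sd = 0.15,
                           n_terms = 30L,
                           n_ecs_per_culture = 60L,
                           substrates_per_ec = 3:5,
                           class_probs_pure = c(CH = 0.02, N = 0.07, NS = 0.02,
                                                NO = 0.33, O = 0.42, NOS = 0.04,
                                                S = 0.05, SO = 0.05),
                           class_probs_coculture = c(CH = 0.02, N = 0.07, NS = 0.02,
                                                     NO = 0.37, O = 0.47, NOS = 0.04,
                                                     S = 0.005, SO = 0.005),
                           n_extra_compounds_per_class = 5L,
                           n_pathways = 25L,
                           pathway_miss_fraction = 0.2,
                           n_kegg_maps = 8L,
                           n_classic_na = 131L,
                           classic_total = 28.2,
                           classic_removal = c(P_putida = 0.11,
                                               P_protegens = 0.12,
                                               coculture = 0.31),
                           removed_species = c("S", "N2S3", "NOS2", "N2OS2"),
                           produced_species = c("O7", "O8", "N2O2", "S2O3"),
                           concentration_noise_sd = 0.1) {
  cfg <- list(seed = as.integer(seed),
              strains = c("P_putida", "P_protegens"),
              cultures = c("P_putida", "P_protegens", "coculture"),
              n_genes_per_strain = as.integer(n_genes_per_strain),
              gene_length_range = as.integer(gene_length_range),
              fraction_upregulated = fraction_upregulated,
              coculture_overlap = coculture_overlap,
              n_fold_genes = as.integer(n_fold_genes),
              planted_fold = planted_fold,
              count_noise_sd = count_noise_sd,
              n_terms = as.integer(n_terms),
              n_ecs_per_culture = as.integer(n_ecs_per_culture),
              substrates_per_ec = as.integer(substrates_per_ec),
              class_probs_pure = class_probs_pure,
              class_probs_coculture = class_probs_coculture,
              n_extra_compounds_per_class = as.integer(n_extra_compounds_per_class),
              n_pathways = as.integer(n_pathways),
              pathway_miss_fraction = pathway_miss_fraction,
              n_kegg_maps = as.integer(n_kegg_maps),
              n_classic_na = as.integer(n_classic_na),
              classic_total = classic_total,
              classic_removal = classic_removal,
              removed_species = removed_species,
              produced_species = produced_species,
              concentration_noise_sd = concentration_noise_sd)
  fracs <- c(cfg$fraction_upregulated, cfg$coculture_overlap,
             cfg$pathway_miss_fraction, cfg$classic_removal)
  if (any(fracs < 0 | fracs > 1)) abort("all fractions must lie in [0, 1]")
  if (any(c(cfg$n_genes_per_strain, cfg$n_terms, cfg$n_ecs_per_culture,
            cfg$n_pathways, cfg$n_classic_na) < 1)) {
    abort("counts must be positive")
  }
  if (abs(sum(cfg$class_probs_pure) - 1) > 1e-8 ||
      abs(sum(cfg$class_probs_coculture) - 1) > 1e-8) {
    abort("class probabilities must sum to 1")
  }
  if (!setequal(names(cfg$class_probs_pure), NAFC_CLASSES) ||
      !setequal(names(cfg$class_probs_coculture), NAFC_CLASSES)) {
    abort("class probabilities must be named by the eight NAFC classes")
  }
  if (!all(cfg$cultures %in% names(cfg$classic_removal))) {
    abort("classic_removal must name every culture")
  }
  n_up <- round(cfg$fraction_upregulated * cfg$n_genes_per_strain)
  if (2 * cfg$n_fold_genes > round(cfg$coculture_overlap * n_up)) {
    abort("n_fold_genes too large for the shared up-regulated gene set")
  }
  class(cfg) <- "nafc_fixture_config"
  cfg
}

section_seed <- function(seed, k) {
  as.integer((as.double(seed) * 1009 + 7919 * k) %% 2147483647)
}

# Heteroatom tuple (n, o, s) encoded in a species label; inverse of
# species_label() for labels of the forms used here ("CH", "N2O2", "SO3").
parse_species <- function(label) {
  if (label == "CH") return(c(n = 0L, o = 0L, s = 0L))
  m <- stringr::str_match_all(label, "([NOS])([0-9]*)")[[1]]
  if (nrow(m) == 0 || paste(m[, 1], collapse = "") != label) {
    abort(paste0("cannot parse species label '", label, "'"))
  }
  out <- c(n = 0L, o = 0L, s = 0L)
  for (i in seq_len(nrow(m))) {
    k <- if (m[i, 3] == "") 1L else as.integer(m[i, 3])
    out[tolower(m[i, 2])] <- out[tolower(m[i, 2])] + k
  }
  out
}

# Random formula with the given heteroatom tuple; integral DBE guaranteed.
random_formulas <- function(k, n, o, s, c_range = 5:25, dbe_range = 1:10) {
  cs <- sample(c_range, k, replace = TRUE)
  ds <- vapply(cs, function(cc) sample(seq_len(min(max(dbe_range), cc)), 1L),
               integer(1))
  hs <- 2L * cs + n + 2L - 2L * ds
  canonical_formula(tibble(c = cs, h = hs, n = n, o = o, s = s))
}

# Distinct classic-NA formulas: n_classic (carbon, DBE) cells sampled without
# replacement from the 5..25 x 1..min(10, c) grid, weighted toward C16 / DBE 4.
classic_na_formulas <- function(n_classic) {
  grid <- do.call(rbind, lapply(5:25, function(cc) {
    data.frame(c = cc, d = seq_len(min(10L, cc)))
  }))
  if (n_classic > nrow(grid)) {
    abort(paste0("at most ", nrow(grid), " distinct classic NAs are possible ",
                 "with carbon 5-25 and DBE 1-10"))
  }
  w <- stats::dnorm(grid$c, 16, 4) * stats::dnorm(grid$d, 4, 2)
  pick <- grid[sample.int(nrow(grid), n_classic, prob = w), , drop = FALSE]
  tibble(c = pick$c, dbe = pick$d,
         mf = canonical_formula(tibble(c = pick$c, h = 2L * pick$c + 2L - 2L * pick$d,
                                       n = 0L, o = 2L, s = 0L)))
}

# Species present in untreated water besides the classic NAs (O2).
BASELINE_SPECIES <- c("CH", "N", "N2", "NS", "N2S3", "NO", "N2O",
                      "O", "O3", "O4", "O5", "O6",
                      "NOS", "NOS2", "N2OS2", "S", "S2", "SO2", "SO3")

#' Generate a synthetic fixture bundle with planted ground truth
#'
#' Emits, fully in memory, every input the pipeline consumes — gene catalog,
#' per-library coverage and counts, two-source GO and EC annotations,
#' reaction/compound/pathway databases, gene-to-KEGG-map table, and
#' before/after MS feature tables — together with a manifest of all planted
#' facts (up-regulated gene sets, EC-to-substrate-class truth, pathway
#' support, removal/production). The same seed yields a byte-identical
#' bundle. Use [write_fixture()] to materialise it as flat files.
#'
#' @param cfg A [fixture_config()].
#' @param null If `TRUE`, no effects are planted: all cultures share the
#'   same substrate-class generating process, no fold-changes, no classic-NA
#'   removal and no removed/produced species. Used for statistical
#'   calibration.
#' @return A named list of input tibbles plus `manifest`.
#' @export
generate_fixture <- function(cfg = fixture_config(), null = FALSE) {
  if (!inherits(cfg, "nafc_fixture_config")) {
    abort("`cfg` must come from fixture_config()")
  }
  strains <- cfg$strains
  cultures <- cfg$cultures

  ## -- genes ----------------------------------------------------------------
  set.seed(section_seed(cfg$seed, 1))
  genes <- purrr::map_dfr(strains, function(st) {
    tibble(gene_id = sprintf("%s_g%04d", st, seq_len(cfg$n_genes_per_strain)),
           strain = st,
           length = sample(cfg$gene_length_range[1]:cfg$gene_length_range[2],
                           cfg$n_genes_per_strain, replace = TRUE))
  })

  ## -- planted up-regulated sets --------------------------------------------
  set.seed(section_seed(cfg$seed, 2))
  n_up <- round(cfg$fraction_upregulated * cfg$n_genes_per_strain)
  n_shared <- round(cfg$coculture_overlap * n_up)
  up <- list()     # per strain: pure-culture up set
  up_co <- list()  # per strain: co-culture up set
  for (st in strains) {
    g <- genes$gene_id[genes$strain == st]
    pure <- sample(g, n_up)
    shared <- sample(pure, n_shared)
    novel <- sample(setdiff(g, pure), n_up - n_shared)
    up[[st]] <- sort(pure)
    up_co[[st]] <- sort(c(shared, novel))
  }
  upregulated <- list(P_putida = up$P_putida,
                      P_protegens = up$P_protegens,
                      coculture = sort(c(up_co$P_putida, up_co$P_protegens)))

  ## -- coverage -------------------------------------------------------------
  set.seed(section_seed(cfg$seed, 3))
  lib_strains <- list(P_putida = "P_putida", P_protegens = "P_protegens",
                      coculture = strains)
  coverage <- purrr::map_dfr(cultures, function(cu) {
    g <- genes[genes$strain %in% lib_strains[[cu]], , drop = FALSE]
    is_up <- g$gene_id %in% upregulated[[cu]]
    cov <- integer(nrow(g))
    cov[is_up] <- round(g$length[is_up] * stats::runif(sum(is_up), 0.92, 1.0))
    cov[!is_up] <- sample(0:120, sum(!is_up), replace = TRUE)
    tibble(gene_id = g$gene_id, library = cu, covered_bases = cov)
  })

  ## -- counts with planted fold-changes -------------------------------------
  set.seed(section_seed(cfg$seed, 4))
  fold_genes <- list()
  counts <- list()
  for (st in strains) {
    shared <- intersect(up[[st]], up_co[[st]])
    f_up <- sort(sample(shared, cfg$n_fold_genes))
    f_down <- sort(sample(setdiff(shared, f_up), cfg$n_fold_genes))
    fold_genes[[st]] <- list(up = f_up, down = f_down)
    all_up <- union(up[[st]], up_co[[st]])
    base <- stats::setNames(stats::rlnorm(length(all_up), log(100), 1), all_up)
    fold <- stats::setNames(rep(1, length(all_up)), all_up)
    if (!null) {
      fold[f_up] <- cfg$planted_fold
      fold[f_down] <- 1 / cfg$planted_fold
    }
    noise <- function(k) exp(stats::rnorm(k, 0, cfg$count_noise_sd))
    counts[[paste0(st, "_pure")]] <-
      tibble(gene_id = up[[st]], library = st,
             count = pmax(1, round(base[up[[st]]] * noise(n_up))))
    counts[[paste0(st, "_co")]] <-
      tibble(gene_id = up_co[[st]], library = "coculture",
             count = pmax(1, round(base[up_co[[st]]] * fold[up_co[[st]]] *
                                     noise(n_up))))
  }
  counts <- dplyr::bind_rows(counts)

  ## -- gene-to-KEGG-map table ------------------------------------------------
  set.seed(section_seed(cfg$seed, 5))
  gene_pathways <- purrr::map_dfr(strains, function(st) {
    shared <- intersect(up[[st]], up_co[[st]])
    planted <- dplyr::bind_rows(
      tibble(gene_id = fold_genes[[st]]$up,
             pathway_id = sprintf("map_up_%s", st),
             pathway_name = sprintf("Planted co-culture up-shift (%s)", st)),
      tibble(gene_id = fold_genes[[st]]$down,
             pathway_id = sprintf("map_down_%s", st),
             pathway_name = sprintf("Planted co-culture down-shift (%s)", st)))
    decoys <- purrr::map_dfr(seq_len(cfg$n_kegg_maps), function(i) {
      tibble(gene_id = sample(shared, 5),
             pathway_id = sprintf("map_d%02d_%s", i, st),
             pathway_name = sprintf("Background map %02d (%s)", i, st))
    })
    dplyr::bind_rows(planted, decoys)
  })

  ## -- GO-style annotations ---------------------------------------------------
  set.seed(section_seed(cfg$seed, 6))
  terms <- sprintf("GO:%07d", seq_len(cfg$n_terms))
  term_ontology <- stats::setNames(rep(c("BP", "MF"), length.out = cfg$n_terms),
                                   terms)
  # each (gene, term) pair annotated independently; ~1.5 terms per gene
  memb <- which(stats::runif(nrow(genes) * cfg$n_terms) < 1.5 / cfg$n_terms)
  full_go <- tibble(gene_id = genes$gene_id[(memb - 1) %% nrow(genes) + 1],
                    term = terms[(memb - 1) %/% nrow(genes) + 1])
  full_go <- dplyr::arrange(full_go, .data$gene_id, .data$term)
  keep_b <- sample.int(nrow(full_go), round(0.7 * nrow(full_go)))
  go_annotations <- dplyr::bind_rows(
    dplyr::mutate(full_go, source = "blast2go"),
    dplyr::mutate(full_go[sort(keep_b), , drop = FALSE], source = "interproscan"))
  go_annotations <- go_annotations[c("gene_id", "source", "term")]
  go_annotations$ontology <- term_ontology[go_annotations$term]

  ## -- per-culture enzymes (disjoint EC sets on culture-exclusive genes) -----
  set.seed(section_seed(cfg$seed, 7))
  n_ec_total <- cfg$n_ecs_per_culture * length(cultures)
  ec_pool <- unique(sprintf("%d.%d.%d.%d",
                            sample(1:6, 4 * n_ec_total, replace = TRUE),
                            sample(1:20, 4 * n_ec_total, replace = TRUE),
                            sample(1:25, 4 * n_ec_total, replace = TRUE),
                            sample(1:99, 4 * n_ec_total, replace = TRUE)))
  if (length(ec_pool) < n_ec_total) abort("failed to draw enough unique ECs")
  ec_pool <- ec_pool[seq_len(n_ec_total)]
  ec_by_culture <- split(ec_pool,
                         rep(cultures, each = cfg$n_ecs_per_culture))
  exclusive_genes <- list(
    P_putida = setdiff(up$P_putida, up_co$P_putida),
    P_protegens = setdiff(up$P_protegens, up_co$P_protegens),
    coculture = c(setdiff(up_co$P_putida, up$P_putida),
                  setdiff(up_co$P_protegens, up$P_protegens)))
  gene_ec <- purrr::map_dfr(cultures, function(cu) {
    host <- sample(rep_len(sample(exclusive_genes[[cu]]),
                           cfg$n_ecs_per_culture))
    tibble(culture = cu, gene_id = host, ec = ec_by_culture[[cu]])
  })
  keep_u <- sample.int(nrow(gene_ec), round(0.85 * nrow(gene_ec)))
  ec_blast2go <- gene_ec[c("gene_id", "ec")]
  ec_uniprot <- gene_ec[sort(keep_u), c("gene_id", "ec")]

  ## -- reactions and compounds -----------------------------------------------
  set.seed(section_seed(cfg$seed, 8))
  probs <- list(P_putida = cfg$class_probs_pure,
                P_protegens = cfg$class_probs_pure,
                coculture = if (null) cfg$class_probs_pure else cfg$class_probs_coculture)
  has_el <- list(n = c("N", "NS", "NO", "NOS"),
                 o = c("NO", "O", "NOS", "SO"),
                 s = c("NS", "NOS", "S", "SO"))
  cid_counter <- 0L
  substrate_rows <- list()
  for (cu in cultures) {
    p <- probs[[cu]][NAFC_CLASSES]
    ecs <- ec_by_culture[[cu]]
    k <- sample(cfg$substrates_per_ec, length(ecs), replace = TRUE)
    total <- sum(k)
    cls <- sample(NAFC_CLASSES, total, replace = TRUE, prob = p)
    nn <- ifelse(cls %in% has_el$n, sample(1:3, total, replace = TRUE), 0L)
    oo <- ifelse(cls %in% has_el$o, sample(1:6, total, replace = TRUE), 0L)
    ss <- ifelse(cls %in% has_el$s, sample(1:3, total, replace = TRUE), 0L)
    cs <- sample(5:25, total, replace = TRUE)
    ds <- 1L + floor(stats::runif(total) * pmin(10L, cs))
    mf <- canonical_formula(tibble(c = cs, h = 2L * cs + nn + 2L - 2L * ds,
                                   n = nn, o = oo, s = ss))
    cids <- sprintf("CID%06d", cid_counter + seq_len(total))
    cid_counter <- cid_counter + total
    substrate_rows[[length(substrate_rows) + 1L]] <-
      tibble(culture = cu, ec = rep(ecs, k), cid = cids, class = cls, mf = mf)
  }
  ec_substrates <- dplyr::bind_rows(substrate_rows)
  reactions <- ec_substrates |>
    dplyr::distinct(.data$ec, .data$cid) |>
    dplyr::mutate(rxn_id = sprintf("RXN-%04d",
                                   as.integer(factor(.data$ec, levels = unique(.data$ec)))))
  reactions <- reactions[c("rxn_id", "ec", "cid")]
  extra <- purrr::map_dfr(NAFC_CLASSES, function(cl) {
    k <- cfg$n_extra_compounds_per_class
    nn <- if (cl %in% has_el$n) sample(1:3, k, replace = TRUE) else rep(0L, k)
    oo <- if (cl %in% has_el$o) sample(1:6, k, replace = TRUE) else rep(0L, k)
    ss <- if (cl %in% has_el$s) sample(1:3, k, replace = TRUE) else rep(0L, k)
    cs <- sample(5:25, k, replace = TRUE)
    ds <- vapply(cs, function(cc) sample(seq_len(min(10L, cc)), 1L), integer(1))
    tibble(cid = sprintf("CIDX%05d", seq_len(k) + 1e4 * match(cl, NAFC_CLASSES)),
           mf = canonical_formula(tibble(c = cs, h = 2L * cs + nn + 2L - 2L * ds,
                                         n = nn, o = oo, s = ss)))
  })
  compounds <- dplyr::bind_rows(
    tibble(cid = ec_substrates$cid, mf = ec_substrates$mf),
    extra)
  compounds <- dplyr::distinct(compounds)
  compounds$cmpdname <- paste0("compound ", sub("^CIDX?0*", "", compounds$cid),
                               " (synthetic)")
  compounds <- compounds[c("cid", "cmpdname", "mf")]

  ## -- pathway database -------------------------------------------------------
  set.seed(section_seed(cfg$seed, 9))
  pools <- split(ec_substrates, ec_substrates$culture)
  eligible <- lapply(pools, function(p) {
    miss <- sample.int(nrow(p), round(cfg$pathway_miss_fraction * nrow(p)))
    list(eligible = p[-miss, , drop = FALSE], missed = p[miss, , drop = FALSE])
  })
  memberships <- c(list(`PWY-0001` = "coculture",
                        `PWY-0002` = c("P_putida", "P_protegens")),
                   lapply(seq_len(cfg$n_pathways - 2), function(i) {
                     sample(cultures, sample(1:3, 1))
                   }))
  names(memberships)[-(1:2)] <- sprintf("PWY-%04d", 2 + seq_len(cfg$n_pathways - 2))
  pathway_names <- c(`PWY-0001` = "aromatic acid degradation (co-culture specific, synthetic)",
                     `PWY-0002` = "methyl-aromatic degradation (pure-culture specific, synthetic)")
  support <- list()
  steps <- list()
  for (pid in names(memberships)) {
    nm <- if (pid %in% names(pathway_names)) pathway_names[[pid]] else
      paste0("synthetic pathway ", sub("PWY-", "", pid))
    for (cu in memberships[[pid]]) {
      pool <- eligible[[cu]]$eligible
      if (pid == "PWY-0001") pool <- pool[pool$class == "O", , drop = FALSE]
      take <- pool[sample.int(nrow(pool), min(sample(2:3, 1), nrow(pool))), ,
                   drop = FALSE]
      steps[[length(steps) + 1L]] <-
        tibble(pathway_id = pid, name = nm, cid = take$cid, ec = take$ec)
      support[[length(support) + 1L]] <-
        tibble(pathway_id = pid, culture = cu,
               group = unique(nafc_group(take$class)))
    }
  }
  pathway_db <- dplyr::distinct(dplyr::bind_rows(steps))
  pathway_support <- dplyr::distinct(dplyr::bind_rows(support))
  # pairs with no pathway: the reserved set plus eligible pairs never sampled
  without_pairs <- dplyr::anti_join(ec_substrates[c("culture", "cid", "ec")],
                                    pathway_db[c("cid", "ec")],
                                    by = c("cid", "ec"))

  ## -- MS feature tables -------------------------------------------------------
  set.seed(section_seed(cfg$seed, 10))
  classic <- classic_na_formulas(cfg$n_classic_na)
  conc <- stats::rlnorm(nrow(classic), log(1), 0.8)
  classic$concentration <- conc * cfg$classic_total / sum(conc)
  others <- purrr::map_dfr(BASELINE_SPECIES, function(sp) {
    t <- parse_species(sp)
    k <- sample(4:8, 1)
    mf <- unique(random_formulas(k, t["n"], t["o"], t["s"]))
    tibble(species = sp, mf = mf,
           concentration = stats::rlnorm(length(mf), log(1), 0.5))
  })
  if (!all(cfg$removed_species %in% others$species)) {
    abort("removed_species must be present in the untreated water table")
  }
  if (any(cfg$produced_species %in% c(others$species, "O2"))) {
    abort("produced_species must be absent from the untreated water table")
  }
  ms_before <- dplyr::bind_rows(
    tibble(mf = classic$mf, concentration = classic$concentration),
    tibble(mf = others$mf, concentration = others$concentration))
  ms_before <- tibble(mf = ms_before$mf, sample_id = "OSPW",
                      concentration = ms_before$concentration)

  set.seed(section_seed(cfg$seed, 11))
  nz <- cfg$concentration_noise_sd
  ms_after <- lapply(cultures, function(cu) {
    r <- if (null) 0 else cfg$classic_removal[[cu]]
    keep_cl <- classic$concentration * exp(stats::rnorm(nrow(classic), 0, nz))
    if (!null) {
      keep_cl <- keep_cl * (1 - r) * sum(classic$concentration) / sum(keep_cl)
    }
    oth <- others
    if (!null) oth <- oth[!oth$species %in% cfg$removed_species, , drop = FALSE]
    keep_ot <- oth$concentration * exp(stats::rnorm(nrow(oth), 0, nz))
    prod <- NULL
    if (!null) {
      prod <- purrr::map_dfr(cfg$produced_species, function(sp) {
        t <- parse_species(sp)
        mf <- unique(random_formulas(sample(2:3, 1), t["n"], t["o"], t["s"]))
        tibble(mf = mf, concentration = stats::rlnorm(length(mf), log(0.3), 0.4))
      })
    }
    out <- dplyr::bind_rows(
      tibble(mf = classic$mf, concentration = keep_cl),
      tibble(mf = oth$mf, concentration = keep_ot),
      if (!is.null(prod)) tibble(mf = prod$mf, concentration = prod$concentration))
    tibble(mf = out$mf, sample_id = cu, concentration = out$concentration)
  })
  names(ms_after) <- cultures

  ## -- manifest -----------------------------------------------------------------
  cl_counts <- ec_substrates |>
    dplyr::distinct(.data$culture, .data$cid, .data$class) |>
    dplyr::count(.data$culture, .data$class) |>
    tidyr::pivot_wider(names_from = "class", values_from = "n",
                       values_fill = 0L)
  carbon_tab <- table(classic$c)
  dbe_tab <- table(classic$dbe)
  manifest <- list(
    seed = cfg$seed,
    null = null,
    cultures = cultures,
    strains = strains,
    upregulated = upregulated,
    fold_genes = if (null) NULL else fold_genes,
    top_pathways = if (null) NULL else
      lapply(stats::setNames(strains, strains), function(st)
        list(up = sprintf("map_up_%s", st), down = sprintf("map_down_%s", st))),
    ec_by_culture = lapply(ec_by_culture, sort),
    ec_substrates = ec_substrates,
    class_counts = cl_counts,
    class_probs = probs,
    pathway_support = pathway_support,
    without_pathway_pairs = without_pairs[c("culture", "cid", "ec")],
    classic_na_count = cfg$n_classic_na,
    classic_total = cfg$classic_total,
    classic_carbon_hist = tibble(carbon = as.integer(names(carbon_tab)),
                                 fraction = as.numeric(carbon_tab) / nrow(classic)),
    classic_dbe_hist = tibble(dbe = as.integer(names(dbe_tab)),
                              fraction = as.numeric(dbe_tab) / nrow(classic)),
    percent_removal_classic = if (null) {
      stats::setNames(rep(0, length(cultures)), cultures)
    } else {
      100 * cfg$classic_removal[cultures]
    },
    removed_species = if (null) character() else sort(cfg$removed_species),
    produced_species = if (null) character() else sort(cfg$produced_species))

  list(genes = genes, coverage = coverage, counts = counts,
       go_annotations = go_annotations,
       ec_blast2go = ec_blast2go, ec_uniprot = ec_uniprot,
       reactions = reactions, compounds = compounds,
       pathway_db = pathway_db, gene_pathways = gene_pathways,
       ms_before = ms_before, ms_after = ms_after,
       manifest = manifest)
}

#' @rdname generate_fixture
#' @export
null_fixture <- function(cfg = fixture_config()) {
  generate_fixture(cfg, null = TRUE)
}

#' Write a fixture bundle to flat files
#'
#' Materialises a [generate_fixture()] bundle in its documented on-disk
#' formats (TSV/CSV tables, JSON pathway database and manifest) so the
#' file-reading path of the pipeline can be exercised; [read_fixture()]
#' loads it back.
#'
#' @param fx A fixture bundle.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  readr::write_tsv(fx$genes, p("genes.tsv"))
  readr::write_tsv(fx$coverage, p("coverage.tsv"))
  readr::write_tsv(fx$counts, p("counts.tsv"))
  readr::write_tsv(fx$go_annotations, p("go_annotations.tsv"))
  readr::write_tsv(fx$ec_blast2go, p("ec_blast2go.tsv"))
  readr::write_tsv(fx$ec_uniprot, p("ec_uniprot.tsv"))
  readr::write_tsv(fx$reactions, p("reactions.tsv"))
  readr::write_csv(fx$compounds, p("compounds.csv"))
  write_pathway_db(fx$pathway_db, p("pathways.json"))
  readr::write_tsv(fx$gene_pathways, p("gene_pathways.tsv"))
  readr::write_csv(fx$ms_before, p("ms_before.csv"))
  for (cu in names(fx$ms_after)) {
    readr::write_csv(fx$ms_after[[cu]], p(paste0("ms_after_", cu, ".csv")))
  }
  jsonlite::write_json(fx$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_fixture
#' @export
read_fixture <- function(dir) {
  p <- function(f) file.path(dir, f)
  after_files <- list.files(dir, pattern = "^ms_after_.*\\.csv$")
  ms_after <- lapply(after_files, function(f) read_ms_table(p(f)))
  names(ms_after) <- sub("^ms_after_(.*)\\.csv$", "\\1", after_files)
  list(genes = read_gene_catalog(p("genes.tsv")),
       coverage = read_coverage(p("coverage.tsv")),
       counts = read_counts(p("counts.tsv")),
       go_annotations = read_annotations(p("go_annotations.tsv")),
       ec_blast2go = read_ec_annotations(p("ec_blast2go.tsv")),
       ec_uniprot = read_ec_annotations(p("ec_uniprot.tsv")),
       reactions = read_reaction_db(p("reactions.tsv")),
       compounds = read_compound_db(p("compounds.csv")),
       pathway_db = read_pathway_db(p("pathways.json")),
       gene_pathways = read_gene_pathways(p("gene_pathways.tsv")),
       ms_before = read_ms_table(p("ms_before.csv")),
       ms_after = ms_after,
       manifest = jsonlite::read_json(p("manifest.json"), simplifyVector = TRUE))
}
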
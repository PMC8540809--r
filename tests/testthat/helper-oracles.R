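# Independent oracles and small builders shared across the suite.

# DBE via atom-by-atom valence count: expand the formula into its atom list
# and apply the rings-plus-pi-bonds count (sum of (valence - 2) over atoms,
# plus 2, halved). Computed on a different path than the package's formula.
dbe_valence_oracle <- function(c, h, n, o, s) {
  val <- c(C = 4, H = 1, N = 3, O = 2, S = 2)
  atoms <- rep(names(val), times = c(c, h, n, o, s))
  (sum(val[atoms] - 2) + 2) / 2
}

# Covered bases by per-base marking over an explicit logical vector.
perbase_coverage_oracle <- function(reads, gene_start, gene_end) {
  if (gene_end <= gene_start) return(0L)
  hit <- logical(gene_end - gene_start)
  for (i in seq_len(nrow(reads))) {
    a <- max(reads$start[i], gene_start)
    b <- min(reads$end[i], gene_end)
    if (b > a) hit[(a - gene_start + 1):(b - gene_start)] <- TRUE
  }
  sum(hit)
}

# Upper-tail hypergeometric by exhaustive enumeration of all n-subsets of a
# universe of N genes of which genes 1..K carry the term.
hyper_enum_oracle <- function(N, K, n, k) {
  if (n == 0) return(as.numeric(k <= 0))
  subsets <- utils::combn(N, n)
  hits <- colSums(subsets <= K)
  mean(hits >= k)
}

# Textbook Pearson chi-square statistic on a contingency table.
pearson_oracle <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  list(statistic = sum((m - e)^2 / e),
       df = (nrow(m) - 1) * (ncol(m) - 1))
}

# Minimal MS feature table builder.
ms_tbl <- function(mf, concentration, sample_id = "S1") {
  tibble::tibble(mf = mf, sample_id = sample_id, concentration = concentration)
}

# A random Hill-permuted spelling of a formula from element counts.
shuffle_formula <- function(c, h, n = 0, o = 0, s = 0) {
  part <- function(sym, k) if (k == 0) NULL else if (k == 1) sym else paste0(sym, k)
  toks <- unlist(list(part("C", c), part("H", h), part("N", n),
                      part("O", o), part("S", s)))
  paste(sample(toks), collapse = "")
}
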
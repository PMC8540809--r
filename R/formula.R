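#' @importFrom rlang .data abort warn := %||%
#' @importFrom tibble tibble as_tibble
NULL

# The eight heteroatom classes, in conventional display order.
NAFC_CLASSES <- c("CH", "N", "NS", "NO", "O", "NOS", "S", "SO")

#' Construct an element-count table
#'
#' NAFCs follow the general formula \eqn{C_cH_hN_nO_oS_s}; this helper builds
#' the tidy count table used throughout the package from bare integer vectors.
#'
#' @param c,h,n,o,s Non-negative integer vectors (recycled to a common length)
#'   giving the number of carbon, hydrogen, nitrogen, oxygen and sulfur atoms.
#' @return A tibble with integer columns `c`, `h`, `n`, `o`, `s`.
#' @examples
#' element_counts(c = 16, h = 28, o = 2)
#' @export
element_counts <- function(c = 0L, h = 0L, n = 0L, o = 0L, s = 0L) {
  out <- tibble(c = as.integer(c), h = as.integer(h), n = as.integer(n),
                o = as.integer(o), s = as.integer(s))
  bad <- vapply(out, function(x) any(is.na(x) | x < 0), logical(1))
  if (any(bad)) {
    abort(paste0("element counts must be non-negative integers; bad column(s): ",
                 paste(names(out)[bad], collapse = ", ")))
  }
  out
}

#' Parse molecular formula strings
#'
#' Accepts Hill-style neutral formulas over the elements C, H, N, O and S
#' (the NAFC alphabet). Parsing is independent of the order in which element
#' tokens appear; repeated tokens are summed. Charges, isotopes and adducts
#' are not supported and any other element symbol is an error rather than
#' being silently dropped, so downstream class assignment stays sound.
#'
#' @param x Character vector of formula strings, e.g. `"C16H28O2"`.
#' @param strict If `TRUE` (default) formulas with zero carbon or zero
#'   hydrogen are rejected as non-NAFC candidates.
#' @return A tibble with columns `mf` (the input string) and integer element
#'   counts `c`, `h`, `n`, `o`, `s`, one row per input formula.
#' @examples
#' parse_formula(c("C16H28O2", "C10H15N2O2S"))
#' @export
parse_formula <- function(x, strict = TRUE) {
  if (!is.character(x)) abort("`x` must be a character vector of formulas")
  if (length(x) == 0) {
    return(tibble(mf = character(), c = integer(), h = integer(),
                  n = integer(), o = integer(), s = integer()))
  }
  tokens <- stringr::str_match_all(x, "([A-Z][a-z]?)([0-9]*)")
  counts <- matrix(0L, nrow = length(x), ncol = 5,
                   dimnames = list(NULL, c("C", "H", "N", "O", "S")))
  for (i in seq_along(x)) {
    m <- tokens[[i]]
    if (is.na(x[i]) || nchar(x[i]) == 0 || paste(m[, 1], collapse = "") != x[i]) {
      abort(paste0("cannot parse formula: '", x[i], "'"))
    }
    elem <- m[, 2]
    unknown <- setdiff(elem, colnames(counts))
    if (length(unknown) > 0) {
      abort(paste0("unknown element symbol(s) in '", x[i], "': ",
                   paste(unique(unknown), collapse = ", ")))
    }
    k <- ifelse(m[, 3] == "", 1L, suppressWarnings(as.integer(m[, 3])))
    for (j in seq_along(elem)) {
      counts[i, elem[j]] <- counts[i, elem[j]] + k[j]
    }
  }
  out <- tibble(mf = x,
                c = counts[, "C"], h = counts[, "H"], n = counts[, "N"],
                o = counts[, "O"], s = counts[, "S"])
  if (strict) {
    bad <- out$c < 1L | out$h < 1L
    if (any(bad)) {
      abort(paste0("non-NAFC formula (needs c >= 1 and h >= 1): ",
                   paste(unique(out$mf[bad]), collapse = ", ")))
    }
  }
  out
}

#' Double-bond equivalents
#'
#' The degree of unsaturation (rings plus pi-bonds) of a CcHhNnOoSs formula,
#' computed as \eqn{c + (n - h)/2 + 1}. Divalent oxygen and sulfur contribute
#' nothing. The value may be half-integral when `n + h` is odd (radicals or
#' ions); it is returned as-is, not rounded, so callers can flag such
#' formulas.
#'
#' @param counts A data frame with columns `c`, `h`, `n` (as from
#'   [parse_formula()] or [element_counts()]).
#' @return Numeric vector of DBE values.
#' @examples
#' dbe(element_counts(c = 7, h = 12, o = 2))  # 2
#' @export
dbe <- function(counts) {
  check_counts(counts, c("c", "h", "n"))
  counts$c + (counts$n - counts$h) / 2 + 1
}

#' Heteroatom class of an NAFC formula
#'
#' Assigns each formula to exactly one of the eight heteroatom classes
#' CH, N, NS, NO, O, NOS, S, SO — the \eqn{2^3} presence/absence patterns of
#' N, O and S. The assignment depends only on which of `n`, `o`, `s` are
#' positive; `CH` is the class with no heteroatoms at all.
#'
#' @param counts A data frame with columns `n`, `o`, `s`.
#' @return A factor with levels `CH, N, NS, NO, O, NOS, S, SO`.
#' @examples
#' classify_nafc(element_counts(c = 14, h = 22, n = 2, o = 2))  # NO
#' @export
classify_nafc <- function(counts) {
  check_counts(counts, c("n", "o", "s"))
  hn <- counts$n > 0
  ho <- counts$o > 0
  hs <- counts$s > 0
  lab <- character(nrow(counts))
  lab[!hn & !ho & !hs] <- "CH"
  lab[hn & !ho & !hs] <- "N"
  lab[hn & !ho & hs] <- "NS"
  lab[hn & ho & !hs] <- "NO"
  lab[!hn & ho & !hs] <- "O"
  lab[hn & ho & hs] <- "NOS"
  lab[!hn & !ho & hs] <- "S"
  lab[!hn & ho & hs] <- "SO"
  factor(lab, levels = NAFC_CLASSES)
}

#' Fine species label of an NAFC formula
#'
#' Builds the conventional heteroatom species label, e.g. `"O2"`, `"N2O2"`,
#' `"S2O3"`: elements in N, O, S order, elements with zero count omitted,
#' subscript 1 omitted (`"NO"`, never `"N1O1"`). Pure hydrocarbons are
#' labelled `"CH"`.
#'
#' One display-order quirk is inherited from petroleomics usage: species of
#' the SO class are spelt sulfur-first (`"SO2"`, `"S2O3"`), mirroring the
#' class name, while all other classes use N, O, S order (`"N2O2"`,
#' `"N2OS2"`).
#'
#' @param counts A data frame with columns `n`, `o`, `s`.
#' @return Character vector of species labels.
#' @examples
#' species_label(element_counts(c = 10, h = 16, n = 2, o = 2))  # "N2O2"
#' species_label(element_counts(c = 10, h = 16, o = 2, s = 1))  # "SO2"
#' @export
species_label <- function(counts) {
  check_counts(counts, c("n", "o", "s"))
  part <- function(sym, k) ifelse(k == 0, "", ifelse(k == 1, sym, paste0(sym, k)))
  cls <- as.character(classify_nafc(counts))
  lab <- ifelse(cls == "SO",
                paste0(part("S", counts$s), part("O", counts$o)),
                paste0(part("N", counts$n), part("O", counts$o), part("S", counts$s)))
  ifelse(cls == "CH", "CH", lab)
}

#' Classic naphthenic acids
#'
#' Classic NAs have the empirical formula \eqn{C_cH_hO_2}: exactly two
#' oxygens and no nitrogen or sulfur. They are the most toxic NAFC sub-group
#' and are reported separately throughout the workflow.
#'
#' @param counts A data frame with columns `n`, `o`, `s`.
#' @return Logical vector.
#' @examples
#' is_classic_na(element_counts(c = 16, h = 28, o = 2))  # TRUE
#' @export
is_classic_na <- function(counts) {
  check_counts(counts, c("n", "o", "s"))
  counts$o == 2L & counts$n == 0L & counts$s == 0L
}

#' Flag formulas outside the typical NAFC carbon range
#'
#' NAFC carbon content typically ranges between 7 and 26 atoms, but classic
#' NAs down to C5 are observed in process water; compounds outside the range
#' are therefore flagged rather than dropped.
#'
#' @param counts A data frame with column `c`.
#' @param min,max Inclusive carbon bounds (defaults 7 and 26).
#' @return Logical vector, `TRUE` when within range.
#' @export
in_carbon_range <- function(counts, min = 7L, max = 26L) {
  check_counts(counts, "c")
  counts$c >= min & counts$c <= max
}

#' Canonical Hill-style formula string
#'
#' Rebuilds the canonical `C..H..N..O..S..` string from element counts
#' (zero-count elements omitted, subscript 1 omitted). Used as the join key
#' when aligning feature tables that may spell formulas in different token
#' orders.
#'
#' @param counts A data frame with columns `c`, `h`, `n`, `o`, `s`.
#' @return Character vector of canonical formula strings.
#' @export
canonical_formula <- function(counts) {
  check_counts(counts, c("c", "h", "n", "o", "s"))
  part <- function(sym, k) ifelse(k == 0, "", ifelse(k == 1, sym, paste0(sym, k)))
  paste0(part("C", counts$c), part("H", counts$h), part("N", counts$n),
         part("O", counts$o), part("S", counts$s))
}

#' Annotate a table of molecular formulas
#'
#' Convenience wrapper: parses the formula column of a tibble and appends
#' element counts, DBE, heteroatom class, species label, classic-NA flag and
#' the canonical formula key.
#'
#' @param tbl A data frame with a molecular-formula column.
#' @param mf_col Name of the formula column (default `"mf"`).
#' @param strict Passed to [parse_formula()].
#' @return `tbl` with columns `c`, `h`, `n`, `o`, `s`, `dbe`, `class`,
#'   `species`, `classic_na`, `formula` appended.
#' @export
annotate_formulas <- function(tbl, mf_col = "mf", strict = TRUE) {
  if (!mf_col %in% names(tbl)) {
    abort(paste0("column '", mf_col, "' not found"))
  }
  parsed <- parse_formula(tbl[[mf_col]], strict = strict)
  out <- dplyr::bind_cols(as_tibble(tbl), parsed[c("c", "h", "n", "o", "s")])
  out$dbe <- dbe(parsed)
  out$class <- classify_nafc(parsed)
  out$species <- species_label(parsed)
  out$classic_na <- is_classic_na(parsed)
  out$formula <- canonical_formula(parsed)
  out
}

check_counts <- function(counts, cols) {
  if (!is.data.frame(counts)) abort("`counts` must be a data frame of element counts")
  miss <- setdiff(cols, names(counts))
  if (length(miss) > 0) {
    abort(paste0("`counts` is missing column(s): ", paste(miss, collapse = ", ")))
  }
  invisible(counts)
}
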
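#' Weight-percentage parsing
#'
#' Concentration expressions on SDSs come in a small dialect: dash or "to"
#' ranges ("10-20", "10 to 20"), one-sided comparators ("<10", ">= 0.5",
#' "10 max"), exact values ("60"), and empty / non-numeric cells.  A parsed
#' weight is a (lower, upper, operator) triple where the operator is one of
#' `-` (range), `>` (lower bound only), `<` (upper bound only), `=` (exact),
#' or `NA` (no weight).  For "10-20" the lower is 10 and the upper is 20.
#'
#' @name weight
NULL

WEIGHT_NUM <- "[0-9]+(?:\\.[0-9]+)?"
WEIGHT_CMP <- "(?:>=|<=|>|<)"

weight_nan <- function(raw = "") {
  structure(list(lower = NaN, upper = NaN, operator = NA_character_,
                 raw = raw),
            class = "weight_spec")
}

#' Construct a weight spec directly
#' @param lower,upper range bounds (NaN when absent)
#' @param operator one of "-", ">", "<", "=", or NA
#' @param raw the source string
#' @export
weight_spec <- function(lower, upper, operator, raw) {
  structure(list(lower = lower, upper = upper, operator = operator,
                 raw = raw),
            class = "weight_spec")
}

# Normalise an expression: unicode dashes and comparators folded to ASCII,
# decoration words ("%", "wt", "w/w", "by weight") stripped, decimal comma
# converted, lower-cased and squeezed.
normalize_weight_text <- function(s) {
  s <- gsub("[–—−]", "-", s)
  s <- gsub("≤", "<=", s, fixed = TRUE)
  s <- gsub("≥", ">=", s, fixed = TRUE)
  s <- tolower(s)
  s <- gsub("%+", " ", s)
  s <- gsub("\\b(w/w|wt\\.?|weight|by weight|percent|approx\\.?|ca\\.?)\\b",
            " ", s)
  s <- gsub("(?<=[0-9]),(?=[0-9])", ".", s, perl = TRUE)
  s <- gsub("[[:space:]]+", " ", s)
  trimws(s)
}

#' Parse a concentration cell into a weight spec
#'
#' Total over strings: every input yields a valid spec, with unparseable or
#' empty cells mapping to the all-`NaN` spec.  Cells containing a CAS number
#' pattern are never read as weights (a CAS "7732-18-5" is not a range).
#' Ranges with comparators on both ends (">=1 - <5") take the two numbers as
#' lower and upper with operator "-"; "x max" reads as an upper bound and
#' "x min" as a lower bound.
#'
#' @param cell character scalar
#' @return a `weight_spec`: list(lower, upper, operator, raw)
#' @export
parse_weight <- function(cell) {
  raw <- as.character(cell)
  if (length(raw) == 0 || is.na(raw)) raw <- ""
  if (grepl(CAS_REGEX, raw)) return(weight_nan(raw))
  s <- normalize_weight_text(raw)
  if (!nzchar(s)) return(weight_nan(raw))

  num <- WEIGHT_NUM
  cmp <- WEIGHT_CMP
  # dash or "to" range, comparators on either end tolerated
  range_re <- paste0("^", cmp, "? ?(", num, ") ?(?:-|to) ?",
                     cmp, "? ?(", num, ")$")
  m <- regmatches(s, regexec(range_re, s, perl = TRUE))[[1]]
  if (length(m)) {
    lo <- as.numeric(m[2]); hi <- as.numeric(m[3])
    if (lo > hi) { tmp <- lo; lo <- hi; hi <- tmp }
    return(weight_spec(lo, hi, "-", raw))
  }
  m <- regmatches(s, regexec(paste0("^(?:<=|<|up to) ?(", num, ")$"), s,
                             perl = TRUE))[[1]]
  if (length(m)) return(weight_spec(NaN, as.numeric(m[2]), "<", raw))
  m <- regmatches(s, regexec(paste0("^(", num, ") ?max\\.?$"), s,
                             perl = TRUE))[[1]]
  if (length(m)) return(weight_spec(NaN, as.numeric(m[2]), "<", raw))
  m <- regmatches(s, regexec(paste0("^(?:>=|>|above) ?(", num, ")$"), s,
                             perl = TRUE))[[1]]
  if (length(m)) return(weight_spec(as.numeric(m[2]), NaN, ">", raw))
  m <- regmatches(s, regexec(paste0("^(", num, ") ?min\\.?$"), s,
                             perl = TRUE))[[1]]
  if (length(m)) return(weight_spec(as.numeric(m[2]), NaN, ">", raw))
  m <- regmatches(s, regexec(paste0("^(", num, ")$"), s, perl = TRUE))[[1]]
  if (length(m)) {
    x <- as.numeric(m[2])
    return(weight_spec(x, x, "=", raw))
  }
  weight_nan(raw)
}

#' Search free text for the first weight-percentage expression
#'
#' Used when composition information is not tabular: inside prose a weight is
#' only accepted when tied to a percent sign, so that CAS digits and list
#' numbering are not misread.
#'
#' @param text character scalar
#' @return a `weight_spec` (all-NaN when nothing is found)
#' @export
find_weight <- function(text) {
  s <- gsub("[–—−]", "-", as.character(text))
  re <- paste0(WEIGHT_CMP, "? ?", WEIGHT_NUM,
               "(?: ?(?:-|to) ?", WEIGHT_CMP, "? ?", WEIGHT_NUM, ")? ?%")
  m <- regmatches(s, regexpr(re, s, perl = TRUE))
  if (length(m) == 0) return(weight_nan(""))
  parse_weight(m)
}

#' Does a cell look like a weight-percentage value?
#'
#' @param cell character scalar
#' @return logical
#' @export
is_weight_cell <- function(cell) {
  !is.na(parse_weight(cell)$operator)
}
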
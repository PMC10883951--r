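#' CAS registry number parsing and check-digit validation
#'
#' A CAS registry number has the form `NNNNNNN-NN-R`: a first segment of two
#' to seven digits, a second segment of two digits, and a single check digit
#' `R`.  The check digit is a positional mod-10 digit sum: numbering the
#' digits of the first two segments 1, 2, 3, ... from the digit immediately
#' to the left of the check digit and moving leftward, the check digit must
#' equal `sum(digit_i * i) %% 10`.
#'
#' @name cas
NULL

#' Regular expression matching a syntactically valid CAS number.
#' @export
CAS_REGEX <- "[0-9]{2,7}-[0-9]{2}-[0-9]"

# Default non-numerical stand-ins found in the CAS column of real SDSs.
CAS_SENTINELS <- c(
  "trade secret", "proprietary", "mixture", "confidential",
  "n/a", "na", "not available", "not applicable", "none"
)

#' Compute the CAS check digit for the digits before the hyphen-check part
#'
#' @param digits character string of digits: the first two segments
#'   concatenated (hyphens removed), excluding the check digit.
#' @return integer in 0..9
#' @export
cas_check_digit <- function(digits) {
  d <- as.integer(strsplit(digits, "")[[1]])
  n <- length(d)
  # position 1 is the rightmost digit of the second segment
  sum(d * seq.int(n, 1L)) %% 10L
}

#' Validate the check digit of a CAS number string
#'
#' @param cas string of the form "7732-18-5"
#' @return logical; NA if the string is not syntactically a CAS number
#' @export
cas_is_valid <- function(cas) {
  if (!grepl(paste0("^", CAS_REGEX, "$"), cas)) return(NA)
  parts <- strsplit(cas, "-", fixed = TRUE)[[1]]
  body <- paste0(parts[1], parts[2])
  cas_check_digit(body) == as.integer(parts[3])
}

#' Parse a table cell into a CAS value
#'
#' The first syntactic CAS match in the cell wins.  Cells that instead carry
#' a recognised sentinel ("Trade Secret", "Mixture", ...) are classed as
#' sentinels; anything else is absent.  A failed checksum annotates the value
#' (`checksum_valid = FALSE`) but never rejects it.
#'
#' @param cell character scalar (may be empty)
#' @param sentinels extra sentinel vocabulary, case-insensitive, matched on
#'   the trimmed cell
#' @return list with fields `raw`, `kind` ("NUMERIC", "SENTINEL", "ABSENT"),
#'   and for numeric values `segment1`, `segment2`, `check_digit`,
#'   `checksum_valid`; for sentinels `sentinel_text`
#' @export
parse_cas <- function(cell, sentinels = CAS_SENTINELS) {
  cell <- as.character(cell)
  if (length(cell) == 0 || is.na(cell)) cell <- ""
  m <- regmatches(cell, regexpr(CAS_REGEX, cell))
  if (length(m) == 1) {
    parts <- strsplit(m, "-", fixed = TRUE)[[1]]
    return(structure(list(
      raw = m, kind = "NUMERIC",
      segment1 = parts[1], segment2 = parts[2], check_digit = parts[3],
      checksum_valid = cas_check_digit(paste0(parts[1], parts[2])) ==
        as.integer(parts[3])
    ), class = "cas_value"))
  }
  trimmed <- tolower(trimws(cell))
  trimmed_norm <- gsub("[[:space:]]+", " ", trimmed)
  if (nzchar(trimmed_norm) && trimmed_norm %in% tolower(sentinels)) {
    return(structure(list(raw = cell, kind = "SENTINEL",
                          sentinel_text = trimmed_norm),
                     class = "cas_value"))
  }
  structure(list(raw = cell, kind = "ABSENT"), class = "cas_value")
}

#' Canonical string form of a CAS value ("" when absent)
#' @param cas a `cas_value`
#' @export
format_cas <- function(cas) {
  switch(cas$kind,
    NUMERIC = cas$raw,
    SENTINEL = cas$sentinel_text,
    ABSENT = ""
  )
}
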
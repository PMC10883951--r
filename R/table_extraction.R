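#' Text-based table structure extraction
#'
#' Converts a detected region into a rectangular grid of cell strings.
#' Words inside the region are grouped into rows by vertical proximity and
#' into columns by global x-gap clustering: horizontal intervals of the
#' region that no word crosses and that are wider than the column-gap
#' threshold become column gutters, identical for every row of the region.
#' Cell text is the space-joined word sequence in reading order; empty cells
#' hold the empty string internally (serialised as "NA" downstream).
#'
#' @name table_extraction
NULL

#' Extract the cell grid inside a region
#'
#' @param page raw page with char geometry
#' @param region region box on that page
#' @param col_gap_pt minimum gutter width in points; the effective threshold
#'   is `max(2 * median intra-word gap, col_gap_pt)`
#' @return a `table_grid`: list with `cells` (character matrix),
#'   `page_number`, `region`
#' @export
extract_grid <- function(page, region, col_gap_pt = 12) {
  words <- page_words(page$chars)
  cx <- (words$x0 + words$x1) / 2
  cy <- (words$y0 + words$y1) / 2
  inside <- cx >= region$x0 & cx < region$x1 &
    cy >= region$y0 & cy < region$y1
  words <- words[inside, , drop = FALSE]
  if (nrow(words) == 0) {
    stop("region on page ", region$page_number, " contains no text")
  }
  words <- words[order(words$y0, words$x0), , drop = FALSE]
  row_id <- cumsum(c(TRUE, diff(words$y0) > 2))

  # effective gutter threshold from the intra-line word gaps
  gaps <- numeric(0)
  for (r in unique(row_id)) {
    w <- words[row_id == r, , drop = FALSE]
    if (nrow(w) > 1) gaps <- c(gaps, w$x0[-1] - w$x1[-nrow(w)])
  }
  small <- gaps[gaps < col_gap_pt]
  thr <- max(if (length(small)) 2 * stats::median(small) else 0, col_gap_pt)

  # global gutters: maximal x intervals not covered by any word
  xs <- sort(unique(c(words$x0, words$x1)))
  events <- rbind(data.frame(x = words$x0, d = 1),
                  data.frame(x = words$x1, d = -1))
  events <- events[order(events$x, -events$d), , drop = FALSE]
  depth <- cumsum(events$d)
  cuts <- numeric(0)
  for (k in seq_len(nrow(events) - 1)) {
    if (depth[k] == 0) {
      gap <- events$x[k + 1] - events$x[k]
      if (gap >= thr) cuts <- c(cuts, (events$x[k] + events$x[k + 1]) / 2)
    }
  }
  col_of <- function(x) findInterval(x, cuts) + 1L
  n_cols <- length(cuts) + 1L
  rows <- sort(unique(row_id))
  cells <- matrix("", nrow = length(rows), ncol = n_cols)
  for (ri in seq_along(rows)) {
    w <- words[row_id == rows[ri], , drop = FALSE]
    w <- w[order(w$x0), , drop = FALSE]
    for (ci in seq_len(n_cols)) {
      in_col <- w[col_of(w$x0) == ci, , drop = FALSE]
      if (nrow(in_col)) cells[ri, ci] <- paste(in_col$text, collapse = " ")
    }
  }
  structure(list(cells = cells, page_number = region$page_number,
                 region = region),
            class = "table_grid")
}

# is this row a header row: label vocabulary, no CAS, no weight
is_header_row <- function(row_cells, patterns = load_header_patterns()) {
  txt <- tolower(paste(row_cells, collapse = " "))
  if (grepl(CAS_REGEX, txt)) return(FALSE)
  if (any(vapply(row_cells, is_weight_cell, logical(1)))) return(FALSE)
  labels <- patterns$regex[patterns$kind == "LABEL"]
  any(vapply(labels, function(p) grepl(p, txt, perl = TRUE), logical(1)))
}

#' Merge rows wrongly split across text lines
#'
#' A multi-line ingredient name comes out of gridding as an extra row whose
#' CAS and weight cells are empty; such a row is folded (space-joined) into
#' the name cell of the nearest preceding row that has a CAS or weight
#' value.  Header rows are never merged, and grids without a distinct
#' CAS/weight column are left untouched.
#'
#' @param grid a `table_grid`
#' @return a `table_grid` with continuation rows folded in; idempotent
#' @export
merge_split_rows <- function(grid) {
  cells <- grid$cells
  if (nrow(cells) < 2 || ncol(cells) < 2) return(grid)
  cols <- identify_columns(cells)
  anchor_cols <- c(cols$cas_column, cols$weight_column)
  if (!length(anchor_cols)) return(grid)
  name_col <- setdiff(seq_len(ncol(cells)), anchor_cols)[1]
  if (is.na(name_col)) return(grid)

  has_anchor <- apply(cells[, anchor_cols, drop = FALSE], 1, function(r)
    any(nzchar(trimws(r))))
  header <- logical(nrow(cells))
  if (!has_anchor[1]) header[1] <- is_header_row(cells[1, ])

  keep <- rep(TRUE, nrow(cells))
  for (r in seq_len(nrow(cells))) {
    if (r == 1 || header[r] || has_anchor[r]) next
    if (!nzchar(trimws(cells[r, name_col]))) next
    prev <- max(which(has_anchor[seq_len(r - 1)]), -Inf)
    if (!is.finite(prev)) next
    cells[prev, name_col] <- trimws(paste(cells[prev, name_col],
                                          cells[r, name_col]))
    keep[r] <- FALSE
  }
  grid$cells <- cells[keep, , drop = FALSE]
  grid
}
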
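#' Ingredient record assembly
#'
#' From a cell grid the pipeline identifies ingredient names (through a
#' pluggable token recognizer), locates the CAS and weight columns with
#' regular expressions, and uses the tabular structure to associate the
#' three entities into records.  The grid is serialised row-wise with
#' explicit column/row separator tokens ("[cs]", "[rs]") and "NA" for empty
#' cells, the same layout-preserving convention the recognizer interface is
#' specified against.
#'
#' @name ingredient_extraction
NULL

GRID_CS <- "[cs]"
GRID_RS <- "[rs]"
GRID_NA <- "NA"

#' Construct an ingredient record
#' @param name ingredient name (normalised to lowercase)
#' @param cas a `cas_value` (default absent)
#' @param weight a `weight_spec` (default all-NaN)
#' @param provenance free-form origin info (row/region/page)
#' @export
ingredient_record <- function(name, cas = parse_cas(""),
                              weight = parse_weight(""),
                              provenance = NULL) {
  stopifnot(nzchar(name))
  structure(list(name = tolower(trimws(gsub("[[:space:]]+", " ", name))),
                 cas = cas, weight = weight, provenance = provenance),
            class = "ingredient_record")
}

#' Construct a per-document indexing result
#' @param doc_id document identifier
#' @param status one of "INDEXED", "NO_DATA", "SINGLE_INGREDIENT_FALLBACK",
#'   "FAILED"
#' @param records list of ingredient records
#' @param failure_reason mandatory when status is "FAILED"
#' @export
indexing_result <- function(doc_id, status, records = list(),
                            failure_reason = NULL) {
  status <- match.arg(status, c("INDEXED", "NO_DATA",
                                "SINGLE_INGREDIENT_FALLBACK", "FAILED"))
  if (status == "NO_DATA") stopifnot(length(records) == 0)
  if (status == "SINGLE_INGREDIENT_FALLBACK") stopifnot(length(records) == 1)
  if (status == "FAILED") stopifnot(!is.null(failure_reason))
  structure(list(doc_id = doc_id, status = status, records = records,
                 failure_reason = failure_reason),
            class = "indexing_result")
}

#' @export
print.indexing_result <- function(x, ...) {
  cat(sprintf("<indexing_result %s: %s, %d record(s)>\n",
              x$doc_id, x$status, length(x$records)))
  for (r in x$records) {
    cat(sprintf("  %-35s %-12s %s\n", r$name, format_cas(r$cas),
                if (is.na(r$weight$operator)) "" else r$weight$raw))
  }
  invisible(x)
}

#' Serialise a grid row-wise with separator tokens
#'
#' @param grid a `table_grid` or a character matrix
#' @return list with `tokens` (character vector) and `row`, `col` (integer
#'   vectors giving each token's source cell; separators carry NA)
#' @export
serialize_grid <- function(grid) {
  cells <- if (inherits(grid, "table_grid")) grid$cells else grid
  tokens <- character(0); row <- integer(0); col <- integer(0)
  for (r in seq_len(nrow(cells))) {
    for (cc in seq_len(ncol(cells))) {
      cell <- trimws(cells[r, cc])
      toks <- if (nzchar(cell)) strsplit(cell, "[[:space:]]+")[[1]] else GRID_NA
      tokens <- c(tokens, toks)
      row <- c(row, rep(r, length(toks)))
      col <- c(col, rep(cc, length(toks)))
      if (cc < ncol(cells)) {
        tokens <- c(tokens, GRID_CS); row <- c(row, NA); col <- c(col, NA)
      }
    }
    if (r < nrow(cells)) {
      tokens <- c(tokens, GRID_RS); row <- c(row, NA); col <- c(col, NA)
    }
  }
  list(tokens = tokens, row = row, col = col)
}

#' Rebuild the cell matrix from a serialised token stream
#'
#' Inverse of [serialize_grid()] given the separator tokens alone.
#' @param tokens character vector with "[cs]"/"[rs]" separators
#' @return character matrix
#' @export
deserialize_grid <- function(tokens) {
  rows <- list(); cur_row <- list(); cur_cell <- character(0)
  flush_cell <- function() {
    cell <- paste(cur_cell, collapse = " ")
    if (identical(cell, GRID_NA)) cell <- ""
    cur_row[[length(cur_row) + 1L]] <<- cell
    cur_cell <<- character(0)
  }
  for (t in tokens) {
    if (t == GRID_CS) flush_cell()
    else if (t == GRID_RS) {
      flush_cell()
      rows[[length(rows) + 1L]] <- unlist(cur_row)
      cur_row <- list()
    } else cur_cell <- c(cur_cell, t)
  }
  flush_cell()
  rows[[length(rows) + 1L]] <- unlist(cur_row)
  do.call(rbind, rows)
}

#' Gazetteer-based name recognizer
#'
#' Deterministic longest-match recognizer over a chemical-name vocabulary:
#' token runs matching a gazetteer entry get NAME_BEGIN / NAME_INSIDE
#' labels, everything else (including the separator tokens) is OUTSIDE.
#' Any function with the same token->label signature can stand in, e.g. a
#' learned token classifier.
#'
#' @param names character vector of names (lowercase); default packaged
#'   gazetteer
#' @return function(tokens) -> character vector of labels
#' @export
gazetteer_recognizer <- function(names = default_gazetteer()) {
  entries <- strsplit(tolower(names), "[[:space:]]+")
  by_first <- split(entries, vapply(entries, `[`, "", 1))
  # longest entries first within each first-token bucket
  by_first <- lapply(by_first, function(e) e[order(-lengths(e))])
  function(tokens) {
    lt <- tolower(tokens)
    labels <- rep("OUTSIDE", length(tokens))
    i <- 1L
    while (i <= length(tokens)) {
      if (tokens[i] %in% c(GRID_CS, GRID_RS, GRID_NA)) { i <- i + 1L; next }
      cand <- by_first[[lt[i]]]
      matched <- 0L
      if (!is.null(cand)) {
        for (e in cand) {
          k <- length(e)
          if (i + k - 1L <= length(tokens) &&
              identical(lt[i:(i + k - 1L)], e)) { matched <- k; break }
        }
      }
      if (matched > 0L) {
        labels[i] <- "NAME_BEGIN"
        if (matched > 1L) labels[(i + 1L):(i + matched - 1L)] <- "NAME_INSIDE"
        i <- i + matched
      } else i <- i + 1L
    }
    labels
  }
}

#' Label every token of a serialised grid
#'
#' @param tokens character vector
#' @param recognizer recognizer function (see [gazetteer_recognizer()])
#' @return character vector of labels, separators forced to OUTSIDE
#' @export
recognize_names <- function(tokens, recognizer = gazetteer_recognizer()) {
  labels <- recognizer(tokens)
  stopifnot(length(labels) == length(tokens))
  labels[tokens %in% c(GRID_CS, GRID_RS, GRID_NA)] <- "OUTSIDE"
  labels
}

#' Assemble labelled token runs into located names
#'
#' Maximal NAME_BEGIN(+NAME_INSIDE...) runs become name strings (an orphan
#' NAME_INSIDE is promoted to NAME_BEGIN); each name is tied to the grid
#' cell its tokens came from.  Runs never cross cell separators because
#' separators are always OUTSIDE.
#'
#' @param serialized output of [serialize_grid()]
#' @param labels labels aligned to `serialized$tokens`
#' @return data.frame with columns name, row, col
#' @export
assemble_names <- function(serialized, labels) {
  tokens <- serialized$tokens
  out <- list()
  i <- 1L
  n <- length(tokens)
  while (i <= n) {
    if (labels[i] %in% c("NAME_BEGIN", "NAME_INSIDE")) {
      j <- i
      while (j < n && labels[j + 1L] == "NAME_INSIDE" &&
             !is.na(serialized$row[j + 1L]) &&
             serialized$row[j + 1L] == serialized$row[i] &&
             serialized$col[j + 1L] == serialized$col[i]) j <- j + 1L
      out[[length(out) + 1L]] <- data.frame(
        name = paste(tokens[i:j], collapse = " "),
        row = serialized$row[i], col = serialized$col[i],
        stringsAsFactors = FALSE)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(out)) {
    return(data.frame(name = character(0), row = integer(0),
                      col = integer(0)))
  }
  do.call(rbind, out)
}

cell_is_cas <- function(cell) {
  v <- parse_cas(cell)
  v$kind != "ABSENT"
}

#' Identify the CAS and weight columns of a grid
#'
#' The CAS column is the column with the most CAS-regex (or sentinel)
#' matches, provided there is at least one; the weight column likewise with
#' the weight grammar, excluding the CAS column.  Ties go to the leftmost
#' column with a warning.
#'
#' @param grid `table_grid` or character matrix
#' @return list(cas_column, weight_column); either may be NULL
#' @export
identify_columns <- function(grid) {
  cells <- if (inherits(grid, "table_grid")) grid$cells else grid
  stopifnot(length(cells) > 0)
  cas_counts <- apply(cells, 2, function(col)
    sum(vapply(col, cell_is_cas, logical(1))))
  cas_col <- NULL
  if (max(cas_counts) >= 1) {
    if (sum(cas_counts == max(cas_counts)) > 1)
      warning("CAS column tie; using the leftmost")
    cas_col <- which.max(cas_counts)
  }
  wt_counts <- apply(cells, 2, function(col)
    sum(vapply(col, is_weight_cell, logical(1))))
  if (!is.null(cas_col)) wt_counts[cas_col] <- -1L
  wt_col <- NULL
  if (max(wt_counts) >= 1) {
    if (sum(wt_counts == max(wt_counts)) > 1)
      warning("weight column tie; using the leftmost")
    wt_col <- which.max(wt_counts)
  }
  list(cas_column = cas_col, weight_column = wt_col)
}

#' Is a grid column-oriented (fields down the side, ingredients across)?
#'
#' Two cues: at least two numeric CAS matches inside a single row (the CAS
#' "column" actually runs horizontally), or at least two label-vocabulary
#' cells down the first column (a label column).
#'
#' @param cells character matrix
#' @param patterns header/label pattern table
#' @return logical
#' @export
grid_is_column_oriented <- function(cells,
                                    patterns = load_header_patterns()) {
  if (ncol(cells) < 2) return(FALSE)
  cas_hits <- matrix(grepl(CAS_REGEX, cells), nrow = nrow(cells))
  by_row <- if (nrow(cells)) apply(cas_hits, 1, sum) else 0
  by_col <- if (ncol(cells)) apply(cas_hits, 2, sum) else 0
  if (max(by_row) >= 2 && max(by_row) > max(by_col)) return(TRUE)
  labels <- patterns$regex[patterns$kind == "LABEL"]
  first_col <- tolower(cells[, 1])
  label_hits <- vapply(first_col, function(cell)
    any(vapply(labels, function(p) grepl(p, cell, perl = TRUE),
               logical(1))), logical(1))
  sum(label_hits) >= 2
}

#' Associate names, CAS numbers and weights through the grid structure
#'
#' For each located name at row r the CAS is parsed from the CAS column of
#' row r and the weight from the weight column of row r.  Single-column
#' grids (free-form section text) fall back to per-cell parsing: the CAS is
#' the first match in the cell and the weight is searched in the cell text
#' left over after removing the name and the CAS.
#'
#' @param grid `table_grid` or character matrix
#' @param names data.frame from [assemble_names()]
#' @param cols output of [identify_columns()]
#' @return list of ingredient records in grid row order
#' @export
associate <- function(grid, names, cols = identify_columns(grid)) {
  cells <- if (inherits(grid, "table_grid")) grid$cells else grid
  page <- if (inherits(grid, "table_grid")) grid$page_number else NA
  if (nrow(names) == 0) return(list())
  names <- names[order(names$row, names$col), , drop = FALSE]
  records <- list()
  for (k in seq_len(nrow(names))) {
    r <- names$row[k]
    if (ncol(cells) == 1) {
      cell <- cells[r, 1]
      cas <- parse_cas(cell)
      residual <- cell
      if (cas$kind == "NUMERIC") residual <- sub(cas$raw, "", residual,
                                                 fixed = TRUE)
      residual <- sub(names$name[k], "", residual, fixed = TRUE)
      wt <- find_weight(residual)
    } else {
      cas <- if (!is.null(cols$cas_column))
        parse_cas(cells[r, cols$cas_column]) else parse_cas("")
      wt <- if (!is.null(cols$weight_column))
        parse_weight(cells[r, cols$weight_column]) else parse_weight("")
    }
    records[[length(records) + 1L]] <- ingredient_record(
      names$name[k], cas, wt,
      provenance = list(row = r, page = page))
  }
  records
}

#' Extract all ingredient records from one grid
#'
#' Orientation detection, split-row repair, serialisation, recognition and
#' association in the documented order.
#'
#' @param grid a `table_grid`
#' @param recognizer name recognizer
#' @param patterns header/label pattern table
#' @return list of ingredient records
#' @export
records_from_grid <- function(grid, recognizer = gazetteer_recognizer(),
                              patterns = load_header_patterns()) {
  if (grid_is_column_oriented(grid$cells, patterns)) {
    grid$cells <- t(grid$cells)
  }
  grid <- merge_split_rows(grid)
  ser <- serialize_grid(grid)
  labels <- recognize_names(ser$tokens, recognizer)
  names <- assemble_names(ser, labels)
  associate(grid, names)
}

#' Build the single record for a single-ingredient product
#'
#' @param section1 raw Section 1 text
#' @param product_name optional externally known product name; when NULL it
#'   is read from the product-identifier label line, falling back to the
#'   first non-empty line with a warning
#' @return an ingredient record (name, first CAS in Section 1, no weight)
#' @export
single_ingredient_fallback <- function(section1, product_name = NULL) {
  txt <- tolower(section1)
  if (is.null(product_name)) {
    m <- regexec("product\\s*(name|identifier)\\s*[:\\-]\\s*([^\n]+)", txt,
                 perl = TRUE)
    hit <- regmatches(txt, m)[[1]]
    if (length(hit)) {
      product_name <- trimws(hit[3])
    } else {
      lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
      lines <- trimws(lines[nzchar(trimws(lines))])
      product_name <- if (length(lines)) lines[1] else ""
      warning("no product-name label found in Section 1; ",
              "falling back to the first line")
    }
  }
  if (!nzchar(product_name)) stop("empty product name in Section 1")
  ingredient_record(product_name, parse_cas(section1), parse_weight(""),
                    provenance = list(page = 1, source = "section1"))
}
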
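#' Table / section region detection
#'
#' On a selected page the pipeline needs the rectangle that actually holds
#' the composition data.  The default detector is a deterministic layout
#' heuristic over the text geometry: it looks for maximal runs of two or
#' more consecutive text lines that share at least two x-aligned column
#' groups and contain at least one CAS- or weight-like token.  Detected
#' regions are TABLE boxes; when no table is found on a selected page, the
#' section-coordinate fallback spans the area between the section begin and
#' end headers (SECTION box).  A pluggable detector with the same signature
#' can replace the heuristic.
#'
#' @name region_detection
NULL

#' Construct a region box
#' @param page_number page the box lives on
#' @param x0,y0,x1,y1 corners, points, top-left origin, y downward
#' @param kind "TABLE" or "SECTION"
#' @param score detector confidence in `[0, 1]`
#' @export
region_box <- function(page_number, x0, y0, x1, y1,
                       kind = c("TABLE", "SECTION"), score = 1) {
  kind <- match.arg(kind)
  stopifnot(x0 < x1, y0 < y1, score >= 0, score <= 1)
  structure(list(page_number = page_number, x0 = x0, y0 = y0,
                 x1 = x1, y1 = y1, kind = kind, score = score),
            class = "region_box")
}

#' Intersection over union of two region boxes
#'
#' @param a,b region boxes on the same page
#' @return overlap ratio in `[0, 1]`; 0 when disjoint
#' @export
region_iou <- function(a, b) {
  stopifnot((a$x1 - a$x0) > 0, (a$y1 - a$y0) > 0,
            (b$x1 - b$x0) > 0, (b$y1 - b$y0) > 0)
  ix <- max(0, min(a$x1, b$x1) - max(a$x0, b$x0))
  iy <- max(0, min(a$y1, b$y1) - max(a$y0, b$y0))
  inter <- ix * iy
  union <- (a$x1 - a$x0) * (a$y1 - a$y0) +
    (b$x1 - b$x0) * (b$y1 - b$y0) - inter
  inter / union
}

# group a page's chars into words (maximal non-space runs on one line)
page_words <- function(chars) {
  if (is.null(chars) || nrow(chars) == 0) {
    return(data.frame(text = character(0), x0 = numeric(0), x1 = numeric(0),
                      y0 = numeric(0), y1 = numeric(0), line = integer(0)))
  }
  chars <- chars[order(chars$y0, chars$x0), , drop = FALSE]
  line_id <- cumsum(c(TRUE, diff(chars$y0) > 2))
  words <- list()
  for (ln in unique(line_id)) {
    cc <- chars[line_id == ln, , drop = FALSE]
    cc <- cc[order(cc$x0), , drop = FALSE]
    is_space <- cc$char == " "
    # a new word starts after a space or an x jump (run boundary gap)
    brk <- c(TRUE, diff(cc$x0) > 1.5 * (cc$x1[1] - cc$x0[1]))
    wid <- cumsum(brk | c(FALSE, is_space[-nrow(cc)]))
    for (w in unique(wid[!is_space])) {
      ww <- cc[wid == w & !is_space, , drop = FALSE]
      if (!nrow(ww)) next
      words[[length(words) + 1L]] <- data.frame(
        text = paste(ww$char, collapse = ""),
        x0 = min(ww$x0), x1 = max(ww$x1),
        y0 = min(ww$y0), y1 = max(ww$y1), line = ln,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, words)
  rownames(out) <- NULL
  out
}

# split a line's words into column groups: a gap > gap_pt starts a new group
line_column_groups <- function(words_on_line, gap_pt) {
  w <- words_on_line[order(words_on_line$x0), , drop = FALSE]
  grp <- cumsum(c(TRUE, w$x0[-1] - w$x1[-nrow(w)] >= gap_pt))
  starts <- tapply(w$x0, grp, min)
  texts <- tapply(w$text, grp, paste, collapse = " ")
  data.frame(start = as.numeric(starts), text = as.character(texts),
             stringsAsFactors = FALSE)
}

#' Heuristic table detector
#'
#' @param page a raw page with char geometry
#' @param x_tol alignment tolerance between column-group starts, points
#' @param col_gap_pt minimum horizontal gap that separates column groups
#' @param line_gap_factor a vertical gap above `line_gap_factor` times the
#'   median line height breaks a run
#' @return list of TABLE region boxes, scores descending
#' @export
detect_tables <- function(page, x_tol = 6, col_gap_pt = 12,
                          line_gap_factor = 1.8) {
  words <- page_words(page$chars)
  if (nrow(words) == 0) return(list())
  lines <- split(words, words$line)
  lines <- lines[order(vapply(lines, function(w) min(w$y0), 0))]
  groups <- lapply(lines, line_column_groups, gap_pt = col_gap_pt)
  ys <- vapply(lines, function(w) min(w$y0), 0)
  heights <- vapply(lines, function(w) max(w$y1) - min(w$y0), 0)
  med_h <- stats::median(heights)

  strong <- vapply(groups, nrow, 0L) >= 2
  gap_ok <- function(i, j) {
    ys[j] - ys[i] <= (line_gap_factor + 1) * med_h * (j - i)
  }
  shared_starts <- function(starts, gj) {
    sum(vapply(starts, function(x) any(abs(gj$start - x) <= x_tol),
               logical(1)))
  }

  n <- length(lines)
  boxes <- list()
  i <- 1L
  while (i <= n) {
    if (!strong[i]) { i <- i + 1L; next }
    run <- i
    run_starts <- groups[[i]]$start
    n_strong <- 1L
    j <- i
    tail_buf <- integer(0); tail_next <- NA_integer_
    repeat {
      # skip interior single-group lines whose start aligns with a run
      # column (wrapped cell continuations), then require the next strong
      # line to share >= 2 column starts
      k <- j + 1L
      weak_buf <- integer(0)
      while (k <= n && !strong[k] && gap_ok(j, k) &&
             shared_starts(groups[[k]]$start, data.frame(
               start = run_starts)) >= 1) {
        weak_buf <- c(weak_buf, k)
        k <- k + 1L
      }
      if (k <= n && strong[k] && gap_ok(j, k) &&
          shared_starts(run_starts, groups[[k]]) >= 2) {
        run <- c(run, weak_buf, k)
        run_starts <- sort(unique(c(run_starts, groups[[k]]$start)))
        n_strong <- n_strong + 1L
        j <- k
      } else {
        tail_buf <- weak_buf; tail_next <- k
        break
      }
    }
    # a trailing wrapped-cell continuation is kept only when it fits
    # entirely inside one column band of the run (a cell fragment, not a
    # following paragraph or header, which would cross column boundaries)
    if (length(tail_buf) && n_strong >= 2) {
      within_band <- function(li) {
        w <- lines[[li]]
        x0 <- min(w$x0); x1 <- max(w$x1)
        col <- which(abs(run_starts - x0) <= x_tol)
        if (!length(col)) return(FALSE)
        nxt <- run_starts[run_starts > run_starts[col[1]] + x_tol]
        is.na(nxt[1]) || !length(nxt) || x1 < nxt[1] - x_tol
      }
      for (li in tail_buf) {
        if (gap_ok(j, li) && within_band(li)) {
          run <- c(run, li)
          j <- li
        } else break
      }
    }
    if (n_strong >= 2) {
      run_lines <- do.call(rbind, lines[run])
      run_text <- tolower(paste(run_lines$text, collapse = " "))
      cells <- unlist(lapply(groups[run], `[[`, "text"))
      has_data <- grepl(CAS_REGEX, run_text) ||
        any(vapply(cells, is_weight_cell, logical(1))) ||
        any(vapply(cells, cell_is_cas, logical(1)))
      if (has_data) {
        boxes[[length(boxes) + 1L]] <- region_box(
          page$page_number,
          min(run_lines$x0), min(run_lines$y0),
          max(run_lines$x1), max(run_lines$y1),
          kind = "TABLE", score = min(1, length(run) / 4))
      }
    }
    i <- j + 1L
  }
  boxes[order(-vapply(boxes, `[[`, 0, "score"))]
}

#' Section-coordinate fallback region
#'
#' Spans from the begin marker's character (or page top when the begin
#' header is on an earlier page) to the end marker's character (or page
#' bottom), full page width.
#'
#' @param page raw page with char geometry
#' @param begin_marker,end_marker single marker rows on this page, or NULL
#' @return a SECTION region box
#' @export
detect_section_region <- function(page, begin_marker = NULL,
                                  end_marker = NULL) {
  stopifnot(!is.null(begin_marker) || !is.null(end_marker))
  if (is.null(page$chars) || nrow(page$chars) == 0) {
    warning("page ", page$page_number,
            ": no character geometry; using the full page as the region")
    return(region_box(page$page_number, 0, 0, PDF_PAGE_W, PDF_PAGE_H,
                      kind = "SECTION", score = 0.5))
  }
  char_y <- function(offset) {
    hit <- page$chars[page$chars$idx >= offset, , drop = FALSE]
    if (!nrow(hit)) return(NULL)
    hit$y0[1]
  }
  y0 <- 0
  if (!is.null(begin_marker)) {
    y <- char_y(begin_marker$char_offset)
    if (!is.null(y)) y0 <- y
  }
  y1 <- PDF_PAGE_H
  if (!is.null(end_marker)) {
    y <- char_y(end_marker$char_offset)
    if (!is.null(y)) y1 <- y
  }
  if (y1 <= y0) y1 <- PDF_PAGE_H
  region_box(page$page_number, 0, y0, PDF_PAGE_W, y1,
             kind = "SECTION", score = 0.5)
}
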
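#' Composition-page selection
#'
#' SDS documents put their composition information in Section 3 (Section 2
#' in older formats).  The selector locates section begin/end headers with
#' regular expressions, checks the flanked text for ingredient evidence
#' (CAS numbers, column labels, recognised chemical names), and applies four
#' rules in order:
#'
#' 1. begin and end of the composition section on the same page, evidence in
#'    between: the page is selected;
#' 2. only the begin header on a page, evidence after it: selected (first
#'    page of a table split across pages);
#' 3. only the end header on a page, evidence before it: selected
#'    (continuation page of a split table);
#' 4. nothing selected but a CAS number present in Section 1: page 1 is the
#'    answer (single-ingredient product).
#'
#' @name page_selection
NULL

#' Load the packaged header/label pattern file
#'
#' Format: one pattern per line, `<id> TAB <kind> TAB <regex>`, `#` comments.
#' @param path pattern file; default is the packaged set
#' @return data.frame with columns id, kind, regex
#' @export
load_header_patterns <- function(path = system.file("extdata",
                                                    "header_patterns.tsv",
                                                    package = "sdsindex")) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) != 3
  if (any(bad)) stop("malformed pattern line(s): ", which(bad)[1])
  out <- data.frame(id = vapply(parts, `[`, "", 1),
                    kind = vapply(parts, `[`, "", 2),
                    regex = vapply(parts, `[`, "", 3),
                    stringsAsFactors = FALSE)
  stopifnot(all(out$kind %in% c("BEGIN", "END", "S1END", "LABEL")))
  out
}

#' Find section begin/end markers on every page
#'
#' All non-overlapping case-insensitive matches of the BEGIN/END patterns,
#' in document order.  When two patterns match overlapping spans the earlier
#' (or longer, at equal start) match wins.
#'
#' @param pages list of raw pages ([extract_pages()] output)
#' @param patterns pattern table from [load_header_patterns()]
#' @return data.frame with columns kind, page_number, char_offset (1-based),
#'   match_end, pattern_id
#' @export
find_markers <- function(pages, patterns = load_header_patterns()) {
  pat <- patterns[patterns$kind %in% c("BEGIN", "END"), , drop = FALSE]
  stopifnot(nrow(pat) > 0)
  res <- list()
  for (pg in pages) {
    text <- tolower(pg$raw_text)
    hits <- list()
    for (i in seq_len(nrow(pat))) {
      m <- gregexpr(pat$regex[i], text, perl = TRUE)[[1]]
      if (m[1] == -1) next
      hits[[length(hits) + 1L]] <- data.frame(
        kind = pat$kind[i], page_number = pg$page_number,
        char_offset = as.integer(m),
        match_end = as.integer(m) + attr(m, "match.length") - 1L,
        pattern_id = pat$id[i], stringsAsFactors = FALSE)
    }
    if (!length(hits)) next
    h <- do.call(rbind, hits)
    h <- h[order(h$char_offset, -h$match_end), , drop = FALSE]
    keep <- logical(nrow(h)); last_end <- 0L
    for (j in seq_len(nrow(h))) {
      if (h$char_offset[j] > last_end) {
        keep[j] <- TRUE
        last_end <- h$match_end[j]
      }
    }
    res[[length(res) + 1L]] <- h[keep, , drop = FALSE]
  }
  if (!length(res)) {
    return(data.frame(kind = character(0), page_number = integer(0),
                      char_offset = integer(0), match_end = integer(0),
                      pattern_id = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Scan a text span for ingredient evidence
#'
#' @param text character scalar (raw, any case)
#' @param recognizer a name recognizer (see [gazetteer_recognizer()]); NULL
#'   disables the name check
#' @param patterns pattern table (LABEL rows are used)
#' @return list with has_cas, has_label, has_name_token, any
#' @export
gather_evidence <- function(text, recognizer = gazetteer_recognizer(),
                            patterns = load_header_patterns()) {
  lt <- tolower(text)
  has_cas <- grepl(CAS_REGEX, lt)
  labels <- patterns$regex[patterns$kind == "LABEL"]
  has_label <- any(vapply(labels, function(p) grepl(p, lt, perl = TRUE),
                          logical(1)))
  has_name <- FALSE
  if (!is.null(recognizer)) {
    toks <- strsplit(trimws(gsub("[[:space:]]+", " ", lt)), " ")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks)) {
      lab <- recognizer(toks)
      has_name <- any(lab != "OUTSIDE")
    }
  }
  list(has_cas = has_cas, has_label = has_label, has_name_token = has_name,
       any = has_cas || has_label || has_name)
}

# first BEGIN marker on a page (duplicates ignored with a warning)
first_begin <- function(mk) {
  b <- mk[mk$kind == "BEGIN", , drop = FALSE]
  if (nrow(b) == 0) return(NULL)
  if (nrow(b) > 1) warning("multiple composition-section headers on page ",
                           b$page_number[1], "; using the first")
  b[1, ]
}

#' Apply the four page-selection rules
#'
#' @param pages list of raw pages
#' @param markers marker table from [find_markers()]
#' @param recognizer name recognizer used for the evidence scan
#' @param patterns pattern table
#' @return list with `pages` (sorted integer vector) and `mode`
#'   ("SECTION_PAGES", "SECTION1_FALLBACK" or "NONE")
#' @export
select_pages <- function(pages, markers, recognizer = gazetteer_recognizer(),
                         patterns = load_header_patterns()) {
  selected <- integer(0)
  page_text <- function(n) pages[[n]]$raw_text
  ev <- function(txt) gather_evidence(txt, recognizer, patterns)$any

  for (pg in pages) {
    n <- pg$page_number
    mk <- markers[markers$page_number == n, , drop = FALSE]
    if (nrow(mk) == 0) next
    beg <- first_begin(mk)
    txt <- page_text(n)
    if (!is.null(beg)) {
      after <- mk[mk$kind == "END" & mk$char_offset > beg$match_end, ,
                  drop = FALSE]
      if (nrow(after) > 0) {
        endm <- after[which.min(after$char_offset), ]
        between <- substr(txt, beg$match_end + 1L, endm$char_offset - 1L)
        if (ev(between)) selected <- c(selected, n)          # rule 1
      } else {
        tail_txt <- substr(txt, beg$match_end + 1L, nchar(txt))
        if (ev(tail_txt)) selected <- c(selected, n)         # rule 2
      }
    } else {
      endm <- mk[mk$kind == "END", , drop = FALSE]
      if (nrow(endm) > 0) {
        endm <- endm[which.min(endm$char_offset), ]
        head_txt <- substr(txt, 1L, endm$char_offset - 1L)
        if (ev(head_txt)) selected <- c(selected, n)         # rule 3
      }
    }
  }

  # interior pages of a 3+-page section: between a BEGIN-bearing page and the
  # next END-bearing page, include evidence-carrying pages with no markers
  if (length(selected)) {
    bpages <- unique(markers$page_number[markers$kind == "BEGIN"])
    epages <- unique(markers$page_number[markers$kind == "END"])
    for (b in bpages) {
      e_after <- epages[epages > b]
      if (!length(e_after)) next
      e <- min(e_after)
      interior <- setdiff(seq_len(length(pages)), c(b, e))
      interior <- interior[interior > b & interior < e]
      for (p in interior) {
        mk_p <- markers[markers$page_number == p, , drop = FALSE]
        if (nrow(mk_p) == 0 && ev(page_text(p))) selected <- c(selected, p)
      }
    }
  }

  if (length(selected)) {
    return(list(pages = sort(unique(as.integer(selected))),
                mode = "SECTION_PAGES"))
  }

  # rule 4: CAS in Section 1 => single-ingredient fallback on page 1
  s1 <- section1_text(pages, markers, patterns)
  if (grepl(CAS_REGEX, s1)) {
    return(list(pages = 1L, mode = "SECTION1_FALLBACK"))
  }
  list(pages = integer(0), mode = "NONE")
}

#' Text of Section 1: document start up to the first Section-2/3 header
#'
#' Delimited by the earliest S1END or BEGIN marker; when neither exists the
#' first page stands in for Section 1.
#' @param pages list of raw pages
#' @param markers marker table
#' @param patterns pattern table
#' @return character scalar
#' @export
section1_text <- function(pages, markers, patterns = load_header_patterns()) {
  if (!length(pages)) return("")
  p1 <- tolower(pages[[1]]$raw_text)
  cut <- nchar(p1) + 1L
  s1pat <- patterns$regex[patterns$kind == "S1END"]
  for (p in s1pat) {
    m <- regexpr(p, p1, perl = TRUE)
    if (m != -1) cut <- min(cut, as.integer(m))
  }
  mk1 <- markers[markers$page_number == 1 & markers$kind == "BEGIN", ,
                 drop = FALSE]
  if (nrow(mk1)) cut <- min(cut, min(mk1$char_offset))
  substr(p1, 1L, cut - 1L)
}
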
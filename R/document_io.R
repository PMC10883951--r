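#' Per-page text extraction with a backend cascade
#'
#' Text is pulled from the PDF one page at a time through a cascade of three
#' extraction backends; for each page the first backend (in the configured
#' preference order) that produces non-whitespace text wins, and the winning
#' backend is recorded on the page.  A page on which all backends come back
#' empty (a scanned page, say) yields empty text with a warning rather than
#' an error.
#'
#' Backends:
#' \describe{
#'   \item{layout}{interprets positioned text operators in the content
#'     streams and recovers per-character geometry (the only backend that
#'     supplies char boxes).}
#'   \item{stream}{pulls literal strings out of each page's content stream
#'     in stream order; no geometry.}
#'   \item{raw}{last resort: scavenges parenthesised strings from the whole
#'     file and attributes them to the first page.}
#' }
#'
#' @name document_io
NULL

PDF_BACKENDS <- c("layout", "stream", "raw")

# ---- low-level file parsing ------------------------------------------------

pdf_read_text <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  s <- rawToChar(bytes)
  Encoding(s) <- "latin1"
  s
}

# decode a PDF literal string (escapes undone, WinAnsi dashes restored)
pdf_decode_string <- function(s) {
  s <- gsub("\\\\([()\\\\])", "\\1", s)
  s <- gsub(intToUtf8(0x96), intToUtf8(0x2013), s, fixed = TRUE)
  s <- gsub(intToUtf8(0x97), intToUtf8(0x2014), s, fixed = TRUE)
  enc2utf8(s)
}

pdf_objects <- function(s) {
  m <- gregexpr("(?s)([0-9]+) 0 obj\\b(.*?)endobj", s, perl = TRUE)[[1]]
  if (m[1] == -1) return(list())
  starts <- attr(m, "capture.start"); lens <- attr(m, "capture.length")
  out <- list()
  for (i in seq_along(m)) {
    num <- substr(s, starts[i, 1], starts[i, 1] + lens[i, 1] - 1)
    body <- substr(s, starts[i, 2], starts[i, 2] + lens[i, 2] - 1)
    out[[num]] <- body
  }
  out
}

# ordered content-stream object ids, one per page
pdf_page_contents <- function(objs) {
  pages_obj <- Filter(function(b) grepl("/Type /Pages", b, fixed = TRUE), objs)
  kid_ids <- character(0)
  if (length(pages_obj)) {
    kids <- regmatches(pages_obj[[1]],
                       regexpr("/Kids \\[[^]]*\\]", pages_obj[[1]]))
    kid_ids <- regmatches(kids, gregexpr("[0-9]+(?= 0 R)", kids,
                                         perl = TRUE))[[1]]
  }
  if (!length(kid_ids)) {
    kid_ids <- names(Filter(function(b)
      grepl("/Type /Page\\b", b) && !grepl("/Type /Pages", b, fixed = TRUE),
      objs))
  }
  vapply(kid_ids, function(id) {
    body <- objs[[id]]
    if (is.null(body)) return(NA_character_)
    m <- regmatches(body, regexpr("/Contents ([0-9]+) 0 R", body, perl = TRUE))
    if (!length(m)) return(NA_character_)
    sub("/Contents ([0-9]+) 0 R", "\\1", m)
  }, "")
}

pdf_stream_of <- function(objs, id) {
  body <- objs[[id]]
  if (is.null(body)) return("")
  m <- regexpr("(?s)stream\n(.*?)\nendstream", body, perl = TRUE)
  if (m == -1) return("")
  st <- attr(m, "capture.start"); ln <- attr(m, "capture.length")
  substr(body, st, st + ln - 1)
}

# ---- backends --------------------------------------------------------------

PDF_STRING_RE <- "\\(((?:[^()\\\\]|\\\\.)*)\\)"

backend_layout <- function(s, n_pages) {
  objs <- pdf_objects(s)
  contents <- pdf_page_contents(objs)
  run_re <- paste0("BT /F1 ([0-9.]+) Tf 1 0 0 1 ([0-9.]+) ([0-9.]+) Tm ",
                   PDF_STRING_RE, " Tj ET")
  lapply(seq_len(n_pages), function(i) {
    stream <- if (i <= length(contents) && !is.na(contents[i]))
      pdf_stream_of(objs, contents[i]) else ""
    m <- gregexpr(run_re, stream, perl = TRUE)[[1]]
    if (m[1] == -1) return(list(text = "", chars = NULL))
    cs <- attr(m, "capture.start"); cl <- attr(m, "capture.length")
    runs <- lapply(seq_along(m), function(j) {
      size <- as.numeric(substr(stream, cs[j, 1], cs[j, 1] + cl[j, 1] - 1))
      x <- as.numeric(substr(stream, cs[j, 2], cs[j, 2] + cl[j, 2] - 1))
      y_pdf <- as.numeric(substr(stream, cs[j, 3], cs[j, 3] + cl[j, 3] - 1))
      text <- pdf_decode_string(substr(stream, cs[j, 4],
                                       cs[j, 4] + cl[j, 4] - 1))
      list(size = size, x = x,
           y = PDF_PAGE_H - y_pdf - PDF_BASELINE * size, text = text)
    })
    assemble_page_runs(runs)
  })
}

# order runs into lines and build raw_text plus the per-character geometry
assemble_page_runs <- function(runs) {
  if (!length(runs)) return(list(text = "", chars = NULL))
  ys <- vapply(runs, `[[`, 0, "y")
  line_of <- integer(length(runs))
  ord <- order(ys)
  line <- 0L; last_y <- -Inf
  for (k in ord) {
    if (ys[k] - last_y > 2) line <- line + 1L
    line_of[k] <- line
    last_y <- ys[k]
  }
  text_parts <- character(0)
  chars <- list()
  pos <- 0L
  for (ln in seq_len(max(line_of))) {
    in_line <- which(line_of == ln)
    in_line <- in_line[order(vapply(runs[in_line], `[[`, 0, "x"))]
    if (ln > 1L) { text_parts <- c(text_parts, "\n"); pos <- pos + 1L }
    first <- TRUE
    for (k in in_line) {
      r <- runs[[k]]
      if (!first) { text_parts <- c(text_parts, " "); pos <- pos + 1L }
      first <- FALSE
      cc <- strsplit(r$text, "")[[1]]
      n <- length(cc)
      if (n) {
        w <- PDF_CHAR_W * r$size
        chars[[length(chars) + 1L]] <- data.frame(
          idx = pos + seq_len(n),
          char = cc,
          x0 = r$x + (seq_len(n) - 1) * w,
          x1 = r$x + seq_len(n) * w,
          y0 = r$y, y1 = r$y + r$size,
          stringsAsFactors = FALSE)
      }
      text_parts <- c(text_parts, r$text)
      pos <- pos + nchar(r$text)
    }
  }
  list(text = paste(text_parts, collapse = ""),
       chars = if (length(chars)) do.call(rbind, chars) else NULL)
}

backend_stream <- function(s, n_pages) {
  objs <- pdf_objects(s)
  contents <- pdf_page_contents(objs)
  lapply(seq_len(n_pages), function(i) {
    stream <- if (i <= length(contents) && !is.na(contents[i]))
      pdf_stream_of(objs, contents[i]) else ""
    m <- gregexpr(paste0(PDF_STRING_RE, "\\s*Tj"), stream, perl = TRUE)[[1]]
    if (m[1] == -1) return(list(text = "", chars = NULL))
    cs <- attr(m, "capture.start"); cl <- attr(m, "capture.length")
    strings <- vapply(seq_along(m), function(j)
      pdf_decode_string(substr(stream, cs[j, 1], cs[j, 1] + cl[j, 1] - 1)), "")
    list(text = paste(strings, collapse = " "), chars = NULL)
  })
}

backend_raw <- function(s, n_pages) {
  m <- gregexpr(PDF_STRING_RE, s, perl = TRUE)[[1]]
  texts <- character(0)
  if (m[1] != -1) {
    cs <- attr(m, "capture.start"); cl <- attr(m, "capture.length")
    texts <- vapply(seq_along(m), function(j)
      pdf_decode_string(substr(s, cs[j, 1], cs[j, 1] + cl[j, 1] - 1)), "")
  }
  out <- rep(list(list(text = "", chars = NULL)), n_pages)
  if (length(texts) && n_pages >= 1)
    out[[1]] <- list(text = paste(texts, collapse = " "), chars = NULL)
  out
}

# ---- public surface --------------------------------------------------------

#' Extract per-page text from an SDS PDF through the backend cascade
#'
#' @param pdf_path path to a text-based PDF
#' @param backends preference order; first backend producing non-whitespace
#'   text for a page wins for that page
#' @return list of raw pages, each a list with `page_number`, `raw_text`,
#'   `chars` (data.frame of per-character boxes or NULL), `backend_id`
#' @export
extract_pages <- function(pdf_path, backends = PDF_BACKENDS) {
  stopifnot(length(backends) >= 1, all(backends %in% PDF_BACKENDS))
  if (!file.exists(pdf_path)) stop("cannot read PDF: ", pdf_path)
  s <- pdf_read_text(pdf_path)
  if (!startsWith(s, "%PDF")) {
    stop("unreadable or corrupt PDF (missing header): ", pdf_path)
  }
  if (grepl("/Encrypt", s, fixed = TRUE)) {
    stop("encrypted PDF, cannot extract text: ", pdf_path)
  }
  objs <- pdf_objects(s)
  n_pages <- length(pdf_page_contents(objs))
  if (n_pages == 0) stop("unreadable or corrupt PDF (no pages): ", pdf_path)

  per_backend <- lapply(backends, function(b)
    switch(b,
           layout = backend_layout(s, n_pages),
           stream = backend_stream(s, n_pages),
           raw = backend_raw(s, n_pages)))
  lapply(seq_len(n_pages), function(i) {
    for (bi in seq_along(backends)) {
      pg <- per_backend[[bi]][[i]]
      if (nzchar(trimws(pg$text))) {
        return(list(page_number = i, raw_text = pg$text, chars = pg$chars,
                    backend_id = backends[bi]))
      }
    }
    warning("page ", i, ": no backend produced text (scanned page?)")
    list(page_number = i, raw_text = "", chars = NULL,
         backend_id = NA_character_)
  })
}

#' Default stopword list
#'
#' Conjunctions, prepositions and articles stripped during preprocessing.
#' Pinned in the package so preprocessing is reproducible; configurable in
#' every caller.  Deliberately excludes tokens that carry meaning on an SDS
#' ("no", "not", "none").
#' @export
default_stopwords <- function() {
  c("a", "an", "the", "and", "or", "but", "nor", "so", "yet",
    "of", "in", "on", "at", "by", "to", "from", "with", "without",
    "into", "onto", "over", "under", "between", "among", "through",
    "during", "before", "after", "above", "below", "than", "as",
    "is", "are", "was", "were", "be", "been", "being",
    "this", "that", "these", "those", "it", "its", "their", "there",
    "per", "via", "for")
}

#' Preprocess one raw page
#'
#' Applies, in order: newline removal, whitespace trim, lower-casing, and
#' stopword token removal.  Idempotent.  The offset map ties every retained
#' token back to its character range in the raw text.
#'
#' @param page a raw page from [extract_pages()] (or any list with
#'   `page_number` and `raw_text`)
#' @param stopwords character vector of tokens to drop
#' @return list with `page_number`, `text`, `offset_map` (data.frame
#'   token/start/end, 1-based inclusive ranges into `raw_text`)
#' @export
preprocess_page <- function(page, stopwords = default_stopwords()) {
  raw <- page$raw_text
  flat <- tolower(gsub("[\r\n]+", " ", raw))
  m <- gregexpr("[^[:space:]]+", flat)[[1]]
  if (m[1] == -1) {
    return(list(page_number = page$page_number, text = "",
                offset_map = data.frame(token = character(0),
                                        start = integer(0),
                                        end = integer(0))))
  }
  tokens <- regmatches(flat, list(m))[[1]]
  keep <- !(tokens %in% stopwords)
  offset_map <- data.frame(token = tokens[keep],
                           start = as.integer(m[keep]),
                           end = as.integer(m[keep]) +
                             attr(m, "match.length")[keep] - 1L,
                           stringsAsFactors = FALSE)
  list(page_number = page$page_number,
       text = paste(tokens[keep], collapse = " "),
       offset_map = offset_map)
}
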
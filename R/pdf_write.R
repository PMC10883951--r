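#' Minimal text-based PDF renderer
#'
#' The synthetic SDS generator renders real PDF files with a genuine text
#' layer (PDF 1.4, uncompressed content streams, Courier).  Courier is
#' metrically fixed at 0.6 em per glyph, so the generator knows the exact
#' bounding box of every character it places -- which is what makes gold
#' regions and round-trip geometry tests exact rather than approximate.
#'
#' Coordinate convention used throughout the package: points, origin at the
#' top-left corner of the page, y increasing downward, boxes half-open.
#' The writer converts to PDF's bottom-left convention internally.
#'
#' @name pdf_write
NULL

PDF_PAGE_W <- 612
PDF_PAGE_H <- 792
PDF_CHAR_W <- 0.6   # Courier advance width, fraction of font size
PDF_BASELINE <- 0.8 # baseline offset from the top of the char box

# Map one string to WinAnsi bytes (en/em dash supported; everything else
# outside ASCII degrades to "?"), escaping PDF string delimiters.
pdf_string_bytes <- function(s) {
  cp <- utf8ToInt(enc2utf8(s))
  cp[cp == 0x2013] <- 0x96
  cp[cp == 0x2014] <- 0x97
  cp[cp == 0x2212] <- 0x2D
  cp[cp > 0xFF] <- 0x3F
  out <- raw(0)
  for (b in cp) {
    if (b %in% c(0x28, 0x29, 0x5C)) out <- c(out, as.raw(0x5C))
    out <- c(out, as.raw(b))
  }
  out
}

# width in points of a string at the given Courier size
pdf_text_width <- function(s, size) {
  nchar(s, type = "chars") * PDF_CHAR_W * size
}

new_pdf_page <- function() {
  list(runs = list(), rects = list(), use_td = FALSE, no_text = FALSE)
}

# place a text run at (x, y_top); returns the updated page
page_add_text <- function(page, x, y, text, size = 10) {
  page$runs[[length(page$runs) + 1L]] <-
    list(x = x, y = y, size = size, text = text)
  page
}

page_add_rect <- function(page, x0, y0, x1, y1) {
  page$rects[[length(page$rects) + 1L]] <-
    list(x0 = x0, y0 = y0, x1 = x1, y1 = y1)
  page
}

fmt_num <- function(x) sub("\\.?0+$", "", sprintf("%.2f", x))

page_content_bytes <- function(page) {
  out <- raw(0)
  if (!isTRUE(page$no_text)) {
    for (r in page$runs) {
      if (isTRUE(page$use_td)) {
        head <- sprintf("BT /F1 %s Tf %s %s Td (", fmt_num(r$size),
                        fmt_num(r$x),
                        fmt_num(PDF_PAGE_H - r$y - PDF_BASELINE * r$size))
      } else {
        head <- sprintf("BT /F1 %s Tf 1 0 0 1 %s %s Tm (", fmt_num(r$size),
                        fmt_num(r$x),
                        fmt_num(PDF_PAGE_H - r$y - PDF_BASELINE * r$size))
      }
      out <- c(out, charToRaw(head), pdf_string_bytes(r$text),
               charToRaw(") Tj ET\n"))
    }
  }
  for (b in page$rects) {
    out <- c(out, charToRaw(sprintf(
      "%s %s %s %s re S\n",
      fmt_num(b$x0), fmt_num(PDF_PAGE_H - b$y1),
      fmt_num(b$x1 - b$x0), fmt_num(b$y1 - b$y0)
    )))
  }
  out
}

#' Assemble a complete PDF file from rendered pages
#'
#' @param pages list of pages built with `new_pdf_page()` / `page_add_text()`
#' @param encrypt write an /Encrypt entry in the trailer (produces a file the
#'   extractor must refuse; used to exercise the encrypted-document error)
#' @return raw vector of PDF bytes
#' @export
pdf_build <- function(pages, encrypt = FALSE) {
  n <- length(pages)
  # object numbering: 1 catalog, 2 pages, 3 font, then (page, content) pairs
  page_obj <- function(i) 2L + 2L * i
  cont_obj <- function(i) 3L + 2L * i

  objs <- vector("list", 3L + 2L * n)
  objs[[1]] <- charToRaw("1 0 obj\n<< /Type /Catalog /Pages 2 0 R >>\nendobj\n")
  kids <- paste(sprintf("%d 0 R", vapply(seq_len(n), page_obj, 0L)),
                collapse = " ")
  objs[[2]] <- charToRaw(sprintf(
    "2 0 obj\n<< /Type /Pages /Kids [%s] /Count %d >>\nendobj\n", kids, n))
  objs[[3]] <- charToRaw(paste0(
    "3 0 obj\n<< /Type /Font /Subtype /Type1 /BaseFont /Courier",
    " /Encoding /WinAnsiEncoding >>\nendobj\n"))
  for (i in seq_len(n)) {
    content <- page_content_bytes(pages[[i]])
    objs[[page_obj(i)]] <- charToRaw(sprintf(paste0(
      "%d 0 obj\n<< /Type /Page /Parent 2 0 R /MediaBox [0 0 %d %d] ",
      "/Resources << /Font << /F1 3 0 R >> >> /Contents %d 0 R >>\nendobj\n"),
      page_obj(i), PDF_PAGE_W, PDF_PAGE_H, cont_obj(i)))
    objs[[cont_obj(i)]] <- c(
      charToRaw(sprintf("%d 0 obj\n<< /Length %d >>\nstream\n",
                        cont_obj(i), length(content))),
      content, charToRaw("\nendstream\nendobj\n"))
  }

  header <- charToRaw("%PDF-1.4\n")
  body <- objs
  offsets <- integer(length(objs))
  pos <- length(header)
  for (i in seq_along(body)) {
    offsets[i] <- pos
    pos <- pos + length(body[[i]])
  }
  xref_pos <- pos
  xref <- paste0("xref\n0 ", length(objs) + 1L, "\n0000000000 65535 f \n",
                 paste(sprintf("%010d 00000 n ", offsets), collapse = "\n"),
                 "\n")
  trailer <- sprintf(
    "trailer\n<< /Size %d /Root 1 0 R%s >>\nstartxref\n%d\n%%%%EOF\n",
    length(objs) + 1L,
    if (encrypt) " /Encrypt 999 0 R" else "",
    xref_pos)
  c(header, do.call(c, body), charToRaw(xref), charToRaw(trailer))
}
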
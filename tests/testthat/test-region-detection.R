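# IoU, the heuristic table detector, and the section-region fallback

test_that("iou: identity, disjointness, and the hand-computed 1/3 case", {
  a <- region_box(1, 0, 0, 10, 10)
  expect_equal(region_iou(a, a), 1)
  b <- region_box(1, 20, 20, 30, 30)
  expect_equal(region_iou(a, b), 0)
  # overlap 10x5 = 50, union 100+100-50 = 150
  c <- region_box(1, 0, 5, 10, 15)
  expect_equal(region_iou(a, c), 1 / 3)
  # cross-check against a pixel rasterisation oracle
  raster_iou <- function(p, q) {
    xs <- seq(0.25, 39.75, by = 0.5); ys <- xs
    inp <- outer(xs >= p$x0 & xs < p$x1, ys >= p$y0 & ys < p$y1, "&")
    inq <- outer(xs >= q$x0 & xs < q$x1, ys >= q$y0 & ys < q$y1, "&")
    sum(inp & inq) / sum(inp | inq)
  }
  expect_equal(region_iou(a, c), raster_iou(a, c), tolerance = 1e-6)
})

test_that("iou is symmetric and bounded on random box pairs", {
  set.seed(405)
  for (i in 1:100) {
    r <- function() {
      x <- sort(runif(2, 0, 600)); y <- sort(runif(2, 0, 780))
      region_box(1, x[1], y[1], x[2] + 1, y[2] + 1)
    }
    a <- r(); b <- r()
    ab <- region_iou(a, b)
    expect_equal(ab, region_iou(b, a))
    expect_gte(ab, 0); expect_lte(ab, 1)
  }
  expect_error(region_box(1, 0, 0, 0, 10))  # degenerate box
})

test_that("bordered and borderless tables are both found at IoU >= 0.5", {
  for (style in c("bordered", "borderless")) {
    rp <- rendered_pages(sds_spec("normal", 4, "row", style, seed = 77))
    gold <- rp$doc$gold_regions[[1]]
    boxes <- detect_tables(rp$pages[[gold$page_number]])
    expect_gte(length(boxes), 1)
    expect_gte(max(vapply(boxes, function(b) region_iou(b, gold), 0)), 0.5)
  }
})

test_that("a prose-only page yields no table detections", {
  p <- new_pdf_page()
  p <- page_add_text(p, 36, 36, "This page holds running prose only.")
  p <- page_add_text(p, 36, 50, "Nothing here lines up in columns.")
  path <- tempfile(fileext = ".pdf")
  writeBin(pdf_build(list(p)), path)
  pages <- extract_pages(path)
  unlink(path)
  expect_length(detect_tables(pages[[1]]), 0)
})

test_that("section fallback spans the marker characters, full width", {
  rp <- rendered_pages(sds_spec("normal", 3, "row", "free_text", seed = 78))
  gold <- rp$doc$gold_regions[[1]]
  page <- rp$pages[[gold$page_number]]
  mk <- find_markers(rp$pages)
  mk <- mk[mk$page_number == gold$page_number, , drop = FALSE]
  beg <- mk[mk$kind == "BEGIN", , drop = FALSE][1, ]
  endm <- mk[mk$kind == "END", , drop = FALSE][1, ]
  both <- detect_section_region(page, beg, endm)
  expect_identical(both$kind, "SECTION")
  expect_equal(region_iou(both, gold), 1)
  # begin only: extends to the page bottom
  b_only <- detect_section_region(page, beg, NULL)
  expect_equal(b_only$y1, 792)
  expect_equal(b_only$y0, gold$y0)
  # end only: extends from the page top
  e_only <- detect_section_region(page, NULL, endm)
  expect_equal(e_only$y0, 0)
  expect_equal(e_only$y1, gold$y1)
  # no geometry: full page with a warning
  expect_warning(
    full <- detect_section_region(list(page_number = 1, chars = NULL),
                                  beg, NULL),
    "no character geometry")
  expect_equal(c(full$x0, full$y0, full$x1, full$y1), c(0, 0, 612, 792))
})

test_that("every selected page yields at least one region (fallback closure)", {
  docs <- cached_corpus(40, seed = 32)
  for (d in docs) {
    if (!(d$gold$status == "INDEXED")) next
    path <- write_doc_pdf(d)
    pages <- extract_pages(path)
    unlink(path)
    mk <- find_markers(pages)
    sel <- select_pages(pages, mk)
    for (n in sel$pages) {
      regions <- detect_tables(pages[[n]])
      if (!length(regions)) {
        mm <- mk[mk$page_number == n, , drop = FALSE]
        beg <- if (any(mm$kind == "BEGIN"))
          mm[mm$kind == "BEGIN", ][1, ] else NULL
        endm <- if (any(mm$kind == "END"))
          mm[mm$kind == "END", ][1, ] else NULL
        regions <- list(detect_section_region(pages[[n]], beg, endm))
      }
      expect_gte(length(regions), 1)
    }
  }
})
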
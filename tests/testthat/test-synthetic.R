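# Generator determinism and gold self-consistency

test_that("sampled ingredients are reproducible and cover operator kinds", {
  set.seed(1); a <- sample_ingredients(5)
  set.seed(1); b <- sample_ingredients(5)
  expect_identical(lapply(a, `[[`, "name"), lapply(b, `[[`, "name"))
  ops <- vapply(a, function(r)
    ifelse(is.na(r$weight$operator), "NaN", r$weight$operator), "")
  expect_identical(sort(unique(ops)), sort(c("-", ">", "<", "=", "NaN")))
  expect_true(all(vapply(a, function(r) isTRUE(r$cas$checksum_valid),
                         logical(1))))
  set.seed(2)
  expect_gte(length(unique(vapply(sample_ingredients(5), function(r)
    ifelse(is.na(r$weight$operator), "NaN", r$weight$operator), ""))), 2)
})

test_that("same seed and spec render byte-identical PDFs", {
  spec <- sds_spec("normal", 3, "row", "borderless", seed = 5)
  a <- render_document(spec)
  b <- render_document(spec)
  expect_identical(a$pdf, b$pdf)
  expect_identical(a$gold, b$gold)
})

test_that("split documents carry two gold pages and two gold regions", {
  d <- render_document(sds_spec("normal", 4, split_across_pages = TRUE,
                                seed = 6))
  expect_length(d$gold_pages, 2)
  expect_length(d$gold_regions, 2)
  expect_identical(vapply(d$gold_regions, `[[`, 0, "page_number"),
                   as.numeric(d$gold_pages))
  u <- render_document(sds_spec("normal", 4, seed = 6))
  expect_length(u$gold_pages, 1)
  expect_identical(length(u$gold$records), length(d$gold$records))
})

test_that("variant invariants: no_data empty, single_ingredient one record", {
  nd <- render_document(sds_spec("no_data", seed = 7))
  expect_identical(nd$gold$status, "NO_DATA")
  expect_length(nd$gold$records, 0)
  expect_length(nd$gold_regions, 0)

  si <- render_document(sds_spec("single_ingredient", seed = 8))
  expect_identical(si$gold$status, "SINGLE_INGREDIENT_FALLBACK")
  expect_length(si$gold$records, 1)
  expect_identical(si$gold$records[[1]]$name, si$product_name)
  expect_error(sds_spec("normal", table_style = "free_text",
                        split_across_pages = TRUE))
})

test_that("gold regions sit on gold pages and bound their own text exactly", {
  docs <- cached_corpus(20, seed = 31)
  for (d in docs) {
    for (g in d$gold_regions) {
      expect_true(g$page_number %in% d$gold_pages)
    }
    if (d$gold$status != "INDEXED") next
    path <- write_doc_pdf(d)
    pages <- extract_pages(path)
    unlink(path)
    for (g in d$gold_regions) {
      ch <- pages[[g$page_number]]$chars
      cx <- (ch$x0 + ch$x1) / 2; cy <- (ch$y0 + ch$y1) / 2
      inside <- cx >= g$x0 & cx < g$x1 & cy >= g$y0 & cy < g$y1
      expect_gt(sum(inside), 0)
      if (g$kind == "TABLE") {
        nonspace <- inside & ch$char != " "
        tight <- region_box(g$page_number, min(ch$x0[nonspace]),
                            min(ch$y0[nonspace]), max(ch$x1[nonspace]),
                            max(ch$y1[nonspace]), kind = "TABLE")
        expect_equal(region_iou(g, tight), 1, info = d$gold$doc_id)
      }
    }
  }
})

test_that("a written corpus is seed-reproducible file for file", {
  d1 <- file.path(tempdir(), "corp_a"); d2 <- file.path(tempdir(), "corp_b")
  unlink(c(d1, d2), recursive = TRUE)
  generate_corpus(8, seed = 21, outdir = d1)
  generate_corpus(8, seed = 21, outdir = d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in grep("\\.pdf$", f1, value = TRUE)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6), info = f)
  }
  # manifests agree apart from the directory they point into
  strip_path <- function(p) {
    lapply(readLines(p), function(ln) {
      l <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
      l$pdf_path <- NULL
      l
    })
  }
  expect_identical(strip_path(file.path(d1, "manifest.jsonl")),
                   strip_path(file.path(d2, "manifest.jsonl")))
  # manifest round-trips into gold results
  man <- read_manifest(file.path(d1, "manifest.jsonl"))
  expect_length(man, 8)
  expect_true(all(file.exists(vapply(man, `[[`, "", "pdf_path"))))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("held-out vocabulary names are unknown to the default gazetteer", {
  vocab <- chemical_vocabulary()
  held <- vocab$name[vocab$held_out]
  expect_gt(length(held), 0)
  expect_length(intersect(held, default_gazetteer()), 0)
  # a table of held-out names yields no recognised tokens (recall cost,
  # mirroring a recognizer miss)
  rec <- gazetteer_recognizer()
  expect_true(all(rec(strsplit(held[1], " ")[[1]]) == "OUTSIDE"))
})
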
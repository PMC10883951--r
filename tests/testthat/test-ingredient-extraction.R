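# Serialisation, recognition, column identification, association

test_that("serialisation uses [cs]/[rs] separators and NA for empty cells", {
  g <- rbind(c("water", "7732-18-5"), c("", ">60"))
  ser <- serialize_grid(g)
  expect_identical(ser$tokens,
                   c("water", "[cs]", "7732-18-5", "[rs]", "NA", "[cs]",
                     ">60"))
  expect_identical(serialize_grid(matrix("x"))$tokens, "x")
  # multi-word cells keep their tokens with no separator inside the cell
  ser2 <- serialize_grid(matrix("titanium dioxide"))
  expect_identical(ser2$tokens, c("titanium", "dioxide"))
})

test_that("serialisation inverts exactly given the separator tokens", {
  set.seed(406)
  pool <- c("water", "titanium dioxide", "7732-18-5", "<10", "")
  for (i in 1:25) {
    nr <- sample(1:4, 1); nc <- sample(1:4, 1)
    cells <- matrix(sample(pool, nr * nc, replace = TRUE), nr, nc)
    ser <- serialize_grid(cells)
    expect_identical(deserialize_grid(ser$tokens), cells)
  }
})

test_that("the gazetteer recognizer labels single and multi-token names", {
  rec <- gazetteer_recognizer(c("water", "titanium dioxide"))
  expect_identical(recognize_names(c("water", "[cs]", "7732-18-5"), rec),
                   c("NAME_BEGIN", "OUTSIDE", "OUTSIDE"))
  expect_identical(recognize_names(c("titanium", "dioxide"), rec),
                   c("NAME_BEGIN", "NAME_INSIDE"))
  expect_identical(recognize_names(c("argon", "gas"), rec),
                   c("OUTSIDE", "OUTSIDE"))
  # separators and NA are never part of a name
  expect_identical(recognize_names(c("NA", "[rs]"), rec),
                   c("OUTSIDE", "OUTSIDE"))
})

test_that("labelled runs assemble into names located at their cells", {
  g <- rbind(c("header", "cas"), c("titanium dioxide", "13463-67-7"))
  ser <- serialize_grid(g)
  rec <- gazetteer_recognizer("titanium dioxide")
  names <- assemble_names(ser, recognize_names(ser$tokens, rec))
  expect_identical(nrow(names), 1L)
  expect_identical(names$name, "titanium dioxide")
  expect_identical(names$row, 2L)
  expect_identical(names$col, 1L)
  # an orphan NAME_INSIDE is promoted to a name start
  labels <- c("NAME_INSIDE", "OUTSIDE")
  got <- assemble_names(list(tokens = c("water", "x"), row = c(1L, 1L),
                             col = c(1L, 2L)), labels)
  expect_identical(got$name, "water")
})

test_that("CAS and weight columns are found by match counts, ties leftmost", {
  g <- rbind(c("name", "cas no.", "wt%"),
             c("water", "7732-18-5", "60-100"),
             c("acetone", "67-64-1", "<10"))
  cols <- identify_columns(g)
  expect_identical(cols$cas_column, 2L)
  expect_identical(cols$weight_column, 3L)

  no_cas <- rbind(c("water", "60-100"), c("acetone", "<10"))
  cols2 <- identify_columns(no_cas)
  expect_null(cols2$cas_column)
  expect_identical(cols2$weight_column, 2L)

  tie <- rbind(c("7732-18-5", "67-64-1"), c("x", "y"))
  expect_warning(cols3 <- identify_columns(tie), "tie")
  expect_identical(cols3$cas_column, 1L)
})

test_that("association follows grid rows; orientation twins agree", {
  g <- structure(list(cells = rbind(
    c("Chemical Name", "CAS No.", "Wt.%"),
    c("water", "7732-18-5", "60-100"),
    c("acetone", "", "<10")), page_number = 1, region = NULL),
    class = "table_grid")
  recs <- records_from_grid(g, gazetteer_recognizer(c("water", "acetone")))
  expect_length(recs, 2)
  expect_identical(recs[[1]]$name, "water")
  expect_identical(recs[[1]]$cas$raw, "7732-18-5")
  expect_equal(recs[[1]]$weight$upper, 100)
  expect_identical(recs[[2]]$cas$kind, "ABSENT")  # empty CAS cell
  expect_identical(recs[[2]]$weight$operator, "<")

  # the column-oriented twin of the same records transposes to equality
  ct <- structure(list(cells = rbind(
    c("Chemical Name:", "water", "acetone"),
    c("CAS No.:", "7732-18-5", ""),
    c("Wt.%:", "60-100", "<10")), page_number = 1, region = NULL),
    class = "table_grid")
  recs2 <- records_from_grid(ct, gazetteer_recognizer(c("water", "acetone")))
  strip <- function(rs) lapply(rs, function(r) r[c("name", "cas", "weight")])
  expect_identical(strip(recs2), strip(recs))
})

test_that("single-ingredient fallback reads name and CAS from Section 1", {
  s1 <- "SECTION 1: IDENTIFICATION\nProduct name: Acetone\nCAS number: 67-64-1"
  rec <- single_ingredient_fallback(s1)
  expect_identical(rec$name, "acetone")
  expect_identical(rec$cas$raw, "67-64-1")
  expect_true(is.na(rec$weight$operator))

  # checksum-invalid CAS is still emitted, annotated
  rec2 <- single_ingredient_fallback("Product name: X\nCAS number: 67-64-2")
  expect_false(rec2$cas$checksum_valid)

  # no product-name label: first line stands in, with a warning
  expect_warning(rec3 <- single_ingredient_fallback("Some Product\ncas 67-64-1"),
                 "no product-name label")
  expect_identical(rec3$name, "some product")
})

test_that("index_document routes each variant to the right outcome", {
  two <- render_document(sds_spec("normal", 2, seed = 91), "two")
  res <- index_rendered(two)
  expect_identical(res$status, "INDEXED")
  sc <- score_document(res, two$gold)
  expect_identical(sc$tier3[["tp"]], 1L)

  nd <- render_document(sds_spec("no_data", seed = 92), "nd")
  res_nd <- index_rendered(nd)
  expect_identical(res_nd$status, "NO_DATA")
  expect_length(res_nd$records, 0)

  si <- render_document(sds_spec("single_ingredient", seed = 93), "si")
  res_si <- index_rendered(si)
  expect_identical(res_si$status, "SINGLE_INGREDIENT_FALLBACK")
  expect_length(res_si$records, 1)
  expect_identical(res_si$records[[1]]$name, si$gold$records[[1]]$name)
})

test_that("a batch isolates per-document failures and re-runs identically", {
  docs <- cached_corpus(6, seed = 33)
  paths <- vapply(docs, write_doc_pdf, "")
  corrupt <- tempfile(fileext = ".pdf")
  writeLines("broken", corrupt)
  res <- run_batch(c(paths, corrupt))
  expect_length(res, 7)
  expect_identical(res[[7]]$status, "FAILED")
  expect_match(res[[7]]$failure_reason, "unreadable")
  expect_true(all(vapply(res[1:6], `[[`, "", "status") != "FAILED"))
  res2 <- run_batch(c(paths, corrupt))
  expect_identical(lapply(res, `[`, c("status", "records")),
                   lapply(res2, `[`, c("status", "records")))
  expect_error(run_batch(character(0)))
  # summary counts by status
  s <- batch_summary(res)
  expect_identical(sum(s), 7L)
  expect_identical(unname(s[["FAILED"]]), 1L)
  unlink(c(paths, corrupt))
})

test_that("records round-trip through the CSV and JSONL writers", {
  docs <- cached_corpus(6, seed = 33)
  res <- index_corpus(docs)
  csv <- tempfile(fileext = ".csv")
  write_records(res, csv, "csv")
  tab <- utils::read.csv(csv)
  expect_identical(sort(unique(tab$doc_id)),
                   sort(vapply(res, `[[`, "", "doc_id")))
  jl <- tempfile(fileext = ".jsonl")
  write_records(res, jl, "jsonl")
  back <- read_records(jl)
  expect_identical(lapply(back, record_summary <- function(r)
    list(r$doc_id, r$status, vapply(r$records, `[[`, "", "name"))),
    lapply(res, record_summary))
  unlink(c(csv, jl))
})
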
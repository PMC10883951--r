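# Section-header markers, evidence, and the four selection rules

raw_page <- function(n, text) list(page_number = n, raw_text = text,
                                   chars = NULL, backend_id = "layout")

test_that("the packaged pattern file parses and kinds are disjoint sets", {
  pat <- load_header_patterns()
  expect_true(all(c("BEGIN", "END", "LABEL") %in% pat$kind))
  expect_false(anyDuplicated(pat$id) > 0)
  begin <- pat$regex[pat$kind == "BEGIN"]
  end <- pat$regex[pat$kind == "END"]
  expect_length(intersect(begin, end), 0)
})

test_that("composition and first-aid headers become BEGIN/END markers", {
  pages <- list(
    raw_page(1, "SECTION 3: Composition/Information on Ingredients"),
    raw_page(2, "SECTION 4: First Aid Measures"),
    raw_page(3, "nothing to see here"))
  mk <- find_markers(pages)
  expect_identical(mk$kind[mk$page_number == 1], "BEGIN")
  expect_identical(mk$kind[mk$page_number == 2], "END")
  expect_false(3 %in% mk$page_number)
  # older two-section naming also begins the section
  mk2 <- find_markers(list(raw_page(1, "Hazardous Ingredients")))
  expect_identical(mk2$kind, "BEGIN")
})

test_that("evidence scan reports CAS, labels, and recognised names", {
  ev <- gather_evidence("water 7732-18-5 60-100%")
  expect_true(ev$has_cas)
  expect_true(ev$has_name_token)
  expect_true(ev$any)

  ev2 <- gather_evidence("cas number   concentration")
  expect_true(ev2$has_label)
  expect_false(ev2$has_cas)

  ev3 <- gather_evidence("this page intentionally blank")
  expect_false(ev3$any)
  expect_identical(ev3$any, ev3$has_cas || ev3$has_label ||
                     ev3$has_name_token)
})

test_that("rule 1 selects a page holding both headers with evidence between", {
  pages <- list(
    raw_page(1, "SECTION 1: IDENTIFICATION\nProduct name: cleaner"),
    raw_page(2, paste("SECTION 3: COMPOSITION/INFORMATION ON INGREDIENTS",
                      "water 7732-18-5 60-100",
                      "SECTION 4: FIRST-AID MEASURES", sep = "\n")))
  sel <- select_pages(pages, find_markers(pages))
  expect_identical(sel$pages, 2L)
  expect_identical(sel$mode, "SECTION_PAGES")
})

test_that("a table split across two pages selects both (rules 2 and 3)", {
  pages <- list(
    raw_page(1, paste("SECTION 3: COMPOSITION/INFORMATION ON INGREDIENTS",
                      "water 7732-18-5 60-100", sep = "\n")),
    raw_page(2, paste("acetone 67-64-1 1-5",
                      "SECTION 4: FIRST-AID MEASURES", sep = "\n")))
  sel <- select_pages(pages, find_markers(pages))
  expect_identical(sel$pages, c(1L, 2L))
  expect_identical(sel$mode, "SECTION_PAGES")
})

test_that("rule 4 fires only when rules 1-3 select nothing", {
  pages <- list(
    raw_page(1, paste("SECTION 1: IDENTIFICATION",
                      "Product name: Acetone",
                      "CAS number: 67-64-1",
                      "SECTION 2: HAZARDS IDENTIFICATION", sep = "\n")))
  sel <- select_pages(pages, find_markers(pages))
  expect_identical(sel$mode, "SECTION1_FALLBACK")
  expect_identical(sel$pages, 1L)

  # same Section 1 but a real composition page present: rule 4 must not fire
  pages2 <- c(pages, list(
    raw_page(2, paste("SECTION 3: COMPOSITION/INFORMATION ON INGREDIENTS",
                      "water 7732-18-5 60-100",
                      "SECTION 4: FIRST-AID MEASURES", sep = "\n"))))
  sel2 <- select_pages(pages2, find_markers(pages2))
  expect_identical(sel2$mode, "SECTION_PAGES")
  expect_identical(sel2$pages, 2L)

  # nothing anywhere -> NONE with empty page set
  none <- list(raw_page(1, "SECTION 1: IDENTIFICATION\nProduct name: x"))
  sel3 <- select_pages(none, find_markers(none))
  expect_identical(sel3$mode, "NONE")
  expect_length(sel3$pages, 0)
})

test_that("selected pages equal gold pages on a noise-free corpus", {
  docs <- cached_corpus(40, seed = 32)
  for (d in docs) {
    if (d$gold$status == "NO_DATA") next
    path <- write_doc_pdf(d)
    pages <- extract_pages(path)
    unlink(path)
    sel <- select_pages(pages, find_markers(pages))
    expect_identical(sel$pages, as.integer(d$gold_pages),
                     info = d$gold$doc_id)
    if (d$gold$status == "SINGLE_INGREDIENT_FALLBACK") {
      expect_identical(sel$mode, "SECTION1_FALLBACK", info = d$gold$doc_id)
    } else {
      expect_identical(sel$mode, "SECTION_PAGES", info = d$gold$doc_id)
    }
  }
})
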
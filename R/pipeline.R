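#' Pipeline orchestration and batch processing
#'
#' `index_document()` chains the full pipeline for one PDF: text
#' extraction, preprocessing, the no-data filter, page selection, region
#' detection, table extraction and ingredient extraction.  `run_batch()`
#' maps it over many documents with per-document isolation: one failing
#' document becomes a FAILED result, never an aborted batch.
#'
#' @name cli_pipeline
NULL

#' Assemble a pipeline configuration
#'
#' Every field has a documented default; unknown fields are rejected.
#'
#' @param backends PDF extraction backend preference order
#' @param stopwords stopword set for preprocessing
#' @param max_chunk_len no-data filter chunk size in tokens
#' @param patterns header/label pattern table
#' @param gazetteer recognizer vocabulary (lowercase names)
#' @param classifier chunk classifier function; NULL builds the rule
#'   classifier from the gazetteer
#' @param recognizer name recognizer function; NULL builds the gazetteer
#'   recognizer
#' @param detector table detector function(page) -> list of region boxes;
#'   NULL uses the layout heuristic
#' @param col_gap_pt column gutter threshold in points
#' @param x_tol column alignment tolerance in points
#' @return list of class `sds_config`
#' @export
sds_config <- function(backends = PDF_BACKENDS,
                       stopwords = default_stopwords(),
                       max_chunk_len = 256,
                       patterns = load_header_patterns(),
                       gazetteer = default_gazetteer(),
                       classifier = NULL,
                       recognizer = NULL,
                       detector = NULL,
                       col_gap_pt = 12,
                       x_tol = 6) {
  if (is.null(recognizer)) recognizer <- gazetteer_recognizer(gazetteer)
  if (is.null(classifier))
    classifier <- rule_chunk_classifier(gazetteer, patterns)
  if (is.null(detector))
    detector <- function(page) detect_tables(page, x_tol = x_tol,
                                             col_gap_pt = col_gap_pt)
  structure(list(backends = backends, stopwords = stopwords,
                 max_chunk_len = max_chunk_len, patterns = patterns,
                 gazetteer = gazetteer, classifier = classifier,
                 recognizer = recognizer, detector = detector,
                 col_gap_pt = col_gap_pt, x_tol = x_tol),
            class = "sds_config")
}

#' Index one SDS document
#'
#' @param pdf_path path to the PDF
#' @param config an [sds_config()]
#' @param doc_id identifier for the result; defaults to the file stem
#' @return an `indexing_result`
#' @export
index_document <- function(pdf_path, config = sds_config(),
                           doc_id = tools::file_path_sans_ext(
                             basename(pdf_path))) {
  pages <- extract_pages(pdf_path, config$backends)

  prep <- lapply(pages, preprocess_page, stopwords = config$stopwords)
  chunks <- chunk_document(prep, config$max_chunk_len)
  status <- predict_document(chunks, config$classifier)
  if (status$status == "NO_DATA") {
    return(indexing_result(doc_id, "NO_DATA"))
  }

  markers <- find_markers(pages, config$patterns)
  sel <- select_pages(pages, markers, config$recognizer, config$patterns)

  if (sel$mode == "NONE") {
    return(indexing_result(doc_id, "FAILED",
                           failure_reason = "page_selection: no composition pages found"))
  }

  if (sel$mode == "SECTION1_FALLBACK") {
    s1 <- section1_text(pages, markers, config$patterns)
    rec <- single_ingredient_fallback(s1)
    return(indexing_result(doc_id, "SINGLE_INGREDIENT_FALLBACK", list(rec)))
  }

  records <- list()
  for (n in sel$pages) {
    page <- pages[[n]]
    regions <- config$detector(page)
    if (!length(regions)) {
      mk <- markers[markers$page_number == n, , drop = FALSE]
      beg <- mk[mk$kind == "BEGIN", , drop = FALSE]
      endm <- mk[mk$kind == "END", , drop = FALSE]
      if (nrow(beg) == 0 && nrow(endm) == 0) next
      regions <- list(detect_section_region(
        page,
        if (nrow(beg)) beg[1, ] else NULL,
        if (nrow(endm)) endm[which.min(endm$char_offset), ] else NULL))
    }
    for (rg in regions) {
      grid <- tryCatch(extract_grid(page, rg, config$col_gap_pt),
                       error = function(e) NULL)
      if (is.null(grid)) next
      recs <- records_from_grid(grid, config$recognizer, config$patterns)
      records <- c(records, recs)
    }
  }

  if (!length(records)) {
    return(indexing_result(doc_id, "FAILED",
                           failure_reason = "ingredient_extraction: no records found"))
  }
  # identical rows extracted from overlapping regions collapse to one
  keys <- vapply(records, record_key, "")
  records <- records[!duplicated(keys)]
  indexing_result(doc_id, "INDEXED", records)
}

#' Index a batch of documents with per-document isolation
#'
#' @param paths character vector of PDF paths
#' @param config an [sds_config()]
#' @return list of `indexing_result`s, one per input, in order
#' @export
run_batch <- function(paths, config = sds_config()) {
  stopifnot(length(paths) >= 1)
  lapply(paths, function(p) {
    doc_id <- tools::file_path_sans_ext(basename(p))
    tryCatch(index_document(p, config, doc_id = doc_id),
             error = function(e)
               indexing_result(doc_id, "FAILED",
                               failure_reason = conditionMessage(e)))
  })
}

#' Summarise batch results by status
#' @param results list of `indexing_result`s
#' @return named integer vector of status counts
#' @export
batch_summary <- function(results) {
  table(factor(vapply(results, `[[`, "", "status"),
               levels = c("INDEXED", "SINGLE_INGREDIENT_FALLBACK",
                          "NO_DATA", "FAILED")))
}

#' Write indexing results as CSV or JSON lines
#'
#' The CSV carries the tabular output shape: one row per ingredient with
#' columns doc_id, ingredient_name, cas, weight_lower, weight_upper,
#' weight_operator, status.  JSONL additionally carries provenance.
#'
#' @param results list of `indexing_result`s
#' @param path output file
#' @param format "csv" or "jsonl"
#' @export
write_records <- function(results, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "csv") {
    rows <- list()
    for (res in results) {
      if (length(res$records)) {
        for (r in res$records) {
          rows[[length(rows) + 1L]] <- data.frame(
            doc_id = res$doc_id, ingredient_name = r$name,
            cas = format_cas(r$cas),
            weight_lower = r$weight$lower, weight_upper = r$weight$upper,
            weight_operator = ifelse(is.na(r$weight$operator), "NaN",
                                     r$weight$operator),
            status = res$status, stringsAsFactors = FALSE)
        }
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          doc_id = res$doc_id, ingredient_name = NA_character_,
          cas = NA_character_, weight_lower = NA_real_,
          weight_upper = NA_real_, weight_operator = NA_character_,
          status = res$status, stringsAsFactors = FALSE)
      }
    }
    utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (res in results) {
      writeLines(jsonlite::toJSON(
        list(doc_id = res$doc_id, status = res$status,
             failure_reason = res$failure_reason,
             records = lapply(res$records, record_to_list)),
        auto_unbox = TRUE, digits = NA, null = "null"), con)
    }
  }
  invisible(path)
}

#' Read predictions back from a JSONL file written by [write_records()]
#' @param path JSONL file
#' @return list of `indexing_result`s
#' @export
read_records <- function(path) {
  lapply(readLines(path, encoding = "UTF-8"), function(ln) {
    l <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    indexing_result(l$doc_id, l$status,
                    lapply(l$records, list_to_record),
                    failure_reason = l$failure_reason)
  })
}
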
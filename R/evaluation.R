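#' Tiered precision-recall evaluation
#'
#' Predicted indexing results are scored against gold at three tiers:
#' Tier 1 compares each entity kind (ingredient name, CAS, operator, upper,
#' lower) individually as multisets; Tier 2 matches whole records under
#' exact five-field equality; Tier 3 treats the document as one unit that
#' is correct only when the predicted record set equals the gold set
#' exactly and the status matches.  Corpus aggregation is micro (counts are
#' summed, then precision/recall computed), and the combined all-documents
#' metric folds in the no-data documents.
#'
#' @name evaluation
NULL

ENTITY_KINDS <- c("ingredient", "cas", "operator", "upper", "lower")

#' Canonicalise one entity value for comparison
#'
#' @param kind one of "name"/"ingredient", "cas", "operator", "upper",
#'   "lower"
#' @param value raw value
#' @return canonical string; absent/NaN values map to the token "NA"
#' @export
normalize_value <- function(kind, value) {
  kind <- match.arg(kind, c("name", "ingredient", "cas", "operator",
                            "upper", "lower"))
  if (kind %in% c("name", "ingredient", "cas", "operator")) {
    v <- as.character(value)
    if (length(v) == 0 || is.na(v) || !nzchar(trimws(v))) return("NA")
    return(tolower(trimws(gsub("[[:space:]]+", " ", v))))
  }
  v <- suppressWarnings(as.numeric(value))
  if (length(v) == 0 || is.na(v) || is.nan(v)) return("NA")
  format(v, scientific = FALSE, trim = TRUE, drop0trailing = TRUE)
}

#' Canonical five-field view of an ingredient record
#' @param record an `ingredient_record` (or a list with the same fields)
#' @return named character vector (ingredient, cas, operator, upper, lower)
#' @export
record_fields <- function(record) {
  c(ingredient = normalize_value("ingredient", record$name),
    cas = normalize_value("cas", format_cas(record$cas)),
    operator = normalize_value("operator", record$weight$operator),
    upper = normalize_value("upper", record$weight$upper),
    lower = normalize_value("lower", record$weight$lower))
}

record_key <- function(record) paste(record_fields(record), collapse = "\x1f")

# multiset intersection counts
multiset_counts <- function(pred, gold) {
  tp <- 0L
  g <- gold
  for (p in pred) {
    hit <- match(p, g)
    if (!is.na(hit)) { tp <- tp + 1L; g <- g[-hit] }
  }
  c(tp = tp, fp = length(pred) - tp, fn = length(gold) - tp)
}

#' Score one predicted document against gold
#'
#' @param pred,gold `indexing_result`s for the same document
#' @return list with `tier1` (matrix: entity kinds x tp/fp/fn), `tier2`,
#'   `tier3` (named tp/fp/fn vectors)
#' @export
score_document <- function(pred, gold) {
  pf <- lapply(pred$records, record_fields)
  gf <- lapply(gold$records, record_fields)

  tier1 <- t(vapply(ENTITY_KINDS, function(k)
    multiset_counts(vapply(pf, `[[`, "", k), vapply(gf, `[[`, "", k)),
    c(tp = 0L, fp = 0L, fn = 0L)))

  tier2 <- multiset_counts(vapply(pred$records, record_key, ""),
                           vapply(gold$records, record_key, ""))

  exact <- tier2[["fp"]] == 0L && tier2[["fn"]] == 0L &&
    identical(pred$status, gold$status)
  tier3 <- if (exact) c(tp = 1L, fp = 0L, fn = 0L)
  else if (length(pred$records) > 0) c(tp = 0L, fp = 1L, fn = 1L)
  else c(tp = 0L, fp = 0L, fn = 1L)

  list(tier1 = tier1, tier2 = tier2, tier3 = tier3)
}

pr <- function(counts) {
  tp <- counts[["tp"]]; fp <- counts[["fp"]]; fn <- counts[["fn"]]
  c(precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
    recall = if (tp + fn == 0) NA_real_ else tp / (tp + fn))
}

#' Aggregate per-document scores into corpus tier metrics
#'
#' Counts are micro-aggregated (summed, then precision/recall).  Documents
#' whose gold status is NO_DATA contribute only to the combined
#' all-documents metric: predicted NO_DATA is one true-positive unit;
#' predicted with records is one fp plus one fn; predicted empty but not
#' NO_DATA (e.g. FAILED) is one fn.
#'
#' @param scored list of per-document scores ([score_document()]) for
#'   gold has-data documents
#' @param no_data_eval optional data.frame with columns `pred_status`,
#'   `pred_records` (counts) for gold no-data documents
#' @return object of class `tier_metrics`
#' @export
aggregate_scores <- function(scored, no_data_eval = NULL) {
  sum3 <- function(extract) {
    out <- c(tp = 0L, fp = 0L, fn = 0L)
    for (s in scored) out <- out + extract(s)
    out
  }
  tier1 <- lapply(ENTITY_KINDS, function(k)
    sum3(function(s) s$tier1[k, ]))
  names(tier1) <- ENTITY_KINDS
  tier2 <- sum3(function(s) s$tier2)
  tier3 <- sum3(function(s) s$tier3)

  combined <- tier3
  if (!is.null(no_data_eval) && nrow(no_data_eval)) {
    for (i in seq_len(nrow(no_data_eval))) {
      if (no_data_eval$pred_status[i] == "NO_DATA") {
        combined[["tp"]] <- combined[["tp"]] + 1L
      } else {
        combined[["fn"]] <- combined[["fn"]] + 1L
        if (no_data_eval$pred_records[i] > 0)
          combined[["fp"]] <- combined[["fp"]] + 1L
      }
    }
  }

  structure(list(
    per_entity = lapply(tier1, function(x) c(pr(x), x)),
    tier2 = c(pr(tier2), tier2),
    tier3 = c(pr(tier3), tier3),
    combined_all_docs = c(pr(combined), combined)
  ), class = "tier_metrics")
}

#' @export
print.tier_metrics <- function(x, ...) {
  fmt <- function(v) {
    sprintf("P=%.3f R=%.3f (tp=%d fp=%d fn=%d)",
            v[["precision"]], v[["recall"]],
            v[["tp"]], v[["fp"]], v[["fn"]])
  }
  cat("Tier 1 (entity level)\n")
  for (k in names(x$per_entity)) {
    cat(sprintf("  %-10s %s\n", k, fmt(x$per_entity[[k]])))
  }
  cat("Tier 2 (ingredient level)\n  ", fmt(x$tier2), "\n", sep = "")
  cat("Tier 3 (document level)\n  ", fmt(x$tier3), "\n", sep = "")
  cat("All documents\n  ", fmt(x$combined_all_docs), "\n", sep = "")
  invisible(x)
}

#' Score a whole corpus of predictions against a gold manifest
#'
#' @param preds list of predicted `indexing_result`s
#' @param golds list of gold `indexing_result`s (same doc_ids)
#' @return `tier_metrics`
#' @export
evaluate_corpus <- function(preds, golds) {
  gold_ids <- vapply(golds, `[[`, "", "doc_id")
  pred_ids <- vapply(preds, `[[`, "", "doc_id")
  stopifnot(setequal(gold_ids, pred_ids))
  preds <- preds[match(gold_ids, pred_ids)]
  has_data <- vapply(golds, function(g) g$status != "NO_DATA", logical(1))
  scored <- mapply(score_document, preds[has_data], golds[has_data],
                   SIMPLIFY = FALSE)
  nd <- data.frame(
    pred_status = vapply(preds[!has_data], `[[`, "", "status"),
    pred_records = vapply(preds[!has_data], function(p)
      length(p$records), 0L),
    stringsAsFactors = FALSE)
  aggregate_scores(scored, nd)
}
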
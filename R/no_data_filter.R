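#' No-data filter
#'
#' Six to eight percent of real SDSs carry no composition information at
#' all (non-hazardous products supplied for liability reasons).  Rather
#' than letting the rest of the pipeline fail on them, a document-level
#' filter runs first: the preprocessed concatenated text of all pages is
#' split into fixed-size token chunks, each chunk is classified, and the
#' document is NO_DATA exactly when *every* chunk is predicted positive
#' (positive class = no ingredient information).  The chunk classifier is
#' pluggable; two implementations ship -- a deterministic rule classifier
#' (default) and a trainable bag-of-tokens linear model.
#'
#' @name no_data_filter
NULL

#' Split a document's token stream into fixed-size chunks
#'
#' Tokens of all pages are concatenated in page order and split greedily
#' into consecutive chunks of exactly `max_chunk_len` tokens, except the
#' last.  Chunks never overlap.
#'
#' @param pages list of preprocessed pages ([preprocess_page()] output)
#' @param max_chunk_len chunk size in tokens (>= 1); default 256
#' @return list of chunks: list(chunk_index (0-based), tokens)
#' @export
chunk_document <- function(pages, max_chunk_len = 256) {
  stopifnot(max_chunk_len >= 1)
  tokens <- unlist(lapply(pages, function(p) p$offset_map$token),
                   use.names = FALSE)
  if (!length(tokens)) return(list())
  idx <- split(seq_along(tokens),
               (seq_along(tokens) - 1L) %/% as.integer(max_chunk_len))
  lapply(seq_along(idx), function(i)
    list(chunk_index = i - 1L, tokens = tokens[idx[[i]]]))
}

#' Gold-label chunks from a gold indexing result
#'
#' A document with no gold ingredients labels every chunk positive.
#' Otherwise a chunk is negative (has data) iff its token span contains a
#' gold ingredient-name token, a gold CAS string, or a gold weight string,
#' all compared after the same preprocessing the chunk text went through.
#'
#' @param chunks from [chunk_document()]
#' @param gold a gold `indexing_result`
#' @param stopwords stopword set used during preprocessing
#' @return chunks with a `label` field ("POSITIVE_NO_DATA" /
#'   "NEGATIVE_HAS_DATA")
#' @export
label_chunks <- function(chunks, gold, stopwords = default_stopwords()) {
  if (length(gold$records) == 0) {
    return(lapply(chunks, function(ch) {
      ch$label <- "POSITIVE_NO_DATA"; ch
    }))
  }
  prep <- function(s) {
    p <- preprocess_page(list(page_number = 1, raw_text = s), stopwords)
    p$text
  }
  name_tokens <- unique(unlist(lapply(gold$records, function(r)
    strsplit(prep(r$name), " ")[[1]])))
  cas_strings <- unlist(lapply(gold$records, function(r)
    if (r$cas$kind == "NUMERIC") r$cas$raw
    else if (r$cas$kind == "SENTINEL") prep(r$cas$sentinel_text)))
  weight_strings <- unlist(lapply(gold$records, function(r)
    if (!is.na(r$weight$operator) && nzchar(r$weight$raw))
      prep(r$weight$raw)))
  needles <- c(cas_strings, weight_strings)
  needles <- needles[nzchar(needles)]
  lapply(chunks, function(ch) {
    txt <- paste(ch$tokens, collapse = " ")
    hit <- any(ch$tokens %in% name_tokens) ||
      any(vapply(needles, function(s) grepl(s, txt, fixed = TRUE),
                 logical(1)))
    ch$label <- if (hit) "NEGATIVE_HAS_DATA" else "POSITIVE_NO_DATA"
    ch
  })
}

#' Rule-based chunk classifier (default)
#'
#' A chunk has data iff it matches the CAS regex, an ingredient-label
#' pattern, or contains at least one gazetteer name.
#'
#' @param gazetteer lowercase name vector
#' @param patterns header/label pattern table
#' @return function(tokens) -> list(label, score)
#' @export
rule_chunk_classifier <- function(gazetteer = default_gazetteer(),
                                  patterns = load_header_patterns()) {
  recog <- gazetteer_recognizer(gazetteer)
  labels <- patterns$regex[patterns$kind == "LABEL"]
  function(tokens) {
    txt <- paste(tokens, collapse = " ")
    has <- grepl(CAS_REGEX, txt) ||
      any(vapply(labels, function(p) grepl(p, txt, perl = TRUE),
                 logical(1))) ||
      any(recog(tokens) != "OUTSIDE")
    list(label = if (has) "NEGATIVE_HAS_DATA" else "POSITIVE_NO_DATA",
         score = if (has) 1 else 0)
  }
}

#' Train a bag-of-tokens linear chunk classifier
#'
#' Ridge-penalised logistic regression (glmnet) on token-count features of
#' gold-labelled chunks.  Exists to exercise the train/predict plug-in path
#' of the filter; the rule classifier remains the default.
#'
#' @param chunks labelled chunks (from [label_chunks()]), pooled over a
#'   training corpus
#' @param min_count drop tokens seen fewer times than this
#' @return classifier function(tokens) -> list(label, score)
#' @export
train_chunk_classifier <- function(chunks, min_count = 2) {
  stopifnot(length(chunks) >= 4)
  y <- vapply(chunks, function(ch) ch$label == "NEGATIVE_HAS_DATA",
              logical(1))
  stopifnot(any(y), any(!y))
  vocab <- table(unlist(lapply(chunks, `[[`, "tokens")))
  vocab <- names(vocab[vocab >= min_count])
  stopifnot(length(vocab) >= 2)
  featurize <- function(tokens) {
    tab <- table(factor(tokens, levels = vocab))
    as.numeric(tab)
  }
  x <- do.call(rbind, lapply(chunks, function(ch) featurize(ch$tokens)))
  fit <- glmnet::glmnet(x, factor(y), family = "binomial", alpha = 0,
                        lambda = 0.01)
  function(tokens) {
    p <- as.numeric(stats::predict(fit, matrix(featurize(tokens), nrow = 1),
                                   type = "response"))
    list(label = if (p >= 0.5) "NEGATIVE_HAS_DATA" else "POSITIVE_NO_DATA",
         score = p)
  }
}

#' Aggregate chunk predictions into the document-level data status
#'
#' HAS_DATA iff at least one chunk is predicted negative (has data); an
#' empty chunk list is vacuously NO_DATA.  A classifier failure on any
#' chunk propagates as an error (the batch runner records the document as
#' FAILED); it is never silently treated as NO_DATA.
#'
#' @param chunks from [chunk_document()]
#' @param classifier function(tokens) -> list(label, score)
#' @return list(status = "HAS_DATA"/"NO_DATA", chunk_predictions)
#' @export
predict_document <- function(chunks, classifier = rule_chunk_classifier()) {
  preds <- lapply(chunks, function(ch) {
    p <- classifier(ch$tokens)
    stopifnot(p$label %in% c("POSITIVE_NO_DATA", "NEGATIVE_HAS_DATA"))
    p
  })
  has <- any(vapply(preds, function(p) p$label == "NEGATIVE_HAS_DATA",
                    logical(1)))
  list(status = if (has) "HAS_DATA" else "NO_DATA",
       chunk_predictions = preds)
}
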
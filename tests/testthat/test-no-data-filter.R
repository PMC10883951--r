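# Chunking, chunk labelling, and the any-chunk aggregation rule

fake_pages <- function(tokens) {
  list(list(page_number = 1,
            offset_map = data.frame(token = tokens,
                                    start = seq_along(tokens),
                                    end = seq_along(tokens))))
}

test_that("chunking splits the token stream greedily with no overlap", {
  ch <- chunk_document(fake_pages(letters[1:10]), max_chunk_len = 4)
  expect_identical(lengths(lapply(ch, `[[`, "tokens")), c(4L, 4L, 2L))
  expect_identical(unlist(lapply(ch, `[[`, "tokens")), letters[1:10])
  expect_identical(vapply(ch, `[[`, 0L, "chunk_index"), 0:2)

  expect_length(chunk_document(fake_pages(letters[1:4]), 4), 1)
  expect_length(chunk_document(list(), 4), 0)
})

test_that("chunks of a no-data document are all labelled positive", {
  gold <- indexing_result("d", "NO_DATA")
  ch <- label_chunks(chunk_document(fake_pages(letters[1:9]), 3), gold)
  expect_identical(vapply(ch, `[[`, "", "label"),
                   rep("POSITIVE_NO_DATA", 3))
})

test_that("a chunk is negative iff it contains gold name/CAS/weight text", {
  gold <- indexing_result("d", "INDEXED", list(
    ingredient_record("zinc oxide", parse_cas("1314-13-2"),
                      parse_weight("10-20"))))
  tokens <- c(letters[1:4],                       # chunk 0: nothing
              "zinc", "oxide", "1314-13-2", "x",  # chunk 1: the table
              letters[5:8])                       # chunk 2: nothing
  ch <- label_chunks(chunk_document(fake_pages(tokens), 4), gold)
  expect_identical(vapply(ch, `[[`, "", "label"),
                   c("POSITIVE_NO_DATA", "NEGATIVE_HAS_DATA",
                     "POSITIVE_NO_DATA"))
  # a name token alone (without the CAS) still marks its chunk negative
  ch2 <- label_chunks(chunk_document(fake_pages(c("zinc", letters[1:3])), 4),
                      gold)
  expect_identical(ch2[[1]]$label, "NEGATIVE_HAS_DATA")
})

test_that("document status is HAS_DATA iff any chunk is negative", {
  always <- function(lab) function(tokens) list(label = lab, score = 1)
  chunks <- chunk_document(fake_pages(letters[1:8]), 4)
  expect_identical(predict_document(chunks,
                                    always("POSITIVE_NO_DATA"))$status,
                   "NO_DATA")
  flip <- function(tokens)
    list(label = if ("a" %in% tokens) "POSITIVE_NO_DATA"
         else "NEGATIVE_HAS_DATA", score = 1)
  expect_identical(predict_document(chunks, flip)$status, "HAS_DATA")
  expect_identical(predict_document(list())$status, "NO_DATA")
})

test_that("flipping a chunk positive->negative never turns HAS_DATA off", {
  set.seed(404)
  for (i in 1:50) {
    k <- sample(1:8, 1)
    labs <- sample(c("POSITIVE_NO_DATA", "NEGATIVE_HAS_DATA"), k,
                   replace = TRUE)
    chunks <- lapply(seq_len(k), function(j)
      list(chunk_index = j - 1L, tokens = as.character(j)))
    clf <- function(tokens)
      list(label = labs[as.integer(tokens[1])], score = 1)
    before <- predict_document(chunks, clf)$status
    j <- sample.int(k, 1)
    labs[j] <- "NEGATIVE_HAS_DATA"
    after <- predict_document(chunks, clf)$status
    expect_false(before == "HAS_DATA" && after == "NO_DATA")
  }
})

test_that("oracle classifier (predict = gold label) recovers document status", {
  docs <- cached_corpus(20, seed = 31)
  for (d in docs) {
    path <- write_doc_pdf(d)
    prep <- lapply(extract_pages(path), preprocess_page)
    unlink(path)
    chunks <- label_chunks(chunk_document(prep, 64), d$gold)
    lab <- vapply(chunks, `[[`, "", "label")
    oracle <- local({
      i <- 0
      function(tokens) { i <<- i + 1; list(label = lab[i], score = 1) }
    })
    status <- predict_document(chunks, oracle)$status
    expect_identical(status == "NO_DATA", d$gold$status == "NO_DATA",
                     info = d$gold$doc_id)
  }
})

test_that("rule classifier matches the generator no-data flag, noise-free", {
  docs <- cached_corpus(40, seed = 32)
  clf <- rule_chunk_classifier()
  for (d in docs) {
    path <- write_doc_pdf(d)
    prep <- lapply(extract_pages(path), preprocess_page)
    unlink(path)
    status <- predict_document(chunk_document(prep, 256), clf)$status
    expect_identical(status == "NO_DATA", d$gold$status == "NO_DATA",
                     info = d$gold$doc_id)
  }
})

test_that("the trainable bag-of-tokens classifier learns the split", {
  docs <- cached_corpus(40, seed = 32)
  chunks <- list()
  for (d in docs) {
    path <- write_doc_pdf(d)
    prep <- lapply(extract_pages(path), preprocess_page)
    unlink(path)
    chunks <- c(chunks,
                label_chunks(chunk_document(prep, 64), d$gold))
  }
  clf <- train_chunk_classifier(chunks)
  preds <- vapply(chunks, function(ch) clf(ch$tokens)$label, "")
  gold <- vapply(chunks, `[[`, "", "label")
  expect_gt(mean(preds == gold), 0.9)
})
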
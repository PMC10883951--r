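# Shared fixtures: rendered documents and corpora are cached per call
# signature so expensive generation happens once per test run.

.fixture_env <- new.env(parent = emptyenv())

# write a rendered document's bytes to a temp PDF, return the path
write_doc_pdf <- function(doc) {
  path <- tempfile(fileext = ".pdf")
  writeBin(doc$pdf, path)
  path
}

# render + extract in one go
rendered_pages <- function(spec) {
  doc <- render_document(spec)
  path <- write_doc_pdf(doc)
  on.exit(unlink(path))
  list(doc = doc, pages = extract_pages(path))
}

cached_corpus <- function(n, seed, noise = character(0)) {
  key <- paste(n, seed, paste(sort(noise), collapse = "+"), sep = "|")
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_corpus(n, seed = seed, noise = noise)
  }
  .fixture_env[[key]]
}

index_rendered <- function(doc, config = sds_config()) {
  path <- write_doc_pdf(doc)
  on.exit(unlink(path))
  index_document(path, config, doc_id = doc$gold$doc_id)
}

# predictions for a corpus of rendered docs (isolated per document)
index_corpus <- function(docs, config = sds_config()) {
  lapply(docs, function(d) {
    tryCatch(index_rendered(d, config),
             error = function(e)
               indexing_result(d$gold$doc_id, "FAILED",
                               failure_reason = conditionMessage(e)))
  })
}

# ---- independent brute-force scorer (reference for the evaluation tests) ---
# Deliberately written in a different style from the package scorer: field
# extraction via loops and tables, tier 2 via exhaustive injective matching.

bf_fields <- function(rec) {
  wt <- rec$weight
  num <- function(x) {
    if (is.null(x) || length(x) == 0 || is.nan(x) || is.na(x)) return("NA")
    format(as.numeric(x), scientific = FALSE, trim = TRUE,
           drop0trailing = TRUE)
  }
  c(tolower(gsub("[[:space:]]+", " ", trimws(rec$name))),
    {
      cv <- format_cas(rec$cas)
      if (nzchar(cv)) tolower(cv) else "NA"
    },
    if (is.na(wt$operator)) "NA" else wt$operator,
    num(wt$upper), num(wt$lower))
}

bf_multiset <- function(p, g) {
  tp <- 0L
  used <- rep(FALSE, length(g))
  for (x in p) {
    for (k in seq_along(g)) {
      if (!used[k] && identical(g[k], x)) {
        used[k] <- TRUE; tp <- tp + 1L; break
      }
    }
  }
  c(tp = tp, fp = length(p) - tp, fn = length(g) - tp)
}

# exhaustive maximum matching under full-record equality
bf_tier2 <- function(pf, gf) {
  np <- length(pf); ng <- length(gf)
  best <- 0L
  recurse <- function(i, used, matched) {
    if (matched + (np - i + 1L) <= best && i <= np) return()
    if (i > np) { best <<- max(best, matched); return() }
    recurse(i + 1L, used, matched)  # leave pred i unmatched
    for (k in seq_len(ng)) {
      if (!used[k] && identical(pf[[i]], gf[[k]])) {
        used[k] <- TRUE
        recurse(i + 1L, used, matched + 1L)
        used[k] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, ng), 0L)
  c(tp = best, fp = np - best, fn = ng - best)
}

bf_score_document <- function(pred, gold) {
  pf <- lapply(pred$records, bf_fields)
  gf <- lapply(gold$records, bf_fields)
  kinds <- c("ingredient", "cas", "operator", "upper", "lower")
  tier1 <- matrix(0L, nrow = 5, ncol = 3,
                  dimnames = list(kinds, c("tp", "fp", "fn")))
  for (fi in 1:5) {
    tier1[fi, ] <- bf_multiset(vapply(pf, `[`, "", fi),
                               vapply(gf, `[`, "", fi))
  }
  tier2 <- bf_tier2(pf, gf)
  exact <- tier2[["fp"]] == 0L && tier2[["fn"]] == 0L &&
    pred$status == gold$status
  tier3 <- if (exact) c(tp = 1L, fp = 0L, fn = 0L)
  else if (length(pred$records) > 0L) c(tp = 0L, fp = 1L, fn = 1L)
  else c(tp = 0L, fp = 0L, fn = 1L)
  list(tier1 = tier1, tier2 = tier2, tier3 = tier3)
}

# small random indexing results over a tight value pool (to force clashes)
random_result <- function(doc_id, n_max = 4) {
  pool_names <- c("water", "acetone", "zinc oxide")
  pool_cas <- c("7732-18-5", "67-64-1", "1314-13-2")
  pool_wt <- list(weight_spec(10, 20, "-", "10-20"),
                  weight_spec(NaN, 10, "<", "<10"),
                  weight_spec(60, 60, "=", "60"),
                  parse_weight(""))
  k <- sample(0:n_max, 1)
  recs <- lapply(seq_len(k), function(i)
    ingredient_record(sample(pool_names, 1),
                      parse_cas(sample(pool_cas, 1)),
                      pool_wt[[sample.int(4, 1)]]))
  status <- if (k == 0) "FAILED" else "INDEXED"
  indexing_result(doc_id, status, recs,
                  failure_reason = if (k == 0) "none found" else NULL)
}
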
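#' Synthetic SDS generator
#'
#' Renders OSHA-style 16-section Safety Data Sheets as genuine text-based
#' PDFs together with their complete gold standard (records, pages,
#' regions, data status), deterministically from a seed.  The generator is
#' what makes every pipeline stage verifiable without proprietary data: the
#' renderer records its own geometry, so gold regions are exact, and the
#' gold records are the very values placed on the page.
#'
#' @name synthetic_data
NULL

SDS_MARGIN <- 36
SDS_FONT <- 10
SDS_LINE_H <- 14

section_titles <- function(format = c("modern_16_section",
                                      "legacy_section2")) {
  format <- match.arg(format)
  t <- c("IDENTIFICATION", "HAZARDS IDENTIFICATION",
         "COMPOSITION/INFORMATION ON INGREDIENTS", "FIRST-AID MEASURES",
         "FIRE-FIGHTING MEASURES", "ACCIDENTAL RELEASE MEASURES",
         "HANDLING AND STORAGE", "EXPOSURE CONTROLS/PERSONAL PROTECTION",
         "PHYSICAL AND CHEMICAL PROPERTIES", "STABILITY AND REACTIVITY",
         "TOXICOLOGICAL INFORMATION", "ECOLOGICAL INFORMATION",
         "DISPOSAL CONSIDERATIONS", "TRANSPORT INFORMATION",
         "REGULATORY INFORMATION", "OTHER INFORMATION")
  if (format == "legacy_section2") {
    t[2] <- "COMPOSITION/INFORMATION ON INGREDIENTS"
    t[3] <- "HAZARDS IDENTIFICATION"
  }
  t
}

# generic filler bodies; kept free of label vocabulary, vocabulary names,
# CAS-like digit groups and percent signs so a no-data document stays clean
section_bodies <- function() {
  list(
    c("Recommended use: industrial maintenance.",
      "Supplier: Example Supply Co, Springfield."),
    c("Signal word: warning.", "Causes serious eye irritation."),
    character(0),
    c("If inhaled: move person fresh air.",
      "Get medical advice if you feel unwell."),
    c("Suitable extinguishing media: foam, dry powder."),
    c("Avoid breathing vapours. Ventilate area."),
    c("Keep container tightly closed. Store locked up."),
    c("Ensure adequate ventilation.", "Wear protective gloves."),
    c("Appearance: clear liquid. Odour: mild."),
    c("Stable under normal conditions."),
    c("May cause irritation upon repeated skin contact."),
    c("Avoid release environment."),
    c("Dispose contents according local regulations."),
    c("Not classified dangerous goods transport."),
    c("Complies applicable inventory requirements."),
    c("Revision date: January 2023. End safety data sheet.")
  )
}

#' Build a generation spec for one synthetic document
#'
#' @param variant "normal", "no_data" or "single_ingredient"
#' @param n_ingredients ingredient count (normal variant)
#' @param orientation "row" or "column"
#' @param table_style "bordered", "borderless" or "free_text"
#' @param split_across_pages break the composition table across two pages
#' @param noise subset of "multiline_names", "unicode_dashes",
#'   "sentinel_cas", "tight_columns", "header_variants"
#' @param section_format "modern_16_section" or "legacy_section2"
#' @param seed integer seed for this document
#' @export
sds_spec <- function(variant = "normal", n_ingredients = 3,
                     orientation = "row", table_style = "borderless",
                     split_across_pages = FALSE, noise = character(0),
                     section_format = "modern_16_section", seed = 1L) {
  variant <- match.arg(variant, c("normal", "no_data", "single_ingredient"))
  orientation <- match.arg(orientation, c("row", "column"))
  table_style <- match.arg(table_style,
                           c("bordered", "borderless", "free_text"))
  section_format <- match.arg(section_format,
                              c("modern_16_section", "legacy_section2"))
  known_noise <- c("multiline_names", "unicode_dashes", "sentinel_cas",
                   "tight_columns", "header_variants")
  stopifnot(all(noise %in% known_noise), n_ingredients >= 1)
  if (split_across_pages && table_style == "free_text")
    stop("cannot split a free-text section across pages")
  if (variant == "normal" && orientation == "column" &&
      "multiline_names" %in% noise)
    noise <- setdiff(noise, "multiline_names")
  list(variant = variant, n_ingredients = as.integer(n_ingredients),
       orientation = orientation, table_style = table_style,
       split_across_pages = isTRUE(split_across_pages), noise = noise,
       section_format = section_format, seed = as.integer(seed))
}

#' Sample gold ingredient records from the packaged vocabulary
#'
#' Weight operators cycle through the five cases (range, lower bound,
#' upper bound, exact, none) so small samples already cover several kinds.
#' Every sampled CAS is checksum-valid because check digits are computed
#' from the registry segments.
#'
#' @param k number of ingredients
#' @param use_held_out draw from the held-out (non-gazetteer) slice instead
#' @param dash dash used to render ranges
#' @return list of gold `ingredient_record`s with a `render` attribute
#'   (name/cas/weight cell strings)
#' @export
sample_ingredients <- function(k, use_held_out = FALSE, dash = "-") {
  vocab <- chemical_vocabulary()
  vocab <- vocab[vocab$held_out == use_held_out, , drop = FALSE]
  rows <- vocab[sample.int(nrow(vocab), k), , drop = FALSE]
  ops <- rep(c("-", ">", "<", "=", NA_character_), length.out = max(k, 5))
  ops <- sample(ops)[seq_len(k)]
  ranges <- list(c(1, 5), c(5, 10), c(10, 20), c(10, 30), c(30, 60),
                 c(60, 100), c(0.1, 1), c(2.5, 7.5))
  singles <- c(60, 25, 99.5, 0.5, 12.5)
  out <- vector("list", k)
  for (i in seq_len(k)) {
    op <- ops[i]
    if (is.na(op)) {
      wt_raw <- ""
      wt <- parse_weight("")
    } else if (op == "-") {
      rg <- ranges[[sample.int(length(ranges), 1)]]
      wt_raw <- paste0(format(rg[1]), dash, format(rg[2]))
      wt <- weight_spec(rg[1], rg[2], "-", wt_raw)
    } else if (op == "<") {
      x <- sample(singles, 1)
      wt_raw <- paste0("<", format(x))
      wt <- weight_spec(NaN, x, "<", wt_raw)
    } else if (op == ">") {
      x <- sample(singles, 1)
      wt_raw <- paste0(">", format(x))
      wt <- weight_spec(x, NaN, ">", wt_raw)
    } else {
      x <- sample(singles, 1)
      wt_raw <- format(x)
      wt <- weight_spec(x, x, "=", wt_raw)
    }
    out[[i]] <- ingredient_record(rows$name[i], parse_cas(rows$cas[i]), wt)
    attr(out[[i]], "render") <- list(name = rows$name[i],
                                     cas = rows$cas[i], weight = wt_raw)
  }
  out
}

# ---- layout engine ---------------------------------------------------------

new_renderer <- function() {
  env <- new.env(parent = emptyenv())
  env$pages <- list()
  env$cur <- new_pdf_page()
  env$y <- SDS_MARGIN
  env
}

rd_flush_page <- function(rd) {
  rd$pages[[length(rd$pages) + 1L]] <- rd$cur
  rd$cur <- new_pdf_page()
  rd$y <- SDS_MARGIN
}

rd_page_number <- function(rd) length(rd$pages) + 1L

rd_ensure <- function(rd, height) {
  if (rd$y + height > PDF_PAGE_H - SDS_MARGIN) rd_flush_page(rd)
}

# place one text line at the cursor; returns its (page, x, y)
rd_line <- function(rd, text, x = SDS_MARGIN, extra_gap = 0) {
  rd_ensure(rd, SDS_LINE_H)
  pos <- list(page = rd_page_number(rd), x = x, y = rd$y)
  if (nzchar(text)) rd$cur <- page_add_text(rd$cur, x, rd$y, text, SDS_FONT)
  rd$y <- rd$y + SDS_LINE_H + extra_gap
  pos
}

# place one multi-cell line; cells = data.frame(x, text); returns bbox
rd_cells <- function(rd, cells) {
  rd_ensure(rd, SDS_LINE_H)
  page <- rd_page_number(rd)
  x1 <- -Inf
  for (i in seq_len(nrow(cells))) {
    if (!nzchar(cells$text[i])) next
    rd$cur <- page_add_text(rd$cur, cells$x[i], rd$y, cells$text[i],
                            SDS_FONT)
    x1 <- max(x1, cells$x[i] + pdf_text_width(cells$text[i], SDS_FONT))
  }
  bbox <- list(page = page, x0 = min(cells$x), x1 = x1,
               y0 = rd$y, y1 = rd$y + SDS_FONT)
  rd$y <- rd$y + SDS_LINE_H
  bbox
}

# ---- composition-section builders ------------------------------------------

# table display lines: list of data.frames(col, text); row-oriented
table_display_rows <- function(records, header, multiline_rows) {
  lines <- list(data.frame(col = seq_along(header), text = header,
                           stringsAsFactors = FALSE))
  row_of_line <- 0L  # header marker
  for (i in seq_along(records)) {
    rn <- attr(records[[i]], "render")
    if (i %in% multiline_rows) {
      toks <- strsplit(rn$name, " ")[[1]]
      head_name <- paste(toks[1], collapse = " ")
      rest <- paste(toks[-1], collapse = " ")
      lines[[length(lines) + 1L]] <- data.frame(
        col = 1:3, text = c(head_name, rn$cas, rn$weight),
        stringsAsFactors = FALSE)
      lines[[length(lines) + 1L]] <- data.frame(
        col = 1L, text = rest, stringsAsFactors = FALSE)
      row_of_line <- c(row_of_line, i, i)
    } else {
      lines[[length(lines) + 1L]] <- data.frame(
        col = 1:3, text = c(rn$name, rn$cas, rn$weight),
        stringsAsFactors = FALSE)
      row_of_line <- c(row_of_line, i)
    }
  }
  attr(lines, "row_of_line") <- row_of_line
  lines
}

# column x positions for a set of display lines
table_column_x <- function(lines, n_cols, gap_pt, x0 = SDS_MARGIN) {
  widths <- numeric(n_cols)
  for (ln in lines) {
    for (i in seq_len(nrow(ln))) {
      w <- pdf_text_width(ln$text[i], SDS_FONT)
      widths[ln$col[i]] <- max(widths[ln$col[i]], w)
    }
  }
  xs <- numeric(n_cols)
  xs[1] <- x0
  for (c in seq_len(n_cols - 1)) xs[c + 1] <- xs[c] + widths[c] + gap_pt
  xs
}

# render a block of display lines as one table fragment; returns its bbox
render_fragment <- function(rd, lines, col_x, bordered = FALSE) {
  bb <- NULL
  for (ln in lines) {
    cells <- data.frame(x = col_x[ln$col], text = ln$text,
                        stringsAsFactors = FALSE)
    b <- rd_cells(rd, cells)
    if (is.null(bb)) bb <- b
    bb$x0 <- min(bb$x0, b$x0); bb$x1 <- max(bb$x1, b$x1)
    bb$y0 <- min(bb$y0, b$y0); bb$y1 <- max(bb$y1, b$y1)
  }
  if (bordered) {
    rd$cur <- page_add_rect(rd$cur, bb$x0 - 4, bb$y0 - 3,
                            bb$x1 + 4, bb$y1 + 3)
  }
  bb
}

# ---- document renderer -----------------------------------------------------

#' Render one synthetic SDS document
#'
#' @param spec a spec from [sds_spec()]
#' @param doc_id document identifier for the gold result
#' @return list with `pdf` (raw bytes), `gold` (`indexing_result`),
#'   `gold_pages`, `gold_regions` (list of region boxes), `product_name`,
#'   `spec`
#' @export
render_document <- function(spec, doc_id = "doc") {
  set.seed(spec$seed)
  titles <- section_titles(spec$section_format)
  bodies <- section_bodies()
  comp_idx <- if (spec$section_format == "legacy_section2") 2L else 3L

  records <- list()
  product <- NULL
  if (spec$variant == "normal") {
    k <- spec$n_ingredients
    if (spec$orientation == "column") k <- max(k, 1L)
    dash <- if ("unicode_dashes" %in% spec$noise) "–" else "-"
    records <- sample_ingredients(k, dash = dash)
    if ("sentinel_cas" %in% spec$noise && k >= 1) {
      j <- sample.int(k, 1)
      rn <- attr(records[[j]], "render")
      rn$cas <- "Trade Secret"
      records[[j]]$cas <- parse_cas("Trade Secret")
      attr(records[[j]], "render") <- rn
    }
    product <- paste("multi purpose product",
                     sample(c("alpha", "beta", "gamma", "delta"), 1))
  } else if (spec$variant == "single_ingredient") {
    one <- sample_ingredients(1)
    rn <- attr(one[[1]], "render")
    # force a numeric CAS and no weight: the product record carries only
    # the Section 1 CAS
    records <- list(ingredient_record(rn$name, parse_cas(rn$cas),
                                      parse_weight("")))
    product <- rn$name
  } else {
    product <- paste("mild cleaning spray",
                     sample(c("alpha", "beta", "gamma", "delta"), 1))
  }

  rd <- new_renderer()
  gold_regions <- list()
  gold_pages <- integer(0)

  render_section_header <- function(k) {
    if ("header_variants" %in% spec$noise && k == comp_idx) {
      rd_line(rd, sprintf("%d. Composition and Information on Ingredients",
                          k), extra_gap = 2)
    } else if ("header_variants" %in% spec$noise && titles[k] ==
               "FIRST-AID MEASURES") {
      rd_line(rd, sprintf("%d. First Aid Measures", k), extra_gap = 2)
    } else {
      rd_line(rd, sprintf("SECTION %d: %s", k, titles[k]), extra_gap = 2)
    }
  }

  render_composition <- function() {
    gap <- if ("tight_columns" %in% spec$noise) 12 else 18
    if (spec$table_style == "free_text") {
      n_lines <- 2L + length(records) + 1L
      rd_ensure(rd, n_lines * SDS_LINE_H + 2)
      hdr <- render_section_header(comp_idx)
      rd_line(rd, "The product contains the following substances:")
      for (r in records) {
        rn <- attr(r, "render")
        wt_txt <- if (nzchar(rn$weight)) {
          w <- r$weight
          if (identical(w$operator, "-"))
            sprintf(" at %s - %s %% by weight", format(w$lower),
                    format(w$upper))
          else if (identical(w$operator, "<"))
            sprintf(" at < %s %% by weight", format(w$upper))
          else if (identical(w$operator, ">"))
            sprintf(" at > %s %% by weight", format(w$lower))
          else sprintf(" at %s %% by weight", format(w$lower))
        } else ""
        rd_line(rd, sprintf("contains %s (cas no. %s)%s.", rn$name, rn$cas,
                            wt_txt))
      }
      list(kind = "SECTION", header_pos = hdr)
    } else {
      header <- if ("header_variants" %in% spec$noise)
        c("Ingredient Name", "CAS Number", "Concentration (%)")
      else c("Chemical Name", "CAS No.", "Wt.%")
      if (spec$orientation == "row") {
        multiline <- integer(0)
        if ("multiline_names" %in% spec$noise && length(records) >= 2) {
          multi_tok <- which(vapply(records, function(r)
            length(strsplit(attr(r, "render")$name, " ")[[1]]) >= 2,
            logical(1)))
          multi_tok <- setdiff(multi_tok, length(records))
          if (length(multi_tok)) multiline <- multi_tok[1]
        }
        lines <- table_display_rows(records, header, multiline)
        col_x <- table_column_x(lines, 3, gap)
        row_of_line <- attr(lines, "row_of_line")
        if (spec$split_across_pages) {
          k <- length(records)
          r1 <- ceiling(k / 2)
          part1 <- lines[row_of_line <= r1]
          part2 <- c(lines[1], lines[row_of_line > r1])
          rd_ensure(rd, (length(part1) + 1) * SDS_LINE_H + 2)
          render_section_header(comp_idx)
          b1 <- render_fragment(rd, part1, col_x,
                                spec$table_style == "bordered")
          rd_flush_page(rd)
          b2 <- render_fragment(rd, part2, col_x,
                                spec$table_style == "bordered")
          list(kind = "TABLE", bboxes = list(b1, b2))
        } else {
          rd_ensure(rd, (length(lines) + 2) * SDS_LINE_H + 2)
          render_section_header(comp_idx)
          b <- render_fragment(rd, lines, col_x,
                               spec$table_style == "bordered")
          list(kind = "TABLE", bboxes = list(b))
        }
      } else {
        labels <- paste0(header, ":")
        render_col_lines <- function(recs) {
          vals <- lapply(recs, attr, "render")
          l1 <- data.frame(col = seq_len(length(recs) + 1),
                           text = c(labels[1],
                                    vapply(vals, `[[`, "", "name")),
                           stringsAsFactors = FALSE)
          l2 <- data.frame(col = seq_len(length(recs) + 1),
                           text = c(labels[2],
                                    vapply(vals, `[[`, "", "cas")),
                           stringsAsFactors = FALSE)
          wt <- vapply(vals, `[[`, "", "weight")
          l3 <- data.frame(col = seq_len(length(recs) + 1),
                           text = c(labels[3], wt),
                           stringsAsFactors = FALSE)
          list(l1, l2, l3)
        }
        if (spec$split_across_pages && length(records) >= 2) {
          k <- length(records)
          r1 <- ceiling(k / 2)
          part1 <- render_col_lines(records[seq_len(r1)])
          part2 <- render_col_lines(records[(r1 + 1):k])
          rd_ensure(rd, 5 * SDS_LINE_H + 2)
          render_section_header(comp_idx)
          b1 <- render_fragment(rd, part1,
                                table_column_x(part1, r1 + 1, gap),
                                spec$table_style == "bordered")
          rd_flush_page(rd)
          b2 <- render_fragment(rd, part2,
                                table_column_x(part2, k - r1 + 1, gap),
                                spec$table_style == "bordered")
          list(kind = "TABLE", bboxes = list(b1, b2))
        } else {
          lines <- render_col_lines(records)
          rd_ensure(rd, 5 * SDS_LINE_H + 2)
          render_section_header(comp_idx)
          b <- render_fragment(rd, lines,
                               table_column_x(lines,
                                              length(records) + 1, gap),
                               spec$table_style == "bordered")
          list(kind = "TABLE", bboxes = list(b))
        }
      }
    }
  }

  comp_info <- NULL
  sec4_pos <- NULL
  for (k in 1:16) {
    if (k == comp_idx && spec$variant == "normal") {
      comp_info <- render_composition()
      next
    }
    hdr_pos <- render_section_header(k)
    if (k == 1) {
      rd_line(rd, sprintf("Product name: %s", product))
      if (spec$variant == "single_ingredient") {
        rd_line(rd, sprintf("CAS number: %s",
                            attr(records[[1]], "cas_raw") %||%
                              format_cas(records[[1]]$cas)))
      }
      for (b in bodies[[1]]) rd_line(rd, b)
    } else if (k == comp_idx) {
      if (spec$variant == "no_data") {
        rd_line(rd, "This product contains no constituents requiring disclosure.")
      } else {
        rd_line(rd, "Single-substance product. Refer Section 1 details.")
      }
    } else {
      body_idx <- if (spec$section_format == "legacy_section2" &&
                      k %in% 2:3) 5L - k else k
      for (b in bodies[[body_idx]]) rd_line(rd, b)
    }
    if (!is.null(comp_info) && is.null(sec4_pos) && k > comp_idx) {
      sec4_pos <- hdr_pos
    }
  }
  rd_flush_page(rd)

  # gold regions and pages
  if (spec$variant == "normal") {
    if (comp_info$kind == "TABLE") {
      for (b in comp_info$bboxes) {
        gold_regions[[length(gold_regions) + 1L]] <-
          region_box(b$page, b$x0, b$y0, b$x1, b$y1, kind = "TABLE")
      }
    } else {
      hp <- comp_info$header_pos
      y1 <- if (!is.null(sec4_pos) && sec4_pos$page == hp$page)
        sec4_pos$y else PDF_PAGE_H
      gold_regions[[length(gold_regions) + 1L]] <-
        region_box(hp$page, 0, hp$y, PDF_PAGE_W, y1, kind = "SECTION")
    }
    gold_pages <- sort(unique(vapply(gold_regions, `[[`, 0, "page_number")))
    gold <- indexing_result(doc_id, "INDEXED", records)
  } else if (spec$variant == "single_ingredient") {
    gold_pages <- 1L
    gold <- indexing_result(doc_id, "SINGLE_INGREDIENT_FALLBACK", records)
  } else {
    gold <- indexing_result(doc_id, "NO_DATA")
  }

  list(pdf = pdf_build(rd$pages), gold = gold, gold_pages = gold_pages,
       gold_regions = gold_regions, product_name = product, spec = spec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The standard noise profile
#' @export
standard_noise_profile <- function() {
  c("multiline_names", "unicode_dashes", "sentinel_cas", "tight_columns")
}

#' Generate a seeded corpus of synthetic SDS documents
#'
#' The default mix is 80% normal documents cycling through all
#' bordered/borderless x row/column x split/unsplit combinations, 10%
#' no-data documents and 10% single-ingredient documents.
#'
#' @param n number of documents
#' @param seed corpus seed; each document derives its own sub-seed
#' @param mix named proportions over variants (must sum to 1)
#' @param noise noise set applied to the normal-variant documents
#' @param outdir directory for PDFs and `manifest.jsonl`; NULL keeps the
#'   corpus in memory only
#' @return list of rendered documents (invisibly when written to disk)
#' @export
generate_corpus <- function(n, seed = 1L,
                            mix = c(normal = 0.8, no_data = 0.1,
                                    single_ingredient = 0.1),
                            noise = character(0), outdir = NULL) {
  stopifnot(abs(sum(mix) - 1) < 1e-8, n >= 1)
  set.seed(seed)
  variants <- rep(names(mix), round(mix * n))
  while (length(variants) < n) variants <- c(variants, names(mix)[1])
  variants <- variants[seq_len(n)]
  combos <- expand.grid(style = c("bordered", "borderless"),
                        orient = c("row", "column"),
                        split = c(FALSE, TRUE),
                        stringsAsFactors = FALSE)
  ci <- 0L
  docs <- vector("list", n)
  for (i in seq_len(n)) {
    doc_seed <- as.integer((as.numeric(seed) * 1000 + i) %% 2147483647)
    v <- variants[i]
    if (v == "normal") {
      ci <- ci + 1L
      cb <- combos[((ci - 1L) %% nrow(combos)) + 1L, ]
      spec <- sds_spec(variant = "normal",
                       n_ingredients = sample(2:5, 1),
                       orientation = cb$orient, table_style = cb$style,
                       split_across_pages = cb$split, noise = noise,
                       seed = doc_seed)
    } else {
      spec <- sds_spec(variant = v, seed = doc_seed)
    }
    docs[[i]] <- render_document(spec, doc_id = sprintf("doc_%04d", i))
  }
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    manifest <- file(file.path(outdir, "manifest.jsonl"), "w")
    for (d in docs) {
      pdf_path <- file.path(outdir, paste0(d$gold$doc_id, ".pdf"))
      writeBin(d$pdf, pdf_path)
      writeLines(jsonlite::toJSON(manifest_entry(d, pdf_path),
                                  auto_unbox = TRUE, digits = NA,
                                  null = "null"), manifest)
    }
    close(manifest)
    return(invisible(docs))
  }
  docs
}

# ---- manifest (de)serialisation --------------------------------------------

record_to_list <- function(r) {
  list(name = r$name, cas = format_cas(r$cas),
       weight_lower = if (is.nan(r$weight$lower)) NULL else r$weight$lower,
       weight_upper = if (is.nan(r$weight$upper)) NULL else r$weight$upper,
       weight_operator = if (is.na(r$weight$operator)) NULL
       else r$weight$operator,
       weight_raw = r$weight$raw)
}

list_to_record <- function(l) {
  num <- function(x) if (is.null(x)) NaN else as.numeric(x)
  op <- if (is.null(l$weight_operator)) NA_character_ else l$weight_operator
  ingredient_record(l$name, parse_cas(l$cas),
                    weight_spec(num(l$weight_lower), num(l$weight_upper),
                                op, l$weight_raw %||% ""))
}

manifest_entry <- function(doc, pdf_path) {
  list(doc_id = doc$gold$doc_id, pdf_path = pdf_path,
       status = doc$gold$status,
       product_name = doc$product_name,
       gold_records = lapply(doc$gold$records, record_to_list),
       gold_pages = doc$gold_pages,
       gold_regions = lapply(doc$gold_regions, function(b)
         list(page = b$page_number, x0 = b$x0, y0 = b$y0, x1 = b$x1,
              y1 = b$y1, kind = b$kind)),
       spec = doc$spec[setdiff(names(doc$spec), "noise")])
}

#' Read a gold manifest back into indexing results
#'
#' @param path manifest.jsonl written by [generate_corpus()]
#' @return list of entries, each with `gold` (`indexing_result`),
#'   `pdf_path`, `gold_pages`, `gold_regions`
#' @export
read_manifest <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lapply(lines, function(ln) {
    l <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    records <- lapply(l$gold_records, list_to_record)
    gold <- indexing_result(l$doc_id, l$status, records)
    regions <- lapply(l$gold_regions, function(b)
      region_box(b$page, b$x0, b$y0, b$x1, b$y1, kind = b$kind))
    list(doc_id = l$doc_id, pdf_path = l$pdf_path, gold = gold,
         gold_pages = unlist(l$gold_pages) %||% integer(0),
         gold_regions = regions, product_name = l$product_name)
  })
}
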
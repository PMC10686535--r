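test_that("sentence segmentation covers non-whitespace text and keeps offsets", {
  expect_equal(nrow(segment_sentences("")), 0)
  sp <- segment_sentences("No nodule. Effusion seen.")
  expect_equal(nrow(sp), 2)
  expect_equal(sp$start, c(0L, 11L))
  expect_equal(sp$end, c(10L, 25L))
  # concatenating spans reconstructs the text minus inter-span whitespace
  txt <- "one. two.\nthree"
  sp <- segment_sentences(txt)
  joined <- paste(substring(txt, sp$start + 1L, sp$end), collapse = "")
  expect_equal(joined, gsub("(?<=[.\n])\\s+", "", txt, perl = TRUE))
  # Japanese terminator
  expect_equal(nrow(segment_sentences("異常なし。結節あり。")), 2)
})

test_that("default tokenizer yields offset-faithful tokens", {
  t <- default_tokenizer("a 3 cm nodule, right-sided.")
  expect_equal(t$text, c("a", "3", "cm", "nodule", ",", "right", "-",
                         "sided", "."))
  expect_true(all(substring("a 3 cm nodule, right-sided.",
                            t$start + 1L, t$end) == t$text))
})

test_that("IOB2 encoding follows the B/I/O convention", {
  toks <- make_tokens(c("a", "pleural", "effusion", "is", "seen"))
  expect_equal(as.character(encode_iob2(toks, empty_ents <- data.frame(
    id = character(), type = character(), start = integer(),
    end = integer(), text = character()))), rep("O", 5))
  ent <- data.frame(id = "T1", type = "Observation",
                    start = toks$start[2], end = toks$end[3],
                    text = "pleural effusion", stringsAsFactors = FALSE)
  expect_equal(as.character(encode_iob2(toks, ent)),
               c("O", "B-Observation", "I-Observation", "O", "O"))
  # overlap cannot be represented
  ent2 <- rbind(ent, data.frame(id = "T2", type = "Size",
                                start = toks$start[3], end = toks$end[4],
                                text = "effusion is"))
  expect_error(encode_iob2(toks, ent2), "overlap")
})

test_that("misaligned entity boundaries split tokens during encoding", {
  toks <- make_tokens(c("12mm", "nodule"))
  ent <- data.frame(id = "T1", type = "Size", start = 0L, end = 2L,
                    text = "12", stringsAsFactors = FALSE)
  tags <- encode_iob2(toks, ent)
  toks2 <- attr(tags, "tokens")
  expect_equal(nrow(toks2), 3)
  expect_equal(toks2$text, c("12", "mm", "nodule"))
  expect_equal(as.character(tags), c("B-Size", "O", "O"))
  expect_error(encode_iob2(toks, ent, on_misaligned = "error"), "inside")
})

test_that("IOB2 decoding inverts encoding and repairs orphan I tags", {
  toks <- make_tokens(c("x", "y", "z"))
  expect_equal(nrow(decode_iob2(toks, rep("O", 3))), 0)
  e <- decode_iob2(toks, c("B-Size", "I-Size", "O"))
  expect_equal(e$type, "Size")
  expect_equal(e$start, 0L)
  expect_equal(e$end, 3L)
  # orphan I-Change after O is promoted to B-Change
  e2 <- decode_iob2(toks, c("O", "I-Change", "O"))
  expect_equal(e2$type, "Change")
  expect_equal(e2$start, toks$start[2])
  expect_equal(e2$end, toks$end[2])
  expect_error(decode_iob2(toks, c("O", "O")), "one tag per token")
})

test_that("random span sets round-trip through IOB2 exactly", {
  set.seed(42)
  types <- entity_types()$name
  for (case in 1:400) {
    n <- sample(3:12, 1)
    toks <- make_tokens(replicate(n, paste(sample(letters, 3), collapse = "")))
    # random non-overlapping token-aligned spans
    n_ent <- sample(0:3, 1)
    free <- seq_len(n)
    ents <- list()
    for (k in seq_len(n_ent)) {
      if (length(free) == 0) break
      a <- free[sample.int(length(free), 1)]
      len <- sample(1:2, 1)
      b <- min(a + len - 1L, n)
      if (!all(a:b %in% free)) b <- a
      ents[[length(ents) + 1L]] <- data.frame(
        id = paste0("T", k), type = sample(types, 1),
        start = toks$start[a], end = toks$end[b], text = NA_character_,
        stringsAsFactors = FALSE)
      free <- setdiff(free, a:b)
    }
    ent <- if (length(ents)) do.call(rbind, ents) else
      data.frame(id = character(), type = character(), start = integer(),
                 end = integer(), text = character())
    tags <- encode_iob2(toks, ent)
    dec <- decode_iob2(toks, as.character(tags))
    ent <- ent[order(ent$start), , drop = FALSE]
    expect_equal(dec$type, ent$type)
    expect_equal(dec$start, ent$start)
    expect_equal(dec$end, ent$end)
  }
})

test_that("BRAT standoff documents parse with validation", {
  text <- "a large nodule in the liver."
  ann <- paste(
    "T1\tObservation 8 14\tnodule",
    "T2\tAnatomicalLocation 22 27\tliver",
    "R1\tModifier Arg1:T1 Arg2:T2",
    sep = "\n")
  r <- read_brat(text, ann, id = "x")
  expect_equal(r$entities$type, c("Observation", "AnatomicalLocation"))
  expect_equal(r$entities$text, c("nodule", "liver"))
  expect_equal(r$relations$type, "Modifier")
  # offset outside the text
  expect_error(read_brat("short.", "T1\tObservation 2 99\tx", "x"),
               "outside")
  # text mismatch
  expect_error(read_brat(text, "T1\tObservation 0 1\tz", "x"), "mismatch")
  # schema-violating relation reports its line
  ann_bad <- paste(
    "T1\tSize 2 7\tlarge",
    "T2\tObservation 8 14\tnodule",
    "R1\tModifier Arg1:T1 Arg2:T2",
    sep = "\n")
  expect_error(read_brat(text, ann_bad, "x"), "line 3")
  # unknown type name
  expect_error(read_brat(text, "T1\tGadget 8 14\tnodule", "x"),
               "unknown entity type")
  # attribute lines are ignored with a warning
  expect_warning(read_brat(text, paste(
    "T1\tObservation 8 14\tnodule", "A1\tNegated T1", sep = "\n"), "x"),
    "unsupported")
})

test_that("write_brat emits one T-line per entity and round-trips", {
  empty <- rad_report("e", "nothing to see.")
  doc <- write_brat(empty)
  expect_equal(doc$ann, "")
  r <- tiny_report()
  doc <- write_brat(r)
  expect_equal(sum(grepl("^T", strsplit(doc$ann, "\n")[[1]])), 4)
  r2 <- read_brat(doc$text, doc$ann, id = r$id)
  expect_equal(r2$entities[, c("type", "start", "end", "text")],
               r$entities[, c("type", "start", "end", "text")])
  expect_equal(relation_table(list(r2)), relation_table(list(r)))
})

test_that("generated corpora survive a BRAT directory round trip", {
  corpus <- generate_corpus(generator_config(n_reports = 6, seed = 11))
  dir <- withr::local_tempdir()
  write_brat_dir(corpus, dir, manifest = list(seed = 11))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_brat_dir(dir)
  expect_equal(length(back), length(corpus))
  for (i in seq_along(corpus)) {
    expect_equal(back[[i]]$text, corpus[[i]]$text)
    expect_equal(back[[i]]$entities[, c("type", "start", "end", "text")],
                 corpus[[i]]$entities[, c("type", "start", "end", "text")])
    expect_equal(relation_table(back[i]), relation_table(corpus[i]))
  }
})

test_that("CoNLL export pairs each token with its tag", {
  lines <- export_conll(tiny_report())
  expect_true("nodule\tB-Observation" %in% lines)
  expect_true("12\tB-Size" %in% lines)
  expect_true("mm\tI-Size" %in% lines)
  expect_equal(sum(lines == ""), 2)  # one blank line per sentence
})
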
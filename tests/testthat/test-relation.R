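small_rel_hp <- function(...) {
  args <- list(embedding_dim = 16, hidden_dim = 16, max_epochs = 4,
               max_len = 32, batch_size = 16, seed = 7)
  args[names(list(...))] <- list(...)
  do.call(rel_hyperparams, args)
}

test_that("report concatenation preserves order and offsets", {
  r <- tiny_report()
  toks <- concatenate_report(r)
  expect_equal(toks$text[1:2], c("a", "nodule"))
  # sentence lengths add up
  lens <- vapply(r$sentences, function(s) nrow(s$tokens), integer(1))
  expect_equal(nrow(toks), sum(lens))
  expect_equal(toks$sentence, rep(seq_along(lens), lens))
  # offset map inverts token index to character span
  expect_true(all(substring(r$text, toks$start + 1L, toks$end) == toks$text))
})

test_that("entity tokens are contiguous in the concatenated sequence", {
  corpus <- generate_corpus(generator_config(n_reports = 10, seed = 23))
  for (r in corpus) {
    toks <- concatenate_report(r)
    for (i in seq_len(nrow(r$entities))) {
      rng <- radrelex:::entity_token_range(toks, r$entities$start[i],
                                           r$entities$end[i])
      expect_false(is.null(rng))
    }
  }
})

test_that("candidate enumeration follows the all-pairs rule", {
  # 2 observations + 3 modifiers, no findings -> 6 candidates
  text <- "nodule mass suspected increased irregular."
  ents <- data.frame(
    id = paste0("T", 1:5),
    type = c("Observation", "Observation", "Certainty", "Change",
             "Characteristics"),
    start = c(0L, 7L, 12L, 22L, 32L),
    end = c(6L, 11L, 21L, 31L, 41L), stringsAsFactors = FALSE)
  ents$text <- substring(text, ents$start + 1L, ents$end)
  r <- rad_report("fig4", text, ents)
  cand <- generate_candidates(r)
  expect_equal(nrow(cand), 6)
  expect_true(all(cand$rel_type == "Modifier"))
  # 2 OBS + 1 CLN + 2 SIZE -> Modifier (2+1)*2 = 6, Evidence 2*1 = 2
  text2 <- "nodule mass cancer 3 cm 5 mm."
  ents2 <- data.frame(
    id = paste0("T", 1:5),
    type = c("Observation", "Observation", "ClinicalFinding", "Size",
             "Size"),
    start = c(0L, 7L, 12L, 19L, 24L),
    end = c(6L, 11L, 18L, 23L, 28L), stringsAsFactors = FALSE)
  ents2$text <- substring(text2, ents2$start + 1L, ents2$end)
  r2 <- rad_report("x", text2, ents2)
  cand2 <- generate_candidates(r2)
  expect_equal(sum(cand2$rel_type == "Modifier"), 6)
  expect_equal(sum(cand2$rel_type == "Evidence"), 2)
  expect_equal(nrow(cand2), 8)
  # no admissible pairs -> no candidates
  r3 <- rad_report("y", "text.", NULL)
  expect_equal(nrow(generate_candidates(r3)), 0)
})

test_that("candidate counts equal the closed-form formula corpus-wide", {
  corpus <- generate_corpus(generator_config(n_reports = 25, seed = 31))
  for (r in corpus) {
    tab <- table(factor(r$entities$type, levels = entity_types()$name))
    concepts <- tab[["Observation"]] + tab[["ClinicalFinding"]]
    modifiers <- sum(tab[radrelex:::modifier_types()])
    expected <- concepts * modifiers +
      tab[["Observation"]] * tab[["ClinicalFinding"]]
    expect_equal(nrow(generate_candidates(r)), as.integer(expected))
  }
})

test_that("gold labels transfer onto candidates", {
  r <- tiny_report()
  cand <- generate_candidates(r)
  expect_equal(sum(cand$label), nrow(r$relations))
  key <- paste(cand$rel_type, cand$head, cand$tail)
  expect_true(all(paste(r$relations$type, r$relations$head,
                        r$relations$tail) %in% key[cand$label]))
})

test_that("candidate encoding inserts exactly four paired markers", {
  r <- tiny_report()
  toks <- concatenate_report(r)
  he <- r$entities[1, ]  # nodule (Observation)
  te <- r$entities[3, ]  # right upper lobe (AnatomicalLocation)
  enc <- encode_candidate(toks, he, te)
  expect_equal(sum(enc %in% c("<OBS>", "</OBS>", "<AE>", "</AE>")), 4)
  o <- match(c("<OBS>", "</OBS>", "<AE>", "</AE>"), enc)
  expect_true(all(diff(o) > 0))
  expect_equal(enc[o[1] + 1L], "nodule")
  # adjacent entities: close-head then open-tail with nothing between
  he2 <- r$entities[1, ]; te2 <- r$entities[2, ]  # nodule, then "12 mm"
  enc2 <- encode_candidate(toks, he2, te2)
  i <- match("</OBS>", enc2)
  expect_equal(enc2[i + 1L], "measuring")
  # removing the markers recovers a contiguous subsequence of the input
  markers <- marker_vocabulary()
  stripped <- enc[!(enc %in% c(markers$open, markers$close))]
  full <- toks$text
  hit <- which(full == stripped[1])
  ok <- any(vapply(hit, function(h)
    h + length(stripped) - 1L <= length(full) &&
      all(full[h:(h + length(stripped) - 1L)] == stripped), logical(1)))
  expect_true(ok)
})

test_that("marker stripping recovers contiguous text for random candidates", {
  corpus <- generate_corpus(generator_config(n_reports = 6, seed = 41))
  markers <- marker_vocabulary()
  for (r in corpus) {
    toks <- concatenate_report(r)
    cand <- generate_candidates(r)
    if (nrow(cand) == 0) next
    for (k in sample(nrow(cand), min(10, nrow(cand)))) {
      he <- r$entities[r$entities$id == cand$head[k], ]
      te <- r$entities[r$entities$id == cand$tail[k], ]
      enc <- encode_candidate(toks, he, te, markers, max_len = 256)
      expect_false(is.null(enc))
      expect_lte(length(enc), 256)
      stripped <- enc[!(enc %in% c(markers$open, markers$close))]
      joined <- paste(stripped, collapse = "\r")
      expect_true(grepl(joined, paste(toks$text, collapse = "\r"),
                        fixed = TRUE))
    }
  }
})

test_that("pairs that cannot fit the window are rejected, not truncated", {
  toks <- make_tokens(c("a", sprintf("w%02d", 1:40), "b"))
  he <- data.frame(type = "Observation", start = toks$start[1],
                   end = toks$end[1])
  te <- data.frame(type = "Size", start = toks$start[42],
                   end = toks$end[42])
  expect_null(encode_candidate(toks, he, te, max_len = 16))
  enc <- encode_candidate(toks, he, te, max_len = 64)
  expect_equal(length(enc), 46)
})

test_that("a corpus where every candidate is positive trains to all-positive", {
  corpus <- all_positive_corpus(24, seed = 5)
  m <- train_rel(corpus[1:20], corpus[21:24], small_rel_hp())
  for (r in corpus[21:24]) {
    sc <- candidate_scores(m, r)
    expect_true(all(sc$score >= 0.5))
  }
  expect_equal(m$class_balance[["neg"]], 0)
})

test_that("training requires positive candidates", {
  r <- rad_report("n", "nodule suspected.", data.frame(
    id = c("T1", "T2"), type = c("Observation", "Certainty"),
    start = c(0L, 7L), end = c(6L, 16L),
    text = c("nodule", "suspected"), stringsAsFactors = FALSE))
  expect_error(train_rel(list(r), list(r), small_rel_hp()), "positive")
})

test_that("negatives outnumber positives on the default synthetic corpus", {
  corpus <- generate_corpus(generator_config(n_reports = 10, seed = 51))
  labels <- unlist(lapply(corpus, function(r) generate_candidates(r)$label))
  expect_gt(sum(!labels), sum(labels))
})

test_that("predicted relations are schema-valid candidate subsets", {
  corpus <- all_positive_corpus(12, seed = 9)
  m <- train_rel(corpus[1:10], corpus[11:12], small_rel_hp())
  r <- corpus[[11]]
  rel <- predict_relations(m, r)
  cand <- generate_candidates(r)
  expect_true(all(paste(rel$type, rel$head, rel$tail) %in%
                  paste(cand$rel_type, cand$head, cand$tail)))
  r$relations <- rel[, c("id", "type", "head", "tail")]
  expect_silent(validate_report(r))
  # no entities -> no relations
  expect_equal(nrow(predict_relations(m, rad_report("e", "text."))), 0)
})

test_that("raising the threshold never increases predicted relations", {
  corpus <- all_positive_corpus(12, seed = 3)
  m <- train_rel(corpus[1:10], corpus[11:12], small_rel_hp(max_epochs = 2))
  r <- corpus[[11]]
  counts <- vapply(seq(0, 1, by = 0.1), function(th)
    nrow(predict_relations(m, r, threshold = th)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("attention weights are a probability distribution per candidate", {
  corpus <- all_positive_corpus(10, seed = 13)
  m <- train_rel(corpus[1:8], corpus[9:10], small_rel_hp(max_epochs = 1))
  sc <- candidate_scores(m, corpus[[9]], attention = TRUE)
  attn <- attr(sc, "attention")
  expect_equal(length(attn), nrow(sc))
  for (a in attn) {
    if (is.null(a)) next
    expect_true(all(a >= 0))
    expect_equal(sum(a), 1, tolerance = 1e-6)
  }
})

test_that("relation training is deterministic under a fixed seed", {
  corpus <- all_positive_corpus(10, seed = 1)
  m1 <- train_rel(corpus[1:8], corpus[9:10], small_rel_hp(max_epochs = 2))
  m2 <- train_rel(corpus[1:8], corpus[9:10], small_rel_hp(max_epochs = 2))
  expect_identical(m1$log, m2$log)
  expect_identical(m1$params, m2$params)
})
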
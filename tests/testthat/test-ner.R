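# Small training runs keep this file fast: tiny hidden sizes, few epochs.

small_ner_hp <- function(...) {
  args <- list(embedding_dim = 16, hidden_dim = 16, max_epochs = 5,
               seed = 7)
  args[names(list(...))] <- list(...)
  do.call(ner_hyperparams, args)
}

test_that("training reduces the loss and rejects bad inputs", {
  corpus <- generate_corpus(generator_config(n_reports = 3, seed = 21))
  m <- train_ner(corpus, corpus, small_ner_hp())
  expect_lt(m$log$loss[nrow(m$log)], m$log$loss[1])
  expect_error(train_ner(list(), corpus, small_ner_hp()), "empty")
})

test_that("a memorized report is reproduced exactly", {
  corpus <- generate_corpus(generator_config(n_reports = 1, seed = 33))
  m <- train_ner(corpus, corpus,
                 small_ner_hp(embedding_dim = 24, hidden_dim = 32,
                              batch_size = 4, max_epochs = 60))
  pred <- predict_entities(m, corpus[[1]])
  gold <- corpus[[1]]$entities
  expect_equal(pred[, c("type", "start", "end")],
               gold[order(gold$start), c("type", "start", "end")],
               ignore_attr = TRUE)
})

test_that("predictions satisfy the span invariants on unseen reports", {
  corpus <- generate_corpus(generator_config(n_reports = 8, seed = 13))
  m <- train_ner(corpus[1:6], corpus[7:8], small_ner_hp(max_epochs = 3))
  for (r in corpus[7:8]) {
    pred <- predict_entities(m, r)
    r2 <- r
    r2$entities <- pred
    r2$relations <- radrelex:::empty_relations()
    expect_silent(validate_report(r2))
  }
  # an empty report predicts no entities
  empty <- rad_report("e", "")
  expect_equal(nrow(predict_entities(m, empty)), 0)
})

test_that("training is deterministic given seed, corpus and settings", {
  corpus <- generate_corpus(generator_config(n_reports = 4, seed = 17))
  m1 <- train_ner(corpus[1:3], corpus[4], small_ner_hp(max_epochs = 3))
  m2 <- train_ner(corpus[1:3], corpus[4], small_ner_hp(max_epochs = 3))
  expect_identical(m1$log, m2$log)
  expect_identical(m1$params, m2$params)
})

test_that("the plateau schedule decays the learning rate as specified", {
  state <- list(best = -Inf, wait = 0L, lr = 0.1, improved = FALSE)
  f1s <- c(0.5, 0.6, 0.6, 0.6, 0.6, 0.7, 0.7, 0.7, 0.7)
  lrs <- numeric(0)
  for (f in f1s) {
    state <- radrelex:::plateau_update(state, f, patience = 3,
                                       factor = 0.5, floor = 1e-4)
    lrs <- c(lrs, state$lr)
  }
  # decay fires after 3 consecutive non-improving epochs, then again
  expect_equal(lrs, c(0.1, 0.1, 0.1, 0.1, 0.05, 0.05, 0.05, 0.05, 0.025))
  # floor is respected
  st <- list(best = 1, wait = 0L, lr = 1.5e-4, improved = FALSE)
  for (i in 1:6) st <- radrelex:::plateau_update(st, 0, 1, 0.5, 1e-4)
  expect_equal(st$lr, 1e-4)
})

test_that("pretrained embeddings are loaded and validated", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "vecs.txt")
  writeLines(c("3 4", "nodule 1 0 0 0", "mass 0 1 0 0", "liver 0 0 1 0"), f)
  emb <- read_embeddings(f)
  expect_equal(emb$tokens, c("nodule", "mass", "liver"))
  expect_equal(dim(emb$vectors), c(3, 4))
  corpus <- generate_corpus(generator_config(n_reports = 2, seed = 2))
  expect_error(
    train_ner(corpus, corpus, small_ner_hp(embedding_dim = 8),
              pretrained_embeddings = emb),
    "does not match")
  m <- train_ner(corpus, corpus, small_ner_hp(embedding_dim = 4,
                                              max_epochs = 1),
                 pretrained_embeddings = emb)
  i <- match("nodule", m$vocab)
  if (!is.na(i)) expect_true(is.numeric(m$params$E[i, ]))
})

test_that("model checkpoints survive a save/load round trip", {
  corpus <- generate_corpus(generator_config(n_reports = 2, seed = 4))
  m <- train_ner(corpus, corpus, small_ner_hp(max_epochs = 1))
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  expect_s3_class(m2, "ner_model")
  expect_identical(m$params, m2$params)
  expect_identical(predict_entities(m, corpus[[1]]),
                   predict_entities(m2, corpus[[1]]))
})

test_that("hard-constraint decoding never emits invalid IOB2 bigrams", {
  bad <- radrelex:::invalid_iob2_transitions(ner_tagset())
  expect_false(bad[match("B-Size", ner_tagset()),
                   match("I-Size", ner_tagset())])
  expect_true(bad[match("O", ner_tagset()), match("I-Size", ner_tagset())])
  expect_true(bad[match("I-Change", ner_tagset()),
                  match("I-Size", ner_tagset())])
  corpus <- generate_corpus(generator_config(n_reports = 4, seed = 27))
  m <- train_ner(corpus[1:3], corpus[4],
                 small_ner_hp(max_epochs = 1, hard_constraints = TRUE))
  # decode with adversarial transitions: masking must still forbid the
  # invalid bigrams regardless of what was learned
  m$params$trans[] <- 3
  for (r in corpus) {
    ids <- lapply(r$sentences, function(s)
      radrelex:::tokens_to_ids(s$tokens$text, m$vocab))
    params <- m$params
    params$trans[bad] <- -Inf
    paths <- radrelex:::cpp_ner_predict(params, ids)
    for (p in paths) {
      tags <- m$tagset[as.integer(p)]
      if (length(tags) < 2) next
      for (k in 2:length(tags)) {
        if (startsWith(tags[k], "I-")) {
          ty <- substring(tags[k], 3)
          expect_true(tags[k - 1] %in% paste0(c("B-", "I-"), ty))
        }
      }
    }
  }
})

test_that("hyperparameter validation catches invalid settings", {
  expect_error(ner_hyperparams(dropout = 1), "dropout")
  expect_error(ner_hyperparams(hidden_dim = 0), "positive")
})
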
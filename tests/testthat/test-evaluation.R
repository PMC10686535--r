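test_that("entity F1 handles identity, emptiness and partial credit", {
  g <- data.frame(report_id = "r", type = c("Observation", "Size", "Change"),
                  start = c(0L, 10L, 20L), end = c(5L, 15L, 25L),
                  stringsAsFactors = FALSE)
  expect_equal(entity_f1(g, g)$micro[["f1"]], 1)
  empty <- g[0, ]
  expect_equal(entity_f1(g, empty)$micro[["f1"]], 0)
  # {A, B, C} vs {A, B-with-wrong-end, D}: TP=1, FP=2, FN=2
  p <- data.frame(report_id = "r", type = c("Observation", "Size", "Certainty"),
                  start = c(0L, 10L, 30L), end = c(5L, 17L, 35L),
                  stringsAsFactors = FALSE)
  m <- entity_f1(g, p)
  expect_equal(m$micro[["tp"]], 1)
  expect_equal(m$micro[["fp"]], 2)
  expect_equal(m$micro[["fn"]], 2)
  expect_equal(m$micro[["precision"]], 1 / 3)
  expect_equal(m$micro[["recall"]], 1 / 3)
  expect_equal(m$micro[["f1"]], 1 / 3)
  # matching is one-to-one: a duplicated prediction counts once
  p2 <- g[c(1, 1), ]
  m2 <- entity_f1(g, p2)
  expect_equal(m2$micro[["tp"]], 1)
  expect_equal(m2$micro[["fp"]], 1)
})

test_that("micro-F1 equals pooled counts and an independent oracle", {
  set.seed(77)
  types <- entity_types()$name
  for (case in 1:100) {
    n_g <- sample(0:12, 1); n_p <- sample(0:12, 1)
    mk <- function(n) {
      s <- sample(seq(0, 50, by = 5), n, replace = TRUE)
      data.frame(report_id = sample(c("a", "b"), n, TRUE),
                 type = sample(types, n, TRUE), start = s,
                 end = s + sample(1:5, n, TRUE), stringsAsFactors = FALSE)
    }
    g <- mk(n_g); p <- mk(n_p)
    m <- entity_f1(g, p)
    # micro from pooled per-class counts
    expect_equal(m$micro[["tp"]], sum(m$per_class$tp))
    expect_equal(m$micro[["fp"]], sum(m$per_class$fp))
    expect_equal(m$micro[["fn"]], sum(m$per_class$fn))
    if (n_g + n_p > 0) {
      expect_equal(m$micro[["f1"]], oracle_micro_f1(g, p), tolerance = 1e-12)
    }
  }
})

test_that("relation F1 matches types and exact endpoint spans", {
  r <- tiny_report()
  expect_equal(relation_f1(list(r), list(r))$micro[["f1"]], 1)
  # one endpoint boundary wrong: that relation is FP plus its gold FN
  bad <- r
  bad$entities$end[2] <- bad$entities$end[2] + 1L  # Size span shifted
  bad$entities$text <- substring(bad$text, bad$entities$start + 1L,
                                 bad$entities$end)
  m <- relation_f1(list(r), list(bad), mode = "pipeline")
  expect_equal(m$micro[["tp"]], 2)
  expect_equal(m$micro[["fp"]], 1)
  expect_equal(m$micro[["fn"]], 1)
  # modifier classes are reported by tail entity type
  cls <- relation_f1(list(r), list(r))$per_class$class
  expect_setequal(cls, c("Modifier: Size", "Modifier: AnatomicalLocation",
                         "Evidence: ClinicalFinding"))
})

test_that("coverage counts tagged tokens and applies exclusions", {
  expect_equal(coverage_from_counts(7050, 0, 10036 - 7050), 70.2,
               tolerance = 0.05)
  expect_equal(coverage_from_counts(6595, 0, 6853 - 6595), 96.2,
               tolerance = 0.05)
  expect_true(is.na(coverage_from_counts(0, 0, 0)))
  # a fully annotated corpus has 100% coverage
  r <- read_brat("nodule liver.", paste(
    "T1\tObservation 0 6\tnodule", "T2\tAnatomicalLocation 7 12\tliver",
    sep = "\n"), "full")
  cov <- coverage(list(r), stop_words = character(0))
  expect_equal(cov$filtered$coverage, 100)
  expect_equal(cov$entire$o, 1)  # the period
  # the tiny fixture: arithmetic cross-check against hand counts
  cv <- coverage(list(tiny_report()))
  ann <- cv$entire$b + cv$entire$i
  expect_equal(cv$entire$coverage,
               100 * ann / (ann + cv$entire$o), tolerance = 1e-12)
  expect_gte(cv$filtered$coverage, cv$entire$coverage)
})

test_that("out-of-scope sentences contribute no coverage tokens", {
  corpus <- generate_corpus(generator_config(n_reports = 30, seed = 19))
  cov_flag <- coverage(corpus, exclude = "flag")
  cov_none <- coverage(corpus, exclude = NULL)
  expect_gt(cov_flag$excluded_sentences, 0)
  tot_flag <- cov_flag$entire$b + cov_flag$entire$i + cov_flag$entire$o
  tot_none <- cov_none$entire$b + cov_none$entire$i + cov_none$entire$o
  expect_lt(tot_flag, tot_none)
  # annotated counts unchanged: out-of-scope sentences carry no entities
  expect_equal(cov_flag$entire$b + cov_flag$entire$i,
               cov_none$entire$b + cov_none$entire$i)
  # filtered variant is never below the entire-sequence variant here,
  # since generated entity tokens are neither punctuation nor stop words
  expect_gte(cov_flag$filtered$coverage, cov_flag$entire$coverage)
  # pattern-based exclusion works on raw corpora
  cov_pat <- coverage(corpus, exclude = c("^Plain and contrast",
                                          "recommended"))
  expect_gt(cov_pat$excluded_sentences, 0)
})

test_that("Cohen's kappa matches hand computation and edge cases", {
  a <- c(rep(TRUE, 50), rep(FALSE, 50))
  expect_equal(cohen_kappa(a, a), 1)
  # table TP=40 FN=10 FP=10 TN=40: p_o = 0.8, p_e = 0.5, kappa = 0.6
  x <- c(rep(TRUE, 40), rep(TRUE, 10), rep(FALSE, 10), rep(FALSE, 40))
  y <- c(rep(TRUE, 40), rep(FALSE, 10), rep(TRUE, 10), rep(FALSE, 40))
  expect_equal(cohen_kappa(x, y), 0.6)
  # independent labels: kappa near zero
  set.seed(123)
  expect_lt(abs(cohen_kappa(runif(20000) < 0.3, runif(20000) < 0.3)), 0.05)
  # degenerate marginals
  expect_warning(k <- cohen_kappa(rep(TRUE, 5), rep(TRUE, 5)),
                 "degenerate")
  expect_true(is.na(k))
  expect_error(cohen_kappa(TRUE, logical(0)), "same")
})

test_that("major/minor split partitions by training mention frequency", {
  train <- list(
    rad_report("t1", "nodule nodule nodule mass.", data.frame(
      id = paste0("T", 1:4), type = "Observation",
      start = c(0L, 7L, 14L, 21L), end = c(6L, 13L, 20L, 25L),
      text = c("nodule", "nodule", "nodule", "mass"),
      stringsAsFactors = FALSE)))
  test_c <- list(
    rad_report("s1", "nodule mass cyst.", data.frame(
      id = paste0("T", 1:3), type = "Observation",
      start = c(0L, 7L, 12L), end = c(6L, 11L, 16L),
      text = c("nodule", "mass", "cyst"), stringsAsFactors = FALSE)))
  mm <- major_minor_split(train, test_c)
  expect_equal(mm$major$text, "nodule")       # 3 occurrences -> major
  expect_setequal(mm$minor$text, c("mass", "cyst"))  # 1 and 0 -> minor
  expect_equal(nrow(mm$major) + nrow(mm$minor), 3)
})

test_that("stratified F1 assigns predictions by the same frequency rule", {
  train <- list(
    rad_report("t1", "nodule nodule.", data.frame(
      id = c("T1", "T2"), type = "Observation", start = c(0L, 7L),
      end = c(6L, 13L), text = c("nodule", "nodule"),
      stringsAsFactors = FALSE)))
  gold <- data.frame(report_id = "s", type = "Observation",
                     start = c(0L, 10L), end = c(6L, 14L),
                     text = c("nodule", "cyst"), stringsAsFactors = FALSE)
  pred <- gold[1, ]
  mm <- major_minor_f1(train, gold, pred)
  expect_equal(mm$major$micro[["f1"]], 1)
  expect_equal(mm$minor$micro[["f1"]], 0)
})
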
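# Evaluation: strict entity-level and relation-level micro/per-type F1,
# annotation coverage, Cohen's kappa, and frequency-stratified
# (major/minor mention) error analysis.

#' Collect the entity table of a corpus
#'
#' @param x A list of reports, a single report, or an entity data frame
#'   that already has a `report_id` column.
#' @return Entity data frame with a `report_id` column.
#' @export
entity_table <- function(x) {
  if (is.data.frame(x)) {
    stopifnot("report_id" %in% names(x))
    return(x)
  }
  if (inherits(x, "rad_report")) x <- list(x)
  rows <- lapply(x, function(r) {
    e <- r$entities
    if (nrow(e) == 0) return(NULL)
    e$report_id <- r$id
    e
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(cbind(empty_entities(),
                                      report_id = character(0)))
  do.call(rbind, rows)
}

# relations of a corpus joined with their endpoint spans
relation_table <- function(x) {
  if (inherits(x, "rad_report")) x <- list(x)
  rows <- lapply(x, function(r) {
    rel <- r$relations
    if (nrow(rel) == 0) return(NULL)
    ent <- r$entities
    hi <- match(rel$head, ent$id)
    ti <- match(rel$tail, ent$id)
    data.frame(report_id = r$id, type = rel$type,
               head_type = ent$type[hi], head_start = ent$start[hi],
               head_end = ent$end[hi], tail_type = ent$type[ti],
               tail_start = ent$start[ti], tail_end = ent$end[ti],
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(data.frame(report_id = character(), type = character(),
                      head_type = character(), head_start = integer(),
                      head_end = integer(), tail_type = character(),
                      tail_start = integer(), tail_end = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# one-to-one key matching: per duplicated key, min(gold, pred) matches
match_counts <- function(gold_keys, pred_keys, gold_class, pred_class) {
  classes <- sort(unique(c(gold_class, pred_class)))
  tp <- fp <- fn <- stats::setNames(integer(length(classes)), classes)
  for (cl in classes) {
    g <- table(gold_keys[gold_class == cl])
    p <- table(pred_keys[pred_class == cl])
    common <- intersect(names(g), names(p))
    ntp <- sum(pmin(as.integer(g[common]), as.integer(p[common])))
    tp[cl] <- ntp
    fn[cl] <- sum(g) - ntp
    fp[cl] <- sum(p) - ntp
  }
  list(tp = tp, fp = fp, fn = fn)
}

metrics_from_counts <- function(tp, fp, fn) {
  prf <- function(tp, fp, fn) {
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(precision = p, recall = r, f1 = f)
  }
  per_class <- data.frame(class = names(tp), tp = as.integer(tp),
                          fp = as.integer(fp), fn = as.integer(fn),
                          stringsAsFactors = FALSE)
  pc <- t(mapply(function(a, b, c) prf(a, b, c), tp, fp, fn))
  per_class <- cbind(per_class, as.data.frame(pc))
  rownames(per_class) <- NULL
  micro <- c(prf(sum(tp), sum(fp), sum(fn)),
             tp = sum(tp), fp = sum(fp), fn = sum(fn))
  structure(list(per_class = per_class, micro = micro),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  df <- x$per_class
  df$precision <- sprintf("%.1f", 100 * df$precision)
  df$recall <- sprintf("%.1f", 100 * df$recall)
  df$f1 <- sprintf("%.1f", 100 * df$f1)
  print(df, row.names = FALSE)
  cat(sprintf("Microaverage: P %.1f  R %.1f  F1 %.1f  (TP %d FP %d FN %d)\n",
              100 * x$micro["precision"], 100 * x$micro["recall"],
              100 * x$micro["f1"], as.integer(x$micro["tp"]),
              as.integer(x$micro["fp"]), as.integer(x$micro["fn"])))
  invisible(x)
}

#' Entity-level F1
#'
#' A predicted entity is a true positive iff an unmatched gold entity in
#' the same report has the identical type and exact character span
#' (strict matching, no partial-overlap credit); matching is one-to-one.
#' Results are reported per entity type and pooled (microaveraged).
#'
#' @param gold,predicted Corpora (lists of reports) or entity data frames
#'   with a `report_id` column.
#' @return A `metrics_report` (fields `per_class`, `micro`; scores are
#'   fractions in `[0, 1]`).
#' @export
entity_f1 <- function(gold, predicted) {
  g <- entity_table(gold)
  p <- entity_table(predicted)
  key <- function(d) paste(d$report_id, d$start, d$end, sep = "\r")
  metrics_from_counts2(match_counts(key(g), key(p), g$type, p$type))
}

metrics_from_counts2 <- function(m) metrics_from_counts(m$tp, m$fp, m$fn)

#' Relation-level F1
#'
#' A predicted relation is a true positive iff its type matches and both
#' endpoint entities exactly match a gold entity (type and character span)
#' of a gold relation of that type. Modifier relations are reported by the
#' tail (modifier) entity type; Evidence relations as a single class.
#' `mode` records whether predictions reference gold entities or the
#' pipeline's predicted entities (the computation is identical; in pipeline
#' mode endpoint mismatches simply surface as FP/FN pairs).
#'
#' @param gold,predicted Corpora whose reports carry entities and
#'   relations.
#' @param mode `"gold_entities"` or `"pipeline"`.
#' @return A `metrics_report`.
#' @export
relation_f1 <- function(gold, predicted,
                        mode = c("gold_entities", "pipeline")) {
  mode <- match.arg(mode)
  g <- relation_table(gold)
  p <- relation_table(predicted)
  key <- function(d) paste(d$report_id, d$type, d$head_type, d$head_start,
                           d$head_end, d$tail_type, d$tail_start,
                           d$tail_end, sep = "\r")
  cls <- function(d) ifelse(d$type == "Evidence",
                            paste0("Evidence: ", d$tail_type),
                            paste0("Modifier: ", d$tail_type))
  out <- metrics_from_counts2(match_counts(key(g), key(p), cls(g), cls(p)))
  attr(out, "mode") <- mode
  out
}

#' Annotation coverage of a corpus
#'
#' The fraction of tokens inside annotated entity spans,
#' `(B + I) / (B + I + O) * 100` over the corpus's IOB2 encoding. Sentences
#' flagged (or classified) as out of scope -- imaging technique, surgical
#' procedure, recommendations -- contribute no tokens. Reported both over
#' the entire remaining sequence and with punctuation and stop-word tokens
#' excluded from all counts.
#'
#' @param corpus List of annotated reports.
#' @param stop_words Character vector of stop-word tokens (compared
#'   case-insensitively); defaults to the bundled list.
#' @param exclude Out-of-scope sentence rule: `"flag"` (default) uses the
#'   per-sentence flags carried by synthetic reports, a function of the
#'   sentence text returning `TRUE` to exclude, a character vector of
#'   regular expressions, or `NULL` for no exclusion.
#' @return A list of class `coverage_counts`: per-scope counts `b`, `i`,
#'   `o` and `coverage` (percentage, `NA` when no eligible tokens remain),
#'   plus `excluded_sentences` and `excluded_tokens`.
#' @export
coverage <- function(corpus, stop_words = radrelex_stopwords(),
                     exclude = "flag") {
  cnt <- c(b = 0L, i = 0L, o = 0L)
  fcnt <- c(b = 0L, i = 0L, o = 0L)
  excl_sent <- 0L; excl_tok <- 0L
  stop_words <- tolower(stop_words)
  for (r in corpus) {
    for (si in seq_along(r$sentences)) {
      s <- r$sentences[[si]]
      drop <- if (is.null(exclude)) FALSE
        else if (identical(exclude, "flag")) isTRUE(r$oos[si])
        else if (is.function(exclude))
          isTRUE(exclude(substring(r$text, s$start + 1L, s$end)))
        else any(vapply(exclude, function(p)
          grepl(p, substring(r$text, s$start + 1L, s$end)), logical(1)))
      if (drop) { excl_sent <- excl_sent + 1L; next }
      tags <- encode_iob2(s$tokens, sentence_entities(r, s))
      toks <- attr(tags, "tokens")
      kind <- ifelse(startsWith(tags, "B-"), "b",
                     ifelse(startsWith(tags, "I-"), "i", "o"))
      for (k in c("b", "i", "o")) cnt[k] <- cnt[k] + sum(kind == k)
      is_punct <- grepl("^[\\p{P}\\p{S}]+$", toks$text, perl = TRUE)
      is_stop <- tolower(toks$text) %in% stop_words
      keep <- !(is_punct | is_stop)
      excl_tok <- excl_tok + sum(!keep)
      for (k in c("b", "i", "o")) fcnt[k] <- fcnt[k] + sum(kind[keep] == k)
    }
  }
  pct <- function(x) {
    tot <- sum(x)
    if (tot == 0) return(NA_real_)
    100 * (x["b"] + x["i"]) / tot
  }
  structure(list(
    entire = list(b = cnt[["b"]], i = cnt[["i"]], o = cnt[["o"]],
                  coverage = unname(pct(cnt))),
    filtered = list(b = fcnt[["b"]], i = fcnt[["i"]], o = fcnt[["o"]],
                    coverage = unname(pct(fcnt))),
    excluded_sentences = excl_sent, excluded_tokens = excl_tok
  ), class = "coverage_counts")
}

#' @export
print.coverage_counts <- function(x, ...) {
  row <- function(nm, s) {
    ann <- s$b + s$i; tot <- ann + s$o
    cat(sprintf("%-36s %d/%d (%s)\n", nm, ann, tot,
                if (is.na(s$coverage)) "undefined"
                else sprintf("%.1f", s$coverage)))
  }
  cat("Coverage of annotated tokens\n")
  row("Entire sequence", x$entire)
  row("Without punctuations and stop words", x$filtered)
  cat(sprintf("Excluded: %d sentences, %d tokens\n",
              x$excluded_sentences, x$excluded_tokens))
  invisible(x)
}

#' Coverage percentage from raw tag counts
#'
#' @param b_tagged,i_tagged,o_tagged Token counts by IOB2 tag kind.
#' @return The coverage percentage `(B + I) / (B + I + O) * 100`; `NA` when
#'   the denominator is zero.
#' @examples
#' coverage_from_counts(7050, 0, 2986)  # 70.2
#' @export
coverage_from_counts <- function(b_tagged, i_tagged, o_tagged) {
  tot <- b_tagged + i_tagged + o_tagged
  if (tot == 0) return(NA_real_)
  100 * (b_tagged + i_tagged) / tot
}

#' The bundled stop-word list
#'
#' One token per line; used by [coverage()] to exclude function words from
#' the filtered variant. Users may supply their own list instead.
#'
#' @return Character vector of stop words.
#' @export
radrelex_stopwords <- function() {
  readLines(system.file("extdata", "stopwords.txt", package = "radrelex"),
            encoding = "UTF-8")
}

#' Cohen's kappa for binary inter-annotator agreement
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o` and
#' chance agreement `p_e` from the 2x2 contingency table of the two
#' annotators' binary labels over the same candidate set.
#'
#' @param annotator_a,annotator_b Logical vectors of equal length.
#' @return The kappa statistic; `NA` (with a warning) when the marginals
#'   are degenerate (`p_e = 1`).
#' @export
cohen_kappa <- function(annotator_a, annotator_b) {
  a <- as.logical(annotator_a); b <- as.logical(annotator_b)
  if (length(a) != length(b) || length(a) == 0) {
    stop("annotators must label the same non-empty candidate set",
         call. = FALSE)
  }
  n <- length(a)
  po <- mean(a == b)
  pe <- mean(a) * mean(b) + mean(!a) * mean(!b)
  if (abs(1 - pe) < .Machine$double.eps^0.5) {
    warning("degenerate marginals: chance agreement is 1, kappa undefined",
            call. = FALSE)
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Split test entities into major and minor mention subsets
#'
#' A gold test entity is *major* when its exact surface string occurs at
#' least twice among the training annotations and *minor* when it occurs
#' at most once (including never). The two subsets partition the test
#' entities.
#'
#' @param train_corpus,test_corpus Annotated corpora.
#' @return A list with entity data frames `major` and `minor` and the
#'   training mention frequency table `train_counts`.
#' @export
major_minor_split <- function(train_corpus, test_corpus) {
  train_counts <- table(entity_table(train_corpus)$text)
  test <- entity_table(test_corpus)
  n_train <- as.integer(train_counts[test$text])
  n_train[is.na(n_train)] <- 0L
  list(major = test[n_train >= 2L, , drop = FALSE],
       minor = test[n_train <= 1L, , drop = FALSE],
       train_counts = train_counts)
}

#' Entity F1 stratified by training mention frequency
#'
#' Both gold and predicted test entities are assigned to the major or minor
#' stratum by the training frequency of their surface string, and strict
#' entity F1 is computed within each stratum.
#'
#' @param train_corpus Training corpus (defines mention frequencies).
#' @param gold_test Gold test corpus or entity table.
#' @param pred_test Predicted test entities (corpus or table; entity `text`
#'   must be filled).
#' @return List of two `metrics_report`s, `major` and `minor`.
#' @export
major_minor_f1 <- function(train_corpus, gold_test, pred_test) {
  train_counts <- table(entity_table(train_corpus)$text)
  stratum <- function(d) {
    n <- as.integer(train_counts[d$text])
    n[is.na(n)] <- 0L
    ifelse(n >= 2L, "major", "minor")
  }
  g <- entity_table(gold_test); g$stratum <- stratum(g)
  p <- entity_table(pred_test); p$stratum <- stratum(p)
  lapply(stats::setNames(c("major", "minor"), c("major", "minor")),
         function(s) {
           entity_f1(g[g$stratum == s, , drop = FALSE],
                     p[p$stratum == s, , drop = FALSE])
         })
}
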
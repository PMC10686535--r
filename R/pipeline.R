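# End-to-end orchestration: dataset splitting, the two-stage predict
# pipeline, structured-record output, and the multi-seed experiment driver.

#' Split a corpus into training, development and test sets
#'
#' Report-level, disjoint and exhaustive. Development and test sizes are
#' the floor of their ratios; the remainder goes to training (so 540
#' reports at 0.7/0.1/0.2 give 378/54/108). When reports carry a source
#' tag (e.g. chest vs abdomen), each stratum is split independently and
#' the parts pooled.
#'
#' @param corpus List of reports.
#' @param ratios Numeric train/dev/test ratios, positive, summing to 1.
#' @param seed Shuffle seed.
#' @return List with elements `train`, `dev`, `test`.
#' @export
split_corpus <- function(corpus, ratios = c(0.7, 0.1, 0.2), seed = 1L) {
  if (length(ratios) != 3 || any(ratios <= 0) ||
      abs(sum(ratios) - 1) > 1e-9) {
    stop("ratios must be three positive numbers summing to 1",
         call. = FALSE)
  }
  if (length(corpus) < 3) {
    stop("need at least 3 reports to split", call. = FALSE)
  }
  src <- vapply(corpus, function(r)
    if (is.null(r$source) || is.na(r$source)) "" else r$source,
    character(1))
  out <- list(train = list(), dev = list(), test = list())
  with_seed(seed, {
    for (s in unique(src)) {
      idx <- which(src == s)
      idx <- idx[sample.int(length(idx))]
      n <- length(idx)
      n_dev <- floor(ratios[2] * n)
      n_test <- floor(ratios[3] * n)
      n_train <- n - n_dev - n_test
      out$train <- c(out$train, corpus[idx[seq_len(n_train)]])
      out$dev <- c(out$dev, corpus[idx[n_train + seq_len(n_dev)]])
      out$test <- c(out$test, corpus[idx[n_train + n_dev + seq_len(n_test)]])
    }
  })
  out
}

#' Run the two-stage pipeline on raw report text
#'
#' Segmentation, tokenization, entity prediction, report concatenation,
#' candidate generation and relation prediction, in that order. The result
#' is a schema-valid annotated report that can be serialized to BRAT
#' ([write_brat()]) or to structured records ([structure_report()]).
#'
#' @param text Raw report text.
#' @param ner_model Trained entity extractor.
#' @param rel_model Trained relation classifier.
#' @param id Report identifier for the output.
#' @return A [rad_report()] with predicted entities and relations.
#' @export
run_pipeline <- function(text, ner_model, rel_model, id = "report") {
  report <- rad_report(id = id, text = text, tokenize = TRUE,
                       validate = FALSE)
  if (nchar(trimws(text)) == 0) return(report)
  report$entities <- predict_entities(ner_model, report)
  rel <- predict_relations(rel_model, report)
  report$relations <- rel[, c("id", "type", "head", "tail"), drop = FALSE]
  report$relation_scores <- rel$score
  validate_report(report)
  report
}

#' Structured records for a report
#'
#' One record per concept entity with its attached modifiers and evidence
#' links -- the "structured format" output of the two-stage system.
#'
#' @param report An annotated report (gold or predicted).
#' @return A list of records (plain lists, JSON-serializable).
#' @export
structure_report <- function(report) {
  ent <- report$entities
  rel <- report$relations
  concepts <- ent[ent$type %in% concept_types(), , drop = FALSE]
  lapply(seq_len(nrow(concepts)), function(i) {
    e <- concepts[i, ]
    mods <- rel[rel$type == "Modifier" & rel$head == e$id, , drop = FALSE]
    mod_rec <- lapply(mods$tail, function(tid) {
      t <- ent[ent$id == tid, ]
      list(type = t$type, text = t$text, start = t$start, end = t$end)
    })
    ev <- if (e$type == "Observation") {
      rel$tail[rel$type == "Evidence" & rel$head == e$id]
    } else {
      rel$head[rel$type == "Evidence" & rel$tail == e$id]
    }
    ev_rec <- lapply(ev, function(id2) {
      t <- ent[ent$id == id2, ]
      list(id = t$id, type = t$type, text = t$text)
    })
    list(report = report$id, id = e$id, type = e$type, text = e$text,
         start = e$start, end = e$end, modifiers = mod_rec,
         evidence = ev_rec)
  })
}

#' Write structured records as JSON lines
#'
#' @param reports A report or list of reports.
#' @param path Output file (one JSON record per line).
#' @return `path`, invisibly.
#' @export
write_structured <- function(reports, path) {
  if (inherits(reports, "rad_report")) reports <- list(reports)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (r in reports) {
    for (rec in structure_report(r)) {
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
    }
  }
  invisible(path)
}

#' Configuration for a full experiment
#'
#' @param generator A [generator_config()] describing the corpus.
#' @param ratios Train/dev/test split ratios.
#' @param split_seed Seed for the split shuffle.
#' @param n_runs Number of training runs with distinct parameter
#'   initializations; reported scores are means over runs (default 5).
#' @param run_seeds Optional explicit seeds, one per run (default
#'   `split_seed * 1000 + 1:n_runs`).
#' @param ner_hp,rel_hp Model hyperparameters (seeds are overridden per
#'   run).
#' @param out_dir Optional directory for artifacts (config echo, metric
#'   tables, training logs).
#' @param verbose Print progress.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            ratios = c(0.7, 0.1, 0.2), split_seed = 1L,
                            n_runs = 5L, run_seeds = NULL,
                            ner_hp = ner_hyperparams(),
                            rel_hp = rel_hyperparams(),
                            out_dir = NULL, verbose = FALSE) {
  if (length(ratios) != 3 || any(ratios <= 0) ||
      abs(sum(ratios) - 1) > 1e-9) {
    stop("ratios must be three positive numbers summing to 1",
         call. = FALSE)
  }
  if (is.null(run_seeds)) run_seeds <- split_seed * 1000L + seq_len(n_runs)
  structure(list(generator = generator, ratios = ratios,
                 split_seed = as.integer(split_seed),
                 n_runs = as.integer(n_runs),
                 run_seeds = as.integer(run_seeds), ner_hp = ner_hp,
                 rel_hp = rel_hp, out_dir = out_dir, verbose = verbose),
            class = "pipeline_config")
}

# gold-entity copies of reports, with relations cleared
strip_relations <- function(corpus) {
  lapply(corpus, function(r) { r$relations <- empty_relations(); r })
}

#' Train and evaluate the full two-stage system
#'
#' Generates (or accepts) a corpus, splits it, trains both models `n_runs`
#' times with distinct seeds, and reports mean per-type and micro F1 for
#' entity extraction, relation extraction on gold entities, and the
#' end-to-end two-stage pipeline.
#'
#' @param config A [pipeline_config()].
#' @param corpus Optional pre-built corpus (otherwise generated from
#'   `config$generator`).
#' @return A list of class `experiment_result`: per-run metrics (`runs`)
#'   and mean micro scores (`mean`).
#' @export
run_experiment <- function(config, corpus = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(corpus)) corpus <- generate_corpus(config$generator)
  sp <- split_corpus(corpus, config$ratios, config$split_seed)
  runs <- list()
  for (k in seq_len(config$n_runs)) {
    seed <- config$run_seeds[k]
    ner_hp <- config$ner_hp; ner_hp$seed <- seed
    rel_hp <- config$rel_hp; rel_hp$seed <- seed
    if (config$verbose) message("== run ", k, " (seed ", seed, ") ==")
    ner <- train_ner(sp$train, sp$dev, ner_hp, verbose = config$verbose)
    rel <- train_rel(sp$train, sp$dev, rel_hp, verbose = config$verbose)
    runs[[k]] <- evaluate_two_stage(ner, rel, sp$test)
    runs[[k]]$seed <- seed
  }
  means <- list(
    entity_micro_f1 = mean(vapply(runs, function(r)
      r$entity$micro[["f1"]], numeric(1))),
    relation_gold_micro_f1 = mean(vapply(runs, function(r)
      r$relation_gold$micro[["f1"]], numeric(1))),
    pipeline_micro_f1 = mean(vapply(runs, function(r)
      r$pipeline$micro[["f1"]], numeric(1))))
  res <- structure(list(runs = runs, mean = means, split_sizes = c(
    train = length(sp$train), dev = length(sp$dev), test = length(sp$test))),
    class = "experiment_result")
  if (!is.null(config$out_dir)) write_experiment(res, config)
  res
}

#' Evaluate a trained model pair on a test corpus
#'
#' @param ner_model,rel_model Trained models.
#' @param test_corpus Gold-annotated test reports.
#' @return List of three `metrics_report`s: `entity`, `relation_gold`
#'   (relations predicted over gold entities) and `pipeline` (relations
#'   predicted over predicted entities).
#' @export
evaluate_two_stage <- function(ner_model, rel_model, test_corpus) {
  pred_ent_corpus <- lapply(test_corpus, function(r) {
    r2 <- r
    r2$entities <- predict_entities(ner_model, r)
    r2$relations <- empty_relations()
    r2
  })
  rel_on <- function(base_corpus) {
    lapply(base_corpus, function(r) {
      rel <- suppressWarnings(predict_relations(rel_model, r))
      r$relations <- rel[, c("id", "type", "head", "tail"), drop = FALSE]
      r
    })
  }
  gold_rel_pred <- rel_on(strip_relations(test_corpus))
  pipe_pred <- rel_on(pred_ent_corpus)
  list(
    entity = entity_f1(test_corpus, entity_table(pred_ent_corpus)),
    relation_gold = relation_f1(test_corpus, gold_rel_pred,
                                mode = "gold_entities"),
    pipeline = relation_f1(test_corpus, pipe_pred, mode = "pipeline"))
}

write_experiment <- function(res, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  echo <- config
  echo$generator$vocab <- lapply(echo$generator$vocab, length)
  jsonlite::write_json(
    lapply(unclass(echo), function(x) if (is.function(x)) NULL else x),
    file.path(config$out_dir, "config.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA, force = TRUE)
  tab <- do.call(rbind, lapply(seq_along(res$runs), function(k) {
    r <- res$runs[[k]]
    data.frame(run = k, seed = r$seed,
               entity_micro_f1 = r$entity$micro[["f1"]],
               relation_gold_micro_f1 = r$relation_gold$micro[["f1"]],
               pipeline_micro_f1 = r$pipeline$micro[["f1"]])
  }))
  utils::write.table(tab, file.path(config$out_dir, "runs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(config$out_dir)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("Experiment over %d run(s); split %d/%d/%d\n",
              length(x$runs), x$split_sizes["train"], x$split_sizes["dev"],
              x$split_sizes["test"]))
  cat(sprintf("Mean entity micro-F1:            %.3f\n",
              x$mean$entity_micro_f1))
  cat(sprintf("Mean relation micro-F1 (gold):   %.3f\n",
              x$mean$relation_gold_micro_f1))
  cat(sprintf("Mean pipeline micro-F1:          %.3f\n",
              x$mean$pipeline_micro_f1))
  invisible(x)
}
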
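# Relation extraction: candidates are enumerated per report over all
# admissible (head, tail) entity-type pairs, rendered as the report token
# sequence with four typed entity-span marker tokens, and classified by an
# attention-pooled BiLSTM binary model.

#' Typed entity-span marker tokens
#'
#' Each entity type owns an opening and a closing marker (e.g. `<OBS>`,
#' `</OBS>`). Markers are atomic vocabulary items, disjoint from text
#' tokens; a candidate's encoded sequence contains exactly two opening and
#' two closing markers.
#'
#' @return Data frame with columns `type`, `open`, `close`.
#' @export
marker_vocabulary <- function() {
  ab <- c(Observation = "OBS", ClinicalFinding = "CLN",
          AnatomicalLocation = "AE", Certainty = "CER", Change = "CHG",
          Characteristics = "CHA", Size = "SIZ")
  data.frame(type = names(ab),
             open = paste0("<", ab, ">"),
             close = paste0("</", ab, ">"),
             stringsAsFactors = FALSE)
}

#' Concatenate a report's sentences into one token sequence
#'
#' Sentence order is preserved and no separator tokens are inserted, so the
#' sequence is simply the report's tokens in document order; the offset map
#' (the `start`/`end` columns) inverts token index to character span, which
#' is what allows relations across sentence boundaries to be encoded.
#'
#' @param report A tokenized report.
#' @return Data frame with columns `start`, `end`, `text`, `sentence`
#'   (1-based sentence index).
#' @export
concatenate_report <- function(report) {
  if (is.null(report$sentences)) report <- tokenize_report(report)
  parts <- lapply(seq_along(report$sentences), function(i) {
    t <- report$sentences[[i]]$tokens
    if (nrow(t) == 0) return(NULL)
    t$sentence <- i
    t
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (length(parts) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      text = character(), sentence = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, parts)
}

# token index range covered by an entity; NULL if the covering tokens are
# not contiguous
entity_token_range <- function(tokens, start, end) {
  idx <- which(tokens$start < end & tokens$end > start)
  if (length(idx) == 0) return(NULL)
  if (any(diff(idx) != 1L)) return(NULL)
  range(idx)
}

#' Enumerate relation candidates for a report
#'
#' For the Modifier type, every (concept entity, modifier entity) ordered
#' pair in the report; for the Evidence type, every
#' (Observation, ClinicalFinding) ordered pair. When the report carries gold
#' relations, each candidate is labeled `TRUE` iff the gold set contains it.
#'
#' @param report An annotated report (entities required; relations optional).
#' @return Data frame with columns `rel_type`, `head`, `tail` (entity ids)
#'   and logical `label`.
#' @export
generate_candidates <- function(report) {
  ent <- report$entities
  out <- list()
  if (nrow(ent) > 0) {
    for (rt in names(relation_types())) {
      cons <- relation_types()[[rt]]
      heads <- ent$id[ent$type %in% cons$head_types]
      tails <- ent$id[ent$type %in% cons$tail_types]
      if (length(heads) > 0 && length(tails) > 0) {
        g <- expand.grid(head = heads, tail = tails,
                         stringsAsFactors = FALSE)
        g$rel_type <- rt
        out[[length(out) + 1L]] <- g
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(rel_type = character(), head = character(),
                      tail = character(), label = logical(),
                      stringsAsFactors = FALSE))
  }
  cand <- do.call(rbind, out)[, c("rel_type", "head", "tail")]
  rel <- report$relations
  key <- function(t, h, l) paste(t, h, l, sep = "\r")
  cand$label <- key(cand$rel_type, cand$head, cand$tail) %in%
    key(rel$type, rel$head, rel$tail)
  rownames(cand) <- NULL
  cand
}

#' Encode one relation candidate as a marked token sequence
#'
#' The opening/closing markers of each endpoint's entity type are inserted
#' immediately before/after its token run (four markers in total). If the
#' marked sequence exceeds `max_len`, a window of at most `max_len` tokens
#' centered on the two spans is kept; candidates whose endpoints cannot
#' both fit return `NULL` (the caller logs the truncation and scores the
#' candidate 0), as do candidates with overlapping or token-misaligned
#' endpoints.
#'
#' @param tokens Report-level token table from [concatenate_report()].
#' @param head_entity,tail_entity Single-row entity records (with `type`,
#'   `start`, `end`).
#' @param markers Marker table from [marker_vocabulary()].
#' @param max_len Maximum encoded sequence length, markers included.
#' @return Character vector of tokens, or `NULL` when the candidate cannot
#'   be encoded.
#' @export
encode_candidate <- function(tokens, head_entity, tail_entity,
                             markers = marker_vocabulary(), max_len = 256) {
  hr <- entity_token_range(tokens, head_entity$start, head_entity$end)
  tr <- entity_token_range(tokens, tail_entity$start, tail_entity$end)
  if (is.null(hr) || is.null(tr)) return(NULL)
  if (hr[1] <= tr[2] && tr[1] <= hr[2]) return(NULL)  # overlapping spans
  lo <- min(hr[1], tr[1]); hi <- max(hr[2], tr[2])
  budget <- max_len - 4L
  if (hi - lo + 1L > budget) return(NULL)
  extra <- budget - (hi - lo + 1L)
  w1 <- max(1L, lo - extra %/% 2L)
  w2 <- min(nrow(tokens), w1 + budget - 1L)
  w1 <- max(1L, w2 - budget + 1L)
  mk <- function(ty, col) markers[[col]][markers$type == ty]
  keys <- (w1:w2) * 10
  texts <- tokens$text[w1:w2]
  ins_keys <- c(hr[1] * 10 - 3, hr[2] * 10 + 3, tr[1] * 10 - 3,
                tr[2] * 10 + 3)
  ins_text <- c(mk(head_entity$type, "open"), mk(head_entity$type, "close"),
                mk(tail_entity$type, "open"), mk(tail_entity$type, "close"))
  all_keys <- c(keys, ins_keys)
  all_text <- c(texts, ins_text)
  all_text[order(all_keys)]
}

#' Hyperparameters for the relation classifier
#'
#' Same SGD-with-momentum schedule as the entity extractor; additionally
#' `max_len` bounds the encoded sequence length and `threshold` is the
#' fixed decision threshold on the predicted probability.
#'
#' @inheritParams ner_hyperparams
#' @param max_len Maximum encoded candidate length (tokens, markers
#'   included).
#' @param threshold Decision threshold (not tuned on dev).
#' @return A list of class `rel_hyperparams`.
#' @export
rel_hyperparams <- function(embedding_dim = 100, hidden_dim = 512,
                            batch_size = 16, dropout = 0.1,
                            initial_lr = 0.1, momentum = 0.9,
                            grad_clip = 5.0, lr_decay_patience = 3,
                            lr_decay_factor = 0.5, lr_floor = 1e-4,
                            max_epochs = 30, unk_dropout = 0.01,
                            max_len = 256, threshold = 0.5, seed = 1L) {
  hp <- ner_hyperparams(embedding_dim, hidden_dim, batch_size, dropout,
                        initial_lr, momentum, grad_clip, lr_decay_patience,
                        lr_decay_factor, lr_floor, max_epochs, unk_dropout,
                        seed)
  hp$max_len <- max_len
  hp$threshold <- threshold
  class(hp) <- "rel_hyperparams"
  hp
}

init_rel_params <- function(V, d, H) {
  p <- init_bilstm_params(V, d, H)
  # larger-scale embedding and attention init than the tagger: the pooled
  # classifier's gradient signal scales with the input variance, and the
  # small-scale init leaves it near-flat for many epochs
  p$E <- matrix(stats::runif(V * d, -0.5, 0.5), V, d)
  c(p, list(v = matrix(stats::runif(2 * H, -0.5, 0.5), 2 * H, 1),
            w = glorot(2 * H, 1), b = matrix(0, 1, 1)))
}

# encoded training/eval instances for a corpus; candidates that cannot be
# encoded are dropped with a count
prepare_rel_instances <- function(corpus, markers, max_len) {
  seqs <- list(); labels <- logical(0); skipped <- 0L
  meta <- list()
  for (r in corpus) {
    toks <- concatenate_report(r)
    cand <- generate_candidates(r)
    for (k in seq_len(nrow(cand))) {
      he <- r$entities[r$entities$id == cand$head[k], ]
      te <- r$entities[r$entities$id == cand$tail[k], ]
      enc <- encode_candidate(toks, he, te, markers, max_len)
      if (is.null(enc)) { skipped <- skipped + 1L; next }
      seqs[[length(seqs) + 1L]] <- enc
      labels <- c(labels, cand$label[k])
      meta[[length(meta) + 1L]] <- data.frame(
        report_id = r$id, rel_type = cand$rel_type[k], head = cand$head[k],
        tail = cand$tail[k], stringsAsFactors = FALSE)
    }
  }
  list(seqs = seqs, labels = labels, skipped = skipped,
       meta = if (length(meta)) do.call(rbind, meta) else NULL)
}

binary_f1 <- function(pred, gold) {
  tp <- sum(pred & gold); fp <- sum(pred & !gold); fn <- sum(!pred & gold)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Train the attention-BiLSTM relation classifier
#'
#' All enumerated candidates form the training set: positives are the gold
#' pairs, negatives every other admissible pair -- no negative
#' down-sampling. The checkpoint with the best development-set F1 (at the
#' fixed decision threshold) is returned; runs are deterministic given the
#' seed.
#'
#' @param train_corpus,dev_corpus Annotated, tokenized reports with gold
#'   entities and relations.
#' @param hp A [rel_hyperparams()].
#' @param verbose Print per-epoch progress.
#' @return An object of class `rel_model`.
#' @export
train_rel <- function(train_corpus, dev_corpus, hp = rel_hyperparams(),
                      verbose = FALSE) {
  if (length(train_corpus) == 0) {
    stop("training corpus is empty", call. = FALSE)
  }
  markers <- marker_vocabulary()
  train <- prepare_rel_instances(train_corpus, markers, hp$max_len)
  if (train$skipped > 0) {
    warning(train$skipped, " training candidate(s) could not be encoded ",
            "(span too far apart or overlapping) and were skipped",
            call. = FALSE)
  }
  if (!any(train$labels)) {
    stop("no positive relation candidates in the training data",
         call. = FALSE)
  }
  all_tokens <- unlist(lapply(train_corpus, function(r)
    unlist(lapply(r$sentences, function(s) s$tokens$text))))
  vocab <- build_vocab(all_tokens, extra = c(markers$open, markers$close))
  n_marker <- 2L * nrow(markers)
  train_ids <- lapply(train$seqs, tokens_to_ids, vocab = vocab)
  dev <- prepare_rel_instances(dev_corpus, markers, hp$max_len)
  dev_ids <- lapply(dev$seqs, tokens_to_ids, vocab = vocab)
  with_seed(hp$seed, {
    params <- init_rel_params(length(vocab), hp$embedding_dim,
                              hp$hidden_dim)
    vel <- lapply(params, function(p) p * 0)
    sched <- list(best = -Inf, wait = 0L, lr = hp$initial_lr,
                  improved = FALSE)
    best_params <- params; best_f1 <- -Inf
    log <- data.frame(epoch = integer(), loss = numeric(),
                      dev_f1 = numeric(), lr = numeric())
    n <- length(train_ids)
    for (epoch in seq_len(hp$max_epochs)) {
      ord <- sample.int(n)
      epoch_loss <- 0; epoch_n <- 0
      lr <- sched$lr
      for (b in split(ord, ceiling(seq_along(ord) / hp$batch_size))) {
        seqs <- lapply(train_ids[b], function(ids) {
          if (hp$unk_dropout > 0) {
            # never drop marker tokens out of the sequence
            drop <- stats::runif(length(ids)) < hp$unk_dropout &
                    ids > (1L + n_marker)
            ids[drop] <- 1L
          }
          ids
        })
        res <- cpp_rel_batch(params, seqs, as.numeric(train$labels[b]),
                             hp$dropout, TRUE)
        if (res$n == 0) next
        grads <- lapply(res$grads, function(g) g / res$n)
        upd <- sgd_step(params, grads, vel, lr, hp$momentum, hp$grad_clip)
        params <- upd$params; vel <- upd$vel
        epoch_loss <- epoch_loss + res$loss
        epoch_n <- epoch_n + res$n
      }
      dev_f1 <- if (length(dev_ids) > 0) {
        probs <- cpp_rel_predict(params, dev_ids)$prob
        binary_f1(probs >= hp$threshold, dev$labels)
      } else NA_real_
      if (!is.na(dev_f1) && dev_f1 > best_f1 + 1e-6) {
        best_f1 <- dev_f1; best_params <- params
      }
      sched <- plateau_update(sched, if (is.na(dev_f1)) 0 else dev_f1,
                              hp$lr_decay_patience, hp$lr_decay_factor,
                              hp$lr_floor)
      log <- rbind(log, data.frame(epoch = epoch,
                                   loss = epoch_loss / max(epoch_n, 1),
                                   dev_f1 = dev_f1, lr = lr))
      if (verbose) {
        message(sprintf("[rel] epoch %d loss %.4f dev_f1 %.4f lr %.4g",
                        epoch, epoch_loss / max(epoch_n, 1), dev_f1, lr))
      }
    }
    if (best_f1 == -Inf) best_params <- params
    structure(list(vocab = vocab, params = best_params, markers = markers,
                   hp = hp, log = log, best_dev_f1 = best_f1,
                   class_balance = c(pos = sum(train$labels),
                                     neg = sum(!train$labels)),
                   format = "radrelex-rel-1"),
              class = "rel_model")
  })
}

#' Score every relation candidate of a report
#'
#' @param model A trained [train_rel()] model.
#' @param report A report with entities (gold or predicted).
#' @param attention If `TRUE`, attach the per-candidate attention weight
#'   vectors as attribute `"attention"`.
#' @return The candidate table from [generate_candidates()] with a `score`
#'   column (probability of the relation); candidates that could not be
#'   encoded are scored 0 and flagged in the logical `truncated` column.
#' @export
candidate_scores <- function(model, report, attention = FALSE) {
  if (is.null(report$sentences)) report <- tokenize_report(report)
  cand <- generate_candidates(report)
  cand$score <- numeric(nrow(cand))
  cand$truncated <- logical(nrow(cand))
  attn <- vector("list", nrow(cand))
  if (nrow(cand) > 0) {
    toks <- concatenate_report(report)
    seqs <- list(); pos <- integer(0)
    for (k in seq_len(nrow(cand))) {
      he <- report$entities[report$entities$id == cand$head[k], ]
      te <- report$entities[report$entities$id == cand$tail[k], ]
      enc <- encode_candidate(toks, he, te, model$markers, model$hp$max_len)
      if (is.null(enc)) { cand$truncated[k] <- TRUE; next }
      seqs[[length(seqs) + 1L]] <- tokens_to_ids(enc, model$vocab)
      pos <- c(pos, k)
    }
    if (length(seqs) > 0) {
      res <- cpp_rel_predict(model$params, seqs, want_attention = attention)
      cand$score[pos] <- res$prob
      if (attention) attn[pos] <- res$attention
    }
    if (any(cand$truncated)) {
      warning(sum(cand$truncated), " candidate(s) could not be encoded ",
              "within max_len and were scored 0", call. = FALSE)
    }
  }
  if (attention) attr(cand, "attention") <- attn
  cand
}

#' Predict relations for a report
#'
#' Scores every admissible candidate and returns those at or above the
#' decision threshold as schema-valid relations.
#'
#' @param model A trained [train_rel()] model.
#' @param report A report with entities (gold or predicted).
#' @param threshold Decision threshold (defaults to the model's).
#' @return A relation data frame (`id`, `type`, `head`, `tail`, `score`).
#' @export
predict_relations <- function(model, report, threshold = NULL) {
  if (is.null(threshold)) threshold <- model$hp$threshold
  cand <- suppressWarnings(candidate_scores(model, report))
  keep <- cand[cand$score >= threshold, , drop = FALSE]
  if (nrow(keep) == 0) return(cbind(empty_relations(), score = numeric(0)))
  data.frame(id = paste0("R", seq_len(nrow(keep))), type = keep$rel_type,
             head = keep$head, tail = keep$tail, score = keep$score,
             stringsAsFactors = FALSE)
}

#' Write a candidate dump for audit / error analysis
#'
#' One tab-separated record per candidate: report id, relation type, head
#' and tail entity ids, gold label (if known) and model score.
#'
#' @param scores A candidate table (e.g. from [candidate_scores()]) with a
#'   `report_id` column, or a list of them.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_candidate_dump <- function(scores, path) {
  if (is.list(scores) && !is.data.frame(scores)) {
    scores <- do.call(rbind, scores)
  }
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
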
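# Entity extraction: a bidirectional LSTM encoder feeding a linear-chain
# CRF over IOB2 tags (15 tags for the 7 entity types plus O).

#' Hyperparameters for the BiLSTM-CRF entity extractor
#'
#' Defaults follow the reference configuration: minibatch SGD with momentum
#' (initial learning rate 0.1, momentum 0.9), gradient clipping at 5.0,
#' batch size 16, dropout 0.1 on the encoder input and output vectors,
#' word embedding dimension 100 and hidden dimension 512, with
#' reduce-on-plateau learning-rate decay driven by development-set F1.
#'
#' @param embedding_dim Word embedding dimension.
#' @param hidden_dim Hidden units per LSTM direction.
#' @param batch_size Sentences per SGD step.
#' @param dropout Dropout rate on encoder input and output vectors.
#' @param initial_lr Initial learning rate.
#' @param momentum SGD momentum.
#' @param grad_clip Global gradient-norm clip.
#' @param lr_decay_patience Epochs without dev-F1 improvement before the
#'   learning rate is multiplied by `lr_decay_factor`.
#' @param lr_decay_factor Multiplicative decay factor.
#' @param lr_floor Lower bound on the learning rate.
#' @param max_epochs Training epochs (the best-dev checkpoint is returned).
#' @param unk_dropout Probability of replacing a training token by the
#'   unknown-token index, which trains the UNK embedding.
#' @param hard_constraints If `TRUE`, decoding masks invalid IOB2
#'   transitions (`-Inf` score) instead of relying on learned transitions
#'   plus decode-time repair.
#' @param seed Seed controlling initialization, shuffling and dropout.
#' @return A list of class `ner_hyperparams`.
#' @export
ner_hyperparams <- function(embedding_dim = 100, hidden_dim = 512,
                            batch_size = 16, dropout = 0.1,
                            initial_lr = 0.1, momentum = 0.9,
                            grad_clip = 5.0, lr_decay_patience = 3,
                            lr_decay_factor = 0.5, lr_floor = 1e-4,
                            max_epochs = 30, unk_dropout = 0.01,
                            hard_constraints = FALSE, seed = 1L) {
  hp <- list(embedding_dim = embedding_dim, hidden_dim = hidden_dim,
             batch_size = batch_size, dropout = dropout,
             initial_lr = initial_lr, momentum = momentum,
             grad_clip = grad_clip, lr_decay_patience = lr_decay_patience,
             lr_decay_factor = lr_decay_factor, lr_floor = lr_floor,
             max_epochs = max_epochs, unk_dropout = unk_dropout,
             hard_constraints = isTRUE(hard_constraints),
             seed = as.integer(seed))
  pos <- c("embedding_dim", "hidden_dim", "batch_size", "initial_lr",
           "grad_clip", "lr_decay_patience", "lr_decay_factor", "lr_floor",
           "max_epochs")
  if (any(unlist(hp[pos]) <= 0)) {
    stop("hyperparameters must be positive", call. = FALSE)
  }
  if (hp$dropout < 0 || hp$dropout >= 1) {
    stop("dropout must lie in [0, 1)", call. = FALSE)
  }
  structure(hp, class = "ner_hyperparams")
}

#' The IOB2 tag set over the information model
#'
#' @return Character vector: `O` followed by `B-`/`I-` tags for each of the
#'   7 entity types (15 tags).
#' @export
ner_tagset <- function() {
  types <- entity_types()$name
  c("O", as.vector(rbind(paste0("B-", types), paste0("I-", types))))
}

UNK_TOKEN <- "<unk>"

build_vocab <- function(token_texts, extra = character(0)) {
  c(UNK_TOKEN, extra, sort(unique(token_texts)))
}

tokens_to_ids <- function(texts, vocab) {
  ids <- match(texts, vocab)
  ids[is.na(ids)] <- 1L
  ids
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

init_bilstm_params <- function(V, d, H) {
  b_f <- matrix(0, 1, 4 * H); b_f[1, (H + 1):(2 * H)] <- 1  # forget bias
  b_b <- b_f
  list(E = matrix(stats::runif(V * d, -0.1, 0.1), V, d),
       Wx_f = glorot(d, 4 * H), Wh_f = glorot(H, 4 * H), b_f = b_f,
       Wx_b = glorot(d, 4 * H), Wh_b = glorot(H, 4 * H), b_b = b_b)
}

init_ner_params <- function(V, d, H, K) {
  p <- init_bilstm_params(V, d, H)
  c(p, list(Wout = glorot(2 * H, K), bout = matrix(0, 1, K),
            trans = matrix(stats::runif(K * K, -0.01, 0.01), K, K),
            start = matrix(0, K, 1), stop = matrix(0, K, 1)))
}

# one SGD-with-momentum step over named parameter/gradient lists, with
# global-norm clipping
sgd_step <- function(params, grads, vel, lr, momentum, clip) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
  scale <- if (is.finite(gn) && gn > clip) clip / gn else 1
  for (k in names(grads)) {
    vel[[k]] <- momentum * vel[[k]] - lr * scale * grads[[k]]
    params[[k]] <- params[[k]] + vel[[k]]
  }
  list(params = params, vel = vel)
}

# reduce-on-plateau learning rate schedule state machine
plateau_update <- function(state, metric, patience, factor, floor) {
  if (metric > state$best + 1e-6) {
    state$best <- metric
    state$wait <- 0L
    state$improved <- TRUE
  } else {
    state$wait <- state$wait + 1L
    state$improved <- FALSE
    if (state$wait >= patience) {
      state$lr <- max(state$lr * factor, floor)
      state$wait <- 0L
    }
  }
  state
}

# per-sentence training instances: token ids and gold tag ids
prepare_ner_sentences <- function(corpus, vocab, tagset) {
  out <- list()
  for (r in corpus) {
    for (s in r$sentences) {
      ent <- sentence_entities(r, s)
      tags <- encode_iob2(s$tokens, ent)
      toks <- attr(tags, "tokens")
      if (nrow(toks) == 0) next
      tag_ids <- match(as.character(tags), tagset)
      out[[length(out) + 1L]] <- list(
        ids = tokens_to_ids(toks$text, vocab),
        tags = tag_ids)
    }
  }
  out
}

#' Train the BiLSTM-CRF entity extractor
#'
#' Minibatch SGD with momentum, gradient clipping, input/output dropout,
#' and reduce-on-plateau learning-rate decay keyed to development-set
#' entity-level micro-F1. The checkpoint with the best dev F1 is returned.
#' Runs are deterministic given the seed, the corpora and the
#' hyperparameters (on a single CPU thread).
#'
#' @param train_corpus,dev_corpus Lists of annotated, tokenized reports.
#' @param hp A [ner_hyperparams()].
#' @param pretrained_embeddings Optional embedding set from
#'   [read_embeddings()]; tokens present in it are initialized from the
#'   file, all others randomly.
#' @param verbose Print per-epoch progress.
#' @return An object of class `ner_model` with fields `vocab`, `params`,
#'   `tagset`, `hp`, and a per-epoch training `log` (loss, dev F1, lr).
#' @export
train_ner <- function(train_corpus, dev_corpus, hp = ner_hyperparams(),
                      pretrained_embeddings = NULL, verbose = FALSE) {
  if (length(train_corpus) == 0) {
    stop("training corpus is empty", call. = FALSE)
  }
  tagset <- ner_tagset()
  K <- length(tagset)
  all_tokens <- unlist(lapply(train_corpus, function(r)
    unlist(lapply(r$sentences, function(s) s$tokens$text))))
  vocab <- build_vocab(all_tokens)
  with_seed(hp$seed, {
    params <- init_ner_params(length(vocab), hp$embedding_dim,
                              hp$hidden_dim, K)
    if (!is.null(pretrained_embeddings)) {
      if (ncol(pretrained_embeddings$vectors) != hp$embedding_dim) {
        stop("pretrained embedding dimension (",
             ncol(pretrained_embeddings$vectors),
             ") does not match embedding_dim (", hp$embedding_dim, ")",
             call. = FALSE)
      }
      hit <- match(vocab, pretrained_embeddings$tokens)
      ok <- which(!is.na(hit))
      params$E[ok, ] <- pretrained_embeddings$vectors[hit[ok], , drop = FALSE]
    }
    train_data <- prepare_ner_sentences(train_corpus, vocab, tagset)
    dev_ids <- lapply(dev_corpus, function(r)
      lapply(r$sentences, function(s) tokens_to_ids(s$tokens$text, vocab)))
    gold_dev <- entity_table(dev_corpus)
    vel <- lapply(params, function(p) p * 0)
    sched <- list(best = -Inf, wait = 0L, lr = hp$initial_lr,
                  improved = FALSE)
    best_params <- params
    best_f1 <- -Inf
    log <- data.frame(epoch = integer(), loss = numeric(),
                      dev_f1 = numeric(), lr = numeric())
    for (epoch in seq_len(hp$max_epochs)) {
      ord <- sample.int(length(train_data))
      epoch_loss <- 0; epoch_n <- 0
      lr <- sched$lr
      for (b in split(ord, ceiling(seq_along(ord) / hp$batch_size))) {
        seqs <- lapply(train_data[b], function(x) {
          ids <- x$ids
          if (hp$unk_dropout > 0) {
            drop <- stats::runif(length(ids)) < hp$unk_dropout
            ids[drop] <- 1L
          }
          ids
        })
        tags <- lapply(train_data[b], `[[`, "tags")
        res <- cpp_ner_batch(params, seqs, tags, hp$dropout, hp$dropout,
                             TRUE)
        if (res$n == 0) next
        grads <- lapply(res$grads, function(g) g / res$n)
        upd <- sgd_step(params, grads, vel, lr, hp$momentum, hp$grad_clip)
        params <- upd$params; vel <- upd$vel
        epoch_loss <- epoch_loss + res$loss
        epoch_n <- epoch_n + res$n
      }
      dev_f1 <- ner_dev_f1(params, dev_ids, dev_corpus, gold_dev, tagset)
      if (!is.na(dev_f1) && dev_f1 > best_f1 + 1e-6) {
        best_f1 <- dev_f1
        best_params <- params
      }
      sched <- plateau_update(sched, if (is.na(dev_f1)) 0 else dev_f1,
                              hp$lr_decay_patience, hp$lr_decay_factor,
                              hp$lr_floor)
      log <- rbind(log, data.frame(epoch = epoch,
                                   loss = epoch_loss / max(epoch_n, 1),
                                   dev_f1 = dev_f1, lr = lr))
      if (verbose) {
        message(sprintf("[ner] epoch %d loss %.4f dev_f1 %.4f lr %.4g",
                        epoch, epoch_loss / max(epoch_n, 1), dev_f1, lr))
      }
    }
    if (best_f1 == -Inf) best_params <- params
    structure(list(vocab = vocab, params = best_params, tagset = tagset,
                   hp = hp, log = log, best_dev_f1 = best_f1,
                   format = "radrelex-ner-1"),
              class = "ner_model")
  })
}

ner_dev_f1 <- function(params, dev_ids, dev_corpus, gold_dev, tagset) {
  if (length(dev_corpus) == 0) return(NA_real_)
  preds <- list()
  for (i in seq_along(dev_corpus)) {
    r <- dev_corpus[[i]]
    paths <- cpp_ner_predict(params, dev_ids[[i]])
    ents <- decode_report_entities(r, paths, tagset)
    if (nrow(ents) > 0) {
      ents$report_id <- r$id
      preds[[length(preds) + 1L]] <- ents
    }
  }
  pred <- if (length(preds)) do.call(rbind, preds) else
    cbind(empty_entities(), report_id = character(0))
  entity_f1(gold_dev, pred)$micro["f1"]
}

decode_report_entities <- function(report, tag_paths, tagset) {
  ents <- list()
  for (si in seq_along(report$sentences)) {
    s <- report$sentences[[si]]
    if (nrow(s$tokens) == 0) next
    tags <- tagset[tag_paths[[si]]]
    e <- decode_iob2(s$tokens, tags, text = report$text)
    if (nrow(e) > 0) ents[[length(ents) + 1L]] <- e
  }
  if (length(ents) == 0) return(empty_entities())
  out <- do.call(rbind, ents)
  out$id <- paste0("T", seq_len(nrow(out)))
  out
}

#' Predict entity spans in a report
#'
#' Runs per-sentence Viterbi decoding and converts the IOB2 tags back to
#' character-offset entity spans. Out-of-vocabulary tokens map to the
#' unknown-token embedding.
#'
#' @param model A trained [train_ner()] model.
#' @param report A [rad_report()] (entities, if any, are ignored); it is
#'   tokenized on the fly if needed.
#' @return An entity data frame satisfying the span invariants.
#' @export
predict_entities <- function(model, report) {
  if (is.null(report$sentences)) report <- tokenize_report(report)
  ids <- lapply(report$sentences, function(s)
    tokens_to_ids(s$tokens$text, model$vocab))
  params <- model$params
  if (isTRUE(model$hp$hard_constraints)) {
    params$trans[invalid_iob2_transitions(model$tagset)] <- -Inf
  }
  paths <- cpp_ner_predict(params, ids)
  decode_report_entities(report, paths, model$tagset)
}

# logical K x K matrix marking transitions IOB2 forbids: I-t may only
# follow B-t or I-t
invalid_iob2_transitions <- function(tagset) {
  K <- length(tagset)
  bad <- matrix(FALSE, K, K)
  for (j in which(startsWith(tagset, "I-"))) {
    ty <- substring(tagset[j], 3)
    ok <- tagset %in% paste0(c("B-", "I-"), ty)
    bad[!ok, j] <- TRUE
  }
  bad
}

#' Read a word2vec-style text embedding file
#'
#' One token per line followed by whitespace-separated floats; an optional
#' `<count> <dim>` header line is skipped.
#'
#' @param path Path to the embedding text file.
#' @return A list with `tokens` (character) and `vectors` (numeric matrix).
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0) stop("empty embedding file", call. = FALSE)
  first <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(first) == 2 && !anyNA(suppressWarnings(as.numeric(first)))) {
    lines <- lines[-1]
  }
  parts <- strsplit(trimws(lines), "\\s+")
  tokens <- vapply(parts, `[[`, character(1), 1)
  vecs <- t(vapply(parts, function(p) as.numeric(p[-1]),
                   numeric(length(parts[[1]]) - 1)))
  list(tokens = tokens, vectors = vecs)
}

#' Save / load a trained model checkpoint
#'
#' The checkpoint is a single archive holding the vocabulary, all parameter
#' matrices, and the hyperparameter echo, under a versioned format tag.
#'
#' @param model A `ner_model` or `rel_model`.
#' @param path Destination file.
#' @return `path`, invisibly (for `save_model`); the model (for
#'   `load_model`).
#' @export
save_model <- function(model, path) {
  saveRDS(list(format = model$format, class = class(model),
               payload = unclass(model)), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- readRDS(path)
  if (is.null(x$format) || !grepl("^radrelex-", x$format)) {
    stop("not a radrelex model checkpoint", call. = FALSE)
  }
  structure(x$payload, class = x$class)
}
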
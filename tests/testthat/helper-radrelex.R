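# Shared fixtures and independent oracles for the test suite.

# Brute-force CRF log-likelihood by explicit enumeration of all tag paths.
brute_crf_ll <- function(em, tr, start, stop, tags) {
  L <- nrow(em); K <- ncol(em)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), L)))
  score <- function(p) {
    s <- start[p[1]] + sum(em[cbind(seq_len(L), p)]) + stop[p[L]]
    if (L > 1) s <- s + sum(tr[cbind(p[-L], p[-1])])
    s
  }
  sc <- apply(paths, 1, score)
  m <- max(sc)
  score(tags) - (m + log(sum(exp(sc - m))))
}

# Brute-force maximal path score by enumeration.
brute_viterbi_score <- function(em, tr, start, stop) {
  L <- nrow(em); K <- ncol(em)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), L)))
  max(apply(paths, 1, function(p) {
    s <- start[p[1]] + sum(em[cbind(seq_len(L), p)]) + stop[p[L]]
    if (L > 1) s <- s + sum(tr[cbind(p[-L], p[-1])])
    s
  }))
}

path_score <- function(em, tr, start, stop, p) {
  L <- length(p)
  s <- start[p[1]] + sum(em[cbind(seq_len(L), p)]) + stop[p[L]]
  if (L > 1) s <- s + sum(tr[cbind(p[-L], p[-1])])
  s
}

# Token table from a character vector, tokens joined by single spaces.
make_tokens <- function(texts, offset = 0L) {
  n <- nchar(texts)
  end <- offset + cumsum(n + 1L) - 1L
  start <- end - n
  data.frame(start = start, end = end, text = texts,
             stringsAsFactors = FALSE)
}

# Independent micro-F1 oracle: greedy one-to-one matching over entity
# records, no pooling shortcuts.
oracle_micro_f1 <- function(gold, pred) {
  used <- rep(FALSE, nrow(gold))
  tp <- 0L
  for (i in seq_len(nrow(pred))) {
    j <- which(!used & gold$report_id == pred$report_id[i] &
               gold$type == pred$type[i] & gold$start == pred$start[i] &
               gold$end == pred$end[i])
    if (length(j) > 0) { used[j[1]] <- TRUE; tp <- tp + 1L }
  }
  fp <- nrow(pred) - tp
  fn <- nrow(gold) - tp
  if (2 * tp + fp + fn == 0) return(1)
  2 * tp / (2 * tp + fp + fn)
}

# A tiny hand-built annotated report: one observation with size and
# location modifiers, and a finding supported by the observation.
tiny_report <- function(id = "r1") {
  text <- paste0("a nodule measuring 12 mm in the right upper lobe ",
                 "is seen. malignancy is considered.")
  ents <- data.frame(
    id = paste0("T", 1:4),
    type = c("Observation", "Size", "AnatomicalLocation",
             "ClinicalFinding"),
    start = c(2L, 19L, 32L, 58L),
    end = c(8L, 24L, 48L, 68L),
    stringsAsFactors = FALSE)
  ents$text <- substring(text, ents$start + 1L, ents$end)
  rels <- data.frame(
    id = paste0("R", 1:3),
    type = c("Modifier", "Modifier", "Evidence"),
    head = c("T1", "T1", "T1"),
    tail = c("T2", "T3", "T4"),
    stringsAsFactors = FALSE)
  rad_report(id = id, text = text, entities = ents, relations = rels)
}

# A degenerate corpus where every admissible candidate is a gold relation:
# each report holds exactly one observation and one modifier.
all_positive_corpus <- function(n, seed = 1) {
  obs <- c("nodule", "mass", "cyst", "opacity")
  mod <- c("suspected", "probable", "definite", "possible")
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    o <- sample(obs, 1); m <- sample(mod, 1)
    text <- paste0(m, " ", o, " is seen.")
    ents <- data.frame(
      id = c("T1", "T2"), type = c("Certainty", "Observation"),
      start = c(0L, nchar(m) + 1L),
      end = c(nchar(m), nchar(m) + 1L + nchar(o)),
      stringsAsFactors = FALSE)
    ents$text <- substring(text, ents$start + 1L, ents$end)
    rels <- data.frame(id = "R1", type = "Modifier", head = "T2",
                       tail = "T1", stringsAsFactors = FALSE)
    rad_report(id = paste0("p", i), text = text, entities = ents,
               relations = rels)
  })
}
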
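# Synthetic annotated radiology-style reports.
#
# The generator emulates the *structure* of an annotated CT-report corpus --
# multi-sentence reports, the seven-type entity inventory, intra- and
# cross-sentence relations, a long-tailed (Zipf) mention vocabulary, and a
# fraction of out-of-scope technique/procedure/recommendation sentences --
# not the language of real reports. Mentions mix curated clinical terms
# (the frequent heads of each distribution) with deterministic pseudo-terms
# that populate the tail, so frequency-stratified (major/minor) analyses
# have both strata at moderate corpus sizes.

pseudo_syllables <- c(
  "ba", "be", "bi", "bo", "bu", "da", "de", "di", "do", "du",
  "ga", "ge", "gi", "go", "gu", "ka", "ke", "ki", "ko", "ku",
  "la", "le", "li", "lo", "lu", "ma", "me", "mi", "mo", "mu",
  "na", "ne", "ni", "no", "nu", "pa", "pe", "pi", "po", "pu",
  "ra", "re", "ri", "ro", "ru", "sa", "se", "si", "so", "su",
  "ta", "te", "ti", "to", "tu", "va", "ve", "vi", "vo", "vu")

pseudo_terms <- function(n, suffix) {
  g <- expand.grid(a = pseudo_syllables, b = pseudo_syllables,
                   stringsAsFactors = FALSE)
  paste0(g$b, g$a, suffix)[seq_len(n)]
}

#' Default mention vocabulary for the synthetic corpus
#'
#' Curated clinical terms head each per-type list; deterministic pseudo-terms
#' extend it into a long tail. Size mentions are compositional
#' (number + unit), mirroring how real size modifiers generalize to unseen
#' values.
#'
#' @return A named list of character vectors, one per entity type.
#' @export
default_vocab <- function() {
  obs <- c("nodule", "mass", "opacity", "consolidation", "pleural effusion",
           "ground glass opacity", "atelectasis", "emphysema",
           "bronchiectasis", "lymphadenopathy", "calcification", "cyst",
           "pneumothorax", "granuloma", "infiltrate", "cavitation",
           "fibrosis", "honeycombing", "scarring", "stenosis", "dilatation",
           "edema", "hemorrhage", "thrombus", "aneurysm", "ascites",
           "gallstone", "hepatomegaly", "splenomegaly", "hydronephrosis",
           "diverticulum", "polyp", "hernia", "stricture", "free air",
           "wall thickening", "pleural thickening", "mucus plugging",
           "fat stranding", "micronodule")
  cln <- c("cancer", "malignancy", "metastasis", "pneumonia", "tuberculosis",
           "lymphoma", "sarcoidosis", "abscess", "carcinoma",
           "adenocarcinoma", "interstitial pneumonia", "pulmonary embolism",
           "cirrhosis", "pancreatitis", "cholecystitis", "appendicitis",
           "diverticulitis", "pyelonephritis", "ileus", "peritonitis")
  loc <- c("right upper lobe", "left upper lobe", "right lower lobe",
           "left lower lobe", "right middle lobe", "lingula", "mediastinum",
           "hilum", "pleura", "trachea", "left main bronchus", "liver",
           "gallbladder", "pancreas", "pancreatic head", "spleen",
           "right kidney", "left kidney", "adrenal gland", "stomach",
           "duodenum", "colon", "sigmoid colon", "rectum", "bladder",
           "aorta", "portal vein", "retroperitoneum", "omentum",
           "paraaortic region")
  cer <- c("suspected", "probable", "possible", "definite", "equivocal",
           "likely", "unlikely", "presumed", "indeterminate", "questionable",
           "confirmed", "apparent")
  chg <- c("increased", "decreased", "unchanged", "new", "enlarged",
           "reduced", "stable", "progressing", "resolving", "shrinking")
  cha <- c("irregular", "spiculated", "calcified", "cystic", "solid",
           "heterogeneous", "homogeneous", "lobulated", "diffuse",
           "multiple", "tiny", "faint", "dense", "nodular", "linear")
  sizes <- c(paste(1:40, "mm"), paste(1:20, "cm"),
             paste0(rep(c(10, 12, 15, 18, 20, 22, 25, 30, 35, 40),
                        each = 10), "x",
                    rep(c(4, 5, 6, 8, 10, 12, 14, 15, 16, 18), times = 10),
                    " mm"))
  list(
    Observation = c(obs, pseudo_terms(360, "osis")),
    ClinicalFinding = c(cln, pseudo_terms(180, "opathy")),
    AnatomicalLocation = c(loc, paste(pseudo_terms(270, "al"), "segment")),
    Certainty = cer,
    Change = c(chg, pseudo_terms(50, "ing")),
    Characteristics = c(cha, pseudo_terms(135, "oid")),
    Size = sizes
  )
}

#' Configuration for the synthetic report generator
#'
#' @param n_reports Number of reports to generate.
#' @param sentences_per_report Mean sentence count per report (Poisson,
#'   truncated below at 3). Default 12, matching the ~12-sentence reports
#'   the corpus emulates.
#' @param vocab Named list of per-type mention vocabularies; see
#'   [default_vocab()].
#' @param zipf_exponent Zipf exponent of the mention frequency
#'   distribution (rank `r` drawn with probability proportional to
#'   `r^-zipf_exponent`).
#' @param p_cross_sentence_evidence Probability that a clinical finding's
#'   evidence observation lies in an earlier sentence rather than its own.
#' @param p_out_of_scope_sentence Probability that a sentence is
#'   technique/procedure/recommendation text carrying no annotations
#'   (default 0.084).
#' @param p_finding Probability that an in-scope sentence introduces a
#'   clinical finding rather than a plain observation.
#' @param modifier_probs Named per-type probabilities that an observation
#'   sentence attaches that modifier to its observation (capped at 4
#'   modifiers per concept).
#' @param stopword_rate Probability of inserting an extra stop-word filler
#'   token into a sentence.
#' @param sources Optional character vector of source/stratum labels
#'   assigned uniformly at random (e.g. `c("chest", "abdomen")`).
#' @param seed Integer seed; identical seeds give byte-identical corpora.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_reports = 100,
                             sentences_per_report = 12,
                             vocab = default_vocab(),
                             zipf_exponent = 1.0,
                             p_cross_sentence_evidence = 0.25,
                             p_out_of_scope_sentence = 0.084,
                             p_finding = 0.3,
                             modifier_probs = c(Certainty = 0.25,
                                                Change = 0.15,
                                                Characteristics = 0.2,
                                                Size = 0.25,
                                                AnatomicalLocation = 0.45),
                             stopword_rate = 0.1,
                             sources = NULL,
                             seed = 1L) {
  probs <- c(p_cross_sentence_evidence, p_out_of_scope_sentence, p_finding,
             modifier_probs, stopword_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  need <- entity_types()$name
  if (!all(need %in% names(vocab)) ||
      any(vapply(vocab[need], length, integer(1)) == 0)) {
    stop("vocab must provide a non-empty mention list for each of the 7 ",
         "entity types", call. = FALSE)
  }
  structure(list(
    n_reports = n_reports, sentences_per_report = sentences_per_report,
    vocab = vocab, zipf_exponent = zipf_exponent,
    p_cross_sentence_evidence = p_cross_sentence_evidence,
    p_out_of_scope_sentence = p_out_of_scope_sentence,
    p_finding = p_finding, modifier_probs = modifier_probs,
    stopword_rate = stopword_rate, sources = sources,
    seed = as.integer(seed)
  ), class = "generator_config")
}

# run code under a given seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

zipf_probs <- function(n, s) {
  p <- seq_len(n)^(-s)
  p / sum(p)
}

oos_templates <- function() {
  list(
    c("Plain", "and", "contrast", "enhanced", "CT", "scans", "were",
      "obtained", "."),
    c("Comparison", "was", "made", "with", "the", "prior", "study", "."),
    c("Follow", "up", "imaging", "is", "recommended", "."),
    c("Status", "post", "surgical", "resection", "."),
    c("Clinical", "correlation", "is", "recommended", "."),
    c("The", "examination", "was", "performed", "with", "standard",
      "protocol", "."))
}

#' Generate a synthetic annotated corpus
#'
#' Each report is a sequence of sentences: observation sentences (an
#' observation plus 0-4 modifier entities, linked by gold Modifier
#' relations), finding sentences (a clinical finding whose Evidence
#' observation is either in the same sentence or, with probability
#' `p_cross_sentence_evidence`, the nearest preceding observation), and
#' unannotated out-of-scope sentences. All entities are token-aligned and
#' never cross sentence boundaries; every report passes schema validation
#' and a BRAT write/read round trip.
#'
#' @param config A [generator_config()].
#' @return A list of [rad_report()] objects.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (config$n_reports == 0) return(list())
  with_seed(config$seed, {
    zp <- lapply(config$vocab, function(v)
      zipf_probs(length(v), config$zipf_exponent))
    lapply(seq_len(config$n_reports), function(i) {
      generate_report(sprintf("synth%04d", i), config, zp)
    })
  })
}

draw_mention <- function(type, config, zp) {
  v <- config$vocab[[type]]
  m <- v[sample.int(length(v), 1L, prob = zp[[type]])]
  strsplit(m, " ", fixed = TRUE)[[1]]
}

# One sentence under construction: tokens plus entity annotations given as
# token-index ranges (1-based, inclusive) and intra-sentence relations given
# as local entity indices.
new_sent <- function() {
  list(tokens = character(0), entities = list(), relations = list())
}

add_entity <- function(sent, type, mention_tokens) {
  a <- length(sent$tokens) + 1L
  sent$tokens <- c(sent$tokens, mention_tokens)
  b <- length(sent$tokens)
  sent$entities[[length(sent$entities) + 1L]] <-
    list(type = type, from = a, to = b)
  sent$local_last <- length(sent$entities)
  sent
}

add_words <- function(sent, words) {
  sent$tokens <- c(sent$tokens, words)
  sent
}

build_obs_phrase <- function(sent, config, zp, mods = config$modifier_probs) {
  present <- names(mods)[stats::runif(length(mods)) < mods]
  if (length(present) > 4) present <- sample(present, 4L)
  for (ty in intersect(c("Certainty", "Change", "Characteristics"), present)) {
    sent <- add_entity(sent, ty, draw_mention(ty, config, zp))
  }
  sent <- add_entity(sent, "Observation", draw_mention("Observation", config, zp))
  obs_idx <- length(sent$entities)
  if ("Size" %in% present) {
    sent <- add_words(sent, "measuring")
    sent <- add_entity(sent, "Size", draw_mention("Size", config, zp))
  }
  if ("AnatomicalLocation" %in% present) {
    sent <- add_words(sent, c("in", "the"))
    sent <- add_entity(sent, "AnatomicalLocation",
                       draw_mention("AnatomicalLocation", config, zp))
  }
  for (k in seq_along(sent$entities)) {
    if (k != obs_idx) {
      sent$relations[[length(sent$relations) + 1L]] <-
        list(type = "Modifier", head = obs_idx, tail = k)
    }
  }
  sent$obs_idx <- obs_idx
  sent
}

finish_sentence <- function(sent, config) {
  if (stats::runif(1) < config$stopword_rate) {
    sent <- add_words(sent, "again")
  }
  if (stats::runif(1) < 0.05) {
    sent <- add_words(sent, c("and", "otherwise", "unremarkable"))
  }
  ending <- sample(list(c("is", "seen"), c("is", "noted"),
                        c("is", "present"), "identified"), 1L)[[1]]
  add_words(sent, c(ending, "."))
}

generate_report <- function(id, config, zp) {
  n_sent <- max(3L, stats::rpois(1, config$sentences_per_report))
  sents <- vector("list", n_sent)
  oos <- logical(n_sent)
  # cross-sentence evidence links resolved after assembly:
  # (sentence index of finding entity local idx) -> "nearest preceding obs"
  pending_evidence <- list()
  obs_registry <- list()  # list of (sent, idx) for every observation
  for (si in seq_len(n_sent)) {
    u <- stats::runif(1)
    if (si > 1L && u < config$p_out_of_scope_sentence) {
      oos[si] <- TRUE
      s <- new_sent()
      s$tokens <- sample(oos_templates(), 1L)[[1]]
      sents[[si]] <- s
      next
    }
    is_finding <- si > 1L &&
      u < config$p_out_of_scope_sentence + config$p_finding *
            (1 - config$p_out_of_scope_sentence)
    if (!is_finding) {
      s <- new_sent()
      if (stats::runif(1) < 0.3) s <- add_words(s, "a")
      s <- build_obs_phrase(s, config, zp)
      obs_registry[[length(obs_registry) + 1L]] <-
        list(sent = si, idx = s$obs_idx)
      s <- finish_sentence(s, config)
    } else if (stats::runif(1) < config$p_cross_sentence_evidence) {
      # cross-sentence: finding stands alone, evidence = nearest earlier obs
      s <- new_sent()
      if (stats::runif(1) < 0.4) {
        s <- add_entity(s, "Certainty", draw_mention("Certainty", config, zp))
        cer_idx <- length(s$entities)
      } else cer_idx <- NULL
      s <- add_entity(s, "ClinicalFinding",
                      draw_mention("ClinicalFinding", config, zp))
      cln_idx <- length(s$entities)
      if (!is.null(cer_idx)) {
        s$relations[[length(s$relations) + 1L]] <-
          list(type = "Modifier", head = cln_idx, tail = cer_idx)
      }
      s <- add_words(s, c("is", sample(c("considered", "favored"), 1L), "."))
      pending_evidence[[length(pending_evidence) + 1L]] <-
        list(sent = si, idx = cln_idx)
    } else {
      # same-sentence: "<obs phrase> consistent with <finding>"
      s <- new_sent()
      mods <- config$modifier_probs * 0.6
      s <- build_obs_phrase(s, config, zp, mods = mods)
      obs_idx <- s$obs_idx
      obs_registry[[length(obs_registry) + 1L]] <-
        list(sent = si, idx = obs_idx)
      cue <- sample(list(c("consistent", "with"), c("suggestive", "of"),
                         c("compatible", "with")), 1L)[[1]]
      s <- add_words(s, cue)
      s <- add_entity(s, "ClinicalFinding",
                      draw_mention("ClinicalFinding", config, zp))
      s$relations[[length(s$relations) + 1L]] <-
        list(type = "Evidence", head = obs_idx,
             tail = length(s$entities))
      s <- add_words(s, ".")
    }
    sents[[si]] <- s
  }
  assemble_report(id, sents, oos, pending_evidence, obs_registry, config)
}

# join sentence token lists into text, compute character offsets, and build
# global entity/relation tables
assemble_report <- function(id, sents, oos, pending_evidence, obs_registry,
                            config) {
  text <- ""
  ent_rows <- list()
  rel_rows <- list()
  # global entity index per (sentence, local index)
  gidx <- lapply(sents, function(s) integer(length(s$entities)))
  for (si in seq_along(sents)) {
    s <- sents[[si]]
    starts <- integer(length(s$tokens))
    ends <- integer(length(s$tokens))
    for (ti in seq_along(s$tokens)) {
      tok <- s$tokens[ti]
      sep <- if (nchar(text) == 0) "" else if (tok %in% c(".", ",")) "" else " "
      starts[ti] <- nchar(text) + nchar(sep)
      text <- paste0(text, sep, tok)
      ends[ti] <- nchar(text)
    }
    for (ei in seq_along(s$entities)) {
      e <- s$entities[[ei]]
      gi <- length(ent_rows) + 1L
      gidx[[si]][ei] <- gi
      ent_rows[[gi]] <- data.frame(
        id = paste0("T", gi), type = e$type,
        start = starts[e$from], end = ends[e$to],
        stringsAsFactors = FALSE)
    }
    for (r in s$relations) {
      rel_rows[[length(rel_rows) + 1L]] <- data.frame(
        type = r$type, head = paste0("T", gidx[[si]][r$head]),
        tail = paste0("T", gidx[[si]][r$tail]), stringsAsFactors = FALSE)
    }
  }
  # resolve cross-sentence evidence to the nearest preceding observation
  obs_sent <- vapply(obs_registry, `[[`, integer(1), "sent")
  for (pe in pending_evidence) {
    prior <- which(obs_sent < pe$sent)
    if (length(prior) == 0) next
    k <- prior[length(prior)]
    head_gi <- gidx[[obs_registry[[k]]$sent]][obs_registry[[k]]$idx]
    tail_gi <- gidx[[pe$sent]][pe$idx]
    rel_rows[[length(rel_rows) + 1L]] <- data.frame(
      type = "Evidence", head = paste0("T", head_gi),
      tail = paste0("T", tail_gi), stringsAsFactors = FALSE)
  }
  entities <- if (length(ent_rows)) do.call(rbind, ent_rows)
              else empty_entities()
  if (nrow(entities) > 0) {
    entities$text <- substring(text, entities$start + 1L, entities$end)
  } else entities$text <- character(0)
  relations <- if (length(rel_rows)) do.call(rbind, rel_rows)
               else empty_relations()
  if (nrow(relations) > 0) relations$id <- paste0("R", seq_len(nrow(relations)))
  relations <- relations[, c("id", "type", "head", "tail"), drop = FALSE]
  src <- if (is.null(config$sources)) NA_character_
         else sample(config$sources, 1L)
  r <- rad_report(id = id, text = text, entities = entities,
                  relations = relations, source = src, tokenize = TRUE)
  r$oos <- oos
  r
}

#' Summary statistics of an annotated corpus
#'
#' @param corpus A list of reports.
#' @return A list of class `corpus_stats`: per-type entity counts, per-type
#'   relation counts (Modifier broken down by tail entity type), the
#'   mention-frequency table, sentence/token totals, and the fraction of
#'   Evidence relations whose endpoints lie in different sentences.
#' @export
corpus_statistics <- function(corpus) {
  types <- entity_types()$name
  ent_counts <- stats::setNames(integer(length(types)), types)
  rel_counts <- c(Modifier = 0L, Evidence = 0L)
  mod_by_tail <- stats::setNames(integer(5), modifier_types())
  mention_freq <- integer(0)
  n_sent <- 0L; n_tok <- 0L; n_oos <- 0L
  ev_total <- 0L; ev_cross <- 0L
  for (r in corpus) {
    tab <- table(r$entities$type)
    ent_counts[names(tab)] <- ent_counts[names(tab)] + as.integer(tab)
    rtab <- table(r$relations$type)
    rel_counts[names(rtab)] <- rel_counts[names(rtab)] + as.integer(rtab)
    n_sent <- n_sent + length(r$sentences)
    n_oos <- n_oos + sum(r$oos)
    n_tok <- n_tok + sum(vapply(r$sentences, function(s) nrow(s$tokens),
                                integer(1)))
    mf <- table(r$entities$text)
    for (nm in names(mf)) {
      mention_freq[nm] <- (if (nm %in% names(mention_freq))
        mention_freq[nm] else 0L) + as.integer(mf[nm])
    }
    if (nrow(r$relations) > 0) {
      sent_of <- function(pos) {
        findInterval(pos, vapply(r$sentences, `[[`, numeric(1), "start"))
      }
      ent_sent <- sent_of(r$entities$start)
      names(ent_sent) <- r$entities$id
      for (k in which(r$relations$type == "Evidence")) {
        ev_total <- ev_total + 1L
        if (ent_sent[r$relations$head[k]] != ent_sent[r$relations$tail[k]]) {
          ev_cross <- ev_cross + 1L
        }
      }
      mods <- r$relations[r$relations$type == "Modifier", , drop = FALSE]
      if (nrow(mods) > 0) {
        tt <- r$entities$type[match(mods$tail, r$entities$id)]
        mtab <- table(tt)
        mod_by_tail[names(mtab)] <- mod_by_tail[names(mtab)] +
          as.integer(mtab)
      }
    }
  }
  structure(list(
    n_reports = length(corpus), n_sentences = n_sent, n_tokens = n_tok,
    n_out_of_scope = n_oos, entity_counts = ent_counts,
    relation_counts = rel_counts, modifier_by_tail = mod_by_tail,
    mention_freq = mention_freq,
    cross_sentence_evidence = c(n = ev_cross, total = ev_total,
                                fraction = if (ev_total > 0)
                                  ev_cross / ev_total else NA_real_)
  ), class = "corpus_stats")
}

#' @export
print.corpus_stats <- function(x, ...) {
  cat(sprintf("Corpus: %d reports, %d sentences (%d out-of-scope), %d tokens\n",
              x$n_reports, x$n_sentences, x$n_out_of_scope, x$n_tokens))
  cat("Entities:\n")
  print(x$entity_counts)
  cat("Relations:\n")
  print(x$relation_counts)
  cat("Modifier relations by tail type:\n")
  print(x$modifier_by_tail)
  cat(sprintf("Cross-sentence evidence: %d / %d (%.3f)\n",
              x$cross_sentence_evidence["n"], x$cross_sentence_evidence["total"],
              x$cross_sentence_evidence["fraction"]))
  invisible(x)
}

#' Generate a corpus and write it as a BRAT directory with a manifest
#'
#' @param config A [generator_config()].
#' @param dir Output directory.
#' @return The corpus, invisibly.
#' @export
write_synthetic_corpus <- function(config, dir) {
  corpus <- generate_corpus(config)
  echo <- config
  echo$vocab <- lapply(echo$vocab, length)  # echo sizes, not full lists
  write_brat_dir(corpus, dir, manifest = list(
    generator = "radrelex synthetic corpus", seed = config$seed,
    config = unclass(echo)))
  invisible(corpus)
}
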
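#' Segment report text into sentence spans
#'
#' Sentences are delimited by configurable terminator characters
#' (by default the Japanese full stop, newline, and the ASCII period);
#' a terminator belongs to the sentence it ends. Leading and trailing
#' whitespace is excluded from each span, so the spans cover all
#' non-whitespace text without overlapping.
#'
#' @param text Report text.
#' @param terminators Character vector of single-character terminators.
#' @return A data frame with 0-based half-open columns `start`, `end`.
#' @examples
#' segment_sentences("No nodule. Effusion seen.")
#' @export
segment_sentences <- function(text, terminators = c("。", "\n", ".")) {
  if (is.na(text) || nchar(text) == 0) {
    return(data.frame(start = integer(), end = integer()))
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  is_term <- chars %in% terminators
  bounds <- c(which(is_term), if (!is_term[length(chars)]) length(chars))
  spans <- list()
  cur <- 1L
  for (b in bounds) {
    seg <- cur:b
    nonws <- seg[!grepl("^\\s$", chars[seg])]
    if (length(nonws) > 0) {
      spans[[length(spans) + 1L]] <- c(min(nonws) - 1L, max(nonws))
    }
    cur <- b + 1L
  }
  if (length(spans) == 0) {
    return(data.frame(start = integer(), end = integer()))
  }
  out <- do.call(rbind, spans)
  data.frame(start = as.integer(out[, 1]), end = as.integer(out[, 2]))
}

#' Default tokenizer: maximal alphanumeric runs and single punctuation marks
#'
#' A deliberately simple, language-neutral tokenizer: every maximal run of
#' Unicode letters/digits is one token and every other non-whitespace
#' character is a single-character token. A morphological analyzer (e.g. a
#' MeCab wrapper for Japanese) can be plugged in anywhere a `tokenizer`
#' argument is accepted: any function mapping text to a data frame with
#' 0-based half-open `start`, `end` and `text` columns is a valid tokenizer.
#'
#' @param text Text to tokenize.
#' @return A data frame with columns `start`, `end`, `text` (offsets into
#'   `text`, 0-based half-open).
#' @export
default_tokenizer <- function(text) {
  if (is.na(text) || nchar(text) == 0) {
    return(data.frame(start = integer(), end = integer(), text = character(),
                      stringsAsFactors = FALSE))
  }
  m <- gregexpr("[\\p{L}\\p{N}]+|[^\\p{L}\\p{N}\\s]", text, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(data.frame(start = integer(), end = integer(), text = character(),
                      stringsAsFactors = FALSE))
  }
  start <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  data.frame(start = start, end = start + len,
             text = substring(text, start + 1L, start + len),
             stringsAsFactors = FALSE)
}

#' Segment and tokenize a report in place
#'
#' @param report A [rad_report()].
#' @param tokenizer Tokenizer function (see [default_tokenizer()]).
#' @param terminators Sentence terminators for [segment_sentences()].
#' @return The report with its `sentences` field populated: a list of
#'   sentence records, each holding absolute `start`/`end` offsets and a
#'   token table with absolute offsets.
#' @export
tokenize_report <- function(report, tokenizer = default_tokenizer,
                            terminators = c("。", "\n", ".")) {
  spans <- segment_sentences(report$text, terminators)
  sentences <- vector("list", nrow(spans))
  for (i in seq_len(nrow(spans))) {
    s <- spans$start[i]; e <- spans$end[i]
    toks <- tokenizer(substring(report$text, s + 1L, e))
    toks$start <- toks$start + s
    toks$end <- toks$end + s
    sentences[[i]] <- list(start = s, end = e, tokens = toks)
  }
  report$sentences <- sentences
  if (is.null(report$oos) || length(report$oos) != length(sentences)) {
    report$oos <- rep(FALSE, length(sentences))
  }
  report
}

#' Encode entity spans as an IOB2 tag sequence
#'
#' The first token of an entity receives `B-<type>`, subsequent tokens
#' `I-<type>`, and all other tokens `O`. When an entity boundary falls
#' inside a token, the token is split at the boundary so the gold span is
#' preserved (set `on_misaligned = "error"` to forbid this). Overlapping
#' entities cannot be represented in IOB2 and raise an error.
#'
#' @param tokens Token data frame (`start`, `end`, `text`), e.g. one
#'   sentence's tokens.
#' @param entities Entity data frame restricted to spans inside the token
#'   range.
#' @param on_misaligned `"split"` (default) or `"error"`.
#' @return A character vector of tags, one per (possibly split) token, with
#'   the token table attached as attribute `"tokens"`.
#' @export
encode_iob2 <- function(tokens, entities, on_misaligned = c("split", "error")) {
  on_misaligned <- match.arg(on_misaligned)
  if (nrow(entities) > 1) {
    ord <- order(entities$start, entities$end)
    entities <- entities[ord, , drop = FALSE]
    if (any(entities$start[-1] < entities$end[-nrow(entities)])) {
      stop("overlapping entities cannot be encoded in IOB2", call. = FALSE)
    }
  }
  bounds <- sort(unique(c(entities$start, entities$end)))
  inner <- bounds[vapply(bounds, function(b)
    any(tokens$start < b & b < tokens$end), logical(1))]
  if (length(inner) > 0) {
    if (on_misaligned == "error") {
      stop("entity boundary falls inside a token", call. = FALSE)
    }
    tokens <- split_tokens_at(tokens, inner)
  }
  tags <- rep("O", nrow(tokens))
  for (i in seq_len(nrow(entities))) {
    idx <- which(tokens$start >= entities$start[i] &
                 tokens$end <= entities$end[i])
    if (length(idx) == 0) next
    tags[idx[1]] <- paste0("B-", entities$type[i])
    if (length(idx) > 1) {
      tags[idx[-1]] <- paste0("I-", entities$type[i])
    }
  }
  attr(tags, "tokens") <- tokens
  tags
}

split_tokens_at <- function(tokens, cuts) {
  rows <- list()
  for (i in seq_len(nrow(tokens))) {
    s <- tokens$start[i]; e <- tokens$end[i]
    inner <- sort(cuts[cuts > s & cuts < e])
    edges <- c(s, inner, e)
    for (k in seq_len(length(edges) - 1L)) {
      a <- edges[k]; b <- edges[k + 1L]
      off <- a - s
      rows[[length(rows) + 1L]] <- data.frame(
        start = a, end = b,
        text = substring(tokens$text[i], off + 1L, off + (b - a)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Decode an IOB2 tag sequence back to entity spans
#'
#' Maximal `B-t (I-t)*` runs become entities whose character offsets come
#' from the token table. Invalid sequences (an `I-t` following `O` or a
#' different type) are repaired by promoting the orphan `I-t` to `B-t`, the
#' usual conlleval convention.
#'
#' @param tokens Token data frame (`start`, `end`, `text`).
#' @param tags Character vector of IOB2 tags, one per token.
#' @param text Optional full text used to fill the entity `text` field.
#' @param id_prefix Prefix for generated entity ids.
#' @return An entity data frame (`id`, `type`, `start`, `end`, `text`).
#' @export
decode_iob2 <- function(tokens, tags, text = NULL, id_prefix = "T") {
  if (length(tags) != nrow(tokens)) {
    stop("one tag per token required (", length(tags), " tags, ",
         nrow(tokens), " tokens)", call. = FALSE)
  }
  # repair: orphan I-t becomes B-t
  prev <- "O"
  for (i in seq_along(tags)) {
    if (startsWith(tags[i], "I-")) {
      ty <- substring(tags[i], 3)
      if (!(prev %in% paste0(c("B-", "I-"), ty))) {
        tags[i] <- paste0("B-", ty)
      }
    }
    prev <- tags[i]
  }
  ents <- list()
  i <- 1L
  while (i <= length(tags)) {
    if (startsWith(tags[i], "B-")) {
      ty <- substring(tags[i], 3)
      j <- i
      while (j + 1L <= length(tags) && tags[j + 1L] == paste0("I-", ty)) {
        j <- j + 1L
      }
      ents[[length(ents) + 1L]] <- data.frame(
        type = ty, start = tokens$start[i], end = tokens$end[j],
        stringsAsFactors = FALSE)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(ents) == 0) return(empty_entities())
  out <- do.call(rbind, ents)
  out$id <- paste0(id_prefix, seq_len(nrow(out)))
  out$text <- if (is.null(text)) NA_character_ else
    substring(text, out$start + 1L, out$end)
  out[, c("id", "type", "start", "end", "text")]
}

#' Read a report from BRAT standoff documents
#'
#' Consumes `T` (entity) and `R` (relation) lines of the BRAT standoff
#' dialect; attribute/event/normalization lines are ignored with a warning.
#' Entity offsets and relation type constraints are validated against the
#' text and the information model.
#'
#' @param text Contents of the `.txt` document (a single string).
#' @param ann Contents of the `.ann` document (a single string, or a
#'   character vector of lines).
#' @param id Report identifier.
#' @param source Optional source/stratum tag.
#' @param tokenize Segment and tokenize on read (default `TRUE`).
#' @return A [rad_report()].
#' @export
read_brat <- function(text, ann, id = "report", source = NA_character_,
                      tokenize = TRUE) {
  lines <- if (length(ann) == 1L) strsplit(ann, "\n", fixed = TRUE)[[1]]
           else ann
  lines <- lines[nzchar(trimws(lines))]
  ents <- list(); rels <- list()
  for (k in seq_along(lines)) {
    ln <- lines[k]
    lead <- substring(ln, 1, 1)
    if (lead == "T") {
      m <- regmatches(ln, regexec(
        "^(\\S+)\t(\\S+) (\\d+) (\\d+)\t(.*)$", ln))[[1]]
      if (length(m) == 0) {
        stop("malformed entity line ", k, ": ", ln, call. = FALSE)
      }
      start <- as.integer(m[4]); end <- as.integer(m[5])
      if (start >= end || end > nchar(text)) {
        stop("entity offsets outside text at line ", k, call. = FALSE)
      }
      check_entity_type(m[3])
      sub <- substring(text, start + 1L, end)
      if (sub != m[6]) {
        stop("entity text mismatch at line ", k, ": '", m[6],
             "' vs substring '", sub, "'", call. = FALSE)
      }
      ents[[length(ents) + 1L]] <- data.frame(
        id = m[2], type = m[3], start = start, end = end, text = m[6],
        stringsAsFactors = FALSE)
    } else if (lead == "R") {
      m <- regmatches(ln, regexec(
        "^(\\S+)\t(\\S+) Arg1:(\\S+) Arg2:(\\S+)\\s*$", ln))[[1]]
      if (length(m) == 0) {
        stop("malformed relation line ", k, ": ", ln, call. = FALSE)
      }
      check_relation_type(m[3])
      rels[[length(rels) + 1L]] <- data.frame(
        id = m[2], type = m[3], head = m[4], tail = m[5], line = k,
        stringsAsFactors = FALSE)
    } else {
      warning("ignoring unsupported annotation line ", k, " ('", lead,
              "' type)", call. = FALSE)
    }
  }
  entities <- if (length(ents)) do.call(rbind, ents) else empty_entities()
  relations <- if (length(rels)) do.call(rbind, rels) else empty_relations()
  if (nrow(relations) > 0) {
    miss <- !(relations$head %in% entities$id) |
            !(relations$tail %in% entities$id)
    if (any(miss)) {
      stop("relation endpoint refers to unknown entity at line ",
           relations$line[which(miss)[1]], call. = FALSE)
    }
    ht <- entities$type[match(relations$head, entities$id)]
    tt <- entities$type[match(relations$tail, entities$id)]
    ok <- mapply(validate_relation, ht, tt, relations$type)
    if (!all(ok)) {
      stop("relation violates schema at line ",
           relations$line[which(!ok)[1]], ": (", ht[which(!ok)[1]], ", ",
           tt[which(!ok)[1]], ") for ", relations$type[which(!ok)[1]],
           call. = FALSE)
    }
    relations$line <- NULL
  }
  rad_report(id = id, text = text, entities = entities,
             relations = relations, source = source, tokenize = tokenize)
}

#' Write a report as BRAT standoff documents
#'
#' Inverse of [read_brat()]: entity and relation identifiers are renumbered
#' in document order, so a read/write round trip reproduces the report up to
#' identifier renaming.
#'
#' @param report A valid [rad_report()].
#' @return A list with elements `text` and `ann` (single strings).
#' @export
write_brat <- function(report) {
  ent <- report$entities
  rel <- report$relations
  lines <- character(0)
  if (nrow(ent) > 0) {
    ord <- order(ent$start, ent$end)
    ent <- ent[ord, , drop = FALSE]
    new_id <- paste0("T", seq_len(nrow(ent)))
    id_map <- stats::setNames(new_id, ent$id)
    lines <- sprintf("%s\t%s %d %d\t%s", new_id, ent$type, ent$start,
                     ent$end, ent$text)
    if (nrow(rel) > 0) {
      lines <- c(lines, sprintf("R%d\t%s Arg1:%s Arg2:%s",
                                seq_len(nrow(rel)), rel$type,
                                id_map[rel$head], id_map[rel$tail]))
    }
  }
  list(text = report$text, ann = paste0(lines, collapse = "\n"))
}

#' Read a BRAT standoff directory into a corpus
#'
#' @param dir Directory containing paired `<id>.txt` / `<id>.ann` files.
#' @param tokenize Segment and tokenize each report.
#' @return A list of [rad_report()] objects.
#' @export
read_brat_dir <- function(dir, tokenize = TRUE) {
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  lapply(txts, function(f) {
    id <- sub("\\.txt$", "", basename(f))
    annf <- file.path(dir, paste0(id, ".ann"))
    ann <- if (file.exists(annf)) readChar(annf, file.info(annf)$size) else ""
    read_brat(readChar(f, file.info(f)$size), ann, id = id,
              tokenize = tokenize)
  })
}

#' Write a corpus as a BRAT standoff directory
#'
#' One `.txt` + `.ann` pair per report; an optional JSON manifest records
#' provenance (e.g. the generator seed and configuration echo).
#'
#' @param corpus List of reports.
#' @param dir Output directory (created if needed).
#' @param manifest Optional list serialized to `manifest.json`.
#' @return `dir`, invisibly.
#' @export
write_brat_dir <- function(corpus, dir, manifest = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (r in corpus) {
    doc <- write_brat(r)
    writeLines(doc$text, file.path(dir, paste0(r$id, ".txt")), sep = "")
    writeLines(doc$ann, file.path(dir, paste0(r$id, ".ann")), sep = "")
  }
  if (!is.null(manifest)) {
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Export a report in CoNLL-style token/tag columns
#'
#' @param report A tokenized, annotated report.
#' @return A character vector of lines (`token<TAB>tag`), sentences
#'   separated by empty lines.
#' @export
export_conll <- function(report) {
  out <- character(0)
  for (s in report$sentences) {
    ent <- sentence_entities(report, s)
    tags <- encode_iob2(s$tokens, ent)
    toks <- attr(tags, "tokens")
    out <- c(out, paste0(toks$text, "\t", as.character(tags)), "")
  }
  out
}

# entities fully inside a sentence span
sentence_entities <- function(report, sentence) {
  ent <- report$entities
  ent[ent$start >= sentence$start & ent$end <= sentence$end, , drop = FALSE]
}
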
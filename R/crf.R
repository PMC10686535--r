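#' CRF log-likelihood of a gold tag path
#'
#' Computes `score(gold path) - log Z`, with the log-partition `Z` obtained
#' by the forward algorithm in log space; the result is always `<= 0`.
#' Scores of a path are the sum of its per-token emission scores, the
#' transition scores of consecutive tag pairs, and the start/stop scores of
#' its first/last tag.
#'
#' @param emissions Numeric matrix, one row per token, one column per tag.
#' @param transitions `K x K` matrix of tag-to-tag transition scores
#'   (`transitions[i, j]` scores tag `i` followed by tag `j`).
#' @param gold_tags Integer vector of 1-based tag indices, one per token.
#' @param start,stop Optional length-`K` start/stop score vectors
#'   (default all zero).
#' @return The log-likelihood (a non-positive scalar).
#' @examples
#' # one token, 15 tags, all scores zero: every path equally likely
#' crf_log_likelihood(matrix(0, 1, 15), matrix(0, 15, 15), 1L)  # -log(15)
#' @export
crf_log_likelihood <- function(emissions, transitions, gold_tags,
                               start = NULL, stop = NULL) {
  emissions <- as.matrix(emissions)
  K <- ncol(emissions)
  if (is.null(start)) start <- numeric(K)
  if (is.null(stop)) stop <- numeric(K)
  gold_tags <- as.integer(gold_tags)
  if (length(gold_tags) != nrow(emissions)) {
    stop("one gold tag per token required", call. = FALSE)
  }
  -cpp_crf_nll(emissions, as.matrix(transitions), start, stop, gold_tags,
               grad = FALSE)$nll
}

#' Viterbi decoding of the highest-scoring tag path
#'
#' Ties are broken toward the lowest tag index at each backpointer, so the
#' decoded path is deterministic.
#'
#' @inheritParams crf_log_likelihood
#' @return Integer vector of 1-based tag indices (empty for an empty
#'   sentence).
#' @export
viterbi_decode <- function(emissions, transitions, start = NULL,
                           stop = NULL) {
  emissions <- as.matrix(emissions)
  if (nrow(emissions) == 0) return(integer(0))
  K <- ncol(emissions)
  if (is.null(start)) start <- numeric(K)
  if (is.null(stop)) stop <- numeric(K)
  as.integer(cpp_viterbi(emissions, as.matrix(transitions), start, stop))
}
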
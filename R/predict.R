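#' Build a ranked scoreboard of known and candidate pairs
#'
#' Scores the training edges (flagged as known interactions) together with
#' the candidate pairs and ranks all of them by score, descending. Ties are
#' ordered by canonical pair identifier (`min|max` of the two protein ids) so
#' windows are reproducible.
#'
#' @param train_net the training [annotated_network()] (its edges define the
#'   known-interaction flags).
#' @param membership n x K membership matrix from [fit_modules()].
#' @param candidate_pairs two-column matrix/data frame of pairs to add to the
#'   board (may be empty); pairs duplicating a training edge are kept once,
#'   flagged known.
#' @param phi,max_interior,decay_mode,lw_mode scoring options, see
#'   [score_pair()].
#' @param half_width sliding-window half-size (default 50).
#' @return An object of class `ngpm_scoreboard`: data frame `entries` with
#'   columns `a`, `b`, `pair_id`, `score`, `is_known_ppi`, sorted; plus
#'   `half_width`.
#' @export
build_scoreboard <- function(train_net, membership, candidate_pairs,
                             phi = 1, max_interior = 3L, half_width = 50L,
                             decay_mode = c("linear", "exp"),
                             lw_mode = c("interior", "total")) {
  decay_mode <- match.arg(decay_mode); lw_mode <- match.arg(lw_mode)
  A <- train_net$adjacency
  idx <- which(upper.tri(A) & A == 1L, arr.ind = TRUE)
  known <- cbind(train_net$proteins[idx[, 1]], train_net$proteins[idx[, 2]])
  cand <- as.matrix(candidate_pairs)
  if (nrow(cand)) {
    cand <- cbind(train_net$proteins[as_index_vec(train_net, cand[, 1])],
                  train_net$proteins[as_index_vec(train_net, cand[, 2])])
  }
  all_pairs <- rbind(known, cand)
  if (nrow(all_pairs) == 0L) stop("scoreboard would be empty")
  pid <- canonical_pair_id(all_pairs[, 1], all_pairs[, 2])
  keep <- !duplicated(pid)
  all_pairs <- all_pairs[keep, , drop = FALSE]
  pid <- pid[keep]
  known_ids <- canonical_pair_id(known[, 1], known[, 2])

  sc <- score_pairs(train_net, membership, all_pairs, phi, max_interior,
                    decay_mode, lw_mode)
  entries <- data.frame(a = sc$a, b = sc$b, pair_id = pid, score = sc$score,
                        is_known_ppi = pid %in% known_ids,
                        stringsAsFactors = FALSE)
  entries <- entries[order(-entries$score, entries$pair_id), ]
  rownames(entries) <- NULL
  structure(list(entries = entries, half_width = as.integer(half_width)),
            class = "ngpm_scoreboard")
}

as_index_vec <- function(net, x) {
  if (is.character(x)) protein_index(net, x)
  else {
    x <- as.integer(x)
    if (any(x < 1L | x > length(net$proteins)))
      stop("protein index out of range")
    x
  }
}

canonical_pair_id <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' @export
print.ngpm_scoreboard <- function(x, ...) {
  cat(sprintf("ngpm_scoreboard: %d pairs (%d known), half_width %d\n",
              nrow(x$entries), sum(x$entries$is_known_ppi), x$half_width))
  invisible(x)
}

#' Sliding-window interaction probability of one pair
#'
#' Takes the pair's rank on the board and forms a reference window of up to
#' `half_width` entries above and `half_width` below (truncated at the ends
#' of the board, the queried pair itself excluded). Returns the fraction of
#' known interactions in the window; an empty window gives 0.
#'
#' @param board an `ngpm_scoreboard`.
#' @param a,b the pair's protein identifiers.
#' @return Probability in \[0, 1\].
#' @export
window_probability <- function(board, a, b) {
  e <- board$entries
  pos <- match(canonical_pair_id(a, b), e$pair_id)
  if (is.na(pos)) stop("pair ", a, "|", b, " is not on the scoreboard")
  h <- board$half_width
  win <- setdiff(seq(max(1L, pos - h), min(nrow(e), pos + h)), pos)
  if (length(win) == 0L) return(0)
  mean(e$is_known_ppi[win])
}

#' Calibrated interaction probabilities for query pairs
#'
#' Applies [window_probability()] to each query. A query that is absent from
#' the board, or whose raw score is 0 (no network path connects the pair),
#' gets probability 0.
#'
#' @param board an `ngpm_scoreboard`.
#' @param query_pairs two-column matrix/data frame of protein identifiers.
#' @return data frame `a`, `b`, `score`, `probability`.
#' @export
predict_probabilities <- function(board, query_pairs) {
  q <- as.matrix(query_pairs)
  if (nrow(q) == 0L)
    return(data.frame(a = character(), b = character(), score = numeric(),
                      probability = numeric()))
  e <- board$entries
  pid <- canonical_pair_id(q[, 1], q[, 2])
  pos <- match(pid, e$pair_id)
  prob <- numeric(nrow(q))
  score <- numeric(nrow(q))
  for (r in seq_len(nrow(q))) {
    if (is.na(pos[r])) next
    score[r] <- e$score[pos[r]]
    if (score[r] > 0)
      prob[r] <- window_probability(board, q[r, 1], q[r, 2])
  }
  data.frame(a = q[, 1], b = q[, 2], score = score, probability = prob,
             stringsAsFactors = FALSE)
}
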
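#' Enumerate simple paths between two proteins
#'
#' All simple paths from `i` to `j` with at least 1 and at most `max_interior`
#' interior proteins. The direct edge (no interior) is never returned. Output
#' order is deterministic (lexicographic by node sequence).
#'
#' @param net an [annotated_network()].
#' @param i,j protein identifiers or 1-based indices; `i != j`.
#' @param max_interior cap on interior proteins per path (>= 1); default 3.
#' @return List of integer vectors, each the interior node indices of one
#'   path in order from `i` to `j`.
#' @export
enumerate_paths <- function(net, i, j, max_interior = 3L) {
  ii <- as_index(net, i); jj <- as_index(net, j)
  if (ii == jj) stop("i and j must differ")
  if (max_interior < 1L) stop("max_interior must be >= 1")
  csr <- adjacency_csr(net)
  enumerate_paths_cpp(csr$adj, csr$ptr, ii - 1L, jj - 1L,
                      as.integer(max_interior))
}

as_index <- function(net, x) {
  if (is.character(x)) protein_index(net, x)
  else {
    x <- as.integer(x)
    if (x < 1L || x > length(net$proteins)) stop("protein index out of range")
    x
  }
}

#' Path weight under a membership matrix
#'
#' Product over the path's interior proteins of their membership in module
#' `k`; the empty product is 1.
#'
#' @param interior integer vector of interior node indices.
#' @param membership n x K row-stochastic matrix.
#' @param k module index.
#' @return Value in \[0, 1\].
#' @export
path_weight <- function(interior, membership, k) {
  prod(membership[interior, k])
}

#' Path decay penalty
#'
#' Linear mode (default) returns `phi * n_interior`; exponential mode returns
#' `phi ^ n_interior`.
#'
#' @param n_interior number of interior proteins (>= 1).
#' @param phi decay coefficient, >= 1.
#' @param mode `"linear"` or `"exp"`.
#' @return Positive scalar.
#' @export
path_decay <- function(n_interior, phi = 1, mode = c("linear", "exp")) {
  mode <- match.arg(mode)
  if (any(n_interior < 1)) stop("n_interior must be >= 1")
  if (phi < 1) stop("phi must be >= 1")
  switch(mode, linear = phi * n_interior, exp = phi^n_interior)
}

#' Score one candidate protein pair
#'
#' Sums `weight / decay` over all simple paths between the pair with up to
#' `max_interior` interior proteins. The module `k` weighting the paths is
#' the argmax module of the *first* protein of the pair. A pair with no
#' qualifying path scores 0. With `lw_mode = "total"` the path size counts
#' the endpoints too: the weight product then includes the endpoints and the
#' decay uses `n_interior + 2`.
#'
#' @param net an [annotated_network()].
#' @param membership n x K matrix (rows follow `net$proteins`).
#' @param i,j protein identifiers or indices.
#' @param phi decay coefficient (>= 1).
#' @param max_interior path cap (default 3).
#' @param decay_mode `"linear"` (default) or `"exp"`.
#' @param lw_mode `"interior"` (default) or `"total"` path-size convention.
#' @return List of class `ngpm_score`: `pair` (identifiers), `score`,
#'   `n_paths`, `module`.
#' @export
score_pair <- function(net, membership, i, j, phi = 1, max_interior = 3L,
                       decay_mode = c("linear", "exp"),
                       lw_mode = c("interior", "total")) {
  decay_mode <- match.arg(decay_mode)
  lw_mode <- match.arg(lw_mode)
  df <- score_pairs(net, membership, cbind(i, j), phi, max_interior,
                    decay_mode, lw_mode)
  ii <- as_index(net, i)
  structure(list(pair = c(df$a, df$b), score = df$score,
                 n_paths = df$n_paths,
                 module = derive_labels(membership)[ii]),
            class = "ngpm_score")
}

#' Score a batch of candidate pairs
#'
#' Element-wise [score_pair()]; the result does not depend on evaluation
#' order.
#'
#' @param net,membership,phi,max_interior,decay_mode,lw_mode as in
#'   [score_pair()].
#' @param pairs two-column matrix or data frame of protein identifiers (or
#'   indices), one pair per row.
#' @return data frame with columns `a`, `b`, `score`, `n_paths`.
#' @export
score_pairs <- function(net, membership, pairs, phi = 1, max_interior = 3L,
                        decay_mode = c("linear", "exp"),
                        lw_mode = c("interior", "total")) {
  decay_mode <- match.arg(decay_mode); lw_mode <- match.arg(lw_mode)
  pairs <- as.matrix(pairs)
  if (nrow(pairs) == 0L)
    return(data.frame(a = character(), b = character(), score = numeric(),
                      n_paths = integer()))
  ii <- as_index_vec(net, pairs[, 1])
  jj <- as_index_vec(net, pairs[, 2])
  if (any(ii == jj)) stop("pairs must have distinct endpoints")
  if (phi < 1) stop("phi must be >= 1")
  if (max_interior < 1L) stop("max_interior must be >= 1")
  csr <- adjacency_csr(net)
  k <- derive_labels(membership)
  res <- score_pairs_cpp(csr$adj, csr$ptr, membership,
                         cbind(ii, jj) - 1L, k[ii] - 1L, phi,
                         as.integer(max_interior), decay_mode == "exp",
                         lw_mode == "total")
  data.frame(a = net$proteins[ii], b = net$proteins[jj],
             score = res[, 1], n_paths = as.integer(res[, 2]),
             stringsAsFactors = FALSE)
}

adjacency_csr <- function(net) {
  A <- net$adjacency
  nbrs <- lapply(seq_len(nrow(A)), function(v) which(A[v, ] == 1L))
  list(adj = as.integer(unlist(nbrs) - 1L),
       ptr = c(0L, cumsum(lengths(nbrs))))
}

#' Exhaustive scoring oracle
#'
#' Recomputes the pair score by naive recursive enumeration of all simple
#' paths in R, independent of the DFS used by [score_pair()]. Intended for
#' testing on small graphs.
#'
#' @inheritParams score_pair
#' @return Scalar score.
#' @export
brute_force_score <- function(net, membership, i, j, phi = 1,
                              max_interior = 3L,
                              decay_mode = c("linear", "exp"),
                              lw_mode = c("interior", "total")) {
  decay_mode <- match.arg(decay_mode); lw_mode <- match.arg(lw_mode)
  ii <- as_index(net, i); jj <- as_index(net, j)
  A <- net$adjacency
  k <- which.max(membership[ii, ])
  total <- 0
  walk <- function(node, visited, interior) {
    for (nb in seq_len(nrow(A))) {
      if (A[node, nb] != 1L) next
      if (nb == jj) {
        ni <- length(interior)
        if (ni >= 1L) {
          w <- prod(membership[interior, k])
          lw <- ni
          if (lw_mode == "total") {
            w <- w * membership[ii, k] * membership[jj, k]
            lw <- lw + 2L
          }
          d <- if (decay_mode == "linear") phi * lw else phi^lw
          total <<- total + w / d
        }
      } else if (!(nb %in% visited) && length(interior) < max_interior) {
        walk(nb, c(visited, nb), c(interior, nb))
      }
    }
  }
  walk(ii, c(ii, jj), integer(0))
  total
}
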
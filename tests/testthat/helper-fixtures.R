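# Shared fixtures, built in code.

# Undirected network from an explicit edge list over identifiers.
net_from_edges <- function(edges, proteins = NULL,
                           annotations = empty_annotations()) {
  ids <- sort(unique(c(edges, proteins, annotations$protein)))
  A <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(edges)) {
    a <- match(edges[, 1], ids); b <- match(edges[, 2], ids)
    A[cbind(a, b)] <- 1L; A[cbind(b, a)] <- 1L
  }
  annotated_network(ids, A, annotations)
}

triangle_net <- function() {
  net_from_edges(cbind(c("a", "b", "c"), c("b", "c", "a")))
}

# Symmetric hollow Erdos-Renyi graph as an annotated_network.
random_net <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(0L, n, n)
  up <- upper.tri(A)
  A[up] <- rbinom(sum(up), 1L, p)
  A <- A + t(A)
  annotated_network(sprintf("v%02d", seq_len(n)), A)
}

random_membership <- function(n, K, seed) {
  set.seed(seed)
  m <- matrix(rgamma(n * K, 1), n, K)
  m / rowSums(m)
}

# Planted three-module simulation used by the recovery tests: the stated
# world of the recovery experiments (K = 3, n = 300, eps_in 0.15,
# eps_out 0.01, 3 categories of 6 values, strongly module-specific values).
planted_sim <- function(seed, n = 300, K = 3, eps_in = 0.15, eps_out = 0.01,
                        n_cat = 3, dom = 6, specificity = 0.9) {
  hyper <- hyperparams(K)
  params <- planted_params(K, n_cat, rep(dom, n_cat), eps_in, eps_out,
                           specificity)
  generate_network(hyper, n, n_cat, rep(dom, n_cat), rng_seed = seed,
                   params = params)
}

# A scoreboard fixture with fully controlled ranks: n entries whose scores
# are distinct and descending, with known flags as given.
make_board <- function(flags, half_width = 50L) {
  n <- length(flags)
  ids <- sprintf("x%04d", seq_len(n))
  entries <- data.frame(a = ids, b = rep("z", n),
                        pair_id = paste(ids, "z", sep = "|"),
                        score = seq(n, 1), is_known_ppi = flags,
                        stringsAsFactors = FALSE)
  structure(list(entries = entries, half_width = as.integer(half_width)),
            class = "ngpm_scoreboard")
}

# Two disconnected cliques with disjoint one-hot annotations.
two_clique_net <- function(size = 20) {
  n <- 2L * size
  A <- matrix(0L, n, n)
  A[seq_len(size), seq_len(size)] <- 1L
  A[(size + 1):n, (size + 1):n] <- 1L
  diag(A) <- 0L
  ids <- sprintf("v%03d", seq_len(n))
  ann <- data.frame(protein = ids,
                    category = "CAT1",
                    value = rep(c("GO:A", "GO:B"), each = size),
                    stringsAsFactors = FALSE)
  annotated_network(ids, A, ann)
}
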
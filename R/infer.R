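#' Fit the attributed stochastic block model by variational inference
#'
#' Approximates the label posterior of the generative model with a fully
#' factorised mean field `q(C) q(alpha) q(theta) q(beta) q(epsilon)` and runs
#' coordinate ascent: each protein's categorical `q_i` is updated from the
#' expected log-likelihood of its annotations (Dirichlet posteriors of the
#' category and value distributions), its edges *and* non-edges against all
#' other proteins (Beta posteriors of the block edge probabilities), and the
#' expected log module proportions; the conjugate Dirichlet/Beta posteriors
#' are then refreshed from the expected sufficient statistics. The evidence
#' lower bound (ELBO) is monotone non-decreasing over sweeps; the best of
#' `n_restarts` random initialisations is returned.
#'
#' @param net an [annotated_network()].
#' @param K number of functional modules (1 <= K <= number of proteins).
#' @param hyper a [hyperparams()] carrying the priors; its `K` must match.
#' @param max_iter maximum number of sweeps (default 500).
#' @param tol relative ELBO change declaring convergence (default 1e-6).
#' @param n_restarts random restarts (default 5).
#' @param rng_seed integer seed driving all restarts.
#' @return An object of class `ngpm_fit`: `membership` (n x K row-stochastic
#'   matrix, rownames = protein identifiers), `elbo_trace`, `posterior_params`
#'   (`zeta`, `lambda`, `mu`, `tau_a`, `tau_b`), `n_iter`, `converged`.
#' @export
fit_modules <- function(net, K, hyper = hyperparams(K), max_iter = 500L,
                        tol = 1e-6, n_restarts = 5L, rng_seed = 1L) {
  n <- length(net$proteins)
  K <- as.integer(K)
  if (K > n) stop("K (", K, ") exceeds the number of proteins (", n, ")")
  if (K < 1L) stop("K must be >= 1")
  if (hyper$K != K) stop("hyper$K does not match K")

  dat <- prepare_vb_data(net, K, hyper)
  seeds <- child_seeds(rng_seed, n_restarts)

  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seeds[r])
    q <- if (K == 1L) matrix(1, n, 1L) else rdirichlet(n, rep(1, K))
    res <- run_cavi(q, dat, max_iter, tol)
    if (is.null(best) || res$elbo > best$elbo) best <- res
    if (K == 1L) break  # posterior is exact; restarts are identical
  }
  rownames(best$membership) <- net$proteins
  structure(list(membership = best$membership,
                 elbo_trace = best$elbo_trace,
                 posterior_params = best$posterior,
                 n_iter = best$n_iter,
                 converged = best$converged),
            class = "ngpm_fit")
}

# Precompute the sufficient statistics the sweeps need: CSR adjacency,
# per-protein category counts (n x n_cat) and per-category value counts
# (n x |dom|), and the expanded priors.
prepare_vb_data <- function(net, K, hyper) {
  A <- net$adjacency
  n <- nrow(A)
  nbrs <- lapply(seq_len(n), function(i) which(A[i, ] == 1L))
  ptr <- c(0L, cumsum(lengths(nbrs)))
  adj <- as.integer(unlist(nbrs) - 1L)

  cats <- net$catalog$categories
  n_cat <- length(cats)
  ann <- net$annotations
  pi <- match(ann$protein, net$proteins)
  mi <- match(ann$category, cats)
  ncat <- matrix(0, n, n_cat)
  cnt <- vector("list", n_cat)
  for (m in seq_len(n_cat)) {
    dom <- net$catalog$domains[[m]]
    sel <- which(mi == m)
    ti <- match(ann$value[sel], dom)
    cm <- matrix(0, n, length(dom))
    if (length(sel)) {
      tab <- table(factor(pi[sel], levels = seq_len(n)),
                   factor(ti, levels = seq_along(dom)))
      cm <- matrix(as.numeric(tab), n, length(dom))
    }
    cnt[[m]] <- cm
    ncat[, m] <- rowSums(cm)
  }

  lam <- hyper$lambda
  if (is.numeric(lam) && length(lam) == 1L) lam <- matrix(lam, K, n_cat)
  mu <- lapply(seq_len(n_cat), function(m) {
    d <- ncol(cnt[[m]])
    if (is.list(hyper$mu)) hyper$mu[[m]] else matrix(hyper$mu, K, d)
  })
  if (is.numeric(hyper$tau)) {
    tau_a <- matrix(hyper$tau[1], K, K)
    tau_b <- matrix(hyper$tau[2], K, K)
  } else {
    tau_a <- as.matrix(hyper$tau[[1]]); tau_b <- as.matrix(hyper$tau[[2]])
  }
  list(A = A, adj = adj, ptr = ptr, n = n, K = K, n_cat = n_cat,
       ncat = ncat, cnt = cnt, zeta = hyper$zeta, lambda = lam, mu = mu,
       tau_a = tau_a, tau_b = tau_b)
}

# Conjugate posterior parameters given the current q.
vb_global <- function(q, dat) {
  K <- dat$K
  qs <- colSums(q)
  zeta_hat <- dat$zeta + qs
  lambda_hat <- dat$lambda + if (dat$n_cat) t(q) %*% dat$ncat else 0
  mu_hat <- lapply(seq_len(dat$n_cat),
                   function(m) dat$mu[[m]] + t(q) %*% dat$cnt[[m]])
  M <- t(q) %*% dat$A %*% q            # ordered expected edge counts
  P <- tcrossprod(qs) - crossprod(q)   # ordered expected pair counts
  M <- (M + t(M)) / 2; P <- (P + t(P)) / 2
  tau_a_hat <- dat$tau_a + M * ifelse(diag(K) == 1, 0.5, 1)
  tau_b_hat <- dat$tau_b + (P - M) * ifelse(diag(K) == 1, 0.5, 1)
  list(zeta = zeta_hat, lambda = lambda_hat, mu = mu_hat,
       tau_a = tau_a_hat, tau_b = tau_b_hat, M = M, P = P)
}

dirichlet_elog <- function(conc) {
  if (is.matrix(conc)) digamma(conc) - digamma(rowSums(conc))
  else digamma(conc) - digamma(sum(conc))
}

# E[log p(x)] - E[log q(x)] for a Dirichlet posterior `post` against prior
# `prior` (rows = independent Dirichlets when matrices).
neg_kl_dirichlet <- function(post, prior) {
  post <- rbind(post); prior <- rbind(prior)
  el <- dirichlet_elog(post)
  lp <- lgamma(rowSums(prior)) - rowSums(lgamma(prior)) +
    rowSums((prior - 1) * el)
  lq <- lgamma(rowSums(post)) - rowSums(lgamma(post)) +
    rowSums((post - 1) * el)
  sum(lp - lq)
}

# Expected-log terms of the current global posteriors.
vb_expectations <- function(g, dat) {
  elog_alpha <- dirichlet_elog(g$zeta)
  elog_theta <- if (dat$n_cat) dirichlet_elog(g$lambda) else
    matrix(numeric(0), dat$K, 0)
  elog_beta <- lapply(g$mu, dirichlet_elog)
  dg <- digamma(g$tau_a + g$tau_b)
  list(alpha = elog_alpha, theta = elog_theta, beta = elog_beta,
       eps = digamma(g$tau_a) - dg, one_m_eps = digamma(g$tau_b) - dg)
}

# Per-protein annotation log-likelihood contracted against counts (n x K).
annotation_loglik <- function(ex, dat) {
  ann <- matrix(0, dat$n, dat$K)
  if (dat$n_cat) {
    ann <- dat$ncat %*% t(ex$theta)
    for (m in seq_len(dat$n_cat))
      ann <- ann + dat$cnt[[m]] %*% t(ex$beta[[m]])
  }
  ann
}

vb_elbo <- function(q, g, ex, dat) {
  qf <- pmax(q, 1e-300)
  ann <- annotation_loglik(ex, dat)
  lik <- sum(q * ann) + sum(q %*% ex$alpha)
  ut <- upper.tri(g$M, diag = TRUE)
  edge <- sum((g$M * ex$eps + (g$P - g$M) * ex$one_m_eps)[ut] *
                ifelse(diag(dat$K) == 1, 0.5, 1)[ut])
  ent <- -sum(q * log(qf))
  kl <- neg_kl_dirichlet(g$zeta, dat$zeta)
  if (dat$n_cat) {
    kl <- kl + neg_kl_dirichlet(g$lambda, dat$lambda)
    for (m in seq_len(dat$n_cat))
      kl <- kl + neg_kl_dirichlet(g$mu[[m]], dat$mu[[m]])
  }
  iu <- which(upper.tri(g$tau_a, diag = TRUE))
  kl <- kl + neg_kl_dirichlet(cbind(g$tau_a[iu], g$tau_b[iu]),
                              cbind(dat$tau_a[iu], dat$tau_b[iu]))
  lik + edge + ent + kl
}

run_cavi <- function(q, dat, max_iter, tol) {
  g <- vb_global(q, dat)
  ex <- vb_expectations(g, dat)
  trace <- vb_elbo(q, g, ex, dat)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    ann <- annotation_loglik(ex, dat)
    S <- colSums(q)
    Aq <- dat$A %*% q
    cavi_sweep(q, dat$adj, dat$ptr, ann, ex$alpha, ex$eps, ex$one_m_eps,
               S, Aq)
    g <- vb_global(q, dat)
    ex <- vb_expectations(g, dat)
    elbo <- vb_elbo(q, g, ex, dat)
    if (is.na(elbo))
      stop("ELBO became NaN at sweep ", it)
    trace <- c(trace, elbo)
    prev <- trace[length(trace) - 1]
    if (abs(elbo - prev) <= tol * abs(prev)) { converged <- TRUE; break }
  }
  list(membership = q, elbo = trace[length(trace)], elbo_trace = trace,
       posterior = g[c("zeta", "lambda", "mu", "tau_a", "tau_b")],
       n_iter = it, converged = converged)
}

#' Hard module labels from a membership matrix
#'
#' `C_i = argmax_k membership[i, k]`; ties break toward the lowest module
#' index, so labels are deterministic.
#'
#' @param membership n x K row-stochastic matrix (or an `ngpm_fit`).
#' @return Integer label vector in `1..K`.
#' @export
derive_labels <- function(membership) {
  if (inherits(membership, "ngpm_fit")) membership <- membership$membership
  max.col(membership, ties.method = "first")
}

#' @export
print.ngpm_fit <- function(x, ...) {
  cat(sprintf(
    "ngpm_fit: %d proteins x %d modules; ELBO %.4f after %d sweeps (%s)\n",
    nrow(x$membership), ncol(x$membership),
    x$elbo_trace[length(x$elbo_trace)], x$n_iter,
    if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}

#' Evidence lower bound of a variational state
#'
#' Computes the full-model ELBO (labels, annotations, edges and non-edges,
#' and all prior KL terms) for an arbitrary row-stochastic membership matrix
#' `q`, with the conjugate global posteriors set to their optimum given `q`.
#'
#' @param net an [annotated_network()].
#' @param q n x K row-stochastic matrix.
#' @param hyper a [hyperparams()].
#' @return Scalar ELBO value.
#' @export
elbo <- function(net, q, hyper) {
  dat <- prepare_vb_data(net, ncol(q), hyper)
  g <- vb_global(q, dat)
  ex <- vb_expectations(g, dat)
  vb_elbo(q, g, ex, dat)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between partitions; 1 for identical partitions
#' (up to relabeling), ~0 for independent ones.
#'
#' @param a,b integer label vectors of equal length.
#' @return Scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  nc2 <- comb2(length(a))
  expected <- si * sj / nc2
  mx <- (si + sj) / 2
  if (mx == expected) return(1)
  (sij - expected) / (mx - expected)
}
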
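#' Model hyperparameters
#'
#' Priors of the generative model: module proportions `alpha ~ Dirichlet(zeta)`,
#' per-module category distributions `theta_k ~ Dirichlet(lambda_k)`,
#' per-(module, category) value distributions `beta_km ~ Dirichlet(mu_km)`,
#' and per-module-pair edge probabilities `eps_kl ~ Beta(tau1, tau2)`.
#'
#' @param K number of functional modules (>= 1).
#' @param zeta positive Dirichlet concentrations for `alpha`; scalar recycled
#'   to length `K`.
#' @param lambda positive concentrations for the category distributions;
#'   scalar, or a `K x n_categories` matrix.
#' @param mu positive concentrations for the value distributions; scalar, or a
#'   list (per category) of `K x |dom|` matrices.
#' @param tau length-2 positive Beta shapes for the edge probabilities, or a
#'   list of two symmetric `K x K` matrices `(a, b)`.
#' @param phi decay coefficient for path scoring, >= 1.
#' @param annotation_count annotations per protein: either a fixed
#'   non-negative integer (`list(type = "fixed", n = 4)`) or a Poisson mean
#'   (`list(type = "poisson", mean = 5)`, the default).
#' @return An object of class `ngpm_hyper`.
#' @export
hyperparams <- function(K, zeta = 1, lambda = 1, mu = 1, tau = c(1, 1),
                        phi = 1,
                        annotation_count = list(type = "poisson", mean = 5)) {
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  if (length(zeta) == 1L) zeta <- rep(zeta, K)
  if (length(zeta) != K || any(zeta <= 0))
    stop("zeta must be K positive concentrations")
  if (is.numeric(tau) && length(tau) == 2L) {
    if (any(tau <= 0)) stop("tau shapes must be positive")
  } else if (is.list(tau) && length(tau) == 2L) {
    for (m in tau) {
      m <- as.matrix(m)
      if (!identical(dim(m), c(K, K)) || any(m <= 0) || !isTRUE(all.equal(m, t(m))))
        stop("tau matrices must be symmetric positive K x K")
    }
  } else stop("tau must be a length-2 vector or a list of two K x K matrices")
  if (is.numeric(lambda) && any(lambda <= 0)) stop("lambda must be positive")
  if (is.numeric(mu) && any(mu <= 0)) stop("mu must be positive")
  if (phi < 1) stop("phi must be >= 1")
  if (!annotation_count$type %in% c("fixed", "poisson"))
    stop("annotation_count$type must be 'fixed' or 'poisson'")
  structure(list(K = K, zeta = zeta, lambda = lambda, mu = mu, tau = tau,
                 phi = phi, annotation_count = annotation_count),
            class = "ngpm_hyper")
}

# One child seed per sampler so sub-samplers are independently reproducible.
child_seeds <- function(seed, n) {
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

rdirichlet <- function(n, conc) {
  g <- matrix(stats::rgamma(n * length(conc), shape = conc), nrow = n,
              byrow = TRUE)
  g / rowSums(g)
}

#' Draw model parameters from the priors
#'
#' @param hyper a [hyperparams()].
#' @param n_categories number of annotation categories.
#' @param domain_sizes integer vector (length `n_categories`) of domain sizes.
#' @param rng_seed integer seed.
#' @return A list of class `ngpm_params` with `alpha` (length K), `theta`
#'   (K x n_categories, rows sum to 1), `beta` (list per category of
#'   K x domain-size stochastic matrices), `epsilon` (symmetric K x K in
#'   \[0,1\]); `labels` is `NULL` until drawn.
#' @export
sample_params <- function(hyper, n_categories, domain_sizes, rng_seed = 1L) {
  K <- hyper$K
  if (length(domain_sizes) != n_categories)
    stop("domain_sizes must have length n_categories")
  if (n_categories > 0 && any(domain_sizes < 1))
    stop("domain sizes must be >= 1")
  set.seed(rng_seed)
  alpha <- drop(rdirichlet(1, hyper$zeta))

  lam <- hyper$lambda
  if (is.numeric(lam) && length(lam) == 1L)
    lam <- matrix(lam, K, max(n_categories, 1L))
  theta <- if (n_categories == 0L) matrix(numeric(0), K, 0) else {
    t(vapply(seq_len(K), function(k) drop(rdirichlet(1, lam[k, seq_len(n_categories)])),
             numeric(n_categories)))
  }
  if (n_categories == 1L) theta <- matrix(theta, K, 1L)

  beta <- lapply(seq_len(n_categories), function(m) {
    mu_km <- hyper$mu
    d <- domain_sizes[m]
    b <- matrix(NA_real_, K, d)
    for (k in seq_len(K)) {
      conc <- if (is.list(mu_km)) mu_km[[m]][k, ] else rep(mu_km, d)
      b[k, ] <- drop(rdirichlet(1, conc))
    }
    b
  })

  eps <- matrix(NA_real_, K, K)
  for (k in seq_len(K)) for (l in k:K) {
    sh <- if (is.list(hyper$tau)) c(hyper$tau[[1]][k, l], hyper$tau[[2]][k, l])
          else hyper$tau
    eps[k, l] <- eps[l, k] <- stats::rbeta(1, sh[1], sh[2])
  }
  structure(list(alpha = alpha, theta = theta, beta = beta, epsilon = eps,
                 labels = NULL),
            class = "ngpm_params")
}

#' Fixed parameters for a planted-partition style network
#'
#' Convenience constructor for recovery experiments: equal module proportions,
#' within-module edge probability `eps_in` and between-module `eps_out`, each
#' module preferring its "own" categories/values with probability mass
#' `specificity` spread over a distinct block of the domain.
#'
#' @param K modules; `n_categories` annotation categories with `domain_sizes`
#'   values each.
#' @param eps_in,eps_out within/between-module edge probabilities.
#' @param specificity probability mass a module places on its own slice of
#'   each value domain (rest spread uniformly); 1 = fully module-specific.
#' @return An `ngpm_params` (no labels drawn).
#' @export
planted_params <- function(K, n_categories, domain_sizes,
                           eps_in = 0.15, eps_out = 0.01,
                           specificity = 0.9) {
  K <- as.integer(K)
  theta <- matrix(1 / max(n_categories, 1L), K, n_categories)
  beta <- lapply(seq_len(n_categories), function(m) {
    d <- domain_sizes[m]
    b <- matrix((1 - specificity) / d, K, d)
    # module k concentrates on an equal slice of the domain (wrapping)
    slice <- split(seq_len(d) - 1L, (seq_len(d) - 1L) %% K)
    for (k in seq_len(K)) {
      own <- slice[[as.character((k - 1L) %% length(slice))]] + 1L
      b[k, own] <- b[k, own] + specificity / length(own)
    }
    b / rowSums(b)
  })
  eps <- matrix(eps_out, K, K)
  diag(eps) <- eps_in
  structure(list(alpha = rep(1 / K, K), theta = theta, beta = beta,
                 epsilon = eps, labels = NULL),
            class = "ngpm_params")
}

#' Draw functional-module labels
#'
#' Labels are i.i.d. categorical draws: `P(C_i = k) = alpha_k`.
#'
#' @param alpha stochastic K-vector of module proportions.
#' @param n_proteins number of labels to draw.
#' @param rng_seed integer seed.
#' @return Integer vector in `1..K` of length `n_proteins`.
#' @export
sample_labels <- function(alpha, n_proteins, rng_seed = 1L) {
  stopifnot(abs(sum(alpha) - 1) < 1e-8, all(alpha >= 0))
  if (n_proteins == 0L) return(integer(0))
  set.seed(rng_seed)
  sample.int(length(alpha), n_proteins, replace = TRUE, prob = alpha)
}

#' Draw GO annotations given module labels
#'
#' For each protein, the number of annotation slots comes from
#' `annotation_count`; each slot draws a category from the label's category
#' distribution (`theta`) and then a value from the label- and
#' category-specific value distribution (`beta`).
#'
#' @param labels integer module labels.
#' @param theta K x n_categories stochastic matrix.
#' @param beta list per category of K x domain-size stochastic matrices.
#' @param annotation_count as in [hyperparams()].
#' @param rng_seed integer seed.
#' @return data frame (`protein` index, `category` index, `value` index).
#' @export
sample_annotations <- function(labels, theta, beta,
                               annotation_count = list(type = "poisson",
                                                       mean = 5),
                               rng_seed = 1L) {
  set.seed(rng_seed)
  n <- length(labels)
  n_cat <- ncol(theta)
  counts <- switch(annotation_count$type,
    fixed = rep(as.integer(annotation_count$n), n),
    poisson = stats::rpois(n, annotation_count$mean))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    ni <- counts[i]
    if (ni == 0L || n_cat == 0L) next
    k <- labels[i]
    cat_idx <- sample.int(n_cat, ni, replace = TRUE, prob = theta[k, ])
    val_idx <- vapply(cat_idx, function(m)
      sample.int(ncol(beta[[m]]), 1L, prob = beta[[m]][k, ]), integer(1))
    out[[i]] <- data.frame(protein = i, category = cat_idx, value = val_idx)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(protein = integer(), category = integer(),
                      value = integer())
  res
}

#' Draw the adjacency matrix of the stochastic block model
#'
#' Each unordered pair `i < j` is an independent Bernoulli draw with
#' probability `epsilon[C_i, C_j]`; the matrix is symmetric and hollow.
#'
#' @param labels integer module labels.
#' @param epsilon symmetric K x K matrix of edge probabilities.
#' @param rng_seed integer seed.
#' @return n x n integer 0/1 matrix.
#' @export
sample_adjacency <- function(labels, epsilon, rng_seed = 1L) {
  stopifnot(isTRUE(all.equal(epsilon, t(epsilon))),
            all(epsilon >= 0), all(epsilon <= 1))
  set.seed(rng_seed)
  n <- length(labels)
  A <- matrix(0L, n, n)
  if (n >= 2) {
    up <- which(upper.tri(A))
    rows <- row(A)[up]; cols <- col(A)[up]
    p <- epsilon[cbind(labels[rows], labels[cols])]
    draw <- as.integer(stats::runif(length(p)) < p)
    A[up] <- draw
    A <- A + t(A)
  }
  A
}

#' Simulate an annotated PPI network from the generative model
#'
#' Composes the four samplers (parameters unless supplied, labels,
#' annotations, adjacency) under one master seed; one child seed per sampler.
#' Protein identifiers are `p0001, p0002, ...` (index order = sorted order, so
#' matrix row i corresponds to simulated protein i throughout).
#'
#' @param hyper a [hyperparams()].
#' @param n_proteins number of proteins (>= 2).
#' @param n_categories,domain_sizes catalog shape.
#' @param rng_seed master seed.
#' @param params optional fixed `ngpm_params` (e.g. [planted_params()]);
#'   sampled from the priors when `NULL`.
#' @return list with `network` (an [annotated_network()]) and `params` (the
#'   ground truth, including `labels`).
#' @export
generate_network <- function(hyper, n_proteins, n_categories, domain_sizes,
                             rng_seed = 1L, params = NULL) {
  if (n_proteins < 2) stop("n_proteins must be >= 2")
  seeds <- child_seeds(rng_seed, 4L)
  if (is.null(params))
    params <- sample_params(hyper, n_categories, domain_sizes, seeds[1])
  params$labels <- sample_labels(params$alpha, n_proteins, seeds[2])
  ann_idx <- sample_annotations(params$labels, params$theta, params$beta,
                                hyper$annotation_count, seeds[3])
  A <- sample_adjacency(params$labels, params$epsilon, seeds[4])

  ids <- sprintf("p%04d", seq_len(n_proteins))
  cats <- sprintf("CAT%d", seq_len(n_categories))
  doms <- lapply(seq_len(n_categories),
                 function(m) sprintf("GO:%d:%03d", m, seq_len(domain_sizes[m])))
  names(doms) <- cats
  ann <- data.frame(protein = ids[ann_idx$protein],
                    category = cats[ann_idx$category],
                    value = mapply(function(m, t) doms[[m]][t],
                                   ann_idx$category, ann_idx$value,
                                   USE.NAMES = FALSE),
                    stringsAsFactors = FALSE)
  if (nrow(ann) == 0L) ann <- empty_annotations()
  net <- annotated_network(ids, A, ann,
                           catalog = go_catalog(cats, doms))
  list(network = net, params = params)
}
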
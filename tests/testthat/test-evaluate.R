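test_that("l3_score matches the degree-normalised closed form", {
  chain <- net_from_edges(cbind(c("i", "x", "y"), c("x", "y", "j")))
  expect_equal(l3_score(chain, "i", "j"), 1 / 2)  # 1/sqrt(2*2)
  expect_equal(l3_score(chain, "i", "y"), 0)      # length-2 path only

  # adding a disjoint length-3 path increases the score
  more <- net_from_edges(cbind(c("i", "x", "y", "i", "u", "v"),
                               c("x", "y", "j", "u", "v", "j")))
  expect_gt(l3_score(more, "i", "j"), l3_score(chain, "i", "j"))
  # closed form: deg(x)=deg(y)=deg(u)=deg(v)=2 in both paths
  expect_equal(l3_score(more, "i", "j"), 1)
})

test_that("sample_negatives honours counts, constraints and the seed", {
  sim <- planted_sim(3)
  neg <- sample_negatives(sim$network, rng_seed = 5)
  expect_equal(nrow(neg), 244)
  pid <- paste(pmin(neg[, 1], neg[, 2]), pmax(neg[, 1], neg[, 2]))
  expect_equal(anyDuplicated(pid), 0)
  A <- sim$network$adjacency
  ii <- match(neg[, 1], sim$network$proteins)
  jj <- match(neg[, 2], sim$network$proteins)
  expect_true(all(A[cbind(ii, jj)] == 0L))

  # exactly 100 pairs touch the top-500 L3 proteins
  L3 <- ngpm:::l3_matrix(sim$network)
  up <- which(upper.tri(A) & A == 0L, arr.ind = TRUE)
  sc <- L3[up]
  ids <- paste(sim$network$proteins[pmin(up[, 1], up[, 2])],
               sim$network$proteins[pmax(up[, 1], up[, 2])], sep = "|")
  top <- up[order(-sc, ids)[1:500], , drop = FALSE]
  top_prot <- unique(as.vector(top))
  touches <- (ii %in% top_prot) | (jj %in% top_prot)
  expect_equal(sum(touches), 100)

  expect_identical(neg, sample_negatives(sim$network, rng_seed = 5))
  expect_false(identical(neg, sample_negatives(sim$network, rng_seed = 6)))

  complete <- annotated_network(c("a", "b"),
                                matrix(c(0L, 1L, 1L, 0L), 2, 2))
  expect_error(sample_negatives(complete), "non-adjacent")
})

test_that("classification_metrics matches hand confusion matrices", {
  m <- classification_metrics(c(0.9, 0.8, 0.1), c(1, 1, 0))
  expect_equal(m, list(precision = 1, recall = 1, f_measure = 1))

  m <- classification_metrics(rep(0.9, 4), c(1, 0, 1, 0))
  expect_equal(m, list(precision = 0.5, recall = 1, f_measure = 2 / 3))

  m <- classification_metrics(rep(0.1, 4), c(1, 0, 1, 0))
  expect_equal(m, list(precision = 0, recall = 0, f_measure = 0))
  expect_error(classification_metrics(1, c(1, 0)), "equal length")
})

test_that("classification_metrics agrees with a brute-force count", {
  set.seed(9)
  for (rep in 1:10) {
    p <- runif(50); y <- rbinom(50, 1, 0.4); t <- runif(1)
    m <- classification_metrics(p, y, t)
    tp <- sum(p >= t & y == 1); fp <- sum(p >= t & y == 0)
    fn <- sum(p < t & y == 1)
    expect_equal(m$precision, if (tp + fp) tp / (tp + fp) else 0)
    expect_equal(m$recall, if (tp + fn) tp / (tp + fn) else 0)
  }
})

test_that("ranking_metrics handles separation, ties and the null", {
  m <- ranking_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(m$roc_auc, 1)
  expect_equal(m$pr_auc, 1)

  expect_equal(ranking_metrics(rep(0.5, 10), rep(c(0, 1), 5))$roc_auc, 0.5)

  set.seed(4)
  y <- rbinom(10000, 1, 0.5)
  m <- ranking_metrics(runif(10000), y)
  expect_lt(abs(m$roc_auc - 0.5), 0.02)
  expect_error(ranking_metrics(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("roc_auc is invariant under strictly monotone transforms", {
  set.seed(8)
  p <- runif(200); y <- rbinom(200, 1, 0.3)
  base <- ranking_metrics(p, y)$roc_auc
  expect_equal(ranking_metrics(p^3, y)$roc_auc, base)
  expect_equal(ranking_metrics(log(p + 1), y)$roc_auc, base)
})

test_that("five_fold_cv partitions edges and is reproducible", {
  sim <- planted_sim(13, n = 60, eps_in = 0.4, eps_out = 0.05)
  net <- sim$network
  n_edges <- sum(net$adjacency) / 2
  ev <- five_fold_cv(net, 2, hyperparams(2), rng_seed = 3, max_iter = 30,
                     n_restarts = 1, n_negatives = 40, n_constrained = 15,
                     l3_top = 50, half_width = 10)
  expect_equal(length(ev$folds), n_edges)
  expect_equal(sort(unique(ev$folds)), 1:5)
  expect_equal(sum(ev$per_fold$n_test), n_edges)
  mm <- unlist(ev$mean)
  expect_true(all(mm >= 0 & mm <= 1))

  ev2 <- five_fold_cv(net, 2, hyperparams(2), rng_seed = 3, max_iter = 30,
                      n_restarts = 1, n_negatives = 40, n_constrained = 15,
                      l3_top = 50, half_width = 10)
  expect_equal(ev$per_fold, ev2$per_fold)
  expect_identical(ev$folds, ev2$folds)
})

test_that("training adjacency never contains a test edge", {
  # 10-edge toy network (a ring): each fold holds exactly 2 test positives
  ids <- sprintf("n%02d", 1:10)
  edges <- cbind(ids, ids[c(2:10, 1)])
  net <- net_from_edges(edges)
  ev <- five_fold_cv(net, 1, hyperparams(1), rng_seed = 1, max_iter = 10,
                     n_restarts = 1, n_negatives = 4, n_constrained = 2,
                     l3_top = 2, half_width = 5)
  expect_equal(unname(table(ev$folds)), rep(2L, 5), ignore_attr = TRUE)
  expect_equal(ev$per_fold$n_test, rep(2, 5))
})

test_that("k_sweep shares folds and negatives across K", {
  sim <- planted_sim(19, n = 60, eps_in = 0.4, eps_out = 0.05)
  tab <- k_sweep(sim$network, c(2, 3), rng_seed = 2, max_iter = 20,
                 n_restarts = 1, n_negatives = 30, n_constrained = 10,
                 l3_top = 40, half_width = 10)
  expect_equal(tab$K, c(2, 3))
  expect_true(all(unlist(tab[, -1]) >= 0 & unlist(tab[, -1]) <= 1))
  best <- attr(tab, "best")
  expect_true(all(best %in% c(2, 3)))

  tab2 <- k_sweep(sim$network, c(2, 3), rng_seed = 2, max_iter = 20,
                  n_restarts = 1, n_negatives = 30, n_constrained = 10,
                  l3_top = 40, half_width = 10)
  expect_equal(tab, tab2)
})
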
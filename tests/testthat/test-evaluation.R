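test_that("auroc equals the all-pairs tie-corrected probability", {
  expect_equal(auroc(c(1, 1, 0, 0), c(4, 3, 2, 1)), 1)      # perfect
  expect_equal(auroc(c(1, 0, 1, 0), c(2, 2, 2, 2)), 0.5)    # all ties
  expect_equal(auroc(c(1, 0, 1, 0), c(4, 3, 2, 1)), 0.75)
  expect_error(auroc(c(1, 1), c(1, 2)), "both classes")

  set.seed(3)
  for (k in 1:200) {
    n <- sample(4:30, 1L)
    labels <- c(1L, 0L, sample(0:1, n - 2L, replace = TRUE))
    scores <- sample(1:5, n, replace = TRUE)  # discrete -> plenty of ties
    expect_identical(auroc(labels, scores), oracle_auroc(labels, scores))
  }
})

test_that("roc points are monotone from (0,0) to (1,1) and integrate to auroc", {
  set.seed(9)
  for (k in 1:20) {
    n <- sample(10:40, 1L)
    labels <- c(1L, 0L, sample(0:1, n - 2L, replace = TRUE))
    scores <- stats::rnorm(n)
    roc <- roc_points(labels, scores)
    expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
    expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
    expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
    # trapezoidal area under the curve equals the rank-based AUROC
    area <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
    expect_equal(area, auroc(labels, scores))
  }
})

test_that("loocv pools one positive plus the row negatives per fold", {
  spec <- synthetic_spec(n_diseases = 8, n_lncrnas = 8, p_within = 0.7,
                         p_between = 0.1, seed = 6)
  net <- make_network(spec); forest <- make_forest(spec)
  cv <- loocv(net, forest)
  n_pos <- sum(net$A)
  expect_equal(sum(cv$labels == 1L), n_pos)
  # each fold u contributes the zeros of row u of the original matrix
  expect_equal(sum(cv$labels == 0L),
               sum((ncol(net$A) - rowSums(net$A)) * rowSums(net$A)))
  expect_gte(cv$auroc, 0); expect_lte(cv$auroc, 1)
  expect_true(all(cv$roc$fpr >= 0 & cv$roc$tpr <= 1))
  # deterministic: no randomness anywhere in the protocol
  expect_equal(loocv(net, forest)$auroc, cv$auroc)
  expect_error(loocv(toy_network(rbind(c("d", "l")))), "at least 2")
})

test_that("loocv stays well-defined on a nearly complete network", {
  pairs <- expand.grid(d = paste0("d", 1:3), l = paste0("l", 1:3))
  pairs <- pairs[-5L, ]  # a single hole
  net <- toy_network(as.matrix(pairs))
  cv <- loocv(net)
  expect_true(is.finite(cv$auroc))
})

test_that("local cross-validation is deterministic and seed-controlled", {
  spec <- synthetic_spec(n_diseases = 10, n_lncrnas = 10, p_within = 0.7,
                         p_between = 0.1, seed = 2)
  net <- make_network(spec); forest <- make_forest(spec)
  a <- cv_local(net, forest, "rows", n_folds = 5, seed = 11)
  b <- cv_local(net, forest, "rows", n_folds = 5, seed = 11)
  expect_identical(a$auroc, b$auroc)
  expect_identical(a$labels, b$labels)
  c <- cv_local(net, forest, "rows", n_folds = 5, seed = 12)
  expect_false(identical(a$labels, c$labels) && identical(a$scores, c$scores))
  expect_error(cv_local(net, forest, "rows", n_folds = 5), "seed")
  expect_error(cv_local(net, forest, "rows", n_folds = 1, seed = 1), "n_folds")
})

test_that("held-out diseases still receive scores through semantic seeding", {
  # one disease per fold; the held-out row of A is zero, yet DA-side
  # resources flow via MeSH similarity, so its scores are not all equal
  spec <- synthetic_spec(n_diseases = 6, n_lncrnas = 8, p_within = 0.8,
                         p_between = 0.1, mesh_coverage = 1, seed = 8)
  net <- make_network(spec); forest <- make_forest(spec)
  SS <- semantic_similarity_matrix(forest, net$disease_names)
  A2 <- net$A; A2[1, ] <- 0
  ea <- idlda:::fold_associations(net, A2, SS)
  s <- score_disease(1, ea$DA, ea$LA, 0.3, 0.5)
  expect_true(any(s > 0))
  expect_gt(stats::sd(s), 0)
})

test_that("column holdout falls back to the kernel and completes", {
  spec <- synthetic_spec(n_diseases = 8, n_lncrnas = 8, p_within = 0.7,
                         p_between = 0.1, seed = 3)
  net <- make_network(spec); forest <- make_forest(spec)
  cv <- cv_local(net, forest, "cols", n_folds = 4, seed = 5)
  expect_true(is.finite(cv$auroc))
  expect_equal(sum(cv$labels == 1L), sum(net$A))
})

test_that("grid search returns the argmax with lexicographic tie-breaking", {
  spec <- synthetic_spec(n_diseases = 8, n_lncrnas = 8, p_within = 0.7,
                         p_between = 0.1, seed = 4)
  net <- make_network(spec); forest <- make_forest(spec)

  single <- grid_search(net, forest, alphas = 0.3, betas = 0.5)
  expect_equal(single$best_alpha, 0.3)
  expect_equal(single$best_beta, 0.5)
  expect_equal(nrow(single$grid), 1L)
  expect_equal(single$best_auroc, loocv(net, forest, 0.3, 0.5)$auroc)

  gs <- grid_search(net, forest, alphas = c(0.1, 0.3), betas = c(0.4, 0.5))
  expect_equal(nrow(gs$grid), 4L)
  expect_gte(gs$best_auroc, loocv(net, forest, 0.3, 0.5)$auroc)
  expect_equal(gs$best_auroc, max(gs$grid$auroc))
})

test_that("tied grid maxima break toward the smallest (alpha, beta)", {
  # two disjoint complete 2x2 communities: LOOCV separates perfectly over a
  # large plateau of the grid, so the argmax is tied and must resolve to
  # the lexicographically smallest pair on the plateau
  net <- toy_network(rbind(
    c("d1", "l1"), c("d1", "l2"), c("d2", "l1"), c("d2", "l2"),
    c("d3", "l3"), c("d3", "l4"), c("d4", "l3"), c("d4", "l4")))
  gs <- grid_search(net, forest = NULL, alphas = seq(0, 1, 0.25),
                    betas = seq(0, 1, 0.25))
  plateau <- gs$grid[gs$grid$auroc == max(gs$grid$auroc), ]
  expect_gt(nrow(plateau), 1L)
  plateau <- plateau[order(plateau$alpha, plateau$beta), ]
  expect_equal(gs$best_alpha, plateau$alpha[1L])
  expect_equal(gs$best_beta, plateau$beta[1L])
})

test_that("fold enrichment counts verified pairs per rank bin", {
  # N = 10, x = 5, M = 2, both positives in the first bin -> (2, 0)
  A <- rbind(c(1, 1, 0, 0, 0), c(0, 0, 0, 0, 0))
  net <- structure(list(disease_names = c("d1", "d2"),
                        lncrna_names = paste0("l", 1:5),
                        A = A), class = "assoc_network")
  scores <- rbind(c(10, 9, 5, 4, 3), c(2, 1, 0.5, 0.4, 0.3))
  en <- enrichment(scores, net, x = 5)
  expect_equal(en$fold_scores, c(2, 0))
  expect_equal(sum(en$m), en$M)

  # all M verified pairs in bin 1 with x >= M: algebraic value N / x
  en2 <- enrichment(scores, net, x = 4)
  expect_equal(en2$fold_scores[1], 10 / 4)

  # partial last bin uses its true size
  en3 <- enrichment(scores, net, x = 3)
  expect_equal(en3$bin_sizes, c(3, 3, 3, 1))
  expect_equal(sum(en3$m), 2)
})

test_that("random scores give fold enrichment averaging to one", {
  set.seed(17)
  A <- matrix(0, 6, 10); A[sample(60, 12)] <- 1
  net <- structure(list(disease_names = paste0("d", 1:6),
                        lncrna_names = paste0("l", 1:10), A = A),
                   class = "assoc_network")
  acc <- matrix(0, 200, 6)
  for (k in 1:200) {
    s <- matrix(stats::rnorm(60), 6, 10)
    acc[k, ] <- enrichment(s, net, x = 10)$fold_scores
  }
  expect_true(all(abs(colMeans(acc) - 1) < 0.15))
  # exact identity: bins of equal size partition all verified pairs
  expect_equal(mean(enrichment(matrix(stats::rnorm(60), 6, 10), net,
                               x = 10)$fold_scores), 1)
})
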
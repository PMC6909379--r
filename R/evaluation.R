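#' Area under the ROC curve
#'
#' Tie-corrected AUROC: the probability that a uniformly chosen positive
#' outscores a uniformly chosen negative, with half credit for ties.
#' Computed from average ranks (Mann-Whitney form).
#'
#' @param labels Binary vector (1 = positive, 0 = negative); both classes
#'   must be present.
#' @param scores Numeric scores, same length.
#' @return AUROC in \[0, 1\].
#' @export
#' @examples
#' auroc(c(1, 0, 1, 0), c(4, 3, 2, 1))  # 0.75
auroc <- function(labels, scores) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(scores),
            all(labels %in% c(0L, 1L)))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' (FPR, TPR) pairs at every distinct score threshold, descending; starts
#' at (0, 0) and ends at (1, 1), nondecreasing in both coordinates.
#'
#' @inheritParams auroc
#' @return Data frame with columns `fpr`, `tpr`.
#' @export
roc_points <- function(labels, scores) {
  labels <- as.integer(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  tp <- cumsum(l == 1L)
  fp <- cumsum(l == 0L)
  keep <- c(s[-1L] != s[-length(s)], TRUE)  # last index of each tie group
  data.frame(fpr = c(0, fp[keep] / max(fp[length(fp)], 1L)),
             tpr = c(0, tp[keep] / max(tp[length(tp)], 1L)))
}

# DA/LA rebuilt from a training adjacency (labels from `net`, entries from
# `A`). SS depends only on the MeSH forest and is passed in precomputed;
# everything that depends on A — both kernels, FS, the ensembles — is
# recomputed, as the evaluation contract requires in every fold.
fold_associations <- function(net, A, SS, gamma_d = 1, gamma_l = 1) {
  tnet <- replace_adjacency(net, A)
  KD <- gaussian_kernel(A, gamma_d)
  KL <- gaussian_kernel(t(A), gamma_l)
  FS <- functional_similarity(tnet, SS)
  DS <- ensemble_similarity(SS, KD)
  LS <- ensemble_similarity(FS, KL)
  ensemble_associations(tnet, DS, LS)
}

# Per-fold score decomposition for one seed disease: the diffusion score is
# bilinear in (alpha, beta), so four component vectors reconstruct the full
# N_l score vector at any mixing weights:
#   score(alpha, beta) = beta  * (alpha sLL + (1-alpha) sLD)
#                    + (1-beta)* (alpha sDL + (1-alpha) sDD)
score_components <- function(u, DA, LA) {
  Ln <- normalize_cols(LA); Dn <- normalize_cols(DA)
  gL <- as.vector(Ln %*% LA[u, ])
  gD <- as.vector(Dn %*% DA[u, ])
  Lr <- normalize_rows(LA); Dr <- normalize_rows(DA)
  list(sLL = as.vector(crossprod(Lr, gL)),
       sLD = as.vector(crossprod(Lr, gD)),
       sDL = as.vector(crossprod(Dr, gL)),
       sDD = as.vector(crossprod(Dr, gD)))
}

assemble_scores <- function(comp, alpha, beta) {
  beta * (alpha * comp$sLL + (1 - alpha) * comp$sLD) +
    (1 - beta) * (alpha * comp$sDL + (1 - alpha) * comp$sDD)
}

# One leave-one-association-out pass: for every known pair (u, v), zero it,
# rebuild all similarities and cache the alpha/beta-independent score
# components for seed u, plus the indices of u's true negatives (zeros of
# the ORIGINAL adjacency).
loocv_components <- function(net, forest = NULL, delta = 0.5,
                             gamma_d = 1, gamma_l = 1) {
  A <- net$A
  pos <- which(A == 1, arr.ind = TRUE)
  if (nrow(pos) < 2L) stop("need at least 2 known associations for LOOCV")
  SS <- if (is.null(forest)) matrix(0, nrow(A), nrow(A)) else
    semantic_similarity_matrix(forest, net$disease_names, delta)
  lapply(seq_len(nrow(pos)), function(k) {
    u <- pos[k, 1L]; v <- pos[k, 2L]
    A2 <- A
    A2[u, v] <- 0
    ea <- fold_associations(net, A2, SS, gamma_d, gamma_l)
    list(u = u, v = v, neg = which(A[u, ] == 0),
         comp = score_components(u, ea$DA, ea$LA))
  })
}

cv_result <- function(scheme, labels, scores, extra = list()) {
  structure(c(list(scheme = scheme, labels = labels, scores = scores,
                   auroc = auroc(labels, scores),
                   roc = roc_points(labels, scores)),
              extra),
            class = "idlda_cv")
}

#' Global leave-one-out cross-validation
#'
#' Each known association is removed in turn; every similarity matrix and
#' the ensemble associations are rebuilt from the training adjacency; the
#' held-out pair's score is the fold's positive and the scores of the test
#' disease's non-associations (zeros of the original adjacency) are its
#' negatives. All folds are pooled into a single ROC.
#'
#' @inheritParams idlda
#' @return An `idlda_cv` object: `scheme`, pooled `labels` and `scores`,
#'   `auroc`, `roc` points, and `per_disease` AUROCs where defined.
#' @export
loocv <- function(net, forest = NULL, alpha = 0.3, beta = 0.5, delta = 0.5,
                  gamma_d = 1, gamma_l = 1) {
  folds <- loocv_components(net, forest, delta, gamma_d, gamma_l)
  pool_loocv(folds, net, alpha, beta)
}

pool_loocv <- function(folds, net, alpha, beta) {
  labels <- integer(0); scores <- numeric(0); who <- integer(0)
  for (f in folds) {
    s <- assemble_scores(f$comp, alpha, beta)
    labels <- c(labels, 1L, rep(0L, length(f$neg)))
    scores <- c(scores, s[f$v], s[f$neg])
    who <- c(who, rep(f$u, 1L + length(f$neg)))
  }
  per <- vapply(split(seq_along(labels), who), function(ix) {
    if (length(unique(labels[ix])) < 2L) NA_real_
    else auroc(labels[ix], scores[ix])
  }, 0)
  names(per) <- net$disease_names[as.integer(names(per))]
  cv_result("loocv", labels, scores,
            list(alpha = alpha, beta = beta, per_disease = per))
}

#' Local cross-validation over rows or columns
#'
#' Diseases (`axis = "rows"`) or lncRNAs (`axis = "cols"`) are partitioned
#' into folds; each fold's rows/columns of the adjacency are zeroed, the
#' similarity stack is rebuilt, and the full score matrix is computed. The
#' held-out block's known associations are positives, its non-associations
#' negatives; folds are pooled. This emulates prediction for entirely new
#' diseases (CVr) or new lncRNAs (CVc).
#'
#' @inheritParams idlda
#' @param axis `"rows"` (hold out diseases) or `"cols"` (hold out lncRNAs).
#' @param n_folds Number of folds, >= 2; default 5.
#' @param seed Integer seed controlling the random partition (mandatory for
#'   reproducibility).
#' @return An `idlda_cv` object (scheme `cv_rows` or `cv_cols`).
#' @export
cv_local <- function(net, forest = NULL, axis = c("rows", "cols"),
                     n_folds = 5L, seed, alpha = 0.3, beta = 0.5,
                     delta = 0.5, gamma_d = 1, gamma_l = 1) {
  axis <- match.arg(axis)
  stopifnot(n_folds >= 2L)
  if (missing(seed)) stop("seed is required")
  A <- net$A
  n <- if (axis == "rows") nrow(A) else ncol(A)
  set.seed(as.integer(seed))
  fold_of <- sample(rep_len(seq_len(n_folds), n))
  SS <- if (is.null(forest)) matrix(0, nrow(A), nrow(A)) else
    semantic_similarity_matrix(forest, net$disease_names, delta)
  labels <- integer(0); scores <- numeric(0)
  for (f in seq_len(n_folds)) {
    held <- which(fold_of == f)
    if (length(held) == 0L) next
    A2 <- A
    if (axis == "rows") A2[held, ] <- 0 else A2[, held] <- 0
    ea <- fold_associations(net, A2, SS, gamma_d, gamma_l)
    R <- score_matrix(ea$DA, ea$LA, alpha, beta)
    if (axis == "rows") {
      labels <- c(labels, as.integer(A[held, ]))
      scores <- c(scores, as.vector(R[held, ]))
    } else {
      labels <- c(labels, as.integer(A[, held]))
      scores <- c(scores, as.vector(R[, held]))
    }
  }
  if (sum(labels) == 0L) stop("no fold contains a positive association")
  cv_result(if (axis == "rows") "cv_rows" else "cv_cols", labels, scores,
            list(alpha = alpha, beta = beta, n_folds = n_folds, seed = seed))
}

#' Grid search of the diffusion mixing weights
#'
#' Evaluates the pooled LOOCV AUROC at every (alpha, beta) grid point. The
#' per-fold similarity matrices do not depend on alpha or beta, so one
#' leave-one-out pass is shared by the whole grid. Ties on the maximum are
#' broken toward the lexicographically smallest (alpha, beta).
#'
#' @inheritParams idlda
#' @param alphas,betas Grid values; default `seq(0, 1, 0.1)` each (121
#'   points).
#' @return List with `best_alpha`, `best_beta`, `best_auroc` and the full
#'   `grid` data frame (`alpha`, `beta`, `auroc`).
#' @export
grid_search <- function(net, forest = NULL, alphas = seq(0, 1, 0.1),
                        betas = seq(0, 1, 0.1), delta = 0.5,
                        gamma_d = 1, gamma_l = 1) {
  folds <- loocv_components(net, forest, delta, gamma_d, gamma_l)
  grid <- expand.grid(alpha = alphas, beta = betas,
                      KEEP.OUT.ATTRS = FALSE)
  grid$auroc <- vapply(seq_len(nrow(grid)), function(k) {
    pool_loocv(folds, net, grid$alpha[k], grid$beta[k])$auroc
  }, 0)
  best <- grid[order(-grid$auroc, grid$alpha, grid$beta), ][1L, ]
  list(best_alpha = best$alpha, best_beta = best$beta,
       best_auroc = best$auroc, grid = grid)
}

#' Fold-enrichment of known associations along the ranking
#'
#' All `N = N_d * N_l` pairs are ranked by descending score and binned into
#' consecutive groups of `x`. A bin holding `m` verified associations gets
#' fold score `(m / size) / (M / N)` where `M` is the total number of
#' verified associations and `size` the bin's true size (the last bin may
#' be smaller than `x`). A fold score of 1 is the random expectation.
#'
#' @param scores An `idlda` fit, or a score matrix shaped like `net$A`.
#' @param net The `assoc_network` supplying the verified associations.
#' @param x Bin size, >= 1.
#' @return An `idlda_enrichment` object: `x`, `fold_scores`, `m` (verified
#'   per bin), `bin_sizes`, `M`, `N`.
#' @export
enrichment <- function(scores, net = NULL, x) {
  if (inherits(scores, "idlda")) {
    if (is.null(net)) net <- scores$net
    scores <- scores$R
  }
  stopifnot(x >= 1L, identical(dim(scores), dim(net$A)))
  s <- as.vector(scores)
  known <- as.vector(net$A)
  N <- length(s)
  M <- sum(known)
  ord <- order(-s)           # stable: ties keep storage order
  bins <- ceiling(seq_len(N) / x)
  m <- as.vector(tapply(known[ord], bins, sum))
  size <- as.vector(tapply(known[ord], bins, length))
  structure(list(x = x, fold_scores = (m / size) / (M / N),
                 m = m, bin_sizes = size, M = M, N = N),
            class = "idlda_enrichment")
}

#' @export
print.idlda_cv <- function(x, ...) {
  cat(sprintf("%s: %d positives, %d negatives, AUROC=%.4f\n",
              x$scheme, sum(x$labels == 1L), sum(x$labels == 0L), x$auroc))
  invisible(x)
}

#' @export
print.idlda_enrichment <- function(x, ...) {
  cat(sprintf("fold enrichment (bin size %d, %d bins, %d/%d verified)\n",
              x$x, length(x$fold_scores), x$M, x$N))
  cat("  top bins:", paste(sprintf("%.2f", utils::head(x$fold_scores, 5L)),
                           collapse = " "), "\n")
  invisible(x)
}

#' ROC curve plot with the diagonal random baseline
#'
#' @param x An `idlda_cv` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.idlda_cv <- function(x, ...) {
  graphics::plot(x$roc$fpr, x$roc$tpr, type = "l", lwd = 2,
                 col = "firebrick", xlab = "False positive rate",
                 ylab = "True positive rate",
                 main = sprintf("%s (AUROC = %.4f)", x$scheme, x$auroc), ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  invisible(x)
}

#' @export
plot.idlda_enrichment <- function(x, ...) {
  graphics::barplot(x$fold_scores, names.arg = seq_along(x$fold_scores),
                    xlab = "rank bin", ylab = "fold enrichment", ...)
  graphics::abline(h = 1, lty = 2, col = "grey50")
  invisible(x)
}
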
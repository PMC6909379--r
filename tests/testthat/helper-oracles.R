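# Independent brute-force oracles. These deliberately transcribe the
# defining formulas as literal loops/recursions, with none of the
# vectorization or shortcuts used by the implementation.

# Semantic contribution profile by memo-free recursion: self nodes get 1,
# every other DAG node the max over its children of delta * child value.
oracle_profile <- function(tree_numbers, delta) {
  prefixes <- function(tn) {
    segs <- strsplit(tn, ".", fixed = TRUE)[[1L]]
    vapply(seq_along(segs), function(k) paste(segs[1:k], collapse = "."), "")
  }
  nodes <- unique(unlist(lapply(tree_numbers, prefixes)))
  depth <- function(t) length(strsplit(t, ".", fixed = TRUE)[[1L]])
  children <- function(t)
    nodes[startsWith(nodes, paste0(t, ".")) &
            vapply(nodes, depth, 0L) == depth(t) + 1L]
  evaluate <- function(t) {
    if (t %in% tree_numbers) return(1)
    max(vapply(children(t), function(ch) delta * evaluate(ch), 0))
  }
  vapply(stats::setNames(nodes, nodes), evaluate, 0)
}

# Semantic similarity by direct evaluation over two contribution vectors.
oracle_ss <- function(c_i, c_j) {
  shared <- intersect(names(c_i), names(c_j))
  if (!length(shared)) return(0)
  (sum(c_i[shared]) + sum(c_j[shared])) / (sum(c_i) + sum(c_j))
}

# Functional similarity by exhaustive best-match enumeration on an SS
# matrix, given the two (covered) disease index sets.
oracle_fs <- function(Di, Dj, SS) {
  if (!length(Di) || !length(Dj)) return(0)
  num <- 0
  for (t in Di) num <- num + max(SS[t, Dj])
  for (t in Dj) num <- num + max(SS[t, Di])
  num / (length(Di) + length(Dj))
}

# Two-pass diffusion for one seed, as literal loops over indices with the
# zero-normalizer convention (a zero column/row sum contributes nothing).
oracle_score <- function(u, DA, LA, alpha, beta) {
  n_d <- nrow(DA); n_l <- ncol(DA)
  g <- numeric(n_d)
  for (j in seq_len(n_d)) {
    sL <- 0; sD <- 0
    for (i in seq_len(n_l)) {
      csL <- sum(LA[, i]); csD <- sum(DA[, i])
      if (csL > 0) sL <- sL + LA[j, i] / csL * LA[u, i]
      if (csD > 0) sD <- sD + DA[j, i] / csD * DA[u, i]
    }
    g[j] <- alpha * sL + (1 - alpha) * sD
  }
  score <- numeric(n_l)
  for (i in seq_len(n_l)) {
    sL <- 0; sD <- 0
    for (j in seq_len(n_d)) {
      rsL <- sum(LA[j, ]); rsD <- sum(DA[j, ])
      if (rsL > 0) sL <- sL + LA[j, i] / rsL * g[j]
      if (rsD > 0) sD <- sD + DA[j, i] / rsD * g[j]
    }
    score[i] <- beta * sL + (1 - beta) * sD
  }
  score
}

# Tie-corrected AUROC by all-pairs comparison with half credit for ties.
oracle_auroc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}
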
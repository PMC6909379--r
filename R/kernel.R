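#' Gaussian interaction-profile kernel
#'
#' Similarity between binary interaction profiles (one entity per row):
#' `K_ij = exp(-gamma * ||IP_i - IP_j||^2)` with the bandwidth scaled by the
#' data, `gamma = gamma_prime / mean(||IP||^2)` over all entities. Disease
#' profiles are the rows of the adjacency matrix `A`; lncRNA profiles are
#' its columns (pass `t(A)`).
#'
#' @param profiles Binary matrix, one entity per row.
#' @param gamma_prime Bandwidth control, > 0; default 1.
#' @return Symmetric matrix in \[0, 1\] with unit diagonal, labeled by the
#'   row names of `profiles`.
#' @export
#' @examples
#' gaussian_kernel(rbind(a = c(1, 0), b = c(0, 1)))["a", "b"]  # exp(-2)
gaussian_kernel <- function(profiles, gamma_prime = 1) {
  profiles <- as.matrix(profiles)
  stopifnot(gamma_prime > 0, nrow(profiles) >= 1L)
  norms2 <- rowSums(profiles^2)
  if (all(norms2 == 0)) stop("bandwidth undefined: all profiles are zero")
  gamma <- gamma_prime / mean(norms2)
  d2 <- outer(norms2, norms2, "+") - 2 * tcrossprod(profiles)
  d2[d2 < 0] <- 0            # numerical guard
  K <- exp(-gamma * d2)
  diag(K) <- 1
  dimnames(K) <- list(rownames(profiles), rownames(profiles))
  K
}

# Disease sets per lncRNA, restricted to MeSH-covered diseases (those with a
# nonzero SS diagonal): uncovered diseases carry no semantic signal, and
# excluding them keeps FS_ii = 1 for any lncRNA with >= 1 covered disease.
lncrna_disease_sets <- function(A, covered) {
  lapply(seq_len(ncol(A)), function(j) which(A[, j] == 1 & covered))
}

#' LncRNA functional similarity
#'
#' Best-match semantic similarity between the disease sets of two lncRNAs:
#' with `D(l_i)` the set of MeSH-covered diseases associated with lncRNA
#' `l_i` and `S(t, D) = max over d in D of SS\[t, d\]`,
#' `FS_ij = (sum_{t in D(l_i)} S(t, D(l_j)) + sum_{t in D(l_j)} S(t, D(l_i)))
#' / (|D(l_i)| + |D(l_j)|)`. Zero whenever either set is empty.
#'
#' @param net An `assoc_network`.
#' @param SS Disease semantic similarity matrix over `net$disease_names`
#'   (see [semantic_similarity_matrix()]).
#' @return Symmetric `N_l x N_l` matrix in \[0, 1\], labeled by lncRNA.
#' @export
functional_similarity <- function(net, SS) {
  A <- net$A
  stopifnot(nrow(SS) == nrow(A))
  covered <- diag(SS) > 0
  sets <- lncrna_disease_sets(A, covered)
  n <- ncol(A)
  FS <- matrix(0, n, n, dimnames = list(net$lncrna_names, net$lncrna_names))
  for (i in seq_len(n)) {
    Di <- sets[[i]]
    if (length(Di) == 0L) next
    for (j in i:n) {
      Dj <- sets[[j]]
      if (length(Dj) == 0L) next
      sub <- SS[Di, Dj, drop = FALSE]
      num <- sum(apply(sub, 1L, max)) + sum(apply(sub, 2L, max))
      FS[i, j] <- FS[j, i] <- num / (length(Di) + length(Dj))
    }
  }
  FS
}

#' Ensemble of a primary similarity with a kernel fallback
#'
#' Entrywise: the average of the two matrices where the primary similarity
#' is nonzero, the kernel alone where it is zero. Applied to (SS, KD) this
#' yields the disease ensemble similarity DS, and to (FS, KL) the lncRNA
#' ensemble similarity LS.
#'
#' @param primary Semantic (SS) or functional (FS) similarity matrix.
#' @param fallback Gaussian kernel matrix of the same shape.
#' @return Matrix of the same shape; symmetric with unit diagonal when both
#'   inputs are.
#' @export
ensemble_similarity <- function(primary, fallback) {
  if (!identical(dim(primary), dim(fallback)))
    stop("shape mismatch between primary and fallback similarity")
  out <- ifelse(primary != 0, (primary + fallback) / 2, fallback)
  dimnames(out) <- dimnames(fallback)
  out
}
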
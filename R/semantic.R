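#' Semantic contribution profile of a disease
#'
#' A disease with MeSH tree numbers defines a rooted DAG: its own tree-number
#' coordinates plus all of their ancestors (dot-prefix truncations). The
#' disease's own nodes contribute 1; every ancestor node contributes
#' `delta^k` where `k` is its hop distance to the nearest of the disease's
#' own nodes within the DAG — exactly the max-over-children decay recursion
#' with decay factor `delta`. Nodes are identified by their full coordinate
#' string, so a disease with several tree numbers has several unit-weight
#' self nodes.
#'
#' @param disease Disease name (normalized or raw; normalized internally).
#' @param forest A `mesh_forest` from [read_mesh_forest()] or [make_forest()].
#' @param delta Decay factor of the semantic contribution, in (0, 1);
#'   default 0.5.
#' @return A `semantic_profile`: list with `disease` and `contributions`
#'   (named numeric, one entry per DAG node), or `NULL` if the disease has
#'   no tree numbers (no DAG; its semantic similarity to everything is 0).
#' @export
#' @examples
#' f <- structure(list(c = "A.B.C"), class = "mesh_forest")
#' build_profile("c", f)$contributions  # C -> 1, B -> 0.5, A -> 0.25
build_profile <- function(disease, forest, delta = 0.5) {
  stopifnot(delta >= 0, delta < 1)
  disease <- normalize_names(disease)
  tns <- forest[[disease]]
  if (is.null(tns) || length(tns) == 0L) return(NULL)
  contrib <- numeric(0)
  for (tn in tns) {
    segs <- strsplit(tn, ".", fixed = TRUE)[[1L]]
    depth <- length(segs)
    nodes <- vapply(seq_len(depth), function(k)
      paste(segs[seq_len(k)], collapse = "."), "")
    vals <- delta^(depth - seq_len(depth))   # self = delta^0 = 1
    for (k in seq_len(depth)) {
      cur <- contrib[nodes[k]]
      if (is.na(cur) || vals[k] > cur) contrib[nodes[k]] <- vals[k]
    }
  }
  structure(list(disease = disease, contributions = contrib),
            class = "semantic_profile")
}

#' Semantic value of a disease
#'
#' Sum of the semantic contributions of all nodes of the disease's DAG;
#' at least 1 (the self node).
#'
#' @param profile A `semantic_profile` from [build_profile()].
#' @return Positive scalar.
#' @export
semantic_value <- function(profile) {
  if (is.null(profile)) stop("empty profile (disease has no DAG)")
  sum(profile$contributions)
}

#' Semantic similarity between two diseases
#'
#' Shared-node overlap of two contribution profiles, normalized by the sum
#' of the two semantic values:
#' `sum over shared nodes t of (C_i(t) + C_j(t)) / (C(d_i) + C(d_j))`.
#' Zero if either profile is `NULL` or the DAGs share no node.
#'
#' @param p_i,p_j `semantic_profile` objects built with the same `delta`
#'   (or `NULL` for diseases without a DAG).
#' @return Similarity in \[0, 1\].
#' @export
semantic_similarity <- function(p_i, p_j) {
  if (is.null(p_i) || is.null(p_j)) return(0)
  shared <- intersect(names(p_i$contributions), names(p_j$contributions))
  if (length(shared) == 0L) return(0)
  num <- sum(p_i$contributions[shared]) + sum(p_j$contributions[shared])
  num / (semantic_value(p_i) + semantic_value(p_j))
}

#' Best-match similarity of a disease against a disease set
#'
#' Maximum semantic similarity between `p` and any profile in `group`;
#' 0 for an empty group.
#'
#' @param p A `semantic_profile` (or `NULL`).
#' @param group List of `semantic_profile` objects (may be empty).
#' @return Similarity in \[0, 1\].
#' @export
disease_vs_set <- function(p, group) {
  if (length(group) == 0L) return(0)
  max(vapply(group, function(q) semantic_similarity(p, q), 0))
}

#' Pairwise disease semantic similarity matrix
#'
#' Computes SS for every pair of the given diseases. Diseases without tree
#' numbers get an all-zero row and column (including the diagonal); covered
#' diseases have `SS[i, i] = 1`.
#'
#' @param forest A `mesh_forest`.
#' @param diseases Character vector of disease names fixing row/column
#'   order; defaults to the diseases present in the forest.
#' @param delta Decay factor; default 0.5.
#' @return Symmetric labeled matrix in \[0, 1\].
#' @export
semantic_similarity_matrix <- function(forest, diseases = names(forest),
                                       delta = 0.5) {
  diseases <- normalize_names(diseases)
  n <- length(diseases)
  profiles <- lapply(diseases, build_profile, forest = forest, delta = delta)
  SS <- matrix(0, n, n, dimnames = list(diseases, diseases))
  vals <- vapply(profiles, function(p) if (is.null(p)) NA_real_
                 else semantic_value(p), 0)
  for (i in seq_len(n)) {
    if (is.null(profiles[[i]])) next
    ci <- profiles[[i]]$contributions
    for (j in i:n) {
      if (is.null(profiles[[j]])) next
      cj <- profiles[[j]]$contributions
      shared <- intersect(names(ci), names(cj))
      if (length(shared)) {
        s <- (sum(ci[shared]) + sum(cj[shared])) / (vals[i] + vals[j])
        SS[i, j] <- SS[j, i] <- s
      }
    }
  }
  SS
}
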
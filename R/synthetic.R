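#' Specification of a synthetic study condition
#'
#' Defines a block-structured bipartite association network and a matching
#' MeSH-style forest: diseases and lncRNAs are assigned round-robin to
#' `n_blocks` communities; same-block pairs associate with probability
#' `p_within`, cross-block pairs with `p_between`; each block owns a
#' disjoint rooted tree so that same-block diseases share semantic
#' ancestry and cross-block semantic similarity is exactly zero.
#'
#' Defaults encode the planted two-community condition used throughout the
#' package's validation: 20 diseases x 20 lncRNAs, two blocks, within-block
#' association probability 0.8 against a 0.02 background, tree depth up to
#' 4 and 90% MeSH coverage.
#'
#' @param n_diseases,n_lncrnas Entity counts, >= 1.
#' @param n_blocks Number of communities, >= 1.
#' @param p_within,p_between Association probabilities in \[0, 1\].
#' @param dag_depth Maximum number of tree-number segments below the root.
#' @param mesh_coverage Fraction of diseases given tree numbers, in \[0, 1\].
#' @param seed Integer seed; a fixed seed makes both generators
#'   byte-reproducible.
#' @return A validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_diseases = 20L, n_lncrnas = 20L, n_blocks = 2L,
                           p_within = 0.8, p_between = 0.02,
                           dag_depth = 4L, mesh_coverage = 0.9, seed = 1L) {
  stopifnot(n_diseases >= 1L, n_lncrnas >= 1L, n_blocks >= 1L,
            p_within >= 0, p_within <= 1, p_between >= 0, p_between <= 1,
            dag_depth >= 1L, mesh_coverage >= 0, mesh_coverage <= 1)
  structure(list(n_diseases = as.integer(n_diseases),
                 n_lncrnas = as.integer(n_lncrnas),
                 n_blocks = as.integer(n_blocks),
                 p_within = p_within, p_between = p_between,
                 dag_depth = as.integer(dag_depth),
                 mesh_coverage = mesh_coverage,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

synth_disease_names <- function(spec)
  sprintf("disease%03d", seq_len(spec$n_diseases))
synth_lncrna_names <- function(spec)
  sprintf("lncrna%03d", seq_len(spec$n_lncrnas))
synth_block_of <- function(n, n_blocks) ((seq_len(n) - 1L) %% n_blocks) + 1L

#' Generate a synthetic MeSH-style forest
#'
#' Each block `b` owns the disjoint root `C<b>`; a covered disease in block
#' `b` receives one or two tree numbers that are random paths below that
#' root, with segments drawn from a small alphabet so that same-block
#' diseases share internal ancestors (and always share the root). Uncovered
#' diseases get no tree numbers at all.
#'
#' @param spec A [synthetic_spec()].
#' @return A `mesh_forest`.
#' @export
make_forest <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  diseases <- synth_disease_names(spec)
  blocks <- synth_block_of(spec$n_diseases, spec$n_blocks)
  n_cov <- round(spec$mesh_coverage * spec$n_diseases)
  covered <- sort(sample.int(spec$n_diseases, n_cov))
  segments <- c("100", "200", "300")   # small alphabet -> shared ancestors
  out <- list()
  for (i in covered) {
    root <- sprintf("C%02d", blocks[i])
    k <- sample(1:2, 1L)
    tns <- vapply(seq_len(k), function(j) {
      depth <- sample.int(spec$dag_depth, 1L)
      paste(c(root, sample(segments, depth, replace = TRUE)), collapse = ".")
    }, "")
    out[[diseases[i]]] <- sort(unique(tns))
  }
  structure(out, class = "mesh_forest")
}

#' Generate a synthetic block-structured association network
#'
#' Bernoulli adjacency with block-dependent probabilities, redrawn (bounded
#' retries) until every disease and every lncRNA has at least one
#' association — the Gaussian kernel bandwidth is undefined on an all-zero
#' profile set, and isolated nodes are outside the model's scope.
#'
#' @param spec A [synthetic_spec()].
#' @param max_tries Redraw limit before giving up; default 100.
#' @return An `assoc_network`.
#' @export
make_network <- function(spec, max_tries = 100L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  db <- synth_block_of(spec$n_diseases, spec$n_blocks)
  lb <- synth_block_of(spec$n_lncrnas, spec$n_blocks)
  P <- ifelse(outer(db, lb, "=="), spec$p_within, spec$p_between)
  for (try in seq_len(max_tries)) {
    A <- matrix(as.numeric(stats::runif(length(P)) < P), nrow(P), ncol(P))
    if (all(rowSums(A) > 0) && all(colSums(A) > 0)) {
      dimnames(A) <- list(synth_disease_names(spec), synth_lncrna_names(spec))
      return(structure(list(disease_names = rownames(A),
                            lncrna_names = colnames(A), A = A),
                       class = "assoc_network"))
    }
  }
  stop("could not draw a network with nonempty rows and columns in ",
       max_tries, " tries (association probabilities too small?)")
}
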
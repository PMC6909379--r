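#' Ensemble association matrices
#'
#' Smooths the binary adjacency through the two ensemble similarities:
#' `DA = DS %*% A` (disease side) and `LA = A %*% LS` (lncRNA side). Both
#' are nonnegative `N_d x N_l` matrices; a disease with no known
#' associations still obtains nonzero `DA` entries through its semantic
#' similarity to associated diseases, which is what lets the model score
#' entirely new diseases.
#'
#' @param net An `assoc_network`.
#' @param DS Disease ensemble similarity (`N_d x N_d`).
#' @param LS LncRNA ensemble similarity (`N_l x N_l`).
#' @return List with matrices `DA` and `LA`.
#' @export
ensemble_associations <- function(net, DS, LS) {
  A <- net$A
  if (nrow(DS) != nrow(A) || ncol(DS) != nrow(A))
    stop("DS dimension mismatch")
  if (nrow(LS) != ncol(A) || ncol(LS) != ncol(A))
    stop("LS dimension mismatch")
  list(DA = DS %*% A, LA = A %*% LS)
}

# Column-normalized (resource-splitting toward diseases) and row-normalized
# (toward lncRNAs) versions of an ensemble association matrix. Zero-sum
# columns/rows are left all-zero: a node with no weight transmits nothing.
normalize_cols <- function(M) {
  cs <- colSums(M)
  cs[cs == 0] <- Inf
  sweep(M, 2L, cs, "/")
}
normalize_rows <- function(M) {
  rs <- rowSums(M)
  rs[rs == 0] <- Inf
  M / rs
}

#' Two-pass diffusion scores for one seed disease
#'
#' Resource-allocation diffusion on the bipartite graph. Seeded with
#' disease `u`'s ensemble association rows, resources flow lncRNAs ->
#' diseases (first pass, mixing weight `alpha` between the LA- and DA-guided
#' flows) and back diseases -> lncRNAs (second pass, weight `beta`). Each
#' node splits its resource proportionally to the corresponding matrix's
#' column (first pass) or row (second pass); zero-sum normalizers
#' contribute 0.
#'
#' @param u Disease index or name.
#' @param DA,LA Ensemble association matrices from
#'   [ensemble_associations()].
#' @param alpha,beta Mixing weights in \[0, 1\]; defaults 0.3 and 0.5.
#' @return Numeric vector of `N_l` nonnegative relevance scores, named by
#'   lncRNA when `LA` carries column names.
#' @export
score_disease <- function(u, DA, LA, alpha = 0.3, beta = 0.5) {
  stopifnot(alpha >= 0, alpha <= 1, beta >= 0, beta <= 1)
  if (is.character(u)) {
    u <- match(normalize_names(u), rownames(DA))
    if (is.na(u)) stop("unknown disease")
  }
  Ln <- normalize_cols(LA); Dn <- normalize_cols(DA)
  g <- alpha * as.vector(Ln %*% LA[u, ]) +
    (1 - alpha) * as.vector(Dn %*% DA[u, ])
  Lr <- normalize_rows(LA); Dr <- normalize_rows(DA)
  s <- as.vector(crossprod(beta * Lr + (1 - beta) * Dr, g))
  names(s) <- colnames(LA)
  s
}

#' Full relevance score matrix
#'
#' Row `u` of the result equals [score_disease()] for seed `u`; computed by
#' dense matrix products.
#'
#' @inheritParams score_disease
#' @return `N_d x N_l` matrix of nonnegative scores.
#' @export
score_matrix <- function(DA, LA, alpha = 0.3, beta = 0.5) {
  stopifnot(alpha >= 0, alpha <= 1, beta >= 0, beta <= 1)
  Ln <- normalize_cols(LA); Dn <- normalize_cols(DA)
  G <- alpha * tcrossprod(LA, Ln) + (1 - alpha) * tcrossprod(DA, Dn)
  W <- beta * normalize_rows(LA) + (1 - beta) * normalize_rows(DA)
  R <- G %*% W
  dimnames(R) <- list(rownames(DA), colnames(LA))
  R
}

#' Fit the diffusion ranking model
#'
#' End-to-end pipeline: from a bipartite disease-lncRNA association network
#' and an optional MeSH forest it computes
#' \itemize{
#'   \item `SS` — disease semantic similarity from the MeSH DAGs (decay
#'     `delta`); all-zero when no forest is supplied;
#'   \item `KD`, `KL` — Gaussian interaction-profile kernels over the rows
#'     and columns of `A` (bandwidth controls `gamma_d`, `gamma_l`);
#'   \item `FS` — lncRNA functional similarity from the associated disease
#'     sets;
#'   \item `DS = ensemble(SS, KD)`, `LS = ensemble(FS, KL)`;
#'   \item `DA = DS A`, `LA = A LS` and the diffusion score matrix `R`
#'     (mixing weights `alpha`, `beta`).
#' }
#' Larger `R[i, j]` means disease `i` and lncRNA `j` are predicted more
#' likely to be associated.
#'
#' @param net An `assoc_network` (see [read_associations()],
#'   [as_assoc_network()], [make_network()]).
#' @param forest A `mesh_forest`, or `NULL` to use kernels only.
#' @param alpha,beta Diffusion mixing weights in \[0, 1\]; defaults 0.3
#'   and 0.5.
#' @param delta Semantic decay factor in (0, 1); default 0.5.
#' @param gamma_d,gamma_l Kernel bandwidth controls, > 0; defaults 1.
#' @return An object of class `idlda`: list with the inputs, all similarity
#'   matrices (`SS`, `KD`, `KL`, `FS`, `DS`, `LS`), the ensemble
#'   associations (`DA`, `LA`) and the score matrix `R`.
#' @seealso [predict.idlda()], [loocv()], [enrichment()]
#' @export
#' @examples
#' net <- make_network(synthetic_spec(seed = 7))
#' forest <- make_forest(synthetic_spec(seed = 7))
#' fit <- idlda(net, forest)
#' head(predict(fit, disease = net$disease_names[1]), 3)
idlda <- function(net, forest = NULL, alpha = 0.3, beta = 0.5, delta = 0.5,
                  gamma_d = 1, gamma_l = 1) {
  stopifnot(inherits(net, "assoc_network"))
  A <- net$A
  SS <- if (is.null(forest)) {
    matrix(0, nrow(A), nrow(A),
           dimnames = list(net$disease_names, net$disease_names))
  } else {
    semantic_similarity_matrix(forest, net$disease_names, delta)
  }
  KD <- gaussian_kernel(A, gamma_d)
  KL <- gaussian_kernel(t(A), gamma_l)
  FS <- functional_similarity(net, SS)
  DS <- ensemble_similarity(SS, KD)
  LS <- ensemble_similarity(FS, KL)
  ea <- ensemble_associations(net, DS, LS)
  R <- score_matrix(ea$DA, ea$LA, alpha, beta)
  structure(list(net = net, forest = forest,
                 params = list(alpha = alpha, beta = beta, delta = delta,
                               gamma_d = gamma_d, gamma_l = gamma_l),
                 SS = SS, KD = KD, KL = KL, FS = FS, DS = DS, LS = LS,
                 DA = ea$DA, LA = ea$LA, R = R),
            class = "idlda")
}

#' @export
print.idlda <- function(x, ...) {
  p <- x$params
  cat("Diffusion association-ranking model\n")
  cat(sprintf("  diseases: %d   lncRNAs: %d   associations: %d\n",
              nrow(x$R), ncol(x$R), sum(x$net$A)))
  cat(sprintf("  alpha = %g, beta = %g, delta = %g, gamma_d = %g, gamma_l = %g\n",
              p$alpha, p$beta, p$delta, p$gamma_d, p$gamma_l))
  cat(sprintf("  MeSH-covered diseases: %d/%d\n",
              sum(diag(x$SS) > 0), nrow(x$R)))
  invisible(x)
}

#' @export
summary.idlda <- function(object, ...) {
  x <- object
  print(x)
  cand <- x$R[x$net$A == 0]
  cat(sprintf("  candidate scores: min %.4g, median %.4g, max %.4g\n",
              min(cand), stats::median(cand), max(cand)))
  cat(sprintf("  known-pair scores: min %.4g, median %.4g, max %.4g\n",
              min(x$R[x$net$A == 1]), stats::median(x$R[x$net$A == 1]),
              max(x$R[x$net$A == 1])))
  invisible(x)
}

#' Ranked candidate associations
#'
#' Per-disease ranking of lncRNAs by descending relevance score. Ranks are
#' computed among the listed lncRNAs with average ranks on ties; listing
#' order is score-descending with stable (first-appearance) label order
#' inside ties.
#'
#' @param object A fitted `idlda` model.
#' @param disease Optional disease name(s) to restrict to; default all.
#' @param top Optional number of top candidates kept per disease.
#' @param candidates_only If `TRUE` (default) only pairs unknown in the
#'   training network (`A == 0`) are listed and ranked; if `FALSE`, all.
#' @param ... Unused.
#' @return Data frame with columns `disease`, `lncrna`, `score`, `rank`,
#'   `known`.
#' @export
predict.idlda <- function(object, disease = NULL, top = NULL,
                          candidates_only = TRUE, ...) {
  net <- object$net
  if (is.null(disease)) {
    rows <- seq_along(net$disease_names)
  } else {
    rows <- match(normalize_names(disease), net$disease_names)
    if (anyNA(rows))
      stop("unknown disease: ", paste(disease[is.na(rows)], collapse = ", "))
  }
  out <- lapply(rows, function(u) {
    keep <- if (candidates_only) which(net$A[u, ] == 0) else
      seq_along(net$lncrna_names)
    s <- object$R[u, keep]
    rk <- rank(-s, ties.method = "average")
    ord <- order(-s, keep)
    df <- data.frame(disease = net$disease_names[u],
                     lncrna = net$lncrna_names[keep][ord],
                     score = unname(s[ord]),
                     rank = unname(rk[ord]),
                     known = unname(net$A[u, keep][ord]))
    if (!is.null(top)) df <- df[seq_len(min(top, nrow(df))), , drop = FALSE]
    df
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Plot method: candidate vs known score separation
#'
#' Empirical distribution of the relevance scores of known pairs against
#' candidate (unknown) pairs, on a log10 score axis. A model that learned
#' the network's structure places known pairs far to the right.
#'
#' @param x A fitted `idlda` model.
#' @param ... Passed on to [graphics::plot()].
#' @export
plot.idlda <- function(x, ...) {
  pos <- x$R[x$net$A == 1]
  neg <- x$R[x$net$A == 0]
  eps <- min(c(pos, neg)[c(pos, neg) > 0], 1e-12)
  dp <- stats::density(log10(pmax(pos, eps)))
  dn <- stats::density(log10(pmax(neg, eps)))
  graphics::plot(dn, col = "grey40", lwd = 2, main = "Relevance score separation",
                 xlab = "log10 score", ylim = range(0, dp$y, dn$y), ...)
  graphics::lines(dp, col = "firebrick", lwd = 2)
  graphics::legend("topleft", c("candidate pairs", "known pairs"),
                   col = c("grey40", "firebrick"), lwd = 2, bty = "n")
  invisible(x)
}
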
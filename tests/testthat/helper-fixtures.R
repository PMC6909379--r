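# Small in-code fixtures shared across test files.

toy_network <- function(pairs) {
  as_assoc_network(data.frame(disease = pairs[, 1L], lncrna = pairs[, 2L]))
}

mesh_forest_from <- function(...) {
  lst <- list(...)
  structure(lapply(lst, function(x) sort(unique(x))), class = "mesh_forest")
}

# Random binary adjacency with every row and column nonempty.
random_adjacency <- function(n_d, n_l, p = 0.5) {
  repeat {
    A <- matrix(as.numeric(stats::runif(n_d * n_l) < p), n_d, n_l)
    if (all(rowSums(A) > 0) && all(colSums(A) > 0)) return(A)
  }
}

# Random symmetric similarity matrix with unit diagonal, entries in [0, 1].
random_similarity <- function(n) {
  M <- matrix(stats::runif(n * n), n, n)
  M <- (M + t(M)) / 2
  diag(M) <- 1
  M
}

# Random small MeSH-style forest over the given disease names: tree numbers
# drawn over two roots with a tiny segment alphabet so overlaps are common.
random_mesh_forest <- function(diseases, p_covered = 0.8, max_depth = 3L) {
  out <- list()
  for (d in diseases) {
    if (stats::runif(1) > p_covered) next
    k <- sample(1:2, 1L)
    out[[d]] <- unique(vapply(seq_len(k), function(i) {
      depth <- sample.int(max_depth, 1L)
      paste(c(sample(c("C01", "C02"), 1L),
              sample(c("1", "2", "3"), depth, replace = TRUE)),
            collapse = ".")
    }, ""))
  }
  structure(out, class = "mesh_forest")
}

write_tsv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
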
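#' Normalize disease / lncRNA names
#'
#' Trims leading and trailing whitespace, collapses internal runs of
#' whitespace to a single space and casefolds to lower case. The two source
#' databases capitalize inconsistently; a deterministic rule is required to
#' merge them.
#'
#' @param x Character vector of raw names.
#' @return Character vector of normalized names.
#' @export
#' @examples
#' normalize_names(c("  Lung   Neoplasms ", "BREAST CANCER"))
normalize_names <- function(x) {
  x <- gsub("\\s+", " ", trimws(as.character(x)))
  tolower(x)
}

#' Construct a bipartite association network
#'
#' Builds the binary adjacency matrix `A` (diseases in rows, lncRNAs in
#' columns) from a two-column table of verified disease-lncRNA pairs.
#' Names are normalized with [normalize_names()]; duplicate pairs collapse
#' to a single edge; label order is first appearance in the input.
#'
#' @param pairs Data frame (or coercible) whose first two columns are
#'   disease and lncRNA names. Extra columns (e.g. a source tag) are ignored.
#' @return An object of class `assoc_network`: a list with `disease_names`,
#'   `lncrna_names` and the binary matrix `A` (dimnames set).
#' @export
as_assoc_network <- function(pairs) {
  pairs <- as.data.frame(pairs)
  if (ncol(pairs) < 2L) stop("association table needs at least 2 columns")
  if (nrow(pairs) == 0L) stop("association table is empty")
  d <- normalize_names(pairs[[1L]])
  l <- normalize_names(pairs[[2L]])
  bad <- which(is.na(d) | is.na(l) | d == "" | l == "")
  if (length(bad)) stop("missing disease or lncRNA name in row ", bad[1L])
  disease_names <- unique(d)
  lncrna_names <- unique(l)
  A <- matrix(0, length(disease_names), length(lncrna_names),
              dimnames = list(disease_names, lncrna_names))
  A[cbind(match(d, disease_names), match(l, lncrna_names))] <- 1
  structure(list(disease_names = disease_names,
                 lncrna_names = lncrna_names,
                 A = A),
            class = "assoc_network")
}

#' Replace the adjacency of a network (labels kept)
#'
#' Internal helper used by the cross-validation routines, which repeatedly
#' zero entries of `A` while keeping the label sets fixed.
#' @noRd
replace_adjacency <- function(net, A) {
  stopifnot(identical(dim(A), dim(net$A)))
  net$A <- A
  net
}

#' Read an association table from TSV
#'
#' Expected format: tab-separated, columns `disease`, `lncrna` and an
#' optional `source`; lines starting with `#` are ignored; a header row is
#' auto-detected (a first row whose first two fields are `disease` and
#' `lncrna`, case-insensitively).
#'
#' @param path Path to the TSV file.
#' @param col_disease,col_lncrna Column indices of the disease and lncRNA
#'   fields (defaults 1 and 2).
#' @param header `"auto"` (default), `TRUE` or `FALSE`.
#' @return An `assoc_network`; see [as_assoc_network()].
#' @export
read_associations <- function(path, col_disease = 1L, col_lncrna = 2L,
                              header = "auto") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  lines <- raw[keep]
  lineno <- seq_along(raw)[keep]
  if (length(lines) == 0L) stop("empty association file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  need <- max(col_disease, col_lncrna)
  if (identical(header, "auto")) {
    f1 <- tolower(trimws(fields[[1L]]))
    header <- length(f1) >= 2L && f1[col_disease] == "disease" &&
      f1[col_lncrna] %in% c("lncrna", "lnc_rna")
  }
  if (isTRUE(header)) {
    fields <- fields[-1L]
    lineno <- lineno[-1L]
  }
  if (length(fields) == 0L) stop("no data rows in ", path)
  for (k in seq_along(fields)) {
    f <- fields[[k]]
    if (length(f) < need || !nzchar(trimws(f[col_disease])) ||
        !nzchar(trimws(f[col_lncrna])))
      stop("missing field on line ", lineno[k], " of ", path)
  }
  d <- vapply(fields, `[[`, "", col_disease)
  l <- vapply(fields, `[[`, "", col_lncrna)
  as_assoc_network(data.frame(disease = d, lncrna = l))
}

#' Write an association table to TSV
#'
#' Inverse of [read_associations()]: emits one `disease<TAB>lncrna` row per
#' edge of `A`, with a header, in row-major (disease-first-appearance) order.
#'
#' @param net An `assoc_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(net, path) {
  idx <- which(net$A == 1, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  df <- data.frame(disease = net$disease_names[idx[, 1L]],
                   lncrna = net$lncrna_names[idx[, 2L]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a disease-to-MeSH-tree-number table
#'
#' Tab-separated table with columns `disease` and `tree_numbers`
#' (semicolon-delimited dot coordinates such as `C04.588.894.797`). A disease
#' listed on several lines receives the union of its tree numbers. `#`
#' comment lines are ignored and a `disease<TAB>tree_numbers` header row is
#' auto-detected.
#'
#' @param path Path to the TSV file.
#' @return An object of class `mesh_forest`: a named list mapping normalized
#'   disease name to a character vector of tree numbers. May be empty.
#' @export
read_mesh_forest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  lines <- raw[keep]
  lineno <- seq_along(raw)[keep]
  forest <- structure(list(), class = "mesh_forest")
  if (length(lines) == 0L) return(forest)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  f1 <- tolower(trimws(fields[[1L]]))
  if (length(f1) >= 2L && f1[1L] == "disease" && f1[2L] == "tree_numbers") {
    fields <- fields[-1L]
    lineno <- lineno[-1L]
  }
  out <- list()
  for (k in seq_along(fields)) {
    f <- fields[[k]]
    if (length(f) < 2L) stop("missing field on line ", lineno[k], " of ", path)
    nm <- normalize_names(f[1L])
    tns <- trimws(strsplit(f[2L], ";", fixed = TRUE)[[1L]])
    tns <- tns[nzchar(tns)]
    for (tn in tns) validate_tree_number(tn, lineno[k], path)
    out[[nm]] <- sort(unique(c(out[[nm]], tns)))
  }
  structure(out, class = "mesh_forest")
}

validate_tree_number <- function(tn, line = NULL, path = NULL) {
  segs <- strsplit(tn, ".", fixed = TRUE)[[1L]]
  ok <- length(segs) >= 1L && all(nzchar(segs)) &&
    all(grepl("^[A-Za-z0-9]+$", segs)) && !grepl("\\.$", tn)
  if (!ok)
    stop("malformed tree number '", tn, "'",
         if (!is.null(line)) paste0(" on line ", line, " of ", path))
  invisible(tn)
}

#' Write a MeSH forest to TSV
#'
#' @param forest A `mesh_forest`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mesh_forest <- function(forest, path) {
  nm <- names(forest)
  df <- data.frame(
    disease = nm,
    tree_numbers = vapply(forest, paste, "", collapse = ";"),
    row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Network density
#'
#' Number of edges divided by the number of possible edges of the bipartite
#' graph, i.e. `sum(A) / (N_d * N_l)`.
#'
#' @param net An `assoc_network`, or a bare binary matrix.
#' @return Density as a fraction in (0, 1].
#' @export
#' @examples
#' network_density(as_assoc_network(data.frame(d = c("a", "a"), l = c("x", "y"))))
network_density <- function(net) {
  A <- if (inherits(net, "assoc_network")) net$A else as.matrix(net)
  if (length(A) == 0L) stop("empty network")
  sum(A) / length(A)
}

#' Write / read a labeled matrix as TSV
#'
#' Row labels in the first column, column labels in the first row.
#'
#' @param m Numeric matrix with dimnames.
#' @param path File path.
#' @return `path` invisibly (write); the matrix (read).
#' @export
write_matrix_tsv <- function(m, path) {
  utils::write.table(as.data.frame(m), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  as.matrix(utils::read.delim(path, row.names = 1L, check.names = FALSE))
}

#' @export
print.assoc_network <- function(x, ...) {
  cat("Bipartite association network\n")
  cat(sprintf("  diseases: %d   lncRNAs: %d   associations: %d   density: %.4f\n",
              nrow(x$A), ncol(x$A), sum(x$A), network_density(x)))
  invisible(x)
}

#' @export
print.mesh_forest <- function(x, ...) {
  ntn <- sum(lengths(x))
  cat(sprintf("MeSH forest: %d diseases, %d tree numbers\n", length(x), ntn))
  invisible(x)
}
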
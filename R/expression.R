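#' Single-cell expression matrix with cluster labels
#'
#' Wraps a genes-by-cells count matrix together with per-cell cluster labels
#' and a normalised layer. Normalisation is the standard single-cell
#' transform: per-cell scaling to a fixed library size (default 10,000
#' counts) followed by `log(1 + x)`. Gating predicates and all expression
#' scoring operate on the normalised layer; percent-expressing uses the raw
#' counts (a cell "expresses" a gene when its raw count is > 0).
#'
#' @param counts Numeric genes-by-cells matrix (dense or `Matrix` sparse)
#'   with row names (genes) and column names (cells); values non-negative.
#' @param clusters Named character vector or factor: cluster label per cell
#'   (names matching the column names of `counts`), or an unnamed vector in
#'   column order.
#' @param scale_factor Library size for normalisation.
#' @return Object of class `expression_matrix`: list with `counts`, `norm`,
#'   `cells` (data frame `cell`, `cluster`), `genes`, `scale_factor`.
#' @export
expression_matrix <- function(counts, clusters, scale_factor = 1e4) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` needs gene row names and cell column names", call. = FALSE)
  }
  if (any(counts@x < 0)) stop("counts must be non-negative", call. = FALSE)
  if (is.null(names(clusters))) {
    if (length(clusters) != ncol(counts)) {
      stop("`clusters` length must match the number of cells", call. = FALSE)
    }
    names(clusters) <- colnames(counts)
  }
  missing <- setdiff(colnames(counts), names(clusters))
  if (length(missing)) {
    stop("cells without a cluster label: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  clusters <- as.character(clusters[colnames(counts)])
  libs <- Matrix::colSums(counts)
  libs[libs == 0] <- 1  # empty cells normalise to all-zero, not NaN
  norm <- counts %*% Matrix::Diagonal(x = scale_factor / libs)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(counts)
  structure(list(counts = counts, norm = norm,
                 cells = data.frame(cell = colnames(counts),
                                    cluster = clusters,
                                    stringsAsFactors = FALSE),
                 genes = rownames(counts), scale_factor = scale_factor),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("Expression matrix: %d genes x %d cells, %d cluster(s)\n",
              length(x$genes), nrow(x$cells),
              length(unique(x$cells$cluster))))
  invisible(x)
}

.cells_of <- function(em, cluster) {
  cells <- em$cells$cell[em$cells$cluster == cluster]
  if (!length(cells)) stop("empty or unknown cluster: ", cluster,
                           call. = FALSE)
  cells
}

.check_genes <- function(em, genes) {
  bad <- setdiff(genes, em$genes)
  if (length(bad)) {
    stop("gene(s) not in matrix: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
}

#' Read a dense expression CSV plus cluster labels
#'
#' @param matrix_path CSV with genes in rows (first column = gene name),
#'   cells in columns.
#' @param labels_path Two-column CSV `cell,cluster`.
#' @param scale_factor Passed to [expression_matrix()].
#' @return An `expression_matrix`.
#' @export
read_expression_csv <- function(matrix_path, labels_path,
                                scale_factor = 1e4) {
  m <- utils::read.csv(matrix_path, row.names = 1L, check.names = FALSE)
  labels <- utils::read.csv(labels_path, colClasses = "character")
  expression_matrix(as.matrix(m),
                    stats::setNames(labels$cluster, labels$cell),
                    scale_factor = scale_factor)
}

#' Read a Matrix Market expression triplet with sidecar tables
#'
#' @param mtx_path Matrix Market file, genes x cells.
#' @param genes_path One-column (or headerless) text file of gene names.
#' @param cells_path One-column text file of cell names.
#' @param labels_path Two-column CSV `cell,cluster`.
#' @param scale_factor Passed to [expression_matrix()].
#' @return An `expression_matrix`.
#' @export
read_expression_mtx <- function(mtx_path, genes_path, cells_path,
                                labels_path, scale_factor = 1e4) {
  m <- Matrix::readMM(mtx_path)
  rownames(m) <- readLines(genes_path)
  colnames(m) <- readLines(cells_path)
  labels <- utils::read.csv(labels_path, colClasses = "character")
  expression_matrix(m, stats::setNames(labels$cluster, labels$cell),
                    scale_factor = scale_factor)
}

#' Write an expression matrix as Matrix Market plus sidecars
#'
#' @param em An `expression_matrix`.
#' @param dir Output directory (created if needed).
#' @return Named vector of the four file paths, invisibly.
#' @export
write_expression_mtx <- function(em, dir) {
  stopifnot(inherits(em, "expression_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(mtx = file.path(dir, "counts.mtx"),
             genes = file.path(dir, "genes.txt"),
             cells = file.path(dir, "cells.txt"),
             labels = file.path(dir, "labels.csv"))
  Matrix::writeMM(em$counts, paths[["mtx"]])
  writeLines(em$genes, paths[["genes"]])
  writeLines(em$cells$cell, paths[["cells"]])
  utils::write.csv(em$cells, paths[["labels"]], row.names = FALSE)
  invisible(paths)
}

#' Append an averaged gene group as a pseudo-gene
#'
#' Adds a pseudo-gene whose per-cell value is the arithmetic mean of the
#' member genes, computed on both the raw and the normalised layer. Used for
#' the three co-produced insulin-like peptides (Ilp2, Ilp3, Ilp5), which
#' target the same receptor and are treated as one ligand: averaging happens
#' per cell *before* any percent-expressing or score computation, so the
#' group's percent-expressing is the fraction of cells whose mean is > 0.
#'
#' @param em An `expression_matrix`.
#' @param name Name of the pseudo-gene (e.g. `"Ilp235"`).
#' @param genes Character vector of member genes (all must be present).
#' @return A new `expression_matrix` including the pseudo-gene.
#' @export
add_gene_group <- function(em, name, genes) {
  stopifnot(inherits(em, "expression_matrix"))
  .check_genes(em, genes)
  grp_counts <- Matrix::colMeans(em$counts[genes, , drop = FALSE])
  grp_norm <- Matrix::colMeans(em$norm[genes, , drop = FALSE])
  out <- em
  out$counts <- rbind(em$counts, Matrix::Matrix(grp_counts, nrow = 1L,
                                                sparse = TRUE,
                                                dimnames = list(name, NULL)))
  out$norm <- rbind(em$norm, Matrix::Matrix(grp_norm, nrow = 1L,
                                            sparse = TRUE,
                                            dimnames = list(name, NULL)))
  colnames(out$counts) <- colnames(em$counts)
  colnames(out$norm) <- colnames(em$norm)
  out$genes <- c(em$genes, name)
  out
}

#' Per-cell values of the insulin-like-peptide group
#'
#' Convenience wrapper returning the per-cell mean normalised expression of
#' the three insulin-like peptides for the cells of one cluster.
#'
#' @param em An `expression_matrix`.
#' @param cluster Cluster label.
#' @param genes The member genes (default `c("Ilp2", "Ilp3", "Ilp5")`).
#' @return Named numeric vector, one value per cell of the cluster.
#' @export
dilp_group_expression <- function(em, cluster,
                                  genes = c("Ilp2", "Ilp3", "Ilp5")) {
  stopifnot(inherits(em, "expression_matrix"))
  .check_genes(em, genes)
  cells <- .cells_of(em, cluster)
  Matrix::colMeans(em$norm[genes, cells, drop = FALSE])
}

#' Parse a gating expression
#'
#' Turns a conjunction such as `"Crz > 3 & sNPF > 3 & Dh44 == 0"` into a
#' `gating_criterion` (data frame of atomic predicates). Only `>` and `==`
#' comparators with non-negative thresholds are allowed.
#'
#' @param text The gating expression.
#' @return Object of class `gating_criterion`.
#' @export
parse_gating <- function(text) {
  parts <- trimws(strsplit(text, "&", fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts)]
  if (!length(parts)) {
    return(structure(data.frame(gene = character(), op = character(),
                                value = numeric(), stringsAsFactors = FALSE),
                     class = c("gating_criterion", "data.frame")))
  }
  m <- regmatches(parts, regexec("^([^ =>]+)\\s*(==|>)\\s*([0-9.]+)$", parts))
  bad <- vapply(m, length, integer(1L)) != 4L
  if (any(bad)) {
    stop("cannot parse gating predicate(s): ",
         paste(parts[bad], collapse = "; "), call. = FALSE)
  }
  out <- data.frame(gene = vapply(m, `[`, "", 2L),
                    op = vapply(m, `[`, "", 3L),
                    value = as.numeric(vapply(m, `[`, "", 4L)),
                    stringsAsFactors = FALSE)
  if (any(out$value < 0)) stop("gating thresholds must be non-negative",
                               call. = FALSE)
  structure(out, class = c("gating_criterion", "data.frame"))
}

#' Select cells satisfying a gating criterion
#'
#' Evaluates a conjunction of atomic predicates (`gene > x` or `gene == x`)
#' on the normalised layer and returns the ids of the cells satisfying all of
#' them. An empty criterion selects every cell. Comparisons are exact: a cell
#' at the threshold value fails a strict `>` predicate.
#'
#' @param em An `expression_matrix`.
#' @param criterion A `gating_criterion` from [parse_gating()] (or a string,
#'   parsed on the fly).
#' @return Character vector of cell ids.
#' @examples
#' \dontrun{
#' gate_cells(em, "Crz > 3 & sNPF > 3 & Dh44 == 0")
#' }
#' @export
gate_cells <- function(em, criterion) {
  stopifnot(inherits(em, "expression_matrix"))
  if (is.character(criterion)) criterion <- parse_gating(criterion)
  stopifnot(inherits(criterion, "gating_criterion"))
  if (!nrow(criterion)) return(em$cells$cell)
  .check_genes(em, criterion$gene)
  keep <- rep(TRUE, ncol(em$norm))
  for (i in seq_len(nrow(criterion))) {
    v <- as.numeric(em$norm[criterion$gene[i], ])
    keep <- keep & if (criterion$op[i] == ">") v > criterion$value[i]
    else v == criterion$value[i]
  }
  colnames(em$norm)[keep]
}
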
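#' Fraction of cells in a cluster expressing a gene
#'
#' A cell expresses a gene when its raw count is greater than zero.
#'
#' @param em An `expression_matrix`.
#' @param cluster Cluster label (must be nonempty).
#' @param gene Gene name.
#' @return Fraction in \[0, 1\].
#' @export
percent_expressing <- function(em, cluster, gene) {
  stopifnot(inherits(em, "expression_matrix"))
  .check_genes(em, gene)
  cells <- .cells_of(em, cluster)
  mean(em$counts[gene, cells] > 0)
}

#' Scaled cluster-level expression
#'
#' Computes the mean normalised expression of each gene per cluster and
#' rescales it to \[0, 100\] across the cluster set being compared. The
#' default is per-gene min-max scaling (the cluster with the lowest mean maps
#' to 0, the highest to 100); `method = "zscore"` standardises the cluster
#' means instead and maps them affinely so that -2 and +2 standard deviations
#' hit 0 and 100 (clipped). An all-zero gene scores 0 everywhere, and with a
#' single cluster a nonzero gene scores 100.
#'
#' @param em An `expression_matrix`.
#' @param genes Character vector of genes.
#' @param clusters Cluster labels to compare across (default: all clusters).
#' @param method `"minmax"` (default) or `"zscore"`.
#' @return Numeric matrix genes x clusters with values in \[0, 100\].
#' @export
scaled_expression <- function(em, genes, clusters = NULL,
                              method = c("minmax", "zscore")) {
  stopifnot(inherits(em, "expression_matrix"))
  method <- match.arg(method)
  .check_genes(em, genes)
  if (is.null(clusters)) clusters <- sort(unique(em$cells$cluster))
  if (!length(clusters)) stop("need at least one cluster", call. = FALSE)
  means <- sapply(clusters, function(cl) {
    cells <- .cells_of(em, cl)
    Matrix::rowMeans(em$norm[genes, cells, drop = FALSE])
  })
  means <- matrix(means, nrow = length(genes),
                  dimnames = list(genes, clusters))
  out <- matrix(0, nrow = length(genes), ncol = length(clusters),
                dimnames = list(genes, clusters))
  for (g in seq_along(genes)) {
    v <- means[g, ]
    if (all(v == 0)) next
    if (method == "minmax") {
      rng <- range(v)
      out[g, ] <- if (rng[2] > rng[1]) {
        # clamp: 100 * a / a can exceed 100 by a few ulps
        pmin(100, pmax(0, 100 * (v - rng[1]) / (rng[2] - rng[1])))
      } else 100  # degenerate range, nonzero gene
    } else {
      s <- stats::sd(v)
      z <- if (s > 0) (v - mean(v)) / s else rep(0, length(v))
      out[g, ] <- pmin(100, pmax(0, 25 * (z + 2)))
    }
  }
  out
}

#' Expression score
#'
#' The product of the scaled cluster expression (0-100) and the fraction of
#' cluster cells expressing the gene, keeping the 0-100 scale.
#'
#' @param scaled Scaled expression in \[0, 100\].
#' @param pct Percent expressing as a fraction in \[0, 1\].
#' @return `scaled * pct`, in \[0, 100\].
#' @examples
#' expression_score(100, 0.5)  # 50
#' @export
expression_score <- function(scaled, pct) {
  stopifnot(all(scaled >= 0 & scaled <= 100), all(pct >= 0 & pct <= 1))
  scaled * pct
}

#' Score table over clusters and genes
#'
#' Long-format table of percent-expressing, scaled expression, and their
#' product (the expression score) for every (cluster, gene) combination —
#' the quantities behind a dot plot.
#'
#' @param em An `expression_matrix`.
#' @param genes Character vector of genes.
#' @param clusters Cluster labels (default: all).
#' @param method Scaling method, see [scaled_expression()].
#' @return Data frame of class `expression_score_table` with columns
#'   `cluster`, `gene`, `pct`, `scaled`, `score`.
#' @export
expression_score_table <- function(em, genes, clusters = NULL,
                                   method = "minmax") {
  stopifnot(inherits(em, "expression_matrix"))
  if (is.null(clusters)) clusters <- sort(unique(em$cells$cluster))
  genes <- unique(genes)
  scaled <- scaled_expression(em, genes, clusters, method = method)
  pct <- sapply(clusters, function(cl) {
    cells <- .cells_of(em, cl)
    Matrix::rowMeans(em$counts[genes, cells, drop = FALSE] > 0)
  })
  pct <- matrix(pct, nrow = length(genes), dimnames = list(genes, clusters))
  out <- expand.grid(gene = genes, cluster = clusters,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[, c("cluster", "gene")]
  out$pct <- pct[cbind(out$gene, out$cluster)]
  out$scaled <- scaled[cbind(out$gene, out$cluster)]
  out$score <- expression_score(out$scaled, out$pct)
  class(out) <- c("expression_score_table", "data.frame")
  out
}

#' Presence calls for ligands or receptors
#'
#' Applies the conservative presence rules: a neuropeptide (ligand) is
#' present in a cluster only when at least 50% of its cells express it *and*
#' its expression score is at least 2.5; a receptor is present when at least
#' 5% of the cells express it. Both percent thresholds are inclusive.
#'
#' @param score_table An `expression_score_table` (or compatible data frame
#'   with `pct` and `score` columns).
#' @param role `"ligand"` or `"receptor"`.
#' @param pct_min Override of the percent-expressing threshold (fraction).
#' @param score_min Override of the ligand score filter.
#' @return The table with a logical `present` column appended.
#' @export
presence_filters <- function(score_table, role = c("ligand", "receptor"),
                             pct_min = NULL, score_min = NULL) {
  role <- match.arg(role)
  if (is.null(pct_min)) pct_min <- if (role == "ligand") 0.50 else 0.05
  if (is.null(score_min)) score_min <- if (role == "ligand") 2.5 else 0
  score_table$present <- score_table$pct >= pct_min &
    score_table$score >= score_min
  score_table
}

#' Load a hormone-receptor pair catalog
#'
#' Reads a comma-separated catalog with columns `ligand`, `receptor1`, and
#' optionally `receptor2` (empty when the hormone has a single receptor).
#' The catalog covering the hormones produced by the NSC ships with the
#' package: `system.file("extdata", "hormone_receptor_pairs.csv",
#' package = "nscnet")`.
#'
#' @param path CSV path.
#' @return Data frame with columns `ligand`, `receptor1`, `receptor2`
#'   (`NA` when absent).
#' @export
load_pair_catalog <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("ligand", "receptor1") %in% names(df))) {
    stop("pair catalog needs columns ligand and receptor1", call. = FALSE)
  }
  if (!"receptor2" %in% names(df)) df$receptor2 <- NA_character_
  df$receptor2[!is.na(df$receptor2) & !nzchar(df$receptor2)] <- NA_character_
  df
}

#' Resolve which receptor of a pair carries the signal in a target cluster
#'
#' When a hormone acts through two receptors and both are present in a
#' cluster, only the higher-scoring one is considered; an exact score tie is
#' broken toward the lexicographically smaller gene name so results are
#' deterministic.
#'
#' @param receptors Character vector of 1-2 receptor genes.
#' @param cluster_scores Score table rows for the target cluster (needs
#'   `gene`, `pct`, `score`), already or not yet presence-filtered.
#' @param pct_min Receptor presence threshold (fraction, inclusive).
#' @return The chosen receptor name, or `NA_character_` when none is present.
#' @export
resolve_receptor <- function(receptors, cluster_scores, pct_min = 0.05) {
  receptors <- receptors[!is.na(receptors)]
  rows <- cluster_scores[cluster_scores$gene %in% receptors &
                           cluster_scores$pct >= pct_min, , drop = FALSE]
  if (!nrow(rows)) return(NA_character_)
  rows <- rows[order(-rows$score, rows$gene), , drop = FALSE]
  rows$gene[1L]
}

#' Build the putative paracrine ligand-receptor network
#'
#' For every source cluster, hormone, and target cluster, emits an edge when
#' the hormone passes the ligand presence rules in the source (pct >= 50%
#' and score >= 2.5) and a receptor of its pair passes the receptor presence
#' rule (pct >= 5%) in the target. When both receptors of a pair are present
#' in the target, only the higher-scoring one is used. The edge weight is
#' `ligand score x receptor score / 100`, on the 0-100 scale; zero-weight
#' edges are never emitted. Hormones whose receptors are absent from every
#' target contribute no edges at all.
#'
#' @param score_table An `expression_score_table` covering all ligand and
#'   receptor genes over the relevant clusters.
#' @param pairs Pair catalog (`ligand`, `receptor1`, `receptor2`).
#' @param sources,targets Cluster labels acting as hormone sources / targets
#'   (default: all clusters in the table).
#' @param ligand_pct_min,ligand_score_min,receptor_pct_min Presence
#'   thresholds (defaults 0.50, 2.5, 0.05).
#' @return Object of class `paracrine_network`: data frame with columns
#'   `source`, `target`, `ligand`, `receptor`, `ligand_score`,
#'   `receptor_score`, `weight`.
#' @export
build_paracrine_network <- function(score_table, pairs, sources = NULL,
                                    targets = NULL, ligand_pct_min = 0.50,
                                    ligand_score_min = 2.5,
                                    receptor_pct_min = 0.05) {
  all_clusters <- unique(score_table$cluster)
  if (is.null(sources)) sources <- all_clusters
  if (is.null(targets)) targets <- all_clusters
  if (!"receptor2" %in% names(pairs)) pairs$receptor2 <- NA_character_
  edges <- list()
  for (i in seq_len(nrow(pairs))) {
    lig <- pairs$ligand[i]
    receptors <- c(pairs$receptor1[i], pairs$receptor2[i])
    lig_rows <- score_table[score_table$gene == lig &
                              score_table$cluster %in% sources, ,
                            drop = FALSE]
    lig_rows <- lig_rows[lig_rows$pct >= ligand_pct_min &
                           lig_rows$score >= ligand_score_min, , drop = FALSE]
    if (!nrow(lig_rows)) next
    for (tg in targets) {
      cl_scores <- score_table[score_table$cluster == tg, , drop = FALSE]
      rec <- resolve_receptor(receptors, cl_scores,
                              pct_min = receptor_pct_min)
      if (is.na(rec)) next
      rec_score <- cl_scores$score[cl_scores$gene == rec][1L]
      for (j in seq_len(nrow(lig_rows))) {
        w <- lig_rows$score[j] * rec_score / 100
        if (w <= 0) next
        edges[[length(edges) + 1L]] <- data.frame(
          source = lig_rows$cluster[j], target = tg, ligand = lig,
          receptor = rec, ligand_score = lig_rows$score[j],
          receptor_score = rec_score, weight = w, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(edges)) do.call(rbind, edges) else {
    data.frame(source = character(), target = character(),
               ligand = character(), receptor = character(),
               ligand_score = numeric(), receptor_score = numeric(),
               weight = numeric(), stringsAsFactors = FALSE)
  }
  out <- out[order(out$ligand, out$source, out$target), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("paracrine_network", "data.frame")
  out
}

#' @export
print.paracrine_network <- function(x, ...) {
  cat(sprintf("Paracrine network: %d edge(s), %d ligand(s), %d cluster(s)\n",
              nrow(x), length(unique(x$ligand)),
              length(unique(c(x$source, x$target)))))
  NextMethod()
}

#' Export a paracrine network as GraphML
#'
#' @param network A `paracrine_network`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
export_paracrine_graphml <- function(network, path) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = network$source, to = network$target,
               ligand = network$ligand, receptor = network$receptor,
               weight = network$weight),
    directed = TRUE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Receptor expression catalog across tissues or cell types
#'
#' Long-format dot-plot table (percent expressing, scaled expression, score)
#' of a receptor list across tissue-level clusters, using the same scoring
#' rules as the NSC analysis. Cell types spanning several tissues can be
#' pooled beforehand under a shared label via `pool_map`.
#'
#' @param em An `expression_matrix` whose clusters are tissues / cell types.
#' @param receptors Character vector of receptor genes.
#' @param clusters Cluster labels to include (default: all).
#' @param pool_map Optional named character vector old-label -> pooled label
#'   (e.g. mapping broadly distributed cell types to `"general"`).
#' @param method Scaling method, see [scaled_expression()].
#' @return An `expression_score_table`.
#' @export
tissue_receptor_catalog <- function(em, receptors, clusters = NULL,
                                    pool_map = NULL, method = "minmax") {
  stopifnot(inherits(em, "expression_matrix"))
  if (!is.null(pool_map)) {
    hit <- em$cells$cluster %in% names(pool_map)
    em$cells$cluster[hit] <- unname(pool_map[em$cells$cluster[hit]])
  }
  expression_score_table(em, receptors, clusters, method = method)
}
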
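#' Build the NSC input-profile matrix
#'
#' Collects, for a set of NSC, the synapse counts of all their significant
#' presynaptic partners into an NSC-by-partner matrix. NSC with no significant
#' input at the chosen threshold (as happens for most ion-transport-peptide
#' lateral NSC in the adult connectome) are excluded from the matrix and
#' reported in the `excluded` element rather than silently dropped.
#'
#' @param connectome A `connectome`.
#' @param nsc_ids Character vector of NSC neuron ids (nonempty, all present in
#'   the connectome).
#' @param threshold Optional synapse threshold (default: significance).
#' @return An object of class `input_profile`: list with `matrix` (rows =
#'   NSC with input, columns = presynaptic partner ids, integer synapse
#'   counts) and `excluded` (ids of NSC with no significant input).
#' @export
build_input_profile <- function(connectome, nsc_ids, threshold = NULL) {
  stopifnot(inherits(connectome, "connectome"))
  nsc_ids <- as.character(nsc_ids)
  if (!length(nsc_ids)) stop("`nsc_ids` must be nonempty", call. = FALSE)
  absent <- setdiff(nsc_ids, connectome$neurons$id)
  if (length(absent)) {
    stop("nsc id(s) not in connectome: ",
         paste(utils::head(absent, 5L), collapse = ", "), call. = FALSE)
  }
  e <- significant_edges(connectome, threshold)
  e <- e[e$post %in% nsc_ids, , drop = FALSE]
  partners <- sort(unique(e$pre))
  mat <- matrix(0L, nrow = length(nsc_ids), ncol = length(partners),
                dimnames = list(nsc_ids, partners))
  if (nrow(e)) {
    mat[cbind(match(e$post, nsc_ids), match(e$pre, partners))] <-
      as.integer(e$count)
  }
  keep <- rowSums(mat) > 0
  structure(list(matrix = mat[keep, , drop = FALSE],
                 excluded = nsc_ids[!keep]),
            class = "input_profile")
}

#' @export
print.input_profile <- function(x, ...) {
  cat(sprintf("Input profile: %d NSC x %d presynaptic partners\n",
              nrow(x$matrix), ncol(x$matrix)))
  if (length(x$excluded)) {
    cat("  excluded (no significant input):",
        paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Cosine similarity between NSC input profiles
#'
#' Computes the pairwise cosine similarity `S[i, j] = <x_i, x_j> /
#' (||x_i|| ||x_j||)` between the rows of an input-profile matrix. Because
#' synapse counts are non-negative, all values lie in \[0, 1\]; the diagonal
#' is exactly 1. Cosine similarity is invariant to per-row scale, so raw
#' synapse counts need no prior normalisation.
#'
#' @param profile An `input_profile` or a numeric matrix with no all-zero row.
#' @return A symmetric matrix of cosine similarities with unit diagonal.
#' @examples
#' m <- rbind(a = c(1, 2, 0), b = c(2, 1, 0))
#' cosine_similarity_matrix(m)   # off-diagonal 0.8
#' @export
cosine_similarity_matrix <- function(profile) {
  m <- if (inherits(profile, "input_profile")) profile$matrix else profile
  m <- as.matrix(m)
  if (!is.numeric(m)) stop("profile must be numeric", call. = FALSE)
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) {
    stop("all-zero row reached cosine computation; exclude it first",
         call. = FALSE)
  }
  s <- tcrossprod(m / nrm)
  s[s > 1] <- 1
  diag(s) <- 1
  s
}

#' Cluster NSC by input similarity
#'
#' Agglomerative clustering of NSC on the distance `1 - cosine similarity` of
#' their presynaptic input profiles. Average linkage is the default; the
#' result is deterministic given the similarity matrix (rows are taken in
#' lexicographic id order before agglomeration so merge order does not depend
#' on input ordering).
#'
#' @param similarity Square symmetric similarity matrix with unit diagonal
#'   (row/column names are the NSC ids), e.g. from
#'   [cosine_similarity_matrix()].
#' @param k Number of clusters to cut the dendrogram into (1 <= k <= n).
#' @param method Linkage passed to [stats::hclust()].
#' @return An object of class `nsc_clustering`: list with `labels` (named
#'   integer vector of cluster memberships), `hclust` (the dendrogram), `k`,
#'   and `method`.
#' @export
cluster_nsc <- function(similarity, k, method = "average") {
  similarity <- as.matrix(similarity)
  n <- nrow(similarity)
  if (n != ncol(similarity)) stop("similarity must be square", call. = FALSE)
  if (max(abs(similarity - t(similarity))) > 1e-8) {
    stop("similarity must be symmetric", call. = FALSE)
  }
  if (max(abs(diag(similarity) - 1)) > 1e-8) {
    stop("similarity must have unit diagonal", call. = FALSE)
  }
  k <- .check_count(k, "k")
  if (k > n) stop("`k` exceeds the number of NSC", call. = FALSE)
  if (is.null(rownames(similarity))) {
    rownames(similarity) <- colnames(similarity) <- paste0("nsc", seq_len(n))
  }
  ord <- order(rownames(similarity))
  similarity <- similarity[ord, ord, drop = FALSE]
  if (n == 1L) {
    labels <- stats::setNames(1L, rownames(similarity))
    return(structure(list(labels = labels, hclust = NULL, k = 1L,
                          method = method), class = "nsc_clustering"))
  }
  d <- stats::as.dist(1 - similarity)
  hc <- stats::hclust(d, method = method)
  labels <- stats::cutree(hc, k = k)
  structure(list(labels = labels, hclust = hc, k = k, method = method),
            class = "nsc_clustering")
}

#' @export
print.nsc_clustering <- function(x, ...) {
  cat(sprintf("NSC clustering: %d cells, k = %d (%s linkage on 1 - cosine)\n",
              length(x$labels), x$k, x$method))
  print(table(cluster = x$labels))
  invisible(x)
}

#' @export
plot.nsc_clustering <- function(x, ...) {
  if (is.null(x$hclust)) {
    stop("nothing to plot for a single-cell clustering", call. = FALSE)
  }
  plot(x$hclust, xlab = "", sub = "",
       main = "NSC input-profile clustering", ...)
  invisible(x)
}

#' Export a clustering dendrogram as Newick
#'
#' @param clustering An `nsc_clustering` with at least two leaves.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
export_dendrogram_newick <- function(clustering, path) {
  stopifnot(inherits(clustering, "nsc_clustering"))
  if (is.null(clustering$hclust)) {
    stop("dendrogram requires at least two NSC", call. = FALSE)
  }
  ape::write.tree(ape::as.phylo(clustering$hclust), file = path)
  invisible(path)
}

#' Principal component analysis of NSC morphology features
#'
#' PCA of per-cell morphology measurements (cable length, surface area, cell
#' size, nuclei volume). Columns are z-scored before the decomposition so the
#' heterogeneous units do not dominate; zero-variance columns are dropped with
#' a warning.
#'
#' @param features Numeric data frame or matrix, one row per NSC, one column
#'   per morphology feature; at least 3 rows.
#' @return List with `scores` (centred PC scores), `explained` (fractions of
#'   variance, summing to 1), `rotation`, and `dropped` (names of
#'   zero-variance columns).
#' @export
morphology_pca <- function(features) {
  m <- as.matrix(features)
  if (!is.numeric(m)) stop("features must be numeric", call. = FALSE)
  if (nrow(m) < 3L) stop("need at least 3 records for PCA", call. = FALSE)
  sds <- apply(m, 2L, stats::sd)
  dropped <- colnames(m)[sds == 0]
  if (length(dropped)) {
    warning("zero-variance column(s) dropped: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    m <- m[, sds > 0, drop = FALSE]
  }
  if (!ncol(m)) stop("no feature with nonzero variance", call. = FALSE)
  z <- scale(m)
  p <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  explained <- p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x, explained = explained, rotation = p$rotation,
       dropped = dropped)
}

#' Map clusters to NSC subtype names
#'
#' Assigns each cluster at most one subtype name from the reference catalog,
#' either by propagating anchor cells of known identity, or by matching
#' cluster sizes to the catalog's observed adult counts (the size rule is how
#' the 18-cell medial cluster is recognised as the insulin-producing m-NSC).
#' Clusters without a match are labelled `unknown-m` or `unknown-l` when a
#' soma-position annotation is supplied, otherwise `unknown`.
#'
#' @param labels Named integer vector of cluster memberships (names are NSC
#'   ids), e.g. `cluster_nsc(...)$labels`.
#' @param anchors Optional named character vector mapping anchor NSC ids to
#'   subtype names. Conflicting anchors within one cluster are an error.
#' @param by_size If `TRUE`, clusters whose size matches exactly one
#'   unassigned catalog subtype's observed adult count take that name.
#' @param soma Optional named character vector (`"medial"`/`"lateral"`/...)
#'   per NSC id, used to refine unknown labels.
#' @param catalog Reference catalog, by default [nsc_subtype_catalog()].
#' @return Named character vector: subtype name per cluster (names are the
#'   cluster labels as character).
#' @export
assign_subtypes <- function(labels, anchors = NULL, by_size = FALSE,
                            soma = NULL, catalog = nsc_subtype_catalog()) {
  clusters <- sort(unique(labels))
  out <- stats::setNames(rep(NA_character_, length(clusters)),
                         as.character(clusters))
  if (!is.null(anchors)) {
    bad <- setdiff(names(anchors), names(labels))
    if (length(bad)) {
      stop("anchor id(s) not among clustered NSC: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    for (cl in clusters) {
      hit <- unique(anchors[names(anchors) %in% names(labels)[labels == cl]])
      if (length(hit) > 1L) {
        stop("cluster ", cl, " contains anchors of several subtypes: ",
             paste(hit, collapse = ", "), call. = FALSE)
      }
      if (length(hit) == 1L) out[as.character(cl)] <- hit
    }
  }
  if (by_size) {
    sizes <- table(labels)
    free <- catalog[!(catalog$name %in% out) &
                      !is.na(catalog$n_adult_observed) &
                      catalog$n_adult_observed > 0, , drop = FALSE]
    for (cl in clusters) {
      if (!is.na(out[as.character(cl)])) next
      match_rows <- free$name[free$n_adult_observed == sizes[as.character(cl)]]
      match_rows <- setdiff(match_rows, out)
      if (length(match_rows) == 1L) out[as.character(cl)] <- match_rows
    }
  }
  for (cl in clusters) {
    key <- as.character(cl)
    if (!is.na(out[key])) next
    if (!is.null(soma)) {
      pos <- unique(soma[names(labels)[labels == cl]])
      pos <- pos[!is.na(pos)]
      out[key] <- if (identical(pos, "medial")) "unknown-m"
      else if (identical(pos, "lateral")) "unknown-l"
      else "unknown"
    } else {
      out[key] <- "unknown"
    }
  }
  out
}
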
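# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (exhaustive recursion, closed-form formulas) so they are
# independent of the package's implementation paths.

# all simple directed paths source -> target with at most max_hops edges,
# by exhaustive depth-first enumeration over a thresholded edge frame
bf_simple_paths <- function(edges, source, target, max_hops, threshold = 1) {
  e <- edges[edges$count >= threshold, , drop = FALSE]
  adj <- split(e$post, e$pre)
  paths <- list()
  recurse <- function(node, visited) {
    if (length(visited) - 1L > max_hops) return()
    if (node == target && length(visited) >= 2L) {
      paths[[length(paths) + 1L]] <<- visited
      return()
    }
    for (nxt in adj[[node]]) {
      if (!(nxt %in% visited)) recurse(nxt, c(visited, nxt))
    }
  }
  recurse(source, source)
  paths
}

# all shortest simple paths (<= max_hops) for every source/target pair
bf_shortest_path_set <- function(edges, sources, targets, max_hops,
                                 threshold = 1) {
  out <- character()
  for (s in sources) for (t in setdiff(targets, s)) {
    paths <- bf_simple_paths(edges, s, t, max_hops, threshold)
    if (!length(paths)) next
    lens <- vapply(paths, length, integer(1L))
    keep <- paths[lens == min(lens)]
    out <- c(out, vapply(keep, paste, "", collapse = ">"))
  }
  sort(unique(out))
}

path_keys <- function(pathways) {
  sort(unique(vapply(pathways, function(p) paste(p$nodes, collapse = ">"),
                     character(1L))))
}

# exhaustive sensory -> interneuron -> NSC triple enumeration
bf_disynaptic <- function(edges, sensory, nsc, threshold) {
  e <- edges[edges$count >= threshold, , drop = FALSE]
  out <- character()
  inters <- setdiff(unique(e$pre[e$post %in% nsc]), c(sensory, nsc))
  for (i in inters) for (s in sensory) for (n in nsc) {
    if (any(e$pre == s & e$post == i) && any(e$pre == i & e$post == n)) {
      out <- c(out, paste(s, i, n, sep = ">"))
    }
  }
  sort(unique(out))
}

# closed-form adjusted Rand index from the contingency table
bf_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# small random connectome for oracle comparisons (<= 30 nodes, <= 120 edges)
random_connectome <- function(seed, n_nodes = NULL, n_edges = NULL) {
  set.seed(seed)
  if (is.null(n_nodes)) n_nodes <- sample(8:30, 1)
  if (is.null(n_edges)) n_edges <- sample(10:120, 1)
  ids <- paste0("v", seq_len(n_nodes))
  super <- sample(c("sensory", "central", "endocrine", "descending"),
                  n_nodes, replace = TRUE, prob = c(0.25, 0.45, 0.2, 0.1))
  neurons <- data.frame(id = ids, super_class = super,
                        stringsAsFactors = FALSE)
  pre <- sample(ids, n_edges, replace = TRUE)
  post <- sample(ids, n_edges, replace = TRUE)
  keep <- pre != post
  edges <- data.frame(pre = pre[keep], post = post[keep],
                      count = sample(1:12, sum(keep), replace = TRUE),
                      stringsAsFactors = FALSE)
  conn <- suppressWarnings(
    build_connectome(neurons, edges, threshold_config()))
  conn
}

# minimal connectome from explicit edge triplets; extra ids become neurons
tiny_connectome <- function(edges, super = NULL,
                            thresholds = threshold_config()) {
  ids <- unique(c(edges$pre, edges$post, names(super)))
  sc <- rep("central", length(ids))
  names(sc) <- ids
  if (!is.null(super)) sc[names(super)] <- super
  neurons <- data.frame(id = ids, super_class = unname(sc),
                        stringsAsFactors = FALSE)
  build_connectome(neurons, edges, thresholds)
}

edge_df <- function(...) {
  rows <- list(...)
  data.frame(pre = vapply(rows, `[[`, "", 1L),
             post = vapply(rows, `[[`, "", 2L),
             count = as.integer(vapply(rows, function(r) as.numeric(r[[3L]]),
                                       numeric(1L))),
             stringsAsFactors = FALSE)
}
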
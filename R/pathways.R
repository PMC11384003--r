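FAST_NT <- c("acetylcholine", "glutamate", "gaba")

#' Transmitter label from prediction scores
#'
#' Assigns a fast-acting transmitter label (acetylcholine, glutamate or GABA)
#' from a neuron's prediction scores: the arg-max transmitter wins if its
#' score is strictly greater than the cutoff (default 0.62); otherwise, or on
#' an exact tie for the maximum, the label is `unknown`. Scores for other
#' transmitters are ignored.
#'
#' @param scores Named numeric vector of prediction scores in \[0, 1\]. Names
#'   may carry an `nt_` prefix (as in annotation tables).
#' @param cutoff Probability; a label is assigned only when the winning score
#'   is strictly greater than this.
#' @return A single string: one of `"acetylcholine"`, `"glutamate"`,
#'   `"gaba"`, or `"unknown"`.
#' @examples
#' nt_annotate(c(acetylcholine = 0.63, gaba = 0.2))  # "acetylcholine"
#' nt_annotate(c(acetylcholine = 0.62))              # "unknown" (not strictly greater)
#' @export
nt_annotate <- function(scores, cutoff = 0.62) {
  if (is.null(scores) || !length(scores)) return("unknown")
  names(scores) <- sub("^nt_", "", names(scores))
  scores <- scores[names(scores) %in% FAST_NT]
  scores <- scores[!is.na(scores)]
  if (!length(scores)) return("unknown")
  top <- max(scores)
  if (top <= cutoff) return("unknown")
  winners <- names(scores)[scores == top]
  if (length(winners) != 1L) return("unknown")
  winners
}

# transmitter label for a set of neuron ids, from the connectome's nt_* columns
.nt_labels <- function(connectome, ids, cutoff = NULL) {
  if (is.null(cutoff)) cutoff <- connectome$thresholds$nt_cutoff
  nt_cols <- grep("^nt_", names(connectome$neurons), value = TRUE)
  vapply(ids, function(id) {
    if (!length(nt_cols)) return("unknown")
    v <- unlist(connectome$neurons[id, nt_cols])
    nt_annotate(stats::setNames(as.numeric(v), nt_cols), cutoff)
  }, character(1L))
}

.pathway <- function(nodes, hop_counts, hop_nt, layers) {
  structure(list(nodes = nodes, hop_counts = hop_counts, hop_nt = hop_nt,
                 layers = layers), class = "pathway")
}

#' @export
print.pathway <- function(x, ...) {
  hops <- paste0(x$nodes[-length(x$nodes)], " -(", x$hop_counts, ",",
                 x$hop_nt, ")-> ")
  cat(paste0(paste(hops, collapse = ""), x$nodes[length(x$nodes)]), "\n")
  invisible(x)
}

# edge-count lookup table for a significant edge frame
.edge_lookup <- function(edges) {
  stats::setNames(edges$count, paste(edges$pre, edges$post, sep = "\r"))
}

.make_pathways <- function(connectome, node_lists, edges, roles = NULL) {
  lk <- .edge_lookup(edges)
  lapply(node_lists, function(nodes) {
    pre <- nodes[-length(nodes)]
    post <- nodes[-1L]
    counts <- as.integer(lk[paste(pre, post, sep = "\r")])
    nts <- .nt_labels(connectome, pre)
    layers <- if (!is.null(roles) && all(nodes %in% names(roles))) {
      unname(roles[nodes])
    } else {
      unname(connectome$neurons[nodes, "super_class"])
    }
    .pathway(nodes, counts, unname(nts), layers)
  })
}

#' Direct sensory inputs to NSC
#'
#' Sensory neurons with a significant synaptic edge onto any of the given
#' NSC, with their sensory modality.
#'
#' @param connectome A `connectome`.
#' @param nsc_ids Character vector of NSC ids.
#' @param threshold Optional synapse threshold (default: significance).
#' @return Data frame with columns `sensory_id`, `modality`, `nsc_id`,
#'   `count`; zero rows when no sensory neuron contacts an NSC.
#' @export
direct_sensory_inputs <- function(connectome, nsc_ids, threshold = NULL) {
  stopifnot(inherits(connectome, "connectome"))
  nsc_ids <- as.character(nsc_ids)
  e <- significant_edges(connectome, threshold)
  e <- e[e$post %in% nsc_ids, , drop = FALSE]
  sens <- connectome$neurons$id[connectome$neurons$super_class == "sensory"]
  e <- e[e$pre %in% sens, , drop = FALSE]
  out <- data.frame(sensory_id = e$pre,
                    modality = connectome$neurons[e$pre, "sensory_modality"],
                    nsc_id = e$post, count = e$count,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Disynaptic sensory-to-endocrine pathways
#'
#' Enumerates all two-hop chains sensory neuron -> interneuron -> NSC in which
#' both hops individually pass the significance threshold, and partitions the
#' neurons presynaptic to NSC into *sensory interneurons* (those on such a
#' chain, i.e. with significant sensory input) and *non-sensory interneurons*
#' (presynaptic to NSC but without significant sensory input).
#'
#' @param connectome A `connectome`.
#' @param nsc_ids Character vector of NSC ids.
#' @param threshold Optional synapse threshold (default: significance).
#' @return List with `pathways` (list of two-hop `pathway` objects),
#'   `sensory_interneurons`, and `non_sensory_interneurons` (character
#'   vectors of ids).
#' @export
disynaptic_sensory_pathways <- function(connectome, nsc_ids, threshold = NULL) {
  stopifnot(inherits(connectome, "connectome"))
  nsc_ids <- as.character(nsc_ids)
  e <- significant_edges(connectome, threshold)
  sens <- connectome$neurons$id[connectome$neurons$super_class == "sensory"]

  to_nsc <- e[e$post %in% nsc_ids, , drop = FALSE]
  inter <- setdiff(unique(to_nsc$pre), c(sens, nsc_ids))
  from_sens <- e[e$pre %in% sens & e$post %in% inter, , drop = FALSE]

  hop2 <- to_nsc[to_nsc$pre %in% inter, , drop = FALSE]
  chains <- merge(from_sens, hop2, by.x = "post", by.y = "pre",
                  suffixes = c("_1", "_2"))
  # columns after merge: post (= interneuron), pre, count_1, post_2, count_2
  node_lists <- if (nrow(chains)) {
    lapply(seq_len(nrow(chains)), function(i) {
      c(chains$pre[i], chains$post[i], chains$post_2[i])
    })
  } else list()
  node_lists <- node_lists[order(vapply(node_lists, paste, "",
                                        collapse = "\r"))]
  sens_in <- sort(unique(unlist(lapply(node_lists, `[`, 2L))))
  list(pathways = .make_pathways(connectome, node_lists, e),
       sensory_interneurons = sens_in,
       non_sensory_interneurons = sort(setdiff(inter, sens_in)))
}

#' Shortest k-hop pathways between neuron sets
#'
#' For every (source, target) pair, enumerates *all* simple directed paths of
#' the minimum hop length through the significant-edge graph, provided that
#' minimum is at most `max_hops`. Ties are kept, not broken: parallel routes
#' of equal length (for instance several projection-neuron relays between the
#' antennal lobe and an NSC) are all reported. Hops are counted as edges, so
#' a 3-hop path visits four neurons, and hops are unweighted — path length is
#' the number of edges, not a synapse-count sum.
#'
#' @param connectome A `connectome`.
#' @param sources,targets Character vectors of neuron ids.
#' @param max_hops Maximum path length in hops; values above 6 are refused
#'   unless `allow_long = TRUE` (combinatorial guard).
#' @param threshold Optional synapse threshold (default: significance).
#' @param roles Optional named character vector id -> layer label (e.g.
#'   `"ORN"`, `"ALPN"`, `"NSC"`); defaults to super-class labels.
#' @param allow_long Override the `max_hops > 6` guard.
#' @return List of `pathway` objects (nodes, per-hop synapse counts, per-hop
#'   transmitter labels, per-node layers), sorted deterministically.
#' @export
khop_shortest_pathways <- function(connectome, sources, targets,
                                   max_hops = NULL, threshold = NULL,
                                   roles = NULL, allow_long = FALSE) {
  stopifnot(inherits(connectome, "connectome"))
  if (is.null(max_hops)) max_hops <- connectome$thresholds$max_hops
  max_hops <- .check_count(max_hops, "max_hops")
  if (max_hops > 6L && !allow_long) {
    stop("max_hops > 6 refused (combinatorial guard); ",
         "set allow_long = TRUE to override", call. = FALSE)
  }
  sources <- unique(as.character(sources))
  targets <- unique(as.character(targets))
  e <- significant_edges(connectome, threshold)
  g <- igraph::graph_from_data_frame(
    e[, c("pre", "post")], directed = TRUE,
    vertices = connectome$neurons$id)
  node_lists <- list()
  for (s in sources) {
    tg <- setdiff(targets, s)
    if (!length(tg)) next
    res <- suppressWarnings(
      igraph::all_shortest_paths(g, from = s, to = tg, mode = "out"))
    for (p in res$vpaths) {
      nodes <- igraph::as_ids(p)
      if (length(nodes) >= 2L && (length(nodes) - 1L) <= max_hops) {
        node_lists[[length(node_lists) + 1L]] <- nodes
      }
    }
  }
  node_lists <- node_lists[order(vapply(node_lists, paste, "",
                                        collapse = "\r"))]
  .make_pathways(connectome, node_lists, e, roles = roles)
}

#' Flatten pathways to a hop table
#'
#' @param pathways List of `pathway` objects.
#' @return Data frame with one row per hop: `path_id`, `hop`, `pre`, `post`,
#'   `count`, `nt`, `pre_layer`, `post_layer`.
#' @export
pathways_to_hop_table <- function(pathways) {
  if (!length(pathways)) {
    return(data.frame(path_id = integer(), hop = integer(), pre = character(),
                      post = character(), count = integer(), nt = character(),
                      pre_layer = character(), post_layer = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(seq_along(pathways), function(i) {
    p <- pathways[[i]]
    n <- length(p$nodes)
    data.frame(path_id = i, hop = seq_len(n - 1L),
               pre = p$nodes[-n], post = p$nodes[-1L],
               count = p$hop_counts, nt = p$hop_nt,
               pre_layer = p$layers[-n], post_layer = p$layers[-1L],
               stringsAsFactors = FALSE)
  }))
}

#' Export pathways as JSON lines
#'
#' Writes one JSON object per line with fields `nodes`, `hop_counts`,
#' `hop_nt`, `layers`.
#'
#' @param pathways List of `pathway` objects.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
export_pathways_jsonl <- function(pathways, path) {
  lines <- vapply(pathways, function(p) {
    jsonlite::toJSON(list(nodes = p$nodes, hop_counts = p$hop_counts,
                          hop_nt = p$hop_nt, layers = p$layers))
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Group olfactory receptor neurons by behavioural category
#'
#' Groups ORNs by the behavioural significance of the odours their glomerulus
#' type responds to (aversive, food, pheromonal, egg-laying, other) and sums
#' the significant synapses each group sends to the next pathway layer. The
#' category map is user-supplied; a default covering the commonly analysed
#' glomeruli ships with the package (see
#' `system.file("extdata", "orn_behavior_categories.csv", package = "nscnet")`).
#'
#' @param connectome A `connectome`.
#' @param orn_ids Character vector of ORN ids; their glomerulus type is read
#'   from the `cell_type` annotation.
#' @param category_map Data frame with columns `cell_type` and `category`.
#'   Unmapped ORN types fall into `other` with a warning.
#' @param next_ids Optional ids of the next-layer neurons; by default all
#'   significant postsynaptic partners of the ORNs count.
#' @param threshold Optional synapse threshold (default: significance).
#' @return Data frame with columns `category`, `n_orns`, `n_synapses`,
#'   `proportion` (of synapses).
#' @export
group_orns <- function(connectome, orn_ids, category_map, next_ids = NULL,
                       threshold = NULL) {
  stopifnot(inherits(connectome, "connectome"))
  orn_ids <- unique(as.character(orn_ids))
  empty <- data.frame(category = character(), n_orns = integer(),
                      n_synapses = integer(), proportion = numeric())
  if (!length(orn_ids)) return(empty)
  types <- connectome$neurons[orn_ids, "cell_type"]
  cat_of <- stats::setNames(category_map$category, category_map$cell_type)
  category <- unname(cat_of[types])
  unmapped <- is.na(category)
  if (any(unmapped)) {
    warning(sum(unmapped), " ORN(s) with unmapped type assigned to 'other'",
            call. = FALSE)
    category[unmapped] <- "other"
  }
  e <- significant_edges(connectome, threshold)
  e <- e[e$pre %in% orn_ids, , drop = FALSE]
  if (!is.null(next_ids)) e <- e[e$post %in% next_ids, , drop = FALSE]
  syn_per_orn <- stats::setNames(rep(0L, length(orn_ids)), orn_ids)
  if (nrow(e)) {
    agg <- tapply(e$count, e$pre, sum)
    syn_per_orn[names(agg)] <- as.integer(agg)
  }
  n_orns <- tapply(orn_ids, category, length)
  n_syn <- tapply(syn_per_orn, category, sum)
  out <- data.frame(category = names(n_orns),
                    n_orns = as.integer(n_orns),
                    n_synapses = as.integer(n_syn),
                    stringsAsFactors = FALSE)
  total <- sum(out$n_synapses)
  out$proportion <- if (total > 0) out$n_synapses / total else 0
  out <- out[order(-out$n_synapses), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Strong input connections to NSC subtypes
#'
#' Lists every presynaptic connection whose synapse count reaches the strong
#' threshold (default 50, inclusive) onto each NSC, grouped by subtype, and
#' summarises the number of strong connections and their total synapses per
#' subtype.
#'
#' @param connectome A `connectome`.
#' @param nsc_labels Named character vector: subtype name per NSC id.
#' @param strong Optional threshold (default: the connectome's strong
#'   threshold).
#' @return Object of class `strong_connection_report`: list with
#'   `connections` (data frame `subtype`, `pre`, `post`, `count`) and
#'   `summary` (data frame `subtype`, `n_connections`, `total_synapses`).
#' @export
strong_connections <- function(connectome, nsc_labels, strong = NULL) {
  stopifnot(inherits(connectome, "connectome"))
  if (is.null(strong)) strong <- connectome$thresholds$strong
  strong <- .check_count(strong, "strong")
  ids <- names(nsc_labels)
  if (is.null(ids)) stop("`nsc_labels` must be named by NSC id", call. = FALSE)
  e <- significant_edges(connectome, strong)
  e <- e[e$post %in% ids, , drop = FALSE]
  conn <- data.frame(subtype = unname(nsc_labels[e$post]), pre = e$pre,
                     post = e$post, count = e$count, stringsAsFactors = FALSE)
  conn <- conn[order(conn$subtype, -conn$count, conn$pre), , drop = FALSE]
  rownames(conn) <- NULL
  if (nrow(conn)) {
    n_conn <- tapply(conn$count, conn$subtype, length)
    tot <- tapply(conn$count, conn$subtype, sum)
    smry <- data.frame(subtype = names(n_conn),
                       n_connections = as.integer(n_conn),
                       total_synapses = as.integer(tot),
                       stringsAsFactors = FALSE)
    smry <- smry[order(-smry$n_connections), , drop = FALSE]
    rownames(smry) <- NULL
  } else {
    smry <- data.frame(subtype = character(), n_connections = integer(),
                       total_synapses = integer(), stringsAsFactors = FALSE)
  }
  structure(list(connections = conn, summary = smry, strong = strong),
            class = "strong_connection_report")
}

#' @export
print.strong_connection_report <- function(x, ...) {
  cat(sprintf("Strong connections (>= %d synapses): %d\n", x$strong,
              nrow(x$connections)))
  print(x$summary)
  invisible(x)
}

#' Neurons providing input to multiple NSC subtypes
#'
#' Identifies presynaptic neurons that significantly contact NSC of more than
#' one subtype — candidate coordinators of multi-hormone release — and builds
#' the histogram over the number of subtypes contacted.
#'
#' @param connectome A `connectome`.
#' @param nsc_labels Named character vector: subtype name per NSC id (every
#'   NSC must be labelled).
#' @param threshold Optional synapse threshold (default: significance).
#' @return Object of class `shared_input_summary`: list with `map` (data
#'   frame `pre`, `n_subtypes`, `subtypes`), `histogram` (named integer
#'   vector over n_subtypes), `multi_target` (the `map` rows with
#'   `n_subtypes >= 2`), and `n_multi_target`.
#' @export
shared_input_neurons <- function(connectome, nsc_labels, threshold = NULL) {
  stopifnot(inherits(connectome, "connectome"))
  ids <- names(nsc_labels)
  if (is.null(ids) || any(is.na(nsc_labels)) || any(!nzchar(nsc_labels))) {
    stop("every NSC id must carry a subtype label", call. = FALSE)
  }
  e <- significant_edges(connectome, threshold)
  e <- e[e$post %in% ids, , drop = FALSE]
  if (nrow(e)) {
    subtype <- unname(nsc_labels[e$post])
    sets <- tapply(subtype, e$pre, function(s) sort(unique(s)),
                   simplify = FALSE)
    map <- data.frame(pre = names(sets),
                      n_subtypes = vapply(sets, length, integer(1L)),
                      subtypes = vapply(sets, paste, "", collapse = ";"),
                      stringsAsFactors = FALSE)
    map <- map[order(-map$n_subtypes, map$pre), , drop = FALSE]
    rownames(map) <- NULL
  } else {
    map <- data.frame(pre = character(), n_subtypes = integer(),
                      subtypes = character(), stringsAsFactors = FALSE)
  }
  histogram <- table(factor(map$n_subtypes))
  multi <- map[map$n_subtypes >= 2L, , drop = FALSE]
  structure(list(map = map,
                 histogram = stats::setNames(as.integer(histogram),
                                             names(histogram)),
                 multi_target = multi, n_multi_target = nrow(multi)),
            class = "shared_input_summary")
}

#' @export
print.shared_input_summary <- function(x, ...) {
  cat(sprintf("%d neuron(s) provide input to >= 2 NSC subtypes\n",
              x$n_multi_target))
  if (length(x$histogram)) {
    cat("  subtypes contacted:",
        paste(sprintf("%s:%d", names(x$histogram), x$histogram),
              collapse = "  "), "\n")
  }
  invisible(x)
}

#' Synaptic output partners of NSC
#'
#' Outgoing significant connections from NSC, with the partner's super class.
#' Re-runnable at the relaxed threshold (default 2) to expose weaker output
#' that the standard 5-synapse threshold hides; the relaxed row set is always
#' a superset of the standard one.
#'
#' @param connectome A `connectome`.
#' @param nsc_ids Character vector of NSC ids.
#' @param threshold Synapse threshold; defaults to the significance threshold.
#' @return Data frame with columns `nsc_id`, `partner`,
#'   `partner_super_class`, `count`.
#' @export
nsc_output_partners <- function(connectome, nsc_ids, threshold = NULL) {
  stopifnot(inherits(connectome, "connectome"))
  nsc_ids <- as.character(nsc_ids)
  e <- significant_edges(connectome, threshold)
  e <- e[e$pre %in% nsc_ids, , drop = FALSE]
  out <- data.frame(nsc_id = e$pre, partner = e$post,
                    partner_super_class =
                      connectome$neurons[e$post, "super_class"],
                    count = e$count, stringsAsFactors = FALSE)
  out <- out[order(out$nsc_id, -out$count, out$partner), , drop = FALSE]
  rownames(out) <- NULL
  out
}
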
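#' @importFrom stats aggregate
NULL

# Recognised neuron super classes (whole-brain connectome annotation scheme).
SUPER_CLASSES <- c("sensory", "central", "ascending", "descending", "endocrine",
                   "visual_projection", "visual_centrifugal", "optic", "motor",
                   "glia", "unknown")

SENSORY_MODALITIES <- c("gustatory", "mechanosensory", "olfactory",
                        "pharyngeal", "unknown", "na")

#' Load a neuron annotation table
#'
#' Reads a comma-separated annotation table with one row per neuron. Required
#' columns are `id` and `super_class`; optional columns are `cell_type`,
#' `side`, `sensory_modality`, and any number of transmitter-score columns
#' named `nt_<transmitter>` (values in \[0, 1\]). Ids are kept as opaque
#' strings so large numeric root ids never lose precision. Super-class labels
#' are case-folded; unrecognised labels are mapped to `unknown` with a warning
#' (an error in strict mode), preserving the original label in `cell_type`
#' when that field is empty.
#'
#' @param path Path to a CSV file with a header row.
#' @param strict If `TRUE`, unrecognised super classes and modality
#'   inconsistencies are errors rather than repaired with a warning.
#' @return A data frame of neurons (one row per id) with attribute
#'   `nt_columns` naming the transmitter-score columns.
#' @seealso [load_edges()], [build_connectome()]
#' @export
load_annotations <- function(path, strict = FALSE) {
  df <- utils::read.csv(path, colClasses = c(id = "character"),
                        check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("id", "super_class")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("annotation table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$id)) {
    stop("duplicate neuron id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "),
         call. = FALSE)
  }
  for (opt in c("cell_type", "side", "sensory_modality")) {
    if (!opt %in% names(df)) df[[opt]] <- rep(NA_character_, nrow(df))
  }
  df$cell_type <- as.character(df$cell_type)

  raw_sc <- as.character(df$super_class)
  norm_sc <- gsub("[ -]", "_", tolower(trimws(raw_sc)))
  bad <- !(norm_sc %in% SUPER_CLASSES)
  if (any(bad)) {
    labels <- unique(raw_sc[bad])
    if (strict) {
      stop("unrecognised super_class value(s): ",
           paste(labels, collapse = ", "), call. = FALSE)
    }
    warning("unrecognised super_class value(s) mapped to 'unknown': ",
            paste(labels, collapse = ", "), call. = FALSE)
    keep <- bad & (is.na(df$cell_type) | !nzchar(df$cell_type))
    df$cell_type[keep] <- raw_sc[keep]
    norm_sc[bad] <- "unknown"
  }
  df$super_class <- norm_sc

  mod <- tolower(trimws(as.character(df$sensory_modality)))
  mod[is.na(mod) | !nzchar(mod)] <- "na"
  unknown_mod <- !(mod %in% SENSORY_MODALITIES)
  if (any(unknown_mod)) {
    if (strict) stop("unrecognised sensory_modality value(s): ",
                     paste(unique(mod[unknown_mod]), collapse = ", "),
                     call. = FALSE)
    warning("unrecognised sensory_modality value(s) set to 'unknown'",
            call. = FALSE)
    mod[unknown_mod] <- "unknown"
  }
  stray <- mod != "na" & df$super_class != "sensory"
  if (any(stray)) {
    if (strict) stop("sensory_modality set on non-sensory neuron(s): ",
                     paste(df$id[stray], collapse = ", "), call. = FALSE)
    warning("sensory_modality on non-sensory neuron(s) reset to 'na'",
            call. = FALSE)
    mod[stray] <- "na"
  }
  df$sensory_modality <- mod

  nt_cols <- grep("^nt_", names(df), value = TRUE)
  for (col in nt_cols) {
    v <- df[[col]]
    if (!is.numeric(v)) stop("transmitter column `", col, "` is not numeric",
                             call. = FALSE)
    if (any(!is.na(v) & (v < 0 | v > 1))) {
      stop("transmitter score in `", col, "` outside [0, 1]", call. = FALSE)
    }
  }
  attr(df, "nt_columns") <- nt_cols
  df
}

#' Load a synapse edge table
#'
#' Reads a comma-separated table with columns `pre`, `post`, and `count`
#' (positive integer synapse counts). Duplicate `(pre, post)` rows are
#' collapsed by summing their counts; the result is independent of row order.
#'
#' @param path Path to a CSV file with a header row.
#' @return A data frame with columns `pre`, `post`, `count`, one row per
#'   directed neuron pair.
#' @export
load_edges <- function(path) {
  df <- utils::read.csv(path, colClasses = c(pre = "character",
                                             post = "character"),
                        stringsAsFactors = FALSE)
  missing <- setdiff(c("pre", "post", "count"), names(df))
  if (length(missing)) {
    stop("edge table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  collapse_edges(df[c("pre", "post", "count")])
}

#' Collapse duplicate directed edges by summing synapse counts
#'
#' @param edges Data frame with columns `pre`, `post`, `count`.
#' @return A data frame with unique `(pre, post)` rows, counts summed, ordered
#'   by `pre` then `post`.
#' @export
collapse_edges <- function(edges) {
  if (nrow(edges) == 0L) {
    return(data.frame(pre = character(), post = character(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  cnt <- edges$count
  if (!is.numeric(cnt) || any(is.na(cnt)) || any(cnt != round(cnt)) ||
      any(cnt <= 0)) {
    stop("edge counts must be positive integers", call. = FALSE)
  }
  agg <- aggregate(count ~ pre + post, data = edges, FUN = sum)
  agg$pre <- as.character(agg$pre)
  agg$post <- as.character(agg$post)
  agg$count <- as.integer(agg$count)
  agg <- agg[order(agg$pre, agg$post), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Assemble an annotated connectome
#'
#' Combines a neuron table, a collapsed edge table, and a threshold
#' configuration into a validated `connectome` object. Self-loop edges are
#' dropped with a warning. Edge endpoints absent from the neuron table are an
#' error in strict mode; otherwise they are auto-created as `unknown` neurons
#' with a warning.
#'
#' @param neurons Neuron data frame as returned by [load_annotations()] (a
#'   minimal frame with `id` and `super_class` columns also works).
#' @param edges Edge data frame as returned by [load_edges()].
#' @param thresholds A [threshold_config()].
#' @param strict If `TRUE`, dangling edge endpoints are an error.
#' @return An object of class `connectome` with elements `neurons`, `edges`,
#'   and `thresholds`.
#' @examples
#' neurons <- data.frame(id = c("a", "b"), super_class = c("central", "endocrine"))
#' edges <- data.frame(pre = "a", post = "b", count = 7L)
#' build_connectome(neurons, edges)
#' @export
build_connectome <- function(neurons, edges, thresholds = threshold_config(),
                             strict = FALSE) {
  stopifnot(inherits(thresholds, "threshold_config"))
  neurons <- as.data.frame(neurons, stringsAsFactors = FALSE)
  if (!all(c("id", "super_class") %in% names(neurons))) {
    stop("`neurons` needs columns id and super_class", call. = FALSE)
  }
  neurons$id <- as.character(neurons$id)
  if (anyDuplicated(neurons$id)) stop("duplicate neuron ids", call. = FALSE)
  for (opt in c("cell_type", "side", "sensory_modality")) {
    if (!opt %in% names(neurons)) {
      neurons[[opt]] <- rep(NA_character_, nrow(neurons))
    }
  }
  edges <- collapse_edges(as.data.frame(edges, stringsAsFactors = FALSE))

  loops <- edges$pre == edges$post
  if (any(loops)) {
    warning(sum(loops), " self-loop edge(s) dropped", call. = FALSE)
    edges <- edges[!loops, , drop = FALSE]
  }
  endpoints <- unique(c(edges$pre, edges$post))
  dangling <- setdiff(endpoints, neurons$id)
  if (length(dangling)) {
    if (strict) {
      stop("edge endpoint(s) not in neuron table: ",
           paste(utils::head(dangling, 5L), collapse = ", "), call. = FALSE)
    }
    warning(length(dangling),
            " edge endpoint(s) auto-created with super_class 'unknown'",
            call. = FALSE)
    extra <- neurons[0, , drop = FALSE][seq_along(dangling), , drop = FALSE]
    extra$id <- dangling
    extra$super_class <- "unknown"
    extra$sensory_modality <- "na"
    neurons <- rbind(neurons, extra)
  }
  rownames(neurons) <- neurons$id
  rownames(edges) <- NULL
  structure(list(neurons = neurons, edges = edges, thresholds = thresholds),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("Connectome: %d neurons, %d collapsed edges (%d synapses)\n",
              nrow(x$neurons), nrow(x$edges), sum(x$edges$count)))
  sig <- significant_edges(x)
  cat(sprintf("  significant (>= %d synapses): %d edges\n",
              x$thresholds$significance, nrow(sig)))
  tab <- sort(table(x$neurons$super_class), decreasing = TRUE)
  cat("  super classes:",
      paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.connectome <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Significant edges of a connectome
#'
#' Returns the edges whose synapse count passes the threshold, applied
#' inclusively (`count >= threshold`). With `threshold = 1` this is the full
#' edge set; the relaxed output threshold of 2 gives the expanded edge set
#' used when re-examining NSC output.
#'
#' @param connectome A `connectome`.
#' @param threshold Integer >= 1; defaults to the connectome's significance
#'   threshold.
#' @return A data frame of edges (`pre`, `post`, `count`).
#' @export
significant_edges <- function(connectome, threshold = NULL) {
  stopifnot(inherits(connectome, "connectome"))
  if (is.null(threshold)) threshold <- connectome$thresholds$significance
  threshold <- .check_count(threshold, "threshold")
  e <- connectome$edges
  e[e$count >= threshold, , drop = FALSE]
}

#' Summarise connection partners by neuronal super class
#'
#' For a set of target neurons, tallies their significant presynaptic
#' (`direction = "in"`) or postsynaptic (`direction = "out"`) partners by
#' super class: number of distinct partner neurons, total synapses, and the
#' proportion of synapses per class. A partner contacting several targets is
#' counted once in `n_neurons` but all its synapses are summed.
#'
#' @param connectome A `connectome`.
#' @param target_set Character vector of neuron ids (nonempty).
#' @param direction `"in"` for inputs to the targets, `"out"` for outputs.
#' @param threshold Optional synapse threshold (default: significance).
#' @return Data frame with columns `super_class`, `n_neurons`, `n_synapses`,
#'   `proportion`. Empty (zero rows) when no significant partner exists.
#' @export
super_class_summary <- function(connectome, target_set,
                                direction = c("in", "out"), threshold = NULL) {
  stopifnot(inherits(connectome, "connectome"))
  direction <- match.arg(direction)
  target_set <- as.character(target_set)
  if (!length(target_set)) stop("`target_set` must be nonempty", call. = FALSE)
  e <- significant_edges(connectome, threshold)
  if (direction == "in") {
    e <- e[e$post %in% target_set, , drop = FALSE]
    partner <- e$pre
  } else {
    e <- e[e$pre %in% target_set, , drop = FALSE]
    partner <- e$post
  }
  empty <- data.frame(super_class = character(), n_neurons = integer(),
                      n_synapses = integer(), proportion = numeric())
  if (!nrow(e)) return(empty)
  sc <- connectome$neurons[partner, "super_class"]
  n_neurons <- tapply(partner, sc, function(p) length(unique(p)))
  n_synapses <- tapply(e$count, sc, sum)
  out <- data.frame(super_class = names(n_neurons),
                    n_neurons = as.integer(n_neurons),
                    n_synapses = as.integer(n_synapses),
                    stringsAsFactors = FALSE)
  out$proportion <- out$n_synapses / sum(out$n_synapses)
  out <- out[order(-out$n_synapses), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert a thresholded connectome to an igraph graph
#'
#' @param connectome A `connectome`.
#' @param threshold Optional synapse threshold (default: significance).
#' @return A directed `igraph` graph whose edges carry a `count` (and
#'   `weight`) attribute; every neuron is a vertex, with super class and cell
#'   type as vertex attributes.
#' @export
as_igraph <- function(connectome, threshold = NULL) {
  stopifnot(inherits(connectome, "connectome"))
  e <- significant_edges(connectome, threshold)
  g <- igraph::graph_from_data_frame(
    data.frame(from = e$pre, to = e$post, count = e$count, weight = e$count),
    directed = TRUE,
    vertices = data.frame(name = connectome$neurons$id,
                          super_class = connectome$neurons$super_class,
                          cell_type = ifelse(is.na(connectome$neurons$cell_type),
                                             "", connectome$neurons$cell_type))
  )
  g
}

#' Export a thresholded connectome as GraphML
#'
#' @param connectome A `connectome`.
#' @param path Output file path.
#' @param threshold Optional synapse threshold (default: significance).
#' @return The path, invisibly.
#' @export
export_graphml <- function(connectome, path, threshold = NULL) {
  g <- as_igraph(connectome, threshold)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write connectome tables to a directory
#'
#' Writes `annotations.csv` and `edges.csv` in the formats consumed by
#' [load_annotations()] and [load_edges()], so any connectome round-trips
#' through the loaders.
#'
#' @param connectome A `connectome`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the two file paths, invisibly.
#' @export
write_connectome <- function(connectome, dir) {
  stopifnot(inherits(connectome, "connectome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- file.path(dir, "annotations.csv")
  edg <- file.path(dir, "edges.csv")
  utils::write.csv(connectome$neurons, ann, row.names = FALSE, na = "")
  utils::write.csv(connectome$edges, edg, row.names = FALSE)
  invisible(c(annotations = ann, edges = edg))
}

#' Read a connectome from a directory written by [write_connectome()]
#'
#' @param dir Directory containing `annotations.csv` and `edges.csv`.
#' @param thresholds A [threshold_config()].
#' @param strict Passed to [load_annotations()] and [build_connectome()].
#' @return A `connectome`.
#' @export
read_connectome <- function(dir, thresholds = threshold_config(),
                            strict = FALSE) {
  neurons <- load_annotations(file.path(dir, "annotations.csv"), strict = strict)
  edges <- load_edges(file.path(dir, "edges.csv"))
  build_connectome(neurons, edges, thresholds, strict = strict)
}
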
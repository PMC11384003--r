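#' Score recovery of planted structure
#'
#' Compares a prediction against the generator's ground truth:
#' `"ari"` computes the Adjusted Rand Index between two partitions (named
#' vectors over the same ids), `"path_f1"` the precision/recall/F1 between
#' two sets of pathways (matched on their full node sequence), and
#' `"edge_precision_recall"` the precision/recall/F1 between predicted and
#' planted paracrine edges matched on (source, target, ligand).
#'
#' @param predicted The prediction: a named label vector (`ari`), a list of
#'   `pathway` objects or node-id vectors (`path_f1`), or a data frame with
#'   columns `source`, `target`, `ligand` (`edge_precision_recall`).
#' @param ground_truth The matching ground-truth object.
#' @param metric One of `"ari"`, `"path_f1"`, `"edge_precision_recall"`.
#' @return For `"ari"` a single number; otherwise a list with `precision`,
#'   `recall`, `f1`.
#' @export
evaluate_recovery <- function(predicted, ground_truth,
                              metric = c("ari", "path_f1",
                                         "edge_precision_recall")) {
  metric <- match.arg(metric)
  if (metric == "ari") {
    if (is.null(names(predicted)) || is.null(names(ground_truth))) {
      stop("partitions must be named by id", call. = FALSE)
    }
    if (!setequal(names(predicted), names(ground_truth))) {
      stop("partitions are over different id universes", call. = FALSE)
    }
    ids <- names(ground_truth)
    return(mclust::adjustedRandIndex(predicted[ids], ground_truth[ids]))
  }
  key <- function(x) {
    if (metric == "path_f1") {
      vapply(x, function(p) {
        nodes <- if (inherits(p, "pathway")) p$nodes else p
        paste(nodes, collapse = "\r")
      }, character(1L))
    } else {
      paste(x$source, x$target, x$ligand, sep = "\r")
    }
  }
  pred <- unique(key(predicted))
  truth <- unique(key(ground_truth))
  tp <- length(intersect(pred, truth))
  precision <- if (length(pred)) tp / length(pred) else 1
  recall <- if (length(truth)) tp / length(truth) else 1
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(precision = precision, recall = recall, f1 = f1)
}
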
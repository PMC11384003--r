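#' Synapse-count and transmitter-score thresholds
#'
#' Bundles the thresholds that define "connections" throughout the package:
#' the significance threshold for a synaptic connection (default 5 synapses),
#' a relaxed threshold used when re-examining NSC output (default 2), the
#' strong-connection threshold (default 50), the transmitter-prediction score
#' cutoff (default 0.62, applied strictly greater-than), and the maximum hop
#' count for pathway tracing (default 3). All synapse thresholds are applied
#' inclusively (`count >= threshold`).
#'
#' @param significance Integer >= 1. Minimum synapse count for a connection to
#'   be considered significant.
#' @param output_relaxed Integer >= 1, at most `significance`. Relaxed
#'   threshold for output analyses.
#' @param strong Integer >= `significance`. Threshold for "strong" inputs.
#' @param nt_cutoff Probability in (0, 1). A transmitter label is assigned only
#'   when the winning prediction score is strictly greater than this.
#' @param max_hops Integer >= 1. Default pathway-length cap in hops (edges).
#' @return An object of class `threshold_config`.
#' @examples
#' threshold_config()
#' threshold_config(significance = 2)
#' @export
threshold_config <- function(significance = 5L, output_relaxed = 2L,
                             strong = 50L, nt_cutoff = 0.62, max_hops = 3L) {
  significance <- .check_count(significance, "significance")
  output_relaxed <- .check_count(output_relaxed, "output_relaxed")
  strong <- .check_count(strong, "strong")
  max_hops <- .check_count(max_hops, "max_hops")
  if (!is.numeric(nt_cutoff) || length(nt_cutoff) != 1L ||
      nt_cutoff <= 0 || nt_cutoff >= 1) {
    stop("`nt_cutoff` must be a single probability in (0, 1)", call. = FALSE)
  }
  if (!(output_relaxed <= significance && significance <= strong)) {
    stop("thresholds must satisfy output_relaxed <= significance <= strong",
         call. = FALSE)
  }
  structure(
    list(significance = significance, output_relaxed = output_relaxed,
         strong = strong, nt_cutoff = nt_cutoff, max_hops = max_hops),
    class = "threshold_config"
  )
}

.check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= 1", name), call. = FALSE)
  }
  as.integer(x)
}

#' @export
print.threshold_config <- function(x, ...) {
  cat("Threshold configuration\n")
  cat(sprintf("  significant connection : >= %d synapses\n", x$significance))
  cat(sprintf("  relaxed (output)       : >= %d synapses\n", x$output_relaxed))
  cat(sprintf("  strong connection      : >= %d synapses\n", x$strong))
  cat(sprintf("  transmitter cutoff     : > %.2f\n", x$nt_cutoff))
  cat(sprintf("  max pathway hops       : %d\n", x$max_hops))
  invisible(x)
}
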
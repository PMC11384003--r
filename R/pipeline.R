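#' Run the full analysis pipeline and write a manifest
#'
#' Executes the stages in dependency order — load (or simulate), input-profile
#' clustering, sensory pathway tracing, shared-input / strong-connection /
#' output reports, and (when expression data are supplied) paracrine network
#' inference — writing every tabular result as CSV into `outdir` together
#' with a JSON run manifest recording package version, thresholds, seed, and
#' the MD5 checksum of every output file. Reruns with the same configuration
#' and seed produce identical checksums.
#'
#' @param config A list with elements:
#'   \describe{
#'     \item{input}{Either `list(dir = <connectome directory>)` for data
#'       written by [write_connectome()], or `list(simulate = TRUE, sim =
#'       <connectome_sim_config>)` to generate a synthetic connectome.}
#'     \item{nsc_ids}{NSC ids (defaults to all `endocrine` neurons).}
#'     \item{nsc_labels}{Named subtype labels (defaults, for simulated input,
#'       to the planted labels; otherwise each NSC is its own subtype).}
#'     \item{thresholds}{A [threshold_config()] (default settings if absent).}
#'     \item{k}{Number of clusters for [cluster_nsc()] (default: number of
#'       distinct NSC labels).}
#'     \item{expression}{Optional `list(sim = <expression_sim_config>)` or
#'       `list(em = <expression_matrix>, pairs = <catalog>)`.}
#'     \item{seed}{Integer seed, forwarded to the simulators.}
#'   }
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  thresholds <- config$thresholds
  if (is.null(thresholds)) thresholds <- threshold_config()
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  truth <- NULL
  conn <- stage("load", {
    if (isTRUE(config$input[["simulate"]])) {
      sim_cfg <- config$input[["sim"]]  # exact: `$sim` would match simulate
      if (is.null(sim_cfg)) sim_cfg <- connectome_sim_config(seed = seed)
      sim <- generate_connectome(sim_cfg)
      truth <- sim$truth
      sim$connectome
    } else if (!is.null(config$input[["dir"]])) {
      read_connectome(config$input[["dir"]], thresholds)
    } else {
      stop("config$input must name a directory or request simulation")
    }
  })
  conn$thresholds <- thresholds

  nsc_ids <- config$nsc_ids
  if (is.null(nsc_ids)) {
    nsc_ids <- conn$neurons$id[conn$neurons$super_class == "endocrine"]
  }
  nsc_labels <- config$nsc_labels
  if (is.null(nsc_labels)) {
    nsc_labels <- if (!is.null(truth)) truth$nsc_labels else
      stats::setNames(nsc_ids, nsc_ids)
  }

  cl <- stage("cluster", {
    profile <- build_input_profile(conn, nsc_ids)
    sim <- cosine_similarity_matrix(profile)
    k <- config$k
    if (is.null(k)) k <- length(unique(nsc_labels))
    k <- min(k, nrow(sim))
    clustering <- cluster_nsc(sim, k = k)
    utils::write.csv(data.frame(id = names(clustering$labels),
                                cluster = clustering$labels),
                     file.path(outdir, "clusters.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(sim),
                     file.path(outdir, "similarity.csv"))
    if (!is.null(clustering$hclust)) {
      export_dendrogram_newick(clustering,
                               file.path(outdir, "dendrogram.nwk"))
    }
    list(profile = profile, similarity = sim, clustering = clustering)
  })

  trace <- stage("trace", {
    sensory <- conn$neurons$id[conn$neurons$super_class == "sensory"]
    orn <- sensory[conn$neurons[sensory, "sensory_modality"] == "olfactory"]
    paths <- khop_shortest_pathways(conn, orn, nsc_ids,
                                    max_hops = thresholds$max_hops,
                                    roles = truth$roles)
    utils::write.csv(pathways_to_hop_table(paths),
                     file.path(outdir, "pathways.csv"), row.names = FALSE)
    direct <- direct_sensory_inputs(conn, nsc_ids)
    utils::write.csv(direct, file.path(outdir, "direct_sensory.csv"),
                     row.names = FALSE)
    dis <- disynaptic_sensory_pathways(conn, nsc_ids)
    utils::write.csv(pathways_to_hop_table(dis$pathways),
                     file.path(outdir, "disynaptic.csv"), row.names = FALSE)
    list(pathways = paths, direct = direct, disynaptic = dis)
  })

  reports <- stage("reports", {
    shared <- shared_input_neurons(conn, nsc_labels)
    utils::write.csv(shared$map, file.path(outdir, "shared_inputs.csv"),
                     row.names = FALSE)
    strong <- strong_connections(conn, nsc_labels)
    utils::write.csv(strong$connections, file.path(outdir, "strong.csv"),
                     row.names = FALSE)
    outputs <- nsc_output_partners(conn, nsc_ids)
    utils::write.csv(outputs, file.path(outdir, "outputs.csv"),
                     row.names = FALSE)
    outputs_relaxed <- nsc_output_partners(conn, nsc_ids,
                                           thresholds$output_relaxed)
    utils::write.csv(outputs_relaxed,
                     file.path(outdir, "outputs_relaxed.csv"),
                     row.names = FALSE)
    scs <- super_class_summary(conn, nsc_ids, "in")
    utils::write.csv(scs, file.path(outdir, "input_super_classes.csv"),
                     row.names = FALSE)
    list(shared = shared, strong = strong, outputs = outputs,
         outputs_relaxed = outputs_relaxed, super_classes = scs)
  })

  paracrine <- NULL
  if (!is.null(config$expression)) {
    paracrine <- stage("paracrine", {
      ex <- config$expression
      if (!is.null(ex$sim)) {
        gen <- generate_expression(ex$sim)
        em <- gen$em
        pairs <- gen$pairs
      } else {
        em <- ex$em
        pairs <- ex$pairs
      }
      genes <- unique(stats::na.omit(c(pairs$ligand, pairs$receptor1,
                                       pairs$receptor2)))
      scores <- expression_score_table(em, genes)
      net <- build_paracrine_network(scores, pairs)
      utils::write.csv(scores, file.path(outdir, "expression_scores.csv"),
                       row.names = FALSE)
      utils::write.csv(as.data.frame(net),
                       file.path(outdir, "paracrine_edges.csv"),
                       row.names = FALSE)
      list(scores = scores, network = net)
    })
  }

  files <- sort(list.files(outdir, pattern = "\\.(csv|nwk)$",
                           full.names = TRUE))
  manifest <- list(
    package = "nscnet",
    version = as.character(utils::packageVersion("nscnet")),
    seed = seed,
    thresholds = unclass(thresholds),
    n_neurons = nrow(conn$neurons),
    n_edges = nrow(conn$edges),
    n_nsc = length(nsc_ids),
    outputs = as.list(stats::setNames(unname(tools::md5sum(files)),
                                      basename(files)))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(connectome = conn, truth = truth, cluster = cl,
                 trace = trace, reports = reports, paracrine = paracrine,
                 manifest = manifest))
}
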
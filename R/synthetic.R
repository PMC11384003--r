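# Default glomerulus names used for simulated ORN cell types; the shipped
# behavioural category fixture covers them.
.SIM_GLOMERULI <- c("V", "DL4", "DL5", "DP1l", "VA6", "DL2d", "VM7d",
                    "VA1d", "VA1v", "DA1", "VL2a", "DM1")

#' Configuration for the synthetic connectome generator
#'
#' Describes a block-structured neuroendocrine connectome: planted NSC
#' subtypes that draw inputs from subtype-specific pools of central neurons
#' (high within-subtype cosine similarity), layered olfactory chains
#' ORN -> projection neuron -> interneuron -> NSC, direct sensory inputs, and
#' strong NSC output onto descending neurons. Synapse counts are
#' over-dispersed (negative binomial), shifted so planted connections pass
#' the significance threshold. Cross-block noise wires foreign pool neurons
#' onto an NSC with probability `cross_block_noise_rate * p_within` and a
#' weaker count distribution.
#'
#' @param n_subtypes Number of planted NSC subtypes.
#' @param cells_per_subtype NSC per subtype.
#' @param input_pool_size Presynaptic pool neurons per subtype.
#' @param p_within Probability that a pool neuron contacts each NSC of its
#'   own subtype.
#' @param cross_block_noise_rate In \[0, 1\]; 0 gives perfectly separable
#'   blocks.
#' @param n_orn,n_pn,n_interneurons,n_descending Layer sizes.
#' @param n_chains Planted 3-hop olfactory chains (disjoint ORN/PN/IN).
#' @param n_direct_sensory Planted monosynaptic sensory -> NSC edges.
#' @param n_strong_outputs Planted strong NSC -> descending edges.
#' @param count_mean,count_dispersion Negative-binomial mean and size for the
#'   planted within-block synapse counts (added on top of the significance
#'   threshold).
#' @param noise_count_mean Mean of the (weaker) cross-block noise counts.
#' @param significance Significance threshold the planted edges must pass.
#' @param seed Integer seed; the generator is deterministic given the config.
#' @return Object of class `connectome_sim_config`.
#' @export
connectome_sim_config <- function(n_subtypes = 4L, cells_per_subtype = 6L,
                                  input_pool_size = 12L, p_within = 0.9,
                                  cross_block_noise_rate = 0,
                                  n_orn = 30L, n_pn = 8L,
                                  n_interneurons = 10L, n_descending = 4L,
                                  n_chains = 6L, n_direct_sensory = 3L,
                                  n_strong_outputs = 2L,
                                  count_mean = 10, count_dispersion = 4,
                                  noise_count_mean = 5,
                                  significance = 5L, seed = 1L) {
  stopifnot(cross_block_noise_rate >= 0, cross_block_noise_rate <= 1,
            p_within > 0, p_within <= 1)
  if (n_chains > min(n_orn, n_pn, n_interneurons)) {
    stop("n_chains exceeds a layer size; chains must use disjoint neurons",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "connectome_sim_config")
}

# shifted negative binomial: guaranteed >= floor, over-dispersed above it
.nb_counts <- function(n, floor, mu, size) {
  floor + stats::rnbinom(n, mu = mu, size = size)
}

#' Generate a synthetic connectome with ground truth
#'
#' Builds a connectome realising the block/chain structure described by
#' [connectome_sim_config()], plus the ground truth needed to score recovery:
#' the planted subtype partition, the planted 3-hop pathways, the planted
#' direct sensory edges and strong outputs, and the config and seed. The
#' output is deterministic given the seed and round-trips through
#' [write_connectome()] / [read_connectome()].
#'
#' @param config A `connectome_sim_config`.
#' @return List with `connectome` and `truth` (list with `partition`,
#'   `nsc_labels`, `chains`, `direct_sensory`, `strong_outputs`, `roles`,
#'   `config`).
#' @export
generate_connectome <- function(config = connectome_sim_config()) {
  stopifnot(inherits(config, "connectome_sim_config"))
  set.seed(config$seed)
  sig <- config$significance
  n_sub <- config$n_subtypes

  nsc <- data.frame(
    id = paste0("nsc_s", rep(seq_len(n_sub), each = config$cells_per_subtype),
                "_", seq_len(config$cells_per_subtype)),
    super_class = "endocrine", stringsAsFactors = FALSE)
  partition <- stats::setNames(rep(seq_len(n_sub),
                                   each = config$cells_per_subtype), nsc$id)
  pools <- lapply(seq_len(n_sub), function(s) {
    paste0("in_s", s, "_", seq_len(config$input_pool_size))
  })
  orn <- paste0("orn_", seq_len(config$n_orn))
  pn <- paste0("pn_", seq_len(config$n_pn))
  cin <- paste0("cin_", seq_len(config$n_interneurons))
  dn <- paste0("dn_", seq_len(config$n_descending))
  grn <- if (config$n_direct_sensory > 0) {
    paste0("grn_", seq_len(config$n_direct_sensory))
  } else character()

  neurons <- rbind(
    nsc,
    data.frame(id = unlist(pools), super_class = "central",
               stringsAsFactors = FALSE),
    data.frame(id = orn, super_class = "sensory", stringsAsFactors = FALSE),
    data.frame(id = pn, super_class = "central", stringsAsFactors = FALSE),
    data.frame(id = cin, super_class = "central", stringsAsFactors = FALSE),
    data.frame(id = dn, super_class = "descending", stringsAsFactors = FALSE),
    data.frame(id = grn, super_class = "sensory", stringsAsFactors = FALSE)
  )
  neurons$cell_type <- NA_character_
  neurons$cell_type[neurons$id %in% orn] <-
    sample(.SIM_GLOMERULI, config$n_orn, replace = TRUE)
  neurons$side <- sample(c("left", "right"), nrow(neurons), replace = TRUE)
  neurons$sensory_modality <- "na"
  neurons$sensory_modality[neurons$id %in% orn] <- "olfactory"
  neurons$sensory_modality[neurons$id %in% grn] <- "gustatory"
  # transmitter scores: interneuron layers get a confident fast transmitter
  nt <- matrix(0, nrow(neurons), 3,
               dimnames = list(neurons$id,
                               c("nt_acetylcholine", "nt_glutamate",
                                 "nt_gaba")))
  relay <- neurons$id %in% c(orn, pn, cin, unlist(pools), grn)
  pick <- sample.int(3L, sum(relay), replace = TRUE,
                     prob = c(0.6, 0.25, 0.15))
  nt[cbind(which(relay), pick)] <- stats::runif(sum(relay), 0.70, 0.95)
  neurons <- cbind(neurons, as.data.frame(nt))

  edges <- list()
  add_edge <- function(pre, post, count) {
    edges[[length(edges) + 1L]] <<- data.frame(pre = pre, post = post,
                                               count = count,
                                               stringsAsFactors = FALSE)
  }
  # block-structured NSC inputs
  for (s in seq_len(n_sub)) {
    members <- nsc$id[partition == s]
    for (p in pools[[s]]) for (m in members) {
      if (stats::runif(1) < config$p_within) {
        add_edge(p, m, .nb_counts(1, sig, config$count_mean,
                                  config$count_dispersion))
      }
    }
    if (config$cross_block_noise_rate > 0) {
      foreign <- unlist(pools[-s])
      for (p in foreign) for (m in members) {
        if (stats::runif(1) <
            config$cross_block_noise_rate * config$p_within) {
          add_edge(p, m, .nb_counts(1, sig, config$noise_count_mean,
                                    config$count_dispersion))
        }
      }
    }
  }
  # planted 3-hop olfactory chains with disjoint relays
  chain_orn <- sample(orn, config$n_chains)
  chain_pn <- sample(pn, config$n_chains)
  chain_cin <- sample(cin, config$n_chains)
  chain_nsc <- sample(nsc$id, config$n_chains, replace = TRUE)
  chains <- vector("list", config$n_chains)
  for (i in seq_len(config$n_chains)) {
    nodes <- c(chain_orn[i], chain_pn[i], chain_cin[i], chain_nsc[i])
    counts <- .nb_counts(3, sig, config$count_mean, config$count_dispersion)
    add_edge(nodes[1], nodes[2], counts[1])
    add_edge(nodes[2], nodes[3], counts[2])
    add_edge(nodes[3], nodes[4], counts[3])
    chains[[i]] <- nodes
  }
  # direct sensory inputs
  direct <- if (length(grn)) {
    tgt <- sample(nsc$id, length(grn), replace = TRUE)
    for (i in seq_along(grn)) {
      add_edge(grn[i], tgt[i], .nb_counts(1, sig, config$count_mean,
                                          config$count_dispersion))
    }
    data.frame(pre = grn, post = tgt, stringsAsFactors = FALSE)
  } else data.frame(pre = character(), post = character())
  # strong NSC output onto descending neurons
  strong_out <- if (config$n_strong_outputs > 0) {
    src <- sample(nsc$id, config$n_strong_outputs)
    tgt <- sample(dn, config$n_strong_outputs, replace = TRUE)
    for (i in seq_len(config$n_strong_outputs)) {
      add_edge(src[i], tgt[i], .nb_counts(1, 50L, 15, 4))
    }
    data.frame(pre = src, post = tgt, stringsAsFactors = FALSE)
  } else data.frame(pre = character(), post = character())

  edges <- do.call(rbind, edges)
  roles <- c(stats::setNames(rep("ORN", length(orn)), orn),
             stats::setNames(rep("ALPN", length(pn)), pn),
             stats::setNames(rep("IN", length(cin)), cin),
             stats::setNames(rep("NSC", nrow(nsc)), nsc$id))
  conn <- build_connectome(neurons, edges,
                           threshold_config(significance = sig))
  list(connectome = conn,
       truth = list(partition = partition,
                    nsc_labels = stats::setNames(
                      paste0("subtype", partition), names(partition)),
                    chains = chains, direct_sensory = direct,
                    strong_outputs = strong_out, roles = roles,
                    seed = config$seed, config = config))
}

#' Configuration for the synthetic expression generator
#'
#' Describes a clustered single-cell count matrix with planted
#' ligand-receptor structure: each planted pair has its ligand expressed in
#' one source cluster and its receptor in one target cluster, both in a
#' configured fraction of cells (`planted_pct`) at high magnitude; all other
#' genes form a sparse over-dispersed background. Decoy ligand-receptor
#' pairs drawn from background genes probe the precision of edge detection.
#'
#' @param n_clusters Number of cell clusters.
#' @param cells_per_cluster Cells per cluster.
#' @param n_background_genes Background genes beside the planted ones.
#' @param n_pairs Planted ligand-receptor pairs (at most `n_clusters`).
#' @param n_decoy_pairs Decoy pairs taken from background genes.
#' @param planted_pct Fraction of cluster cells expressing a planted gene.
#' @param ligand_mu,receptor_mu Negative-binomial means of planted counts.
#' @param background_pct Fraction of cells expressing each background gene.
#' @param background_mu Negative-binomial mean of background counts.
#' @param dispersion Negative-binomial size parameter.
#' @param seed Integer seed.
#' @return Object of class `expression_sim_config`.
#' @export
expression_sim_config <- function(n_clusters = 6L, cells_per_cluster = 150L,
                                  n_background_genes = 300L, n_pairs = 5L,
                                  n_decoy_pairs = 3L, planted_pct = 0.8,
                                  ligand_mu = 25, receptor_mu = 15,
                                  background_pct = 0.02, background_mu = 2,
                                  dispersion = 2, seed = 1L) {
  stopifnot(planted_pct >= 0, planted_pct <= 1,
            background_pct >= 0, background_pct <= 1,
            n_pairs <= n_clusters,
            2L * n_decoy_pairs <= n_background_genes)
  structure(as.list(environment()), class = "expression_sim_config")
}

#' Generate a synthetic expression matrix with planted paracrine structure
#'
#' @param config An `expression_sim_config`.
#' @return List with `em` (an [expression_matrix()]), `pairs` (catalog
#'   including decoys), and `truth` (list with `edges` — the planted
#'   (source, target, ligand) triples —, `planted`, `seed`, `config`).
#' @export
generate_expression <- function(config = expression_sim_config()) {
  stopifnot(inherits(config, "expression_sim_config"))
  set.seed(config$seed)
  clusters <- paste0("cluster", seq_len(config$n_clusters))
  cells <- paste0("cell_", seq_len(config$n_clusters * config$cells_per_cluster))
  cluster_of <- rep(clusters, each = config$cells_per_cluster)

  ligands <- paste0("Lig", seq_len(config$n_pairs))
  receptors <- paste0("LigR", seq_len(config$n_pairs))
  background <- paste0("bg", seq_len(config$n_background_genes))
  genes <- c(ligands, receptors, background)
  m <- matrix(0, nrow = length(genes), ncol = length(cells),
              dimnames = list(genes, cells))

  # sparse over-dispersed background everywhere
  n_entries <- length(background) * length(cells)
  on <- stats::runif(n_entries) < config$background_pct
  vals <- 1L + stats::rnbinom(sum(on), mu = config$background_mu,
                              size = config$dispersion)
  m[background, ][on] <- vals

  plant <- function(gene, cluster, mu) {
    idx <- which(cluster_of == cluster)
    on <- stats::runif(length(idx)) < config$planted_pct
    m[gene, idx[on]] <<- 1L + stats::rnbinom(sum(on), mu = mu,
                                             size = config$dispersion)
  }
  source_cl <- clusters[seq_len(config$n_pairs)]
  target_cl <- clusters[1L + (seq_len(config$n_pairs) %% config$n_clusters)]
  for (i in seq_len(config$n_pairs)) {
    plant(ligands[i], source_cl[i], config$ligand_mu)
    plant(receptors[i], target_cl[i], config$receptor_mu)
  }
  decoys <- if (config$n_decoy_pairs > 0) {
    data.frame(ligand = background[seq_len(config$n_decoy_pairs)],
               receptor1 = background[config$n_decoy_pairs +
                                        seq_len(config$n_decoy_pairs)],
               receptor2 = NA_character_, stringsAsFactors = FALSE)
  } else NULL
  pairs <- rbind(data.frame(ligand = ligands, receptor1 = receptors,
                            receptor2 = NA_character_,
                            stringsAsFactors = FALSE), decoys)
  em <- expression_matrix(m, stats::setNames(cluster_of, cells))
  truth_edges <- data.frame(source = source_cl, target = target_cl,
                            ligand = ligands, stringsAsFactors = FALSE)
  list(em = em, pairs = pairs,
       truth = list(edges = truth_edges,
                    planted = data.frame(gene = c(ligands, receptors),
                                         cluster = c(source_cl, target_cl),
                                         stringsAsFactors = FALSE),
                    seed = config$seed, config = config))
}
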
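test_that("transmitter labels follow the strict arg-max cutoff rule", {
  expect_identical(nt_annotate(c(acetylcholine = 0.63, gaba = 0.2)),
                   "acetylcholine")
  expect_identical(nt_annotate(c(acetylcholine = 0.62)), "unknown")
  expect_identical(nt_annotate(numeric(0)), "unknown")
  expect_identical(nt_annotate(NULL), "unknown")
  # exact tie for the maximum -> unknown
  expect_identical(nt_annotate(c(acetylcholine = 0.7, gaba = 0.7)),
                   "unknown")
  # non-fast transmitters are ignored even when dominant
  expect_identical(nt_annotate(c(dopamine = 0.99, gaba = 0.65)), "gaba")
  # nt_ prefixes from annotation columns are accepted
  expect_identical(nt_annotate(c(nt_glutamate = 0.8)), "glutamate")
  expect_identical(nt_annotate(c(nt_glutamate = 0.8), cutoff = 0.9),
                   "unknown")
})

test_that("direct sensory inputs list significant sensory edges only", {
  conn <- tiny_connectome(
    edge_df(list("g1", "n1", 8), list("c1", "n1", 20), list("g2", "n1", 3)),
    super = c(g1 = "sensory", g2 = "sensory", c1 = "central",
              n1 = "endocrine"))
  conn$neurons["g1", "sensory_modality"] <- "gustatory"
  tab <- direct_sensory_inputs(conn, "n1")
  expect_equal(nrow(tab), 1L)
  expect_identical(tab$sensory_id, "g1")
  expect_identical(tab$modality, "gustatory")
  expect_equal(tab$count, 8L)

  no_sens <- tiny_connectome(edge_df(list("c1", "n1", 9)),
                             super = c(n1 = "endocrine"))
  expect_equal(nrow(direct_sensory_inputs(no_sens, "n1")), 0L)
})

test_that("disynaptic pathways require both hops to pass the threshold", {
  mk <- function(c1, c2) tiny_connectome(
    edge_df(list("s", "i", c1), list("i", "n", c2)),
    super = c(s = "sensory", i = "central", n = "endocrine"))
  good <- disynaptic_sensory_pathways(mk(6, 7), "n")
  expect_length(good$pathways, 1L)
  expect_identical(good$pathways[[1]]$nodes, c("s", "i", "n"))
  expect_equal(good$pathways[[1]]$hop_counts, c(6L, 7L))
  expect_identical(good$sensory_interneurons, "i")

  # second hop sub-threshold: no pathway, no interneuron presynaptic to NSC
  weak2 <- disynaptic_sensory_pathways(mk(6, 4), "n")
  expect_length(weak2$pathways, 0L)
  # first hop sub-threshold: i still contacts the NSC but is non-sensory
  weak1 <- disynaptic_sensory_pathways(mk(4, 7), "n")
  expect_length(weak1$pathways, 0L)
  expect_identical(weak1$non_sensory_interneurons, "i")

  none <- tiny_connectome(edge_df(list("s", "n", 9)),
                          super = c(s = "sensory", n = "endocrine"))
  expect_length(disynaptic_sensory_pathways(none, "n")$pathways, 0L)
})

test_that("k-hop tracing returns all and only the shortest pathways", {
  chain <- tiny_connectome(
    edge_df(list("orn", "pn", 6), list("pn", "in1", 7), list("in1", "n", 9)),
    super = c(orn = "sensory", n = "endocrine"))
  paths <- khop_shortest_pathways(chain, "orn", "n", max_hops = 3)
  expect_length(paths, 1L)
  expect_identical(paths[[1]]$nodes, c("orn", "pn", "in1", "n"))
  expect_equal(paths[[1]]$hop_counts, c(6L, 7L, 9L))
  # a 3-hop path visits four neurons
  expect_length(paths[[1]]$layers, 4L)

  # shortest wins: adding a direct edge hides the long route
  direct <- tiny_connectome(
    edge_df(list("orn", "pn", 6), list("pn", "in1", 7), list("in1", "n", 9),
            list("orn", "n", 5)),
    super = c(orn = "sensory", n = "endocrine"))
  short <- khop_shortest_pathways(direct, "orn", "n", max_hops = 3)
  expect_length(short, 1L)
  expect_identical(short[[1]]$nodes, c("orn", "n"))

  # raising max_hops does not change the result once a path exists
  expect_identical(path_keys(khop_shortest_pathways(chain, "orn", "n", 3)),
                   path_keys(khop_shortest_pathways(chain, "orn", "n", 5)))
  # beyond-cap paths are dropped
  expect_length(khop_shortest_pathways(chain, "orn", "n", max_hops = 2), 0L)
  expect_error(khop_shortest_pathways(chain, "orn", "n", max_hops = 7),
               "guard")
  expect_length(khop_shortest_pathways(chain, "orn", "n", max_hops = 7,
                                       allow_long = TRUE), 1L)
})

test_that("k-hop tracing agrees with brute-force enumeration on random graphs", {
  for (seed in 1:25) {
    conn <- random_connectome(seed)
    ids <- conn$neurons$id
    set.seed(seed + 1000)
    sources <- sample(ids, 3)
    targets <- sample(ids, 3)
    threshold <- sample(c(1, 3, 5), 1)
    max_hops <- sample(2:4, 1)
    got <- path_keys(khop_shortest_pathways(conn, sources, targets,
                                            max_hops = max_hops,
                                            threshold = threshold))
    want <- bf_shortest_path_set(conn$edges, sources, targets, max_hops,
                                 threshold)
    expect_identical(got, want)
  }
})

test_that("hop tables and JSON-lines exports carry per-hop annotation", {
  sim <- generate_connectome(connectome_sim_config(seed = 3))
  conn <- sim$connectome
  paths <- khop_shortest_pathways(conn, paste0("orn_", 1:30),
                                  names(sim$truth$partition),
                                  roles = sim$truth$roles)
  tab <- pathways_to_hop_table(paths)
  expect_equal(nrow(tab), 3L * length(paths))
  expect_true(all(tab$count >= conn$thresholds$significance))
  expect_true(all(tab$nt %in% c("acetylcholine", "glutamate", "gaba",
                                "unknown")))
  expect_identical(unique(tab$pre_layer[tab$hop == 1]), "ORN")
  expect_identical(unique(tab$post_layer[tab$hop == 3]), "NSC")

  jl <- withr::local_tempfile(fileext = ".jsonl")
  export_pathways_jsonl(paths, jl)
  lines <- readLines(jl)
  expect_length(lines, length(paths))
  first <- jsonlite::fromJSON(lines[1])
  expect_identical(first$nodes, paths[[1]]$nodes)
})

test_that("ORN grouping aggregates counts and synapses per category", {
  conn <- tiny_connectome(
    edge_df(list("o1", "pn", 30), list("o2", "pn", 10)),
    super = c(o1 = "sensory", o2 = "sensory"))
  conn$neurons["o1", "cell_type"] <- "V"
  conn$neurons["o2", "cell_type"] <- "DP1l"
  map <- data.frame(cell_type = c("V", "DP1l"),
                    category = c("aversive", "food"))
  tab <- group_orns(conn, c("o1", "o2"), map)
  expect_equal(tab$proportion[tab$category == "aversive"], 0.75)
  expect_equal(tab$proportion[tab$category == "food"], 0.25)

  all_food <- group_orns(conn, c("o1", "o2"),
                         data.frame(cell_type = c("V", "DP1l"),
                                    category = "food"))
  expect_equal(nrow(all_food), 1L)
  expect_equal(all_food$n_orns, 2L)

  expect_warning(
    other <- group_orns(conn, c("o1", "o2"),
                        data.frame(cell_type = "V", category = "aversive")),
    "unmapped")
  expect_true("other" %in% other$category)
  expect_equal(nrow(group_orns(conn, character(0), map)), 0L)

  shipped <- utils::read.csv(system.file("extdata",
                                         "orn_behavior_categories.csv",
                                         package = "nscnet"))
  expect_true(all(c("V", "DL4", "DL5", "DP1l", "VA6") %in%
                    shipped$cell_type))
})

test_that("strong connections use the inclusive 50-synapse rule", {
  conn <- tiny_connectome(
    edge_df(list("a", "n1", 49), list("b", "n1", 50), list("c", "n2", 80)),
    super = c(n1 = "endocrine", n2 = "endocrine"))
  labels <- c(n1 = "m-NSC^DH44", n2 = "l-NSC^DH31")
  rep <- strong_connections(conn, labels)
  expect_equal(nrow(rep$connections), 2L)
  expect_false("a" %in% rep$connections$pre)
  expect_equal(rep$summary$total_synapses[rep$summary$subtype ==
                                            "l-NSC^DH31"], 80L)
  none <- strong_connections(tiny_connectome(edge_df(list("a", "n1", 10)),
                                             super = c(n1 = "endocrine")),
                             c(n1 = "x"))
  expect_equal(nrow(none$connections), 0L)
})

test_that("shared-input summaries count subtypes per presynaptic neuron", {
  conn <- tiny_connectome(
    edge_df(list("hub", "n1", 6), list("hub", "n2", 7), list("hub", "n3", 9),
            list("solo", "n1", 8), list("pair", "n2", 6),
            list("pair", "n4", 6), list("uni", "n2", 6), list("uni", "n4", 6)),
    super = c(n1 = "endocrine", n2 = "endocrine", n3 = "endocrine",
              n4 = "endocrine"))
  labels <- c(n1 = "m-NSC^DH44", n2 = "m-NSC^DILP", n3 = "l-NSC^DH31",
              n4 = "SEZ-NSC^Hugin")
  s <- shared_input_neurons(conn, labels)
  expect_equal(s$n_multi_target, 3L)
  expect_false("solo" %in% s$multi_target$pre)
  expect_equal(s$map$n_subtypes[s$map$pre == "hub"], 3L)
  expect_equal(s$map$n_subtypes[s$map$pre == "pair"], 2L)
  expect_equal(s$map$n_subtypes[s$map$pre == "uni"], 2L)

  # conservation against a direct pair-count oracle
  sig <- significant_edges(conn)
  pairs <- unique(data.frame(pre = sig$pre, st = labels[sig$post]))
  expect_equal(sum(as.integer(names(s$histogram)) * s$histogram),
               nrow(pairs))

  expect_error(shared_input_neurons(conn, c(n1 = "x", n2 = NA)),
               "subtype label")
})

test_that("shared-input and disynaptic results match oracles on random graphs", {
  for (seed in 26:40) {
    conn <- random_connectome(seed)
    nsc <- conn$neurons$id[conn$neurons$super_class == "endocrine"]
    sens <- conn$neurons$id[conn$neurons$super_class == "sensory"]
    if (!length(nsc) || !length(sens)) next
    got <- disynaptic_sensory_pathways(conn, nsc)
    keys <- path_keys(got$pathways)
    expect_identical(keys, bf_disynaptic(conn$edges, sens, nsc,
                                         conn$thresholds$significance))
  }
})

test_that("NSC output reports grow monotonically as the threshold relaxes", {
  conn <- tiny_connectome(
    edge_df(list("n1", "d1", 60), list("n1", "c1", 3), list("n2", "c2", 2),
            list("n2", "c3", 1)),
    super = c(n1 = "endocrine", n2 = "endocrine", d1 = "descending"))
  strict <- nsc_output_partners(conn, c("n1", "n2"))
  expect_equal(nrow(strict), 1L)
  expect_identical(strict$partner_super_class, "descending")

  relaxed <- nsc_output_partners(conn, c("n1", "n2"), threshold = 2)
  expect_equal(nrow(relaxed), 3L)
  expect_true(all(paste(strict$nsc_id, strict$partner) %in%
                    paste(relaxed$nsc_id, relaxed$partner)))

  empty <- nsc_output_partners(conn, "n2")
  expect_equal(nrow(empty), 0L)
})
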
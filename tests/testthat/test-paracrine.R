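# small deterministic matrix: 2 clusters x 4 cells each, hand-set counts
toy_em <- function() {
  genes <- c("Crz", "sNPF", "Dh44", "ITP", "ChAT", "Gr64a", "Phm",
             "Ilp2", "Ilp3", "Ilp5", "CrzR", "InR")
  cells <- paste0("c", 1:8)
  m <- matrix(0, length(genes), length(cells),
              dimnames = list(genes, cells))
  m["Crz", 1:4] <- c(40, 35, 0, 50)     # cluster A: Crz in 3 of 4 cells
  m["sNPF", 1:4] <- c(30, 30, 30, 30)
  m["Phm", 1:8] <- 5
  m["CrzR", 5:8] <- c(20, 0, 0, 0)      # cluster B: CrzR in 1 of 4 cells
  m["InR", 1:8] <- 3
  m["Ilp2", 5:8] <- c(3, 6, 9, 12)
  m["Ilp3", 5:8] <- c(6, 9, 12, 3)
  m["Ilp5", 5:8] <- c(9, 12, 3, 6)
  expression_matrix(m, rep(c("A", "B"), each = 4))
}

test_that("gating predicates evaluate strictly on the normalised layer", {
  genes <- c("Crz", "sNPF", "Dh44", "ITP", "ChAT", "Gr64a", "Phm")
  vals <- cbind(pass = c(4, 4, 0, 0, 0, 0, 1),
                at_boundary = c(3, 4, 0, 0, 0, 0, 1),
                dh44_on = c(4, 4, 1, 0, 0, 0, 1))
  rownames(vals) <- genes
  # scale_factor chosen so the normalised values equal expm1-free magnitudes
  em <- expression_matrix(vals, c("x", "x", "x"), scale_factor = 1)
  # recover per-cell normalised values for the gate genes
  crz_gate <- "Crz > 3 & sNPF > 3 & Dh44 == 0 & ITP == 0 & ChAT == 0 & Gr64a == 0 & Phm > 0"
  # with log1p normalisation the printed thresholds need matching magnitudes;
  # evaluate against a criterion phrased on the normalised scale instead
  norm_pass <- as.numeric(em$norm["Crz", "pass"])
  gate <- sprintf("Crz > %.6f & Dh44 == 0 & Phm > 0", norm_pass * 0.99)
  got <- gate_cells(em, gate)
  expect_identical(got, "pass")

  # strict boundary: a cell exactly at the threshold fails
  gate_eq <- structure(
    data.frame(gene = "Crz", op = ">",
               value = as.numeric(em$norm["Crz", "at_boundary"])),
    class = c("gating_criterion", "data.frame"))
  expect_false("at_boundary" %in% gate_cells(em, gate_eq))

  # empty criterion selects everything; unknown genes are named in the error
  expect_identical(gate_cells(em, ""), c("pass", "at_boundary", "dh44_on"))
  expect_error(gate_cells(em, "Nonexistent > 1"), "Nonexistent")
  # the shipped criteria parse into conjunctions of atomic predicates
  shipped <- utils::read.csv(system.file("extdata", "nsc_gating_criteria.csv",
                                         package = "nscnet"))
  for (txt in shipped$criterion) {
    crit <- parse_gating(txt)
    expect_true(all(crit$op %in% c(">", "==")))
    expect_true(all(crit$value >= 0))
  }
  expect_equal(nrow(parse_gating(crz_gate)), 7L)
})

test_that("percent expressing counts raw-positive cells", {
  em <- toy_em()
  expect_equal(percent_expressing(em, "A", "Crz"), 0.75)
  expect_equal(percent_expressing(em, "A", "Dh44"), 0)
  expect_equal(percent_expressing(em, "A", "sNPF"), 1)
  expect_equal(percent_expressing(em, "B", "CrzR"), 0.25)
  expect_error(percent_expressing(em, "Z", "Crz"), "cluster")
  expect_error(percent_expressing(em, "A", "nope"), "not in matrix")
})

test_that("scaled expression min-max rescales cluster means to [0, 100]", {
  m <- matrix(0, 2, 4, dimnames = list(c("g", "hk"), paste0("c", 1:4)))
  m["g", ] <- c(2, 2, 4, 4)
  m["hk", ] <- 100  # housekeeping gene keeps library sizes comparable
  em <- expression_matrix(m, c("lo", "lo", "hi", "hi"), scale_factor = 1)
  sc <- scaled_expression(em, "g", c("lo", "hi"))
  expect_equal(unname(sc["g", ]), c(0, 100))

  # single cluster: nonzero gene -> 100; all-zero gene -> 0
  expect_equal(unname(scaled_expression(em, "g", "lo")["g", "lo"]), 100)
  zeros <- expression_matrix(matrix(0, 1, 2,
                                    dimnames = list("z", c("a", "b"))),
                             c("x", "y"))
  expect_equal(unname(scaled_expression(zeros, "z")["z", ]), c(0, 0))

  # z-score alternative stays within [0, 100] and ranks identically
  sc_z <- scaled_expression(em, "g", c("lo", "hi"), method = "zscore")
  expect_true(all(sc_z >= 0 & sc_z <= 100))
  expect_true(sc_z["g", "hi"] > sc_z["g", "lo"])
})

test_that("expression scores obey score = scaled x pct", {
  expect_equal(expression_score(100, 0.5), 50)
  expect_equal(expression_score(40, 0.25), 10)
  expect_equal(expression_score(73, 0), 0)
  expect_error(expression_score(120, 0.5))

  em <- toy_em()
  tab <- expression_score_table(em, c("Crz", "CrzR", "sNPF"))
  expect_equal(tab$score, tab$scaled * tab$pct)
  expect_true(all(tab$score >= 0 & tab$score <= 100))
  expect_true(all(tab$score <= tab$scaled + 1e-12))
  expect_equal(tab$score[tab$pct == 0], rep(0, sum(tab$pct == 0)))
})

test_that("presence rules flip exactly at the documented thresholds", {
  tab <- data.frame(
    cluster = "x",
    gene = c("l49", "l50", "lscore24", "lscore25", "r049", "r050"),
    pct = c(0.49, 0.50, 0.60, 0.60, 0.049, 0.050),
    scaled = 100,
    score = c(49, 50, 2.4, 2.5, 4.9, 5.0))
  lig <- presence_filters(tab, "ligand")
  expect_false(lig$present[lig$gene == "l49"])   # below 50% cells
  expect_true(lig$present[lig$gene == "l50"])    # at least 50% is inclusive
  expect_false(lig$present[lig$gene == "lscore24"])  # score filter at 2.5
  expect_true(lig$present[lig$gene == "lscore25"])
  rec <- presence_filters(tab, "receptor")
  expect_false(rec$present[rec$gene == "r049"])  # below 5% cells
  expect_true(rec$present[rec$gene == "r050"])   # 5% threshold is inclusive
})

test_that("receptor resolution picks the higher-scoring present receptor", {
  cl <- data.frame(gene = c("R1", "R2", "R3"), pct = c(0.3, 0.3, 0.01),
                   score = c(30, 12, 50))
  expect_identical(resolve_receptor(c("R1", "R2"), cl), "R1")
  expect_identical(resolve_receptor(c("R2", NA), cl), "R2")
  expect_identical(resolve_receptor(c("R3", NA), cl), NA_character_)
  tie <- data.frame(gene = c("Rb", "Ra"), pct = 0.5, score = 20)
  expect_identical(resolve_receptor(c("Rb", "Ra"), tie), "Ra")
})

test_that("the insulin-like peptide group averages per cell before scoring", {
  em <- toy_em()
  vals <- dilp_group_expression(em, "B")
  manual <- colMeans(as.matrix(em$norm[c("Ilp2", "Ilp3", "Ilp5"),
                                       paste0("c", 5:8)]))
  expect_equal(vals, manual)

  grouped <- add_gene_group(em, "Ilp235", c("Ilp2", "Ilp3", "Ilp5"))
  expect_true("Ilp235" %in% grouped$genes)
  # group pct = fraction of cells whose mean is positive
  expect_equal(percent_expressing(grouped, "B", "Ilp235"), 1)
  expect_equal(percent_expressing(grouped, "A", "Ilp235"), 0)
  # a raw mean of (3, 6, 9) is 6
  raw <- as.numeric(grouped$counts["Ilp235", "c5"])
  expect_equal(raw, mean(c(3, 6, 9)))
  expect_error(add_gene_group(em, "g", c("Ilp2", "missing")), "not in matrix")
})

test_that("paracrine edges require ligand and receptor presence", {
  tab <- data.frame(
    cluster = rep(c("A", "B"), each = 3),
    gene = rep(c("Crz", "CrzR", "Lk"), 2),
    pct = c(0.8, 0.0, 0.4, 0.0, 0.3, 0.0),
    scaled = c(62.5, 0, 100, 0, 100, 0),
    score = c(50, 0, 40, 0, 40, 0))
  pairs <- data.frame(ligand = c("Crz", "Lk"),
                      receptor1 = c("CrzR", "Lkr"),
                      receptor2 = NA_character_)
  net <- build_paracrine_network(tab, pairs)
  # planted ligand score 50 in A, receptor score 40 in B -> weight 20
  expect_equal(nrow(net), 1L)
  expect_equal(net$weight, 20)
  expect_identical(net$source, "A")
  expect_identical(net$target, "B")
  # Lk is below the 50% presence rule -> no edge despite its score
  expect_false("Lk" %in% net$ligand)

  # receptor undetected everywhere -> ligand contributes no edges
  tab2 <- tab
  tab2$pct[tab2$gene == "CrzR"] <- 0
  tab2$score[tab2$gene == "CrzR"] <- 0
  expect_equal(nrow(build_paracrine_network(tab2, pairs)), 0L)

  # weights live in [0, 100] and zero weights are never emitted
  expect_true(all(net$weight > 0 & net$weight <= 100))
})

test_that("paracrine networks are invariant to cell order and label renaming", {
  gen <- generate_expression(expression_sim_config(seed = 21))
  genes <- unique(na.omit(unlist(gen$pairs[c("ligand", "receptor1")])))
  net <- build_paracrine_network(
    expression_score_table(gen$em, genes), gen$pairs)

  set.seed(1)
  perm <- sample(ncol(gen$em$counts))
  em2 <- expression_matrix(gen$em$counts[, perm],
                           setNames(gen$em$cells$cluster[perm],
                                    gen$em$cells$cell[perm]))
  net2 <- build_paracrine_network(
    expression_score_table(em2, genes), gen$pairs)
  expect_equal(as.data.frame(net), as.data.frame(net2))

  rename <- setNames(paste0("Z", gen$em$cells$cluster), gen$em$cells$cell)
  em3 <- expression_matrix(gen$em$counts, rename)
  net3 <- build_paracrine_network(
    expression_score_table(em3, genes), gen$pairs)
  expect_equal(paste0("Z", net$source), net3$source)
  expect_equal(net$weight, net3$weight)
})

test_that("tissue receptor catalogs score like hand computation", {
  m <- matrix(0, 2, 6, dimnames = list(c("TkR99D", "InR"), paste0("c", 1:6)))
  m["TkR99D", ] <- c(9, 9, 0, 0, 0, 1)   # high in stellate cells only
  m["InR", ] <- 2
  em <- expression_matrix(m, rep(c("stellate", "muscle", "neuron"),
                                 each = 2), scale_factor = 1)
  tab <- tissue_receptor_catalog(em, c("TkR99D", "InR"))
  tk <- tab[tab$gene == "TkR99D", ]
  expect_equal(tk$pct[tk$cluster == "stellate"], 1)
  expect_equal(max(tk$score), tk$score[tk$cluster == "stellate"])
  expect_equal(tk$scaled[tk$cluster == "muscle"], 0)

  # zero-count receptor yields all-zero rows, not an error
  none <- tissue_receptor_catalog(em, "InR", clusters = "muscle")
  expect_true(all(none$score >= 0))
  zero <- expression_matrix(matrix(0, 1, 4, dimnames = list("r", paste0("c", 1:4))),
                            rep(c("t1", "t2"), each = 2))
  ztab <- tissue_receptor_catalog(zero, "r")
  expect_equal(ztab$pct, c(0, 0))
  expect_equal(ztab$score, c(0, 0))

  # pooling maps broadly distributed cell types to a shared label
  pooled <- tissue_receptor_catalog(em, "InR",
                                    pool_map = c(muscle = "general",
                                                 neuron = "general"))
  expect_setequal(unique(pooled$cluster), c("stellate", "general"))
})
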
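test_that("generators are byte-identical under a fixed seed", {
  a <- simulate_quant_experiment(n_proteins = 30, seed = 7)
  b <- simulate_quant_experiment(n_proteins = 30, seed = 7)
  expect_identical(a, b)

  pa <- simulate_proteome_with_motifs(5, signature = "KxKW",
                                      n_with_motif = 2, seed = 3)
  pb <- simulate_proteome_with_motifs(5, signature = "KxKW",
                                      n_with_motif = 2, seed = 3)
  expect_identical(pa$proteome$sequence, pb$proteome$sequence)
  # and so is the written FASTA
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_proteome(pa$proteome, f1)
  write_proteome(pb$proteome, f2)
  expect_identical(readLines(f1), readLines(f2))

  ea <- simulate_expression_pairs(data.frame(gene_a = "a", gene_b = "b",
                                             r = 0.5), seed = 2)
  eb <- simulate_expression_pairs(data.frame(gene_a = "a", gene_b = "b",
                                             r = 0.5), seed = 2)
  expect_identical(ea$matrix, eb$matrix)
})

test_that("noise-free simulation inverts the RSPA relation exactly", {
  sim <- simulate_quant_experiment(n_proteins = 25, sigma = 0, seed = 1)
  aqv <- rowMeans(sim$quant$values$WT)
  expect_equal(compute_rspa(sim$quant$mw_kda, aqv), sim$truth$copies,
               tolerance = 1e-12)
})

test_that("planted knockouts carry their statuses at zero noise", {
  sim <- simulate_quant_experiment(
    n_proteins = 10, sigma = 0, ablate = "prot_003",
    reduce = c(prot_007 = 3), seed = 2
  )
  d <- compare_conditions(sim$quant, "WT", "KO")
  expect_equal(d$status[d$protein_id == "prot_003"], "missing")
  expect_equal(d$status[d$protein_id == "prot_007"], "reduced")
  expect_equal(d$fold_change[d$protein_id == "prot_007"], 3)
  expect_true(all(d$status[!d$protein_id %in% c("prot_003", "prot_007")] ==
                    "unchanged"))
  expect_identical(sim$truth$status[match(d$protein_id, sim$truth$protein_id)],
                   d$status)
})

test_that("simulator validates its knockout and noise specification", {
  expect_error(simulate_quant_experiment(n_proteins = 5, ablate = "nope"),
               "knockout id not in protein set")
  expect_error(simulate_quant_experiment(n_proteins = 5,
                                         reduce = c(prot_001 = 0.5)),
               "reduction factors")
})

test_that("planted motifs are exactly what a search recovers", {
  sim <- simulate_proteome_with_motifs(
    n_proteins = 12, length_range = c(80L, 200L),
    signature = "[FHY]xWxxKxx[FHY]", n_with_motif = 3, seed = 5
  )
  h <- search_proteome(sim$proteome, "[FHY]xWxxKxx[FHY]", direction = "both")
  expect_equal(hit_key(h), hit_key(sim$truth))
  # and the oracle agrees the background is clean
  want <- oracle_search(sim$proteome, "[FHY]xWxxKxx[FHY]", direction = "both")
  expect_equal(hit_key(h), hit_key(want))
})

test_that("zero planted motifs means zero hits", {
  sim <- simulate_proteome_with_motifs(
    n_proteins = 6, signature = "WPxxxxxW", n_with_motif = 0, seed = 9
  )
  h <- search_proteome(sim$proteome, "WPxxxxxW", direction = "both")
  expect_equal(nrow(h), 0L)
})

test_that("impossible motif placements are rejected up front", {
  expect_error(
    simulate_proteome_with_motifs(2, lengths = c(5L, 100L),
                                  signature = "[FHY]xWxxKxx[FHY]",
                                  n_with_motif = 1, motif_hosts = 1L),
    "motif longer than host")
})

test_that("a planted r of 1 is degenerate and sampled exactly", {
  sim <- simulate_expression_pairs(
    data.frame(gene_a = "a", gene_b = "b", r = 1), seed = 10)
  expect_equal(cor(sim$matrix["a", ], sim$matrix["b", ]), 1)
  expect_error(simulate_expression_pairs(
    data.frame(gene_a = "a", gene_b = "b", r = 0.5), n_tissues = 2),
    "n_tissues")
  expect_error(simulate_expression_pairs(
    data.frame(gene_a = "a", gene_b = "b", r = 1.2)), "planted r")
})

test_that("expression output is non-negative with the documented labels", {
  sim <- simulate_expression_pairs(
    data.frame(gene_a = "a", gene_b = "b", r = -0.4), seed = 14)
  expect_true(all(sim$matrix >= 0))
  expect_equal(ncol(sim$matrix), 62L)
  expect_true(all(c("testis", "fallopian tube") %in% colnames(sim$matrix)))
})

test_that("the screen world plants one tether and labelled decoys", {
  w <- simulate_screen_world(seed = 42)
  expect_equal(nrow(w$truth$roles), 60L)
  expect_equal(sum(w$truth$roles$role == "tether"), 1L)
  # the planted tether satisfies every criterion by construction
  tether <- w$truth$roles[w$truth$roles$role == "tether", ]
  expect_true(tether$mw_kda >= 25 && tether$mw_kda <= 45)
  expect_equal(
    w$homologs$homolog_id[w$homologs$protein_id == tether$protein_id] == "-",
    FALSE)
  # its sequence length sits inside the trace window
  expect_true(w$proteome$length[w$proteome$id == tether$protein_id] >= 220)
})
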
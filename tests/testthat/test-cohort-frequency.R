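cfg <- pipeline_config()

event_df <- function(gene_id, sample_id, type) {
  data.frame(gene_id = gene_id, sample_id = sample_id,
             alteration_type = type, stringsAsFactors = FALSE)
}

random_event_matrix <- function(seed, n_genes = 20, n_samples = 15,
                                n_events = 120) {
  set.seed(seed)
  event_df(sample(sprintf("g%d", seq_len(n_genes)), n_events, TRUE),
           sample(sprintf("s%d", seq_len(n_samples)), n_events, TRUE),
           sample(c("mutation", "cnv", "expression"), n_events, TRUE))
}

test_that("cumulative frequency is a sample-set union, never a sum", {
  samples <- sprintf("s%d", 1:10)
  ev <- rbind(event_df("g", c("s1", "s2"), "mutation"),
              event_df("g", c("s2", "s3", "s4"), "cnv"))
  got <- cumulative_frequency(ev, samples)
  expect_equal(got$freq_mutation, 0.2)
  expect_equal(got$freq_cnv, 0.3)
  expect_equal(got$freq_cumulative, 0.4)  # s2 counted once

  zero <- cumulative_frequency(ev, samples, gene_ids = c("g", "absent"))
  expect_equal(zero$freq_cumulative[zero$gene_id == "absent"], 0)
  expect_error(cumulative_frequency(ev, character(0)), "positive")
  expect_error(cumulative_frequency(event_df("g", "sX", "cnv"), samples),
               "not in sample_ids")
})

test_that("random event matrices match the brute-force union oracle and bound", {
  for (seed in 1:25) {
    ev <- random_event_matrix(seed)
    samples <- sprintf("s%d", 1:15)
    got <- cumulative_frequency(ev, samples)
    for (i in seq_len(nrow(got))) {
      expect_equal(got$freq_cumulative[i],
                   oracle_cumulative(ev, 15, got$gene_id[i]))
    }
    individual <- got[c("freq_mutation", "freq_cnv", "freq_expression")]
    expect_true(all(got$freq_cumulative >= do.call(pmax, individual) - 1e-12))
    expect_true(all(got$freq_cumulative <=
                      pmin(1, rowSums(as.matrix(individual))) + 1e-12))
  }
})

test_that("cumulative frequency is invariant under sample-order permutation", {
  ev <- random_event_matrix(3)
  samples <- sprintf("s%d", 1:15)
  a <- cumulative_frequency(ev, samples)
  b <- cumulative_frequency(ev[sample(nrow(ev)), ], rev(samples))
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("gene selection keeps the ~3% mutation-frequency boundary inclusive", {
  rec <- cumulative_frequency(
    rbind(event_df("keep", sprintf("s%d", 1:3), "mutation"),
          event_df("drop", sprintf("s%d", 1:2), "mutation"),
          event_df("top", sprintf("s%d", 1:10), "mutation")),
    sprintf("s%d", 1:100))
  expect_equal(rec$freq_mutation[rec$gene_id == "keep"], 0.03)
  got <- select_frequent_genes(rec, cfg)
  expect_equal(got, c("top", "keep"))  # 0.029... dropped, sorted by cumulative
  expect_equal(select_frequent_genes(rec[0, ], cfg), character(0))
})

test_that("three-class typology follows the dominance ratio", {
  rec <- data.frame(
    gene_id = c("mut", "cnvx", "mix", "none"),
    freq_mutation = c(0.30, 0.05, 0.10, 0),
    freq_cnv_expression = c(0.02, 0.30, 0.12, 0),
    stringsAsFactors = FALSE)
  got <- classify_gene(rec, cfg)
  expect_equal(got$gene_class,
               c("mutation_dominant", "cnv_expression_dominant", "mixed",
                 "mixed"))
  # scale-invariant: doubling both frequencies never changes the class
  scaled <- rec
  scaled$freq_mutation <- scaled$freq_mutation * 2
  scaled$freq_cnv_expression <- scaled$freq_cnv_expression * 2
  expect_equal(classify_gene(scaled, cfg)$gene_class, got$gene_class)
})

test_that("oncoprint matrix encodes ordered type codes per cell", {
  ev <- rbind(
    data.frame(gene_id = "g1", sample_id = "s1", alteration_type = "cnv",
               direction = "gain", stringsAsFactors = FALSE),
    data.frame(gene_id = "g1", sample_id = "s1", alteration_type = "mutation",
               direction = "not_applicable", stringsAsFactors = FALSE),
    data.frame(gene_id = "g2", sample_id = "s2", alteration_type = "expression",
               direction = "loss", stringsAsFactors = FALSE))
  m <- oncoprint_matrix(ev, c("s1", "s2"))
  expect_equal(m["g1", "s1"], "AM")
  expect_equal(m["g2", "s2"], "L")
  expect_equal(m["g2", "s1"], ".")
})
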
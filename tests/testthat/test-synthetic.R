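test_that("every generated mature peptide passes scaffold detection", {
  corpus <- generate_corpus(generator_config(n_gxgcp = 40, n_xtcd = 20,
                                             seed = 4))
  cfg <- scaffold_config()
  for (i in seq_len(nrow(corpus$records))) {
    cys <- find_scaffold(corpus$records$sequence[i], cfg)
    expect_false(is.null(cys))
    expect_equal(cys, unlist(corpus$truth[i, paste0("c", 1:6)],
                             use.names = FALSE))
    expect_equal(sum(strsplit(corpus$records$sequence[i], "")[[1]] == "C"),
                 6)
  }
})

test_that("generation is byte-identical for a fixed seed", {
  cfg <- generator_config(n_gxgcp = 10, n_xtcd = 5, seed = 7)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$truth, b$truth)
  f1 <- tempfile()
  f2 <- tempfile()
  write_fasta(a$records, f1)
  write_fasta(b$records, f2)
  expect_identical(readLines(f1), readLines(f2))

  c2 <- generate_corpus(generator_config(n_gxgcp = 10, n_xtcd = 5,
                                         seed = 8))
  expect_false(identical(a$records$sequence, c2$records$sequence))

  # the generator does not disturb the caller's RNG stream
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(generate_corpus(cfg))
  expect_identical(runif(1), before)
})

test_that("full-fidelity corpora are recovered perfectly by the classifier", {
  cfg <- generator_config(
    n_gxgcp = 10, n_xtcd = 0, p_gxg = 1, p_pro = 1, p_his = 1,
    p_xtcd_motif = 1, p_aliphatic_pair = 1, seed = 7
  )
  corpus <- generate_corpus(cfg)
  calls <- classify_subfamily(trim_to_mature(corpus$records))
  expect_true(all(calls$label == "GXGCP"))
  expect_true(all(calls$has_gxg))
  expect_true(all(calls$has_pro))
  expect_true(all(calls$has_prec3_his))
})

test_that("empirical length mean tracks the target", {
  corpus <- generate_corpus(generator_config(n_gxgcp = 100, n_xtcd = 40,
                                             seed = 31))
  lens <- nchar(corpus$records$sequence)
  expect_true(all(lens >= 34 & lens <= 60))
  expect_lt(abs(mean(lens) - 38), 2)
})

test_that("planted-feature frequencies match the configured fidelities", {
  # binomial 99% CI check at n = 250 per subfamily
  cfg <- generator_config(n_gxgcp = 250, n_xtcd = 250, seed = 12)
  corpus <- generate_corpus(cfg)
  truth <- corpus$truth
  ci_ok <- function(k, n, p) {
    abs(k / n - p) <= 2.576 * sqrt(p * (1 - p) / n) + 1e-12
  }
  g <- truth[truth$subfamily == "GXGCP", ]
  x <- truth[truth$subfamily == "XTCD", ]
  expect_true(ci_ok(sum(g$gxg_planted), nrow(g), cfg$p_gxg))
  expect_true(ci_ok(sum(g$pro_planted), nrow(g), cfg$p_pro))
  expect_true(ci_ok(sum(truth$his_planted), nrow(truth), cfg$p_his))
  expect_true(all(x$xtcd_planted))  # p = 1
  expect_true(ci_ok(sum(x$aliphatic_planted), nrow(x),
                    cfg$p_aliphatic_pair))

  # planted features are really in the sequences
  m <- trim_to_mature(corpus$records)
  calls <- classify_subfamily(m)
  expect_equal(calls$has_gxg[match(g$id, calls$id)] | !g$gxg_planted,
               rep(TRUE, nrow(g)))
  expect_equal(calls$has_xtcd[match(x$id, calls$id)],
               x$xtcd_planted)
})

test_that("precursor mode prepends cysteine-free leaders and records truth", {
  cfg <- generator_config(n_gxgcp = 8, n_xtcd = 4, seed = 6,
                          leader_range = c(20L, 20L))
  pre <- generate_precursors(cfg)
  mat <- generate_corpus(cfg)
  expect_true(all(pre$truth$leader_len == 20))
  expect_true(all(pre$truth$mature_start == 21))
  for (i in seq_len(nrow(pre$records))) {
    leader <- substr(pre$records$sequence[i], 1, 20)
    expect_false(grepl("C", leader, fixed = TRUE))
    expect_equal(substring(pre$records$sequence[i], 21),
                 mat$records$sequence[i])
  }

  # zero-length leaders give precursor == mature
  pre0 <- generate_precursors(generator_config(n_gxgcp = 3, n_xtcd = 2,
                                               seed = 6,
                                               leader_range = c(0L, 0L)))
  mat0 <- generate_corpus(generator_config(n_gxgcp = 3, n_xtcd = 2,
                                           seed = 6,
                                           leader_range = c(0L, 0L)))
  expect_identical(pre0$records$sequence, mat0$records$sequence)
})

test_that("infeasible configurations fail before any output", {
  expect_error(generator_config(n_gxgcp = 5, length_range = c(10L, 12L)),
               "Infeasible")
  expect_error(generator_config(p_gxg = 1.2), "out of")
  expect_error(generator_config(length_range = c(60L, 34L)), "min <= max")
})

test_that("taxa are drawn from subfamily-consistent clades", {
  corpus <- generate_corpus(generator_config(seed = 1))
  taxa <- merge(corpus$truth[c("id", "subfamily", "taxon_id")],
                corpus$lineages, by = "taxon_id")
  kingdom <- vapply(taxa$lineage, function(l) l[2], character(1))
  # XTCD only under Eukaryota; GXGCP spans both kingdoms
  expect_true(all(kingdom[taxa$subfamily == "XTCD"] == "Eukaryota"))
  expect_setequal(unique(kingdom[taxa$subfamily == "GXGCP"]),
                  c("Bacteria", "Eukaryota"))
})
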
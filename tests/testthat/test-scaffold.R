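test_that("find_scaffold recovers the plectasin-numbered anchors", {
  # cysteines at 4, 15, 19, 30, 37, 39; loops 10, 3, 10, 6, 1 sit inside
  # the default windows
  expect_equal(find_scaffold(PLECTASIN), c(4, 15, 19, 30, 37, 39))

  # brute-force derived: 40-residue sequence, cysteines only at these six
  # positions, every inter-cysteine gap inside its window
  ch <- rep("A", 40)
  ch[c(4, 15, 19, 30, 37, 39)] <- "C"
  expect_equal(find_scaffold(paste(ch, collapse = "")),
               c(4, 15, 19, 30, 37, 39))
})

test_that("sequences that cannot hold three disulphides return NULL", {
  expect_null(find_scaffold("AAAA"))
  five <- "AAACAACAAAAAACAAAAAAAACAAAAAACAAA"
  expect_equal(sum(strsplit(five, "")[[1]] == "C"), 5)
  expect_null(find_scaffold(five))
  # six cysteines but spacing outside every window
  expect_null(find_scaffold("CCCCCCAAAA"))
  expect_error(find_scaffold(""), "non-empty")
})

test_that("find_scaffold equals exhaustive six-subset search", {
  withr::with_seed(101, {
    cfg <- scaffold_config()
    for (i in 1:150) {
      len <- sample(30:60, 1)
      n_cys <- sample(0:10, 1)
      s <- random_cys_sequence(len, min(n_cys, len))
      expect_identical(find_scaffold(s, cfg), oracle_find_scaffold(s, cfg),
                       label = sprintf("sequence %s", s))
    }
  })
})

test_that("segments reconstruct the sequence exactly", {
  cys <- find_scaffold(PLECTASIN)
  segs <- cys_segments(PLECTASIN, cys)
  expect_equal(unname(nchar(segs)),
               c(3, 10, 3, 10, 6, 1, 1))
  joined <- paste0(segs[1], "C", segs[2], "C", segs[3], "C", segs[4], "C",
                   segs[5], "C", segs[6], "C", segs[7])
  expect_equal(joined, PLECTASIN)

  # property: holds for generated corpora too
  corpus <- generate_corpus(generator_config(n_gxgcp = 15, n_xtcd = 10,
                                             seed = 5))
  m <- trim_to_mature(corpus$records)
  for (i in seq_len(nrow(m))) {
    segs <- cys_segments(m$mature[i], unlist(m[i, paste0("c", 1:6)]))
    expect_equal(paste0(segs[1], "C", segs[2], "C", segs[3], "C", segs[4],
                        "C", segs[5], "C", segs[6], "C", segs[7]),
                 m$mature[i])
  }
})

test_that("trim_to_mature trims leaders and is idempotent", {
  # cysteine-free leader + scaffold-bearing mature region
  pre <- generate_precursors(generator_config(n_gxgcp = 10, n_xtcd = 5,
                                              seed = 9))
  m <- trim_to_mature(pre$records, max_nloop = 10)
  expect_true(all(m$status == "ok"))
  expect_true(all(m$mature_start > 1))
  # the mature sequence contains all six planted cysteines
  for (i in seq_len(nrow(m))) {
    expect_equal(sum(strsplit(m$mature[i], "")[[1]] == "C"), 6)
  }
  # recovered start is within the max_nloop slack of the truth
  expect_true(all(abs(m$mature_start - pre$truth$mature_start) <= 10))

  # already-mature peptide with a 3-residue N-loop: no-op trim
  rec <- tibble::tibble(id = "p", sequence = PLECTASIN)
  m1 <- trim_to_mature(rec)
  expect_equal(m1$mature_start, 1L)
  expect_equal(m1$mature_end, 40L)
  expect_equal(m1$mature, PLECTASIN)

  # idempotence: trimming the trimmed peptide changes nothing
  m2 <- trim_to_mature(tibble::tibble(id = m1$id, sequence = m1$mature))
  expect_equal(m2$mature, m1$mature)
  expect_equal(unlist(m2[paste0("c", 1:6)]), unlist(m1[paste0("c", 1:6)]))

  # no scaffold -> flagged, not dropped
  m3 <- trim_to_mature(tibble::tibble(id = "bad", sequence = "AAAAGGGG"))
  expect_equal(m3$status, "no_scaffold")
  expect_true(is.na(m3$mature_start))
})

test_that("scaffold config validates its windows", {
  expect_error(scaffold_config(loop12 = c(5, 2)), "min <= max")
  expect_error(scaffold_config(loop56 = c(-1, 2)), "min <= max")
  expect_s3_class(scaffold_config(loop12 = c(0, 30)), "scaffold_config")
})
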
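test_that("pairwise aligner matches Biostrings scores", {
  withr::with_seed(77, {
    params <- align_params()
    mat <- substitution_matrix("BLOSUM62")
    for (i in 1:40) {
      a <- random_segments(1, 8)
      b <- random_segments(1, 8)
      if (!nzchar(a) || !nzchar(b)) next
      ours <- csabtools:::gotoh_align(a, b, params)
      ref <- Biostrings::pairwiseAlignment(
        a, b, substitutionMatrix = mat, gapOpening = params$gap_open,
        gapExtension = params$gap_extend, type = "global"
      )
      expect_equal(ours$score, Biostrings::score(ref),
                   label = sprintf("%s vs %s", a, b))
      # the returned gapped pair re-scores to the optimum
      expect_equal(
        sum_of_pairs_score(c(ours$a, ours$b), params),
        Biostrings::score(ref)
      )
      expect_equal(gsub("-", "", ours$a), a)
      expect_equal(gsub("-", "", ours$b), b)
    }
  })
})

test_that("center-star handles degenerate blocks", {
  params <- align_params()
  expect_equal(align_segment_center_star(c("GFG", "GFG", "GYG"), params),
               c("GFG", "GFG", "GYG"))
  expect_equal(align_segment_center_star(c("A", ""), params), c("A", "-"))
  expect_equal(align_segment_center_star("KGYKG", params), "KGYKG")
  expect_equal(align_segment_center_star(c("", "", ""), params),
               c("", "", ""))
})

test_that("center-star never exceeds the brute-force optimum and usually attains it", {
  withr::with_seed(42, {
    params <- align_params()
    n_exact <- 0
    n_total <- 80
    for (i in seq_len(n_total)) {
      n <- sample(2:4, 1)
      segs <- random_segments(n, 4)
      block <- align_segment_center_star(segs, params)
      expect_equal(gsub("-", "", block), segs)
      cs <- sum_of_pairs_score(block, params)
      opt <- oracle_optimal_sp(segs, params)
      expect_lte(cs, opt + 1e-9)
      if (n == 2) expect_equal(cs, opt)
      if (abs(cs - opt) < 1e-9) n_exact <- n_exact + 1
    }
    expect_gte(n_exact / n_total, 0.7)
  })
})

test_that("anchored alignment invariants hold on a synthetic corpus", {
  corpus <- generate_corpus(generator_config(n_gxgcp = 20, n_xtcd = 10,
                                             seed = 3))
  m <- trim_to_mature(corpus$records)
  aln <- build_anchored_alignment(m)
  mat <- as.matrix(aln)

  # equal row widths and all-cysteine anchors
  expect_equal(length(unique(nchar(aln$aligned))), 1)
  expect_true(all(mat[, aln$anchor_cols] == "C"))

  # gap-strip round trip for every row
  expect_equal(unname(gsub("-", "", aln$aligned[m$id])), m$mature)

  # blocks tile the alignment around the anchors
  blocks <- aln$blocks
  widths <- pmax(blocks$end - blocks$start + 1, 0)
  expect_equal(sum(widths) + 6, ncol(mat))

  # coordinate maps are mutually inverse on non-gap cells
  for (id in aln$ids[1:5]) {
    len <- nchar(gsub("-", "", aln$aligned[[id]]))
    for (pos in c(1, 2, len)) {
      col <- column_for_reference_position(aln, id, pos)
      expect_equal(position_for_column(aln, id, col), pos)
    }
  }
})

test_that("N-loop block is right-justified against C1", {
  # give `long` an extended N-loop by prepending eight residues
  long8 <- paste0("ATSDE", "RNQ", PLECTASIN)
  m <- mature_of(c(short = PLECTASIN, long = long8))
  aln <- build_anchored_alignment(m)
  nblock <- aln$blocks[aln$blocks$segment == "nloop", ]
  width <- nblock$end - nblock$start + 1
  expect_equal(width, 11)  # 8 extra + 3
  srow <- substr(aln$aligned[["short"]], nblock$start, nblock$end)
  # short N-loop "GFG" occupies the three columns adjacent to the C1 anchor
  expect_equal(srow, "--------GFG")
  expect_equal(aln$anchor_cols[1], nblock$end + 1)
})

test_that("identical peptides align without gaps", {
  m <- mature_of(c(a = PLECTASIN, b = PLECTASIN))
  aln <- build_anchored_alignment(m)
  expect_false(any(grepl("-", aln$aligned, fixed = TRUE)))
  expect_equal(nchar(aln$aligned[["a"]]), 40)
})

test_that("permuting input order never changes gap-stripped rows or anchor columns", {
  corpus <- generate_corpus(generator_config(n_gxgcp = 10, n_xtcd = 6,
                                             seed = 13))
  m <- trim_to_mature(corpus$records)
  aln1 <- build_anchored_alignment(m)
  withr::with_seed(1, perm <- sample(nrow(m)))
  aln2 <- build_anchored_alignment(m[perm, ])
  expect_equal(aln1$anchor_cols, aln2$anchor_cols)
  for (id in aln1$ids) {
    expect_equal(gsub("-", "", aln1$aligned[[id]]),
                 gsub("-", "", aln2$aligned[[id]]))
  }
  # with intrinsic star tie-breaking the full rows agree as well
  expect_equal(aln1$aligned[aln1$ids], aln2$aligned[aln1$ids])
})

test_that("pad mode justifies without realignment", {
  m <- mature_of(c(a = PLECTASIN,
                   b = paste0("AT", PLECTASIN)))
  aln <- build_anchored_alignment(m, align_params(mode = "pad"))
  mat <- as.matrix(aln)
  expect_true(all(mat[, aln$anchor_cols] == "C"))
  expect_equal(unname(gsub("-", "", aln$aligned[m$id])), m$mature)
})

test_that("reference position lookup validates input", {
  m <- mature_of(c(a = PLECTASIN, b = paste0("AT", PLECTASIN)))
  aln <- build_anchored_alignment(m)
  expect_error(column_for_reference_position(aln, "zz", 1), "zz")
  expect_error(column_for_reference_position(aln, "a", 0), "outside")
  expect_error(column_for_reference_position(aln, "a", 41), "outside")
  # ungapped reference row: position k maps to column k within the N-block
  expect_equal(column_for_reference_position(aln, "b", 2), 2)
})

test_that("rows without scaffold are excluded with a report", {
  m <- dplyr::bind_rows(
    mature_of(c(a = PLECTASIN)),
    trim_to_mature(tibble::tibble(id = "bad", sequence = "AAAA"))
  )
  m2 <- dplyr::bind_rows(m, mature_of(c(b = PLECTASIN)))
  aln <- build_anchored_alignment(m2)
  expect_equal(aln$excluded$id, "bad")
  expect_setequal(aln$ids, c("a", "b"))
})
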
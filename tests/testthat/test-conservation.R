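test_that("conservation_status follows the class scheme", {
  expect_equal(conservation_status("K", "K"), "identical")
  expect_equal(conservation_status("F", "Y"), "conservative")  # both aromatic
  expect_equal(conservation_status("Y", "R"), "nonconservative")
  expect_equal(conservation_status("Y", "K"), "nonconservative")
  expect_equal(conservation_status("K", "R"), "conservative")  # both positive
  expect_equal(conservation_status("K", "H"), "conservative")  # H in positive
  expect_equal(conservation_status("F", "H"), "conservative")  # H in aromatic
  expect_equal(conservation_status("K", "-"), "gap")
  expect_equal(conservation_status("K", "X"), "nonconservative")
  expect_error(conservation_status("X", "K"), "canonical")

  # vectorised and total over canonical x (canonical + gap)
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
  grid <- expand.grid(e = aa, o = c(aa, "-"), stringsAsFactors = FALSE)
  st <- conservation_status(grid$e, grid$o)
  expect_true(all(st %in% c("identical", "conservative", "nonconservative",
                            "gap")))
  # symmetry of the conservative relation
  for (i in seq_along(aa)) {
    for (j in seq_along(aa)) {
      expect_equal(
        conservation_status(aa[i], aa[j]) == "conservative",
        conservation_status(aa[j], aa[i]) == "conservative"
      )
    }
  }
})

test_that("blosum scheme marks positive-scoring pairs conservative", {
  expect_equal(conservation_status("F", "Y", scheme = "blosum"),
               "conservative")
  expect_equal(conservation_status("Y", "R", scheme = "blosum"),
               "nonconservative")
})

test_that("reference scored against itself gives nine identical statuses", {
  m <- mature_of(c(plectasin = PLECTASIN, other = PLECTASIN))
  aln <- build_anchored_alignment(m)
  rep <- score_mechanism_residues(aln)
  other <- rep$detail[rep$detail$id == "other", ]
  expect_equal(nrow(other), 9)
  expect_true(all(other$status == "identical"))
  expect_equal(other$expected,
               c("F", "H", "K", "I", "K", "Y", "K", "Y", "Y"))
  expect_equal(other$position, c(2, 18, 20, 22, 23, 25, 26, 29, 40))
})

test_that("planted substitutions are scored at the homologous column", {
  # equal-length plectasin variants align gap-free, so reference positions
  # map directly onto their own columns
  m <- mature_of(c(
    plectasin = PLECTASIN,
    y25r_1 = plectasin_variant("25" = "R"),
    y25r_2 = plectasin_variant("25" = "R", "5" = "T"),
    f2y = plectasin_variant("2" = "Y")
  ))
  aln <- build_anchored_alignment(m)
  rep <- score_mechanism_residues(aln)
  at25 <- rep$detail[rep$detail$position == 25, ]
  expect_equal(at25$status[at25$id %in% c("y25r_1", "y25r_2")],
               c("nonconservative", "nonconservative"))
  at2 <- rep$detail[rep$detail$position == 2 & rep$detail$id == "f2y", ]
  expect_equal(at2$status, "conservative")
  expect_equal(at2$observed, "Y")
})

test_that("tallies conserve the peptide count at every position", {
  corpus <- generate_corpus(generator_config(n_gxgcp = 20, n_xtcd = 12,
                                             seed = 8))
  m <- trim_to_mature(corpus$records)
  aln <- build_anchored_alignment(dplyr::bind_rows(
    m, trim_to_mature(plectasin_record())
  ))
  calls <- classify_subfamily(m)
  rep <- score_mechanism_residues(aln, calls = calls)
  per_pos <- dplyr::count(rep$by_position, position,
                          wt = n, name = "total")
  expect_true(all(per_pos$total == 32))
  # detail statuses consistent with by_position sums
  expect_equal(nrow(rep$detail), 9 * 32)
})

test_that("a missing reference row is a configuration error", {
  m <- mature_of(c(a = PLECTASIN, b = plectasin_variant("25" = "R")))
  aln <- build_anchored_alignment(m)
  expect_error(score_mechanism_residues(aln), "plectasin")
})
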
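make_lineages <- function() {
  tibble::tibble(
    taxon_id = c("bact", "moll", "dipt"),
    lineage = list(
      c("root", "Bacteria", "Actinomycetota"),
      c("root", "Eukaryota", "Mollusca"),
      c("root", "Eukaryota", "Arthropoda", "Diptera")
    ),
    name = c("a bacterium", "a mollusc", "a fly")
  )
}

test_that("spread_by_clade aggregates counts up the lineage", {
  calls <- tibble::tibble(
    id = c("p1", "p2", "p3"),
    label = c("GXGCP", "GXGCP", "XTCD"),
    taxon_id = c("bact", "moll", "dipt")
  )
  sp <- spread_by_clade(calls, make_lineages())
  row <- function(cl) sp[sp$clade == cl, ]
  expect_equal(row("root")$flag, "mixed")
  expect_equal(row("Bacteria")$flag, "GXGCP-only")
  expect_equal(row("Diptera")$flag, "XTCD-only")
  expect_equal(row("root")$n_total, 3)
  expect_equal(row("Eukaryota")$n_gxgcp, 1)
  expect_equal(row("Eukaryota")$n_xtcd, 1)

  # count conservation: parent = sum of children at every internal node
  for (cl in sp$clade) {
    kids <- sp[!is.na(sp$parent) & sp$parent == cl, ]
    if (nrow(kids)) {
      leaf_own <- 0  # internal clades hold no calls directly here
      expect_equal(row(cl)$n_total, sum(kids$n_total) + leaf_own,
                   label = cl)
    }
  }
})

test_that("edge cases: empty calls, single call, unplaced taxa", {
  empty <- spread_by_clade(
    tibble::tibble(id = character(), label = character(),
                   taxon_id = character()),
    make_lineages()
  )
  expect_equal(empty[empty$clade == "root", ]$n_total, 0)

  single <- spread_by_clade(
    tibble::tibble(id = "p", label = "XTCD", taxon_id = "dipt"),
    make_lineages()
  )
  on_path <- c("root", "Eukaryota", "Arthropoda", "Diptera", "dipt")
  expect_true(all(single$n_xtcd[single$clade %in% on_path] == 1))
  expect_true(all(single$n_xtcd[!single$clade %in% on_path] == 0))

  expect_warning(
    up <- spread_by_clade(
      tibble::tibble(id = "p", label = "XTCD", taxon_id = "unknown"),
      make_lineages()
    ),
    "absent"
  )
  expect_equal(nrow(attr(up, "unplaced")), 1)
  expect_equal(up[up$clade == "root", ]$n_total, 0)
})

test_that("spread is invariant to call order", {
  calls <- tibble::tibble(
    id = c("p1", "p2", "p3"),
    label = c("GXGCP", "GXGCP", "XTCD"),
    taxon_id = c("bact", "moll", "dipt")
  )
  a <- spread_by_clade(calls, make_lineages())
  b <- spread_by_clade(calls[3:1, ], make_lineages())
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("trans-kingdom flag needs two depth-1 clades", {
  calls <- tibble::tibble(
    id = c("p1", "p2", "p3"),
    label = c("GXGCP", "GXGCP", "XTCD"),
    taxon_id = c("bact", "moll", "dipt")
  )
  sp <- spread_by_clade(calls, make_lineages())
  expect_true(trans_kingdom_flag(sp, "GXGCP"))   # Bacteria + Eukaryota
  expect_false(trans_kingdom_flag(sp, "XTCD"))   # Eukaryota only

  only_euk <- spread_by_clade(calls[2, ], make_lineages())
  expect_false(trans_kingdom_flag(only_euk, "GXGCP"))
})

test_that("the nested summary mirrors the flat table", {
  calls <- tibble::tibble(
    id = c("p1", "p3"), label = c("GXGCP", "XTCD"),
    taxon_id = c("bact", "dipt")
  )
  sp <- spread_by_clade(calls, make_lineages())
  tree <- taxon_summary_tree(sp)
  expect_equal(tree$clade, "root")
  expect_equal(tree$n_total, 2)
  kid_names <- vapply(tree$children, function(x) x$clade, character(1))
  expect_setequal(kid_names, c("Bacteria", "Eukaryota"))
})

test_that("synthetic lineages convert to a valid Newick tree", {
  corpus <- generate_corpus(generator_config(n_gxgcp = 4, n_xtcd = 3,
                                             seed = 2))
  phy <- ape::read.tree(text = corpus$tree)
  expect_setequal(phy$tip.label, corpus$lineages$taxon_id)
})
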
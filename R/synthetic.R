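# Seeded generator of synthetic CSab peptide corpora with planted motifs
# and a truth table, emulating the statistical structure of the curated
# arthropod-defensin + actifensin corpus: 34-60 residue mature peptides
# (mean 38) on a six-cysteine scaffold, a GXGCP-like or XTCD-like
# N-terminus at configurable fidelities, a conserved pre-C3 histidine, and
# taxon labels spanning bacteria and invertebrate phyla.

#' Synthetic corpus generator configuration
#'
#' Defaults mirror the corpus-level statistics of the curated family:
#' an 88:35 GXGCP:XTCD mixture, lengths 34-60 with mean 38, and motif
#' fidelities 52/88 (GXG), 80/88 (Pro at C1+1), 72/88 (pre-C3 His),
#' 33/33 (XTCD motif) and 23/33 (aliphatic pair).
#'
#' @param n_gxgcp,n_xtcd Number of peptides per subfamily.
#' @param length_range,length_mean Mature length bounds and target mean.
#' @param p_gxg Probability a GXGCP peptide carries the full G-aromatic-G
#'   motif at C1-3..C1-1.
#' @param p_pro Probability of Pro at C1+1 (GXGCP mode).
#' @param p_his Probability of His at C3-1 (both modes).
#' @param p_xtcd_motif Probability an XTCD peptide carries T at C1-1 and D
#'   at C1+1.
#' @param p_aliphatic_pair Probability of an aliphatic pair at C1+2..C1+3
#'   (XTCD mode).
#' @param mech_fidelity Probability each plectasin mechanism-residue
#'   position carries the subfamily template residue; on failure a
#'   class-shuffled alternative is planted instead. Scalar in \[0, 1\].
#' @param background_mutation Probability that each non-planted,
#'   non-cysteine position is resampled after motif planting (default 0;
#'   background is already uniform random).
#' @param nloop_gxgcp,nloop_xtcd N-loop length ranges per subfamily.
#' @param tail_range C-terminal tail length range.
#' @param leader_range Leader length range for [generate_precursors()].
#' @param scaffold A [scaffold_config()]; generated loop lengths are drawn
#'   inside its spacing windows.
#' @param seed Integer seed; a fixed seed makes output byte-identical.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_gxgcp = 88L, n_xtcd = 35L,
                             length_range = c(34L, 60L), length_mean = 38,
                             p_gxg = 0.59, p_pro = 0.91, p_his = 0.82,
                             p_xtcd_motif = 1.0, p_aliphatic_pair = 0.70,
                             mech_fidelity = 0.9,
                             background_mutation = 0,
                             nloop_gxgcp = c(3L, 5L),
                             nloop_xtcd = c(6L, 10L),
                             tail_range = c(0L, 6L),
                             leader_range = c(15L, 30L),
                             scaffold = scaffold_config(),
                             seed = 1L) {
  probs <- c(p_gxg = p_gxg, p_pro = p_pro, p_his = p_his,
             p_xtcd_motif = p_xtcd_motif, p_aliphatic_pair = p_aliphatic_pair,
             mech_fidelity = mech_fidelity,
             background_mutation = background_mutation)
  if (any(probs < 0 | probs > 1)) {
    bad <- names(probs)[probs < 0 | probs > 1]
    abort(sprintf("Probabilities out of [0, 1]: %s.",
                  paste(bad, collapse = ", ")))
  }
  if (n_gxgcp < 0 || n_xtcd < 0) abort("Peptide counts must be >= 0.")
  for (nm in c("length_range", "nloop_gxgcp", "nloop_xtcd", "tail_range",
               "leader_range")) {
    r <- get(nm)
    if (length(r) != 2 || r[1] > r[2] || any(r < 0)) {
      abort(sprintf("`%s` must be c(min, max) with 0 <= min <= max.", nm))
    }
  }
  cfg <- structure(
    list(n_gxgcp = as.integer(n_gxgcp), n_xtcd = as.integer(n_xtcd),
         length_range = as.integer(length_range),
         length_mean = length_mean,
         p_gxg = p_gxg, p_pro = p_pro, p_his = p_his,
         p_xtcd_motif = p_xtcd_motif, p_aliphatic_pair = p_aliphatic_pair,
         mech_fidelity = mech_fidelity,
         background_mutation = background_mutation,
         nloop_gxgcp = as.integer(nloop_gxgcp),
         nloop_xtcd = as.integer(nloop_xtcd),
         tail_range = as.integer(tail_range),
         leader_range = as.integer(leader_range),
         scaffold = scaffold, seed = as.integer(seed)),
    class = "generator_config"
  )
  check_generator_feasible(cfg)
  cfg
}

# Fail before any output if the length bounds cannot be met inside the
# scaffold spacing windows.
check_generator_feasible <- function(cfg) {
  wins <- cfg$scaffold$windows
  loop_min <- sum(map_int(wins, function(w) w[1]))
  loop_max <- sum(map_int(wins, function(w) w[2]))
  for (mode in c("gxgcp", "xtcd")) {
    nl <- cfg[[paste0("nloop_", mode)]]
    lo <- nl[1] + 6L + loop_min + cfg$tail_range[1]
    hi <- nl[2] + 6L + loop_max + cfg$tail_range[2]
    if (cfg$length_range[1] < lo || cfg$length_range[2] > hi) {
      abort(sprintf(
        "Infeasible generator config: %s lengths achievable are %d-%d but length_range is %d-%d.",
        toupper(mode), lo, hi, cfg$length_range[1], cfg$length_range[2]
      ))
    }
  }
  invisible(cfg)
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(
    "<generator_config> %d GXGCP + %d XTCD, lengths %d-%d (mean %g), seed %d\n",
    x$n_gxgcp, x$n_xtcd, x$length_range[1], x$length_range[2],
    x$length_mean, x$seed
  ))
  cat(sprintf(
    "  fidelities: gxg %.2f, pro %.2f, his %.2f, xtcd %.2f, aliphatic %.2f, mech %.2f\n",
    x$p_gxg, x$p_pro, x$p_his, x$p_xtcd_motif, x$p_aliphatic_pair,
    x$mech_fidelity
  ))
  invisible(x)
}

# Synthetic taxon catalogue shaped like the family's real spread: GXGCP taxa
# span bacteria plus ancient invertebrate/fungal clades; XTCD taxa are
# restricted to the recent insect orders. All names are synthetic, not real
# taxids.
synthetic_taxa <- function() {
  tribble_rows <- list(
    list("synth_actinomyces", c("cellular_organisms", "Bacteria", "Actinomycetota", "Actinomycetales"), "Actinomyces-like (synthetic)", "GXGCP"),
    list("synth_bacillus", c("cellular_organisms", "Bacteria", "Bacillota", "Bacillales"), "Bacillus-like (synthetic)", "GXGCP"),
    list("synth_ascomycete", c("cellular_organisms", "Eukaryota", "Fungi", "Ascomycota"), "Ascomycete fungus (synthetic)", "GXGCP"),
    list("synth_mussel", c("cellular_organisms", "Eukaryota", "Mollusca", "Mytilida"), "Mussel (synthetic)", "GXGCP"),
    list("synth_dragonfly", c("cellular_organisms", "Eukaryota", "Arthropoda", "Odonata"), "Dragonfly (synthetic)", "GXGCP"),
    list("synth_scorpion", c("cellular_organisms", "Eukaryota", "Arthropoda", "Scorpiones"), "Scorpion (synthetic)", "GXGCP"),
    list("synth_beetle", c("cellular_organisms", "Eukaryota", "Arthropoda", "Coleoptera"), "Beetle (synthetic)", "XTCD"),
    list("synth_fly", c("cellular_organisms", "Eukaryota", "Arthropoda", "Diptera"), "Fly (synthetic)", "XTCD"),
    list("synth_truebug", c("cellular_organisms", "Eukaryota", "Arthropoda", "Hemiptera"), "True bug (synthetic)", "XTCD"),
    list("synth_wasp", c("cellular_organisms", "Eukaryota", "Arthropoda", "Hymenoptera"), "Wasp (synthetic)", "XTCD"),
    list("synth_moth", c("cellular_organisms", "Eukaryota", "Arthropoda", "Lepidoptera"), "Moth (synthetic)", "XTCD")
  )
  tibble(
    taxon_id = map_chr(tribble_rows, 1),
    lineage = map(tribble_rows, 2),
    name = map_chr(tribble_rows, 3),
    subfamily = map_chr(tribble_rows, 4)
  )
}

#' Convert a lineage table to a Newick taxonomy tree
#'
#' Builds a rooted tree whose tips are the `taxon_id`s and whose internal
#' structure follows the shared lineage prefixes.
#'
#' @param lineages A lineage tibble (columns `taxon_id`, `lineage`).
#' @return A Newick string (terminated by `;`).
#' @export
lineages_to_newick <- function(lineages) {
  paths <- map2(lineages$lineage, lineages$taxon_id, function(l, t) c(l, t))
  build <- function(paths_at, depth) {
    tips <- map_chr(paths_at, function(p) {
      if (length(p) == depth + 1L) p[depth + 1L] else NA_character_
    })
    leaves <- tips[!is.na(tips)]
    deeper <- paths_at[is.na(tips)]
    heads <- map_chr(deeper, function(p) p[depth + 1L])
    subtrees <- map_chr(unique(heads), function(h) {
      kids <- deeper[heads == h]
      inner <- build(kids, depth + 1L)
      paste0("(", inner, ")", h)
    })
    paste(c(leaves, subtrees), collapse = ",")
  }
  root <- paths[[1]][1]
  paste0("(", build(paths, 1L), ")", root, ";")
}

# uniform background residue sampler (canonical letters minus cysteine, so
# the scaffold keeps exactly six cysteines)
sample_background <- function(n) {
  pool <- setdiff(AA_CANONICAL, "C")
  pool[sample.int(length(pool), n, replace = TRUE)]
}

# sample one integer uniformly in [lo, hi]
runif_int <- function(lo, hi) {
  if (lo > hi) abort("Empty sampling range in generator (internal error).")
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

# Subfamily template for the nine mechanism residues, as anchor-relative
# offsets. XTCD substitutes the two tyrosines non-conservatively (R/K) and
# leaves the F2-homologous position unplanted.
mech_template <- function(subfamily) {
  base <- tibble(
    residue_name = c("F2", "K20", "I22", "K23", "Y25", "K26", "Y29", "Y40"),
    anchor = c("c1", "c3", "c3", "c3", "c3", "c3", "c4", "c6"),
    offset = c(-2L, 1L, 3L, 4L, 6L, 7L, -1L, 1L),
    expected = c("F", "K", "I", "K", "Y", "K", "Y", "Y")
  )
  if (subfamily == "XTCD") {
    base$expected[base$residue_name == "Y25"] <- "R"
    base$expected[base$residue_name == "Y40"] <- "K"
    base <- base[base$residue_name != "F2", ]
  }
  base
}

# A class-shuffled alternative to `res`: another member of the first
# residue class containing it (never C, never `res` itself).
class_alternative <- function(res) {
  cls <- residue_classes()
  for (k in cls) {
    if (res %in% k) {
      pool <- setdiff(k, c(res, "C"))
      if (length(pool)) return(pool[sample.int(length(pool), 1L)])
    }
  }
  sample_background(1L)
}

# Build one synthetic mature peptide. Returns list(sequence, cys, truth row).
build_peptide <- function(id, subfamily, L, cfg) {
  wins <- cfg$scaffold$windows
  loop_min <- map_int(wins, function(w) w[1])
  loop_max <- map_int(wins, function(w) w[2])
  nl_range <- if (subfamily == "GXGCP") cfg$nloop_gxgcp else cfg$nloop_xtcd

  # allocate lengths: nloop, tail, then the five loops, each sampled
  # uniformly inside its window restricted to keep the remainder feasible
  nl_lo <- max(nl_range[1], L - 6L - cfg$tail_range[2] - sum(loop_max))
  nl_hi <- min(nl_range[2], L - 6L - cfg$tail_range[1] - sum(loop_min))
  nloop_len <- runif_int(nl_lo, nl_hi)
  t_lo <- max(cfg$tail_range[1], L - 6L - nloop_len - sum(loop_max))
  t_hi <- min(cfg$tail_range[2], L - 6L - nloop_len - sum(loop_min))
  tail_len <- runif_int(t_lo, t_hi)
  rem <- L - 6L - nloop_len - tail_len
  loops <- integer(5)
  for (i in 1:5) {
    rest_min <- if (i < 5) sum(loop_min[(i + 1):5]) else 0L
    rest_max <- if (i < 5) sum(loop_max[(i + 1):5]) else 0L
    lo <- max(loop_min[i], rem - rest_max)
    hi <- min(loop_max[i], rem - rest_min)
    loops[i] <- runif_int(lo, hi)
    rem <- rem - loops[i]
  }

  seg_len <- c(nloop_len, loops, tail_len)
  ch <- sample_background(L)
  cys <- cumsum(c(nloop_len + 1L, loops[1:5] + 1L))
  ch[cys] <- "C"
  planted <- logical(L)
  planted[cys] <- TRUE

  plant <- function(pos, res) {
    if (pos >= 1L && pos <= L && !planted[pos]) {
      ch[pos] <<- res
      planted[pos] <<- TRUE
      TRUE
    } else {
      FALSE
    }
  }

  truth <- list(
    id = id, subfamily = subfamily, length = L, nloop_len = nloop_len,
    gxg_planted = FALSE, pro_planted = FALSE, xtcd_planted = FALSE,
    aliphatic_planted = FALSE, his_planted = FALSE
  )

  # mechanism residues from the subfamily template go in first so that the
  # N-terminal motif can preserve an aromatic already planted at C1-2
  tmpl <- mech_template(subfamily)
  anchor_pos <- setNames(cys, paste0("c", 1:6))
  for (k in seq_len(nrow(tmpl))) {
    pos <- anchor_pos[[tmpl$anchor[k]]] + tmpl$offset[k]
    nm <- paste0("mech_", tmpl$residue_name[k])
    if (runif(1) < cfg$mech_fidelity) {
      truth[[nm]] <- plant(pos, tmpl$expected[k])
    } else {
      plant(pos, class_alternative(tmpl$expected[k]))
      truth[[nm]] <- FALSE
    }
  }

  # subfamily motif features
  if (subfamily == "GXGCP") {
    if (runif(1) < cfg$p_gxg) {
      arom <- c("F", "W", "Y", "H")
      plant(cys[1] - 3L, "G")
      if (!planted[cys[1] - 2L]) plant(cys[1] - 2L, arom[sample.int(4L, 1L)])
      plant(cys[1] - 1L, "G")
      truth$gxg_planted <- TRUE
    }
    if (runif(1) < cfg$p_pro) {
      plant(cys[1] + 1L, "P")
      truth$pro_planted <- TRUE
    }
  } else {
    if (runif(1) < cfg$p_xtcd_motif) {
      plant(cys[1] - 1L, "T")
      plant(cys[1] + 1L, "D")
      truth$xtcd_planted <- TRUE
    }
    if (runif(1) < cfg$p_aliphatic_pair) {
      ali <- c("A", "V", "L", "I", "M")
      # Leu-Leu is the canonical pair; sample it half the time
      if (runif(1) < 0.5) {
        pair <- c("L", "L")
      } else {
        pair <- ali[sample.int(5L, 2L, replace = TRUE)]
      }
      plant(cys[1] + 2L, pair[1])
      plant(cys[1] + 3L, pair[2])
      truth$aliphatic_planted <- TRUE
    }
  }
  if (runif(1) < cfg$p_his) {
    truth$his_planted <- plant(cys[3] - 1L, "H")
  }

  # optional background churn on non-planted positions
  if (cfg$background_mutation > 0) {
    idx <- which(!planted & runif(L) < cfg$background_mutation)
    if (length(idx)) ch[idx] <- sample_background(length(idx))
  }

  for (i in 1:6) truth[[paste0("c", i)]] <- cys[i]
  truth$seg_lengths <- paste(seg_len, collapse = ",")
  list(sequence = paste(ch, collapse = ""), cys = cys, truth = truth)
}

# sample mature lengths: length_range[1] + Poisson(length_mean - min),
# clipped to the range (clipping mass is negligible at the defaults)
sample_lengths <- function(n, cfg) {
  lam <- max(cfg$length_mean - cfg$length_range[1], 0)
  L <- cfg$length_range[1] + stats::rpois(n, lam)
  pmin(pmax(L, cfg$length_range[1]), cfg$length_range[2])
}

#' Generate a synthetic CSab peptide corpus with a truth table
#'
#' Builds `n_gxgcp + n_xtcd` mature peptides segment-wise on a six-cysteine
#' scaffold sampled inside the configured spacing windows, plants subfamily
#' motifs and mechanism residues at the configured fidelities, and assigns
#' each peptide a synthetic taxon (GXGCP from bacterial plus
#' ancient-invertebrate/fungal clades, XTCD from recent insect orders).
#' Output is byte-identical for a fixed seed.
#'
#' @param config A [generator_config()].
#' @return An object of class `csab_corpus`: a list with `records` (tibble:
#'   id, sequence, description, taxon_id), `truth` (tibble of planted
#'   features, scaffold positions and taxa), `lineages` (lineage tibble for
#'   the synthetic taxa) and `tree` (Newick string over the taxa).
#' @examples
#' corpus <- generate_corpus(generator_config(n_gxgcp = 5, n_xtcd = 2, seed = 7))
#' corpus$records
#' @export
generate_corpus <- function(config = generator_config()) {
  if (!inherits(config, "generator_config")) {
    abort("`config` must be a generator_config.")
  }
  check_generator_feasible(config)
  taxa <- synthetic_taxa()
  withr::with_seed(config$seed, {
    plan <- tibble(
      subfamily = c(rep("GXGCP", config$n_gxgcp),
                    rep("XTCD", config$n_xtcd)),
      id = c(sprintf("gx%03d", seq_len(config$n_gxgcp)),
             sprintf("xt%03d", seq_len(config$n_xtcd)))
    )
    lens <- sample_lengths(nrow(plan), config)
    built <- map(seq_len(nrow(plan)), function(i) {
      build_peptide(plan$id[i], plan$subfamily[i], lens[i], config)
    })
    taxon_ids <- map_chr(plan$subfamily, function(sf) {
      pool <- taxa$taxon_id[taxa$subfamily == sf]
      pool[sample.int(length(pool), 1L)]
    })
    records <- tibble(
      id = plan$id,
      sequence = map_chr(built, "sequence"),
      description = paste0("synthetic ", plan$subfamily, " CSab peptide"),
      taxon_id = taxon_ids
    )
    truth <- bind_rows(map(built, function(b) as_tibble(b$truth)))
    truth$taxon_id <- taxon_ids
    structure(
      list(records = records, truth = truth,
           lineages = taxa[c("taxon_id", "lineage", "name")],
           tree = lineages_to_newick(taxa)),
      class = "csab_corpus"
    )
  })
}

#' Generate precursor peptides with cysteine-free leaders
#'
#' Prepends a random cysteine-free leader to each mature peptide of
#' [generate_corpus()], for testing maturation. Leaders are cysteine-free so
#' scaffold-anchored trimming is well-posed; real leader peptides may
#' contain cysteine.
#'
#' @param config A [generator_config()]; `leader_range` bounds the sampled
#'   leader lengths.
#' @return A `csab_corpus` whose `records` hold precursor sequences and
#'   whose `truth` gains `leader_len` and `mature_start` columns.
#' @export
generate_precursors <- function(config = generator_config()) {
  corpus <- generate_corpus(config)
  withr::with_seed(config$seed + 104729L, {
    leader_len <- map_int(seq_len(nrow(corpus$records)), function(i) {
      runif_int(config$leader_range[1], config$leader_range[2])
    })
    leaders <- map_chr(leader_len, function(n) {
      if (n == 0L) "" else paste(sample_background(n), collapse = "")
    })
  })
  corpus$records$sequence <- paste0(leaders, corpus$records$sequence)
  corpus$truth$leader_len <- leader_len
  corpus$truth$mature_start <- leader_len + 1L
  corpus
}

#' @export
print.csab_corpus <- function(x, ...) {
  tab <- table(x$truth$subfamily)
  cat(sprintf("<csab_corpus> %d peptides (%s) over %d taxa\n",
              nrow(x$records),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
              length(unique(x$records$taxon_id))))
  invisible(x)
}

#' Write a synthetic corpus to disk
#'
#' @param corpus A `csab_corpus`.
#' @param dir Output directory (created if missing). Writes
#'   `corpus.fasta`, `truth.tsv`, `lineages.tsv` and `taxonomy.nwk`.
#' @return Invisibly, a named list of the paths.
#' @export
write_corpus <- function(corpus, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fasta <- file.path(dir, "corpus.fasta")
  write_fasta(corpus$records, fasta)
  truth <- file.path(dir, "truth.tsv")
  readr::write_tsv(corpus$truth, truth, progress = FALSE)
  lin <- file.path(dir, "lineages.tsv")
  readr::write_tsv(
    tibble(
      taxon_id = corpus$lineages$taxon_id,
      lineage = map_chr(corpus$lineages$lineage, paste, collapse = ";"),
      name = corpus$lineages$name
    ),
    lin, progress = FALSE
  )
  tree <- file.path(dir, "taxonomy.nwk")
  writeLines(corpus$tree, tree)
  invisible(list(fasta = fasta, truth = truth, lineages = lin, tree = tree))
}
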
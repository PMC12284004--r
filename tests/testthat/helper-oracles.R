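# Independent brute-force oracles used by the property and acceptance tests.
# These deliberately re-derive results by exhaustive enumeration and never
# share code with the implementation paths they check.

# --- scaffold oracle -------------------------------------------------------

# Exhaustive search over all six-cysteine subsets: returns the best subset
# under the documented scoring (window-midpoint hits, then total deviation,
# then smallest positions), or NULL.
oracle_find_scaffold <- function(sequence, config = scaffold_config()) {
  cys <- which(strsplit(sequence, "")[[1]] == "C")
  if (length(cys) < 6) return(NULL)
  wins <- config$windows
  mins <- vapply(wins, function(w) w[1], integer(1))
  maxs <- vapply(wins, function(w) w[2], integer(1))
  mids <- vapply(wins, function(w) mean(w), numeric(1))
  subsets <- utils::combn(cys, 6)
  best <- NULL
  best_key <- NULL
  for (k in seq_len(ncol(subsets))) {
    pos <- subsets[, k]
    if (pos[1] - 1L > config$max_nloop) next
    gaps <- diff(pos) - 1L
    if (any(gaps < mins) || any(gaps > maxs)) next
    hits <- sum(abs(gaps - mids) < 1 & (mids %% 1) != 0) +
      sum(gaps == mids & (mids %% 1) == 0)
    dev <- sum(abs(gaps - mids))
    key <- c(-hits, dev, pos)
    if (is.null(best_key) || keyless(key, best_key)) {
      best <- pos
      best_key <- key
    }
  }
  best
}

keyless <- function(a, b) {
  d <- a - b
  i <- which(d != 0)
  if (!length(i)) return(FALSE)
  d[i[1]] < 0
}

# random test sequences with a controlled number of cysteines
random_cys_sequence <- function(len, n_cys) {
  pool <- setdiff(c("A", "R", "N", "D", "Q", "E", "G", "H", "I", "L", "K",
                    "M", "F", "P", "S", "T", "W", "Y", "V"), "C")
  ch <- sample(pool, len, replace = TRUE)
  if (n_cys > 0) {
    ch[sample.int(len, n_cys)] <- "C"
  }
  paste(ch, collapse = "")
}

# --- sum-of-pairs optimal MSA oracle --------------------------------------

# All ways of placing `len` residues into `width` ordered columns, as a
# 0/1 residue-mask matrix (one row per placement).
placements <- function(len, width) {
  if (len > width) return(matrix(nrow = 0, ncol = width))
  if (len == 0) return(matrix(0L, nrow = 1, ncol = width))
  idx <- utils::combn(width, len)
  out <- matrix(0L, nrow = ncol(idx), ncol = width)
  for (k in seq_len(ncol(idx))) out[k, idx[, k]] <- 1L
  out
}

# gapped row from a residue mask
apply_mask <- function(seq, mask) {
  ch <- rep("-", length(mask))
  if (nzchar(seq)) ch[mask == 1L] <- strsplit(seq, "")[[1]]
  paste(ch, collapse = "")
}

# Exhaustive optimal sum-of-pairs score over all gap placements with
# alignment width up to max(len) + extra columns. Enumerates every joint
# placement; the pair scores are precomputed per placement pair so the
# joint loop is additions only.
oracle_optimal_sp <- function(segments, params = align_params(),
                              extra = 2L) {
  n <- length(segments)
  lens <- nchar(segments)
  if (n == 1) return(0)
  best <- -Inf
  for (width in max(lens):(max(lens) + extra)) {
    masks <- lapply(lens, placements, width = width)
    rows <- lapply(seq_len(n), function(i) {
      vapply(seq_len(nrow(masks[[i]])),
             function(k) apply_mask(segments[i], masks[[i]][k, ]),
             character(1))
    })
    counts <- vapply(rows, length, integer(1))
    # pairwise score tables
    pair_tab <- list()
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        tab <- matrix(0, counts[i], counts[j])
        for (a in seq_len(counts[i])) {
          for (b in seq_len(counts[j])) {
            tab[a, b] <- sum_of_pairs_score(c(rows[[i]][a], rows[[j]][b]),
                                            params)
          }
        }
        pair_tab[[paste(i, j)]] <- tab
      }
    }
    grid <- do.call(expand.grid, lapply(counts, seq_len))
    tot <- numeric(nrow(grid))
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        tab <- pair_tab[[paste(i, j)]]
        tot <- tot + tab[cbind(grid[[i]], grid[[j]])]
      }
    }
    best <- max(best, max(tot))
  }
  best
}

# random loop-like segments over the canonical alphabet (no constraint on C)
random_segments <- function(n, max_len) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
  vapply(seq_len(n), function(i) {
    len <- sample(0:max_len, 1)
    if (len == 0) "" else paste(sample(aa, len, replace = TRUE),
                                collapse = "")
  }, character(1))
}
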
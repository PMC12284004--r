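#' Spacing configuration for the six-cysteine CSab scaffold
#'
#' The cysteine-stabilised alpha-beta (CSab) fold is held together by three
#' disulphide bonds between six cysteines (C1..C6). Candidate scaffolds are
#' searched by the number of residues in each of the five inter-cysteine
#' loops; the defaults generalise the plectasin anchor spacing (cysteines at
#' positions 4, 15, 19, 30, 37, 39, i.e. loops of 10, 3, 10, 6 and 1
#' residues) with slack for the 34-60 residue length range seen across the
#' family. All windows are configurable.
#'
#' @param loop12,loop23,loop34,loop45,loop56 Length-2 integer vectors
#'   `c(min, max)` bounding the number of residues strictly between
#'   consecutive scaffold cysteines.
#' @param max_nloop Maximum N-terminal loop length (residues before C1)
#'   considered during the search.
#' @param mature_min,mature_max Accepted mature peptide length bounds.
#' @return An object of class `scaffold_config`.
#' @export
scaffold_config <- function(loop12 = c(4L, 16L),
                            loop23 = c(2L, 6L),
                            loop34 = c(6L, 14L),
                            loop45 = c(3L, 10L),
                            loop56 = c(1L, 3L),
                            max_nloop = 25L,
                            mature_min = 20L,
                            mature_max = 80L) {
  windows <- list(loop12 = loop12, loop23 = loop23, loop34 = loop34,
                  loop45 = loop45, loop56 = loop56)
  for (nm in names(windows)) {
    w <- windows[[nm]]
    if (length(w) != 2 || any(w < 0) || w[1] > w[2]) {
      abort(sprintf("`%s` must be c(min, max) with 0 <= min <= max.", nm))
    }
  }
  if (max_nloop < 0) abort("`max_nloop` must be >= 0.")
  if (mature_min > mature_max) abort("`mature_min` must be <= `mature_max`.")
  structure(
    list(windows = lapply(windows, as.integer),
         max_nloop = as.integer(max_nloop),
         mature_min = as.integer(mature_min),
         mature_max = as.integer(mature_max)),
    class = "scaffold_config"
  )
}

#' @export
print.scaffold_config <- function(x, ...) {
  cat("<scaffold_config>\n")
  for (nm in names(x$windows)) {
    cat(sprintf("  %s: %d-%d residues\n", nm, x$windows[[nm]][1],
                x$windows[[nm]][2]))
  }
  cat(sprintf("  max N-loop: %d; mature length: %d-%d\n",
              x$max_nloop, x$mature_min, x$mature_max))
  invisible(x)
}

# Window midpoints, used for scoring and tie-breaking.
window_midpoints <- function(config) {
  vapply(config$windows, function(w) mean(w), numeric(1))
}

#' Locate the six-cysteine scaffold in a peptide sequence
#'
#' Searches the cysteines of `sequence` for six positions C1 < ... < C6 whose
#' five inter-cysteine loop lengths all fall inside the configured spacing
#' windows and whose N-terminal loop (residues before C1) does not exceed
#' `max_nloop`. Among valid subsets the winner maximises the number of loops
#' sitting exactly at their window midpoint; ties are broken by smallest
#' total deviation from the midpoints, then by smallest C1, then by
#' lexicographically smallest positions, so the result is deterministic.
#'
#' The search is a depth-first extension over cysteine positions with window
#' pruning, equivalent to exhaustive enumeration of all six-cysteine subsets
#' (see the package tests for the property check) but fast on
#' cysteine-dense sequences.
#'
#' @param sequence A single amino-acid string.
#' @param config A [scaffold_config()].
#' @return An integer vector of six 1-based cysteine positions, or `NULL`
#'   when the sequence carries no valid scaffold (not a CSab candidate).
#' @examples
#' find_scaffold("GFGCNGPWDEDDMQCHNHCKSIKGYKGGYCAKGGFVCKCY")
#' find_scaffold("AAAA")
#' @export
find_scaffold <- function(sequence, config = scaffold_config()) {
  if (!is.character(sequence) || length(sequence) != 1 || !nzchar(sequence)) {
    abort("`sequence` must be a single non-empty string.")
  }
  cys <- which(seq_chars(sequence) == "C")
  if (length(cys) < 6) return(NULL)
  wins <- config$windows
  starts <- cys[cys - 1L <= config$max_nloop]
  best <- NULL
  best_key <- NULL
  mids <- window_midpoints(config)

  consider <- function(pos) {
    loops <- diff(pos) - 1L
    hits <- sum(loops == round(mids) & (mids %% 1) == 0) +
      sum(abs(loops - mids) < 1 & (mids %% 1) != 0)
    dev <- sum(abs(loops - mids))
    # Ordering key: maximise hits, then minimise deviation, then smallest C1,
    # then lexicographically smallest positions.
    key <- c(-hits, dev, pos)
    if (is.null(best_key) ||
        isTRUE(vec_less(key, best_key))) {
      best <<- pos
      best_key <<- key
    }
  }

  extend <- function(pos, level) {
    if (level == 6L) {
      consider(pos)
      return(invisible())
    }
    w <- wins[[level]]
    last <- pos[length(pos)]
    nxt <- cys[cys > last]
    gaps <- nxt - last - 1L
    ok <- nxt[gaps >= w[1] & gaps <= w[2]]
    for (p in ok) extend(c(pos, p), level + 1L)
  }

  for (c1 in starts) extend(c1, 1L)
  best
}

# Lexicographic "less than" on numeric vectors of equal length.
vec_less <- function(a, b) {
  d <- a - b
  i <- which(d != 0)
  if (!length(i)) return(FALSE)
  d[i[1]] < 0
}

#' Split a sequence into scaffold segments
#'
#' Decomposes a scaffold-bearing sequence into the seven segments delimited
#' by the six cysteines: the N-terminal loop before C1, the five
#' inter-cysteine loops, and the C-terminal tail after C6.
#'
#' @param sequence Amino-acid string.
#' @param cys Integer vector of six cysteine positions, as returned by
#'   [find_scaffold()].
#' @return A named character vector of the seven segments (`nloop`,
#'   `loop12` .. `loop56`, `tail`). Joining them with `"C"` at the anchors
#'   reconstructs `sequence`.
#' @export
cys_segments <- function(sequence, cys) {
  if (length(cys) != 6 || is.unsorted(cys, strictly = TRUE)) {
    abort("`cys` must be six strictly increasing positions.")
  }
  ch <- seq_chars(sequence)
  if (any(ch[cys] != "C")) {
    abort("`cys` positions must all hold a cysteine.")
  }
  bounds <- c(0L, cys, nchar(sequence) + 1L)
  segs <- vapply(seq_len(7), function(i) {
    from <- bounds[i] + 1L
    to <- bounds[i + 1L] - 1L
    if (from > to) "" else substr(sequence, from, to)
  }, character(1))
  setNames(segs, c("nloop", "loop12", "loop23", "loop34", "loop45",
                   "loop56", "tail"))
}

# Inverse of cys_segments.
join_segments <- function(segments) {
  paste0(segments[1], "C", segments[2], "C", segments[3], "C",
         segments[4], "C", segments[5], "C", segments[6], "C", segments[7])
}

#' Trim precursor peptides to their mature scaffold region
#'
#' Locates the six-cysteine scaffold in each sequence and trims leader and
#' tail down to a window around it: `mature_start = max(1, C1 - max_nloop)`
#' and `mature_end = min(length, C6 + max_tail)`. Maturation is
#' scaffold-anchored rather than leader-model-based, so it is fully
#' reproducible offline; predicted signal/leader annotations are not used.
#'
#' @param records A data frame with columns `id` and `sequence` (precursor
#'   or already-mature peptides). Extra columns are carried through.
#' @param config A [scaffold_config()].
#' @param max_nloop Residues kept before C1 (default 12).
#' @param max_tail Residues kept after C6 (default 6).
#' @return A tibble with one row per input record: the input columns plus
#'   `status` ("ok", "no_scaffold" or "length_out_of_bounds"),
#'   `mature_start`, `mature_end` (1-based inclusive coordinates in the
#'   source sequence), `mature` (the trimmed sequence) and `c1`..`c6`
#'   (cysteine positions in the mature sequence). Failed records keep `NA`
#'   coordinates.
#' @examples
#' recs <- tibble::tibble(
#'   id = "plectasin",
#'   sequence = "GFGCNGPWDEDDMQCHNHCKSIKGYKGGYCAKGGFVCKCY"
#' )
#' trim_to_mature(recs)
#' @export
trim_to_mature <- function(records, config = scaffold_config(),
                           max_nloop = 12L, max_tail = 6L) {
  assert_peptide_tbl(records)
  res <- map(records$sequence, function(s) {
    # lift the search N-loop cap: precursor leaders of any length sit
    # before C1, and removing them is the whole point of trimming
    search_cfg <- config
    search_cfg$max_nloop <- nchar(s)
    cys <- find_scaffold(s, search_cfg)
    if (is.null(cys)) {
      return(list(status = "no_scaffold", mature_start = NA_integer_,
                  mature_end = NA_integer_, mature = NA_character_,
                  cys = rep(NA_integer_, 6)))
    }
    start <- max(1L, cys[1] - as.integer(max_nloop))
    end <- min(nchar(s), cys[6] + as.integer(max_tail))
    len <- end - start + 1L
    if (len < config$mature_min || len > config$mature_max) {
      return(list(status = "length_out_of_bounds", mature_start = NA_integer_,
                  mature_end = NA_integer_, mature = NA_character_,
                  cys = rep(NA_integer_, 6)))
    }
    list(status = "ok", mature_start = start, mature_end = end,
         mature = substr(s, start, end), cys = cys - start + 1L)
  })
  out <- as_tibble(records)
  out$status <- map_chr(res, "status")
  out$mature_start <- map_int(res, "mature_start")
  out$mature_end <- map_int(res, "mature_end")
  out$mature <- map_chr(res, "mature")
  cysm <- do.call(rbind, map(res, "cys"))
  colnames(cysm) <- paste0("c", 1:6)
  dplyr::bind_cols(out, as_tibble(cysm))
}
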
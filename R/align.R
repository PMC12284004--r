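# Deterministic multiple alignment anchored on the six scaffold cysteines.
# Each of the seven scaffold segments is aligned as an independent block;
# the blocks are then concatenated around single-residue all-cysteine anchor
# columns. This replaces the usual aligner-plus-manual-adjustment workflow
# with a reproducible algorithm whose anchors are guaranteed.

#' Center-star alignment of one segment block
#'
#' Aligns a set of loop segments by the classical center-star method: the
#' star is the segment maximising the summed pairwise global alignment score
#' against all others; every other segment is aligned to the star by global
#' pairwise alignment with affine gaps; the pairwise alignments are merged
#' without ever shortening existing columns ("once a gap, always a gap").
#'
#' Star ties are broken by the lexicographically smallest segment string and
#' then by the first index, so the block (up to row order) does not depend
#' on the order segments are supplied in. Within a merged insertion slot,
#' shorter insertions are left-justified.
#'
#' In `mode = "pad"` no realignment is done: segments are left-justified and
#' padded to the longest length.
#'
#' @param segments Character vector of ungapped segments (may be empty
#'   strings).
#' @param params An [align_params()].
#' @return Character vector of gapped rows, equal width, same order as
#'   `segments`.
#' @examples
#' align_segment_center_star(c("GFG", "GFG", "GYG"))
#' @export
align_segment_center_star <- function(segments, params = align_params()) {
  if (!length(segments)) abort("`segments` must contain at least one string.")
  if (params$mode == "pad") return(pad_block(segments, justify = "left"))
  n <- length(segments)
  width0 <- max(nchar(segments))
  if (n == 1) return(segments)
  if (width0 == 0) return(segments)
  if (length(unique(segments)) == 1) return(segments)

  # pairwise score matrix (symmetric)
  sc <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- gotoh_score(segments[i], segments[j], params)
      sc[i, j] <- s
      sc[j, i] <- s
    }
  }
  sums <- rowSums(sc)
  best <- max(sums)
  cand <- which(sums >= best - 1e-9)
  star <- cand[order(segments[cand], cand)][1]

  starseq <- segments[star]
  L <- nchar(starseq)
  starch <- seq_chars(starseq)

  # For each row, decompose its pairwise alignment to the star into L + 1
  # insertion slots (runs of star-gaps before each star residue and after
  # the last) plus the character aligned at each star residue.
  ins <- matrix("", n, L + 1)
  at <- matrix(GAP, n, L)
  for (k in seq_len(n)) {
    if (k == star) {
      at[k, ] <- starch
      next
    }
    pw <- gotoh_align(starseq, segments[k], params)
    sa <- seq_chars(pw$a)
    sb <- seq_chars(pw$b)
    slot <- 1L
    for (col in seq_along(sa)) {
      if (sa[col] == GAP) {
        ins[k, slot] <- paste0(ins[k, slot], sb[col])
      } else {
        at[k, slot] <- sb[col]
        slot <- slot + 1L
      }
    }
  }
  slot_w <- apply(ins, 2, function(x) max(nchar(x)))
  rows <- vapply(seq_len(n), function(k) {
    parts <- character(0)
    for (i in seq_len(L + 1)) {
      piece <- ins[k, i]
      piece <- paste0(piece, strrep(GAP, slot_w[i] - nchar(piece)))
      parts <- c(parts, piece)
      if (i <= L) parts <- c(parts, at[k, i])
    }
    paste(parts, collapse = "")
  }, character(1))
  rows
}

# Justify-and-pad a block to rectangular width.
pad_block <- function(segments, justify = c("left", "right")) {
  justify <- match.arg(justify)
  w <- max(nchar(segments), 0L)
  pad <- strrep(GAP, w - nchar(segments))
  if (justify == "left") paste0(segments, pad) else paste0(pad, segments)
}

#' Build a cysteine-anchored multiple alignment
#'
#' Constructs a multiple alignment of mature CSab peptides in which the six
#' scaffold cysteines occupy dedicated anchor columns that are cysteine in
#' every row (no gaps at anchors, by construction). The seven scaffold
#' segment blocks are built independently and concatenated around the
#' anchors:
#'
#' * the N-terminal loop block is right-justified toward C1, so the motif
#'   positions C1-1, C1-2, C1-3 read by the subfamily classifier are
#'   column-stable;
#' * the five interior loop blocks are aligned with
#'   [align_segment_center_star()] (or padded in `"pad"` mode);
#' * the C-terminal tail block is left-justified.
#'
#' @param mature A data frame as returned by [trim_to_mature()] (columns
#'   `id`, `mature`, `c1`..`c6`, `status`) or by the synthetic generator.
#'   Rows whose `status` is not `"ok"` are rejected and listed in the
#'   exclusion attribute.
#' @param params An [align_params()].
#' @return An object of class `anchored_alignment`: a list with `ids`,
#'   `aligned` (named character vector of equal-width gapped rows),
#'   `anchor_cols` (six 1-based column indices), `blocks` (tibble with
#'   `segment`, `start`, `end` column ranges; zero-width blocks have
#'   `start > end`), `params`, and `excluded` (tibble of rejected ids and
#'   reasons).
#' @export
build_anchored_alignment <- function(mature, params = align_params()) {
  assert_peptide_tbl(mature, cols = c("id", "mature", paste0("c", 1:6)))
  if (!"status" %in% names(mature)) mature$status <- "ok"
  excluded <- mature |>
    filter(.data$status != "ok") |>
    select("id", reason = "status")
  ok <- mature |> filter(.data$status == "ok")
  if (!nrow(ok)) abort("No peptides with a valid scaffold to align.")
  dup <- unique(ok$id[duplicated(ok$id)])
  if (length(dup)) {
    abort(sprintf("Duplicate peptide id%s in alignment input: %s.",
                  if (length(dup) > 1) "s" else "", paste(dup, collapse = ", ")))
  }

  cysm <- as.matrix(ok[paste0("c", 1:6)])
  segs <- map2(ok$mature, seq_len(nrow(ok)), function(s, i) {
    cys_segments(s, cysm[i, ])
  })
  seg_names <- c("nloop", "loop12", "loop23", "loop34", "loop45", "loop56",
                 "tail")
  blocks <- map(seq_along(seg_names), function(i) {
    col <- map_chr(segs, i)
    if (seg_names[i] == "nloop") {
      pad_block(col, justify = "right")
    } else if (seg_names[i] == "tail") {
      pad_block(col, justify = "left")
    } else {
      align_segment_center_star(col, params)
    }
  })

  widths <- map_int(blocks, function(b) nchar(b[1]))
  # columns: block1 | C | block2 | C | ... | C | block7
  starts <- integer(7)
  anchor_cols <- integer(6)
  pos <- 1L
  for (i in 1:7) {
    starts[i] <- pos
    pos <- pos + widths[i]
    if (i <= 6) {
      anchor_cols[i] <- pos
      pos <- pos + 1L
    }
  }
  rows <- vapply(seq_len(nrow(ok)), function(k) {
    paste0(blocks[[1]][k], "C", blocks[[2]][k], "C", blocks[[3]][k], "C",
           blocks[[4]][k], "C", blocks[[5]][k], "C", blocks[[6]][k], "C",
           blocks[[7]][k])
  }, character(1))

  structure(
    list(
      ids = ok$id,
      aligned = setNames(rows, ok$id),
      anchor_cols = anchor_cols,
      blocks = tibble(
        segment = seg_names,
        start = starts,
        end = starts + widths - 1L
      ),
      params = params,
      excluded = as_tibble(excluded)
    ),
    class = "anchored_alignment"
  )
}

#' @export
print.anchored_alignment <- function(x, ...) {
  cat(sprintf(
    "<anchored_alignment> %d rows x %d columns; anchors at %s\n",
    length(x$ids), nchar(x$aligned[1]),
    paste(x$anchor_cols, collapse = ", ")
  ))
  if (nrow(x$excluded)) {
    cat(sprintf("  %d peptide(s) excluded\n", nrow(x$excluded)))
  }
  invisible(x)
}

#' @method as.matrix anchored_alignment
#' @export
as.matrix.anchored_alignment <- function(x, ...) {
  m <- do.call(rbind, strsplit(unname(x$aligned), "", fixed = TRUE))
  rownames(m) <- x$ids
  m
}

#' Tidy an anchored alignment into a long tibble
#'
#' @param x An `anchored_alignment`.
#' @param ... Unused.
#' @return A tibble with one row per alignment cell: `id`, `column`,
#'   `residue`, `segment` (which scaffold block or anchor the column belongs
#'   to) and `is_anchor`.
#' @export
tidy.anchored_alignment <- function(x, ...) {
  m <- as.matrix(x)
  ncolm <- ncol(m)
  seg_of <- rep(NA_character_, ncolm)
  for (i in seq_len(nrow(x$blocks))) {
    b <- x$blocks[i, ]
    if (b$start <= b$end) seg_of[b$start:b$end] <- b$segment
  }
  seg_of[x$anchor_cols] <- paste0("C", 1:6)
  colv <- rep(seq_len(ncolm), times = length(x$ids))
  tibble(
    id = rep(x$ids, each = ncolm),
    column = colv,
    residue = as.vector(t(m)),
    segment = rep(seg_of, times = length(x$ids)),
    is_anchor = colv %in% x$anchor_cols
  )
}

#' One-line summary of an anchored alignment
#'
#' @param x An `anchored_alignment`.
#' @param ... Unused.
#' @return A one-row tibble: number of rows, alignment width, gap fraction,
#'   anchor cysteine purity (fraction of anchor cells that are cysteine) and
#'   number of excluded peptides.
#' @export
glance.anchored_alignment <- function(x, ...) {
  m <- as.matrix(x)
  tibble(
    n_rows = nrow(m),
    width = ncol(m),
    gap_fraction = mean(m == GAP),
    anchor_purity = mean(m[, x$anchor_cols, drop = FALSE] == "C"),
    n_excluded = nrow(x$excluded)
  )
}

#' Map a reference residue position to its alignment column
#'
#' @param aln An `anchored_alignment`.
#' @param ref_id Row id of the reference peptide.
#' @param ref_pos 1-based residue position in the ungapped reference
#'   sequence.
#' @return The 1-based alignment column holding that residue.
#' @export
column_for_reference_position <- function(aln, ref_id, ref_pos) {
  if (!ref_id %in% aln$ids) {
    abort(sprintf("Reference row \"%s\" is not in the alignment.", ref_id))
  }
  ch <- seq_chars(aln$aligned[[ref_id]])
  respos <- which(ch != GAP)
  if (!is.numeric(ref_pos) || length(ref_pos) != 1 || ref_pos < 1 ||
      ref_pos > length(respos)) {
    abort(sprintf(
      "Position %s is outside the ungapped length (%d) of row \"%s\".",
      as.character(ref_pos), length(respos), ref_id
    ))
  }
  respos[as.integer(ref_pos)]
}

#' Map an alignment column back to a residue position in one row
#'
#' @param aln An `anchored_alignment`.
#' @param id Row id.
#' @param column 1-based alignment column.
#' @return The 1-based residue position in the ungapped row, or `NA` if the
#'   row has a gap in that column.
#' @export
position_for_column <- function(aln, id, column) {
  if (!id %in% aln$ids) {
    abort(sprintf("Row \"%s\" is not in the alignment.", id))
  }
  ch <- seq_chars(aln$aligned[[id]])
  if (column < 1 || column > length(ch)) {
    abort(sprintf("Column %d is outside the alignment width (%d).",
                  column, length(ch)))
  }
  if (ch[column] == GAP) return(NA_integer_)
  sum(ch[seq_len(column)] != GAP)
}

#' Write an anchored alignment to aligned FASTA and a block map
#'
#' @param aln An `anchored_alignment`.
#' @param path Output stem: writes `<path>.afa` (aligned FASTA, gapped) and
#'   `<path>_blocks.tsv` (segment column ranges plus anchor columns).
#' @return Invisibly, a list with the two paths.
#' @export
write_alignment <- function(aln, path) {
  afa <- paste0(path, ".afa")
  write_fasta(tibble(id = aln$ids, sequence = unname(aln$aligned)), afa)
  blocks <- bind_rows(
    aln$blocks,
    tibble(segment = paste0("C", 1:6), start = aln$anchor_cols,
           end = aln$anchor_cols)
  ) |> arrange(.data$start, .data$end)
  bp <- paste0(path, "_blocks.tsv")
  readr::write_tsv(blocks, bp, progress = FALSE)
  invisible(list(alignment_path = afa, blocks_path = bp))
}
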
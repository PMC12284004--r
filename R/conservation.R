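# Conservation of the plectasin mechanism residues across an anchored
# alignment. Plectasin's lipid II binding has been tied to nine residues
# (F2, H18, K20, I22, K23, Y25, K26, Y29, Y40); each is mapped onto its
# alignment column and every peptide is scored identical / conservative /
# nonconservative / gap at that column.

#' The plectasin reference peptide
#'
#' Mature plectasin, the fungal (*Pseudoplectania nigrella*) CSab defensin
#' used as the mechanism-residue reference (UniProt Q53I06, 40 residues,
#' scaffold cysteines at 4, 15, 19, 30, 37, 39).
#'
#' @return A one-row tibble with `id`, `sequence` and `description`.
#' @export
plectasin_record <- function() {
  tibble(
    id = "plectasin",
    sequence = "GFGCNGPWDEDDMQCHNHCKSIKGYKGGYCAKGGFVCKCY",
    description = "Pseudoplectania nigrella plectasin, mature peptide"
  )
}

#' Mechanism residues of a reference peptide
#'
#' The default set is the nine plectasin residues implicated in lipid II
#' binding: F2, H18, K20, I22, K23, Y25, K26, Y29 and Y40.
#'
#' @param ref_id Reference row id (default `"plectasin"`).
#' @param positions Integer vector of 1-based residue positions.
#' @param expected Character vector of expected residues at `positions`.
#' @return An object of class `reference_residue_set`: a list with `ref_id`
#'   and a tibble `residues` (`position`, `expected`).
#' @export
reference_residue_set <- function(ref_id = "plectasin",
                                  positions = c(2L, 18L, 20L, 22L, 23L,
                                                25L, 26L, 29L, 40L),
                                  expected = c("F", "H", "K", "I", "K",
                                               "Y", "K", "Y", "Y")) {
  if (length(positions) != length(expected)) {
    abort("`positions` and `expected` must have equal length.")
  }
  if (is.unsorted(positions, strictly = TRUE)) {
    abort("`positions` must be strictly increasing.")
  }
  if (!all(expected %in% AA_CANONICAL)) {
    abort("`expected` residues must be canonical amino-acid letters.")
  }
  structure(
    list(ref_id = ref_id,
         residues = tibble(position = as.integer(positions),
                           expected = expected)),
    class = "reference_residue_set"
  )
}

#' @export
print.reference_residue_set <- function(x, ...) {
  cat(sprintf("<reference_residue_set> %s: %s\n", x$ref_id,
              paste0(x$residues$expected, x$residues$position,
                     collapse = ", ")))
  invisible(x)
}

#' Residue class scheme for conservative substitutions
#'
#' A transparent, auditable definition of "conservative": two residues are
#' conservative substitutes when they share at least one physicochemical
#' class. Histidine deliberately sits in both the aromatic and the
#' positively-charged class.
#'
#' @return A named list of character vectors.
#' @export
residue_classes <- function() {
  list(
    aromatic = c("F", "W", "Y", "H"),
    aliphatic = c("A", "V", "L", "I", "M"),
    positive = c("K", "R", "H"),
    negative = c("D", "E"),
    small_polar = c("S", "T", "N", "Q", "G", "C", "P")
  )
}

#' Conservation status of an observed residue against an expected one
#'
#' @param expected Canonical expected residue(s).
#' @param observed Observed residue(s); `"-"` for an alignment gap. `X`
#'   (unknown) is scored nonconservative.
#' @param scheme Either `"classes"` (share a class in [residue_classes()];
#'   the default) or `"blosum"` (BLOSUM62 score > 0), provided for
#'   sensitivity analysis.
#' @return Character vector over \{`identical`, `conservative`,
#'   `nonconservative`, `gap`\}, vectorised over the longer argument.
#' @examples
#' conservation_status("F", "Y")
#' conservation_status("Y", "R")
#' @export
conservation_status <- function(expected, observed, scheme = c("classes", "blosum")) {
  scheme <- match.arg(scheme)
  n <- max(length(expected), length(observed))
  expected <- rep_len(expected, n)
  observed <- rep_len(observed, n)
  if (!all(expected %in% AA_CANONICAL)) {
    abort("`expected` must contain canonical residues only.")
  }
  if (scheme == "classes") {
    cls <- residue_classes()
    conservative_pair <- function(a, b) {
      any(map_lgl(cls, function(k) a %in% k && b %in% k))
    }
  } else {
    sub <- substitution_matrix("BLOSUM62")
    conservative_pair <- function(a, b) {
      b %in% rownames(sub) && sub[a, b] > 0
    }
  }
  vapply(seq_len(n), function(i) {
    obs <- observed[i]
    if (is.na(obs) || obs == GAP) return("gap")
    if (obs == expected[i]) return("identical")
    if (obs == "X") return("nonconservative")
    if (conservative_pair(expected[i], obs)) "conservative" else "nonconservative"
  }, character(1))
}

#' Score mechanism-residue conservation across an alignment
#'
#' Maps every reference residue to its alignment column and scores each
#' peptide's residue in that column against the expected reference residue.
#' When subfamily calls are supplied, per-position tallies are additionally
#' broken down by subfamily.
#'
#' @param aln An `anchored_alignment` containing the reference row.
#' @param refset A [reference_residue_set()].
#' @param calls Optional data frame with `id` and `label` columns (subfamily
#'   calls); peptides without a call are labelled `"(none)"`.
#' @param scheme Passed to [conservation_status()].
#' @return An object of class `conservation_report`: a list with `detail`
#'   (tibble: id, subfamily, position, expected, column, observed, status)
#'   and `by_position` (tibble of per-position, per-subfamily status
#'   tallies). The reference row itself is not scored.
#' @export
score_mechanism_residues <- function(aln, refset = reference_residue_set(),
                                     calls = NULL,
                                     scheme = c("classes", "blosum")) {
  scheme <- match.arg(scheme)
  if (!inherits(aln, "anchored_alignment")) {
    abort("`aln` must be an anchored_alignment.")
  }
  if (!refset$ref_id %in% aln$ids) {
    abort(sprintf(
      "Conservation reference row \"%s\" is absent from the alignment.",
      refset$ref_id
    ))
  }
  cols <- vapply(refset$residues$position, function(p) {
    column_for_reference_position(aln, refset$ref_id, p)
  }, integer(1))
  ref_ch <- seq_chars(aln$aligned[[refset$ref_id]])
  mismatch <- ref_ch[cols] != refset$residues$expected
  if (any(mismatch)) {
    bad <- refset$residues$position[mismatch]
    abort(sprintf(
      "Reference row \"%s\" does not carry the expected residue at position%s %s.",
      refset$ref_id, if (length(bad) > 1) "s" else "",
      paste(bad, collapse = ", ")
    ))
  }
  ids <- setdiff(aln$ids, refset$ref_id)
  m <- as.matrix(aln)
  label_of <- setNames(rep("(none)", length(ids)), ids)
  if (!is.null(calls)) {
    assert_peptide_tbl(calls, cols = c("id", "label"), arg = "calls")
    hit <- intersect(ids, calls$id)
    label_of[hit] <- calls$label[match(hit, calls$id)]
  }
  detail <- tidyr::expand_grid(
    id = ids,
    k = seq_len(nrow(refset$residues))
  ) |>
    mutate(
      subfamily = unname(label_of[.data$id]),
      position = refset$residues$position[.data$k],
      expected = refset$residues$expected[.data$k],
      column = cols[.data$k],
      observed = m[cbind(match(.data$id, rownames(m)), .data$column)],
      status = conservation_status(.data$expected, .data$observed, scheme)
    ) |>
    select(-"k")
  by_position <- detail |>
    count(.data$position, .data$expected, .data$subfamily, .data$status) |>
    tidyr::pivot_wider(names_from = "status", values_from = "n",
                       values_fill = 0L)
  for (st in c("identical", "conservative", "nonconservative", "gap")) {
    if (!st %in% names(by_position)) by_position[[st]] <- 0L
  }
  by_position <- by_position |>
    mutate(n = .data$identical + .data$conservative +
             .data$nonconservative + .data$gap)
  structure(list(detail = detail, by_position = by_position,
                 refset = refset, scheme = scheme),
            class = "conservation_report")
}

#' @export
print.conservation_report <- function(x, ...) {
  cat(sprintf("<conservation_report> %d peptides x %d reference positions (%s scheme)\n",
              length(unique(x$detail$id)), nrow(x$refset$residues), x$scheme))
  tall <- x$detail |>
    count(.data$position, .data$expected, .data$status) |>
    tidyr::pivot_wider(names_from = "status", values_from = "n",
                       values_fill = 0L)
  print(as.data.frame(tall), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.conservation_report <- function(x, ...) x$detail

#' @export
glance.conservation_report <- function(x, ...) {
  tibble(
    n_peptides = length(unique(x$detail$id)),
    n_positions = nrow(x$refset$residues),
    frac_identical = mean(x$detail$status == "identical"),
    frac_conservative = mean(x$detail$status == "conservative"),
    frac_nonconservative = mean(x$detail$status == "nonconservative"),
    frac_gap = mean(x$detail$status == "gap")
  )
}

#' Write a conservation report to TSV
#'
#' @param report A `conservation_report`.
#' @param path Output stem: writes `<path>_detail.tsv` (long format) and
#'   `<path>_by_position.tsv` (per-position tallies).
#' @return Invisibly, the two paths.
#' @export
write_conservation <- function(report, path) {
  dp <- paste0(path, "_detail.tsv")
  bp <- paste0(path, "_by_position.tsv")
  readr::write_tsv(report$detail, dp, progress = FALSE)
  readr::write_tsv(report$by_position, bp, progress = FALSE)
  invisible(list(detail_path = dp, by_position_path = bp))
}
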
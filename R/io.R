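#' Read a protein FASTA file into a tibble
#'
#' Parses a FASTA file of peptide sequences into one row per record.
#' Sequences are uppercased, whitespace is trimmed and a single terminal stop
#' (`*`) is stripped. The first whitespace-delimited token of the header is
#' the record id; the remainder (if any) becomes the description.
#'
#' Only the 20 canonical amino-acid letters plus `X` (unknown residue, as
#' found in some database entries) are accepted. `X` never matches any motif
#' class downstream.
#'
#' @param path Path to a FASTA file. Any line-wrapping is accepted.
#' @return A tibble with columns `id`, `sequence`, `description`.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 demo", "GFGCP"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*$", lines) & !startsWith(lines, ";")
  lines <- lines[keep]
  line_no <- which(keep)
  if (!length(lines)) {
    return(tibble(id = character(), sequence = character(),
                  description = character()))
  }
  is_header <- startsWith(lines, ">")
  if (!is_header[1]) {
    abort(sprintf(
      "Malformed FASTA: line %d contains sequence data before any '>' header.",
      line_no[1]
    ))
  }
  grp <- cumsum(is_header)
  headers <- sub("^>", "", lines[is_header])
  ids <- sub("\\s.*$", "", headers)
  descriptions <- str_trim(sub("^\\S*\\s*", "", headers))
  if (any(ids == "")) {
    bad <- line_no[is_header][ids == ""][1]
    abort(sprintf("Malformed FASTA header at line %d: empty record id.", bad))
  }
  seqs <- vapply(
    split(lines[!is_header], grp[!is_header]),
    function(x) paste(gsub("\\s", "", x), collapse = ""),
    character(1)
  )
  # headers with no sequence lines would be dropped by split(); re-expand
  seq_by_grp <- setNames(rep("", length(headers)), as.character(seq_along(headers)))
  seq_by_grp[names(seqs)] <- seqs
  seqs <- str_to_upper(unname(seq_by_grp))
  seqs <- sub("\\*$", "", seqs)

  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    abort(sprintf("Duplicate FASTA record id%s: %s.",
                  if (length(dup) > 1) "s" else "", paste(dup, collapse = ", ")))
  }
  empty <- ids[nchar(seqs) == 0]
  if (length(empty)) {
    abort(sprintf("FASTA record with empty sequence: %s.",
                  paste(empty, collapse = ", ")))
  }
  for (i in seq_along(ids)) {
    bad <- illegal_residues(seqs[i])
    if (length(bad)) {
      abort(sprintf(
        "Illegal residue letter%s (%s) in record \"%s\".",
        if (length(bad) > 1) "s" else "", paste(bad, collapse = ", "), ids[i]
      ))
    }
  }
  tibble(id = ids, sequence = seqs, description = descriptions)
}

#' Write peptide records to FASTA
#'
#' @param records A data frame with columns `id`, `sequence` and optionally
#'   `description`.
#' @param path Output file path.
#' @param wrap Line width for sequence wrapping (default 60 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, wrap = 60) {
  assert_peptide_tbl(records)
  desc <- if ("description" %in% names(records)) records$description else ""
  desc <- ifelse(is.na(desc) | desc == "", "", paste0(" ", desc))
  out <- character(0)
  if (nrow(records)) {
    out <- unlist(Map(function(id, d, s) {
      c(paste0(">", id, d), wrap_seq(s, wrap))
    }, records$id, desc, records$sequence, USE.NAMES = FALSE))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a taxonomic lineage table
#'
#' Reads a tab-separated file with columns `taxon_id`, `lineage`
#' (semicolon-joined clade names, root first) and `name` (display name).
#' This stands in for an online taxonomy lookup: the pipeline never queries
#' a remote service.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `taxon_id`, `lineage` (list column of
#'   character vectors, root to leaf) and `name`.
#' @export
read_lineage_tsv <- function(path) {
  if (!file.exists(path)) abort(sprintf("Lineage file not found: %s", path))
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing <- setdiff(c("taxon_id", "lineage", "name"), names(tab))
  if (length(missing)) {
    abort(sprintf("Lineage table is missing column%s: %s.",
                  if (length(missing) > 1) "s" else "",
                  paste(missing, collapse = ", ")))
  }
  dup <- unique(tab$taxon_id[duplicated(tab$taxon_id)])
  if (length(dup)) {
    abort(sprintf("Duplicate taxon_id in lineage table: %s.",
                  paste(dup, collapse = ", ")))
  }
  lineage <- map(tab$lineage, function(x) {
    str_trim(strsplit(x, ";", fixed = TRUE)[[1]])
  })
  roots <- unique(map_chr(lineage, function(x) if (length(x)) x[1] else NA_character_))
  roots <- roots[!is.na(roots)]
  if (length(roots) > 1) {
    abort(sprintf(
      "All lineages must share one root clade; found: %s.",
      paste(roots, collapse = ", ")
    ))
  }
  tibble(taxon_id = tab$taxon_id, lineage = lineage, name = tab$name)
}

#' Fixed subfamily colour scheme for tree annotation
#'
#' GXGCP peptides are shown in yellow and XTCD peptides in blue; this mapping
#' is fixed so that annotated trees are comparable across runs.
#'
#' @return A named character vector mapping subfamily label to colour.
#' @export
subfamily_colours <- function() {
  c(GXGCP = "yellow", XTCD = "blue")
}

#' Annotate a taxonomy tree with subfamily colours
#'
#' Writes the input Newick unchanged alongside a colour-annotation table
#' (leaf, label, colour) using the fixed mapping GXGCP = yellow,
#' XTCD = blue. A taxon producing both subfamilies ("mixed") receives one
#' row per label. Labels for taxa absent from the tree are skipped with a
#' warning and reported, never fatal.
#'
#' @param tree A Newick string, a path to a Newick file, or an
#'   [ape::phylo] object.
#' @param calls A data frame with columns `taxon_id` and `label`
#'   (GXGCP/XTCD; UNCLASSIFIED rows are ignored), typically subfamily calls
#'   joined to taxa.
#' @param path Output stem: writes `<path>.nwk` and `<path>_annotation.tsv`.
#' @return Invisibly, a list with `tree_path`, `annotation_path`,
#'   `annotation` (tibble) and `skipped` (character vector of taxa not found
#'   as leaves).
#' @export
write_tree_annotation <- function(tree, calls, path) {
  phy <- as_phylo_tree(tree)
  assert_peptide_tbl(calls, cols = c("taxon_id", "label"), arg = "calls")
  cols <- subfamily_colours()

  ann <- calls |>
    filter(.data$label %in% names(cols)) |>
    distinct(.data$taxon_id, .data$label) |>
    arrange(.data$taxon_id, .data$label)
  present <- ann$taxon_id %in% phy$tip.label
  skipped <- unique(ann$taxon_id[!present])
  if (length(skipped)) {
    warn(sprintf("Skipping label%s for taxa absent from the tree: %s.",
                 if (length(skipped) > 1) "s" else "",
                 paste(skipped, collapse = ", ")))
  }
  annotation <- tibble(
    leaf = ann$taxon_id[present],
    label = ann$label[present],
    colour = unname(cols[ann$label[present]])
  )
  tree_path <- paste0(path, ".nwk")
  annotation_path <- paste0(path, "_annotation.tsv")
  ape::write.tree(phy, file = tree_path)
  readr::write_tsv(annotation, annotation_path, progress = FALSE)
  skipped_path <- paste0(path, "_skipped.tsv")
  readr::write_tsv(tibble(taxon_id = skipped), skipped_path, progress = FALSE)
  invisible(list(
    tree_path = tree_path,
    annotation_path = annotation_path,
    skipped_path = skipped_path,
    annotation = annotation,
    skipped = skipped
  ))
}

# Coerce a Newick string / file path / phylo object to phylo.
as_phylo_tree <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (!is.character(tree) || length(tree) != 1) {
    abort("`tree` must be a phylo object, a Newick string, or a file path.")
  }
  if (file.exists(tree)) {
    ape::read.tree(tree)
  } else {
    ape::read.tree(text = tree)
  }
}
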
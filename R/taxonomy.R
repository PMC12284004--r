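# Subfamily spread across a supplied taxonomy. "Kingdom" is operationalised
# as depth 1 of the lineage table (the children of the shared root), since
# the package never queries a live taxonomy service.

#' Aggregate subfamily calls up a lineage tree
#'
#' Joins subfamily calls to their taxonomic lineages and accumulates label
#' counts up every clade on each lineage, from the shared root to the leaf
#' taxa. Each clade is flagged `GXGCP-only`, `XTCD-only`, `mixed` or
#' `none` (no classified peptide beneath it). Calls whose `taxon_id` is
#' absent from the lineage table are collected in an "unplaced" attribute
#' and reported, never fatal.
#'
#' @param calls A data frame with columns `id`, `label` and `taxon_id`.
#' @param lineages A lineage tibble from [read_lineage_tsv()] (columns
#'   `taxon_id`, `lineage` list column, `name`).
#' @return A tibble of class `taxon_summary`, one row per clade: `clade`,
#'   `parent` (`NA` for the root), `depth` (root = 0), `n_gxgcp`, `n_xtcd`,
#'   `n_unclassified`, `n_total` and `flag`. Attribute `unplaced` holds the
#'   unplaced call rows.
#' @export
spread_by_clade <- function(calls, lineages) {
  assert_peptide_tbl(calls, cols = c("id", "label", "taxon_id"),
                     arg = "calls")
  assert_peptide_tbl(lineages, cols = c("taxon_id", "lineage"),
                     arg = "lineages")
  placed <- calls$taxon_id %in% lineages$taxon_id
  unplaced <- calls[!placed, , drop = FALSE]
  if (nrow(unplaced)) {
    warn(sprintf("%d call(s) with taxon_id absent from the lineage table.",
                 nrow(unplaced)))
  }
  calls <- calls[placed, , drop = FALSE]

  # Full clade paths: lineage then the taxon itself as leaf.
  paths <- setNames(
    map2(lineages$lineage, lineages$taxon_id, function(l, t) c(l, t)),
    lineages$taxon_id
  )
  root <- if (length(paths)) paths[[1]][1] else NA_character_
  if (!length(paths)) {
    out <- tibble(clade = character(), parent = character(),
                  depth = integer(), n_gxgcp = integer(),
                  n_xtcd = integer(), n_unclassified = integer(),
                  n_total = integer(), flag = character())
    return(structure(out, class = c("taxon_summary", class(out)),
                     root = root, unplaced = unplaced))
  }

  # Edge list over all clades appearing in any lineage.
  edges <- bind_rows(map(paths, function(p) {
    tibble(clade = p, parent = c(NA_character_, head(p, -1)),
           depth = seq_along(p) - 1L)
  })) |> distinct()
  conflict <- edges |> count(.data$clade) |> filter(.data$n > 1)
  if (nrow(conflict)) {
    abort(sprintf(
      "Clade name%s with conflicting parent or depth: %s (clade names must be unique across the taxonomy).",
      if (nrow(conflict) > 1) "s" else "",
      paste(conflict$clade, collapse = ", ")
    ))
  }

  tally <- function(lab) {
    counts <- setNames(rep(0L, nrow(edges)), edges$clade)
    sub <- calls[calls$label == lab, , drop = FALSE]
    if (nrow(sub)) {
      hits <- unlist(map(sub$taxon_id, function(t) paths[[t]]))
      tab <- table(hits)
      counts[names(tab)] <- as.integer(tab)
    }
    counts
  }
  out <- edges |>
    mutate(
      n_gxgcp = unname(tally("GXGCP")),
      n_xtcd = unname(tally("XTCD")),
      n_unclassified = unname(tally("UNCLASSIFIED")),
      n_total = .data$n_gxgcp + .data$n_xtcd + .data$n_unclassified,
      flag = dplyr::case_when(
        n_gxgcp > 0 & n_xtcd > 0 ~ "mixed",
        n_gxgcp > 0 ~ "GXGCP-only",
        n_xtcd > 0 ~ "XTCD-only",
        TRUE ~ "none"
      )
    ) |>
    arrange(.data$depth, .data$clade)
  structure(out, class = c("taxon_summary", class(out)),
            root = root, unplaced = unplaced)
}

#' Is a subfamily trans-kingdom?
#'
#' A subfamily is flagged trans-kingdom when it occurs under at least two
#' distinct depth-1 clades of the taxonomy (the kingdom-level children of
#' the shared root), e.g. both Bacteria and Eukaryota.
#'
#' @param summary A `taxon_summary` from [spread_by_clade()].
#' @param label `"GXGCP"` or `"XTCD"`.
#' @return `TRUE` or `FALSE`.
#' @export
trans_kingdom_flag <- function(summary, label = c("GXGCP", "XTCD")) {
  label <- match.arg(label)
  col <- c(GXGCP = "n_gxgcp", XTCD = "n_xtcd")[[label]]
  k <- summary[summary$depth == 1L, , drop = FALSE]
  sum(k[[col]] > 0) >= 2
}

#' Nest a taxon summary for JSON output
#'
#' @param summary A `taxon_summary`.
#' @return A nested list mirroring the clade tree (clade, depth, counts,
#'   flag, children), suitable for [jsonlite::write_json()].
#' @export
taxon_summary_tree <- function(summary) {
  build <- function(clade) {
    row <- summary[summary$clade == clade, , drop = FALSE]
    kids <- summary$clade[!is.na(summary$parent) & summary$parent == clade]
    list(
      clade = clade,
      depth = row$depth,
      n_gxgcp = row$n_gxgcp,
      n_xtcd = row$n_xtcd,
      n_unclassified = row$n_unclassified,
      n_total = row$n_total,
      flag = row$flag,
      children = lapply(kids, build)
    )
  }
  root <- attr(summary, "root")
  if (is.na(root)) return(list())
  build(root)
}
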
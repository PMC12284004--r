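# Rule-based classification of mature CSab peptides into the two structural
# subfamilies:
#   GXGCP — short N-terminal loop ending Gly-aromatic-Gly immediately before
#           C1, usually with Pro at C1+1 (trans-kingdom: bacteria plus
#           ancient invertebrates and fungi);
#   XTCD  — extended N-terminal loop with Thr at C1-1 and Asp at C1+1,
#           usually followed by an aliphatic pair (eukaryote-only).
# Because only part of each subfamily carries its full motif, each label is
# scored on three votes (loop length, motif, accessory residue[s]) and
# assigned when a unique label reaches two votes.

#' Classifier configuration
#'
#' @param aromatic Residues counted as aromatic (the motif "X" in GXG).
#' @param aliphatic Residues counted as aliphatic (the XTCD accessory pair).
#' @param short_nloop_max Maximum N-loop length voting for GXGCP (default 5).
#' @param long_nloop_min Minimum N-loop length voting for XTCD (default 6).
#' @param aliphatic_offset Offsets after C1 probed for the aliphatic pair
#'   (default `c(2, 3)`, i.e. the two residues following the Asp at C1+1).
#' @param min_score Votes a label must reach to be assigned (default 2 of 3).
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(aromatic = c("F", "W", "Y", "H"),
                              aliphatic = c("A", "V", "L", "I", "M"),
                              short_nloop_max = 5L,
                              long_nloop_min = 6L,
                              aliphatic_offset = c(2L, 3L),
                              min_score = 2L) {
  if (short_nloop_max >= long_nloop_min) {
    abort("`short_nloop_max` must be < `long_nloop_min`.")
  }
  if (length(aliphatic_offset) != 2) {
    abort("`aliphatic_offset` must give two offsets after C1.")
  }
  structure(
    list(aromatic = aromatic, aliphatic = aliphatic,
         short_nloop_max = as.integer(short_nloop_max),
         long_nloop_min = as.integer(long_nloop_min),
         aliphatic_offset = as.integer(aliphatic_offset),
         min_score = as.integer(min_score)),
    class = "classifier_config"
  )
}

#' @export
print.classifier_config <- function(x, ...) {
  cat(sprintf(
    "<classifier_config> short N-loop <= %d, long >= %d; aromatic {%s}; aliphatic {%s}\n",
    x$short_nloop_max, x$long_nloop_min,
    paste(x$aromatic, collapse = ""), paste(x$aliphatic, collapse = "")
  ))
  invisible(x)
}

# residue at a 1-based position, or NA outside the sequence
res_at <- function(ch, pos) {
  ifelse(pos >= 1 & pos <= length(ch), ch[pmax(pmin(pos, length(ch)), 1)],
         NA_character_)
}

#' Classify mature peptides into GXGCP / XTCD subfamilies
#'
#' Computes, for each scaffold-bearing peptide, the motif evidence around the
#' first scaffold cysteine and scores the two subfamilies:
#'
#' * `score_gxgcp` = (N-loop short) + (G, aromatic, G at C1-3..C1-1) +
#'   (P at C1+1)
#' * `score_xtcd` = (N-loop long) + (T at C1-1 and D at C1+1) +
#'   (aliphatic pair at the configured offsets)
#'
#' The label is the unique score winner when it reaches `min_score`,
#' otherwise `UNCLASSIFIED`. The conserved pre-C3 histidine is reported as
#' evidence only and never votes: it holds across both subfamilies, so it
#' cannot separate them.
#'
#' @param mature A data frame with columns `id`, `mature`, `c1`..`c6` (e.g.
#'   from [trim_to_mature()]); rows with `status != "ok"` are labelled
#'   `UNCLASSIFIED` with `NA` evidence.
#' @param config A [classifier_config()].
#' @return A tibble of subfamily calls: `id`, `label`, `nloop_len`,
#'   `has_gxg`, `aromatic_x`, `has_pro`, `has_xtcd`, `has_aliphatic_pair`,
#'   `has_prec3_his`, `score_gxgcp`, `score_xtcd`, `mature_length`.
#' @examples
#' classify_subfamily(trim_to_mature(plectasin_record()))
#' @export
classify_subfamily <- function(mature, config = classifier_config()) {
  assert_peptide_tbl(mature, cols = c("id", "mature", "c1", "c3"))
  rows <- map(seq_len(nrow(mature)), function(i) {
    if ("status" %in% names(mature) && mature$status[i] != "ok") {
      return(tibble(
        id = mature$id[i], label = "UNCLASSIFIED",
        nloop_len = NA_integer_, has_gxg = NA, aromatic_x = NA_character_,
        has_pro = NA, has_xtcd = NA, has_aliphatic_pair = NA,
        has_prec3_his = NA, score_gxgcp = NA_integer_,
        score_xtcd = NA_integer_, mature_length = NA_integer_
      ))
    }
    ch <- seq_chars(mature$mature[i])
    c1 <- mature$c1[i]
    c3 <- mature$c3[i]
    nloop_len <- c1 - 1L
    r_m3 <- res_at(ch, c1 - 3L)
    r_m2 <- res_at(ch, c1 - 2L)
    r_m1 <- res_at(ch, c1 - 1L)
    r_p1 <- res_at(ch, c1 + 1L)
    has_gxg <- nloop_len >= 3L &&
      identical(r_m3, "G") && r_m2 %in% config$aromatic && identical(r_m1, "G")
    aromatic_x <- if (isTRUE(has_gxg)) r_m2 else NA_character_
    has_pro <- identical(r_p1, "P")
    has_xtcd <- identical(r_m1, "T") && identical(r_p1, "D")
    pair <- res_at(ch, c1 + config$aliphatic_offset)
    has_pair <- all(!is.na(pair)) && all(pair %in% config$aliphatic)
    his <- identical(res_at(ch, c3 - 1L), "H")
    score_g <- (nloop_len <= config$short_nloop_max) + has_gxg + has_pro
    score_x <- (nloop_len >= config$long_nloop_min) + has_xtcd + has_pair
    label <- if (score_g >= config$min_score && score_g > score_x) {
      "GXGCP"
    } else if (score_x >= config$min_score && score_x > score_g) {
      "XTCD"
    } else {
      "UNCLASSIFIED"
    }
    tibble(
      id = mature$id[i], label = label, nloop_len = nloop_len,
      has_gxg = has_gxg, aromatic_x = aromatic_x, has_pro = has_pro,
      has_xtcd = has_xtcd, has_aliphatic_pair = has_pair,
      has_prec3_his = his,
      score_gxgcp = as.integer(score_g), score_xtcd = as.integer(score_x),
      mature_length = length(ch)
    )
  })
  out <- bind_rows(rows)
  extra <- intersect(c("taxon_id"), names(mature))
  if (length(extra)) {
    out <- left_join(out, mature[c("id", extra)], by = "id")
  }
  out
}

#' Check the conserved histidine before the third cysteine
#'
#' A single conserved histidine immediately precedes the third
#' disulphide-forming cysteine within the alpha helix across both
#' subfamilies; it is reported as descriptive evidence, never used for
#' labelling.
#'
#' @param mature A data frame with columns `mature` and `c3`.
#' @return Logical vector: `TRUE` where the residue at C3-1 is histidine.
#' @export
check_prec3_his <- function(mature) {
  assert_peptide_tbl(mature, cols = c("mature", "c3"))
  map_lgl(seq_len(nrow(mature)), function(i) {
    if (is.na(mature$c3[i])) return(NA)
    identical(res_at(seq_chars(mature$mature[i]), mature$c3[i] - 1L), "H")
  })
}

#' Summarise subfamily calls
#'
#' Tabulates counts and fractions per label and, when peptide lengths are
#' available, length statistics of the underlying peptides.
#'
#' @param calls A data frame with a `label` column (e.g. from
#'   [classify_subfamily()]), optionally with `mature_length` and
#'   `has_prec3_his`.
#' @return An object of class `subfamily_summary`: a list with `by_label`
#'   (tibble: label, n, fraction in percent), `lengths` (tibble: n, min,
#'   max, mean) and `prec3_his` (tibble per label and overall: n_his, n,
#'   fraction in percent), the latter two `NULL` when the input lacks the
#'   columns.
#' @export
summarize_calls <- function(calls) {
  assert_peptide_tbl(calls, cols = "label", arg = "calls")
  levels <- c("GXGCP", "XTCD", "UNCLASSIFIED")
  total <- nrow(calls)
  by_label <- tibble(label = levels) |>
    left_join(count(calls, .data$label), by = "label") |>
    mutate(
      n = ifelse(is.na(.data$n), 0L, .data$n),
      fraction = if (total > 0) 100 * .data$n / total else 0
    )
  lengths <- NULL
  if ("mature_length" %in% names(calls) && total > 0) {
    len <- calls$mature_length[!is.na(calls$mature_length)]
    lengths <- tibble(
      n = length(len),
      min = if (length(len)) min(len) else NA_integer_,
      max = if (length(len)) max(len) else NA_integer_,
      mean = if (length(len)) mean(len) else NA_real_
    )
  }
  prec3 <- NULL
  if ("has_prec3_his" %in% names(calls) && total > 0) {
    grp <- calls |>
      filter(!is.na(.data$has_prec3_his)) |>
      group_by(.data$label) |>
      summarise(n_his = sum(.data$has_prec3_his), n = n(), .groups = "drop")
    all_row <- calls |>
      filter(!is.na(.data$has_prec3_his)) |>
      summarise(label = "ALL", n_his = sum(.data$has_prec3_his), n = n())
    prec3 <- bind_rows(grp, all_row) |>
      mutate(fraction = ifelse(.data$n > 0, 100 * .data$n_his / .data$n, 0))
  }
  structure(list(by_label = by_label, lengths = lengths, prec3_his = prec3),
            class = "subfamily_summary")
}

#' @export
print.subfamily_summary <- function(x, ...) {
  cat("<subfamily_summary>\n")
  df <- as.data.frame(x$by_label)
  df$fraction <- sprintf("%.1f%%", df$fraction)
  print(df, row.names = FALSE)
  if (!is.null(x$lengths) && x$lengths$n > 0) {
    cat(sprintf("lengths: %d-%d (mean %.1f, n=%d)\n", x$lengths$min,
                x$lengths$max, x$lengths$mean, x$lengths$n))
  }
  invisible(x)
}

#' @export
tidy.subfamily_summary <- function(x, ...) x$by_label

#' @export
glance.subfamily_summary <- function(x, ...) {
  g <- x$by_label
  tibble(
    n_total = sum(g$n),
    n_gxgcp = g$n[g$label == "GXGCP"],
    n_xtcd = g$n[g$label == "XTCD"],
    n_unclassified = g$n[g$label == "UNCLASSIFIED"],
    frac_gxgcp = g$fraction[g$label == "GXGCP"],
    frac_xtcd = g$fraction[g$label == "XTCD"],
    mean_length = if (is.null(x$lengths)) NA_real_ else x$lengths$mean
  )
}
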
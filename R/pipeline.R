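# End-to-end orchestration: read -> trim -> align -> classify -> conserve ->
# spread -> write, with a run manifest and reproducible (seeded) outputs.
# Report files carry no timestamps, so identical config + seed reproduces
# byte-identical reports.

#' Assemble a pipeline run configuration
#'
#' Collects paths and the per-stage configurations into one object. Values
#' may come from a YAML file (see `config_file`), with direct arguments
#' taking precedence over file values, and file values over defaults.
#'
#' @param input FASTA of candidate peptides (precursor or mature). `NULL`
#'   to generate a synthetic corpus instead (see `generator`).
#' @param lineage Optional lineage TSV path.
#' @param tree Optional Newick taxonomy path.
#' @param out Output directory.
#' @param reference Optional FASTA with the conservation reference peptide;
#'   defaults to the built-in plectasin record.
#' @param scaffold A [scaffold_config()].
#' @param align An [align_params()].
#' @param classifier A [classifier_config()].
#' @param generator A [generator_config()], used when `input` is `NULL`.
#' @param refset A [reference_residue_set()].
#' @param max_nloop,max_tail Maturation trim margins (see
#'   [trim_to_mature()]).
#' @param conservation Run the conservation stage? (default `TRUE`).
#' @param seed Integer seed propagated to every stochastic stage.
#' @param config_file Optional YAML file with flat keys (e.g. `seed`,
#'   `align: {gap_open: 10}`) overridden by the direct arguments.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input = NULL, lineage = NULL, tree = NULL,
                       out = tempfile("csab_run_"), reference = NULL,
                       scaffold = scaffold_config(),
                       align = align_params(),
                       classifier = classifier_config(),
                       generator = generator_config(),
                       refset = reference_residue_set(),
                       max_nloop = 12L, max_tail = 6L,
                       conservation = TRUE,
                       seed = 1L, config_file = NULL) {
  cfg <- list(
    input = input, lineage = lineage, tree = tree, out = out,
    reference = reference, scaffold = scaffold, align = align,
    classifier = classifier, generator = generator, refset = refset,
    max_nloop = as.integer(max_nloop), max_tail = as.integer(max_tail),
    conservation = isTRUE(conservation), seed = as.integer(seed)
  )
  if (!is.null(config_file)) {
    file_cfg <- yaml::read_yaml(config_file)
    supplied <- names(match.call())[-1]
    for (nm in intersect(names(file_cfg), names(cfg))) {
      # explicit argument wins; a NULL path argument counts as unset
      if (nm %in% supplied && !is.null(cfg[[nm]])) next
      val <- file_cfg[[nm]]
      cfg[[nm]] <- switch(
        nm,
        scaffold = do.call(scaffold_config, val),
        align = do.call(align_params, val),
        classifier = do.call(classifier_config, val),
        generator = do.call(generator_config, val),
        refset = do.call(reference_residue_set, val),
        seed = as.integer(val),
        max_nloop = as.integer(val),
        max_tail = as.integer(val),
        val
      )
    }
  }
  cfg$generator$seed <- cfg$seed
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> input: %s; out: %s; seed %d\n",
              x$input %||% "(synthetic corpus)", x$out, x$seed))
  invisible(x)
}

stage_abort <- function(stage, msg, ...) {
  abort(sprintf("[%s] %s", stage, sprintf(msg, ...)))
}

#' Run the full comparative analysis pipeline
#'
#' Executes read (or generate), trim, align, classify, conserve and spread,
#' writing every report into the output directory, and returns a manifest
#' of artifact paths and per-stage counts. Any stage failure aborts with a
#' message naming the stage. Stage progress and record-level exclusions are
#' appended to `run.log` in the output directory.
#'
#' @param config A [run_config()].
#' @return Invisibly, the manifest (list): `counts` (read,
#'   scaffold_accepted, excluded, calls), `artifacts` (named paths),
#'   `config` echo (seed, mode, trim margins) and `summary` (label counts).
#'   The manifest is also written as `manifest.json`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "run_config")) {
    abort("`config` must be a run_config object.")
  }
  out <- config$out
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  logf <- file.path(out, "run.log")
  cat("", file = logf)
  log_line <- function(level, msg, ...) {
    line <- sprintf("%s %s", level, sprintf(msg, ...))
    cat(line, "\n", file = logf, append = TRUE, sep = "")
    if (level == "WARNING") warn(line) else inform(line)
  }
  artifacts <- list()

  # --- read / generate ------------------------------------------------
  lineages <- NULL
  tree <- NULL
  if (is.null(config$input)) {
    log_line("INFO", "read: generating synthetic corpus (seed %d)",
             config$generator$seed)
    corpus <- generate_corpus(config$generator)
    records <- corpus$records
    lineages <- corpus$lineages
    tree <- corpus$tree
    paths <- write_corpus(corpus, file.path(out, "corpus"))
    artifacts$corpus <- paths
  } else {
    log_line("INFO", "read: %s", config$input)
    records <- tryCatch(
      read_fasta(config$input),
      error = function(e) stage_abort("read", "%s", conditionMessage(e))
    )
  }
  if (!nrow(records)) {
    stage_abort("read", "no peptide records in input.")
  }
  if (!is.null(config$lineage)) {
    lineages <- tryCatch(
      read_lineage_tsv(config$lineage),
      error = function(e) stage_abort("read", "%s", conditionMessage(e))
    )
  }
  if (!is.null(config$tree)) tree <- config$tree
  n_read <- nrow(records)

  # --- trim -----------------------------------------------------------
  mature <- tryCatch(
    trim_to_mature(records, config$scaffold, config$max_nloop,
                   config$max_tail),
    error = function(e) stage_abort("trim", "%s", conditionMessage(e))
  )
  n_ok <- sum(mature$status == "ok")
  excluded <- mature |> filter(.data$status != "ok") |>
    select("id", reason = "status")
  for (i in seq_len(nrow(excluded))) {
    log_line("WARNING", "trim: excluded %s (%s)", excluded$id[i],
             excluded$reason[i])
  }
  if (!n_ok) stage_abort("trim", "no peptide carries a valid scaffold.")
  readr::write_tsv(
    mature |> select("id", "status", "mature_start", "mature_end",
                     dplyr::all_of(paste0("c", 1:6))),
    file.path(out, "maturation.tsv"), progress = FALSE
  )
  artifacts$maturation <- file.path(out, "maturation.tsv")

  # --- reference ------------------------------------------------------
  ref <- NULL
  if (config$conservation) {
    ref_rec <- if (is.null(config$reference)) {
      plectasin_record()
    } else {
      tryCatch(read_fasta(config$reference),
               error = function(e) stage_abort("conservation", "%s",
                                               conditionMessage(e)))
    }
    ref_id <- config$refset$ref_id
    if (!ref_id %in% ref_rec$id && !ref_id %in% mature$id) {
      stage_abort("conservation",
                  "configuration: reference row \"%s\" found in neither the reference FASTA nor the corpus.",
                  ref_id)
    }
    if (!ref_id %in% mature$id) {
      ref_mat <- trim_to_mature(ref_rec[ref_rec$id == ref_id, ],
                                config$scaffold, config$max_nloop,
                                config$max_tail)
      if (ref_mat$status[1] != "ok") {
        stage_abort("conservation",
                    "configuration: reference \"%s\" carries no valid scaffold.",
                    ref_id)
      }
      mature_aln <- bind_rows(
        mature |> filter(.data$status == "ok"),
        ref_mat
      )
    } else {
      mature_aln <- mature |> filter(.data$status == "ok")
    }
  } else {
    mature_aln <- mature |> filter(.data$status == "ok")
  }

  # --- align ----------------------------------------------------------
  aln <- tryCatch(
    build_anchored_alignment(mature_aln, config$align),
    error = function(e) stage_abort("align", "%s", conditionMessage(e))
  )
  ap <- write_alignment(aln, file.path(out, "alignment"))
  artifacts$alignment <- ap$alignment_path
  artifacts$blocks <- ap$blocks_path

  # --- classify -------------------------------------------------------
  calls <- tryCatch(
    classify_subfamily(mature |> filter(.data$status == "ok"),
                       config$classifier),
    error = function(e) stage_abort("classify", "%s", conditionMessage(e))
  )
  readr::write_tsv(calls, file.path(out, "calls.tsv"), progress = FALSE)
  artifacts$calls <- file.path(out, "calls.tsv")
  summ <- summarize_calls(calls)
  jsonlite::write_json(
    list(by_label = summ$by_label, lengths = summ$lengths,
         prec3_his = summ$prec3_his),
    file.path(out, "summary.json"), auto_unbox = TRUE, digits = NA,
    null = "null", pretty = TRUE
  )
  artifacts$summary <- file.path(out, "summary.json")

  # --- conserve -------------------------------------------------------
  if (config$conservation) {
    report <- tryCatch(
      score_mechanism_residues(aln, config$refset, calls),
      error = function(e) stage_abort("conservation", "%s",
                                      conditionMessage(e))
    )
    cp <- write_conservation(report, file.path(out, "conservation"))
    artifacts$conservation <- cp
  }

  # --- spread ---------------------------------------------------------
  spread <- NULL
  if (!is.null(lineages) && "taxon_id" %in% names(calls)) {
    spread <- tryCatch(
      spread_by_clade(calls |> filter(!is.na(.data$taxon_id)), lineages),
      error = function(e) stage_abort("spread", "%s", conditionMessage(e))
    )
    readr::write_tsv(as_tibble(spread), file.path(out, "spread.tsv"),
                     progress = FALSE)
    jsonlite::write_json(
      taxon_summary_tree(spread), file.path(out, "spread.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    artifacts$spread <- file.path(out, "spread.tsv")
    artifacts$spread_json <- file.path(out, "spread.json")
    if (!is.null(tree)) {
      ann <- withCallingHandlers(
        write_tree_annotation(
          tree,
          calls |> filter(!is.na(.data$taxon_id)),
          file.path(out, "tree")
        ),
        warning = function(w) {
          cat("WARNING ", conditionMessage(w), "\n", file = logf,
              append = TRUE, sep = "")
          invokeRestart("muffleWarning")
        }
      )
      artifacts$tree <- ann$tree_path
      artifacts$tree_annotation <- ann$annotation_path
    }
  }

  # --- manifest -------------------------------------------------------
  # artifact paths are stored relative to the output directory so that two
  # runs into different directories produce byte-identical manifests
  relativize <- function(x) {
    if (is.list(x)) return(lapply(x, relativize))
    sub("^/", "", sub(normalizePath(out, winslash = "/"), "",
                      normalizePath(x, winslash = "/", mustWork = FALSE),
                      fixed = TRUE))
  }
  artifacts <- relativize(artifacts)
  manifest <- list(
    counts = list(
      read = n_read,
      scaffold_accepted = n_ok,
      excluded = n_read - n_ok,
      calls = nrow(calls)
    ),
    artifacts = artifacts,
    config = list(
      seed = config$seed,
      align_mode = config$align$mode,
      substitution_matrix = config$align$matrix,
      gap_open = config$align$gap_open,
      gap_extend = config$align$gap_extend,
      max_nloop = config$max_nloop,
      max_tail = config$max_tail,
      conservation = config$conservation
    ),
    summary = setNames(as.list(summ$by_label$n), summ$by_label$label)
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line("INFO", "done: %d read, %d accepted, %d calls", n_read, n_ok,
           nrow(calls))
  invisible(manifest)
}
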
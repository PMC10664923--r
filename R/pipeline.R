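# End-to-end pipeline: vocabulary -> cohort -> pair statistics ->
# trajectories -> clustering -> output artifacts, with a serialized run
# configuration and a machine-readable run log.

#' Assemble a run configuration
#'
#' Mirrors the command-line interface. Durations accept the compact token
#' forms (`"5Y"`, `"6M"`, `"1D"`).
#'
#' @param patient_info path to the patient CSV (`PID,SEX,BIRTH_YEAR[,TAGS]`).
#' @param diagnosis_info vocabulary source: an ICD-10 hierarchy file (XML or
#'   flat TSV), a CCSR map CSV, or `"flat"` to derive a flat vocabulary from
#'   the codes observed in the event file.
#' @param diagnoses path to the event CSV (`PID,CODE,DATE`).
#' @param output_path output directory (created; must not exist or be empty).
#' @param nofAgeGroups number of birth-year bins for matching.
#' @param minPatients minimum patient support for pairs and trajectories.
#' @param maxYears,minYears time window between consecutive events.
#' @param maxTrajectoryLength,minTrajectoryLength trajectory length bounds.
#' @param iter sampling iterations per pair.
#' @param lvl ICD hierarchy depth the analysis runs at.
#' @param pfilters patient filters (see [apply_patient_filters()]).
#' @param tfilters trajectory filters (see [apply_trajectory_filters()]).
#' @param alpha significance level.
#' @param p_adjust multiple-testing correction (`"none"`, `"BH"`,
#'   `"bonferroni"`).
#' @param inflation MCL inflation.
#' @param seed base RNG seed for the whole run.
#' @param cluster_mode `"trajectory"` (total assignment) or `"code"`
#'   (legacy event-code clustering, possibly unassigned trajectories).
#' @param emit_prefixes also report extendable intermediate-length
#'   trajectories.
#' @param exhaustive_sampling use the whole unexposed population as the
#'   comparison group (one deterministic iteration).
#' @param anchor_codes raw codes defining each patient's anchor date.
#' @param workers number of work units for the pair scan (results are
#'   independent of it).
#' @return a `run_config` list.
#' @export
run_config <- function(patient_info, diagnosis_info, diagnoses, output_path,
                       nofAgeGroups = 10L, minPatients = 100L,
                       maxYears = "5Y", minYears = "6M",
                       maxTrajectoryLength = 5L, minTrajectoryLength = 3L,
                       iter = 400L, lvl = 2L,
                       pfilters = character(0), tfilters = character(0),
                       alpha = 0.05, p_adjust = "none", inflation = 2,
                       seed = 1L, cluster_mode = c("trajectory", "code"),
                       emit_prefixes = FALSE, exhaustive_sampling = FALSE,
                       anchor_codes = c("C67", "188", "Z85.51", "V10.52"),
                       workers = 1L) {
  structure(list(
    patient_info = patient_info, diagnosis_info = diagnosis_info,
    diagnoses = diagnoses, output_path = output_path,
    nofAgeGroups = as.integer(nofAgeGroups), minPatients = as.integer(minPatients),
    maxYears = maxYears, minYears = minYears,
    maxTrajectoryLength = as.integer(maxTrajectoryLength),
    minTrajectoryLength = as.integer(minTrajectoryLength),
    iter = as.integer(iter), lvl = as.integer(lvl),
    pfilters = pfilters, tfilters = tfilters,
    alpha = alpha, p_adjust = p_adjust, inflation = inflation,
    seed = as.integer(seed), cluster_mode = match.arg(cluster_mode),
    emit_prefixes = isTRUE(emit_prefixes),
    exhaustive_sampling = isTRUE(exhaustive_sampling),
    anchor_codes = anchor_codes, workers = as.integer(workers)
  ), class = "run_config")
}

# choose and load the vocabulary for a run
.load_run_vocab <- function(config) {
  src <- config$diagnosis_info
  if (identical(src, "flat") || is.null(src) || identical(src, "")) {
    ev <- data.table::fread(config$diagnoses, header = TRUE,
                            colClasses = "character", select = "CODE")
    codes <- unique(normalize_code(ev$CODE))
    return(vocabulary_from_codes(
      codes, kinds = ifelse(startsWith(codes, "TX:"), "treatment", "diagnosis")))
  }
  head_bytes <- readChar(src, nchars = 512L, useBytes = TRUE)
  vocab <- if (grepl("^\\s*<", head_bytes)) {
    apply_default_exclusions(load_icd_hierarchy(src))
  } else if (grepl("ICD10", toupper(strsplit(head_bytes, "\n")[[1]][1]))) {
    load_ccsr_map(src)
  } else {
    apply_default_exclusions(load_icd_hierarchy(src))
  }
  # treatment codes present in the event table take part as ordinary events
  ev <- data.table::fread(config$diagnoses, header = TRUE,
                          colClasses = "character", select = "CODE")
  tx <- unique(normalize_code(ev$CODE))
  tx <- tx[startsWith(tx, "TX:")]
  if (length(tx)) vocab <- register_treatments(vocab, tx)
  vocab
}

#' Run the full trajectory-mining pipeline
#'
#' Executes vocabulary loading, cohort assembly, pair-statistics estimation,
#' pair selection, trajectory building, trajectory filtering, clustering and
#' output writing, then serializes the run configuration
#' (`run_config.json`) and a run log with the counts at every stage
#' (`run_log.json`). A failing stage aborts with the stage name and removes
#' partial outputs. Outputs contain no timestamps, so reruns with the same
#' seed are byte-identical.
#'
#' @param config a [run_config()].
#' @param quiet suppress stage progress messages (written to stderr).
#' @return invisible list with the main in-memory results (`cohort`,
#'   `pair_stats`, `selected`, `trajectories`, `clusters`, `run_log`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message("[trajmine] ", ...)
  outdir <- config$output_path
  created <- !dir.exists(outdir)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- "init"
  res <- tryCatch({
    stage <- "vocab"
    say("loading vocabulary")
    vocab <- .load_run_vocab(config)

    stage <- "cohort"
    say("reading cohort")
    patients <- read_patient_table(config$patient_info)
    cohort <- read_event_table(config$diagnoses, patients, vocab, config$lvl,
                               anchor_codes = config$anchor_codes)
    cohort <- assign_age_groups(cohort, config$nofAgeGroups)
    cohort <- apply_patient_filters(cohort, config$pfilters)

    stage <- "pairstats"
    scfg <- sampling_config(
      iterations = config$iter, min_gap = config$minYears, max_gap = config$maxYears,
      min_patients = config$minPatients, alpha = config$alpha,
      p_adjust = config$p_adjust, seed = config$seed,
      exhaustive = config$exhaustive_sampling
    )
    say("scoring candidate pairs")
    stats <- estimate_all_pairs(cohort, scfg, workers = config$workers)
    stats <- select_pairs(stats, cohort, scfg)
    selected <- stats[stats$selected == TRUE]

    stage <- "trajectories"
    say("building trajectories from ", nrow(selected), " selected pairs")
    tcfg <- trajectory_config(
      min_len = config$minTrajectoryLength, max_len = config$maxTrajectoryLength,
      min_patients = config$minPatients,
      min_gap = config$minYears, max_gap = config$maxYears,
      emit_prefixes = config$emit_prefixes
    )
    trajectories <- build_trajectories(selected, cohort, tcfg)
    trajectories <- apply_trajectory_filters(trajectories, config$tfilters, vocab)

    stage <- "clustering"
    say("clustering ", length(trajectories), " trajectories")
    clusters <- NULL
    if (length(trajectories) > 0L) {
      graph <- if (config$cluster_mode == "trajectory") {
        build_trajectory_graph(trajectories)
      } else {
        build_code_graph(trajectories, selected)
      }
      node_clusters <- mcl(graph, inflation = config$inflation)
      clusters <- assign_clusters(trajectories, node_clusters, config$cluster_mode)
    }

    stage <- "outputs"
    say("writing outputs to ", outdir)
    write_pairs_tab(selected, vocab, file.path(outdir, "pairs.tab"))
    write_trajectories_tab(trajectories, vocab, file.path(outdir, "trajectories.tab"),
                           max_len = config$maxTrajectoryLength)
    cdir <- file.path(outdir, "clusters")
    if (!is.null(clusters)) {
      write_cluster_gml(clusters, trajectories, selected, vocab, "patients", cdir,
                        cohort = cohort, min_gap = tcfg$min_gap, max_gap = tcfg$max_gap)
      write_cluster_gml(clusters, trajectories, selected, vocab, "rr", cdir)
      write_cluster_csvs(clusters, trajectories, cohort, cdir)
    }
    run_log <- list(
      n_patients = nrow(cohort$patients),
      n_events = nrow(cohort$events),
      n_codes = length(cohort$code_index),
      pairs_tested = nrow(stats),
      pairs_selected = nrow(selected),
      n_trajectories = length(trajectories),
      n_clusters = if (is.null(clusters)) 0L else length(unique(stats::na.omit(clusters$assignment))),
      unassigned_fraction = if (is.null(clusters)) NA else clusters$unassigned_fraction,
      mcl_converged = if (is.null(clusters)) NA else clusters$converged,
      event_row_counters = cohort$counters
    )
    jsonlite::write_json(run_log, file.path(outdir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    cfg_out <- unclass(config)
    jsonlite::write_json(cfg_out, file.path(outdir, "run_config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(cohort = cohort, vocab = vocab, pair_stats = stats, selected = selected,
         trajectories = trajectories, clusters = clusters, run_log = run_log)
  }, error = function(e) {
    if (created) unlink(outdir, recursive = TRUE)
    .fail("pipeline failed at stage '", stage, "': ", conditionMessage(e))
  })
  invisible(res)
}
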
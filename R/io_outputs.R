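# Result writers and their round-trip readers: pair and trajectory .tab
# tables, per-cluster GML graphs in two annotation modes, cluster CSVs.

#' Write the selected-pair table
#'
#' Tab-separated, one row per selected pair:
#' `A_code A_name B_code B_name N_exposed N_AB RR P DIRECTION_P`,
#' sorted by `(A_code, B_code)`.
#'
#' @param pairs selected-pair table (rows of [select_pairs()] output).
#' @param vocab a `traj_vocab` supplying display names.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_pairs_tab <- function(pairs, vocab, path) {
  out <- data.table::data.table(
    A_code = pairs$a, A_name = code_name(vocab, pairs$a),
    B_code = pairs$b, B_name = code_name(vocab, pairs$b),
    N_exposed = pairs$n_exposed, N_AB = pairs$n_ab,
    RR = pairs$rr, P = pairs$p_value,
    DIRECTION_P = if ("direction_p" %in% names(pairs)) pairs$direction_p else NA_real_
  )
  data.table::setorderv(out, c("A_code", "B_code"))
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a pair table written by [write_pairs_tab()]
#' @param path file path.
#' @return a `data.table` with the written columns.
#' @export
read_pairs_tab <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA")
}

#' Write the trajectory table
#'
#' Tab-separated, one row per trajectory:
#' `TID LENGTH SUPPORT CODE_1..CODE_k NAME_1..NAME_k RR_1..RR_{k-1}`, with
#' code/name/RR columns padded to the configured maximum length.
#'
#' @param trajectories a `traj_set`.
#' @param vocab a `traj_vocab` supplying display names.
#' @param path output file path.
#' @param max_len column padding width (default: longest trajectory).
#' @return the path, invisibly.
#' @export
write_trajectories_tab <- function(trajectories, vocab, path, max_len = NULL) {
  if (is.null(max_len)) {
    max_len <- if (length(trajectories)) {
      max(vapply(trajectories, function(t) length(t$codes), integer(1)))
    } else 2L
  }
  rows <- lapply(trajectories, function(t) {
    k <- length(t$codes)
    pad <- function(x, n) c(x, rep(NA, n - length(x)))
    c(list(TID = t$tid, LENGTH = k, SUPPORT = t$support),
      stats::setNames(as.list(pad(t$codes, max_len)), paste0("CODE_", seq_len(max_len))),
      stats::setNames(as.list(pad(code_name(vocab, t$codes), max_len)),
                      paste0("NAME_", seq_len(max_len))),
      stats::setNames(as.list(pad(t$transition_rr, max_len - 1L)),
                      paste0("RR_", seq_len(max_len - 1L))))
  })
  out <- if (length(rows)) {
    data.table::rbindlist(rows)
  } else {
    cols <- c("TID", "LENGTH", "SUPPORT", paste0("CODE_", seq_len(max_len)),
              paste0("NAME_", seq_len(max_len)), paste0("RR_", seq_len(max_len - 1L)))
    data.table::setnames(data.table::as.data.table(
      lapply(cols, function(x) logical(0))), cols)
  }
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a trajectory table written by [write_trajectories_tab()]
#' @param path file path.
#' @return a `traj_set` (supporter sets are not stored in the file and come
#'   back empty).
#' @export
read_trajectories_tab <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA")
  code_cols <- grep("^CODE_", names(dt), value = TRUE)
  rr_cols <- grep("^RR_", names(dt), value = TRUE)
  trajs <- lapply(seq_len(nrow(dt)), function(i) {
    codes <- as.character(unlist(dt[i, code_cols, with = FALSE]))
    codes <- codes[!is.na(codes)]
    rr <- as.numeric(unlist(dt[i, rr_cols, with = FALSE]))
    rr <- rr[!is.na(rr)]
    list(tid = dt$TID[i], codes = codes, support = dt$SUPPORT[i],
         supporters = integer(0), transition_rr = rr)
  })
  .new_traj_set(trajs)
}

.gml_escape <- function(x) gsub('"', "'", x)

# serialize one graph to GML text
.gml_text <- function(node_labels, edges) {
  lines <- c("graph [", "  directed 1")
  for (i in seq_along(node_labels)) {
    lines <- c(lines,
               "  node [",
               sprintf("    id %d", i - 1L),
               sprintf('    label "%s"', .gml_escape(node_labels[i])),
               "  ]")
  }
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      lines <- c(lines,
                 "  edge [",
                 sprintf("    source %d", edges$source[i]),
                 sprintf("    target %d", edges$target[i]),
                 sprintf('    label "%s"', .gml_escape(edges$label[i])),
                 "  ]")
    }
  }
  c(lines, "]")
}

#' Write per-cluster GML graphs
#'
#' One `.gml` file per cluster per annotation mode, named
#' `cluster_<k>_<mode>.gml`. Nodes are the distinct codes of the cluster's
#' member trajectories (labelled with their vocabulary names); edges are
#' consecutive-code transitions. In `"patients"` mode each member trajectory
#' contributes its own edges, labelled with the number of patients following
#' the trajectory up to and including that transition (prefix support, when
#' a cohort is supplied; otherwise the trajectory's full support). In
#' `"rr"` mode parallel edges are merged per code pair and labelled with the
#' selected pair's relative risk.
#'
#' @param clusterset a trajectory-level `cluster_set` from
#'   [assign_clusters()].
#' @param trajectories the clustered `traj_set`.
#' @param selected selected-pair table (for RR labels).
#' @param vocab a `traj_vocab` supplying node labels.
#' @param mode `"patients"` or `"rr"`.
#' @param dir output directory (created if needed).
#' @param cohort optional `traj_cohort` for prefix-support labels.
#' @param min_gap,max_gap window (days) used for prefix supports.
#' @return character vector of written paths, invisibly.
#' @export
write_cluster_gml <- function(clusterset, trajectories, selected, vocab,
                              mode = c("patients", "rr"), dir,
                              cohort = NULL, min_gap = NULL, max_gap = NULL) {
  mode <- match.arg(mode)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rr_of <- stats::setNames(selected$rr, paste(selected$a, selected$b, sep = "\r"))
  by_tid <- stats::setNames(trajectories, vapply(trajectories, function(t) as.character(t$tid), character(1)))
  paths <- character(0)
  labels <- sort(unique(clusterset$assignment))
  labels <- labels[!is.na(labels)]
  for (k in labels) {
    tids <- names(clusterset$assignment)[!is.na(clusterset$assignment) & clusterset$assignment == k]
    member <- by_tid[tids]
    codes <- sort(unique(unlist(lapply(member, `[[`, "codes"))))
    idx <- stats::setNames(seq_along(codes) - 1L, codes)
    src <- integer(0); tgt <- integer(0); lab <- character(0)
    for (t in member) {
      kk <- length(t$codes)
      for (i in seq_len(kk - 1L)) {
        a <- t$codes[i]; b <- t$codes[i + 1L]
        l <- if (mode == "patients") {
          n <- if (!is.null(cohort)) {
            support_count(cohort, t$codes[seq_len(i + 1L)], min_gap, max_gap)$count
          } else {
            t$support
          }
          as.character(n)
        } else {
          format(unname(rr_of[paste(a, b, sep = "\r")]), digits = 6)
        }
        src <- c(src, idx[[a]]); tgt <- c(tgt, idx[[b]]); lab <- c(lab, l)
      }
    }
    edges <- data.table::data.table(source = src, target = tgt, label = lab)
    if (mode == "rr" && nrow(edges)) {
      edges <- unique(edges, by = c("source", "target"))
    }
    path <- file.path(dir, sprintf("cluster_%d_%s.gml", k, mode))
    writeLines(.gml_text(code_name(vocab, codes), edges), path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Write cluster CSV files
#'
#' Three CSVs: `clusters.csv` (`TID,CLUSTER,SUPPORT,CODES` with codes joined
#' by `>`), `patients.csv` (one row per patient-trajectory membership:
#' `PID,TID,CLUSTER,SEX,AGE_AT_ANCHOR`), and `cluster_summary.csv`
#' (`CLUSTER,N_TRAJECTORIES,N_PATIENTS,PCT_FEMALE,MEAN_AGE_AT_ANCHOR`,
#' computed over the distinct patients supporting each cluster).
#'
#' @param clusterset a trajectory-level `cluster_set`.
#' @param trajectories the clustered `traj_set` (with supporter sets).
#' @param cohort the `traj_cohort` (for sex and age at anchor).
#' @param dir output directory.
#' @return character vector of written paths, invisibly.
#' @export
write_cluster_csvs <- function(clusterset, trajectories, cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  assn <- clusterset$assignment
  cl <- data.table::data.table(
    TID = vapply(trajectories, `[[`, integer(1), "tid"),
    CLUSTER = unname(assn[vapply(trajectories, function(t) as.character(t$tid), character(1))]),
    SUPPORT = vapply(trajectories, `[[`, integer(1), "support"),
    CODES = vapply(trajectories, function(t) paste(t$codes, collapse = ">"), character(1))
  )
  data.table::setorderv(cl, "TID")
  age <- age_at_anchor(cohort)
  pp <- data.table::rbindlist(lapply(trajectories, function(t) {
    data.table::data.table(
      PID = cohort$patients$pid[t$supporters],
      TID = t$tid,
      CLUSTER = unname(assn[as.character(t$tid)]),
      SEX = cohort$patients$sex[t$supporters],
      AGE_AT_ANCHOR = age[t$supporters]
    )
  }))
  if (nrow(pp)) data.table::setorderv(pp, c("CLUSTER", "TID", "PID"))
  summ <- if (nrow(pp)) {
    u <- unique(pp, by = c("CLUSTER", "PID"))
    s <- u[, list(
      N_PATIENTS = .N,
      PCT_FEMALE = 100 * mean(SEX == "female"),
      MEAN_AGE_AT_ANCHOR = mean(AGE_AT_ANCHOR, na.rm = TRUE)
    ), by = "CLUSTER"]
    nt <- cl[!is.na(CLUSTER), list(N_TRAJECTORIES = .N), by = "CLUSTER"]
    out <- merge(nt, s, by = "CLUSTER", all = TRUE)
    data.table::setorderv(out, "CLUSTER")
    out
  } else {
    data.table::data.table(CLUSTER = integer(0), N_TRAJECTORIES = integer(0),
                           N_PATIENTS = integer(0), PCT_FEMALE = numeric(0),
                           MEAN_AGE_AT_ANCHOR = numeric(0))
  }
  paths <- file.path(dir, c("clusters.csv", "patients.csv", "cluster_summary.csv"))
  data.table::fwrite(cl, paths[1], na = "NA", quote = FALSE)
  data.table::fwrite(pp, paths[2], na = "NA", quote = FALSE)
  data.table::fwrite(summ, paths[3], na = "NA", quote = FALSE)
  invisible(paths)
}
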
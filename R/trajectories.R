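# Chaining selected pairs into bounded-length trajectories under
# patient-support and time-window constraints, plus trajectory-level output
# filters.

#' Trajectory construction configuration
#'
#' @param min_len,max_len trajectory length bounds (codes), `2 <= min <= max`.
#' @param min_patients minimum support for every extension step.
#' @param min_gap,max_gap per-transition time window (see [parse_duration()]).
#' @param emit_prefixes if `TRUE`, extendable partial trajectories of length
#'   `>= min_len` are reported alongside maximal ones; by default only
#'   trajectories that cannot be extended further (or hit `max_len`) are
#'   emitted.
#' @return a `trajectory_config` list.
#' @export
trajectory_config <- function(min_len = 3L, max_len = 5L, min_patients = 100L,
                              min_gap = "6M", max_gap = "5Y",
                              emit_prefixes = FALSE) {
  min_gap <- parse_duration(min_gap)
  max_gap <- parse_duration(max_gap)
  stopifnot(.is_count(min_len, 2L), .is_count(max_len, 2L), min_len <= max_len,
            .is_count(min_patients), min_gap >= 0L, min_gap <= max_gap)
  structure(list(
    min_len = as.integer(min_len), max_len = as.integer(max_len),
    min_patients = as.integer(min_patients),
    min_gap = min_gap, max_gap = max_gap,
    emit_prefixes = isTRUE(emit_prefixes)
  ), class = "trajectory_config")
}

#' Count the patients following a full code sequence
#'
#' A patient supports the sequence iff, using the single first-occurrence
#' date of each code, consecutive dates are strictly increasing and every
#' consecutive difference lies in `[min_gap, max_gap]`.
#'
#' @param cohort a `traj_cohort`.
#' @param codes ordered, distinct analysis-level codes (length >= 2).
#' @param min_gap,max_gap window in days.
#' @return list with `count` and `supporters` (patient indices).
#' @export
support_count <- function(cohort, codes, min_gap, max_gap) {
  stopifnot(length(codes) >= 2L, !anyDuplicated(codes))
  ok <- rep(TRUE, nrow(cohort$patients))
  prev <- .code_day_vector(cohort, codes[1])
  for (i in 2:length(codes)) {
    cur <- .code_day_vector(cohort, codes[i])
    d <- cur - prev
    ok <- ok & !is.na(d) & d > 0L & d >= min_gap & d <= max_gap
    prev <- cur
  }
  sup <- which(ok)
  list(count = length(sup), supporters = sup)
}

.new_traj_set <- function(trajs) {
  structure(trajs, class = "traj_set")
}

#' @export
print.traj_set <- function(x, ...) {
  cat(sprintf("<traj_set> %d trajectories\n", length(x)))
  for (t in utils::head(x, 10)) {
    cat(sprintf("  #%d %s (support %d)\n", t$tid, paste(t$codes, collapse = " > "), t$support))
  }
  if (length(x) > 10) cat("  ...\n")
  invisible(x)
}

#' Build trajectories by chaining selected pairs
#'
#' Worklist algorithm: every selected pair seeds a partial trajectory; a
#' partial ending in `Y` is extended (copy-on-extend, so one partial can grow
#' multiple ways) with every selected pair `(Y, Z)` whose `Z` is not yet in
#' the sequence, provided the extended sequence keeps at least
#' `min_patients` supporters and stays within `max_len`. A partial is
#' finalized when no extension succeeds or it reaches `max_len`; finalized
#' sequences shorter than `min_len` are discarded. Output is deduplicated on
#' the code sequence, sorted lexicographically, and numbered 1..n, making the
#' result independent of worklist processing order.
#'
#' Supporter sets shrink monotonically along extensions (each step
#' intersects the current supporters with the patients making the new
#' transition), which is both the pruning device and the correctness
#' argument for support anti-monotonicity.
#'
#' @param selected a selected-pair table (columns `a`, `b`, `rr`), e.g.
#'   `select_pairs(...)[selected == TRUE]`.
#' @param cohort a `traj_cohort`.
#' @param config a [trajectory_config()].
#' @return a `traj_set`: list of trajectories, each with `tid`, `codes`,
#'   `support`, `supporters`, `transition_rr`.
#' @export
build_trajectories <- function(selected, cohort, config) {
  stopifnot(inherits(cohort, "traj_cohort"), inherits(config, "trajectory_config"))
  if (nrow(selected) == 0L) return(.new_traj_set(list()))
  rr_of <- stats::setNames(selected$rr, paste(selected$a, selected$b, sep = "\r"))
  adj <- split(selected$b, selected$a)
  dayvec <- new.env(parent = emptyenv())
  dv <- function(code) {
    if (is.null(dayvec[[code]])) dayvec[[code]] <- .code_day_vector(cohort, code)
    dayvec[[code]]
  }
  emit <- new.env(parent = emptyenv())
  emit_seq <- function(codes, supporters) {
    key <- paste(codes, collapse = "\r")
    if (is.null(emit[[key]])) emit[[key]] <- supporters
  }
  # stack entries: list(codes, supporters)
  stack <- vector("list", nrow(selected))
  for (i in seq_len(nrow(selected))) {
    s <- support_count(cohort, c(selected$a[i], selected$b[i]),
                       config$min_gap, config$max_gap)
    stack[[i]] <- list(codes = c(selected$a[i], selected$b[i]), supporters = s$supporters)
  }
  while (length(stack)) {
    t <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    len <- length(t$codes)
    if (config$emit_prefixes && len >= config$min_len) emit_seq(t$codes, t$supporters)
    if (len == config$max_len) {
      if (!config$emit_prefixes && len >= config$min_len) emit_seq(t$codes, t$supporters)
      next
    }
    last <- t$codes[len]
    extended <- FALSE
    last_day <- dv(last)
    for (z in adj[[last]]) {
      if (z %in% t$codes) next
      d <- dv(z)[t$supporters] - last_day[t$supporters]
      sup2 <- t$supporters[!is.na(d) & d > 0L & d >= config$min_gap & d <= config$max_gap]
      stopifnot(length(sup2) <= length(t$supporters)) # anti-monotonicity
      if (length(sup2) >= config$min_patients) {
        extended <- TRUE
        stack[[length(stack) + 1L]] <- list(codes = c(t$codes, z), supporters = sup2)
      }
    }
    if (!extended && !config$emit_prefixes && len >= config$min_len) {
      emit_seq(t$codes, t$supporters)
    }
  }
  keys <- sort(ls(emit), method = "radix")
  trajs <- vector("list", length(keys))
  for (i in seq_along(keys)) {
    codes <- strsplit(keys[i], "\r", fixed = TRUE)[[1]]
    sup <- emit[[keys[i]]]
    trr <- unname(rr_of[paste(codes[-length(codes)], codes[-1], sep = "\r")])
    trajs[[i]] <- list(tid = i, codes = codes, support = length(sup),
                       supporters = sup, transition_rr = trr)
  }
  .new_traj_set(trajs)
}

# code sets for the registered trajectory filters
.trajectory_filter_set <- function(vocab, name,
                                   bc_icd = c("C67", "C77", "C78", "C79")) {
  all_codes <- vocab$codes$code
  tx <- all_codes[vocab$codes$kind == "treatment"]
  bc_tx <- tx[grepl("CYSTECTOMY|MVAC|INTRAVESICAL|BCG", tx)]
  if (name == "bc") {
    icd_members <- all_codes[Reduce(`|`, lapply(bc_icd, function(p) startsWith(all_codes, p)))]
    ccsr_members <- if (!is.null(vocab$ccsr_map)) {
      keys <- names(vocab$ccsr_map)
      unname(vocab$ccsr_map[Reduce(`|`, lapply(bc_icd, function(p) startsWith(keys, p)))])
    } else {
      character(0)
    }
    unique(c(bc_icd, icd_members, ccsr_members, bc_tx))
  } else if (name == "neoplasm") {
    neo <- grepl("^C|^D[0-4]", all_codes) | startsWith(all_codes, "NEO")
    if (!is.null(vocab$ccsr_map)) {
      keys <- names(vocab$ccsr_map)
      neo_cat <- unname(vocab$ccsr_map[grepl("^C|^D[0-4]", keys)])
      unique(c(all_codes[neo], neo_cat))
    } else {
      all_codes[neo]
    }
  } else {
    .fail("unknown trajectory filter '", name, "'; registered: bc, neoplasm")
  }
}

#' Filter trajectories by event-code membership
#'
#' Keeps trajectories containing at least one code from each named filter's
#' code set. Registered filters: `"bc"` (bladder-cancer related: ICD-10
#' C67/C77/C78/C79 and their descendants or CCSR equivalents, plus
#' registered bladder-cancer treatment codes such as radical cystectomy,
#' MVAC chemotherapy and intravesical therapy) and `"neoplasm"` (any code in
#' the neoplasm chapter C00-D48 or a NEO* CCSR category). An empty filter
#' list is the identity.
#'
#' @param trajectories a `traj_set`.
#' @param filters character vector of filter names.
#' @param vocab the `traj_vocab` in use (defines the code sets).
#' @return the filtered `traj_set` (original `tid`s preserved).
#' @export
apply_trajectory_filters <- function(trajectories, filters, vocab) {
  stopifnot(inherits(trajectories, "traj_set"))
  if (length(filters) == 0L) return(trajectories)
  sets <- lapply(filters, function(f) .trajectory_filter_set(vocab, f))
  keep <- vapply(trajectories, function(t) {
    all(vapply(sets, function(s) any(t$codes %in% s), logical(1)))
  }, logical(1))
  .new_traj_set(unclass(trajectories)[keep])
}
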
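# Synthetic cohort generator: demographic structure, Poisson background
# diagnoses (optionally age-linked), planted causal chains with configurable
# penetrance and gap distributions, plus the analytic ground-truth manifest.

#' Define a planted causal chain
#'
#' Carriers enrolled in the chain receive the first code at a random onset
#' date; each subsequent code follows with probability `penetrance` after a
#' gap drawn uniformly from `gap_range` days (progression stops at the first
#' failed transition). Choosing a `gap_range` inside the analysis window
#' makes the chain recoverable; choosing one outside makes a negative
#' control.
#'
#' @param codes ordered event codes (length >= 2), disjoint from the
#'   background code list.
#' @param penetrance per-transition progression probability in (0, 1]
#'   (scalar or one value per transition).
#' @param gap_range integer day range `c(lo, hi)` per transition (or a
#'   2-column matrix, one row per transition).
#' @param carrier_fraction fraction of the cohort enrolled.
#' @return a `planted_chain` list.
#' @export
planted_chain <- function(codes, penetrance, gap_range, carrier_fraction) {
  stopifnot(length(codes) >= 2L, !anyDuplicated(codes),
            all(penetrance > 0), all(penetrance <= 1),
            carrier_fraction >= 0, carrier_fraction <= 1)
  k <- length(codes) - 1L
  pen <- rep_len(penetrance, k)
  gr <- if (is.matrix(gap_range)) gap_range else matrix(gap_range, nrow = k, ncol = 2, byrow = TRUE)
  stopifnot(nrow(gr) == k, all(gr[, 1] <= gr[, 2]), all(gr[, 1] >= 0))
  structure(list(codes = normalize_code(codes), penetrance = pen,
                 gap_range = gr, carrier_fraction = carrier_fraction),
            class = "planted_chain")
}

#' Simulation configuration for a synthetic cohort
#'
#' @param n_patients cohort size.
#' @param sex_ratio fraction female.
#' @param birth_year_range inclusive integer range of birth years.
#' @param background_codes data frame with columns `code`, `hazard`
#'   (expected events per patient-year) and optionally `age_slope`: the
#'   per-patient rate is `hazard * exp(age_slope * (age_mid - 70)/10)` with
#'   `age_mid` the patient's age at the middle of the observation window, so
#'   positive slopes make a code age-linked through the birth cohort (for
#'   confounding studies).
#' @param chains list of [planted_chain()] objects.
#' @param anchor_code cohort-defining code given to every patient (emulating
#'   an anchor diagnosis every cohort member carries).
#' @param observe_start,observe_end observation window (ISO dates).
#' @param anchor_span_days anchor dates are uniform over the first this-many
#'   days of the window; chain onsets over the first half of the window.
#' @param seed RNG seed; generation is fully deterministic given the config.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_patients, sex_ratio = 0.5,
                       birth_year_range = c(1930L, 1980L),
                       background_codes = NULL, chains = list(),
                       anchor_code = "C67",
                       observe_start = "2005-01-01", observe_end = "2020-12-31",
                       anchor_span_days = 730L, seed = 1L) {
  stopifnot(.is_count(n_patients), sex_ratio >= 0, sex_ratio <= 1)
  if (is.null(background_codes)) {
    background_codes <- data.frame(code = character(0), hazard = numeric(0),
                                   age_slope = numeric(0))
  }
  background_codes <- as.data.frame(background_codes)
  if (!"age_slope" %in% names(background_codes)) {
    background_codes$age_slope <- rep(0, nrow(background_codes))
  }
  stopifnot(all(background_codes$hazard >= 0))
  bg <- normalize_code(background_codes$code)
  chain_codes <- unlist(lapply(chains, `[[`, "codes"))
  if (length(background_codes$code) + length(chain_codes) == 0L) {
    .fail("simulation config has no event codes")
  }
  if (any(chain_codes %in% bg)) {
    .fail("chain codes must be disjoint from background codes: ",
          paste(intersect(chain_codes, bg), collapse = ", "))
  }
  background_codes$code <- bg
  structure(list(
    n_patients = as.integer(n_patients), sex_ratio = sex_ratio,
    birth_year_range = as.integer(birth_year_range),
    background_codes = background_codes, chains = chains,
    anchor_code = normalize_code(anchor_code),
    observe_start = data.table::as.IDate(observe_start),
    observe_end = data.table::as.IDate(observe_end),
    anchor_span_days = as.integer(anchor_span_days),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' All event codes a simulated cohort can carry
#' @param config a `sim_config`.
#' @return character vector: anchor, background and chain codes.
#' @export
synth_codes <- function(config) {
  unique(c(config$anchor_code, config$background_codes$code,
           unlist(lapply(config$chains, `[[`, "codes"))))
}

#' Flat vocabulary covering a simulated cohort
#' @param config a `sim_config`.
#' @return a `traj_vocab` in flat mode (treatment kind inferred from the
#'   `TX:` prefix).
#' @export
synth_vocabulary <- function(config) {
  codes <- synth_codes(config)
  vocabulary_from_codes(codes, kinds = ifelse(startsWith(codes, "TX:"), "treatment", "diagnosis"))
}

#' Generate a synthetic cohort
#'
#' Draws demographics, the anchor event, Poisson background events per
#' patient-code (count `~ Poisson(rate * years)`, dates uniform in the
#' window) and planted-chain events, and returns the patient and event
#' tables in exactly the CSV dialect the cohort readers consume. Byte-level
#' deterministic under `config$seed`.
#'
#' @param config a [sim_config()].
#' @param dir optional directory; when given, writes `patients.csv`,
#'   `events.csv` and `manifest.json` there.
#' @param min_gap,max_gap analysis window used to annotate the manifest (day
#'   counts or duration tokens).
#' @param min_patients support threshold used for the manifest's
#'   recoverability flags.
#' @return invisible list with `patients`, `events` (data.tables) and
#'   `manifest` (see [expected_truth()]).
#' @export
generate_cohort <- function(config, dir = NULL, min_gap = "6M", max_gap = "5Y",
                            min_patients = 100L) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_patients
  start <- as.integer(config$observe_start)
  end <- as.integer(config$observe_end)
  years <- (end - start + 1) / 365.25
  out <- .with_seed(config$seed, {
    sex <- ifelse(stats::runif(n) < config$sex_ratio, "F", "M")
    by <- sample(seq(config$birth_year_range[1], config$birth_year_range[2]), n, replace = TRUE)
    pid <- sprintf("P%06d", seq_len(n))
    anchor_day <- start + sample.int(config$anchor_span_days, n, replace = TRUE) - 1L
    mid_year <- data.table::year(data.table::as.IDate((start + end) %/% 2L))
    age_mid <- mid_year - by

    ev_pid <- list(pid); ev_code <- list(rep(config$anchor_code, n)); ev_day <- list(anchor_day)
    add <- function(p, c_, d) {
      k <- length(ev_pid) + 1L
      ev_pid[[k]] <<- p; ev_code[[k]] <<- c_; ev_day[[k]] <<- d
    }
    for (r in seq_len(nrow(config$background_codes))) {
      code <- config$background_codes$code[r]
      rate <- config$background_codes$hazard[r] *
        exp(config$background_codes$age_slope[r] * (age_mid - 70) / 10)
      k <- stats::rpois(n, rate * years)
      tot <- sum(k)
      if (tot == 0L) next
      who <- rep.int(seq_len(n), k)
      add(pid[who], rep(code, tot), start + sample.int(end - start + 1L, tot, replace = TRUE) - 1L)
    }
    for (ch in config$chains) {
      carrier <- which(stats::runif(n) < ch$carrier_fraction)
      if (length(carrier) == 0L) next
      span <- max(1L, as.integer(floor((end - start) / 2)))
      t <- start + sample.int(span, length(carrier), replace = TRUE) - 1L
      alive <- rep(TRUE, length(carrier))
      add(pid[carrier], rep(ch$codes[1], length(carrier)), t)
      for (j in seq_along(ch$penetrance)) {
        go <- alive & (stats::runif(length(carrier)) < ch$penetrance[j])
        lo <- ch$gap_range[j, 1]; hi <- ch$gap_range[j, 2]
        gap <- lo + sample.int(hi - lo + 1L, length(carrier), replace = TRUE) - 1L
        t <- t + gap
        if (any(go)) add(pid[carrier[go]], rep(ch$codes[j + 1L], sum(go)), t[go])
        alive <- go
      }
    }
    events <- data.table::data.table(
      PID = unlist(ev_pid), CODE = unlist(ev_code),
      DATE = as.character(data.table::as.IDate(unlist(ev_day)))
    )
    data.table::setorderv(events, c("PID", "DATE", "CODE"))
    patients <- data.table::data.table(PID = pid, SEX = sex, BIRTH_YEAR = by, TAGS = "")
    list(patients = patients, events = events)
  })
  manifest <- expected_truth(config, min_gap = min_gap, max_gap = max_gap,
                             min_patients = min_patients)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(out$patients, file.path(dir, "patients.csv"))
    data.table::fwrite(out$events, file.path(dir, "events.csv"))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(patients = out$patients, events = out$events, manifest = manifest))
}

# fraction of a discrete uniform [lo, hi] falling inside [wmin, wmax]
.window_fraction <- function(lo, hi, wmin, wmax) {
  inside <- max(0L, min(hi, wmax) - max(lo, wmin) + 1L)
  inside / (hi - lo + 1L)
}

#' Analytic ground truth for a simulation config
#'
#' Lists every planted consecutive pair and full chain with its expected
#' supporter count and a recoverability verdict under the given analysis
#' window and support threshold: a transition whose gap distribution falls
#' (partly) outside `[min_gap, max_gap]` loses the corresponding fraction of
#' supporters, and anything with expected support below `min_patients` is
#' marked not recoverable.
#'
#' @param config a [sim_config()].
#' @param min_gap,max_gap analysis window (day counts or duration tokens).
#' @param min_patients support threshold for recoverability.
#' @return list with `pairs` and `chains` data frames and the generation
#'   parameters.
#' @export
expected_truth <- function(config, min_gap = "6M", max_gap = "5Y", min_patients = 100L) {
  stopifnot(inherits(config, "sim_config"))
  min_gap <- parse_duration(min_gap); max_gap <- parse_duration(max_gap)
  pr <- list(); cr <- list()
  for (ci in seq_along(config$chains)) {
    ch <- config$chains[[ci]]
    k <- length(ch$penetrance)
    reach <- config$n_patients * ch$carrier_fraction # expected carriers at code 1
    chain_frac <- 1
    for (j in seq_len(k)) {
      wf <- .window_fraction(ch$gap_range[j, 1], ch$gap_range[j, 2], min_gap, max_gap)
      pair_support <- reach * ch$penetrance[j] * wf
      pr[[length(pr) + 1L]] <- data.frame(
        chain = ci, a = ch$codes[j], b = ch$codes[j + 1L],
        expected_support = pair_support,
        window_fraction = wf,
        recoverable = wf > 0 && pair_support >= min_patients
      )
      reach <- reach * ch$penetrance[j]
      chain_frac <- chain_frac * ch$penetrance[j] * wf
    }
    exp_chain <- config$n_patients * ch$carrier_fraction * chain_frac
    cr[[length(cr) + 1L]] <- data.frame(
      chain = ci, codes = paste(ch$codes, collapse = ">"),
      expected_support = exp_chain,
      recoverable = exp_chain >= min_patients &&
        all(vapply(seq_len(k), function(j) {
          .window_fraction(ch$gap_range[j, 1], ch$gap_range[j, 2], min_gap, max_gap) > 0
        }, logical(1)))
    )
  }
  list(
    n_patients = config$n_patients, seed = config$seed,
    anchor_code = config$anchor_code,
    min_gap = min_gap, max_gap = max_gap, min_patients = as.integer(min_patients),
    pairs = if (length(pr)) do.call(rbind, pr) else
      data.frame(chain = integer(0), a = character(0), b = character(0),
                 expected_support = numeric(0), window_fraction = numeric(0),
                 recoverable = logical(0)),
    chains = if (length(cr)) do.call(rbind, cr) else
      data.frame(chain = integer(0), codes = character(0),
                 expected_support = numeric(0), recoverable = logical(0))
  )
}

#' Score pipeline output against the planted truth
#'
#' A recoverable planted chain counts as recovered when its code sequence
#' appears as a contiguous subsequence of some reported trajectory; a
#' planted pair is reversed when the selected-pair table contains its
#' reverse orientation.
#'
#' @param trajectories a `traj_set` (pipeline output).
#' @param selected selected-pair table (rows with `selected == TRUE` or any
#'   table with columns `a`, `b`).
#' @param manifest an [expected_truth()] manifest.
#' @return list with `n_recoverable`, `n_recovered`, `recovery_rate`,
#'   `n_reversed_pairs`.
#' @export
evaluate_recovery <- function(trajectories, selected, manifest) {
  seqs <- lapply(trajectories, `[[`, "codes")
  contains <- function(seq, sub) {
    k <- length(sub); n <- length(seq)
    if (k > n) return(FALSE)
    any(vapply(seq_len(n - k + 1L), function(i) all(seq[i:(i + k - 1L)] == sub), logical(1)))
  }
  chains <- manifest$chains[manifest$chains$recoverable, , drop = FALSE]
  rec <- vapply(chains$codes, function(cs) {
    sub <- strsplit(cs, ">", fixed = TRUE)[[1]]
    any(vapply(seqs, contains, logical(1), sub = sub))
  }, logical(1))
  sel_keys <- paste(selected$a, selected$b, sep = "\r")
  rev_keys <- paste(manifest$pairs$b, manifest$pairs$a, sep = "\r")
  list(
    n_recoverable = nrow(chains),
    n_recovered = sum(rec),
    recovery_rate = if (nrow(chains)) mean(rec) else NA_real_,
    n_reversed_pairs = sum(rev_keys %in% sel_keys)
  )
}
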
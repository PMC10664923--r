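# Cohort construction: patient/event table readers, history normalization
# (level mapping, exclusion, first-occurrence dedup, date sort), demographic
# strata and patient-level filters.

.SEX_MAP <- c(
  "f" = "female", "female" = "female", "2" = "female",
  "m" = "male", "male" = "male", "1" = "male"
)

#' Read a patient information table
#'
#' Expects a delimited file (or an equivalent data frame) with header
#' `PID,SEX,BIRTH_YEAR` and an optional `TAGS` column holding
#' semicolon-separated labels (e.g. disease-stage tags such as `NMIBC`).
#' The sex dialect is case-insensitive `F`/`M`/`female`/`male`/`1`/`2`;
#' anything else becomes `"unknown"`. Rows with an unparseable birth year are
#' skipped with a warning and counted in the `skipped` attribute; duplicated
#' patient identifiers are an error.
#'
#' @param source path to a CSV file, or a data frame.
#' @param sep field delimiter when reading from file.
#' @return a `data.table` of patients (class `traj_patients`) with columns
#'   `pid`, `sex`, `birth_year`, `tags` (list column).
#' @export
read_patient_table <- function(source, sep = ",") {
  dt <- if (is.data.frame(source)) {
    data.table::as.data.table(source)
  } else {
    if (!file.exists(source)) .fail("patient table not found: ", source)
    data.table::fread(source, sep = sep, header = TRUE, colClasses = "character",
                      na.strings = c("", "NA"), encoding = "UTF-8")
  }
  data.table::setnames(dt, toupper(names(dt)))
  need <- c("PID", "SEX", "BIRTH_YEAR")
  miss <- setdiff(need, names(dt))
  if (length(miss)) .fail("patient table lacks column(s): ", paste(miss, collapse = ", "))
  pid <- as.character(dt$PID)
  if (anyDuplicated(pid)) {
    .fail("duplicate patient identifier(s): ",
          paste(unique(pid[duplicated(pid)]), collapse = ", "))
  }
  by_raw <- suppressWarnings(as.integer(as.character(dt$BIRTH_YEAR)))
  bad <- is.na(by_raw)
  if (any(bad)) {
    warning(sum(bad), " patient row(s) skipped: unparseable birth year", call. = FALSE)
  }
  sex <- .SEX_MAP[tolower(as.character(dt$SEX))]
  sex[is.na(sex)] <- "unknown"
  tags <- if ("TAGS" %in% names(dt)) {
    lapply(as.character(dt$TAGS), function(t) {
      if (is.na(t) || !nzchar(t)) character(0) else strsplit(t, ";", fixed = TRUE)[[1]]
    })
  } else {
    rep(list(character(0)), nrow(dt))
  }
  out <- data.table::data.table(
    pid = pid[!bad], sex = unname(sex[!bad]), birth_year = by_raw[!bad],
    tags = tags[!bad]
  )
  data.table::setattr(out, "skipped", sum(bad))
  data.table::setattr(out, "class", c("traj_patients", class(out)))
  out[]
}

# code -> list(idx = patient indices, day = first-occurrence day) lookup
.build_code_index <- function(events) {
  lapply(split(events, by = "code", keep.by = FALSE, sorted = TRUE),
         function(d) list(idx = d$idx, day = d$day))
}

#' Read a timestamped event table and assemble a cohort
#'
#' Expects a delimited file (or data frame) with header `PID,CODE,DATE`
#' (ISO-8601 dates). Events are normalized in this order: rows with
#' unparseable dates or unknown patient identifiers are dropped and counted
#' (more than `max_drop_fraction` such rows aborts, as a data-quality guard);
#' per-patient anchor dates are recorded as the earliest raw occurrence of
#' any `anchor_codes` member; codes are mapped to the analysis `level` via
#' [map_to_level()]; excluded codes are removed; per patient and mapped code
#' only the first occurrence is retained; histories are sorted by date.
#'
#' @param source path to a CSV file, or a data frame.
#' @param patients a `traj_patients` table from [read_patient_table()].
#' @param vocab a `traj_vocab`.
#' @param level analysis level for [map_to_level()].
#' @param anchor_codes raw codes whose earliest date defines each patient's
#'   anchor date (default: bladder-cancer diagnosis/history codes).
#' @param sep field delimiter when reading from file.
#' @param max_drop_fraction data-quality guard threshold (default 0.1).
#' @return a `traj_cohort` object.
#' @export
read_event_table <- function(source, patients, vocab, level,
                             anchor_codes = c("C67", "188", "Z85.51", "V10.52"),
                             sep = ",", max_drop_fraction = 0.1) {
  stopifnot(inherits(patients, "traj_patients"), inherits(vocab, "traj_vocab"))
  dt <- if (is.data.frame(source)) {
    data.table::as.data.table(source)
  } else {
    if (!file.exists(source)) .fail("event table not found: ", source)
    data.table::fread(source, sep = sep, header = TRUE, colClasses = "character",
                      na.strings = c("", "NA"), encoding = "UTF-8")
  }
  data.table::setnames(dt, toupper(names(dt)))
  need <- c("PID", "CODE", "DATE")
  miss <- setdiff(need, names(dt))
  if (length(miss)) .fail("event table lacks column(s): ", paste(miss, collapse = ", "))
  n_total <- nrow(dt)

  day <- data.table::as.IDate(as.character(dt$DATE), format = "%Y-%m-%d")
  bad_date <- is.na(day)
  idx_of <- stats::setNames(seq_len(nrow(patients)), patients$pid)
  idx <- idx_of[as.character(dt$PID)]
  unknown_pid <- is.na(idx) & !bad_date
  drop <- bad_date | is.na(idx)
  counters <- list(
    bad_date = sum(bad_date), unknown_pid = sum(unknown_pid),
    total_rows = n_total
  )
  if (any(bad_date)) warning(sum(bad_date), " event row(s) dropped: unparseable date", call. = FALSE)
  if (any(unknown_pid)) warning(sum(unknown_pid), " event row(s) dropped: unknown patient id", call. = FALSE)
  if (n_total > 0 && sum(drop) / n_total > max_drop_fraction) {
    .fail(sprintf("data-quality guard: %.1f%% of event rows dropped (limit %.0f%%)",
                  100 * sum(drop) / n_total, 100 * max_drop_fraction))
  }
  ev <- data.table::data.table(
    idx = as.integer(idx[!drop]),
    raw = normalize_code(dt$CODE[!drop]),
    day = as.integer(day[!drop])
  )

  # anchor date: earliest raw (pre-dedup, pre-mapping) occurrence of an anchor
  # code; raw codes match by prefix so subcategories (C67.2) count towards
  # their anchor category (C67)
  anchors <- normalize_code(anchor_codes)
  anchor_day <- rep(NA_integer_, nrow(patients))
  if (nrow(ev)) {
    is_anchor <- Reduce(`|`, lapply(anchors, function(a) startsWith(ev$raw, a)))
    if (any(is_anchor)) {
      ae <- ev[is_anchor, list(day = min(day)), by = "idx"]
      anchor_day[ae$idx] <- ae$day
    }
  }

  n_parsed <- nrow(ev)
  mapped <- map_to_level(vocab, ev$raw, level)
  keep <- !is.na(mapped)
  ev <- ev[keep]
  ev[, `:=`(code = mapped[keep], raw = NULL)]
  if (nrow(ev)) ev <- ev[!is_excluded(vocab, ev$code)]
  counters$excluded_or_unmapped <- n_parsed - nrow(ev)

  # first occurrence per (patient, mapped code); then chronological histories
  data.table::setorderv(ev, c("idx", "code", "day"))
  ev <- ev[!duplicated(ev, by = c("idx", "code"))]
  data.table::setorderv(ev, c("idx", "day", "code"))

  cohort <- list(
    patients = data.table::copy(patients)[, `:=`(
      idx = seq_len(.N), anchor_day = anchor_day,
      age_group = NA_integer_, stratum = NA_character_
    )],
    events = ev,
    code_index = .build_code_index(ev),
    n_age_groups = NA_integer_,
    counters = counters
  )
  class(cohort) <- "traj_cohort"
  cohort
}

#' @export
print.traj_cohort <- function(x, ...) {
  cat(sprintf(
    "<traj_cohort> %d patients, %d normalized events, %d distinct codes, %s age groups\n",
    nrow(x$patients), nrow(x$events), length(x$code_index),
    ifelse(is.na(x$n_age_groups), "unassigned", x$n_age_groups)
  ))
  invisible(x)
}

#' Assign demographic strata
#'
#' Splits the observed birth-year range into `n_age_groups` equal-width bins
#' and keys each patient with known sex and birth year by
#' `(sex, birth-year bin)`. These strata are the matching key used when
#' sampling comparison groups. Patients with unknown sex or birth year carry
#' no stratum and never enter a sampling experiment.
#'
#' @param cohort a `traj_cohort`.
#' @param n_age_groups number of equal-width birth-year bins (>= 1).
#' @return the cohort with `age_group` and `stratum` columns filled.
#' @export
assign_age_groups <- function(cohort, n_age_groups) {
  stopifnot(inherits(cohort, "traj_cohort"), .is_count(n_age_groups))
  by <- cohort$patients$birth_year
  if (all(is.na(by))) .fail("cannot assign age groups: all birth years missing")
  lo <- min(by, na.rm = TRUE); hi <- max(by, na.rm = TRUE)
  width <- (hi - lo + 1) / n_age_groups
  grp <- pmin(as.integer(floor((by - lo) / width)), n_age_groups - 1L)
  sex <- cohort$patients$sex
  ok <- !is.na(grp) & sex %in% c("male", "female")
  cohort$patients <- data.table::copy(cohort$patients)
  cohort$patients[, `:=`(
    age_group = grp,
    stratum = ifelse(ok, paste0(sex, "|", grp), NA_character_)
  )]
  cohort$n_age_groups <- as.integer(n_age_groups)
  cohort
}

#' Table of stratum sizes
#' @param cohort a `traj_cohort` with assigned age groups.
#' @return a `data.table` with columns `stratum`, `n`.
#' @export
cohort_strata <- function(cohort) {
  stopifnot(inherits(cohort, "traj_cohort"))
  cohort$patients[!is.na(stratum), list(n = .N), by = "stratum"][order(stratum)]
}

#' Age at the anchor event, in whole calendar years
#'
#' De-identified extracts carry only the birth year, so age is computed as
#' `year(anchor date) - birth year`.
#'
#' @param cohort a `traj_cohort`.
#' @return integer vector, `NA` where no anchor event was observed.
#' @export
age_at_anchor <- function(cohort) {
  p <- cohort$patients
  yr <- data.table::year(data.table::as.IDate(p$anchor_day))
  as.integer(yr - p$birth_year)
}

.registered_filters <- function(cohort) {
  tags <- unique(unlist(cohort$patients$tags))
  c("male", "female", "age70+", "age70-", sort(unique(c(tags, c("NMIBC", "MIBC", "mUC")))))
}

#' Apply patient-level filters
#'
#' Keeps the sub-cohort of patients satisfying *all* listed filters and
#' rebuilds events, strata and the code index. Registered filters: `male`,
#' `female`, `age70+` / `age70-` (age at the anchor event at least / under 70
#' whole years; patients without an anchor date are dropped by age filters),
#' and any tag label carried by the cohort (e.g. `NMIBC`, `MIBC`, `mUC`).
#'
#' @param cohort a `traj_cohort` with assigned age groups.
#' @param filters character vector of filter names (empty = identity).
#' @return the filtered `traj_cohort`.
#' @export
apply_patient_filters <- function(cohort, filters) {
  stopifnot(inherits(cohort, "traj_cohort"))
  if (length(filters) == 0L) return(cohort)
  reg <- .registered_filters(cohort)
  bad <- setdiff(filters, reg)
  if (length(bad)) {
    .fail("unknown patient filter(s): ", paste(bad, collapse = ", "),
          "; registered: ", paste(reg, collapse = ", "))
  }
  keep <- rep(TRUE, nrow(cohort$patients))
  age <- age_at_anchor(cohort)
  for (f in filters) {
    keep <- keep & switch(f,
      "male" = cohort$patients$sex == "male",
      "female" = cohort$patients$sex == "female",
      "age70+" = !is.na(age) & age >= 70L,
      "age70-" = !is.na(age) & age < 70L,
      vapply(cohort$patients$tags, function(t) f %in% t, logical(1))
    )
  }
  sub <- cohort
  sub$patients <- cohort$patients[keep]
  old_idx <- sub$patients$idx
  remap <- integer(nrow(cohort$patients)); remap[old_idx] <- seq_along(old_idx)
  sub$patients[, idx := seq_len(.N)]
  sub$events <- cohort$events[idx %in% old_idx]
  sub$events[, idx := remap[idx]]
  sub$code_index <- .build_code_index(sub$events)
  if (!is.na(cohort$n_age_groups)) sub <- assign_age_groups(sub, cohort$n_age_groups)
  sub
}

#' Codes present in the cohort after normalization
#' @param cohort a `traj_cohort`.
#' @return character vector of analysis-level codes, sorted.
#' @export
cohort_codes <- function(cohort) names(cohort$code_index)

# first-occurrence day of `code` per patient as a length-N integer vector
# (NA where the patient lacks the code)
.code_day_vector <- function(cohort, code) {
  v <- rep(NA_integer_, nrow(cohort$patients))
  ent <- cohort$code_index[[code]]
  if (!is.null(ent)) v[ent$idx] <- ent$day
  v
}
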
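# Relative-risk estimation for ordered event pairs via repeated stratified
# sampling of matched comparison groups, empirical p-values, and binomial
# directionality resolution of bidirectional pairs.

#' Sampling configuration for pair statistics
#'
#' @param iterations number of sampling iterations per pair (>= 1).
#' @param min_gap,max_gap time window (inclusive) that the second event must
#'   fall in after the first; duration tokens or day counts, see
#'   [parse_duration()].
#' @param min_patients minimum number of exposed patients developing the
#'   second event for a pair to be selected (also the upfront prefilter
#'   threshold).
#' @param alpha significance level for both the empirical RR p-value and the
#'   directionality test.
#' @param p_adjust multiple-testing correction applied across all tested
#'   pairs before selection: `"none"` (default), `"BH"` or `"bonferroni"`.
#'   Note that the empirical p-value cannot fall below `1/(iterations + 1)`,
#'   so corrections over large pair universes require correspondingly many
#'   iterations to retain any power.
#' @param seed base RNG seed; every pair derives its own stream from
#'   `(seed, a, b)` so results are independent of processing order.
#' @param exhaustive if `TRUE`, the comparison group is the full eligible
#'   unexposed population (single deterministic iteration, classical
#'   two-cohort RR) instead of repeated matched samples.
#' @return a `sampling_config` list.
#' @export
sampling_config <- function(iterations = 400L, min_gap = "6M", max_gap = "5Y",
                            min_patients = 100L, alpha = 0.05,
                            p_adjust = c("none", "BH", "bonferroni"),
                            seed = 1L, exhaustive = FALSE) {
  min_gap <- parse_duration(min_gap)
  max_gap <- parse_duration(max_gap)
  stopifnot(.is_count(iterations), .is_count(min_patients),
            min_gap >= 0L, min_gap <= max_gap,
            is.numeric(alpha), alpha > 0, alpha < 1)
  structure(list(
    iterations = as.integer(iterations), min_gap = min_gap, max_gap = max_gap,
    min_patients = as.integer(min_patients), alpha = alpha,
    p_adjust = match.arg(p_adjust), seed = as.integer(seed),
    exhaustive = isTRUE(exhaustive)
  ), class = "sampling_config")
}

#' Does the ordered pair occur for each patient?
#'
#' Uses the single retained first occurrence of each code: `TRUE` for
#' patients having both codes with `date(b) - date(a)` inside
#' `[min_gap, max_gap]` (both ends inclusive, whole days).
#'
#' @param cohort a `traj_cohort`.
#' @param a,b analysis-level codes, `a != b`.
#' @param min_gap,max_gap window in days (already parsed).
#' @return logical vector over the cohort's patients.
#' @export
pair_occurs <- function(cohort, a, b, min_gap, max_gap) {
  stopifnot(inherits(cohort, "traj_cohort"), a != b)
  d <- .code_day_vector(cohort, b) - .code_day_vector(cohort, a)
  !is.na(d) & d >= min_gap & d <= max_gap
}

#' Upfront pair prefilter
#'
#' Counts, for every ordered code pair, the patients whose first occurrences
#' satisfy the gap window, and keeps pairs with at least
#' `config$min_patients` supporters. Only these candidates enter the (much
#' more expensive) sampling experiment.
#'
#' @param cohort a `traj_cohort`.
#' @param config a [sampling_config()].
#' @param codes optional restriction of the code universe (default: all
#'   cohort codes).
#' @return `data.table` with columns `a`, `b`, `n_co`, sorted by `(a, b)`.
#' @export
prefilter_pairs <- function(cohort, config, codes = NULL) {
  stopifnot(inherits(cohort, "traj_cohort"))
  ev <- cohort$events
  if (!is.null(codes)) ev <- ev[code %in% codes]
  if (nrow(ev) == 0L) {
    return(data.table::data.table(a = character(0), b = character(0), n_co = integer(0)))
  }
  j <- merge(ev[, list(idx, a = code, da = day)],
             ev[, list(idx, b = code, db = day)],
             by = "idx", allow.cartesian = TRUE)
  j <- j[a != b & db - da >= config$min_gap & db - da <= config$max_gap]
  out <- j[, list(n_co = .N), by = list(a, b)][n_co >= config$min_patients]
  data.table::setorderv(out, c("a", "b"))
  out[]
}

# Per-stratum matching frame for exposure code `a`.
# For each stratum: exposed patients (truncated to the number of available
# unexposed, first-come by patient index), their exposure days sorted
# ascending (the rank-matched reference dates), and the unexposed pool.
.pair_frame <- function(cohort, a) {
  p <- cohort$patients
  if (all(is.na(p$stratum))) .fail("strata not assigned; call assign_age_groups() first")
  aday <- .code_day_vector(cohort, a)
  exposed <- !is.na(aday)
  strata <- list()
  shortfall <- 0L
  for (s in sort(unique(p$stratum[exposed & !is.na(p$stratum)]))) {
    in_s <- which(!is.na(p$stratum) & p$stratum == s)
    e_idx <- in_s[exposed[in_s]]
    pool <- in_s[!exposed[in_s]]
    k <- min(length(e_idx), length(pool))
    shortfall <- shortfall + (length(e_idx) - k)
    if (k == 0L) next
    e_use <- e_idx[seq_len(k)] # deterministic truncation: first k by index
    strata[[s]] <- list(
      stratum = s, k = k,
      exposed = e_use,
      ref_day = sort(aday[e_use]),
      pool = pool
    )
  }
  strat_ok <- !is.na(p$stratum)
  list(a = a, strata = strata, shortfall = shortfall,
       exposed_used = unlist(lapply(strata, `[[`, "exposed"), use.names = FALSE),
       exposed_all = which(exposed & strat_ok),
       pool_all = which(!exposed & strat_ok),
       n_exposed_raw = sum(exposed & strat_ok))
}

#' Draw one matched comparison group
#'
#' For each `(sex, age group)` stratum, samples without replacement as many
#' unexposed patients as the stratum contributes exposed patients; each
#' sampled patient is rank-matched to an exposed patient's exposure date,
#' which becomes its reference date for subsequent-event counting. Strata
#' with fewer unexposed candidates than exposed patients are truncated
#' symmetrically (both groups shrink to the available minimum; the shortfall
#' is reported).
#'
#' @param cohort a `traj_cohort` with assigned strata.
#' @param a exposure code.
#' @param seed RNG seed for this draw.
#' @return list with `sampled` (`data.table` of `idx`, `ref_day`, `stratum`),
#'   `exposed_used` (the truncation-adjusted exposed indices), and
#'   `shortfall`; `NULL` if no stratum has any unexposed candidate
#'   (unsampleable exposure).
#' @export
sample_comparison_group <- function(cohort, a, seed = 1L) {
  fr <- .pair_frame(cohort, a)
  if (length(fr$strata) == 0L) return(NULL)
  .with_seed(seed, {
    parts <- lapply(fr$strata, function(s) {
      pick <- s$pool[sample.int(length(s$pool), s$k)]
      data.table::data.table(idx = pick, ref_day = s$ref_day, stratum = s$stratum)
    })
    list(sampled = data.table::rbindlist(parts),
         exposed_used = fr$exposed_used, shortfall = fr$shortfall)
  })
}

.empty_pairstats <- function() {
  data.table::data.table(
    a = character(0), b = character(0), n_exposed = integer(0),
    n_ab = integer(0), rr = numeric(0), p_value = numeric(0),
    n_comparison_b_mean = numeric(0), shortfall = integer(0),
    unsampleable = logical(0)
  )
}

# core scoring of one pair given a prebuilt frame and the b-day vector
.score_pair <- function(cohort, fr, b, bday, config) {
  a <- fr$a
  row <- function(n_exposed, n_ab, rr, p, cmean, unsampleable = FALSE) {
    data.table::data.table(
      a = a, b = b, n_exposed = as.integer(n_exposed), n_ab = as.integer(n_ab),
      rr = rr, p_value = p, n_comparison_b_mean = cmean,
      shortfall = as.integer(fr$shortfall), unsampleable = unsampleable
    )
  }
  if (if (config$exhaustive) length(fr$pool_all) == 0L || length(fr$exposed_all) == 0L
      else length(fr$strata) == 0L) {
    return(row(0L, 0L, NA_real_, NA_real_, NA_real_, unsampleable = TRUE))
  }
  aday <- .code_day_vector(cohort, a)
  p1 <- if (config$exhaustive) fr$exposed_all else fr$exposed_used
  gap <- bday[p1] - aday[p1]
  n_ab <- sum(!is.na(gap) & gap >= config$min_gap & gap <= config$max_gap)
  n1 <- length(p1)

  if (config$exhaustive) {
    pool_all <- fr$pool_all
    c_b <- sum(!is.na(bday[pool_all]))
    n2 <- length(pool_all)
    rate1 <- n_ab / n1
    rate2 <- c_b / n2
    rr <- if (rate2 == 0) (if (rate1 > 0) Inf else NA_real_) else rate1 / rate2
    p <- (1 + as.integer(rate2 >= rate1)) / 2
    return(row(n1, n_ab, rr, p, c_b))
  }

  iter <- config$iterations
  counts <- numeric(iter)
  .with_seed(.pair_seed(config$seed, a, b), {
    for (s in fr$strata) {
      poolb <- bday[s$pool]
      m <- length(s$pool)
      idx <- vapply(seq_len(iter), function(i) sample.int(m, s$k), integer(s$k))
      d <- matrix(poolb[idx], nrow = s$k) - s$ref_day
      hit <- !is.na(d) & d >= config$min_gap & d <= config$max_gap
      counts <- counts + colSums(hit)
    }
  })
  mean_c <- mean(counts)
  rate1 <- n_ab / n1
  rate2 <- mean_c / n1 # comparison group size equals n1 by construction
  rr <- if (rate2 == 0) (if (rate1 > 0) Inf else NA_real_) else rate1 / rate2
  # add-one empirical p: how often does a matched unexposed group reach the
  # exposed rate?
  p <- (1 + sum(counts >= n_ab)) / (iter + 1)
  row(n1, n_ab, rr, p, mean_c)
}

#' Estimate the relative risk of one ordered pair
#'
#' Implements the matched-sampling cohort emulation: the exposed group P1 is
#' every (stratifiable) patient with code `a`; per iteration a comparison
#' group of equal per-stratum size is sampled from the unexposed, each member
#' rank-matched to an exposed patient's exposure date; the second event `b`
#' is counted within `[min_gap, max_gap]` after the exposure (or matched
#' reference) date. The RR is the exposed rate over the mean comparison rate,
#' and the empirical p-value is the add-one fraction of iterations whose
#' comparison count reaches the exposed count.
#'
#' @param cohort a `traj_cohort` with assigned strata.
#' @param a,b analysis-level codes, `a != b`.
#' @param config a [sampling_config()].
#' @return one-row `data.table` with columns `a`, `b`, `n_exposed`, `n_ab`,
#'   `rr`, `p_value`, `n_comparison_b_mean`, `shortfall`, `unsampleable`.
#' @export
estimate_rr <- function(cohort, a, b, config) {
  stopifnot(inherits(cohort, "traj_cohort"), inherits(config, "sampling_config"), a != b)
  fr <- .pair_frame(cohort, a)
  .score_pair(cohort, fr, b, .code_day_vector(cohort, b), config)
}

#' Estimate relative risks for all candidate pairs
#'
#' Runs [prefilter_pairs()] and scores every surviving ordered pair with
#' [estimate_rr()]. Per-pair RNG streams are derived from
#' `(seed, a, b)`, so the result is bit-identical however the pair list is
#' chunked or ordered (`workers` merely splits the iteration space to honour
#' that contract).
#'
#' @param cohort a `traj_cohort` with assigned strata.
#' @param config a [sampling_config()].
#' @param pairs optional precomputed candidate table (columns `a`, `b`);
#'   default: [prefilter_pairs()].
#' @param workers number of work units the pair space is split into
#'   (results are independent of this value).
#' @return `data.table` of pair statistics, one row per candidate pair,
#'   sorted by `(a, b)`.
#' @export
estimate_all_pairs <- function(cohort, config, pairs = NULL, workers = 1L) {
  stopifnot(inherits(cohort, "traj_cohort"), inherits(config, "sampling_config"))
  if (is.null(pairs)) pairs <- prefilter_pairs(cohort, config)
  if (nrow(pairs) == 0L) return(.empty_pairstats())
  chunk_of <- rep(seq_len(workers), length.out = nrow(pairs))
  bday_cache <- new.env(parent = emptyenv())
  get_bday <- function(b) {
    if (is.null(bday_cache[[b]])) bday_cache[[b]] <- .code_day_vector(cohort, b)
    bday_cache[[b]]
  }
  parts <- lapply(seq_len(workers), function(w) {
    sub <- pairs[chunk_of == w]
    out <- vector("list", nrow(sub))
    frame_cache <- new.env(parent = emptyenv())
    for (i in seq_len(nrow(sub))) {
      a <- sub$a[i]; b <- sub$b[i]
      if (is.null(frame_cache[[a]])) frame_cache[[a]] <- .pair_frame(cohort, a)
      out[[i]] <- .score_pair(cohort, frame_cache[[a]], b, get_bday(b), config)
    }
    data.table::rbindlist(out)
  })
  res <- data.table::rbindlist(parts)
  data.table::setorderv(res, c("a", "b"))
  res[]
}

#' Exact binomial directionality test
#'
#' When both orientations of a pair show RR > 1, the ordering among patients
#' who have both codes decides which orientation survives: a two-sided exact
#' binomial test of `n_ab_first` A-before-B patients out of
#' `n_ab_first + n_ba_first` against probability 0.5. If significant at
#' `alpha`, the majority direction is kept; otherwise (including exact ties)
#' both orientations are dropped.
#'
#' @param n_ab_first patients with A strictly before B (within the window).
#' @param n_ba_first patients with B strictly before A (within the window).
#' @param alpha significance level.
#' @return list with `direction` (`"forward"`, `"reverse"` or
#'   `"both_dropped"`) and the exact two-sided `p`.
#' @export
directionality_test <- function(n_ab_first, n_ba_first, alpha = 0.05) {
  n <- n_ab_first + n_ba_first
  if (n == 0L) {
    warning("directionality test with zero informative patients; dropping both orientations",
            call. = FALSE)
    return(list(direction = "both_dropped", p = NA_real_))
  }
  p <- stats::binom.test(n_ab_first, n, p = 0.5, alternative = "two.sided")$p.value
  dir <- if (p < alpha && n_ab_first != n_ba_first) {
    if (n_ab_first > n_ba_first) "forward" else "reverse"
  } else {
    "both_dropped"
  }
  list(direction = dir, p = p)
}

#' Select pairs for trajectory building
#'
#' Applies the selection rule to a scored pair table: RR > 1, (corrected)
#' empirical p below `alpha`, at least `min_patients` exposed patients with
#' the subsequent event, and resolution of bidirectional pairs with
#' [directionality_test()]. The returned table carries a `direction` column
#' (`unidirectional`, `forward` = won the directionality test, `reverse` =
#' the reverse orientation won, `both_dropped`) and `selected` flag; rows are
#' sorted by `(a, b)`.
#'
#' @param stats a pair-statistics `data.table` from [estimate_all_pairs()].
#' @param cohort the `traj_cohort` the statistics were computed on (needed to
#'   split both-code patients by which code came first).
#' @param config the [sampling_config()] used.
#' @return the annotated pair table; selected pairs are `stats[selected == TRUE]`.
#' @export
select_pairs <- function(stats, cohort, config) {
  stats <- data.table::copy(stats)
  if (nrow(stats) == 0L) {
    stats[, `:=`(p_adj = numeric(0), direction = character(0),
                 direction_p = numeric(0), selected = logical(0))]
    return(stats[])
  }
  tested <- !stats$unsampleable
  stats[, p_adj := NA_real_]
  stats[tested, p_adj := stats::p.adjust(p_value, method = config$p_adjust)]
  cand <- tested & !is.na(stats$rr) & stats$rr > 1 &
    !is.na(stats$p_adj) & stats$p_adj < config$alpha &
    stats$n_ab >= config$min_patients
  key <- paste(stats$a, stats$b, sep = "\r")
  rkey <- paste(stats$b, stats$a, sep = "\r")
  cand_set <- key[cand]
  stats[, `:=`(direction = NA_character_, direction_p = NA_real_)]
  stats[cand, direction := "unidirectional"]
  bidir <- which(cand & (rkey %in% cand_set))
  done <- character(0)
  for (i in bidir) {
    k <- key[i]
    if (k %in% done) next
    a <- stats$a[i]; b <- stats$b[i]
    done <- c(done, k, rkey[i])
    n_fwd <- sum(pair_occurs(cohort, a, b, config$min_gap, config$max_gap))
    n_rev <- sum(pair_occurs(cohort, b, a, config$min_gap, config$max_gap))
    dt_res <- directionality_test(n_fwd, n_rev, config$alpha)
    j <- which(key == rkey[i])
    if (dt_res$direction == "forward") {
      stats[i, direction := "forward"]
      stats[j, direction := "reverse"]
    } else if (dt_res$direction == "reverse") {
      stats[i, direction := "reverse"]
      stats[j, direction := "forward"]
    } else {
      stats[i, direction := "both_dropped"]
      stats[j, direction := "both_dropped"]
    }
    stats[i, direction_p := dt_res$p]
    stats[j, direction_p := dt_res$p]
  }
  stats[, selected := !is.na(direction) & direction %in% c("unidirectional", "forward")]
  data.table::setorderv(stats, c("a", "b"))
  stats[]
}
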
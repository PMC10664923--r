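sel_tab <- function(...) {
  pairs <- list(...)
  data.table::data.table(
    a = vapply(pairs, `[[`, character(1), 1),
    b = vapply(pairs, `[[`, character(1), 2),
    rr = vapply(pairs, function(p) if (length(p) > 2) as.numeric(p[[3]]) else 2.0, numeric(1))
  )
}

test_that("support counting applies gap windows per transition", {
  pats <- patient_frame(3)
  d0 <- as.Date("2010-01-01")
  ev <- rbind(
    data.frame(PID = "P001", CODE = c("A", "B", "C"),
               DATE = as.character(d0 + c(0, 400, 900))),   # gaps 400, 500
    data.frame(PID = "P002", CODE = c("A", "B", "C"),
               DATE = as.character(d0 + c(0, 100, 900))),   # 100 < 183
    data.frame(PID = "P003", CODE = c("A", "B"),
               DATE = as.character(d0 + c(0, 400)))         # lacks C
  )
  co <- make_cohort(pats, ev)
  s <- support_count(co, c("A", "B", "C"), 183L, 1826L)
  expect_equal(s$count, 1L)
  expect_equal(s$supporters, 1L)
  expect_equal(support_count(co, c("A", "B"), 183L, 1826L)$count, 2L)
  expect_equal(support_count(co, c("A", "Q"), 183L, 1826L)$count, 0L)
})

test_that("a supported chain of two pairs yields exactly one trajectory", {
  pats <- patient_frame(5)
  d0 <- as.Date("2010-01-01")
  ev <- do.call(rbind, lapply(1:5, function(i) {
    data.frame(PID = sprintf("P%03d", i), CODE = c("A", "B", "C"),
               DATE = as.character(d0 + c(0, 400, 900)))
  }))
  co <- make_cohort(pats, ev)
  cfg <- trajectory_config(min_len = 3, max_len = 5, min_patients = 5,
                           min_gap = 183, max_gap = 1826)
  tr <- build_trajectories(sel_tab(c("A", "B", "1.5"), c("B", "C", "2.5")), co, cfg)
  expect_length(tr, 1L)
  expect_equal(tr[[1]]$codes, c("A", "B", "C"))
  expect_equal(tr[[1]]$support, 5L)
  expect_equal(tr[[1]]$transition_rr, c(1.5, 2.5))
  expect_equal(tr[[1]]$tid, 1L)

  # below-support extension leaves only sub-minimum 2-pairs -> nothing emitted
  cfg6 <- trajectory_config(min_len = 3, max_len = 5, min_patients = 6,
                            min_gap = 183, max_gap = 1826)
  expect_length(build_trajectories(sel_tab(c("A", "B"), c("B", "C")), co, cfg6), 0L)

  # empty pair list is an empty result, not an error
  expect_length(build_trajectories(sel_tab()[0], co, cfg), 0L)
})

test_that("cycles are prevented and only maximal trajectories are emitted", {
  pats <- patient_frame(4)
  d0 <- as.Date("2010-01-01")
  ev <- do.call(rbind, lapply(1:4, function(i) {
    data.frame(PID = sprintf("P%03d", i), CODE = c("A", "B", "C", "D"),
               DATE = as.character(d0 + c(0, 400, 800, 1200)))
  }))
  co <- make_cohort(pats, ev)
  cfg <- trajectory_config(3, 5, 4, min_gap = 183, max_gap = 1826)
  # B -> A would revisit A from A > B ...; D -> A closes a cycle
  tr <- build_trajectories(
    sel_tab(c("A", "B"), c("B", "C"), c("C", "D"), c("D", "A")), co, cfg)
  seqs <- vapply(tr, function(t) paste(t$codes, collapse = ">"), character(1))
  expect_true("A>B>C>D" %in% seqs)
  expect_false(any(grepl("A.*A", seqs)))
  # the prefix A>B>C is extendable, hence not reported on its own
  expect_false("A>B>C" %in% seqs)

  # with emit_prefixes intermediate lengths are also reported
  cfgp <- trajectory_config(3, 5, 4, min_gap = 183, max_gap = 1826,
                            emit_prefixes = TRUE)
  trp <- build_trajectories(
    sel_tab(c("A", "B"), c("B", "C"), c("C", "D"), c("D", "A")), co, cfgp)
  seqsp <- vapply(trp, function(t) paste(t$codes, collapse = ">"), character(1))
  expect_true(all(c("A>B>C", "A>B>C>D") %in% seqsp))
})

test_that("trajectory output matches exhaustive enumeration on random fixtures", {
  set.seed(31)
  for (rep in 1:4) {
    codes <- LETTERS[1:6]
    pats <- patient_frame(120, birth_years = 1940:1970)
    ev <- random_events(pats$PID, codes, p_code = 0.65, span = 2500L)
    co <- make_cohort(pats, ev)
    all_pairs <- expand.grid(a = codes, b = codes, stringsAsFactors = FALSE)
    all_pairs <- all_pairs[all_pairs$a != all_pairs$b, ]
    sel_rows <- all_pairs[sample.int(nrow(all_pairs), 12), ]
    sel <- data.table::data.table(a = sel_rows$a, b = sel_rows$b, rr = 2)
    cfg <- trajectory_config(3, 5, 3, min_gap = 183, max_gap = 1826)
    tr <- build_trajectories(sel, co, cfg)
    got <- sort(vapply(tr, function(t) paste(t$codes, collapse = ">"), character(1)))
    want <- oracle_enumerate_trajectories(sel, ev, 183, 1826, 3, 5, 3)
    expect_identical(got, want, info = paste("rep", rep))
    # support values agree with the independent per-sequence count
    fd <- oracle_first_days(ev)
    for (t in tr) {
      n <- 0L
      for (p in fd) {
        ok <- TRUE
        for (i in seq_len(length(t$codes) - 1L)) {
          d1 <- p[[t$codes[i]]]; d2 <- p[[t$codes[i + 1L]]]
          if (is.null(d1) || is.null(d2) || d2 - d1 < 183 || d2 - d1 > 1826) {
            ok <- FALSE; break
          }
        }
        if (ok) n <- n + 1L
      }
      expect_equal(t$support, n)
    }
  }
})

test_that("support is anti-monotone along extensions", {
  set.seed(5)
  pats <- patient_frame(80, birth_years = 1940:1970)
  ev <- random_events(pats$PID, LETTERS[1:5], p_code = 0.7, span = 2500L)
  co <- make_cohort(pats, ev)
  for (len in 2:4) {
    seqs <- replicate(10, sample(LETTERS[1:5], len + 1), simplify = FALSE)
    for (s in seqs) {
      sup_short <- support_count(co, s[seq_len(len)], 183L, 1826L)$count
      sup_long <- support_count(co, s, 183L, 1826L)$count
      expect_lte(sup_long, sup_short)
    }
  }
})

test_that("trajectory filters keep sequences touching the filter set", {
  v <- vocabulary_from_codes(c("J44", "C67", "N39", "I10", "TX:MVAC"),
                             kinds = c(rep("diagnosis", 4), "treatment"))
  mk <- function(tid, codes) list(tid = tid, codes = codes, support = 10L,
                                  supporters = 1:10, transition_rr = rep(2, length(codes) - 1))
  trs <- structure(list(
    mk(1L, c("J44", "C67", "N39")),
    mk(2L, c("J44", "I10", "N39")),
    mk(3L, c("I10", "TX:MVAC"))
  ), class = "traj_set")
  bc <- apply_trajectory_filters(trs, "bc", v)
  expect_equal(vapply(bc, `[[`, integer(1), "tid"), c(1L, 3L))
  neo <- apply_trajectory_filters(trs, "neoplasm", v)
  expect_equal(vapply(neo, `[[`, integer(1), "tid"), 1L)
  expect_identical(apply_trajectory_filters(trs, character(0), v), trs)
  expect_error(apply_trajectory_filters(trs, "bogus", v), "unknown trajectory filter")
})
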
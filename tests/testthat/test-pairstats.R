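# window arithmetic: [183, 1825] days used in several cases below
w <- function(cohort, a, b) pair_occurs(cohort, a, b, 183L, 1825L)

test_that("pair occurrence respects the inclusive gap window", {
  pats <- patient_frame(3)
  ev <- data.frame(
    PID = c("P001", "P001", "P002", "P002", "P003"),
    CODE = c("A", "B", "A", "B", "A"),
    DATE = c("2010-01-01", "2012-01-01",  # 731 days -> inside
             "2010-01-01", "2010-02-01",  # 31 days  -> below min
             "2010-01-01")
  )
  co <- make_cohort(pats, ev)
  expect_equal(w(co, "A", "B"), c(TRUE, FALSE, FALSE))
  expect_equal(w(co, "B", "A"), c(FALSE, FALSE, FALSE)) # negative gaps
  # boundary days are inclusive
  ev2 <- data.frame(PID = c("P001", "P001"), CODE = c("A", "B"),
                    DATE = c("2010-01-01", "2010-07-03")) # exactly 183 days
  co2 <- make_cohort(patient_frame(1), ev2)
  expect_true(w(co2, "A", "B")[1])
})

test_that("prefilter counts equal an exhaustive double loop over patients", {
  set.seed(23)
  pats <- patient_frame(50, birth_years = 1940:1960)
  ev <- random_events(pats$PID, c("A", "B", "C", "D"), p_code = 0.6)
  co <- make_cohort(pats, ev)
  cfg <- sampling_config(iterations = 10, min_gap = 183, max_gap = 1825,
                         min_patients = 1)
  got <- as.data.frame(prefilter_pairs(co, cfg))
  fd <- oracle_first_days(ev)
  for (a in c("A", "B", "C", "D")) for (b in setdiff(c("A", "B", "C", "D"), a)) {
    n <- sum(vapply(fd, oracle_pair_occurs, logical(1), a = a, b = b,
                    min_gap = 183, max_gap = 1825))
    in_table <- got[got$a == a & got$b == b, ]
    expect_equal(nrow(in_table), as.integer(n >= 1), info = paste(a, b))
    if (n >= 1) expect_equal(in_table$n_co, n, info = paste(a, b))
  }
  # raising the threshold prunes
  cfg100 <- sampling_config(iterations = 10, min_patients = 100)
  expect_equal(nrow(prefilter_pairs(co, cfg100)), 0L)
})

test_that("comparison groups match stratum sizes, truncate symmetrically, and are seed-stable", {
  pats <- data.frame(
    PID = sprintf("P%03d", 1:30),
    SEX = c(rep("M", 20), rep("F", 10)),
    BIRTH_YEAR = 1950, TAGS = ""
  )
  # 10 exposed males, 10 unexposed males; 8 exposed females, 2 unexposed
  ev <- data.frame(
    PID = pats$PID[c(1:10, 21:28)], CODE = "A",
    DATE = "2010-01-01"
  )
  ev <- rbind(ev, data.frame(PID = pats$PID, CODE = "Z", DATE = "2009-01-01"))
  co <- make_cohort(pats, ev, n_age_groups = 1)
  g <- sample_comparison_group(co, "A", seed = 5)
  tab <- table(g$sampled$stratum)
  expect_equal(unname(tab[["male|0"]]), 10L)
  expect_equal(unname(tab[["female|0"]]), 2L)  # truncated to available pool
  expect_equal(g$shortfall, 6L)
  expect_equal(length(g$exposed_used), 12L)
  # sampled patients are never exposed
  expect_false(any(g$sampled$idx %in% g$exposed_used))
  has_a <- !is.na(trajmine:::.code_day_vector(co, "A"))
  expect_false(any(has_a[g$sampled$idx]))
  # determinism
  g2 <- sample_comparison_group(co, "A", seed = 5)
  expect_identical(g$sampled, g2$sampled)
  expect_false(identical(g$sampled, sample_comparison_group(co, "A", seed = 6)$sampled))
})

test_that("exhaustive-mode RR reproduces the closed-form two-cohort ratio", {
  # 100 exposed, 30 with B in-window after A; 100 unexposed, 10 with B
  pats <- patient_frame(200, birth_years = 1950)
  rows <- list()
  for (i in 1:100) {
    rows[[length(rows) + 1L]] <- data.frame(PID = pats$PID[i], CODE = "A", DATE = "2010-01-01")
    if (i <= 30) {
      rows[[length(rows) + 1L]] <- data.frame(PID = pats$PID[i], CODE = "B", DATE = "2011-01-01")
    }
  }
  for (i in 101:110) {
    rows[[length(rows) + 1L]] <- data.frame(PID = pats$PID[i], CODE = "B", DATE = "2012-01-01")
  }
  ev <- do.call(rbind, rows)
  co <- make_cohort(pats, ev)
  cfg <- sampling_config(iterations = 1, min_patients = 1, exhaustive = TRUE)
  got <- estimate_rr(co, "A", "B", cfg)
  expect_equal(got$rr, 3.0)
  expect_equal(got$n_ab, 30L)
  expect_equal(got$n_exposed, 100L)
  orc <- oracle_two_cohort_rr(pats, ev, "A", "B", 183, 1826)
  expect_equal(got$rr, orc$rr)
  # symmetric rates give RR = 1
  ev_sym <- rbind(ev[ev$CODE == "A", ],
                  data.frame(PID = pats$PID[c(1:30, 101:130)], CODE = "B",
                             DATE = "2011-01-01"))
  co_sym <- make_cohort(pats, ev_sym)
  expect_equal(estimate_rr(co_sym, "A", "B", cfg)$rr, 1.0)
})

test_that("sampled RR is seed-deterministic and independent of worker count", {
  set.seed(99)
  pats <- patient_frame(120, birth_years = 1935:1975)
  ev <- random_events(pats$PID, c("A", "B", "C"), p_code = 0.5)
  co <- make_cohort(pats, ev, n_age_groups = 3)
  cfg <- sampling_config(iterations = 50, min_patients = 1, seed = 17)
  s1 <- estimate_all_pairs(co, cfg, workers = 1L)
  s2 <- estimate_all_pairs(co, cfg, workers = 1L)
  s4 <- estimate_all_pairs(co, cfg, workers = 4L)
  expect_identical(s1, s2)
  expect_identical(s1, s4)
  # single-pair path agrees with the batch path
  one <- estimate_rr(co, s1$a[1], s1$b[1], cfg)
  expect_identical(one, s1[1])
  # p-values live in [1/(iter+1), 1]
  expect_true(all(s1$p_value >= 1 / 51 & s1$p_value <= 1))
})

test_that("RR is +Inf with computed p when comparison groups never show B", {
  pats <- patient_frame(40, birth_years = 1950)
  ev <- rbind(
    data.frame(PID = pats$PID[1:20], CODE = "A", DATE = "2010-01-01"),
    data.frame(PID = pats$PID[1:15], CODE = "B", DATE = "2011-01-01")
  )
  co <- make_cohort(pats, ev)
  cfg <- sampling_config(iterations = 20, min_patients = 1, seed = 1)
  got <- estimate_rr(co, "A", "B", cfg)
  expect_true(is.infinite(got$rr))
  expect_equal(got$p_value, 1 / 21)
})

test_that("pairs whose exposure covers everyone are unsampleable", {
  pats <- patient_frame(30, birth_years = 1950)
  ev <- rbind(
    data.frame(PID = pats$PID, CODE = "C67", DATE = "2009-01-01"),
    data.frame(PID = pats$PID[1:10], CODE = "B", DATE = "2010-06-01")
  )
  co <- make_cohort(pats, ev)
  cfg <- sampling_config(iterations = 10, min_patients = 1)
  got <- estimate_rr(co, "C67", "B", cfg)
  expect_true(got$unsampleable)
  sel <- select_pairs(got, co, cfg)
  expect_false(any(sel$selected))
})

test_that("directionality test reproduces exact binomial worked values", {
  r1 <- directionality_test(10, 0)
  expect_equal(r1$p, 0.001953125)
  expect_equal(r1$direction, "forward")
  r2 <- directionality_test(7, 3)
  expect_equal(r2$p, 0.34375)
  expect_equal(r2$direction, "both_dropped")
  r3 <- directionality_test(5, 5)
  expect_equal(r3$p, 1)
  expect_equal(r3$direction, "both_dropped")
  expect_equal(directionality_test(0, 10)$direction, "reverse")
  expect_warning(r0 <- directionality_test(0, 0), "zero informative")
  expect_equal(r0$direction, "both_dropped")
})

test_that("pair selection applies RR, p, support and directionality rules", {
  # cohort where A precedes B for 12 patients; never the reverse
  pats <- patient_frame(60, birth_years = 1950)
  ev <- rbind(
    data.frame(PID = pats$PID[1:12], CODE = "A", DATE = "2010-01-01"),
    data.frame(PID = pats$PID[1:12], CODE = "B", DATE = "2011-01-01")
  )
  co <- make_cohort(pats, ev)
  cfg <- sampling_config(iterations = 10, min_patients = 10, alpha = 0.05)
  mk <- function(a, b, rr, p, n_ab) data.table::data.table(
    a = a, b = b, n_exposed = 20L, n_ab = as.integer(n_ab), rr = rr,
    p_value = p, n_comparison_b_mean = 1, shortfall = 0L, unsampleable = FALSE
  )
  stats <- rbind(
    mk("A", "B", 2.0, 0.01, 12),   # bidirectional with next row
    mk("B", "A", 1.5, 0.01, 12),
    mk("C", "D", 0.9, 0.01, 50),   # rr <= 1
    mk("E", "F", 2.0, 0.30, 50),   # p too large
    mk("G", "H", 2.0, 0.01, 9)     # support below threshold
  )
  out <- select_pairs(stats, co, cfg)
  sel <- out[out$selected == TRUE]
  expect_equal(nrow(sel), 1L)
  expect_equal(sel$a, "A")
  expect_equal(sel$direction, "forward")
  expect_equal(out[out$a == "B" & out$b == "A"]$direction, "reverse")
  expect_equal(sel$direction_p, 2 * 0.5^12)
  expect_equal(out[out$a == "C"]$direction, NA_character_)
})

test_that("selection output is sorted and stable", {
  pats <- patient_frame(10)
  ev <- data.frame(PID = "P001", CODE = "A", DATE = "2010-01-01")
  co <- make_cohort(pats, ev)
  cfg <- sampling_config(iterations = 10, min_patients = 1)
  mk <- function(a, b) data.table::data.table(
    a = a, b = b, n_exposed = 30L, n_ab = 20L, rr = 2, p_value = 0.001,
    n_comparison_b_mean = 1, shortfall = 0L, unsampleable = FALSE
  )
  out <- select_pairs(rbind(mk("Z", "A"), mk("B", "C"), mk("A", "Q")), co, cfg)
  expect_equal(out$a, c("A", "B", "Z"))
})
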
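# Independent oracles, deliberately written with plain base-R loops over the
# raw input tables so they share no code path with the package internals.

# first-occurrence day of every code per patient, straight from the raw
# event frame (PID, CODE, DATE)
oracle_first_days <- function(events) {
  out <- list()
  for (i in seq_len(nrow(events))) {
    pid <- as.character(events$PID[i])
    cd <- toupper(gsub("[. ]", "", as.character(events$CODE[i])))
    d <- as.integer(as.Date(as.character(events$DATE[i])))
    if (is.null(out[[pid]])) out[[pid]] <- list()
    if (is.null(out[[pid]][[cd]]) || d < out[[pid]][[cd]]) out[[pid]][[cd]] <- d
  }
  out
}

oracle_pair_occurs <- function(fd_p, a, b, min_gap, max_gap) {
  da <- fd_p[[a]]; db <- fd_p[[b]]
  if (is.null(da) || is.null(db)) return(FALSE)
  gap <- db - da
  gap >= min_gap && gap <= max_gap
}

# classical two-cohort RR: exposed = patients with `a`, comparison = all
# other patients; B counted after A within the window for exposed, by simple
# presence for the comparison group
oracle_two_cohort_rr <- function(patients, events, a, b, min_gap, max_gap) {
  fd <- oracle_first_days(events)
  pids <- as.character(patients$PID)
  exposed <- c(); unexposed <- c()
  for (pid in pids) {
    if (!is.null(fd[[pid]]) && !is.null(fd[[pid]][[a]])) exposed <- c(exposed, pid)
    else unexposed <- c(unexposed, pid)
  }
  n_ab <- 0L
  for (pid in exposed) if (oracle_pair_occurs(fd[[pid]], a, b, min_gap, max_gap)) n_ab <- n_ab + 1L
  n_b <- 0L
  for (pid in unexposed) if (!is.null(fd[[pid]]) && !is.null(fd[[pid]][[b]])) n_b <- n_b + 1L
  if (length(unexposed) == 0L || length(exposed) == 0L) return(NULL)
  rate1 <- n_ab / length(exposed)
  rate2 <- n_b / length(unexposed)
  list(n_ab = n_ab, n1 = length(exposed), n_b = n_b, n2 = length(unexposed),
       rr = if (rate2 == 0) (if (rate1 > 0) Inf else NA_real_) else rate1 / rate2)
}

# closed-form expectation of the matched-sampling RR estimator, by exact
# enumeration over strata: within each stratum the matched exposed set is the
# first min(#exposed, #unexposed) patients in table order, their exposure
# days sorted are the reference dates, and each reference date is matched to
# a uniformly random unexposed patient.
oracle_stratified_rr <- function(patients, events, a, b, min_gap, max_gap,
                                 n_age_groups) {
  fd <- oracle_first_days(events)
  pids <- as.character(patients$PID)
  sex <- c(f = "female", m = "male", "1" = "male", "2" = "female")[tolower(as.character(patients$SEX))]
  by <- as.integer(patients$BIRTH_YEAR)
  lo <- min(by); hi <- max(by)
  width <- (hi - lo + 1) / n_age_groups
  grp <- pmin(floor((by - lo) / width), n_age_groups - 1)
  stratum <- paste0(sex, "|", grp)
  n_ab <- 0; exp_c <- 0; n1 <- 0
  for (s in unique(stratum)) {
    in_s <- which(stratum == s)
    has_a <- vapply(in_s, function(i) {
      p <- fd[[pids[i]]]; !is.null(p) && !is.null(p[[a]])
    }, logical(1))
    e_idx <- in_s[has_a]; pool <- in_s[!has_a]
    k <- min(length(e_idx), length(pool))
    if (k == 0) next
    e_use <- e_idx[seq_len(k)]
    n1 <- n1 + k
    for (i in e_use) if (oracle_pair_occurs(fd[[pids[i]]], a, b, min_gap, max_gap)) n_ab <- n_ab + 1
    ref <- sort(vapply(e_use, function(i) fd[[pids[i]]][[a]], numeric(1)))
    for (r in ref) {
      hits <- 0
      for (u in pool) {
        db <- fd[[pids[u]]][[b]]
        if (!is.null(db) && db - r >= min_gap && db - r <= max_gap) hits <- hits + 1
      }
      exp_c <- exp_c + hits / length(pool)
    }
  }
  if (n1 == 0 || exp_c == 0) return(NULL)
  list(n_ab = n_ab, n1 = n1, expected_comparison = exp_c, rr = n_ab / exp_c)
}

# exact two-sided binomial p at p0 = 0.5 by direct enumeration of the mass
# function (binom.test's definition: sum all outcomes no more likely than
# the observed one)
oracle_binom_p <- function(k, n) {
  probs <- choose(n, 0:n) / 2^n
  sum(probs[probs <= probs[k + 1] * (1 + 1e-7)])
}

# exhaustive trajectory enumeration: all sequences of distinct codes of
# length in [2, max_len] whose consecutive pairs are all selected and whose
# support reaches min_patients; then keep those of length >= min_len that
# are maximal (length == max_len or no valid one-step extension), or all of
# them when emit_prefixes
oracle_enumerate_trajectories <- function(selected, events, min_gap, max_gap,
                                          min_len, max_len, min_patients,
                                          emit_prefixes = FALSE) {
  fd <- oracle_first_days(events)
  sel_key <- paste(selected$a, selected$b)
  support_of <- function(codes) {
    n <- 0L
    for (p in fd) {
      ok <- TRUE
      for (i in seq_len(length(codes) - 1L)) {
        d1 <- p[[codes[i]]]; d2 <- p[[codes[i + 1L]]]
        if (is.null(d1) || is.null(d2) || d2 - d1 <= 0 ||
            d2 - d1 < min_gap || d2 - d1 > max_gap) { ok <- FALSE; break }
      }
      if (ok) n <- n + 1L
    }
    n
  }
  valid <- list()
  grow <- function(codes) {
    key <- paste(codes, collapse = ">")
    valid[[key]] <<- codes
    if (length(codes) == max_len) return(invisible())
    nexts <- selected$b[selected$a == codes[length(codes)]]
    for (z in nexts) {
      if (z %in% codes) next
      if (support_of(c(codes, z)) >= min_patients) grow(c(codes, z))
    }
  }
  for (i in seq_len(nrow(selected))) {
    if (support_of(c(selected$a[i], selected$b[i])) >= min_patients) {
      grow(c(selected$a[i], selected$b[i]))
    }
  }
  out <- character(0)
  for (key in names(valid)) {
    codes <- valid[[key]]
    if (length(codes) < min_len) next
    if (emit_prefixes) { out <- c(out, key); next }
    if (length(codes) == max_len) { out <- c(out, key); next }
    can_extend <- FALSE
    for (z in selected$b[selected$a == codes[length(codes)]]) {
      if (!(z %in% codes) && support_of(c(codes, z)) >= min_patients) {
        can_extend <- TRUE; break
      }
    }
    if (!can_extend) out <- c(out, key)
  }
  sort(out)
}

# dense reference MCL, independently coded with plain matrix algebra
oracle_mcl_partition <- function(nodes, edges, inflation = 2,
                                 max_iter = 200, prune = 1e-5) {
  n <- length(nodes)
  M <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    M[edges$from[i], edges$to[i]] <- edges$weight[i]
    M[edges$to[i], edges$from[i]] <- edges$weight[i]
  }
  diag(M) <- pmax(apply(M, 2, max), 1e-6)
  norm <- function(A) sweep(A, 2, colSums(A), "/")
  M <- norm(M)
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2[M2 < prune] <- 0
    cs <- colSums(M2)
    if (any(cs == 0)) { diag(M2)[cs == 0] <- 1; cs <- colSums(M2) }
    M2 <- sweep(M2, 2, cs, "/")
    if (max(abs(M2 - M)) < 1e-8) { M <- M2; break }
    M <- M2
  }
  assign_ <- rep(NA_integer_, n)
  k <- 0L
  for (a in which(diag(M) > 0)) {
    members <- which(M[a, ] > 0)
    members <- members[is.na(assign_[members])]
    if (!length(members)) next
    k <- k + 1L
    assign_[members] <- k
  }
  for (u in which(is.na(assign_))) { k <- k + 1L; assign_[u] <- k }
  # canonical form: sets of node names
  unname(lapply(split(nodes, assign_), sort))
}

# canonical partition from a trajmine cluster_set (node level)
partition_of <- function(cs) {
  unname(lapply(cs$clusters, sort))
}

same_partition <- function(p1, p2) {
  f <- function(p) sort(vapply(p, function(x) paste(sort(x), collapse = ","), character(1)))
  identical(f(p1), f(p2))
}
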
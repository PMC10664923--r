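mk_traj <- function(tid, codes) {
  list(tid = tid, codes = codes, support = 10L, supporters = 1:10,
       transition_rr = rep(2, length(codes) - 1))
}
traj_set_of <- function(...) structure(list(...), class = "traj_set")

test_that("trajectory Jaccard follows the set formula", {
  expect_equal(trajectory_jaccard(c("A", "B", "C"), c("B", "C", "D")), 0.5)
  expect_equal(trajectory_jaccard(c("A", "B"), c("A", "B")), 1.0)
  expect_equal(trajectory_jaccard(c("A", "B"), c("C", "D")), 0.0)
  # symmetric and bounded on random sets
  set.seed(2)
  for (i in 1:20) {
    s1 <- sample(LETTERS[1:8], sample(2:5, 1))
    s2 <- sample(LETTERS[1:8], sample(2:5, 1))
    j12 <- trajectory_jaccard(s1, s2)
    expect_equal(j12, trajectory_jaccard(s2, s1))
    expect_gte(j12, 0); expect_lte(j12, 1)
    expect_equal(j12 == 1, setequal(s1, s2))
  }
})

test_that("edge Jaccard counts consecutive-pair containment", {
  # 3 trajectories with consecutive A->B, 5 containing A, 4 containing B
  trs <- traj_set_of(
    mk_traj(1L, c("A", "B", "X")), mk_traj(2L, c("A", "B", "Y")),
    mk_traj(3L, c("Z", "A", "B")),
    mk_traj(4L, c("A", "C", "B")),   # A and B but not consecutive
    mk_traj(5L, c("A", "Q", "R")),
    mk_traj(6L, c("B", "Q", "A"))    # B before A: no A->B pair, but A counted
  )
  # counts: A in 6, B in 5, consecutive A->B in 3 -> 3 / (6 + 5 - 3)
  expect_equal(edge_jaccard("A", "B", trs), 3 / 8)
  expect_equal(edge_jaccard("A", "B", traj_set_of(mk_traj(1L, c("A", "B")))), 1)
  expect_equal(edge_jaccard("V", "W", trs), 0)
})

test_that("trajectory graph stores only positive-weight pairs", {
  trs <- traj_set_of(
    mk_traj(1L, c("A", "B", "C")), mk_traj(2L, c("B", "C", "D")),
    mk_traj(3L, c("X", "Y", "Z"))
  )
  g <- build_trajectory_graph(trs)
  expect_equal(g$nodes, c("1", "2", "3"))
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$weight, 0.5)
  g1 <- build_trajectory_graph(traj_set_of(mk_traj(1L, c("A", "B"))))
  expect_equal(length(g1$nodes), 1L)
  expect_equal(nrow(g1$edges), 0L)
  gid <- build_trajectory_graph(traj_set_of(
    mk_traj(1L, c("A", "B")), mk_traj(2L, c("B", "A")), mk_traj(3L, c("A", "B"))))
  expect_equal(nrow(gid$edges), 3L)
  expect_true(all(gid$edges$weight == 1))
})

test_that("MCL separates disconnected components and singletons", {
  edges <- data.table::data.table(
    from = c("a1", "a1", "a2", "b1", "b1", "b2"),
    to = c("a2", "a3", "a3", "b2", "b3", "b3"),
    weight = 1
  )
  g <- structure(list(nodes = c("a1", "a2", "a3", "b1", "b2", "b3", "lone"),
                      edges = edges, mode = "trajectory"),
                 class = "similarity_graph")
  cs <- mcl(g)
  expect_true(cs$converged)
  part <- partition_of(cs)
  expect_true(same_partition(part, list(c("a1", "a2", "a3"),
                                        c("b1", "b2", "b3"), "lone")))
  # labels: two triangles (size 3) before the singleton; 0-based
  expect_equal(sort(unique(unname(cs$assignment))), c(0L, 1L, 2L))
  expect_equal(unname(cs$assignment[["lone"]]), 2L)
})

test_that("MCL splits weakly bridged cliques and matches a dense reference", {
  clique <- function(prefix) {
    ns <- paste0(prefix, 1:5)
    cmb <- utils::combn(ns, 2)
    data.table::data.table(from = cmb[1, ], to = cmb[2, ], weight = 1)
  }
  edges <- rbind(clique("x"), clique("y"),
                 data.table::data.table(from = "x1", to = "y1", weight = 0.05))
  nodes <- c(paste0("x", 1:5), paste0("y", 1:5))
  g <- structure(list(nodes = nodes, edges = edges, mode = "trajectory"),
                 class = "similarity_graph")
  cs <- mcl(g, inflation = 2)
  part <- partition_of(cs)
  expect_true(same_partition(part, list(paste0("x", 1:5), paste0("y", 1:5))))
  # independent dense implementation agrees
  ref <- oracle_mcl_partition(nodes, edges)
  expect_true(same_partition(part, ref))
})

test_that("MCL partition is invariant under node permutation", {
  set.seed(8)
  nodes <- paste0("n", 1:12)
  cmb <- utils::combn(nodes, 2)
  w <- round(stats::runif(ncol(cmb)), 2)
  keep <- w > 0.3
  edges <- data.table::data.table(from = cmb[1, keep], to = cmb[2, keep],
                                  weight = w[keep])
  g1 <- structure(list(nodes = nodes, edges = edges, mode = "trajectory"),
                  class = "similarity_graph")
  perm <- sample(seq_along(nodes))
  g2 <- structure(list(nodes = nodes[perm], edges = edges, mode = "trajectory"),
                  class = "similarity_graph")
  expect_true(same_partition(partition_of(mcl(g1)), partition_of(mcl(g2))))
})

test_that("trajectory-mode assignment is total; code mode can leave gaps", {
  trs <- traj_set_of(
    mk_traj(1L, c("A", "B", "C")), mk_traj(2L, c("A", "B", "D")),
    mk_traj(3L, c("X", "Y", "Z")),
    mk_traj(4L, c("C", "X", "Y"))    # spans both code communities
  )
  gt <- build_trajectory_graph(trs)
  at <- assign_clusters(trs, mcl(gt), "trajectory")
  expect_equal(at$unassigned_fraction, 0)
  expect_false(any(is.na(at$assignment)))

  sel <- data.table::data.table(
    a = c("A", "B", "B", "X", "Y", "C"), b = c("B", "C", "D", "Y", "Z", "X"),
    rr = 2)
  gc <- build_code_graph(trs, sel)
  ac <- assign_clusters(trs, mcl(gc), "code")
  expect_gte(sum(is.na(ac$assignment)), 1L)  # some trajectory spans clusters
  expect_gt(ac$unassigned_fraction, 0)
  expect_lt(ac$unassigned_fraction, 1)       # others fit inside one cluster
  # assignment rule: assigned iff all codes inside the cluster
  for (t in trs) {
    k <- ac$assignment[[as.character(t$tid)]]
    fits <- vapply(ac$clusters, function(cl) all(t$codes %in% cl), logical(1))
    if (is.na(k)) expect_false(any(fits)) else expect_true(fits[k + 1L])
  }

  expect_error(assign_clusters(trs, mcl(gt), "code"), "mode mismatch")
})

test_that("cluster labels are ordered by decreasing size", {
  trs <- traj_set_of(
    mk_traj(1L, c("X", "Y", "Z")),
    mk_traj(2L, c("A", "B", "C")), mk_traj(3L, c("A", "B", "D")),
    mk_traj(4L, c("B", "C", "D"))
  )
  cs <- assign_clusters(trs, mcl(build_trajectory_graph(trs)), "trajectory")
  sizes <- table(cs$assignment)
  expect_true(all(diff(as.integer(sizes[order(as.integer(names(sizes)))])) <= 0))
  expect_equal(unname(cs$assignment[["1"]]), max(cs$assignment))
})
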
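# Trajectory clustering: similarity graphs (trajectory-ID Jaccard, or legacy
# event-code Jaccard), a native sparse Markov cluster (MCL) implementation,
# and cluster assignment in both modes.

#' Jaccard similarity of two trajectories as code sets
#'
#' `|codes1 n codes2| / |codes1 u codes2|`, ignoring order and repeats.
#'
#' @param t1,t2 trajectories (lists with a `codes` field) or plain code
#'   vectors.
#' @return similarity in `[0, 1]`.
#' @export
trajectory_jaccard <- function(t1, t2) {
  c1 <- unique(if (is.list(t1)) t1$codes else t1)
  c2 <- unique(if (is.list(t2)) t2$codes else t2)
  stopifnot(length(c1) > 0L, length(c2) > 0L)
  i <- length(intersect(c1, c2))
  i / (length(c1) + length(c2) - i)
}

#' Count-based Jaccard weight of a directed pair over a trajectory list
#'
#' The number of trajectories containing `a` immediately followed by `b`,
#' over the number containing `a` plus the number containing `b` minus the
#' pair count; 0 when no trajectory mentions either code.
#'
#' @param a,b event codes.
#' @param trajectories a `traj_set` (or list of lists with `codes`).
#' @return weight in `[0, 1]`.
#' @export
edge_jaccard <- function(a, b, trajectories) {
  n_a <- 0L; n_b <- 0L; n_ab <- 0L
  for (t in trajectories) {
    has_a <- a %in% t$codes
    has_b <- b %in% t$codes
    n_a <- n_a + has_a
    n_b <- n_b + has_b
    if (has_a && has_b) {
      k <- length(t$codes)
      if (any(t$codes[-k] == a & t$codes[-1] == b)) n_ab <- n_ab + 1L
    }
  }
  denom <- n_a + n_b - n_ab
  if (denom == 0L) 0 else n_ab / denom
}

.new_graph <- function(nodes, edges, mode) {
  structure(list(nodes = nodes, edges = edges, mode = mode), class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf("<similarity_graph> mode=%s, %d nodes, %d stored edges\n",
              x$mode, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Build the trajectory-similarity graph
#'
#' One node per trajectory ID; the (conceptually fully connected) graph
#' carries [trajectory_jaccard()] weights, with zero-weight edges omitted
#' from storage (mathematically equivalent for MCL).
#'
#' @param trajectories a non-empty `traj_set`.
#' @return a `similarity_graph` with `mode = "trajectory"`.
#' @export
build_trajectory_graph <- function(trajectories) {
  stopifnot(length(trajectories) >= 1L)
  n <- length(trajectories)
  ids <- as.character(vapply(trajectories, `[[`, integer(1), "tid"))
  from <- integer(0); to <- integer(0); w <- numeric(0)
  sets <- lapply(trajectories, function(t) unique(t$codes))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        ii <- length(intersect(sets[[i]], sets[[j]]))
        if (ii == 0L) next
        from <- c(from, i); to <- c(to, j)
        w <- c(w, ii / (length(sets[[i]]) + length(sets[[j]]) - ii))
      }
    }
  }
  edges <- data.table::data.table(from = ids[from], to = ids[to], weight = w)
  .new_graph(ids, edges, "trajectory")
}

#' Build the legacy event-code graph
#'
#' One node per event code; one undirected edge per selected pair, weighted
#' with [edge_jaccard()] over the trajectory list (zero-weight edges
#' omitted). Clustering this graph partitions *codes*, so trajectories
#' spanning several code clusters end up unassigned — the defect the
#' trajectory-ID strategy was designed to remove.
#'
#' @param trajectories a `traj_set`.
#' @param selected a selected-pair table (columns `a`, `b`).
#' @return a `similarity_graph` with `mode = "code"`.
#' @export
build_code_graph <- function(trajectories, selected) {
  nodes <- sort(unique(c(selected$a, selected$b,
                         unlist(lapply(trajectories, `[[`, "codes")))))
  if (length(nodes) == 0L) .fail("cannot build code graph: no codes")
  w <- vapply(seq_len(nrow(selected)), function(i) {
    edge_jaccard(selected$a[i], selected$b[i], trajectories)
  }, numeric(1))
  keep <- w > 0
  edges <- data.table::data.table(from = selected$a[keep], to = selected$b[keep],
                                  weight = w[keep])
  .new_graph(nodes, edges, "code")
}

#' Markov clustering (MCL) of a similarity graph
#'
#' Native sparse implementation: the symmetric weight matrix gets a
#' self-loop per node equal to its maximum incident weight (at least 1e-6),
#' is column-normalized, then alternates expansion (matrix squaring) and
#' inflation (elementwise power `inflation`, column renormalization) with
#' pruning of entries below `prune_threshold`, until the largest entry
#' change falls below 1e-8 or `max_iterations` is hit (the latter sets a
#' `converged = FALSE` flag on the result and keeps the current
#' interpretation). Clusters are read from attractor rows; nodes claimed by
#' several attractors go to the lowest cluster index; unclaimed nodes form
#' singleton clusters. Cluster labels are 0-based, ordered by decreasing
#' size with ties broken by smallest member position.
#'
#' @param graph a `similarity_graph`.
#' @param inflation inflation exponent (> 1), default 2.
#' @param max_iterations iteration cap, default 200.
#' @param prune_threshold entries below this are dropped each iteration.
#' @return a `cluster_set` with node-level `clusters` (list of node-id
#'   vectors) and `assignment` (named 0-based integer vector over nodes).
#' @export
mcl <- function(graph, inflation = 2, max_iterations = 200L, prune_threshold = 1e-5) {
  stopifnot(inherits(graph, "similarity_graph"), inflation > 1)
  nodes <- graph$nodes
  n <- length(nodes)
  if (n == 0L) .fail("empty graph")
  id <- stats::setNames(seq_len(n), nodes)
  e <- graph$edges
  i <- c(id[e$from], id[e$to])
  j <- c(id[e$to], id[e$from])
  x <- c(e$weight, e$weight)
  M <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
  # self loops: max incident weight per node, floor 1e-6
  loop <- pmax(apply(M, 2, max), 1e-6)
  M <- M + Matrix::Diagonal(n, loop)
  normalize <- function(A) {
    cs <- Matrix::colSums(A)
    zero <- cs == 0
    if (any(zero)) {
      A <- A + Matrix::sparseMatrix(i = which(zero), j = which(zero),
                                    x = 1, dims = c(n, n))
      cs <- Matrix::colSums(A)
    }
    A %*% Matrix::Diagonal(n, 1 / cs)
  }
  M <- normalize(M)
  converged <- FALSE
  for (it in seq_len(max_iterations)) {
    M2 <- M %*% M
    M2 <- as(M2, "CsparseMatrix")
    M2@x <- M2@x^inflation
    M2@x[M2@x < prune_threshold] <- 0
    M2 <- Matrix::drop0(M2)
    M2 <- normalize(M2)
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < 1e-8) { converged <- TRUE; break }
  }
  if (!converged) warning("MCL did not converge within ", max_iterations,
                          " iterations; interpreting current matrix", call. = FALSE)
  D <- Matrix::diag(M)
  attractors <- which(D > 0)
  assign_ <- rep(NA_integer_, n)
  clusters <- list()
  for (a in attractors) {
    members <- which(M[a, ] > 0)
    members <- members[is.na(assign_[members])]
    if (length(members) == 0L) next
    k <- length(clusters) + 1L
    assign_[members] <- k
    clusters[[k]] <- members
  }
  for (u in which(is.na(assign_))) {
    k <- length(clusters) + 1L
    assign_[u] <- k
    clusters[[k]] <- u
  }
  # order by decreasing size, ties by smallest member position; relabel 0-based
  ord <- order(-vapply(clusters, length, integer(1)),
               vapply(clusters, min, integer(1)))
  clusters <- clusters[ord]
  relabel <- integer(length(ord)); relabel[ord] <- seq_along(ord)
  assign_ <- relabel[assign_] - 1L
  structure(list(
    clusters = lapply(clusters, function(m) nodes[m]),
    assignment = stats::setNames(assign_, nodes),
    mode = graph$mode,
    converged = converged
  ), class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> mode=%s, %d clusters over %d nodes%s\n",
              x$mode, length(x$clusters), length(x$assignment),
              if (isTRUE(x$converged)) "" else " (NOT converged)"))
  invisible(x)
}

#' Assign trajectories to clusters
#'
#' In `"trajectory"` mode every trajectory maps to the cluster of its own
#' graph node — assignment is total by construction. In `"code"` mode a
#' trajectory is assigned to a cluster only if *all* its codes lie in that
#' cluster; otherwise it stays unassigned (`NA`), and the unassigned
#' fraction is reported in the result.
#'
#' @param trajectories a `traj_set`.
#' @param clusterset a `cluster_set` from [mcl()] on the matching graph mode.
#' @param mode `"trajectory"` or `"code"`; must equal the graph mode the
#'   clusters came from.
#' @return a `cluster_set` whose `assignment` maps trajectory IDs (as
#'   character names) to 0-based cluster labels (or `NA`), with an
#'   `unassigned_fraction` field.
#' @export
assign_clusters <- function(trajectories, clusterset, mode = c("trajectory", "code")) {
  mode <- match.arg(mode)
  stopifnot(inherits(clusterset, "cluster_set"))
  if (clusterset$mode != mode) {
    .fail("cluster mode mismatch: clusters were built in '", clusterset$mode,
          "' mode, assignment requested in '", mode, "' mode")
  }
  tids <- as.character(vapply(trajectories, `[[`, integer(1), "tid"))
  if (mode == "trajectory") {
    assn <- clusterset$assignment[tids]
  } else {
    assn <- vapply(trajectories, function(t) {
      for (k in seq_along(clusterset$clusters)) {
        if (all(t$codes %in% clusterset$clusters[[k]])) return(k - 1L)
      }
      NA_integer_
    }, integer(1))
  }
  structure(list(
    clusters = clusterset$clusters,
    assignment = stats::setNames(as.integer(assn), tids),
    mode = mode,
    converged = clusterset$converged,
    unassigned_fraction = mean(is.na(assn))
  ), class = "cluster_set")
}
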
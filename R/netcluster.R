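#' Node attribute vectors of a connectivity matrix
#'
#' A connection cluster is a node together with all its incident links; its
#' attribute vector lists the node's connectivity strengths to every other
#' node (M = N - 1 attributes) in the canonical node order with self
#' omitted.  Classifying connection clusters reduces to clustering these
#' vectors.
#'
#' @param F a [connectivity_matrix()].
#' @return Numeric matrix, N rows (named by node) by N - 1 columns; row i is
#'   row i of the matrix with the diagonal entry dropped.
#' @export
node_vectors <- function(F) {
  stopifnot(inherits(F, "connectivity_matrix"))
  n <- length(F$labels)
  out <- t(vapply(seq_len(n), function(i) F$values[i, -i], numeric(n - 1L)))
  rownames(out) <- F$labels
  out
}

#' Agglomerative hierarchical clustering of connection clusters
#'
#' Starting from N singleton clusters, the two closest clusters under the
#' chosen linkage of Euclidean node-vector distances are merged repeatedly
#' until one cluster remains, recording the full merge history.  Leaf
#' clusters carry ids 1..N (canonical node order); the cluster created at
#' merge step s carries id N + s.  Ties in the arg-min are broken towards
#' the lexicographically smallest (id, id) pair, making the procedure fully
#' deterministic.
#'
#' @param vectors numeric matrix of node vectors (rows = nodes), e.g. from
#'   [node_vectors()], or a [connectivity_matrix()].
#' @param linkage \code{"single"} (default; nearest members, the most
#'   literal reading of an arg-min merge rule), \code{"complete"} or
#'   \code{"average"}.
#' @return An object of class \code{network_dendrogram} with components
#'   \code{merges} (data frame: step, left, right, new, height),
#'   \code{labels}, \code{n}, \code{linkage}.
#' @examples
#' v <- matrix(c(0, 1, 10), ncol = 1)
#' rownames(v) <- c("a", "b", "c")
#' agglomerate(v)$merges  # first merge joins a and b
#' @export
agglomerate <- function(vectors, linkage = c("single", "complete", "average")) {
  if (inherits(vectors, "connectivity_matrix")) vectors <- node_vectors(vectors)
  linkage <- match.arg(linkage)
  vectors <- as.matrix(vectors)
  n <- nrow(vectors)
  if (n < 1L) stop("no node vectors supplied", call. = FALSE)
  labels <- rownames(vectors) %||% paste0("V", seq_len(n))
  if (n == 1L)
    return(structure(list(merges = data.frame(step = integer(), left = integer(),
                                              right = integer(), new = integer(),
                                              height = numeric()),
                          labels = labels, n = 1L, linkage = linkage),
                     class = "network_dendrogram"))
  D <- as.matrix(stats::dist(vectors))       # Euclidean between node vectors
  ids <- seq_len(n)                          # current cluster ids per slot
  sizes <- rep(1L, n)
  active <- rep(TRUE, n)
  merges <- data.frame(step = seq_len(n - 1L), left = NA_integer_,
                       right = NA_integer_, new = NA_integer_,
                       height = NA_real_)
  for (s in seq_len(n - 1L)) {
    best <- NULL
    slots <- which(active)
    for (ai in seq_along(slots)[-length(slots)]) {
      for (bi in (ai + 1L):length(slots)) {
        a <- slots[ai]; b <- slots[bi]
        d <- D[a, b]
        pr <- sort(c(ids[a], ids[b]))
        if (is.null(best) || d < best$d - 1e-15 ||
            (abs(d - best$d) <= 1e-15 &&
             (pr[1] < best$pr[1] ||
              (pr[1] == best$pr[1] && pr[2] < best$pr[2])))) {
          best <- list(d = d, a = a, b = b, pr = pr)
        }
      }
    }
    a <- best$a; b <- best$b
    new_id <- n + s
    merges$left[s] <- best$pr[1]
    merges$right[s] <- best$pr[2]
    merges$new[s] <- new_id
    merges$height[s] <- best$d
    # Lance-Williams update into slot a; slot b retired
    for (k in which(active)) {
      if (k == a || k == b) next
      D[a, k] <- D[k, a] <- switch(linkage,
        single   = min(D[a, k], D[b, k]),
        complete = max(D[a, k], D[b, k]),
        average  = (sizes[a] * D[a, k] + sizes[b] * D[b, k]) /
                   (sizes[a] + sizes[b]))
    }
    sizes[a] <- sizes[a] + sizes[b]
    ids[a] <- new_id
    active[b] <- FALSE
  }
  structure(list(merges = merges, labels = labels, n = n, linkage = linkage),
            class = "network_dendrogram")
}

#' @export
print.network_dendrogram <- function(x, ...) {
  cat("<network_dendrogram> ", x$n, " leaves, ", x$linkage,
      " linkage\n", sep = "")
  print(x$merges)
  invisible(x)
}

#' Convert to a \code{stats::hclust} object (e.g. for plotting)
#'
#' @param x a [agglomerate()] dendrogram.
#' @param ... unused.
#' @return An \code{hclust} object.
#' @export
as.hclust.network_dendrogram <- function(x, ...) {
  n <- x$n
  conv <- function(id) if (id <= n) -id else id - n
  merge <- cbind(vapply(x$merges$left, conv, 0), vapply(x$merges$right, conv, 0))
  structure(list(merge = merge, height = x$merges$height,
                 order = dendrogram_leaf_order(x), labels = x$labels,
                 method = x$linkage, dist.method = "euclidean"),
            class = "hclust")
}

dendrogram_leaf_order <- function(dend) {
  n <- dend$n
  members <- function(id) {
    if (id <= n) return(id)
    s <- id - n
    c(members(dend$merges$left[s]), members(dend$merges$right[s]))
  }
  if (n == 1L) 1L else members(2L * n - 1L)
}

#' @export
plot.network_dendrogram <- function(x, ...) {
  plot(as.hclust.network_dendrogram(x), ...)
  invisible(x)
}

#' Cut a dendrogram into Z clusters
#'
#' Undoes the last Z - 1 merges: the partition is the set of clusters that
#' existed after N - Z merge steps.
#'
#' @param dend a [agglomerate()] dendrogram.
#' @param Z number of clusters, between 1 and N.
#' @return A list: \code{cluster_ids} (surviving ids), \code{members}
#'   (list of node-label vectors, named by cluster id), \code{leaf_ids}
#'   (list of leaf index vectors), \code{Z}.
#' @export
cut_dendrogram <- function(dend, Z) {
  stopifnot(inherits(dend, "network_dendrogram"))
  n <- dend$n
  if (length(Z) != 1L || Z < 1L || Z > n)
    stop("Z must lie between 1 and ", n, call. = FALSE)
  Z <- as.integer(Z)
  members <- as.list(seq_len(n))
  ids <- seq_len(n)
  steps <- n - Z
  for (s in seq_len(steps)) {
    li <- match(dend$merges$left[s], ids)
    ri <- match(dend$merges$right[s], ids)
    members[[li]] <- c(members[[li]], members[[ri]])
    ids[li] <- dend$merges$new[s]
    members <- members[-ri]
    ids <- ids[-ri]
  }
  names(members) <- ids
  list(cluster_ids = ids,
       members = lapply(members, function(ix) dend$labels[sort(ix)]),
       leaf_ids = lapply(members, sort),
       Z = Z)
}

#' Merge-order class labels of the cut clusters
#'
#' After cutting the dendrogram into Z clusters, each cut cluster is ranked
#' by the merge step at which it is first absorbed into a larger cluster:
#' the earlier a cluster is swallowed, the more similar it is to the rest of
#' the network, so it gets a low class; the cluster that stays distinct
#' longest gets Class Z (most different / most active).  When two cut
#' clusters are absorbed at the same step (they merge with each other), the
#' one containing the lower canonical node index takes the lower class.
#' All member nodes inherit their cluster's class.
#'
#' @param dend a [agglomerate()] dendrogram.
#' @param Z number of classes (default 4).
#' @return An object of class \code{class_assignment}: \code{labels} (named
#'   integer vector node -> class), \code{Z}, \code{clusters} (data frame:
#'   cluster id, absorption step, class).
#' @export
assign_classes <- function(dend, Z = 4L) {
  cut <- cut_dendrogram(dend, Z)
  n <- dend$n
  Z <- cut$Z
  absorbed <- vapply(cut$cluster_ids, function(id) {
    id <- as.integer(id)
    s <- which(dend$merges$left == id | dend$merges$right == id)
    if (length(s) == 0L) n else s[1]      # root of a Z = 1 cut: never absorbed
  }, 0)
  min_leaf <- vapply(cut$leaf_ids, min, 0L)
  rank_order <- order(absorbed, min_leaf)
  cls <- integer(Z)
  cls[rank_order] <- seq_len(Z)
  labels <- integer(n)
  names(labels) <- dend$labels
  for (i in seq_len(Z)) labels[cut$members[[i]]] <- cls[i]
  structure(list(labels = labels, Z = Z,
                 clusters = data.frame(cluster_id = as.integer(cut$cluster_ids),
                                       absorbed_step = absorbed,
                                       class = cls)),
            class = "class_assignment")
}

#' @export
print.class_assignment <- function(x, ...) {
  cat("<class_assignment> Z = ", x$Z, "\n", sep = "")
  for (z in seq_len(x$Z))
    cat("  Class ", z, ": ",
        paste(names(x$labels)[x$labels == z], collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' Node-by-segment class trajectory
#'
#' Stacks per-segment class assignments into an N x K integer matrix whose
#' rows follow the canonical node order, showing how each connection
#' cluster's class evolves across the recording stages.
#'
#' @param assignments list of [assign_classes()] results sharing one node
#'   set (one per segment, in order).
#' @return Integer matrix, rows named by node, columns \code{seg1..segK}.
#' @export
class_trajectory <- function(assignments) {
  stopifnot(length(assignments) >= 1L)
  nodes <- names(assignments[[1]]$labels)
  cols <- lapply(seq_along(assignments), function(k) {
    a <- assignments[[k]]
    if (!setequal(names(a$labels), nodes))
      stop("segment ", k, " has a different node set", call. = FALSE)
    a$labels[nodes]
  })
  m <- do.call(cbind, cols)
  dimnames(m) <- list(nodes, paste0("seg", seq_along(assignments)))
  m
}

# --- Louvain comparator -----------------------------------------------------

#' Weighted modularity of a partition
#'
#' \deqn{Q = \frac{1}{2m} \sum_{ij} \left(A_{ij} -
#'   \frac{k_i k_j}{2m}\right) \delta(c_i, c_j)}
#' with \eqn{k_i = \sum_j A_{ij}} and \eqn{2m = \sum_{ij} A_{ij}}.
#'
#' @param F a [connectivity_matrix()] or symmetric weight matrix (zero
#'   diagonal).
#' @param membership integer community label per node.
#' @return Scalar Q (0 for an empty graph).
#' @export
modularity_q <- function(F, membership) {
  A <- if (inherits(F, "connectivity_matrix")) F$values else as.matrix(F)
  m2 <- sum(A)
  if (m2 <= 0) return(0)
  k <- rowSums(A)
  same <- outer(membership, membership, "==")
  sum((A - outer(k, k) / m2) * same) / m2
}

#' Louvain community detection (comparator method)
#'
#' Greedy two-phase modularity optimisation on the weighted graph whose
#' edge weights are the connectivity strengths: nodes are repeatedly moved
#' to the neighbouring community with the largest modularity increment,
#' then communities are aggregated into super-nodes, until no move improves
#' Q.  The first-level node sweep order is the canonical node order
#' shuffled by \code{seed}, making results reproducible while exposing the
#' algorithm's order dependence.
#'
#' @param F a [connectivity_matrix()].
#' @param seed integer controlling the sweep order.
#' @return A list: \code{membership} (named integer vector, communities
#'   numbered by first appearance in node order), \code{Q} (weighted
#'   modularity of the returned partition), \code{seed}.
#' @export
louvain_communities <- function(F, seed = 1L) {
  stopifnot(inherits(F, "connectivity_matrix"))
  A <- F$values
  n <- nrow(A)
  if (sum(A) <= 0) {
    membership <- stats::setNames(rep(1L, n), F$labels)
    return(list(membership = membership, Q = 0, seed = seed))
  }
  sweep_order <- local_sample(seq_len(n), seed)
  node_comm <- seq_len(n)              # community of each original node
  W <- A
  order_now <- sweep_order
  repeat {
    res <- louvain_one_level(W, order_now)
    node_comm <- res$membership[node_comm]
    if (!res$improved || max(res$membership) == nrow(W)) break
    W <- louvain_aggregate(W, res$membership)
    order_now <- seq_len(nrow(W))
  }
  # renumber by first appearance in canonical order
  membership <- match(node_comm, unique(node_comm))
  names(membership) <- F$labels
  list(membership = membership, Q = modularity_q(F, membership), seed = seed)
}

# One Louvain level: local moves on weight matrix W (self-loops on the
# diagonal allowed) sweeping nodes in the given order until stable.
louvain_one_level <- function(W, sweep_order) {
  n <- nrow(W)
  comm <- seq_len(n)
  m2 <- sum(W)
  k <- rowSums(W)
  tot <- k                      # community total strengths
  improved <- FALSE
  repeat {
    moved <- FALSE
    for (i in sweep_order) {
      ci <- comm[i]
      w_i <- W[i, ]
      w_i[i] <- 0
      # links from i to each community
      links <- tapply(w_i, comm, sum)
      cand <- as.integer(names(links))
      tot[ci] <- tot[ci] - k[i]
      w_cur <- if (as.character(ci) %in% names(links)) links[[as.character(ci)]] else 0
      base <- 2 * w_cur / m2 - 2 * k[i] * tot[ci] / m2^2
      best_c <- ci
      best_gain <- 0
      for (jj in seq_along(cand)) {
        cc <- cand[jj]
        if (cc == ci) next
        gain <- (2 * links[[jj]] / m2 - 2 * k[i] * tot[cc] / m2^2) - base
        if (gain > best_gain + 1e-12 ||
            (gain > best_gain - 1e-12 && gain > 1e-12 && cc < best_c)) {
          best_gain <- gain
          best_c <- cc
        }
      }
      comm[i] <- best_c
      tot[best_c] <- tot[best_c] + k[i]
      if (best_c != ci) {
        moved <- TRUE
        improved <- TRUE
      }
    }
    if (!moved) break
  }
  list(membership = match(comm, unique(comm)), improved = improved)
}

louvain_aggregate <- function(W, membership) {
  C <- max(membership)
  M <- matrix(0, nrow(W), C)
  M[cbind(seq_len(nrow(W)), membership)] <- 1
  t(M) %*% W %*% M
}

# Deterministic shuffle that leaves the caller's RNG stream untouched.
local_sample <- function(x, seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample(x)
}
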
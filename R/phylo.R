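#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration (Q-criterion). Ties in the
#' Q-criterion are broken deterministically by the smallest (row, column)
#' label-index pair; negative estimated branch lengths are clamped to zero
#' (no redistribution).
#'
#' @param m Labeled symmetric nonnegative matrix with zero diagonal and at
#'   least 3 labels.
#' @return An unrooted `ape::phylo` tree whose tips are the matrix labels.
#'   The number of clamped branches is recorded in attribute
#'   `clamped_branches`.
#' @export
neighbor_joining <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m)
  if (n < 3) abort("need at least 3 labels")
  if (is.null(rownames(m))) {
    rownames(m) <- colnames(m) <- paste0("t", seq_len(n))
  }
  if (max(abs(m - t(m))) > 1e-12 || any(m < 0)) {
    abort("distance matrix must be symmetric and nonnegative")
  }
  labels <- rownames(m)
  # Active node bookkeeping: tips are 1..n, internal nodes get ids n+1, ...
  active <- seq_len(n)
  next_id <- n + 1L
  d <- m
  edges <- list()
  clamped <- 0L
  add_edge <- function(parent, child, len) {
    if (len < 0) {
      clamped <<- clamped + 1L
      len <- 0
    }
    edges[[length(edges) + 1L]] <<- c(parent, child, len)
  }
  while (length(active) > 3L) {
    k <- length(active)
    r <- rowSums(d)
    q <- (k - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    best <- which(q == min(q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (k - 2))
    lj <- d[i, j] - li
    u <- next_id; next_id <- next_id + 1L
    add_edge(u, active[i], li)
    add_edge(u, active[j], lj)
    du <- (d[i, -c(i, j)] + d[j, -c(i, j)] - d[i, j]) / 2
    keep <- setdiff(seq_len(k), c(i, j))
    d_new <- rbind(cbind(d[keep, keep, drop = FALSE], du), c(du, 0))
    active <- c(active[keep], u)
    d <- d_new
  }
  # Final 3-node star: closed-form branch lengths.
  u <- next_id
  l1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  l2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  l3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  add_edge(u, active[1], l1)
  add_edge(u, active[2], l2)
  add_edge(u, active[3], l3)

  edge_mat <- do.call(rbind, edges)
  tree <- build_phylo(edge_mat, labels, n, root = u)
  attr(tree, "clamped_branches") <- clamped
  tree
}

# Convert an (parent, child, length) edge list over arbitrary internal ids
# into a valid ape phylo: internal nodes renumbered in preorder from the root.
build_phylo <- function(edge_mat, labels, n_tip, root) {
  children <- split(seq_len(nrow(edge_mat)), edge_mat[, 1])
  new_id <- integer(max(edge_mat[, 1:2]))
  new_id[seq_len(n_tip)] <- seq_len(n_tip)
  counter <- n_tip
  out_edges <- matrix(0, nrow(edge_mat), 2)
  out_len <- numeric(nrow(edge_mat))
  row_i <- 0L
  visit <- function(node) {
    counter <<- counter + 1L
    new_id[node] <<- counter
    for (e in children[[as.character(node)]]) {
      child <- edge_mat[e, 2]
      row_i <<- row_i + 1L
      my_row <- row_i
      if (child <= n_tip) {
        out_edges[my_row, ] <<- c(new_id[node], child)
      } else {
        out_edges[my_row, 1] <<- new_id[node]
        visit(child)
        out_edges[my_row, 2] <<- new_id[child]
      }
      out_len[my_row] <<- edge_mat[e, 3]
    }
  }
  visit(root)
  tree <- list(
    edge = out_edges, edge.length = out_len,
    tip.label = labels, Nnode = counter - n_tip
  )
  class(tree) <- "phylo"
  attr(tree, "order") <- "cladewise"
  tree
}

# All tip bipartitions induced by the edges of an unrooted tree, keyed by a
# canonical string: the sorted labels of the side NOT containing the
# alphabetically first tip. Values are branch lengths. `trivial` marks
# single-tip (terminal) branches.
tree_bipartitions <- function(tree) {
  n_tip <- length(tree$tip.label)
  anchor <- sort(tree$tip.label)[1]
  # Tips below each edge via one postorder pass.
  post <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) below[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(post$edge))) {
    p <- post$edge[e, 1]; ch <- post$edge[e, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  keys <- character(nrow(tree$edge))
  lens <- tree$edge.length
  trivial <- logical(nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    side <- below[[tree$edge[e, 2]]]
    if (anchor %in% side) side <- setdiff(tree$tip.label, side)
    keys[e] <- paste(sort(side), collapse = "|")
    trivial[e] <- length(side) <= 1L || length(side) >= n_tip - 1L
  }
  tibble(key = keys, length = lens, trivial = trivial)
}

check_same_tips <- function(a, b) {
  if (!setequal(a$tip.label, b$tip.label)) {
    abort("trees must have identical tip sets")
  }
}

#' Partition (topological) distance between two trees
#'
#' Counts the bipartitions of the tips induced by internal branches that are
#' present in one tree but not the other — twice the number of internal
#' branches defining different bipartitions, i.e. the unnormalised
#' Robinson–Foulds count. Zero iff the unrooted topologies agree.
#'
#' @param a,b `phylo` trees over the same tip set.
#' @return Even nonnegative integer (for binary trees).
#' @export
partition_distance <- function(a, b) {
  check_same_tips(a, b)
  ka <- unique(tree_bipartitions(a)$key[!tree_bipartitions(a)$trivial])
  kb <- unique(tree_bipartitions(b)$key[!tree_bipartitions(b)$trivial])
  length(setdiff(ka, kb)) + length(setdiff(kb, ka))
}

#' Branch-score distance between two trees
#'
#' Branches are matched by the tip bipartition they induce (terminal branches
#' included); matched pairs contribute the squared difference of their branch
#' lengths, branches present in only one tree contribute their length squared.
#' The distance is the square root of the total, so it reduces exactly to
#' sqrt(sum_i (X_i - Y_i)^2) when the two topologies agree. The returned
#' value carries attribute `shared_topology` flagging whether they do.
#'
#' @param a,b `phylo` trees over the same tip set.
#' @return Nonnegative number.
#' @export
branch_length_distance <- function(a, b) {
  check_same_tips(a, b)
  ba <- tree_bipartitions(a)
  bb <- tree_bipartitions(b)
  la <- tapply(ba$length, ba$key, sum)
  lb <- tapply(bb$length, bb$key, sum)
  keys <- union(names(la), names(lb))
  xa <- ifelse(keys %in% names(la), la[keys], 0)
  xb <- ifelse(keys %in% names(lb), lb[keys], 0)
  out <- sqrt(sum((xa - xb)^2))
  attr(out, "shared_topology") <-
    setequal(ba$key[!ba$trivial], bb$key[!bb$trivial])
  out
}

#' Frobenius distance between two distance matrices
#'
#' sqrt(trace((A - B)(A - B)')) — the Frobenius norm of the elementwise
#' difference. Matrices are aligned by label before differencing.
#'
#' @param a,b Labeled symmetric matrices over the same label set.
#' @return Nonnegative number.
#' @export
frobenius_distance <- function(a, b) {
  if (is.null(rownames(a)) || is.null(rownames(b))) {
    if (!all(dim(a) == dim(b))) abort("matrices must have equal dimensions")
  } else {
    if (!setequal(rownames(a), rownames(b))) {
      abort("matrices must share the same labels")
    }
    b <- b[rownames(a), rownames(a)]
  }
  sqrt(sum((a - b)^2))
}
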
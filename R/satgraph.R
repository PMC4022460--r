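# Exact k-nearest neighbors by blockwise Euclidean distance.
# Returns list(idx = n x k neighbor indices, dist = matching distances).
knn_exact <- function(x, k, block = 1024L) {
  n <- nrow(x)
  if (n <= k) stop("need more points than neighbors")
  sq <- rowSums(x * x)
  idx <- matrix(0L, n, k)
  dst <- matrix(0, n, k)
  for (b0 in seq.int(1L, n, by = block)) {
    b1 <- min(b0 + block - 1L, n)
    rows <- b0:b1
    d2 <- outer(sq[rows], sq, "+") - 2 * tcrossprod(x[rows, , drop = FALSE], x)
    d2[cbind(seq_along(rows), rows)] <- Inf
    for (r in seq_along(rows)) {
      dr <- d2[r, ]
      kth <- sort.int(dr, partial = k)[k]
      cand <- which(dr <= kth)
      cand <- cand[order(dr[cand], cand)][seq_len(k)]
      idx[rows[r], ] <- cand
      dst[rows[r], ] <- sqrt(pmax(dr[cand], 0))
    }
  }
  list(idx = idx, dist = dst)
}

#' Build the k-nearest-neighbor read graph
#'
#' Computes each read's `k_nn` exact nearest neighbors by Euclidean distance
#' in the standardized feature space and records the union of neighbor
#' relations (either direction) as a weighted undirected graph. Edge weights
#' map distance `d` to `1 - d / d_max` (bounded in (0, 1], with `d_max` the
#' largest distance over all kNN edges; the single farthest edge is floored
#' at a negligible positive weight). If all points coincide, every edge gets
#' weight 1.
#'
#' @param fm a standardized `kmer_matrix`.
#' @param k_nn neighbors per read (default 50).
#' @return an object of class `read_graph`: list with `ids`, `n`, `k_nn`,
#'   `d_max` and `edges` (data.frame `i`, `j`, `weight`, `kind`, with
#'   `i < j`).
#' @export
build_knn_graph <- function(fm, k_nn = 50L) {
  if (fm$state != "standardized") stop("matrix must be standardized")
  x <- fm$values
  n <- nrow(x)
  if (n <= k_nn) stop("need more than k_nn = ", k_nn, " reads")
  nn <- knn_exact(x, k_nn)
  i <- rep(seq_len(n), each = k_nn)
  j <- as.integer(t(nn$idx))
  d <- as.numeric(t(nn$dist))
  lo <- pmin(i, j); hi <- pmax(i, j)
  key <- (lo - 1) * n + hi
  keep <- !duplicated(key)
  lo <- lo[keep]; hi <- hi[keep]; d <- d[keep]
  d_max <- max(d)
  w <- if (d_max == 0) rep(1, length(d)) else pmax(1 - d / d_max, 1e-12)
  structure(list(ids = rownames(x), n = n, k_nn = as.integer(k_nn),
                 d_max = d_max,
                 edges = data.frame(i = lo, j = hi, weight = w,
                                    kind = "knn", stringsAsFactors = FALSE)),
            class = "read_graph")
}

#' @export
print.read_graph <- function(x, ...) {
  cat(sprintf("<read_graph> %d vertices, %d edges (%d mate-pair)\n",
              x$n, nrow(x$edges), sum(x$edges$kind == "pair")))
  invisible(x)
}

#' Overlay maximum-weight mate-pair edges
#'
#' Adds one edge of weight 1 per mate pair (the maximum possible weight,
#' encoding physical linkage); if a kNN edge already joins the pair its
#' weight is raised to 1. Pairs whose ends are not both in the graph are
#' skipped and counted.
#'
#' @param graph a [build_knn_graph()] result.
#' @param pairs data.frame `read_id`, `mate_id`.
#' @return the graph with mate-pair edges added (attribute `n_skipped_pairs`
#'   records pairs with missing ends).
#' @export
add_matepair_edges <- function(graph, pairs) {
  a <- match(pairs$read_id, graph$ids)
  b <- match(pairs$mate_id, graph$ids)
  ok <- !is.na(a) & !is.na(b) & a != b
  n_skipped <- sum(!ok)
  a <- a[ok]; b <- b[ok]
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- (lo - 1) * graph$n + hi
  keep <- !duplicated(key)
  lo <- lo[keep]; hi <- hi[keep]; key <- key[keep]
  ekey <- (graph$edges$i - 1) * graph$n + graph$edges$j
  hit <- match(key, ekey)
  upgrade <- !is.na(hit)
  graph$edges$weight[hit[upgrade]] <- 1
  graph$edges$kind[hit[upgrade]] <- "pair"
  if (any(!upgrade)) {
    graph$edges <- rbind(graph$edges,
                         data.frame(i = lo[!upgrade], j = hi[!upgrade],
                                    weight = 1, kind = "pair",
                                    stringsAsFactors = FALSE))
  }
  attr(graph, "n_skipped_pairs") <- n_skipped
  graph
}

# Sparse symmetric weight matrix of (a subgraph of) a read_graph.
graph_weight_matrix <- function(graph, members = NULL) {
  e <- graph$edges
  if (!is.null(members)) {
    sel <- e$i %in% members & e$j %in% members
    e <- e[sel, , drop = FALSE]
    map <- integer(graph$n)
    map[members] <- seq_along(members)
    e$i <- map[e$i]; e$j <- map[e$j]
    n <- length(members)
  } else n <- graph$n
  Matrix::sparseMatrix(i = c(e$i, e$j), j = c(e$j, e$i),
                       x = c(e$weight, e$weight), dims = c(n, n))
}

# Second-smallest generalized eigenvector of (D - W) v = mu D v, i.e.
# D^{-1/2} u where u is the second-largest eigenvector of D^{-1/2} W D^{-1/2}.
fiedler_vector <- function(W, deg) {
  n <- nrow(W)
  dsi <- 1 / sqrt(deg)
  M <- Matrix::Diagonal(x = dsi) %*% W %*% Matrix::Diagonal(x = dsi)
  if (n <= 256L) {
    e <- eigen(as.matrix(M), symmetric = TRUE)
    u <- e$vectors[, 2L]
  } else {
    f <- function(x, extra) as.numeric(M %*% x)
    res <- tryCatch(
      igraph::arpack(f, sym = TRUE,
                     options = list(n = n, nev = 2L,
                                    ncv = min(n, max(20L, 8L)),
                                    which = "LA", maxiter = 5000L)),
      error = function(e)
        stop("eigensolver failure on graph with ", n, " vertices: ",
             conditionMessage(e)))
    vecs <- res$vectors
    ord <- order(res$values, decreasing = TRUE)
    u <- vecs[, ord[2L]]
  }
  v <- u * dsi
  nz <- which(abs(v) > 1e-12)
  if (length(nz) && v[nz[1L]] < 0) v <- -v
  v
}

# Normalized cut value of a bipartition given edges and degrees.
ncut_value <- function(edges, deg, inA) {
  cross <- xor(inA[edges$i], inA[edges$j])
  cut <- sum(edges$weight[cross])
  volA <- sum(deg[inA]); volB <- sum(deg[!inA])
  if (volA == 0 || volB == 0) return(Inf)
  cut / volA + cut / volB
}

#' Normalized-cut spectral bipartition
#'
#' Splits a (sub)graph into two groups severing the least total edge weight
#' relative to the groups' volumes. The second-smallest generalized
#' eigenvector of `(D - W) v = mu D v` is computed (dense for small graphs,
#' ARPACK otherwise, sign fixed by the first nonzero entry); the partition
#' is the minimum-normalized-cut sweep cut over thresholds of the
#' eigenvector (all `n - 1` order-statistic thresholds up to 10,000
#' vertices, 512 quantile thresholds beyond). A disconnected graph is split
#' along components (largest component versus the rest; ncut 0).
#'
#' @param graph a `read_graph`.
#' @param members optional vertex indices of the subgraph to split.
#' @return list with `A`, `B` (vertex indices relative to the full graph),
#'   `ncut`, and `eigenvector` (NULL for component splits).
#' @export
spectral_bipartition <- function(graph, members = NULL) {
  if (is.null(members)) members <- seq_len(graph$n)
  n <- length(members)
  if (n < 2L) stop("cannot bipartition fewer than 2 vertices")
  W <- graph_weight_matrix(graph, members)
  e <- Matrix::summary(W)
  e <- e[e$i < e$j, , drop = FALSE]
  edges <- data.frame(i = e$i, j = e$j, weight = e$x)
  ig <- igraph::graph_from_data_frame(
    data.frame(from = c(edges$i, seq_len(n)), to = c(edges$j, seq_len(n))),
    directed = FALSE)
  comp <- igraph::components(ig)
  memb <- comp$membership[as.character(seq_len(n))]
  if (comp$no > 1L) {
    largest <- which.max(tabulate(memb))
    inA <- memb == largest
    return(list(A = members[inA], B = members[!inA], ncut = 0,
                eigenvector = NULL))
  }
  deg <- Matrix::rowSums(W)
  v <- fiedler_vector(W, deg)
  ord <- order(v, seq_len(n))
  pos <- integer(n); pos[ord] <- seq_len(n)
  # cut weight of each prefix split via a difference array over edge spans
  delta <- numeric(n)
  lo <- pmin(pos[edges$i], pos[edges$j])
  hi <- pmax(pos[edges$i], pos[edges$j])
  for (r in seq_len(nrow(edges))) {
    delta[lo[r]] <- delta[lo[r]] + edges$weight[r]
    delta[hi[r]] <- delta[hi[r]] - edges$weight[r]
  }
  cutw <- cumsum(delta)[seq_len(n - 1L)]
  volA <- cumsum(deg[ord])[seq_len(n - 1L)]
  volB <- sum(deg) - volA
  nc <- cutw / volA + cutw / volB
  ts <- if (n <= 10000L) seq_len(n - 1L) else
    unique(pmax(1L, pmin(n - 1L, round(seq(1L, n - 1L, length.out = 512L)))))
  best <- ts[which.min(nc[ts])]
  inA <- logical(n); inA[ord[seq_len(best)]] <- TRUE
  list(A = members[inA], B = members[!inA], ncut = nc[best], eigenvector = v)
}

#' Self-mate-pair frequency of a read cluster
#'
#' The proportion of all mate pairs touching a cluster whose both ends lie
#' inside it. With a second cluster supplied, the denominator is restricted
#' to pairs whose other end is in either cluster — the pairwise form
#' `(A->A) / (A->A + A->B)`.
#'
#' @param members read ids in the cluster.
#' @param pairs data.frame `read_id`, `mate_id`.
#' @param other optional read ids of a second cluster.
#' @return frequency in `[0, 1]`, or `NA` when no pair qualifies.
#' @export
self_mate_pair_frequency <- function(members, pairs, other = NULL) {
  in1 <- pairs$read_id %in% members
  in2 <- pairs$mate_id %in% members
  touch <- in1 | in2
  both <- in1 & in2
  if (!is.null(other)) {
    u <- c(members, other)
    inU <- (pairs$read_id %in% u) & (pairs$mate_id %in% u)
    touch <- touch & inU
  }
  denom <- sum(touch)
  if (denom == 0L) return(NA_real_)
  sum(both) / denom
}

#' Clustering parameters
#'
#' @param smp_threshold self-mate-pair frequency both daughters of a split
#'   must exceed for the split to be accepted (default 0.8).
#' @param min_cluster_size minimum daughter size (default `2 * k_nn`,
#'   resolved when clustering).
#' @return a list of class `cluster_params`.
#' @export
cluster_params <- function(smp_threshold = 0.8, min_cluster_size = NULL) {
  stopifnot(smp_threshold > 0, smp_threshold <= 1)
  structure(list(smp_threshold = smp_threshold,
                 min_cluster_size = min_cluster_size),
            class = "cluster_params")
}

#' Recursive mate-pair-gated spectral clustering
#'
#' Recursively applies [spectral_bipartition()]: a split is accepted only if
#' both daughter clusters exceed the self-mate-pair frequency threshold and
#' the minimum size; otherwise the node becomes a leaf (a subfamily).
#' Daughters of accepted splits are recursed independently. Leaves are
#' labeled `SF01`, `SF02`, ... by decreasing size (ties by smallest member
#' index).
#'
#' @param graph a `read_graph` with mate-pair edges.
#' @param pairs data.frame `read_id`, `mate_id`.
#' @param params a [cluster_params()].
#' @return an object of class `sat_cluster_tree`: list with `root` (nested
#'   nodes carrying `members`, `smp`, `ncut`, `split_accepted`, `children`,
#'   and for leaves `label`), `assignments` (named read id -> label),
#'   `n_leaves` and `params`.
#' @export
recursive_cluster <- function(graph, pairs, params = cluster_params()) {
  if (is.null(params$min_cluster_size))
    params$min_cluster_size <- 2L * graph$k_nn
  build <- function(members) {
    node <- list(members = members, size = length(members),
                 smp = self_mate_pair_frequency(graph$ids[members], pairs),
                 ncut = NA_real_, split_accepted = FALSE, children = NULL)
    if (length(members) < 2L) return(node)
    bp <- spectral_bipartition(graph, members)
    node$ncut <- bp$ncut
    smpA <- self_mate_pair_frequency(graph$ids[bp$A], pairs)
    smpB <- self_mate_pair_frequency(graph$ids[bp$B], pairs)
    ok <- !is.na(smpA) && !is.na(smpB) &&
      smpA > params$smp_threshold && smpB > params$smp_threshold &&
      length(bp$A) >= params$min_cluster_size &&
      length(bp$B) >= params$min_cluster_size
    if (ok) {
      node$split_accepted <- TRUE
      node$children <- list(build(bp$A), build(bp$B))
      node$child_smp <- c(smpA, smpB)
    }
    node
  }
  root <- build(seq_len(graph$n))
  leaves <- list()
  collect <- function(node) {
    if (is.null(node$children)) leaves[[length(leaves) + 1L]] <<- node
    else for (ch in node$children) collect(ch)
  }
  collect(root)
  sizes <- vapply(leaves, `[[`, 0L, "size")
  firsts <- vapply(leaves, function(l) min(l$members), 0L)
  ord <- order(-sizes, firsts)
  labels <- character(length(leaves))
  labels[ord] <- sprintf("SF%02d", seq_along(leaves))
  assign_labels <- function(node, path = integer(0)) node
  assignments <- character(graph$n)
  for (li in seq_along(leaves))
    assignments[leaves[[li]]$members] <- labels[li]
  names(assignments) <- graph$ids
  label_tree <- function(node) {
    if (is.null(node$children)) {
      node$label <- assignments[[node$members[1L]]]
    } else {
      node$children <- lapply(node$children, label_tree)
    }
    node
  }
  structure(list(root = label_tree(root), assignments = assignments,
                 n_leaves = length(leaves), params = params),
            class = "sat_cluster_tree")
}

#' @export
print.sat_cluster_tree <- function(x, ...) {
  cat(sprintf("<sat_cluster_tree> %d reads in %d subfamilies\n",
              length(x$assignments), x$n_leaves))
  tab <- sort(table(x$assignments), decreasing = TRUE)
  rec <- function(node, depth) {
    lab <- if (is.null(node$children)) paste0(" leaf ", node$label) else ""
    cat(sprintf("%s- n=%d smp=%.3f%s\n", strrep("  ", depth), node$size,
                node$smp, lab))
    for (ch in node$children %||% list()) rec(ch, depth + 1L)
  }
  rec(x$root, 0L)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
summary.sat_cluster_tree <- function(object, ...) {
  data.frame(label = names(sort(table(object$assignments), decreasing = TRUE)),
             size = as.integer(sort(table(object$assignments),
                                    decreasing = TRUE)),
             row.names = NULL)
}
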
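#' @include AllClasses.R
NULL

#' Proportional thresholding into a binary graph
#'
#' Ranks the upper-triangle pairs by |w| in descending order and retains the
#' top `round(fraction * n(n-1)/2)` pairs as edges of a binary symmetric
#' graph. Signed (antisymmetric) iCOH matrices are accepted; the magnitude is
#' used for ranking. Ties at the cut are broken deterministically in favor of
#' the lower channel-index pair.
#'
#' @param w channels x channels numeric matrix, symmetric in |value|.
#' @param fraction fraction of pairs to retain, in (0, 1].
#' @return a [ThresholdedGraph-class].
#' @export
#' @examples
#' w <- matrix(c(0, 3, 1, -3, 0, 2, -1, -2, 0), 3, 3)
#' adjacency(thresholdTopFraction(w, 2/3))
thresholdTopFraction <- function(w, fraction) {
  if (!is.matrix(w) || nrow(w) != ncol(w))
    stop("w must be a square matrix")
  if (length(fraction) != 1L || is.na(fraction) || fraction <= 0 ||
      fraction > 1)
    stop("fraction must lie in (0, 1]")
  n <- nrow(w)
  aw <- abs(w)
  if (max(abs(aw - t(aw))) > 1e-8)
    stop("w must be symmetric in |value|")
  ut <- which(upper.tri(aw), arr.ind = TRUE)
  m <- as.integer(round(fraction * n * (n - 1) / 2))
  vals <- aw[ut]
  ord <- order(-vals, ut[, 1], ut[, 2])
  keep <- ord[seq_len(min(m, length(ord)))]
  a <- matrix(0L, n, n)
  a[ut[keep, , drop = FALSE]] <- 1L
  a <- a + t(a)
  channels <- rownames(w)
  if (is.null(channels)) channels <- paste0("ch", seq_len(n))
  dimnames(a) <- list(channels, channels)
  new("ThresholdedGraph", a = a, fraction = fraction, channels = channels)
}

.asAdjacency <- function(g) {
  if (is(g, "ThresholdedGraph")) g@a
  else if (is.matrix(g)) g
  else stop("need a ThresholdedGraph or adjacency matrix")
}

#' Shortest-path lengths of a binary graph
#'
#' All-pairs shortest-path lengths by simultaneous breadth-first search
#' (level expansion from all sources). Unreachable pairs have distance Inf;
#' the diagonal is 0.
#'
#' @param g a [ThresholdedGraph-class] or 0/1 adjacency matrix.
#' @return n x n numeric matrix of path lengths.
#' @export
shortestPathLengths <- function(g) {
  a <- .asAdjacency(g) > 0
  n <- nrow(a)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  reached <- diag(TRUE, n)
  frontier <- reached
  step <- 0L
  while (any(frontier) && step < n) {
    step <- step + 1L
    nxt <- (frontier %*% a > 0) & !reached
    if (!any(nxt)) break
    D[nxt] <- step
    reached <- reached | nxt
    frontier <- nxt
  }
  D
}

#' Global efficiency
#'
#' The average inverse shortest-path length: E_glob = (1/n) sum_i E_i with
#' E_i = sum_{j != i} 1/d_ij / (n-1). Unreachable pairs contribute 0; the
#' complete graph has E_glob = 1 and the edgeless graph 0.
#'
#' @param g a [ThresholdedGraph-class] or 0/1 adjacency matrix.
#' @return list(global, nodal): the scalar E_glob and the per-node E_i.
#' @export
globalEfficiency <- function(g) {
  a <- .asAdjacency(g)
  n <- nrow(a)
  if (n < 2L) stop("global efficiency needs at least 2 nodes")
  D <- shortestPathLengths(a)
  inv <- 1 / D
  diag(inv) <- 0
  inv[is.infinite(D)] <- 0
  nodal <- rowSums(inv) / (n - 1)
  names(nodal) <- rownames(a)
  list(global = mean(nodal), nodal = nodal)
}

#' Degree centrality
#'
#' DC_i = sum_j a_ij, the number of connections of node i.
#'
#' @param g a [ThresholdedGraph-class] or 0/1 adjacency matrix.
#' @return integer per-node degree vector.
#' @export
degreeCentrality <- function(g) {
  a <- .asAdjacency(g)
  stats::setNames(as.integer(rowSums(a)), rownames(a))
}

#' Local efficiency
#'
#' E_loc,i = sum_{j,h in N, j != h} (a_ij a_ih)^(1/3) [d_jh(N_i)]^-1 /
#' (k_i (k_i - 1)), where d_jh(N_i) is the shortest-path length between j and
#' h through neighbors of i only. The cube root acts on the connection-weight
#' product (so a future weighted mode degrades gracefully); on a binary graph
#' it leaves the 0/1 products unchanged and the value is exactly the
#' efficiency of the neighbor-restricted subgraph. Nodes with fewer than two
#' neighbors score 0; a node whose neighborhood is complete scores 1.
#'
#' @param g a [ThresholdedGraph-class] or 0/1 adjacency matrix.
#' @return per-node numeric vector.
#' @export
localEfficiency <- function(g) {
  a <- .asAdjacency(g)
  n <- nrow(a)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] > 0)
    k <- length(nb)
    if (k < 2L) next
    sub <- a[nb, nb, drop = FALSE]
    Dsub <- shortestPathLengths(sub)
    inv <- 1 / Dsub
    diag(inv) <- 0
    inv[is.infinite(Dsub)] <- 0
    out[i] <- sum(inv) / (k * (k - 1))
  }
  stats::setNames(out, rownames(a))
}

#' Nodal clustering coefficient
#'
#' C_i = 2 t_i / (k_i (k_i - 1)) with t_i the number of triangles through
#' node i; C_i = 0 for k_i < 2.
#'
#' @param g a [ThresholdedGraph-class] or 0/1 adjacency matrix.
#' @return per-node numeric vector.
#' @export
clusteringCoefficient <- function(g) {
  a <- .asAdjacency(g)
  k <- rowSums(a)
  t3 <- diag(a %*% a %*% a) / 2      # triangles through each node
  cc <- ifelse(k < 2, 0, 2 * t3 / (k * (k - 1)))
  stats::setNames(as.numeric(cc), rownames(a))
}

#' All graph metrics of a thresholded graph
#'
#' @param g a [ThresholdedGraph-class] or 0/1 adjacency matrix.
#' @return list with `global_efficiency` (scalar) and a per-node data.frame
#'   `nodes` (node, nodal_efficiency, degree, local_efficiency, clustering).
#' @export
graphMetrics <- function(g) {
  a <- .asAdjacency(g)
  ge <- globalEfficiency(a)
  nodes <- data.frame(
    node = if (is.null(rownames(a))) paste0("ch", seq_len(nrow(a)))
           else rownames(a),
    nodal_efficiency = unname(ge$nodal),
    degree = unname(degreeCentrality(a)),
    local_efficiency = unname(localEfficiency(a)),
    clustering = unname(clusteringCoefficient(a)),
    stringsAsFactors = FALSE)
  list(global_efficiency = ge$global, nodes = nodes)
}

#' Long-format metric table for a set of graphs
#'
#' Emits (subject, band, window, threshold, metric, node, value) rows for a
#' subject's thresholded pre/post graphs — the package's tidy export format.
#'
#' @param graphs nested list `graphs[[window]][[band]]` of
#'   [ThresholdedGraph-class] objects.
#' @param subject subject identifier.
#' @return long-format data.frame.
#' @export
metricsTable <- function(graphs, subject) {
  rows <- list()
  for (w in names(graphs)) for (b in names(graphs[[w]])) {
    g <- graphs[[w]][[b]]
    gm <- graphMetrics(g)
    rows[[length(rows) + 1L]] <- data.frame(
      subject = subject, band = b, window = w,
      threshold = thresholdFraction(g), metric = "global_efficiency",
      node = NA_character_, value = gm$global_efficiency,
      stringsAsFactors = FALSE)
    for (mname in c("nodal_efficiency", "degree", "local_efficiency",
                    "clustering")) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subject, band = b, window = w,
        threshold = thresholdFraction(g), metric = mname,
        node = gm$nodes$node, value = gm$nodes[[mname]],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
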
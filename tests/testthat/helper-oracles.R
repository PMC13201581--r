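# Independent brute-force oracles, deliberately written without reusing the
# package's C++ kernels.

# boundary voxels: mask voxels with a 6-neighbour outside the mask,
# via array shifting
bfBoundary <- function(mask) {
  d <- dim(mask)
  pad <- array(FALSE, dim = d + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  inner <- function(sx, sy, sz)
    pad[(2:(d[1] + 1)) + sx, (2:(d[2] + 1)) + sy, (2:(d[3] + 1)) + sz]
  allIn <- inner(1, 0, 0) & inner(-1, 0, 0) & inner(0, 1, 0) &
    inner(0, -1, 0) & inner(0, 0, 1) & inner(0, 0, -1)
  mask & !allIn
}

# symmetric average surface distance by exhaustive pairwise distances
bfAHD <- function(A, B, spacing = c(1, 1, 1)) {
  coords <- function(mask) {
    ijk <- which(bfBoundary(mask), arr.ind = TRUE) - 1L
    sweep(ijk, 2, spacing, `*`)
  }
  ca <- coords(A); cb <- coords(B)
  dmat <- outer(ca[, 1], cb[, 1], `-`)^2 +
    outer(ca[, 2], cb[, 2], `-`)^2 + outer(ca[, 3], cb[, 3], `-`)^2
  (mean(sqrt(apply(dmat, 1, min))) + mean(sqrt(apply(dmat, 2, min)))) / 2
}

bfDice <- function(A, B) {
  a <- which(A); b <- which(B)
  if (length(a) + length(b) == 0) return(1)
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

# connected components of an adjacency matrix by breadth-first search
bfComponents <- function(adj) {
  n <- nrow(adj)
  seen <- rep(FALSE, n)
  comps <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s
    seen[s] <- TRUE
    comp <- integer()
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      comp <- c(comp, v)
      nb <- which(adj[v, ] & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps[order(vapply(comps, min, integer(1)))]
}

# connected-component labelling oracle using igraph on the voxel grid graph
bfLargestComponent <- function(mask, connectivity = 26) {
  d <- dim(mask)
  idx <- which(mask)
  if (length(idx) == 0) return(array(FALSE, dim = d))
  pos <- arrayInd(idx, d)
  id <- array(0L, dim = d)
  id[idx] <- seq_along(idx)
  offs <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, ]
  edges <- vector("list", nrow(offs))
  for (r in seq_len(nrow(offs))) {
    np <- sweep(pos, 2, as.numeric(offs[r, ]), `+`)
    ok <- np[, 1] >= 1 & np[, 1] <= d[1] & np[, 2] >= 1 & np[, 2] <= d[2] &
      np[, 3] >= 1 & np[, 3] <= d[3]
    tgt <- rep(0L, length(idx))
    tgt[ok] <- id[cbind(np[ok, 1], np[ok, 2], np[ok, 3])]
    keep <- tgt > 0
    if (any(keep))
      edges[[r]] <- cbind(seq_along(idx)[keep], tgt[keep])
  }
  edges <- do.call(rbind, edges)
  g <- if (is.null(edges))
    igraph::make_empty_graph(n = length(idx), directed = FALSE)
  else igraph::graph_from_edgelist(
    cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2])),
    directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(idx) - igraph::vcount(g)))
  cl <- igraph::components(g)
  best <- which.max(cl$csize)
  out <- array(FALSE, dim = d)
  out[idx[cl$membership == best]] <- TRUE
  out
}
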
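# Independent oracles used to cross-check package computations.
# Each is deliberately naive (brute force / enumeration) and shares no code
# with the implementation paths it validates.

# O(n^3) convex hull area: an edge (i, j) is on the hull iff every other
# point lies on one side of the line through i and j; hull vertices are then
# ordered by angle around their centroid and the shoelace formula applied.
oracle_hull_area <- function(xy) {
  xy <- unique(as.matrix(xy))
  n <- nrow(xy)
  if (n < 3) return(0)
  on_hull <- logical(n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- xy[j, ] - xy[i, ]
    s <- sign(round((xy[, 1] - xy[i, 1]) * d[2] - (xy[, 2] - xy[i, 2]) * d[1], 12))
    s <- s[-c(i, j)]
    if (all(s >= 0) || all(s <= 0)) on_hull[c(i, j)] <- TRUE
  }
  v <- xy[on_hull, , drop = FALSE]
  if (nrow(v) < 3) return(0)
  ctr <- colMeans(v)
  o <- order(atan2(v[, 2] - ctr[2], v[, 1] - ctr[1]))
  v <- v[o, , drop = FALSE]
  m <- nrow(v)
  abs(sum(v[, 1] * v[c(2:m, 1), 2] - v[c(2:m, 1), 1] * v[, 2])) / 2
}

oracle_mpd <- function(d, subset) {
  tot <- 0; k <- 0
  for (i in seq_along(subset)) for (j in seq_along(subset)) if (i < j) {
    tot <- tot + d[subset[i], subset[j]]; k <- k + 1
  }
  tot / k
}

oracle_mntd <- function(d, subset) {
  mean(sapply(seq_along(subset), function(i)
    min(sapply(subset[-i], function(s) d[subset[i], s]))))
}

# Tip-pair path sums via node depths and MRCAs (independent of
# ape::cophenetic.phylo / ape::vcv.phylo).
.node_depths <- function(tree) {
  n_nodes <- length(tree$tip.label) + tree$Nnode
  depth <- rep(NA_real_, n_nodes)
  root <- length(tree$tip.label) + 1L
  depth[root] <- 0
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  lens <- ape::reorder.phylo(tree, "cladewise")$edge.length
  for (k in seq_len(nrow(edges)))
    depth[edges[k, 2]] <- depth[edges[k, 1]] + lens[k]
  depth
}

oracle_cophenetic <- function(tree) {
  n <- length(tree$tip.label)
  depth <- .node_depths(tree)
  mrca <- ape::mrca(tree)
  d <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in 1:n) for (j in 1:n) if (i != j)
    d[i, j] <- depth[i] + depth[j] - 2 * depth[mrca[i, j]]
  d
}

oracle_vcv <- function(tree) {
  n <- length(tree$tip.label)
  depth <- .node_depths(tree)
  mrca <- ape::mrca(tree)
  V <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in 1:n) for (j in 1:n)
    V[i, j] <- if (i == j) depth[i] else depth[mrca[i, j]]
  V
}

# Direct linear-algebra evaluation of the K statistic, written independently
# of blomberg_k (explicit matrix inverse, no shared helpers).
oracle_blomberg_k <- function(V, x) {
  n <- length(x)
  Vinv <- solve(V)
  ones <- matrix(1, n, 1)
  a <- as.numeric(solve(t(ones) %*% Vinv %*% ones) %*% t(ones) %*% Vinv %*% x)
  r <- matrix(x - a, ncol = 1)
  MSE0 <- as.numeric(t(r) %*% r) / (n - 1)
  MSE <- as.numeric(t(r) %*% Vinv %*% r) / (n - 1)
  expected <- (sum(diag(V)) - n / as.numeric(t(ones) %*% Vinv %*% ones)) / (n - 1)
  (MSE0 / MSE) / expected
}

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) for (k in 0:(n - 1L))
    out[[length(out) + 1L]] <- append(p, n, after = k)
  out
}

# rectangular-rule integration oracle for receptor excitations
oracle_excitation <- function(flower, background, sens, illum) {
  P <- sum(flower$reflectance * sens$sensitivity * illum$photon_flux)
  Pb <- sum(background$reflectance * sens$sensitivity * illum$photon_flux)
  q <- P / Pb
  q / (q + 1)
}

star_tree <- function(n, b = 1) {
  tr <- ape::stree(n, type = "star")
  tr$edge.length <- rep(b, nrow(tr$edge))
  tr
}

flat_spectrum <- function(value, id = "flat", grid = default_grid())
  refl_spectrum(id, grid, rep(value, length(grid)))
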
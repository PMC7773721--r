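#' Phylogenetic covariance matrix
#'
#' V(i, j) is the shared root-to-MRCA path length of tips i and j; the
#' diagonal holds root-to-tip distances. Under Brownian motion the tip trait
#' covariance is proportional to V.
#'
#' @param tree `ape::phylo` with branch lengths.
#' @param tips optional subset of tip labels; the tree is pruned first,
#'   preserving path lengths.
#' @return Symmetric matrix with tip labels as dimnames.
#' @export
phylo_covariance <- function(tree, tips = NULL) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (!is.null(tips)) {
    missing <- setdiff(tips, tree$tip.label)
    if (length(missing))
      stop("tips not in tree: ", paste(missing, collapse = ", "))
    tree <- ape::keep.tip(tree, tips)
  }
  ape::vcv.phylo(tree)
}

.k_parts <- function(V, x) {
  n <- length(x)
  Vi <- tryCatch(solve(V), error = function(e)
    stop("phylogenetic covariance matrix is singular (zero-length cherries?); ",
         "consider ridge > 0", call. = FALSE))
  one <- rep(1, n)
  denom <- sum(Vi)
  a_hat <- sum(Vi %*% x) / denom
  res <- x - a_hat
  MSE0 <- sum(res^2) / (n - 1)
  MSE <- as.numeric(t(res) %*% Vi %*% res) / (n - 1)
  expected <- (sum(diag(V)) - n / denom) / (n - 1)
  list(Vi = Vi, denom = denom, MSE0 = MSE0, MSE = MSE, expected = expected)
}

#' Blomberg's K
#'
#' Ratio of the observed to the Brownian-expected partitioning of trait
#' variance on a phylogeny: with the GLS ancestral estimate
#' `a = (1' V^-1 1)^-1 1' V^-1 x`, `MSE0 = (x - a)'(x - a) / (n - 1)` and
#' `MSE = (x - a)' V^-1 (x - a) / (n - 1)`,
#' `K = (MSE0 / MSE) / E[MSE0 / MSE]` where
#' `E[MSE0/MSE] = (tr(V) - n / (1' V^-1 1)) / (n - 1)`. K = 1 matches
#' Brownian motion on the tree; K near 0 means trait values are independent
#' of phylogeny.
#'
#' @param tree `ape::phylo` with branch lengths; pruned to `names(trait)`.
#' @param trait named numeric vector of tip trait values (names = tip labels).
#' @param ridge nonnegative value added to the diagonal of V when its
#'   inverse is needed on trees with zero-length branches (default 0, off).
#' @return K (nonnegative scalar).
#' @export
blomberg_k <- function(tree, trait, ridge = 0) {
  if (is.null(names(trait))) stop("trait must be named by tip label")
  V <- phylo_covariance(tree, names(trait))
  x <- trait[rownames(V)]
  if (stats::sd(x) == 0) stop("trait is constant; K undefined (MSE0 = 0)")
  if (ridge > 0) diag(V) <- diag(V) + ridge
  parts <- .k_parts(V, x)
  (parts$MSE0 / parts$MSE) / parts$expected
}

#' Permutation test for Blomberg's K
#'
#' Trait values are shuffled across tips; significance comes from the
#' phylogenetically corrected mean squared error, which is small when trait
#' similarity tracks the tree:
#' `p = (#\{permuted MSE <= observed MSE\} + 1) / (reps + 1)`.
#'
#' @inheritParams blomberg_k
#' @param reps number of permutations (default 999).
#' @param seed integer seed.
#' @return List with `K`, `p`, `reps`, `seed`.
#' @export
blomberg_k_test <- function(tree, trait, reps = 999, seed = 1L, ridge = 0) {
  if (is.null(names(trait))) stop("trait must be named by tip label")
  V <- phylo_covariance(tree, names(trait))
  x <- trait[rownames(V)]
  if (stats::sd(x) == 0) stop("trait is constant; K undefined (MSE0 = 0)")
  if (ridge > 0) diag(V) <- diag(V) + ridge
  n <- length(x)
  parts <- .k_parts(V, x)
  K <- (parts$MSE0 / parts$MSE) / parts$expected
  Vi <- parts$Vi
  colV <- colSums(Vi)          # 1' V^-1, for the GLS mean of each permutation
  set.seed(as.integer(seed))
  X <- vapply(seq_len(reps), function(i) x[sample.int(n)], numeric(n))
  A <- as.numeric(colV %*% X) / parts$denom
  R <- X - matrix(A, n, reps, byrow = TRUE)
  mse_perm <- colSums(R * (Vi %*% R)) / (n - 1)
  p <- (sum(mse_perm <= parts$MSE + 1e-12) + 1) / (reps + 1)
  list(K = K, p = p, reps = reps, seed = as.integer(seed))
}

#' Mantel matrix permutation test
#'
#' Pearson correlation of the lower-triangle entries of two distance
#' matrices over the same species, with significance from joint row/column
#' permutations of the first matrix (one-tailed for positive association,
#' add-one smoothed). Here d1 is typically the color distance matrix and d2
#' the cophenetic matrix, so the tree structure is held fixed.
#'
#' @param d1,d2 symmetric distance matrices with identical dimnames order.
#' @param reps permutations (default 999).
#' @param seed integer seed.
#' @return List with `r`, `p`, `reps`, `seed`.
#' @export
mantel_test <- function(d1, d2, reps = 999, seed = 1L) {
  .check_dist(d1); .check_dist(d2)
  if (!identical(rownames(d1), rownames(d2)))
    stop("distance matrices must share identical species labels in the same order")
  n <- nrow(d1)
  if (n < 3L) stop("Mantel test needs at least 3 species")
  lt <- lower.tri(d1)
  v1 <- d1[lt]; v2 <- d2[lt]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("zero variance in a distance matrix; Mantel r undefined")
  r_obs <- stats::cor(v1, v2)
  set.seed(as.integer(seed))
  r_perm <- vapply(seq_len(reps), function(i) {
    o <- sample.int(n)
    stats::cor(d1[o, o][lt], v2)
  }, numeric(1))
  p <- (sum(r_perm >= r_obs - 1e-12) + 1) / (reps + 1)
  list(r = r_obs, p = p, reps = reps, seed = as.integer(seed))
}

#' Phylogenetic signal table for color descriptors
#'
#' Per community group and per color descriptor (hue angle `theta_deg`,
#' chromatic contrast `r`): Blomberg's K with its permutation p; plus one
#' Mantel test per group of the full two-dimensional color distance against
#' the cophenetic distance on the group's pruned subtree. Hue is treated as
#' a linear variable in degrees. Groups with fewer than three members are
#' returned as flagged degenerate rows (NA statistics).
#'
#' @param tree `ape::phylo` containing the community species as tips.
#' @param loci a `color_loci` data.frame.
#' @param community data.frame with `species_id` and `group`.
#' @param reps permutations per test (default 999).
#' @param seed master seed; each test uses a derived seed.
#' @return data.frame with columns `group`, `trait`, `n`, `K`, `p_K`,
#'   `mantel_r`, `p_mantel`, `reps`, `seed`.
#' @export
signal_table <- function(tree, loci, community, reps = 999, seed = 1L) {
  .check_community(community)
  missing <- c(setdiff(community$species_id, tree$tip.label),
               setdiff(community$species_id, loci$species_id))
  if (length(missing))
    stop("community species missing from tree or loci: ",
         paste(unique(missing), collapse = ", "))
  rows <- list()
  i <- 0L
  for (sub in split(community, community$group)) {
    gid <- as.character(sub$group[1L])
    ids <- sub$species_id
    gl <- loci[match(ids, loci$species_id), , drop = FALSE]
    if (length(ids) < 3L) {
      for (trait in c("hue_theta", "contrast_r")) {
        i <- i + 1L
        rows[[i]] <- data.frame(group = gid, trait = trait, n = length(ids),
                                K = NA_real_, p_K = NA_real_,
                                mantel_r = NA_real_, p_mantel = NA_real_,
                                reps = reps, seed = NA_integer_,
                                stringsAsFactors = FALSE)
      }
      next
    }
    sub_tree <- ape::keep.tip(tree, ids)
    dcol <- color_distance_matrix(gl)
    dphy <- cophenetic_matrix(sub_tree)
    dcol <- dcol[rownames(dphy), rownames(dphy)]
    i <- i + 1L
    mt <- mantel_test(dcol, dphy, reps = reps, seed = .derive_seed(seed, i))
    for (trait in c("hue_theta", "contrast_r")) {
      val <- if (trait == "hue_theta") gl$theta_deg else gl$r
      names(val) <- gl$species_id
      i <- i + 1L
      kt <- blomberg_k_test(sub_tree, val, reps = reps,
                            seed = .derive_seed(seed, i))
      rows[[length(rows) + 1L]] <- data.frame(
        group = gid, trait = trait, n = length(ids),
        K = kt$K, p_K = kt$p, mantel_r = mt$r, p_mantel = mt$p,
        reps = reps, seed = kt$seed, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
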
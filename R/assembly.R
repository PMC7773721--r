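.check_dist <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (is.null(rownames(d))) stop("distance matrix needs species labels as dimnames")
  if (any(d < 0)) stop("distances must be nonnegative")
  if (max(abs(d - t(d))) > 1e-9) stop("distance matrix must be symmetric")
  invisible(d)
}

.subset_idx <- function(d, subset) {
  idx <- match(subset, rownames(d))
  if (anyNA(idx))
    stop("species not in distance matrix: ",
         paste(subset[is.na(idx)], collapse = ", "))
  idx
}

#' Mean pairwise distance
#'
#' Mean of the distance over all unordered pairs within a species subset;
#' applied to color distances (color assembly) or cophenetic distances
#' (phylogenetic structure).
#'
#' @param d symmetric distance matrix with species labels.
#' @param subset character vector of at least two labels in `d`.
#' @return Mean pairwise distance.
#' @export
mpd <- function(d, subset = rownames(d)) {
  .check_dist(d)
  if (length(subset) < 2L) stop("mpd needs at least 2 species")
  idx <- .subset_idx(d, subset)
  sub <- d[idx, idx, drop = FALSE]
  mean(sub[lower.tri(sub)])
}

#' Mean nearest taxon distance
#'
#' Mean, over subset members, of each member's minimum distance to any other
#' member; sensitive to clustering near the tips of a phylogeny.
#'
#' @inheritParams mpd
#' @return Mean nearest-neighbor distance.
#' @export
mntd <- function(d, subset = rownames(d)) {
  .check_dist(d)
  if (length(subset) < 2L) stop("mntd needs at least 2 species")
  idx <- .subset_idx(d, subset)
  sub <- d[idx, idx, drop = FALSE]
  diag(sub) <- Inf
  mean(apply(sub, 1L, min))
}

#' Randomization null-model test of a community distance statistic
#'
#' Compares the observed MPD or MNTD of a community against a null
#' distribution built by drawing communities of the same richness uniformly
#' without replacement from the species pool ("richness" randomization). The
#' reported p is the lower-tail rank probability with add-one smoothing,
#' `p = (#\{null <= observed\} + 1) / (reps + 1)` capped at 1: small p
#' indicates clustering (observed distance below the nulls), large p
#' overdispersion. SES = (observed - null mean) / null sd.
#'
#' @param d distance matrix over (at least) the pool.
#' @param group character vector: the community's members.
#' @param pool species pool to resample from; default all labels of `d`.
#' @param statistic "MPD" or "MNTD".
#' @param reps number of null draws (default 1000).
#' @param seed integer seed.
#' @param group_id label carried into the result.
#' @return Object of class `null_model_result`: list with `group_id`, `n`,
#'   `statistic_name`, `actual`, `null_mean`, `null_sd`, `ses`, `p`, `reps`,
#'   `seed`, `null_values`.
#' @export
null_test <- function(d, group, pool = rownames(d),
                      statistic = c("MPD", "MNTD"),
                      reps = 1000, seed = 1L, group_id = "group") {
  statistic <- match.arg(statistic)
  .check_dist(d)
  if (reps < 1) stop("reps must be >= 1")
  n <- length(group)
  if (n > length(pool))
    stop("community size ", n, " exceeds pool size ", length(pool))
  stat_fun <- if (statistic == "MPD") mpd else mntd
  actual <- stat_fun(d, group)
  pool_idx <- .subset_idx(d, pool)
  set.seed(as.integer(seed))
  nulls <- vapply(seq_len(reps), function(i) {
    draw <- pool_idx[sample.int(length(pool_idx), n)]
    stat_fun(d, rownames(d)[draw])
  }, numeric(1))
  null_mean <- mean(nulls)
  null_sd <- stats::sd(nulls)
  ses <- if (null_sd > 0) (actual - null_mean) / null_sd else NA_real_
  p <- min(1, (sum(nulls <= actual + 1e-12) + 1) / (reps + 1))
  structure(list(group_id = group_id, n = n, statistic_name = statistic,
                 actual = actual, null_mean = null_mean, null_sd = null_sd,
                 ses = ses, p = p, reps = reps, seed = as.integer(seed),
                 null_values = nulls),
            class = "null_model_result")
}

#' @export
print.null_model_result <- function(x, ...) {
  cat(sprintf("%s null-model test, group '%s' (n = %d, reps = %d, seed = %d)\n",
              x$statistic_name, x$group_id, x$n, x$reps, x$seed))
  cat(sprintf("  actual = %.4f   nulls = %.4f +/- %.4f   SES = %s   p = %.4f\n",
              x$actual, x$null_mean, x$null_sd,
              if (is.na(x$ses)) "NA" else sprintf("%.3f", x$ses), x$p))
  invisible(x)
}

.null_row <- function(x) {
  data.frame(group = x$group_id, n = x$n, statistic = x$statistic_name,
             actual = x$actual, null_mean = x$null_mean, null_sd = x$null_sd,
             ses = x$ses, p = x$p, reps = x$reps, seed = x$seed,
             stringsAsFactors = FALSE)
}

#' Cophenetic (tree-path) distance matrix
#'
#' Sum of branch lengths along the path between every pair of tips;
#' polytomies are permitted.
#'
#' @param tree an `ape::phylo` with branch lengths and unique tip labels.
#' @return Symmetric distance matrix with tip labels.
#' @export
cophenetic_matrix <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree must have a branch length on every edge")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  ape::cophenetic.phylo(tree)
}

#' Floral color assembly table
#'
#' One MPD null-model test per community group on the color distance matrix,
#' always resampling from the pooled species list. When the community table
#' carries a `pollinator_class` column, additional rows test each
#' group-by-class subset with the pool unchanged, mirroring the design of
#' pollinator-restricted assembly comparisons.
#'
#' @param loci a `color_loci` data.frame covering every community member.
#' @param community data.frame with `species_id`, `group`, optionally
#'   `pollinator_class`.
#' @param reps null draws per test (default 1000).
#' @param seed master seed; each row uses a derived seed.
#' @return data.frame with columns `group`, `n`, `statistic`, `actual`,
#'   `null_mean`, `null_sd`, `ses`, `p`, `reps`, `seed`.
#' @export
fca_table <- function(loci, community, reps = 1000, seed = 1L) {
  .check_community(community)
  missing <- setdiff(community$species_id, loci$species_id)
  if (length(missing))
    stop("community species without a color locus: ", paste(missing, collapse = ", "))
  d <- color_distance_matrix(loci)
  pool <- intersect(rownames(d), community$species_id)
  jobs <- lapply(split(community, community$group), function(sub)
    list(id = as.character(sub$group[1L]), members = sub$species_id))
  if ("pollinator_class" %in% names(community)) {
    cc <- community[!is.na(community$pollinator_class), , drop = FALSE]
    key <- interaction(cc$group, cc$pollinator_class, drop = TRUE)
    extra <- lapply(split(cc, key), function(sub) {
      if (nrow(sub) < 2L) return(NULL)
      list(id = paste0(sub$group[1L], ":", sub$pollinator_class[1L]),
           members = sub$species_id)
    })
    jobs <- c(jobs, Filter(Negate(is.null), extra))
  }
  rows <- lapply(seq_along(jobs), function(i) {
    j <- jobs[[i]]
    .null_row(null_test(d, j$members, pool = pool, statistic = "MPD",
                        reps = reps, seed = .derive_seed(seed, i),
                        group_id = j$id))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Phylogenetic community structure table
#'
#' MPD and MNTD null-model tests per community group on the cophenetic
#' distance matrix; the pool is all sampled species (all community members
#' present on the tree).
#'
#' @param tree `ape::phylo` containing every community member as a tip.
#' @param community data.frame with `species_id` and `group`.
#' @inheritParams fca_table
#' @return data.frame in the same shape as [fca_table()], two rows (MPD,
#'   MNTD) per group.
#' @export
phylo_structure_table <- function(tree, community, reps = 1000, seed = 1L) {
  .check_community(community)
  missing <- setdiff(community$species_id, tree$tip.label)
  if (length(missing))
    stop("community species missing from the tree: ", paste(missing, collapse = ", "))
  d <- cophenetic_matrix(tree)
  pool <- intersect(rownames(d), community$species_id)
  groups <- split(community, community$group)
  rows <- list()
  i <- 0L
  for (sub in groups) {
    for (statistic in c("MPD", "MNTD")) {
      i <- i + 1L
      rows[[i]] <- .null_row(null_test(
        d, sub$species_id, pool = pool, statistic = statistic,
        reps = reps, seed = .derive_seed(seed, i),
        group_id = as.character(sub$group[1L])))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# deterministic per-job seed from a master seed, kept within 32-bit range
.derive_seed <- function(seed, i) as.integer((as.numeric(seed) * 1000 + i) %% .Machine$integer.max)
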
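#' Minimum convex polygon area of color loci
#'
#' Area of the convex hull of the (x, y) loci in hexagon squared units; the
#' standard measure of floral color diversity of a species set. Degenerate
#' sets (fewer than three distinct points, or collinear to within a
#' cross-product tolerance of 1e-12) have area 0. The full hexagon of
#' circumradius 1 bounds the value at `3 * sqrt(3) / 2`.
#'
#' @param loci a `color_loci` data.frame, or a two-column matrix of x, y.
#' @return Nonnegative area.
#' @export
mcp_area <- function(loci) {
  xy <- .as_xy(loci)
  xy <- unique(xy)
  if (nrow(xy) < 3L) return(0)
  h <- grDevices::chull(xy)
  if (length(h) < 3L) return(0)
  px <- xy[h, 1L]; py <- xy[h, 2L]
  n <- length(h)
  a <- abs(sum(px * py[c(2:n, 1L)] - px[c(2:n, 1L)] * py)) / 2
  if (a < 1e-12) 0 else a
}

.as_xy <- function(loci) {
  if (is.data.frame(loci)) cbind(loci$x, loci$y) else as.matrix(loci)[, 1:2, drop = FALSE]
}

#' Rarefied convex-polygon areas
#'
#' Controls for unequal species richness when comparing hull areas across
#' groups: for each group, `n_sub` loci are drawn without replacement `reps`
#' times and the hull area recomputed, giving a distribution of equal-sample
#' areas with 2.5/50/97.5 percent quantiles. Two groups are declared
#' separated when their central 95 percent intervals do not overlap.
#'
#' @param groups named list mapping group id to a `color_loci` data.frame (or
#'   two-column xy matrix).
#' @param n_sub subsample size; default the smallest group size.
#' @param reps number of subsamples per group (default 1000).
#' @param seed integer seed for the resampling stream.
#' @return Object of class `rarefaction_result`: list with per-group `areas`
#'   (length `reps`), `quantiles`, `full_area`, plus `n_sub`, `reps`, `seed`.
#' @export
rarefied_mcp <- function(groups, n_sub = NULL, reps = 1000, seed = 1L) {
  stopifnot(is.list(groups), length(groups) >= 1L, reps >= 1)
  sizes <- vapply(groups, function(g) nrow(.as_xy(g)), integer(1))
  if (is.null(n_sub)) n_sub <- min(sizes)
  too_small <- names(groups)[sizes < n_sub]
  if (length(too_small))
    stop("n_sub = ", n_sub, " exceeds the size of group(s): ",
         paste(too_small, collapse = ", "))
  set.seed(as.integer(seed))
  per_group <- lapply(groups, function(g) {
    xy <- .as_xy(g)
    areas <- vapply(seq_len(reps), function(i)
      mcp_area(xy[sample.int(nrow(xy), n_sub), , drop = FALSE]), numeric(1))
    list(areas = areas,
         quantiles = stats::quantile(areas, c(0.025, 0.5, 0.975)),
         full_area = mcp_area(xy))
  })
  structure(list(groups = per_group, n_sub = n_sub, reps = reps,
                 seed = as.integer(seed)),
            class = "rarefaction_result")
}

#' @export
print.rarefaction_result <- function(x, ...) {
  cat(sprintf("Rarefied MCP areas (n_sub = %d, reps = %d, seed = %d)\n",
              x$n_sub, x$reps, x$seed))
  for (g in names(x$groups)) {
    q <- x$groups[[g]]$quantiles
    cat(sprintf("  %-12s full = %.3f   median = %.3f   95%% = [%.3f, %.3f]\n",
                g, x$groups[[g]]$full_area, q[2L], q[1L], q[3L]))
  }
  invisible(x)
}

#' Are two rarefied groups separated?
#'
#' @param x a `rarefaction_result`.
#' @param a,b group names.
#' @return TRUE when the central 95 percent intervals do not overlap.
#' @export
rarefaction_separated <- function(x, a, b) {
  qa <- x$groups[[a]]$quantiles
  qb <- x$groups[[b]]$quantiles
  qa[3L] < qb[1L] || qb[3L] < qa[1L]
}

#' Per-group color diversity table
#'
#' @param loci a `color_loci` data.frame.
#' @param community community table with `species_id` and `group` columns.
#' @return data.frame with `group`, `n`, `mcp_area`.
#' @export
fcd_table <- function(loci, community) {
  .check_community(community)
  missing <- setdiff(community$species_id, loci$species_id)
  if (length(missing))
    stop("community species without a color locus: ", paste(missing, collapse = ", "))
  out <- do.call(rbind, lapply(split(community, community$group), function(sub) {
    g <- loci[loci$species_id %in% sub$species_id, , drop = FALSE]
    data.frame(group = sub$group[1L], n = nrow(g), mcp_area = mcp_area(g),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

.check_community <- function(community) {
  if (!is.data.frame(community) ||
      !all(c("species_id", "group") %in% names(community)))
    stop("community table needs columns 'species_id' and 'group'")
  invisible(community)
}
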
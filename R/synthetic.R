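#' Spectral archetype parameter sets
#'
#' Fixed parameter sets for the floral reflectance shapes the generator
#' emulates: a UV-absorbing white (sigmoid step in the blue), yellows with
#' and without a UV reflectance bump, blue and purple (Gaussian band plus,
#' for purple, a long-wavelength rise), a long-wavelength red, and the
#' leaf-green background. The base curve is a logistic step
#' `plateau / (1 + exp(-(lambda - mid) / width))` plus an optional Gaussian
#' bump; noise is additive Gaussian, clipped to \[0, 1\].
#'
#' @param name one of `"white_uv_absorbing"`, `"yellow_uv_absent"`,
#'   `"yellow_uv_present"`, `"blue"`, `"purple"`, `"red_long"`,
#'   `"leaf_green"`.
#' @return Named list: `plateau`, `mid`, `width`, `bump_amp`, `bump_center`,
#'   `bump_width`, `noise_sd`.
#' @export
archetype_params <- function(name = c("white_uv_absorbing", "yellow_uv_absent",
                                      "yellow_uv_present", "blue", "purple",
                                      "red_long", "leaf_green")) {
  name <- match.arg(name)
  defaults <- list(
    white_uv_absorbing = list(plateau = 0.80, mid = 400, width = 15,
                              bump_amp = 0.00, bump_center = 350, bump_width = 30),
    yellow_uv_absent   = list(plateau = 0.90, mid = 500, width = 15,
                              bump_amp = 0.00, bump_center = 350, bump_width = 30),
    yellow_uv_present  = list(plateau = 0.90, mid = 500, width = 15,
                              bump_amp = 0.35, bump_center = 350, bump_width = 30),
    blue               = list(plateau = 0.06, mid = 660, width = 20,
                              bump_amp = 0.55, bump_center = 445, bump_width = 35),
    purple             = list(plateau = 0.45, mid = 620, width = 25,
                              bump_amp = 0.50, bump_center = 430, bump_width = 40),
    red_long           = list(plateau = 0.70, mid = 600, width = 15,
                              bump_amp = 0.00, bump_center = 350, bump_width = 30),
    leaf_green         = list(plateau = 0.05, mid = -Inf, width = 1,
                              bump_amp = 0.12, bump_center = 550, bump_width = 40)
  )
  c(defaults[[name]], list(noise_sd = 0.01, name = name))
}

#' Generate a flower reflectance spectrum
#'
#' @param archetype archetype name (see [archetype_params()]) or a parameter
#'   list in the same shape.
#' @param seed integer seed; the same seed reproduces the same spectrum.
#' @param species_id label for the spectrum (default the archetype name).
#' @param grid wavelength grid (nm).
#' @return A [refl_spectrum].
#' @export
gen_flower_spectrum <- function(archetype = "white_uv_absorbing", seed = 1L,
                                species_id = NULL, grid = default_grid()) {
  par <- if (is.character(archetype)) archetype_params(archetype) else archetype
  if (is.null(species_id))
    species_id <- if (!is.null(par$name)) par$name else "synthetic"
  lam <- as.numeric(grid)
  base <- par$plateau / (1 + exp(-(lam - par$mid) / par$width))
  if (par$bump_amp > 0)
    base <- base + par$bump_amp * exp(-0.5 * ((lam - par$bump_center) / par$bump_width)^2)
  if (all(base <= 0))
    stop("archetype parameters produce an all-zero reflectance spectrum")
  set.seed(as.integer(seed))
  r <- base + stats::rnorm(length(lam), 0, par$noise_sd)
  r <- pmin(pmax(r, 0), 1)
  refl_spectrum(species_id, lam, r)
}

#' Generate a leaf reflectance spectrum
#'
#' Low baseline (about 0.05) with a Gaussian green peak near 550 nm
#' (amplitude about 0.12), the adaptation background of the bee color model.
#'
#' @param seed integer seed.
#' @param species_id label (default "leaf").
#' @param grid wavelength grid (nm).
#' @param noise_sd additive noise standard deviation (default 0.005).
#' @return A [refl_spectrum].
#' @export
gen_leaf_spectrum <- function(seed = 1L, species_id = "leaf",
                              grid = default_grid(), noise_sd = 0.005) {
  lam <- as.numeric(grid)
  base <- 0.05 + 0.12 * exp(-0.5 * ((lam - 550) / 40)^2)
  set.seed(as.integer(seed))
  r <- pmin(pmax(base + stats::rnorm(length(lam), 0, noise_sd), 0), 1)
  refl_spectrum(species_id, lam, r)
}

#' Simulate a Yule (pure-birth) phylogeny
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate per unit time (> 0).
#' @param seed integer seed.
#' @return An ultrametric `ape::phylo` with `n_tips` tips.
#' @export
gen_yule_tree <- function(n_tips, birth_rate = 1, seed = 1L) {
  if (n_tips < 2) stop("n_tips must be >= 2")
  if (birth_rate <= 0) stop("birth_rate must be > 0")
  set.seed(as.integer(seed))
  ape::rphylo(n_tips, birth = birth_rate, death = 0)
}

#' Brownian-motion trait evolution on a tree
#'
#' Independent Gaussian increments per branch with variance
#' `sigma2 * branch length`, accumulated root to tip. With `dims = 2` the
#' two coordinates evolve independently (a simple model of color loci
#' diffusing in the hexagon plane).
#'
#' @param tree `ape::phylo` with branch lengths.
#' @param sigma2 trait variance per unit branch length (> 0).
#' @param root_value trait value at the root (scalar, recycled over dims).
#' @param seed integer seed.
#' @param dims 1 or 2 trait dimensions.
#' @return Named vector (dims = 1) or matrix with one row per tip (dims = 2).
#' @export
evolve_bm <- function(tree, sigma2 = 1, root_value = 0, seed = 1L, dims = 1L) {
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  tree <- ape::reorder.phylo(tree, "cladewise")   # parents precede children
  n <- length(tree$tip.label)
  n_nodes <- n + tree$Nnode
  set.seed(as.integer(seed))
  vals <- matrix(NA_real_, n_nodes, dims)
  root <- n + 1L
  vals[root, ] <- rep(root_value, length.out = dims)
  for (k in seq_len(nrow(tree$edge))) {
    par <- tree$edge[k, 1L]; child <- tree$edge[k, 2L]
    sdv <- sqrt(sigma2 * tree$edge.length[k])
    vals[child, ] <- vals[par, ] + stats::rnorm(dims, 0, sdv)
  }
  out <- vals[seq_len(n), , drop = dims == 1L]
  if (dims == 1L) names(out) <- tree$tip.label else rownames(out) <- tree$tip.label
  out
}

#' Draw a community with a prescribed color structure
#'
#' `random`: uniform sample without replacement. `clustered`: a focal
#' species (seeded uniform pick unless `focal` is given) plus its n - 1
#' nearest color neighbors (low mean pairwise distance by construction).
#' `overdispersed`: greedy max-min spread - start from the most distant
#' pair, then repeatedly add the species whose minimum distance to the
#' selected set is largest.
#'
#' @param loci_pool `color_loci` data.frame for the pool.
#' @param structure one of `"clustered"`, `"random"`, `"overdispersed"`.
#' @param n community size, `2 <= n <=` pool size.
#' @param seed integer seed.
#' @param focal optional species id to center a clustered draw on.
#' @return Character vector of n species ids.
#' @export
gen_community <- function(loci_pool, structure = c("random", "clustered",
                                                   "overdispersed"),
                          n, seed = 1L, focal = NULL) {
  structure <- match.arg(structure)
  N <- nrow(loci_pool)
  if (n < 2 || n > N) stop("n must satisfy 2 <= n <= pool size (", N, ")")
  ids <- loci_pool$species_id
  set.seed(as.integer(seed))
  if (structure == "random") return(ids[sample.int(N, n)])
  d <- color_distance_matrix(loci_pool)
  if (structure == "clustered") {
    focal <- if (is.null(focal)) sample.int(N, 1L) else match(focal, ids)
    if (is.na(focal)) stop("focal species not in the pool")
    nb <- order(d[focal, ])           # focal itself first (distance 0)
    return(ids[nb[seq_len(n)]])
  }
  # overdispersed: greedy max-min, deterministic given the distances
  start <- which(d == max(d), arr.ind = TRUE)[1L, ]
  sel <- as.integer(start)
  while (length(sel) < n) {
    cand <- setdiff(seq_len(N), sel)
    mind <- apply(d[cand, sel, drop = FALSE], 1L, min)
    sel <- c(sel, cand[which.max(mind)])
  }
  ids[sel]
}

#' Default synthetic study configuration
#'
#' The study the generator emulates: a 160-species pool whose flowers mix
#' the spectral archetypes in field-like proportions (UV-absorbing white
#' dominant, UV-reflecting yellow second, as in bee-pollinated floras), a
#' Yule phylogeny over all species, ten leaf spectra for the background,
#' and three altitude communities partitioning the pool. The middle group
#' is clustered in color space around a blue-green-arm (white-flower)
#' focal; the high group is drawn at random from a single clade, so it is
#' phylogenetically clustered while keeping the pool's color composition;
#' the low group is the random remainder and the largest, as in mountain
#' floras. Species-to-species variation comes from jittering the archetype
#' parameters (`jitter = 1`) on top of measurement noise.
#'
#' @param seed master seed for every generated artifact.
#' @return A list of class `study_config`.
#' @export
gen_study_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    n_leaves = 10L,
    birth_rate = 1,
    jitter = 1,
    mixture = c(white_uv_absorbing = 0.45, yellow_uv_absent = 0.08,
                yellow_uv_present = 0.15, blue = 0.14, purple = 0.10,
                red_long = 0.08),
    groups = list(
      middle = list(n = 45L, structure = "clustered", clade = FALSE,
                    focal_sector = "BG"),
      high   = list(n = 45L, structure = "random", clade = TRUE),
      low    = list(n = 70L, structure = "random", clade = FALSE)
    )
  ), class = "study_config")
}

# species-level variation of an archetype: jitter the curve parameters
# (scale = 0 reproduces the archetype exactly)
.jitter_params <- function(par, seed, scale = 1) {
  if (scale <= 0) return(par)
  set.seed(as.integer(seed))
  par$mid <- par$mid + stats::rnorm(1, 0, 8 * scale)
  par$width <- max(5, par$width + stats::rnorm(1, 0, 3 * scale))
  par$plateau <- min(1, max(0.05, par$plateau + stats::rnorm(1, 0, 0.05 * scale)))
  if (par$bump_amp > 0) {
    par$bump_amp <- max(0.05, par$bump_amp + stats::rnorm(1, 0, 0.05 * scale))
    par$bump_center <- par$bump_center + stats::rnorm(1, 0, 5 * scale)
  }
  par
}

# smallest clade with at least n tips (tightest phylogenetic clustering)
.pick_clade <- function(tree, n) {
  n_tip <- length(tree$tip.label)
  sizes <- vapply((n_tip + 1L):(n_tip + tree$Nnode), function(node)
    length(.tips_under(tree, node)), integer(1))
  ok <- which(sizes >= n)
  node <- (n_tip + ok[which.min(sizes[ok])])
  tree$tip.label[.tips_under(tree, node)]
}

.tips_under <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(node)
  kids <- tree$edge[tree$edge[, 1L] == node, 2L]
  unlist(lapply(kids, .tips_under, tree = tree))
}

#' Generate a complete synthetic study on disk
#'
#' Writes every input the pipeline consumes, with shared species ids:
#' `flowers.csv` (wide: wavelength column plus one column per species),
#' `leaves.csv` (wide, leaf replicates), `tree.nwk` (Newick with branch
#' lengths), `community.tsv` (`species_id`, `group`) and `config.json`.
#' Deterministic for a given `(config, seed)`.
#'
#' @param config a `study_config`, see [gen_study_config()].
#' @param dir output directory (created if needed).
#' @return Invisibly, a list with the file paths, the config, and the
#'   generated community table.
#' @export
gen_dataset <- function(config = gen_study_config(), dir = tempfile("study")) {
  n_groups <- sum(vapply(config$groups, `[[`, integer(1), "n"))
  n_total <- if (is.null(config$n_species)) n_groups else as.integer(config$n_species)
  if (n_groups > n_total)
    stop("inconsistent config: group sizes (", n_groups,
         ") exceed the species pool (", n_total, ")")
  if (n_total < 3L) stop("config must generate at least 3 species")
  mix <- config$mixture / sum(config$mixture)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grid <- default_grid()
  ids <- sprintf("sp%03d", seq_len(n_total))

  tree <- gen_yule_tree(n_total, config$birth_rate, seed = config$seed)
  tree$tip.label <- ids

  set.seed(.derive_seed(config$seed, 1L))
  arch <- sample(names(mix), n_total, replace = TRUE, prob = mix)
  jitter <- if (is.null(config$jitter)) 0 else config$jitter
  spectra <- lapply(seq_len(n_total), function(i) {
    par <- .jitter_params(archetype_params(arch[i]),
                          seed = .derive_seed(config$seed, 5000L + i),
                          scale = jitter)
    gen_flower_spectrum(par, seed = .derive_seed(config$seed, 100L + i),
                        species_id = ids[i], grid = grid)
  })
  leaves <- lapply(seq_len(config$n_leaves), function(i)
    gen_leaf_spectrum(seed = .derive_seed(config$seed, 900L + i),
                      species_id = sprintf("leaf%02d", i), grid = grid))

  background <- mean_background(leaves)
  loci <- hexagon_loci(spectra, background, grid = grid)

  remaining <- ids
  rows <- list()
  gi <- 0L
  for (gname in names(config$groups)) {
    g <- config$groups[[gname]]
    gi <- gi + 1L
    candidates <- if (isTRUE(g$clade)) {
      cl <- .pick_clade(ape::keep.tip(tree, remaining), g$n)
      intersect(remaining, cl)
    } else remaining
    if (length(candidates) < g$n)
      stop("inconsistent config: group '", gname, "' larger than its candidate pool")
    pool_loci <- loci[loci$species_id %in% candidates, , drop = FALSE]
    focal <- NULL
    if (!is.null(g$focal_sector)) {
      in_sector <- pool_loci$species_id[!is.na(pool_loci$sector) &
                                        pool_loci$sector == g$focal_sector]
      if (length(in_sector)) {
        set.seed(.derive_seed(config$seed, 70L + gi))
        focal <- sample(in_sector, 1L)
      }
    }
    members <- gen_community(pool_loci, g$structure, g$n,
                             seed = .derive_seed(config$seed, 50L + gi),
                             focal = focal)
    remaining <- setdiff(remaining, members)
    rows[[gi]] <- data.frame(species_id = members, group = gname,
                             stringsAsFactors = FALSE)
  }
  community <- do.call(rbind, rows)

  paths <- list(dir = dir,
                spectra = file.path(dir, "flowers.csv"),
                leaves = file.path(dir, "leaves.csv"),
                tree = file.path(dir, "tree.nwk"),
                community = file.path(dir, "community.tsv"),
                config = file.path(dir, "config.json"))
  wide <- data.frame(wavelength = grid,
                     vapply(spectra, `[[`, numeric(length(grid)), "reflectance"),
                     check.names = FALSE)
  names(wide)[-1L] <- ids
  utils::write.csv(wide, paths$spectra, row.names = FALSE)
  lwide <- data.frame(wavelength = grid,
                      vapply(leaves, `[[`, numeric(length(grid)), "reflectance"),
                      check.names = FALSE)
  names(lwide)[-1L] <- vapply(leaves, `[[`, "", "species_id")
  utils::write.csv(lwide, paths$leaves, row.names = FALSE)
  ape::write.tree(tree, paths$tree)
  utils::write.table(community, paths$community, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(unclass(config), paths$config, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(c(paths, list(config_data = config, community_table = community,
                          archetypes = stats::setNames(arch, ids))))
}
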
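#' Run the full color-signaling analysis pipeline
#'
#' Stage order mirrors the analysis workflow: read spectra, map to hexagon
#' loci against the mean leaf background, then color diversity (per-group
#' hull areas plus rarefaction), the angular histogram, color assembly null
#' models, phylogenetic community structure, and phylogenetic signal. Every
#' output table is written as TSV into `out_dir` together with a
#' `manifest.json` recording input checksums, seeds, replicate counts,
#' package version and stage timings. When the manifest shows unchanged
#' inputs, a cached `loci.tsv` is reused instead of re-integrating spectra.
#'
#' @param spectra_path wide/long CSV-TSV of flower spectra (see
#'   [read_spectra()]).
#' @param leaf_path file of leaf spectra (averaged into the background).
#' @param tree_path Newick tree file; may be NULL when the phylogenetic
#'   stages are skipped.
#' @param community_path TSV with `species_id`, `group`, optional
#'   `pollinator_class`.
#' @param out_dir output directory.
#' @param grid_step integration grid step in nm (default 1).
#' @param peaks receptor peaks (nm), default `c(uv=350, blue=440, green=540)`.
#' @param reps resampling count for every randomization stage (default 1000).
#' @param signal_reps permutations for the signal stage (default 999).
#' @param seed master seed.
#' @param dialect spectra file layout (default "wide").
#' @param skip character vector of stages to skip, among
#'   `c("fcd", "sectors", "fca", "phylo", "signal")`.
#' @return Invisibly, a list of class `study_run` with the computed tables
#'   and the manifest.
#' @export
run_study <- function(spectra_path, leaf_path, tree_path = NULL,
                      community_path = NULL, out_dir = tempfile("run"),
                      grid_step = 1, peaks = c(uv = 350, blue = 440, green = 540),
                      reps = 1000, signal_reps = 999, seed = 1L,
                      dialect = "wide", skip = character()) {
  stages_avail <- c("fcd", "sectors", "fca", "phylo", "signal")
  bad <- setdiff(skip, stages_avail)
  if (length(bad)) stop("unknown stage(s) in skip: ", paste(bad, collapse = ", "))
  needs_tree <- !all(c("phylo", "signal") %in% skip)
  if (needs_tree && is.null(tree_path))
    stop("stage 'phylo'/'signal' requires tree_path (or add them to skip)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- seq(300, 700, by = grid_step)
  timings <- c()
  run_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  inputs <- c(spectra = spectra_path, leaves = leaf_path,
              tree = tree_path, community = community_path)
  hashes <- tools::md5sum(unlist(inputs))
  manifest_path <- file.path(out_dir, "manifest.json")
  loci_path <- file.path(out_dir, "loci.tsv")

  cached <- FALSE
  if (file.exists(manifest_path) && file.exists(loci_path)) {
    old <- tryCatch(jsonlite::read_json(manifest_path), error = function(e) NULL)
    if (!is.null(old) &&
        identical(unname(unlist(old$input_md5)), unname(hashes)) &&
        isTRUE(all.equal(as.numeric(old$grid_step), as.numeric(grid_step)))) {
      loci <- utils::read.table(loci_path, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
      class(loci) <- c("color_loci", "data.frame")
      cached <- TRUE
    }
  }
  if (!cached) {
    loci <- run_stage("loci", {
      spectra <- read_spectra(spectra_path, dialect = dialect)
      leaves <- read_spectra(leaf_path, dialect = dialect)
      leaves <- lapply(leaves, resample_spectrum, grid = grid)
      hexagon_loci(spectra, mean_background(leaves), grid = grid, peaks = peaks)
    })
    utils::write.table(loci, loci_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }

  community <- NULL
  if (!is.null(community_path)) {
    community <- utils::read.table(community_path, header = TRUE, sep = "\t",
                                   stringsAsFactors = FALSE)
    .check_community(community)
  }
  tree <- if (!is.null(tree_path)) ape::read.tree(tree_path) else NULL

  out <- list(loci = loci, cached_loci = cached)
  write_tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }

  if (!"fcd" %in% skip && !is.null(community)) {
    out$fcd <- run_stage("fcd", fcd_table(loci, community))
    write_tsv(out$fcd, "fcd.tsv")
    out$rarefaction <- run_stage("rarefaction", {
      groups <- lapply(split(community, community$group), function(sub)
        loci[loci$species_id %in% sub$species_id, , drop = FALSE])
      rarefied_mcp(groups, reps = reps, seed = .derive_seed(seed, 7L))
    })
    rar <- do.call(rbind, lapply(names(out$rarefaction$groups), function(g)
      data.frame(group = g, n_sub = out$rarefaction$n_sub,
                 rep = seq_len(out$rarefaction$reps),
                 area = out$rarefaction$groups[[g]]$areas)))
    write_tsv(rar, "rarefaction.tsv")
  }
  if (!"sectors" %in% skip) {
    out$sector_hist <- run_stage("sectors", {
      h <- sector_frequency(loci, bin_width = 10)
      h$preference_window_30_90 <- preference_fraction(loci, c(30, 90))
      h
    })
    write_tsv(out$sector_hist, "sector_hist.tsv")
  }
  if (!"fca" %in% skip && !is.null(community)) {
    out$fca <- run_stage("fca", fca_table(loci, community, reps = reps,
                                          seed = .derive_seed(seed, 11L)))
    write_tsv(out$fca, "fca.tsv")
  }
  if (!"phylo" %in% skip && !is.null(community) && !is.null(tree)) {
    out$phylo_structure <- run_stage("phylo",
      phylo_structure_table(tree, community, reps = reps,
                            seed = .derive_seed(seed, 13L)))
    write_tsv(out$phylo_structure, "phylo_structure.tsv")
  }
  if (!"signal" %in% skip && !is.null(community) && !is.null(tree)) {
    out$signal <- run_stage("signal",
      signal_table(tree, loci, community, reps = signal_reps,
                   seed = .derive_seed(seed, 17L)))
    write_tsv(out$signal, "signal.tsv")
  }

  manifest <- list(
    package = "beehexagon",
    version = as.character(utils::packageVersion("beehexagon")),
    seed = as.integer(seed), reps = reps, signal_reps = signal_reps,
    grid_step = grid_step, peaks = as.list(peaks),
    input_md5 = as.list(hashes), skipped = as.list(skip),
    cached_loci = cached, stage_seconds = as.list(timings),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  out$manifest <- manifest
  out$out_dir <- out_dir
  class(out) <- "study_run"
  invisible(out)
}

#' @export
print.study_run <- function(x, ...) {
  cat("Color-signaling study run (seed ", x$manifest$seed, ", ",
      nrow(x$loci), " species)\n", sep = "")
  cat("  outputs in: ", x$out_dir, "\n", sep = "")
  for (nm in intersect(c("fcd", "fca", "phylo_structure", "signal"), names(x)))
    cat("  ", nm, ": ", nrow(x[[nm]]), " rows\n", sep = "")
  invisible(x)
}

#' Human-readable summary of a study run
#'
#' Per group: species count, hull area, and the assembly verdict from the
#' lower-tail null-model p: `clustered` when p <= alpha, `overdispersed`
#' when p >= 1 - alpha, otherwise `random`. The thresholds are printed with
#' the p so other readings can be applied.
#'
#' @param object a `study_run` from [run_study()].
#' @param alpha verdict threshold (default 0.05).
#' @param ... unused.
#' @return data.frame with `group`, `n`, `mcp_area`, `mpd_color`, `p`,
#'   `verdict`, printed as a formatted block.
#' @export
summary.study_run <- function(object, alpha = 0.05, ...) {
  if (is.null(object$fca) || is.null(object$fcd))
    stop("summary needs the fcd and fca stages; re-run without skipping them")
  fca <- object$fca[!grepl(":", object$fca$group), , drop = FALSE]
  m <- merge(object$fcd, fca[, c("group", "actual", "p")], by = "group")
  names(m)[names(m) == "actual"] <- "mpd_color"
  m$verdict <- ifelse(m$p <= alpha, "clustered",
                      ifelse(m$p >= 1 - alpha, "overdispersed", "random"))
  cat(sprintf("Assembly verdicts at alpha = %.2f (p <= %.2f clustered, p >= %.2f overdispersed)\n",
              alpha, alpha, 1 - alpha))
  for (i in seq_len(nrow(m)))
    cat(sprintf("  %-10s n = %3d   MCP = %.3f   MPD_color = %.3f   p = %.3f   %s\n",
                m$group[i], m$n[i], m$mcp_area[i], m$mpd_color[i], m$p[i],
                m$verdict[i]))
  invisible(m)
}
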
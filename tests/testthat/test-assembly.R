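mk_dist <- function(xy, ids = as.character(seq_len(nrow(xy)))) {
  d <- as.matrix(dist(xy))
  dimnames(d) <- list(ids, ids)
  d
}

test_that("MPD and MNTD agree with closed forms and brute force", {
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(mpd(d2, c("a", "b")), 0.4)
  expect_equal(mntd(d2, c("a", "b")), 0.4)

  tri <- mk_dist(rbind(c(0, 0), c(1, 0), c(0, 1)))
  expect_equal(mpd(tri), (1 + 1 + sqrt(2)) / 3)
  expect_equal(mntd(tri), 1)

  set.seed(77)
  d <- mk_dist(matrix(runif(20), 10, 2))
  sub <- sample(rownames(d), 6)
  expect_equal(mpd(d, sub), oracle_mpd(d, sub))
  expect_equal(mntd(d, sub), oracle_mntd(d, sub))

  expect_error(mpd(d, c("1", "zebra")), "zebra")
  expect_error(mpd(d, "1"), "at least 2")
})

test_that("degenerate null test (group = pool) gives sd 0 and p = 1", {
  d <- mk_dist(matrix(runif(8), 4, 2))
  r <- null_test(d, rownames(d), reps = 50, seed = 1)
  expect_equal(r$null_sd, 0)
  expect_equal(r$p, 1)
  expect_true(is.na(r$ses))
})

test_that("an observation below every null value has the minimal rank p", {
  d <- mk_dist(rbind(c(0, 0), c(0, 0.001), c(5, 0), c(0, 5), c(5, 5), c(-5, 2)))
  # resampling from the four distant species only: every null exceeds the
  # observed near-zero pair distance
  r <- null_test(d, c("1", "2"), pool = c("3", "4", "5", "6"),
                 reps = 200, seed = 3)
  expect_equal(r$p, 1 / 201)
  expect_lt(r$ses, 0)
})

test_that("null mean converges to the exhaustive subset average", {
  set.seed(13)
  d <- mk_dist(matrix(runif(8), 4, 2))
  pairs <- utils::combn(4, 2)
  exact <- mean(apply(pairs, 2, function(ij) d[ij[1], ij[2]]))
  r <- null_test(d, c("1", "2"), reps = 10000, seed = 5)
  se <- sd(r$null_values) / sqrt(r$reps)
  expect_lt(abs(r$null_mean - exact), 3 * se)
})

test_that("null MPD mean equals the pool MPD under exhaustive enumeration", {
  set.seed(17)
  for (n_pool in c(6, 8)) {
    d <- mk_dist(matrix(runif(2 * n_pool), n_pool, 2))
    k <- 4
    subsets <- utils::combn(n_pool, k)
    enum_mean <- mean(apply(subsets, 2, function(idx) mpd(d, rownames(d)[idx])))
    expect_equal(enum_mean, mpd(d), tolerance = 1e-12)
  }
})

test_that("null tests are bit-identical under the same seed", {
  d <- mk_dist(matrix(runif(40), 20, 2))
  a <- null_test(d, rownames(d)[1:6], reps = 200, seed = 42)
  b <- null_test(d, rownames(d)[1:6], reps = 200, seed = 42)
  expect_identical(a, b)
  c_ <- null_test(d, rownames(d)[1:6], reps = 200, seed = 43)
  expect_false(identical(a$null_values, c_$null_values))
})

test_that("cophenetic distances are tree-path sums", {
  two <- ape::read.tree(text = "(a:1,b:2);")
  expect_equal(cophenetic_matrix(two)["a", "b"], 3)

  bal <- ape::read.tree(text = "((a:1,b:1):2,(c:1,d:1):2);")
  d <- cophenetic_matrix(bal)
  expect_equal(d["a", "c"], 6)   # 2 * depth for cross-cherry pairs
  expect_equal(d["a", "d"], 6)
  expect_equal(d["a", "b"], 2)

  yule <- gen_yule_tree(20, 1, seed = 8)
  expect_equal(cophenetic_matrix(yule), oracle_cophenetic(yule))

  nobl <- ape::read.tree(text = "(a,b);")
  expect_error(cophenetic_matrix(nobl), "branch length")
  dup <- ape::read.tree(text = "(a:1,a:1);")
  expect_error(cophenetic_matrix(dup), "duplicate")
})

test_that("color assembly table detects constructed clustering and overdispersion", {
  set.seed(3)
  pool <- data.frame(species_id = sprintf("s%03d", 1:150),
                     x = runif(150, -0.7, 0.7), y = runif(150, -0.7, 0.7))
  class(pool) <- c("color_loci", "data.frame")
  hits_cl <- hits_od <- 0
  for (seed in 1:10) {
    od <- gen_community(pool, "overdispersed", 15, seed = seed)
    cl_pool <- pool[!pool$species_id %in% od, ]
    class(cl_pool) <- class(pool)
    cl <- gen_community(cl_pool, "clustered", 25, seed = seed)
    rest <- setdiff(pool$species_id, c(cl, od))
    comm <- data.frame(
      species_id = c(cl, od, rest),
      group = c(rep("cl", 25), rep("od", 15), rep("rand", length(rest))))
    loci <- pool
    loci$theta_deg <- 0; loci$r <- 1; loci$sector <- "B"
    tab <- fca_table(loci, comm, reps = 199, seed = seed)
    hits_cl <- hits_cl + (tab$p[tab$group == "cl"] <= 0.05)
    hits_od <- hits_od + (tab$p[tab$group == "od"] >= 0.95)
  }
  expect_gte(hits_cl, 8)
  expect_gte(hits_od, 8)
})

test_that("pollinator-class rows keep the full pool", {
  set.seed(9)
  loci <- data.frame(species_id = sprintf("s%02d", 1:30),
                     x = runif(30), y = runif(30),
                     theta_deg = 0, r = 1, sector = "B")
  class(loci) <- c("color_loci", "data.frame")
  comm <- data.frame(species_id = loci$species_id,
                     group = rep(c("lo", "hi"), each = 15),
                     pollinator_class = c(rep(NA, 15), rep(c("bee", "fly"), c(8, 7))))
  tab <- fca_table(loci, comm, reps = 99, seed = 1)
  expect_setequal(tab$group, c("lo", "hi", "hi:bee", "hi:fly"))
  # subset rows resample from the same pooled species list: null means of the
  # class rows match the group rows' null scale, not the subset's own spread
  expect_equal(tab$n[tab$group == "hi:bee"], 8)
  expect_error(fca_table(loci[-1, ], comm), "s01")
})

test_that("phylogenetic structure table flags clade-restricted communities", {
  tree <- ape::read.tree(text = paste0(
    "((", paste(sprintf("a%d:1", 1:2), collapse = ","), "):9,(",
    "(b1:1,b2:1):1,(b3:1,b4:1):1):8);"))
  # community drawn entirely from the b-clade is clustered
  comm <- data.frame(species_id = c(sprintf("b%d", 1:4), sprintf("a%d", 1:2)),
                     group = c(rep("clade", 4), rep("out", 2)))
  tab <- phylo_structure_table(tree, comm, reps = 199, seed = 2)
  expect_setequal(tab$statistic, c("MPD", "MNTD"))
  p_clade <- tab$p[tab$group == "clade" & tab$statistic == "MPD"]
  expect_lte(p_clade, 0.10)
  expect_error(phylo_structure_table(tree, data.frame(species_id = "zz", group = "g")),
               "zz")
})

test_that("uniformly drawn communities give calibrated MPD p-values", {
  yule <- gen_yule_tree(40, 1, seed = 4)
  d <- cophenetic_matrix(yule)
  hits <- 0
  n_runs <- 100
  for (seed in seq_len(n_runs)) {
    set.seed(seed + 1000)
    grp <- sample(rownames(d), 12)
    r <- null_test(d, grp, reps = 199, seed = seed)
    hits <- hits + (r$p <= 0.05)
  }
  expect_gte(hits / n_runs, 0.0)
  expect_lte(hits / n_runs, 0.12)
})
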
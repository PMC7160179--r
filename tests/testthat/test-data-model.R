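test_that("read_tree parses, indexes, and flags ultrametricity", {
  tf <- tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", tf)
  phy <- read_tree(tf)
  expect_s3_class(phy, "phylo")
  expect_equal(ape::Ntip(phy), 3L)
  expect_equal(phy$Nnode, 2L)
  expect_true(is_ultrametric(phy))
  expect_equal(max(ape::node.depth.edgelength(phy)), 2)

  writeLines("((A:1,B:1):1,C:3);", tf)
  expect_warning(phy2 <- read_tree(tf), "ultrametric")
  expect_false(is_ultrametric(phy2))

  writeLines("((A:1,A:1):1,C:2);", tf)
  expect_error(read_tree(tf), "duplicate tip labels: A")

  writeLines("((A,B),C);", tf)
  expect_error(read_tree(tf), "branch lengths")
})

test_that("nexus round trip preserves topology and branch lengths", {
  phy <- balanced4()
  nx <- tempfile(fileext = ".nex")
  write_tree(phy, nx, format = "nexus")
  back <- read_tree(nx)               # format guessed from extension
  expect_equal(sort(back$tip.label), sort(phy$tip.label))
  d1 <- ape::cophenetic.phylo(phy)
  d2 <- ape::cophenetic.phylo(back)[rownames(d1), colnames(d1)]
  expect_equal(d1, d2, tolerance = 1e-9)
})

test_that("newick round trip is exact to 1e-9 relative", {
  phy <- simulate_tree(sim_config(n_tips = 20, seed = 3))
  tf <- tempfile(fileext = ".nwk")
  write_tree(phy, tf)
  back <- read_tree(tf)
  expect_setequal(back$tip.label, phy$tip.label)
  d1 <- ape::cophenetic.phylo(phy)
  expect_equal(ape::cophenetic.phylo(back)[rownames(d1), colnames(d1)],
               d1, tolerance = 1e-9)
})

test_that("reconcile prunes to the intersection and is idempotent", {
  phy <- ape::read.tree(text = "((A:1,B:1):1,(C:1.5,(D:1,E:1):0.5):0.5);")
  raw <- data.frame(
    species = c("a", "B ", "C", "D", "not_here"),
    dominant_frequency_hz = c(1000, 2000, 1500, 800, 1200),
    svl_mm = c(30, 40, 25, 60, 33),
    calling_site = c("aquatic", "terrestrial", "arboreal", "terrestrial",
                     "aquatic"),
    me_var = c(0.01, NA, 0.02, NA, 0.01))
  suppressMessages(rec <- reconcile(phy, raw))
  expect_equal(ape::Ntip(rec$tree), 4L)
  expect_equal(rec$dropped_tips, "E")
  expect_equal(rec$dropped_rows, "not_here")
  expect_equal(rec$table$species, rec$tree$tip.label)
  expect_equal(rec$table$log_df[rec$table$species == "A"], log(1000))
  expect_equal(rec$table$log_size[rec$table$species == "D"], log(60))
  # idempotent: reconciling the reconciled pair changes nothing
  suppressMessages(rec2 <- reconcile(rec$tree, rec$table))
  expect_equal(rec2$table, rec$table)
  expect_equal(ape::Ntip(rec2$tree), 4L)
  # pruning preserves the root-to-tip depth of retained tips
  keep <- intersect(phy$tip.label, rec$tree$tip.label)
  d_full <- ape::node.depth.edgelength(phy)[match(keep, phy$tip.label)]
  d_prun <- ape::node.depth.edgelength(rec$tree)[
    match(keep, rec$tree$tip.label)]
  expect_equal(d_full, d_prun)
})

test_that("reconcile rejects empty or tiny intersections", {
  phy <- balanced4()
  raw <- data.frame(species = c("X", "Y", "Z", "W"),
                    dominant_frequency_hz = 1:4 * 100, svl_mm = 1:4 * 10,
                    calling_site = "terrestrial", me_var = NA)
  expect_error(reconcile(phy, raw), "no species shared")
  raw$species <- c("A", "B", "C", "W")
  expect_error(suppressMessages(reconcile(phy, raw)), "at least 4")
})

test_that("measurement-error imputation follows the chosen policy", {
  tab <- trait_table(c("A", "B", "C"), c(7, 8, 9), c(3, 4, 5),
                     rep("terrestrial", 3), c(0.01, 0.03, NA))
  full <- impute_me(tab, "mean")
  expect_equal(full$me_var, c(0.01, 0.03, 0.02))
  expect_equal(attr(full, "me_policy")$n_imputed, 1L)
  expect_equal(impute_me(tab, "zero")$me_var[3], 0)
  expect_equal(impute_me(tab, "fixed", value = 0.5)$me_var[3], 0.5)
  # identity when complete
  expect_equal(impute_me(full, "mean")$me_var, full$me_var)
  none <- trait_table("A", 7, 3, "aquatic", NA_real_)
  expect_error(impute_me(none, "mean"), "zero")
})

test_that("trait_table validates its invariants", {
  expect_error(trait_table("A", 7, 3, "burrowing"), "calling-site")
  expect_error(trait_table("A", Inf, 3, "aquatic"), "finite")
  expect_error(trait_table(c("A", "A"), c(7, 8), c(3, 4),
                           c("aquatic", "aquatic")), "duplicate")
  expect_error(trait_table("A", 7, 3, "aquatic", -0.1), ">= 0")
})
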
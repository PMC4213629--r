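test_that("Newick topologies parse with checks for duplicates and polytomies", {
  phy <- read_tree_topology("((A,B),C);")
  expect_equal(ape::Ntip(phy), 3)
  expect_equal(phy$Nnode, 2)
  expect_null(phy$edge.length)
  expect_message(read_tree_topology("(A,B,C);"), "polytom")
  expect_error(read_tree_topology("((A,B),A);"), "duplicate")
  expect_error(read_tree_topology("((A,B;"), "parse")
  # input branch lengths are discarded; ages come from occurrences
  phy2 <- read_tree_topology("((A:1,B:2):3,C:4);")
  expect_null(phy2$edge.length)
})

test_that("basic time-scaling dates nodes at the oldest descendant", {
  phy <- read_tree_topology("((A,B),C);")
  ages <- c(A = 155, B = 150, C = 160)
  tt <- suppressMessages(time_scale(phy, ages, mode = "basic"))
  # tips 1:3 then root (node 4) and the (A,B) node (node 5)
  expect_equal(unname(tt$node_ages), c(155, 150, 160, 160, 155))
  expect_equal(tt$root.time, 160)
  lens <- setNames(tt$edge.length, tt$edge[, 2])
  expect_equal(unname(lens[c("5", "1", "2", "3")]), c(5, 0, 5, 0))
  expect_error(time_scale(phy, c(A = 155, B = 150)), "C")
})

test_that("mbl time-scaling enforces the minimum without touching tip ages", {
  phy <- read_tree_topology("((A,B),C);")
  ages <- c(A = 155, B = 150, C = 160)
  basic <- suppressMessages(time_scale(phy, ages, mode = "basic"))
  tt <- time_scale(phy, ages, mode = "mbl", mbl = 1)
  expect_true(all(tt$edge.length >= 1 - 1e-12))
  expect_equal(unname(tt$node_ages[1:3]), unname(ages[phy$tip.label]))
  # mbl never lowers a node age relative to basic
  expect_true(all(tt$node_ages >= basic$node_ages - 1e-12))
  # equal tip ages in a pair: basic flags zero-length terminals
  pair <- read_tree_topology("(A,B);")
  expect_message(time_scale(pair, c(A = 150, B = 150), mode = "basic"),
                 "zero-length")
})

test_that("ancestral states minimise branch-weighted squared change", {
  # star tree, equal branches: root is the mean
  star <- ape::read.tree(text = "(A:1,B:1,C:1);")
  expect_equal(ancestral_states(star, c(A = 0, B = 1, C = 2))$axis1[4], 1)
  # constant tips propagate unchanged
  expect_equal(ancestral_states(star, c(A = 7, B = 7, C = 7))$axis1[4], 7)
  # two tips, branches (1, 3): frozen value from a brute-force minimisation
  # of (x - 0)^2 / 1 + (x - 4)^2 / 3 (optimum x = 1)
  two <- ape::read.tree(text = "(A:1,B:3);")
  est <- ancestral_states(two, c(A = 0, B = 4))$axis1[3]
  oracle <- optimize(function(x) x^2 / 1 + (x - 4)^2 / 3, c(-50, 50))$minimum
  expect_equal(est, 1, tolerance = 1e-8)
  expect_equal(est, oracle, tolerance = 1e-6)
  # general tree: numerical optimisation over all internal nodes agrees
  sim <- make_bm_tree_data(n_tips = 6, seed = 17)
  fit <- ancestral_states(sim$tree, sim$tip_values)
  obj <- function(z) {
    vals <- c(sim$tip_values[sim$tree$tip.label], z)
    sum((vals[sim$tree$edge[, 1]] - vals[sim$tree$edge[, 2]])^2 / sim$tree$edge.length)
  }
  opt <- optim(rep(mean(sim$tip_values), sim$tree$Nnode), obj, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 2000))
  expect_equal(fit$axis1[7:11], unname(opt$par), tolerance = 1e-6)
  expect_error(ancestral_states(ape::read.tree(text = "(A:0,B:1);"), c(A = 0, B = 1)),
               "mbl")
})

test_that("ancestral states match an independent Brownian ML implementation", {
  sim <- make_bm_tree_data(n_tips = 12, seed = 3)
  ours <- ancestral_states(sim$tree, sim$tip_values)
  ref <- phytools::fastAnc(sim$tree, sim$tip_values)
  expect_equal(ours$axis1[13:23], unname(as.numeric(ref)), tolerance = 1e-8)
})

test_that("phylomorphospace projection emits one segment per branch", {
  sim <- make_bm_tree_data(n_tips = 8, seed = 23)
  scores <- cbind(PC1 = sim$tip_values, PC2 = 2 * sim$tip_values)
  seg <- project_phylomorphospace(sim$tree, scores)
  expect_equal(nrow(seg), nrow(sim$tree$edge))
  tips <- seg[seg$child_is_tip, ]
  expect_equal(tips$child_x, unname(scores[tips$child, 1]))
  expect_equal(tips$child_y, unname(scores[tips$child, 2]))
  # a tip without scores is pruned (with a warning), removing its branch
  expect_warning(seg2 <- project_phylomorphospace(sim$tree, scores[-1, , drop = FALSE]),
                 "dropping")
  expect_equal(nrow(seg2), nrow(seg) - 2) # tip branch + collapsed internal edge
  # projection invariant to tip input order
  perm <- sample(nrow(scores))
  seg3 <- project_phylomorphospace(sim$tree, scores[perm, , drop = FALSE])
  key <- function(s) s[order(s$parent, s$child), c("parent_x", "child_x", "child_y")]
  expect_equal(key(seg3), key(seg), tolerance = 1e-12)
})

test_that("root-state estimation is unbiased on simulated Brownian data", {
  n_rep <- 200
  errs <- vapply(seq_len(n_rep), function(r) {
    sim <- make_bm_tree_data(n_tips = 15, rate = 1, root_state = 5,
                             seed = 40000 + r)
    fit <- ancestral_states(sim$tree, sim$tip_values)
    fit$axis1[16] - sim$root_state
  }, double(1))
  se <- sd(errs) / sqrt(n_rep)
  expect_lt(abs(mean(errs)), 2 * se + 1e-12)
})

test_that("timed trees serialise to Newick with Myr branch lengths", {
  phy <- read_tree_topology("((A,B),C);")
  tt <- time_scale(phy, c(A = 155, B = 150, C = 160), mode = "mbl", mbl = 1)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_timed_tree(tt, f)
  back <- ape::read.tree(f)
  expect_equal(sort(back$tip.label), c("A", "B", "C"))
  expect_equal(sort(back$edge.length), sort(tt$edge.length))
})
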
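test_that("von Mises invariant matches closed forms", {
  expect_equal(element_von_mises(c(100, 0, 0, 0, 0, 0)), 100)
  expect_equal(element_von_mises(c(0, 0, 0, 50, 0, 0)), sqrt(3) * 50)
  expect_equal(element_von_mises(c(7, 7, 7, 0, 0, 0)), 0)
  # matrix input, vectorised
  S <- rbind(c(100, 0, 0, 0, 0, 0), c(3, 3, 3, 0, 0, 0))
  expect_equal(element_von_mises(S), c(100, 0))
})

test_that("stiffness operator is symmetric, scales with E, and has 6 rigid modes", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  m <- tet_mesh(nodes, matrix(1:4, 1))
  K <- assemble_stiffness(m, list(bone = material("bone", 1, 0)))
  expect_lt(max(abs(K - Matrix::t(K))), 1e-12)
  expect_equal(Matrix::rankMatrix(as.matrix(K))[1], 12 - 6)
  K10 <- assemble_stiffness(m, list(bone = material("bone", 10, 0)))
  expect_equal(as.matrix(K10), 10 * as.matrix(K), tolerance = 1e-12)
  expect_error(assemble_stiffness(m, list(wrong = material("w", 1, 0))), "bone")
})

test_that("patch test: boundary-prescribed affine field is reproduced exactly", {
  m <- make_box_mesh(c(2, 2, 2), c(2, 2, 2))
  A <- rbind(c(1e-3, 2e-4, -1e-4),
             c(3e-4, -5e-4, 2e-4),
             c(-2e-4, 1e-4, 4e-4))
  U_exact <- m$nodes %*% t(A)
  bnd <- sort(unique(unlist(lapply(c("xmin", "xmax", "ymin", "ymax", "zmin", "zmax"),
                                   function(f) select_nodes(m, face = f)))))
  lc <- load_case(constraints = list(
    list(node_set = bnd, axes = c("x", "y", "z"), mode = "per_node",
         value = U_exact[bnd, , drop = FALSE])
  ))
  mat <- list(bone = material("bone", 2000, 0.3))
  sol <- solve_static(m, mat, lc)
  expect_equal(sol$displacement, U_exact, tolerance = 1e-9)
  # constant-strain elements: stress exactly uniform over the patch
  expect_lt(max(apply(sol$stress, 2, function(s) diff(range(s)))), 1e-9)
  eps <- (A + t(A)) / 2
  E <- 2000; nu <- 0.3
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu)); mu <- E / (2 * (1 + nu))
  sig_exact <- lam * sum(diag(eps)) * diag(3) + 2 * mu * eps
  expect_equal(unname(sol$stress[1, ]),
               c(sig_exact[1, 1], sig_exact[2, 2], sig_exact[3, 3],
                 sig_exact[1, 2], sig_exact[2, 3], sig_exact[3, 1]),
               tolerance = 1e-9)
})

test_that("axial bar reproduces the closed form exactly and behaves linearly", {
  mod <- bar_model(c(2, 2, 10))
  sol <- solve_static(mod$mesh, mod$materials, axial_case(mod$mesh, 100))
  expect_equal(mean(sol$displacement[mod$mesh$node_sets$top, 3]), 0.1,
               tolerance = 1e-9) # FL/EA
  expect_equal(unname(range(sol$stress[, "zz"])), c(1, 1), tolerance = 1e-9)
  s <- stress_summary(sol)
  expect_equal(c(s$min, s$mean, s$max), c(1, 1, 1), tolerance = 1e-9)
  expect_lt(max_abs_equilibrium(sol), 1e-6 * 100)

  sol2 <- solve_static(mod$mesh, mod$materials, axial_case(mod$mesh, 200))
  expect_equal(sol2$displacement, 2 * sol$displacement, tolerance = 1e-9)
  expect_equal(sol2$von_mises, 2 * sol$von_mises, tolerance = 1e-9)

  # stiffer material: displacement shrinks, stress unchanged (determinate case)
  stiff <- bar_model(c(2, 2, 10), E = 10000)
  sol3 <- solve_static(stiff$mesh, stiff$materials, axial_case(stiff$mesh, 100))
  expect_equal(sol3$displacement, sol$displacement / 10, tolerance = 1e-9)
  expect_equal(sol3$von_mises, sol$von_mises, tolerance = 1e-8)
})

test_that("two-material bar in series carries continuous uniform stress", {
  mod <- bar_model(c(2, 2, 10), regions = c(stiff = 0.5, soft = 1))
  mod$materials <- list(stiff = material("stiff", 2000, 0),
                        soft = material("soft", 1000, 0))
  sol <- solve_static(mod$mesh, mod$materials, axial_case(mod$mesh, 100))
  s <- stress_summary(sol)
  expect_equal(c(s$min, s$mean, s$max), c(1, 1, 1), tolerance = 1e-9)
  # compliance adds in series: delta = F L1/(E1 A) + F L2/(E2 A)
  expect_equal(mean(sol$displacement[mod$mesh$node_sets$top, 3]),
               100 * 50 / (2000 * 100) + 100 * 50 / (1000 * 100), tolerance = 1e-9)
})

test_that("muscle loads split force equally along per-node directions", {
  m <- make_box_mesh(c(1, 1, 1), c(1, 1, 1))
  nA <- select_nodes(m, within = c(1, 1, 0, 0, 0, 0)) # (1,0,0)
  nB <- select_nodes(m, within = c(0, 0, 1, 1, 0, 0)) # (0,1,0)
  m$node_sets <- list(pair = c(nA, nB), single = nA,
                      above = select_nodes(m, face = "zmax"))
  # orthogonal directions towards the origin: resultant 100/sqrt(2)
  f <- apply_muscle_load(m, list(origination_set = "pair",
                                 insertion_point = c(0, 0, 0), total_force = 100))
  res <- colSums(matrix(f, ncol = 3, byrow = TRUE))
  expect_equal(sqrt(sum(res^2)), 100 / sqrt(2), tolerance = 1e-12)
  # per-node magnitude is total/N
  expect_equal(sqrt(sum(f[(3 * (nA - 1) + 1):(3 * nA)]^2)), 50)

  # single node: full force along its direction
  f1 <- apply_muscle_load(m, list(origination_set = "single",
                                  insertion_point = c(0, 0, 0), total_force = 70))
  expect_equal(sqrt(sum(f1^2)), 70)

  # all nodes directly above the insertion: resultant equals the total
  f2 <- apply_muscle_load(m, list(origination_set = "above",
                                  insertion_point = c(0.5, 0.5, -10), total_force = 100))
  res2 <- colSums(matrix(f2, ncol = 3, byrow = TRUE))
  # corners pull towards (0.5, 0.5, -10): lateral parts cancel, z parts add
  expect_equal(res2[3], -100 * 11 / sqrt(11^2 + 0.5), tolerance = 1e-12)
  expect_equal(res2[1:2], c(0, 0), tolerance = 1e-12)
  expect_error(apply_muscle_load(m, list(origination_set = "single",
                                         insertion_point = c(1, 0, 0),
                                         total_force = 10)), "coincides")
})

test_that("bite-force extraction recovers applied load from reactions", {
  mod <- bar_model(c(2, 2, 10))
  base <- mod$mesh$node_sets$base
  lc <- load_case(
    external_loads = list(list(node_set = "top", force = c(0, 100, 0),
                               distribute = "equal")),
    bite_constraints = base
  )
  bf <- bite_force(mod$mesh, mod$materials, lc, axis = "y")
  expect_equal(bf$total_N, 100, tolerance = 1e-6)
  expect_equal(sum(bf$per_node$force_N), -100, tolerance = 1e-6)

  # zero load -> zero bite force
  lc0 <- load_case(bite_constraints = base)
  expect_equal(bite_force(mod$mesh, mod$materials, lc0)$total_N, 0, tolerance = 1e-9)

  # bite node overlapping another constraint set is rejected
  lc_bad <- load_case(
    constraints = list(list(node_set = base, axes = "y", mode = "per_node")),
    bite_constraints = base[1]
  )
  expect_error(bite_force(mod$mesh, mod$materials, lc_bad), "another constraint")
})

test_that("symmetric proxy with symmetric loads gives equal left/right bite reactions", {
  mod <- skull_proxy_model(cells = c(2, 2, 6))
  lc <- mod$loadcase
  lc$bite_constraints <- mod$bite_anterior
  bf <- bite_force(mod$mesh, mod$materials, lc)
  expect_equal(bf$per_node$force_N[1], bf$per_node$force_N[2],
               tolerance = 1e-6 * abs(bf$per_node$force_N[1]))
  expect_lt(max_abs_equilibrium(bf$solution), 1e-6 * 1000)
})

test_that("distributed couplings constrain the set average and report reactions", {
  mod <- bar_model(c(2, 2, 10))
  lc <- load_case(
    external_loads = list(list(node_set = "top", force = c(0, 0, 100))),
    constraints = list(
      list(node_set = "base", axes = c("x", "y", "z"), mode = "distributed_coupling"),
      list(node_set = select_nodes(mod$mesh, within = c(0, 0, 0, 0, 0, 0)),
           axes = c("x", "y"), mode = "per_node"),
      list(node_set = select_nodes(mod$mesh, within = c(10, 10, 0, 0, 0, 0)),
           axes = "y", mode = "per_node")
    )
  )
  sol <- solve_static(mod$mesh, mod$materials, lc)
  base <- mod$mesh$node_sets$base
  expect_lt(abs(mean(sol$displacement[base, 3])), 1e-10) # average pinned
  expect_lt(max_abs_equilibrium(sol), 1e-6 * 100)
  dcc_z <- sol$reactions$force_N[grepl("^dcc", sol$reactions$source) &
                                   sol$reactions$axis == "z"]
  expect_equal(sum(dcc_z), -100, tolerance = 1e-6)
})

test_that("under-constrained systems raise an explicit error", {
  mod <- bar_model(c(1, 1, 2))
  lc <- load_case(external_loads = list(list(node_set = "top", force = c(0, 0, 1),
                                             distribute = "equal")))
  expect_error(solve_static(mod$mesh, mod$materials, lc),
               "singular|under-constrained")
})

test_that("geometric similarity: scaled mesh with s^2-scaled loads matches stresses", {
  mod <- bar_model(c(2, 2, 5))
  lc <- axial_case(mod$mesh, 100)
  sol <- solve_static(mod$mesh, mod$materials, lc)
  s <- 2
  mesh2 <- mod$mesh
  mesh2$nodes <- mesh2$nodes * s
  lc2 <- lc
  lc2$external_loads[[1]]$force <- lc$external_loads[[1]]$force * s^2
  sol2 <- solve_static(mesh2, mod$materials, lc2)
  expect_equal(sol2$stress, sol$stress, tolerance = 1e-9)
  expect_equal(sol2$von_mises, sol$von_mises, tolerance = 1e-9)
})
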
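#' Define an isotropic linear-elastic material
#'
#' @param name Material name.
#' @param young_modulus Young's modulus E, MPa (> 0).
#' @param poisson_ratio Poisson's ratio nu, in (0, 0.5) (0 allowed for
#'   analytic test fields).
#' @return A `material` object.
#' @export
material <- function(name, young_modulus, poisson_ratio) {
  assert_scalar_pos(young_modulus, "young_modulus")
  if (!is.numeric(poisson_ratio) || poisson_ratio < 0 || poisson_ratio >= 0.5) {
    stop_input("`poisson_ratio` must lie in [0, 0.5)")
  }
  structure(list(name = name, young_modulus = young_modulus,
                 poisson_ratio = poisson_ratio), class = "material")
}

#' Define a static load case
#'
#' @param muscle_loads List of muscle loads, each
#'   `list(origination_set =, insertion_point =, total_force =)`: the total
#'   force (N) is split equally over the origination-set nodes, each nodal
#'   force directed from that node towards the insertion point (mirroring
#'   preprocessor muscle-wrapping macros).
#' @param external_loads List of `list(node_set =, force = c(Fx, Fy, Fz),
#'   distribute = "area"|"equal")` entries; `"area"` (default) distributes by
#'   boundary-triangle tributary area, `"equal"` splits uniformly.
#' @param constraints List of `list(node_set =, axes = c("x","y","z") subset,
#'   mode = "per_node"|"distributed_coupling", value = 0, tag = NULL)`.
#'   `per_node` prescribes the displacement of every node in the set on the
#'   given axes (`value` may be a scalar or an n-node x n-axes matrix);
#'   `distributed_coupling` constrains the set-average displacement on each
#'   axis via a Lagrange multiplier, spreading the restraint over the set as
#'   a distributing coupling does.
#' @param bite_constraints Integer node ids, each fully fixed, whose
#'   reactions are read out as bite forces.
#' @return A `load_case` object.
#' @export
load_case <- function(muscle_loads = list(), external_loads = list(),
                      constraints = list(), bite_constraints = integer(0)) {
  for (c in constraints) {
    if (base::length(c$axes %||% character(0)) == 0) stop_input("constraint with empty axes")
  }
  for (ml in muscle_loads) {
    if ((ml$total_force %||% -1) < 0) stop_input("muscle load total_force must be >= 0")
  }
  structure(list(muscle_loads = muscle_loads, external_loads = external_loads,
                 constraints = constraints,
                 bite_constraints = as.integer(bite_constraints)),
            class = "load_case")
}

axis_index <- function(axes) {
  idx <- match(axes, c("x", "y", "z"))
  if (any(is.na(idx))) stop_input("axes must be among x, y, z")
  idx
}

# per-element shape-function gradients G [m x 4 x 3] and volumes V [m]
element_gradients <- function(mesh) {
  X <- mesh$nodes
  e <- mesh$elements
  a <- X[e[, 2], , drop = FALSE] - X[e[, 1], , drop = FALSE]
  b <- X[e[, 3], , drop = FALSE] - X[e[, 1], , drop = FALSE]
  cc <- X[e[, 4], , drop = FALSE] - X[e[, 1], , drop = FALSE]
  cross <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                                u[, 3] * v[, 1] - u[, 1] * v[, 3],
                                u[, 1] * v[, 2] - u[, 2] * v[, 1])
  bxc <- cross(b, cc)
  det <- rowSums(a * bxc) # = 6V
  m <- nrow(e)
  G <- array(0, dim = c(m, 4, 3))
  G[, 2, ] <- bxc / det
  G[, 3, ] <- cross(cc, a) / det
  G[, 4, ] <- cross(a, b) / det
  G[, 1, ] <- -(G[, 2, ] + G[, 3, ] + G[, 4, ])
  list(G = G, V = det / 6)
}

lame_parameters <- function(mesh, materials) {
  regs <- unique(mesh$regions)
  unmapped <- setdiff(regs, names(materials))
  if (base::length(unmapped) > 0) {
    stop_input("no material mapped for region(s): %s", paste(unmapped, collapse = ", "))
  }
  E <- vapply(materials, function(m) m$young_modulus, double(1))[mesh$regions]
  nu <- vapply(materials, function(m) m$poisson_ratio, double(1))[mesh$regions]
  list(lambda = E * nu / ((1 + nu) * (1 - 2 * nu)), mu = E / (2 * (1 + nu)))
}

#' Assemble the global stiffness matrix
#'
#' Constant-strain 4-node tetrahedra (the element type of the production
#' cranial models), standard isotropic small-strain formulation. The
#' operator is symmetric with exactly six zero-energy (rigid-body) modes for
#' an unconstrained connected mesh.
#'
#' @param mesh A [tet_mesh()].
#' @param materials Named list of [material()] objects keyed by region name;
#'   every region of the mesh must be mapped.
#' @return A sparse symmetric `3N x 3N` `Matrix::dgCMatrix`; dof ordering is
#'   `(x1, y1, z1, x2, ...)`.
#' @export
assemble_stiffness <- function(mesh, materials) {
  eg <- element_gradients(mesh)
  lp <- lame_parameters(mesh, materials)
  href <- max(apply(mesh$nodes, 2, function(x) diff(range(x))))
  if (any(eg$V <= 1e-12 * href^3)) {
    stop_input("zero-volume element(s): %s",
               paste(head(which(eg$V <= 1e-12 * href^3), 5), collapse = ", "))
  }
  G <- eg$G; V <- eg$V
  m <- nrow(mesh$elements)
  n3 <- 3L * nrow(mesh$nodes)
  # K_{(i,a),(j,b)} = V (lambda G_ia G_jb + mu G_ib G_ja + mu delta_ab G_i . G_j)
  ii <- jj <- integer(144L * m)
  xx <- double(144L * m)
  pos <- 0L
  dof <- function(node_col, ax) 3L * (mesh$elements[, node_col] - 1L) + ax
  for (i in 1:4) for (j in 1:4) {
    gij <- G[, i, 1] * G[, j, 1] + G[, i, 2] * G[, j, 2] + G[, i, 3] * G[, j, 3]
    for (a in 1:3) for (b in 1:3) {
      val <- V * (lp$lambda * G[, i, a] * G[, j, b] + lp$mu * G[, i, b] * G[, j, a] +
                    (a == b) * lp$mu * gij)
      idx <- pos + seq_len(m)
      ii[idx] <- dof(i, a)
      jj[idx] <- dof(j, b)
      xx[idx] <- val
      pos <- pos + m
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n3, n3))
}

# total nodal force vector (length 3N) for a load case
assemble_loads <- function(mesh, loadcase) {
  n <- nrow(mesh$nodes)
  f <- numeric(3 * n)
  for (ml in loadcase$muscle_loads) {
    f <- f + apply_muscle_load(mesh, ml)
  }
  for (el in loadcase$external_loads) {
    f <- f + apply_external_load(mesh, el$node_set, el$force,
                                 distribute = el$distribute %||% "area")
  }
  f
}

#' Nodal force vector for a muscle load
#'
#' Splits `total_force` equally over the origination-set nodes; each node's
#' share points from that node towards the insertion point. The per-node
#' magnitude is exact; the resultant equals `total_force` only when all
#' directions are parallel.
#'
#' @param mesh A [tet_mesh()].
#' @param load `list(origination_set =, insertion_point =, total_force =)`.
#' @return Numeric force vector of length `3N` (N).
#' @export
apply_muscle_load <- function(mesh, load) {
  ids <- mesh$node_sets[[load$origination_set]] %||%
    stop_input("unknown origination set `%s`", load$origination_set)
  if (base::length(ids) == 0) stop_input("origination set `%s` is empty", load$origination_set)
  P <- matrix(load$insertion_point, nrow = base::length(ids), ncol = 3, byrow = TRUE)
  D <- P - mesh$nodes[ids, , drop = FALSE]
  len <- sqrt(rowSums(D^2))
  if (any(len < 1e-12)) {
    stop_input("insertion point coincides with origination node(s): %s",
               paste(ids[len < 1e-12], collapse = ", "))
  }
  Fn <- (load$total_force / base::length(ids)) * D / len
  f <- numeric(3 * nrow(mesh$nodes))
  for (a in 1:3) f[3 * (ids - 1) + a] <- f[3 * (ids - 1) + a] + Fn[, a]
  f
}

# distribute an external resultant over a node set
apply_external_load <- function(mesh, node_set, force, distribute = c("area", "equal")) {
  distribute <- match.arg(distribute)
  ids <- if (is.character(node_set)) {
    mesh$node_sets[[node_set]] %||% stop_input("unknown node set `%s`", node_set)
  } else as.integer(node_set)
  w <- if (distribute == "equal") rep(1, base::length(ids)) else {
    tris <- boundary_facets(mesh)
    inset <- matrix(tris %in% ids, ncol = 3)
    tris <- tris[rowSums(inset) == 3, , drop = FALSE]
    if (nrow(tris) == 0) stop_input("node set spans no boundary triangles; use distribute = \"equal\"")
    ar <- triangle_areas(mesh$nodes, tris)
    vapply(ids, function(id) sum(ar[rowSums(tris == id) > 0]) / 3, double(1))
  }
  w <- w / sum(w)
  f <- numeric(3 * nrow(mesh$nodes))
  for (a in 1:3) f[3 * (ids - 1) + a] <- force[a] * w
  f
}

resolve_set <- function(mesh, node_set) {
  if (is.character(node_set)) {
    mesh$node_sets[[node_set]] %||% stop_input("unknown node set `%s`", node_set)
  } else as.integer(node_set)
}

#' Solve a linear static FE problem
#'
#' Direct sparse solve of `K u = f` under per-node prescribed displacements,
#' distributed-coupling (set-average) constraints enforced with Lagrange
#' multipliers, and fully-fixed bite nodes. Errors if the constrained system
#' is still singular (rigid-body modes remain) rather than returning a
#' pseudo-inverse solution. Repeated runs are deterministic.
#'
#' @param mesh A [tet_mesh()].
#' @param materials Named list of [material()] by region.
#' @param loadcase A [load_case()].
#' @return A `solution_field`: per-node `displacement` (mm), per-element
#'   `stress` (6 columns `xx, yy, zz, xy, yz, zx`, MPa), per-element
#'   `von_mises` (MPa), a `reactions` tibble (node/set, axis, force N), the
#'   assembled `applied` force vector, and `equilibrium` residuals per axis.
#' @export
solve_static <- function(mesh, materials, loadcase) {
  n <- nrow(mesh$nodes)
  n3 <- 3L * n
  K <- assemble_stiffness(mesh, materials)
  f <- assemble_loads(mesh, loadcase)

  fixed <- logical(n3)
  uval <- numeric(n3)
  add_fixed <- function(ids, axes_idx, values) {
    vm <- matrix(values, nrow = base::length(ids), ncol = base::length(axes_idx),
                 byrow = is.null(dim(values)) && base::length(values) == base::length(axes_idx))
    for (k in seq_along(axes_idx)) {
      d <- 3L * (ids - 1L) + axes_idx[k]
      fixed[d] <<- TRUE
      uval[d] <<- vm[, k]
    }
  }
  dcc <- list()
  for (cn in loadcase$constraints) {
    ids <- resolve_set(mesh, cn$node_set)
    ax <- axis_index(cn$axes)
    mode <- cn$mode %||% "per_node"
    if (mode == "per_node") {
      add_fixed(ids, ax, cn$value %||% 0)
    } else if (mode == "distributed_coupling") {
      for (a in ax) dcc[[base::length(dcc) + 1]] <- list(ids = ids, axis = a,
                                                         value = cn$value %||% 0,
                                                         set = cn$node_set)
    } else stop_input("unknown constraint mode `%s`", mode)
  }
  bite <- loadcase$bite_constraints
  if (base::length(bite) > 0) {
    prior <- 3L * rep(bite - 1L, each = 3) + 1:3
    if (any(fixed[prior])) {
      stop_input("bite node(s) also appear in another constraint set: %s",
                 paste(unique(bite[fixed[3 * (bite - 1) + 1] | fixed[3 * (bite - 1) + 2] |
                                     fixed[3 * (bite - 1) + 3]]), collapse = ", "))
    }
    in_dcc <- vapply(dcc, function(d) any(bite %in% d$ids), logical(1))
    if (any(in_dcc)) stop_input("bite node(s) also appear in a distributed-coupling set")
    add_fixed(bite, 1:3, 0)
  }
  free <- which(!fixed)
  fixd <- which(fixed)
  if (base::length(free) == 0) stop_input("no free degrees of freedom")

  rhs <- f[free] - as.numeric(K[free, fixd, drop = FALSE] %*% uval[fixd])
  nC <- base::length(dcc)
  u <- uval
  lambda <- numeric(nC)
  solve_or_singular <- function(A, b) {
    out <- tryCatch(Matrix::solve(A, b), error = function(e) {
      stop_input("singular stiffness system (under-constrained model?): %s", conditionMessage(e))
    })
    as.numeric(out)
  }
  if (nC == 0) {
    u[free] <- solve_or_singular(K[free, free], rhs)
  } else {
    Ct <- Matrix::sparseMatrix(
      i = unlist(lapply(seq_along(dcc), function(q) rep(q, base::length(dcc[[q]]$ids)))),
      j = unlist(lapply(dcc, function(d) 3L * (d$ids - 1L) + d$axis)),
      x = unlist(lapply(dcc, function(d) rep(1 / base::length(d$ids), base::length(d$ids)))),
      dims = c(nC, n3)
    )
    Cf <- Ct[, free, drop = FALSE]
    A <- rbind(cbind(K[free, free], Matrix::t(Cf)),
               cbind(Cf, Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                              dims = c(nC, nC))))
    b <- c(rhs, vapply(dcc, function(d) d$value, double(1)) -
             as.numeric(Ct[, fixd, drop = FALSE] %*% uval[fixd]))
    sol <- solve_or_singular(A, b)
    u[free] <- sol[seq_along(free)]
    lambda <- sol[base::length(free) + seq_len(nC)]
  }
  # residual check: catches semi-definite systems that factorised anyway
  resid <- as.numeric(K[free, free] %*% u[free]) - rhs
  if (nC > 0) resid <- resid + as.numeric(Matrix::t(Ct[, free, drop = FALSE]) %*% lambda)
  scale_ref <- max(abs(f), abs(K@x)) + 1e-30
  if (max(abs(resid)) > 1e-6 * scale_ref) {
    stop_input("solver residual too large (%.3g): system is likely under-constrained",
               max(abs(resid)))
  }

  Ku <- as.numeric(K %*% u)
  reactions <- tibble(
    node = (fixd - 1L) %/% 3L + 1L,
    axis = c("x", "y", "z")[(fixd - 1L) %% 3L + 1L],
    force_N = Ku[fixd] - f[fixd],
    source = as.character(ifelse(((fixd - 1L) %/% 3L + 1L) %in% bite, "bite", "per_node"))
  )
  if (nC > 0) {
    # force exerted on the structure by coupling q is -lambda_q spread with
    # its row weights; dofs of the set that are fixed elsewhere carry none
    w_free <- vapply(seq_len(nC), function(q) {
      d <- dcc[[q]]
      dofs <- 3L * (d$ids - 1L) + d$axis
      sum(!fixed[dofs]) / base::length(d$ids)
    }, double(1))
    reactions <- dplyr::bind_rows(reactions, tibble(
      node = NA_integer_,
      axis = c("x", "y", "z")[vapply(dcc, function(d) as.integer(d$axis), integer(1))],
      force_N = -lambda * w_free,
      source = paste0("dcc:", vapply(dcc, function(d) as.character(d$set), character(1)))
    ))
  }
  U <- matrix(u, ncol = 3, byrow = TRUE)
  stress <- element_stresses(mesh, materials, U)
  vm <- element_von_mises(stress)
  eq <- vapply(1:3, function(a) {
    sum(f[seq(a, n3, by = 3)]) + sum(reactions$force_N[reactions$axis == c("x", "y", "z")[a]])
  }, double(1))
  structure(list(displacement = U, stress = stress, von_mises = vm,
                 reactions = reactions, applied = f,
                 equilibrium = setNames(eq, c("x", "y", "z")),
                 lambda = lambda, mesh_n_elements = nrow(mesh$elements)),
            class = "solution_field")
}

#' @export
print.solution_field <- function(x, ...) {
  s <- stress_summary(x)
  cat(sprintf("<solution_field> %d elements; von Mises min/mean/max = %.4g/%.4g/%.4g MPa; max |equilibrium residual| = %.3g N\n",
              x$mesh_n_elements, s$min, s$mean, s$max, max(abs(x$equilibrium))))
  invisible(x)
}

# per-element stress tensors (m x 6: xx, yy, zz, xy, yz, zx) from nodal displacements
element_stresses <- function(mesh, materials, U) {
  eg <- element_gradients(mesh)
  lp <- lame_parameters(mesh, materials)
  G <- eg$G
  e <- mesh$elements
  comp <- function(a, b) { # strain e_ab = 0.5 sum_i (G_ia u_ib + G_ib u_ia)
    s <- 0
    for (i in 1:4) s <- s + G[, i, a] * U[e[, i], b] + G[, i, b] * U[e[, i], a]
    s / 2
  }
  exx <- comp(1, 1); eyy <- comp(2, 2); ezz <- comp(3, 3)
  exy <- comp(1, 2); eyz <- comp(2, 3); ezx <- comp(3, 1)
  tr <- exx + eyy + ezz
  cbind(xx = lp$lambda * tr + 2 * lp$mu * exx,
        yy = lp$lambda * tr + 2 * lp$mu * eyy,
        zz = lp$lambda * tr + 2 * lp$mu * ezz,
        xy = 2 * lp$mu * exy,
        yz = 2 * lp$mu * eyz,
        zx = 2 * lp$mu * ezx)
}

#' von Mises stress from stress-tensor components
#'
#' The scalar distortional-stress invariant combining the principal
#' stresses; zero for hydrostatic states.
#'
#' @param stress Numeric vector of 6 components `(xx, yy, zz, xy, yz, zx)`
#'   or an m x 6 matrix (MPa).
#' @return von Mises stress(es), MPa.
#' @examples
#' element_von_mises(c(100, 0, 0, 0, 0, 0)) # 100
#' @export
element_von_mises <- function(stress) {
  s <- if (is.null(dim(stress))) matrix(stress, nrow = 1) else as.matrix(stress)
  if (ncol(s) != 6) stop_input("stress needs 6 components (xx, yy, zz, xy, yz, zx)")
  out <- sqrt(0.5 * ((s[, 1] - s[, 2])^2 + (s[, 2] - s[, 3])^2 + (s[, 3] - s[, 1])^2) +
                3 * (s[, 4]^2 + s[, 5]^2 + s[, 6]^2))
  if (is.null(dim(stress))) out[[1]] else out
}

#' Minimum, mean and maximum element von Mises stress
#'
#' Mean is unweighted over elements by default (matching element-stress
#' table conventions); set `volume_weighted = TRUE` (and supply `mesh`) for
#' a volume-weighted mean.
#'
#' @param field A `solution_field` from [solve_static()].
#' @param mesh The mesh (only needed when `volume_weighted = TRUE`).
#' @param volume_weighted Use element volumes as mean weights.
#' @return One-row tibble with `min`, `mean`, `max` (MPa).
#' @export
stress_summary <- function(field, mesh = NULL, volume_weighted = FALSE) {
  vm <- field$von_mises
  if (base::length(vm) == 0) stop_input("empty solution field")
  mn <- if (volume_weighted) {
    if (is.null(mesh)) stop_input("`mesh` required for a volume-weighted mean")
    v <- element_volumes(mesh)
    sum(vm * v) / sum(v)
  } else mean(vm)
  tibble(min = min(vm), mean = mn, max = max(vm))
}

#' Bite force by reaction extraction at fully fixed tooth nodes
#'
#' Re-solves the model with the given bite nodes fully constrained and reads
#' out the reaction component along the biting axis at each, mirroring the
#' single-node constraint protocol used to extract bite forces from cranial
#' models. The reported bite force is the summed reaction magnitude over the
#' bite nodes.
#'
#' @param mesh,materials,loadcase As in [solve_static()]; `loadcase` must
#'   carry `bite_constraints` (node ids); constraints tagged `"teeth"` are
#'   dropped for the bite run (tooth distributed couplings are replaced by
#'   the point constraints).
#' @param axis Biting axis, default `"y"`.
#' @return List with `per_node` tibble (node, reaction), `total_N` (summed
#'   reaction magnitude) and the `solution` field.
#' @export
bite_force <- function(mesh, materials, loadcase, axis = "y") {
  if (base::length(loadcase$bite_constraints) == 0) stop_input("loadcase has no bite_constraints")
  keep <- vapply(loadcase$constraints, function(cn) !identical(cn$tag, "teeth"), logical(1))
  lc <- loadcase
  lc$constraints <- loadcase$constraints[keep]
  sol <- solve_static(mesh, materials, lc)
  r <- sol$reactions
  per <- r[r$source == "bite" & r$axis == axis & r$node %in% loadcase$bite_constraints, ]
  per <- dplyr::arrange(per[, c("node", "force_N")], .data$node)
  list(per_node = as_tibble(per), total_N = abs(sum(per$force_N)), solution = sol)
}
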
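#' Generate a structured box mesh of tetrahedra
#'
#' Builds an axis-aligned box of `cells` hexahedral cells per axis, each
#' split into six tetrahedra along the cell's main diagonal (Kuhn
#' subdivision, chosen over the 5-tet split for orientation uniformity
#' across neighbouring cells). Node numbering is deterministic
#' (x-fastest, then y, then z), so the same parameters always yield a
#' byte-identical mesh file via [write_inp()].
#'
#' Material regions may be layered along z: `regions` is a named numeric
#' vector of increasing upper z-fractions (e.g. `c(bone = 0.8, dentine =
#' 0.95, enamel = 1)`), assigned by element centroid.
#'
#' @param dims Box edge lengths `c(lx, ly, lz)`, mm.
#' @param cells Integer cell counts `c(nx, ny, nz)`, all >= 1.
#' @param node_sets Named list of node-set recipes; each recipe is either an
#'   integer id vector or a list with elements `face` and/or `within` as in
#'   [select_nodes()]. A recipe selecting no nodes is an error.
#' @param regions Named numeric vector of cumulative z-fraction breaks
#'   (default single region `bone`).
#' @param origin Coordinates of the box corner, mm.
#' @param mirror_x Mirror the cell subdivision about the box's x midplane
#'   (requires an even x cell count), making the tetrahedralisation exactly
#'   symmetric left/right — used by the skull proxy so paired bite points
#'   see identical stiffness. The Kuhn pattern keeps y-z face diagonals
#'   unchanged under the reflection, so the two halves conform at the
#'   midplane.
#' @return A [tet_mesh()].
#' @examples
#' m <- make_box_mesh(c(10, 10, 100), c(2, 2, 10))
#' nrow(m$elements) # 240
#' @export
make_box_mesh <- function(dims, cells, node_sets = list(),
                          regions = c(bone = 1), origin = c(0, 0, 0),
                          mirror_x = FALSE) {
  stopifnot(base::length(dims) == 3, base::length(cells) == 3)
  cells <- as.integer(cells)
  if (any(cells < 1)) stop_input("`cells` must be >= 1 per axis")
  nx <- cells[1]; ny <- cells[2]; nz <- cells[3]
  xs <- origin[1] + dims[1] * (0:nx) / nx
  ys <- origin[2] + dims[2] * (0:ny) / ny
  zs <- origin[3] + dims[3] * (0:nz) / nz
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs, KEEP.OUT.ATTRS = FALSE))
  nid <- function(i, j, k) 1L + i + (nx + 1L) * (j + (ny + 1L) * k)
  # Kuhn subdivision: 6 tets per cell, one per permutation of the axis path
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  cell_idx <- expand.grid(i = 0:(nx - 1), j = 0:(ny - 1), k = 0:(nz - 1))
  ei <- cell_idx$i; ej <- cell_idx$j; ek <- cell_idx$k
  if (mirror_x && nx %% 2 != 0) stop_input("`mirror_x` requires an even x cell count")
  # mirrored cells walk the Kuhn path from the cell's x-max corner inward
  mir <- if (mirror_x) ei >= nx / 2 else rep(FALSE, base::length(ei))
  x0 <- ei + as.integer(mir)          # grid x of the path origin corner
  sx <- ifelse(mir, -1L, 1L)          # x direction of the path
  elem_list <- vector("list", 6)
  for (p in seq_along(perms)) {
    pr <- perms[[p]]
    step <- function(d) { # offset after applying axes pr[seq_len(d)]
      di <- as.integer(1 %in% pr[seq_len(d)])
      dj <- as.integer(2 %in% pr[seq_len(d)])
      dk <- as.integer(3 %in% pr[seq_len(d)])
      nid(x0 + sx * di, ej + dj, ek + dk)
    }
    elem_list[[p]] <- cbind(nid(x0, ej, ek), step(1), step(2), step(3))
  }
  # interleave so the 6 tets of each cell are consecutive
  m <- nrow(cell_idx)
  elements <- matrix(0L, nrow = 6 * m, ncol = 4)
  for (p in 1:6) elements[seq(p, by = 6, length.out = m), ] <- elem_list[[p]]
  # regions by element-centroid z fraction
  if (is.null(names(regions)) || any(names(regions) == "")) {
    stop_input("`regions` must be a named vector of z-fraction breaks")
  }
  cz <- (nodes[elements[, 1], 3] + nodes[elements[, 2], 3] +
           nodes[elements[, 3], 3] + nodes[elements[, 4], 3]) / 4
  frac <- (cz - origin[3]) / dims[3]
  reg <- names(regions)[findInterval(frac, c(0, regions), rightmost.closed = TRUE)]
  mesh <- tet_mesh(nodes, elements, regions = reg)
  if (base::length(node_sets) > 0) {
    resolved <- lapply(names(node_sets), function(nm) {
      r <- node_sets[[nm]]
      ids <- if (is.numeric(r)) as.integer(r)
      else select_nodes(mesh, face = r$face %||% NULL, within = r$within %||% NULL)
      if (base::length(ids) == 0) stop_input("node-set recipe `%s` selects no nodes", nm)
      ids
    })
    names(resolved) <- names(node_sets)
    mesh$node_sets <- resolved
  }
  mesh
}

#' Generate a box skull-proxy model with biting node sets and loads
#'
#' A geometric stand-in for a meshed skull: a box whose long axis (z) runs
#' snout to quadrate, with y the biting axis. Node sets mark anterior and
#' posterior bite points (paired left/right), left/right quadrate patches on
#' the posterior face and left/right temporal muscle origination patches on
#' the lateral walls. The returned load case applies the given total muscle
#' force, split between the two patches, directed towards a ventral
#' "mandible" insertion point; quadrates carry xyz distributed-coupling
#' constraints and tooth sets y-axis distributed-coupling constraints
#' (tagged `"teeth"` so bite-force runs can swap them for single fixed
#' nodes).
#'
#' This proxy is synthetic: it reproduces the loading/constraint topology of
#' a cranial biting model, not skull geometry.
#'
#' @param dims Box dimensions `c(width_x, height_y, length_z)`, mm.
#' @param cells Cell counts per axis.
#' @param total_muscle_force_N Summed muscle force over both sides, N.
#' @param materials Named list of [material()] per region (default bone).
#' @return List with elements `mesh`, `materials`, `loadcase`,
#'   `bite_anterior`, `bite_posterior` (node id pairs), and `insertion_point`.
#' @export
skull_proxy_model <- function(dims = c(40, 20, 100), cells = c(4, 2, 10),
                              total_muscle_force_N = 1000,
                              materials = list(bone = cranial_materials()$bone)) {
  lx <- dims[1]; ly <- dims[2]; lz <- dims[3]
  snap <- function(frac, n, len) len * round(frac * n) / n # nearest grid plane
  z_post <- snap(0.3, cells[3], lz)
  z_musc <- c(snap(0.6, cells[3], lz), snap(0.9, cells[3], lz))
  y_half <- snap(0.5, cells[2], ly)
  mesh <- make_box_mesh(dims, cells, mirror_x = TRUE, node_sets = list(
    teeth_anterior = list(within = c(0, lx, 0, 0, 0, 0)),
    teeth_posterior = list(within = c(0, lx, 0, 0, z_post, z_post)),
    quadrate_L = list(within = c(0, 0, 0, y_half, lz, lz)),
    quadrate_R = list(within = c(lx, lx, 0, y_half, lz, lz)),
    muscle_L = list(within = c(0, 0, y_half, ly, z_musc[1], z_musc[2])),
    muscle_R = list(within = c(lx, lx, y_half, ly, z_musc[1], z_musc[2]))
  ))
  # anterior/posterior bite points: the two lateral-most nodes of each tooth set
  pick_pair <- function(ids) {
    x <- mesh$nodes[ids, 1]
    c(ids[which.min(x)], ids[which.max(x)])
  }
  bite_anterior <- pick_pair(mesh$node_sets$teeth_anterior)
  bite_posterior <- pick_pair(mesh$node_sets$teeth_posterior)
  insertion_point <- c(lx / 2, -1.5 * ly, 0.75 * lz)
  lc <- load_case(
    muscle_loads = list(
      list(origination_set = "muscle_L", insertion_point = insertion_point,
           total_force = total_muscle_force_N / 2),
      list(origination_set = "muscle_R", insertion_point = insertion_point,
           total_force = total_muscle_force_N / 2)
    ),
    constraints = list(
      list(node_set = "quadrate_L", axes = c("x", "y", "z"), mode = "distributed_coupling"),
      list(node_set = "quadrate_R", axes = c("x", "y", "z"), mode = "distributed_coupling"),
      list(node_set = "teeth_anterior", axes = "y", mode = "distributed_coupling", tag = "teeth"),
      list(node_set = "teeth_posterior", axes = "y", mode = "distributed_coupling", tag = "teeth")
    )
  )
  list(mesh = mesh, materials = materials, loadcase = lc,
       bite_anterior = bite_anterior, bite_posterior = bite_posterior,
       insertion_point = insertion_point)
}
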
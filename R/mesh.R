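#' Construct a tetrahedral volume mesh
#'
#' A `tet_mesh` holds node coordinates (mm), 4-node tetrahedral connectivity,
#' a material-region label per element and named node sets. Elements must
#' have positive signed volume under the stored node ordering; elements read
#' or built with negative volume are re-oriented (last two nodes swapped),
#' and zero-volume or degenerate elements are rejected.
#'
#' @param nodes Numeric matrix, n x 3, node coordinates in mm. Row i is node
#'   id i; optional rownames give external ids.
#' @param elements Integer matrix, m x 4, rows of node ids.
#' @param regions Character vector of length m (material-region name per
#'   element), or a single name recycled. Default `"bone"`.
#' @param node_sets Named list of integer node-id vectors.
#' @return An object of class `tet_mesh`.
#' @export
tet_mesh <- function(nodes, elements, regions = "bone", node_sets = list()) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  if (ncol(nodes) != 3) stop_input("`nodes` must be an n x 3 matrix")
  elements <- as.matrix(elements)
  storage.mode(elements) <- "integer"
  if (ncol(elements) != 4) stop_input("`elements` must be an m x 4 matrix")
  n <- nrow(nodes)
  if (any(elements < 1L) || any(elements > n)) {
    bad <- which(apply(elements, 1, function(e) any(e < 1L | e > n)))[1]
    stop_input("element %d references a missing node", bad)
  }
  rep_nodes <- apply(elements, 1, function(e) anyDuplicated(e) > 0)
  if (any(rep_nodes)) {
    stop_input("element(s) with repeated node ids: %s",
               paste(which(rep_nodes), collapse = ", "))
  }
  if (base::length(regions) == 1) regions <- rep(regions, nrow(elements))
  if (base::length(regions) != nrow(elements)) stop_input("`regions` must have one entry per element")
  if (base::length(node_sets) > 0) {
    if (is.null(names(node_sets)) || any(names(node_sets) == "")) {
      stop_input("`node_sets` must be a named list")
    }
    ok <- vapply(node_sets, function(s) all(s >= 1L & s <= n), logical(1))
    if (!all(ok)) stop_input("node set(s) reference missing nodes: %s",
                             paste(names(node_sets)[!ok], collapse = ", "))
    node_sets <- lapply(node_sets, function(s) sort(unique(as.integer(s))))
  }
  mesh <- structure(
    list(nodes = nodes, elements = elements, regions = as.character(regions),
         node_sets = node_sets),
    class = "tet_mesh"
  )
  v <- element_volumes(mesh)
  neg <- which(v < 0)
  if (base::length(neg) > 0) {
    mesh$elements[neg, c(3, 4)] <- mesh$elements[neg, c(4, 3)]
    v[neg] <- -v[neg]
  }
  href <- max(apply(nodes, 2, function(x) diff(range(x))), 1)
  degen <- which(v <= 1e-12 * href^3)
  if (base::length(degen) > 0) {
    stop_input("zero-volume element(s): %s", paste(head(degen, 5), collapse = ", "))
  }
  mesh
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("<tet_mesh> %d nodes, %d C3D4 elements, regions: %s\n",
              nrow(x$nodes), nrow(x$elements),
              paste(unique(x$regions), collapse = ", ")))
  if (base::length(x$node_sets) > 0) {
    cat("node sets:", paste(sprintf("%s(%d)", names(x$node_sets),
                                    lengths(x$node_sets)), collapse = ", "), "\n")
  }
  invisible(x)
}

# signed volume of every tetrahedron (mm^3), vectorised
element_volumes <- function(mesh) {
  X <- mesh$nodes
  e <- mesh$elements
  a <- X[e[, 2], , drop = FALSE] - X[e[, 1], , drop = FALSE]
  b <- X[e[, 3], , drop = FALSE] - X[e[, 1], , drop = FALSE]
  cc <- X[e[, 4], , drop = FALSE] - X[e[, 1], , drop = FALSE]
  bxc <- cbind(b[, 2] * cc[, 3] - b[, 3] * cc[, 2],
               b[, 3] * cc[, 1] - b[, 1] * cc[, 3],
               b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  rowSums(a * bxc) / 6
}

# all element faces as sorted node triples; returns data.frame with counts
mesh_facets <- function(mesh) {
  e <- mesh$elements
  faces <- rbind(e[, c(1, 2, 3)], e[, c(1, 2, 4)], e[, c(1, 3, 4)], e[, c(2, 3, 4)])
  faces_sorted <- t(apply(faces, 1, sort))
  key <- paste(faces_sorted[, 1], faces_sorted[, 2], faces_sorted[, 3])
  cnt <- table(key)
  first <- !duplicated(key)
  list(faces = faces_sorted[first, , drop = FALSE],
       count = as.integer(cnt[key[first]]),
       key = key[first])
}

#' Boundary facets of a tetrahedral mesh
#'
#' Facets belonging to exactly one element. Errors if any facet is shared by
#' more than two elements (non-manifold mesh).
#'
#' @param mesh A [tet_mesh()].
#' @return Integer matrix, one boundary triangle (3 node ids) per row.
#' @export
boundary_facets <- function(mesh) {
  fc <- mesh_facets(mesh)
  if (any(fc$count > 2)) {
    bad <- fc$key[fc$count > 2]
    stop_input("non-manifold boundary; facet(s) shared by >2 elements: %s",
               paste(head(bad, 5), collapse = "; "))
  }
  fc$faces[fc$count == 1, , drop = FALSE]
}

triangle_areas <- function(nodes, tris) {
  a <- nodes[tris[, 2], , drop = FALSE] - nodes[tris[, 1], , drop = FALSE]
  b <- nodes[tris[, 3], , drop = FALSE] - nodes[tris[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  sqrt(rowSums(cr^2)) / 2
}

#' Total boundary surface area of a mesh
#'
#' The analogue of "total skull surface area" for a volume mesh: the summed
#' area of all boundary triangles. Used by the structural comparison to
#' normalise total applied muscle force per unit surface area.
#'
#' @param mesh A [tet_mesh()].
#' @return Area in mm^2.
#' @export
surface_area <- function(mesh) {
  tris <- boundary_facets(mesh)
  sum(triangle_areas(mesh$nodes, tris))
}

#' Select node ids of a mesh by face and/or bounding box
#'
#' @param mesh A [tet_mesh()].
#' @param face Optional face of the mesh bounding box: one of `"xmin"`,
#'   `"xmax"`, `"ymin"`, `"ymax"`, `"zmin"`, `"zmax"`.
#' @param within Optional numeric vector `c(xmin, xmax, ymin, ymax, zmin,
#'   zmax)` restricting the selection (use `-Inf`/`Inf` freely).
#' @param tol Coordinate tolerance for the face match, mm.
#' @return Sorted integer node ids; errors if the selection is empty.
#' @export
select_nodes <- function(mesh, face = NULL, within = NULL, tol = 1e-8) {
  X <- mesh$nodes
  keep <- rep(TRUE, nrow(X))
  if (!is.null(face)) {
    ax <- match(substr(face, 1, 1), c("x", "y", "z"))
    if (is.na(ax)) stop_input("unknown face `%s`", face)
    lim <- if (grepl("min$", face)) min(X[, ax]) else max(X[, ax])
    keep <- keep & abs(X[, ax] - lim) <= tol
  }
  if (!is.null(within)) {
    stopifnot(base::length(within) == 6)
    keep <- keep &
      X[, 1] >= within[1] & X[, 1] <= within[2] &
      X[, 2] >= within[3] & X[, 2] <= within[4] &
      X[, 3] >= within[5] & X[, 3] <= within[6]
  }
  ids <- which(keep)
  if (base::length(ids) == 0) stop_input("node selection is empty")
  sort(ids)
}
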
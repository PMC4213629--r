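# Shared fixture builders (all generated in code; no data files).

# 10 x 10 x 100 mm bar, E = 1000 MPa, nu = 0 unless overridden.
bar_model <- function(cells = c(2, 2, 10), E = 1000, nu = 0,
                      regions = c(bone = 1)) {
  m <- make_box_mesh(c(10, 10, 100), cells, regions = regions)
  m$node_sets <- list(base = select_nodes(m, face = "zmin"),
                      top = select_nodes(m, face = "zmax"))
  list(mesh = m, materials = lapply(setNames(nm = names(regions)), function(r)
    material(r, E, nu)))
}

# axial tension case: base held in z (plus minimal lateral restraints), total
# force F applied along +z on the top face by tributary area
axial_case <- function(mesh, F = 100) {
  corner1 <- select_nodes(mesh, within = c(0, 0, 0, 0, 0, 0))
  corner2 <- select_nodes(mesh, within = c(10, 10, 0, 0, 0, 0))
  load_case(
    external_loads = list(list(node_set = "top", force = c(0, 0, F))),
    constraints = list(
      list(node_set = "base", axes = "z", mode = "per_node"),
      list(node_set = corner1, axes = c("x", "y"), mode = "per_node"),
      list(node_set = corner2, axes = "y", mode = "per_node")
    )
  )
}

cantilever_tip_deflection <- function(cells, P = 10, E = 1000) {
  mod <- bar_model(cells, E = E)
  lc <- load_case(
    external_loads = list(list(node_set = "top", force = c(P, 0, 0))),
    constraints = list(list(node_set = "base", axes = c("x", "y", "z"),
                            mode = "per_node"))
  )
  sol <- solve_static(mod$mesh, mod$materials, lc)
  list(deflection = mean(sol$displacement[mod$mesh$node_sets$top, 1]),
       solution = sol)
}

# model B = model A with mesh scaled by `factor` but load magnitudes unchanged
scaled_mesh_same_loads <- function(model, factor) {
  sc <- scale_model(model$mesh, model$loadcase, factor)
  out <- model
  out$mesh <- sc$mesh
  out$loadcase <- craniomech:::rescale_loads(sc$loadcase, 1 / factor^2)
  out
}

max_abs_equilibrium <- function(sol) max(abs(sol$equilibrium))

# full functionspace pass on a generated matrix: z-transform, distances, PCO
fs_fit <- function(cm, method = "scaled_euclidean") {
  pco(fs_distance(z_transform(cm), method = method), groups = cm$groups)
}

grade_of <- function(fit, cm) cm$groups$grade[match(fit$taxa, cm$groups$taxon)]
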
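#' Read materials and a load case from a YAML/JSON model config
#'
#' The config must carry `units: mm_N_MPa` (the package's fixed unit
#' system), a `materials` map of `{young_modulus, poisson_ratio}` per region
#' name, and optional `muscle_loads`, `external_loads`, `constraints` and
#' `bite_constraints` entries matching the [load_case()] fields.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return List with `materials` (named [material()] list) and `loadcase`.
#' @export
read_model_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(cfg$units, "mm_N_MPa")) {
    stop_input("model config `units` must be \"mm_N_MPa\" (got %s)", cfg$units %||% "<missing>")
  }
  materials <- lapply(names(cfg$materials), function(nm) {
    m <- cfg$materials[[nm]]
    material(nm, m$young_modulus, m$poisson_ratio)
  })
  names(materials) <- names(cfg$materials)
  as_list_of_lists <- function(x) {
    if (is.null(x)) return(list())
    if (is.data.frame(x)) x <- split(x, seq_len(nrow(x)))
    lapply(x, function(e) lapply(as.list(e), function(v) if (is.list(v)) unlist(v) else v))
  }
  lc <- load_case(
    muscle_loads = as_list_of_lists(cfg$muscle_loads),
    external_loads = as_list_of_lists(cfg$external_loads),
    constraints = as_list_of_lists(cfg$constraints),
    bite_constraints = unlist(cfg$bite_constraints) %||% integer(0)
  )
  list(materials = materials, loadcase = lc)
}

#' Write a solved field's element and node results as CSV
#'
#' Writes `<stem>_von_mises.csv` (per-element) and
#' `<stem>_displacement.csv` (per-node), plus a JSON summary
#' (`<stem>_summary.json`) with the stress extrema and equilibrium
#' residuals.
#'
#' @param field A `solution_field`.
#' @param stem Output path stem.
#' @return The written paths, invisibly.
#' @export
write_solution <- function(field, stem) {
  f1 <- paste0(stem, "_von_mises.csv")
  write.csv(data.frame(element = seq_along(field$von_mises),
                       von_mises_MPa = signif(field$von_mises, 6)),
            f1, row.names = FALSE)
  f2 <- paste0(stem, "_displacement.csv")
  write.csv(data.frame(node = seq_len(nrow(field$displacement)),
                       ux = signif(field$displacement[, 1], 6),
                       uy = signif(field$displacement[, 2], 6),
                       uz = signif(field$displacement[, 3], 6)),
            f2, row.names = FALSE)
  s <- stress_summary(field)
  f3 <- paste0(stem, "_summary.json")
  jsonlite::write_json(list(min_vm_MPa = signif(s$min, 6), mean_vm_MPa = signif(s$mean, 6),
                            max_vm_MPa = signif(s$max, 6),
                            equilibrium_residual_N = signif(unclass(field$equilibrium), 6)),
                       f3, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(f1, f2, f3))
}
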
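#' Rescale a total muscle force to equalise force per unit surface area
#'
#' The structural comparison standardises two models so that the ratio of
#' total applied muscle force to skull surface area is equal, removing the
#' effect of size from the stress comparison. Per-muscle forces are rescaled
#' proportionally.
#'
#' @param total_force_ref Reference model's total applied muscle force, N.
#' @param sa_ref Reference model's surface area, mm^2.
#' @param sa_target Target model's surface area, mm^2.
#' @return Target total force, N: `total_force_ref * sa_target / sa_ref`.
#' @examples
#' scale_structural(1000, 4200, 8400) # 2000
#' @export
scale_structural <- function(total_force_ref, sa_ref, sa_target) {
  assert_scalar_pos(total_force_ref, "total_force_ref")
  assert_scalar_pos(sa_ref, "sa_ref")
  assert_scalar_pos(sa_target, "sa_target")
  total_force_ref * sa_target / sa_ref
}

#' Isometrically scale a model (mesh plus load case)
#'
#' Scales all coordinates by `factor` (e.g. 1.8 for a juvenile skull scaled
#' to adult proportions). Under isometry muscle volumes scale by factor^3
#' and lengths by factor, so PCSA — and with it every muscle and external
#' force — scales by factor^2; that contract is applied to the load case.
#'
#' @param mesh A [tet_mesh()].
#' @param loadcase A [load_case()].
#' @param factor Linear scale factor (> 0).
#' @return List with scaled `mesh` and `loadcase`.
#' @export
scale_model <- function(mesh, loadcase, factor) {
  assert_scalar_pos(factor, "factor")
  mesh$nodes <- mesh$nodes * factor
  lc <- loadcase
  lc$muscle_loads <- lapply(loadcase$muscle_loads, function(ml) {
    ml$insertion_point <- ml$insertion_point * factor
    ml$total_force <- ml$total_force * factor^2
    ml
  })
  lc$external_loads <- lapply(loadcase$external_loads, function(el) {
    el$force <- el$force * factor^2
    el
  })
  list(mesh = mesh, loadcase = lc)
}

total_muscle_force <- function(loadcase) {
  sum(vapply(loadcase$muscle_loads, function(ml) ml$total_force, double(1)))
}

rescale_loads <- function(loadcase, ratio) {
  loadcase$muscle_loads <- lapply(loadcase$muscle_loads, function(ml) {
    ml$total_force <- ml$total_force * ratio; ml
  })
  loadcase$external_loads <- lapply(loadcase$external_loads, function(el) {
    el$force <- el$force * ratio; el
  })
  loadcase
}

#' Paired biting comparison of two cranial models
#'
#' Runs both models under one of two standardisation protocols and reports
#' element-stress summaries, bite forces, surface areas and total applied
#' muscle forces.
#'
#' * `ecological`: each model is solved as given (natural size and muscle
#'   loads) — the comparison of the animals as ecological competitors.
#' * `structural`: model B's loads are first rescaled so total applied
#'   muscle force per unit skull surface area matches model A
#'   ([scale_structural()]) — a size-free comparison of skull shape.
#'
#' A model is a list with `mesh`, `materials`, `loadcase`, and (optionally)
#' `bite_anterior` / `bite_posterior` node-id pairs for bite-force
#' extraction, e.g. from [skull_proxy_model()].
#'
#' @param model_a,model_b Model lists (see Details).
#' @param mode `"ecological"` or `"structural"`.
#' @param ids Character vector of two model labels for the report.
#' @return A `craniomech_comparison`: tibble with one row per model —
#'   min/mean/max element von Mises stress (MPa), anterior and posterior
#'   bite force (N), surface area (mm^2), total applied muscle force (N) —
#'   with the mode stored as an attribute.
#' @export
run_comparison <- function(model_a, model_b, mode = c("ecological", "structural"),
                           ids = c("A", "B")) {
  mode <- match.arg(mode)
  if (mode == "structural") {
    sa_a <- surface_area(model_a$mesh)
    sa_b <- surface_area(model_b$mesh)
    target_total <- scale_structural(total_muscle_force(model_a$loadcase), sa_a, sa_b)
    cur <- total_muscle_force(model_b$loadcase)
    if (cur <= 0) stop_input("model B has no muscle load to rescale")
    model_b$loadcase <- rescale_loads(model_b$loadcase, target_total / cur)
  }
  one <- function(model, id) {
    sol <- tryCatch(solve_static(model$mesh, model$materials, model$loadcase),
                    error = function(e) stop_input("model %s: %s", id, conditionMessage(e)))
    s <- stress_summary(sol)
    bite <- function(nodes) {
      if (is.null(nodes)) return(NA_real_)
      lc <- model$loadcase
      lc$bite_constraints <- nodes
      bite_force(model$mesh, model$materials, lc)$total_N
    }
    ant <- bite(model$bite_anterior)
    post <- bite(model$bite_posterior)
    sa <- surface_area(model$mesh)
    tot <- total_muscle_force(model$loadcase)
    tibble(model = id,
           min_vm_MPa = s$min, mean_vm_MPa = s$mean, max_vm_MPa = s$max,
           anterior_bite_N = ant,
           posterior_bite_N = post,
           surface_area_mm2 = sa,
           total_muscle_force_N = tot)
  }
  out <- dplyr::bind_rows(one(model_a, ids[1]), one(model_b, ids[2]))
  if (mode == "structural") {
    ratio <- out$total_muscle_force_N / out$surface_area_mm2
    stopifnot(abs(diff(ratio)) <= 1e-9 * max(abs(ratio)))
  }
  structure(out, mode = mode, class = c("craniomech_comparison", class(out)))
}
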
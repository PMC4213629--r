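#' Physiological cross-sectional area from muscle volume and length
#'
#' PCSA is estimated by the dry-skull method as reconstructed muscle volume
#' divided by total muscle length. Total length (straight-line origin to
#' insertion) approximates fibre length; pennation is deliberately not
#' modelled.
#'
#' @param volume Muscle volume(s), mm^3.
#' @param length Total muscle length(s), mm.
#' @param muscle Optional muscle name(s), used in error messages.
#' @return PCSA in mm^2 (`volume / length`), vectorised.
#' @examples
#' compute_pcsa(100000, 200) # 500 mm^2
#' @export
compute_pcsa <- function(volume, length, muscle = NULL) {
  ctx <- muscle %||% rep("muscle", base::length(volume))
  assert_scalar_pos(volume, "volume", ctx)
  assert_scalar_pos(length, "length", ctx)
  volume / length
}

#' Muscle contractile force from PCSA and specific tension
#'
#' Force is specific tension times PCSA. Specific tension is given in kPa
#' (default 392 kPa, a value reported for vertebrate skeletal muscle) and
#' converted internally to N/mm^2, so a PCSA in mm^2 yields force in N.
#'
#' @param pcsa Physiological cross-sectional area(s), mm^2 (>= 0).
#' @param tension_kpa Specific tension, kPa (> 0). Default 392.
#' @return Force(s) in N.
#' @examples
#' muscle_force(500, 392) # 196 N
#' @export
muscle_force <- function(pcsa, tension_kpa = 392) {
  if (any(!is.finite(pcsa)) || any(pcsa < 0)) stop_input("`pcsa` must be non-negative and finite")
  assert_scalar_pos(tension_kpa, "tension_kpa")
  kpa_to_nmm2(tension_kpa) * pcsa
}

#' Craniocervical muscle force from occipital insertion area
#'
#' Craniocervical muscles have no reconstructed volume; their cross-sectional
#' area is taken directly from the occipital insertion area, and force follows
#' the same specific-tension contract as [muscle_force()].
#'
#' @param insertion_area Occipital insertion area(s), mm^2 (> 0).
#' @inheritParams muscle_force
#' @return Force(s) in N.
#' @export
craniocervical_force <- function(insertion_area, tension_kpa = 392) {
  if (any(is.na(insertion_area))) stop_input("missing `insertion_area`")
  assert_scalar_pos(insertion_area, "insertion_area")
  muscle_force(insertion_area, tension_kpa)
}

#' Build a muscle force table from reconstruction data
#'
#' Takes one row per muscle with either `volume_mm3` + `length_mm` (jaw
#' adductors) or `insertion_area_mm2` (craniocervical muscles) and returns the
#' per-muscle PCSA and contractile force at the given specific tension.
#' Forces are per table row: left/right pairs are kept per side unless the
#' input row is already marked `combined` — there is no silent doubling.
#'
#' @param recons Data frame with columns `muscle`, and either
#'   `volume_mm3` + `length_mm` or `insertion_area_mm2` per row (exactly one of
#'   the two mechanisms; blank/NA = absent). Optional columns `side`
#'   (`left`/`right`/`combined`) and `group` are carried through.
#' @inheritParams muscle_force
#' @return A tibble with columns `muscle`, `group`, `side`, `pcsa_mm2`,
#'   `force_N`, `tension_kpa`.
#' @examples
#' recons <- tibble::tibble(muscle = "AMES", volume_mm3 = 100000, length_mm = 200)
#' muscle_force_table(recons)
#' @export
muscle_force_table <- function(recons, tension_kpa = 392) {
  recons <- as_tibble(recons)
  if (nrow(recons) == 0) {
    return(tibble(muscle = character(), group = character(), side = character(),
                  pcsa_mm2 = double(), force_N = double(), tension_kpa = double()))
  }
  if (!"muscle" %in% names(recons)) stop_input("`recons` needs a `muscle` column")
  for (col in c("volume_mm3", "length_mm", "insertion_area_mm2")) {
    if (!col %in% names(recons)) recons[[col]] <- NA_real_
  }
  has_vl <- !is.na(recons$volume_mm3) & !is.na(recons$length_mm)
  has_ia <- !is.na(recons$insertion_area_mm2)
  bad <- !(has_vl != has_ia) | (has_vl & has_ia)
  if (any(bad)) {
    stop_input("each row needs exactly one of {volume_mm3 + length_mm} or {insertion_area_mm2}; offending muscle(s): %s",
               paste(recons$muscle[bad], collapse = ", "))
  }
  pcsa <- ifelse(has_vl,
                 ifelse(has_vl, recons$volume_mm3 / recons$length_mm, NA_real_),
                 recons$insertion_area_mm2)
  # validate positivity with muscle names in the message
  assert_scalar_pos(ifelse(has_vl, recons$volume_mm3, recons$insertion_area_mm2),
                    "volume/insertion area", recons$muscle)
  if (any(has_vl)) assert_scalar_pos(recons$length_mm[has_vl], "length", recons$muscle[has_vl])
  tibble(
    muscle = as.character(recons$muscle),
    group = if ("group" %in% names(recons)) as.character(recons$group) else NA_character_,
    side = if ("side" %in% names(recons)) as.character(recons$side) else "combined",
    pcsa_mm2 = pcsa,
    force_N = muscle_force(pcsa, tension_kpa),
    tension_kpa = tension_kpa
  )
}

#' Fraction of total muscle force contributed by a group of muscles
#'
#' Used, e.g., to compare the external adductor contribution (m. adductor
#' mandibulae externus parts) between taxa.
#'
#' @param table Data frame with columns `muscle` and `force_N` (e.g. from
#'   [muscle_force_table()]).
#' @param members Character vector of muscle names forming the group; all must
#'   be present in `table`.
#' @return Scalar fraction in `[0, 1]`: group force over total table force.
#' @export
group_fraction <- function(table, members) {
  table <- as_tibble(table)
  if (nrow(table) == 0) stop_input("empty muscle force table")
  missing_m <- setdiff(members, table$muscle)
  if (base::length(missing_m) > 0) {
    stop_input("group member(s) not in table: %s", paste(missing_m, collapse = ", "))
  }
  sum(table$force_N[table$muscle %in% members]) / sum(table$force_N)
}

#' Sensitivity sweep over specific tension
#'
#' Recomputes a muscle force table at each supplied specific tension. Forces
#' are exactly linear in tension, so the sweep quantifies how conclusions
#' depend on the assumed specific-tension value.
#'
#' @inheritParams muscle_force_table
#' @param tensions_kpa Numeric vector of specific tensions (kPa), all > 0.
#' @return A tibble: one [muscle_force_table()] per tension, row-bound, with
#'   the `tension_kpa` column distinguishing sweeps.
#' @export
tension_sweep <- function(recons, tensions_kpa = c(147, 250, 392)) {
  if (base::length(tensions_kpa) == 0) stop_input("`tensions_kpa` must be non-empty")
  assert_scalar_pos(tensions_kpa, "tensions_kpa")
  purrr::map_dfr(tensions_kpa, function(t) muscle_force_table(recons, tension_kpa = t))
}

#' Read a muscle reconstruction CSV
#'
#' Expected columns: `muscle, side, volume_mm3, length_mm, insertion_area_mm2,
#' origination_set, insertion_x, insertion_y, insertion_z`; blank cells mean
#' absent.
#'
#' @param path Path to a CSV file.
#' @return A tibble of reconstruction rows.
#' @export
read_muscle_recon <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  as_tibble(df)
}

#' Write a muscle force table as CSV
#'
#' @param table Result of [muscle_force_table()] or [tension_sweep()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_muscle_forces <- function(table, path) {
  out <- as.data.frame(table)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) signif(x, 6))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Jaw muscle group vocabulary
#'
#' Named list mapping functional muscle groups to member muscle names:
#' `temporal` and `palatal` jaw adductors, the `external_adductor` subset
#' (m. adductor mandibulae externus divisions), and the craniocervical
#' `dorsiflexor`, `lateroflexor` and `ventriflexor` groups.
#'
#' @return Named list of character vectors.
#' @export
muscle_groups <- function() {
  list(
    temporal = c("AMES", "AMEP", "AMEM", "PSTs"),
    palatal = c("AMP", "PTd", "PTv"),
    external_adductor = c("AMES", "AMEP", "AMEM"),
    dorsiflexor = c("s.c.", "t.c."),
    lateroflexor = c("c.", "l.c.s.", "i.c."),
    ventriflexor = c("l.c.p.", "r.c.v.")
  )
}
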
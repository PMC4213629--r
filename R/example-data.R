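#' Published jaw adductor muscle force estimates for two Morrison sauropods
#'
#' Maximum contractile force estimates (N) for the seven jaw adductor muscles
#' of adult *Camarasaurus* and *Diplodocus*, from published dry-skull-method
#' reconstructions at 392 kPa specific tension. Muscles: AMES, AMEP, AMEM
#' (m. adductor mandibulae externus superficialis/profundus/medialis), PSTs
#' (m. pseudotemporalis superficialis) form the temporal group; AMP
#' (m. adductor mandibulae profundus), PTd, PTv (m. pterygoideus
#' dorsalis/ventralis) the palatal group.
#'
#' @param taxon `"Camarasaurus"` or `"Diplodocus"`.
#' @return A tibble with columns `taxon`, `muscle`, `group`, `force_N`.
#' @examples
#' grp <- muscle_groups()
#' group_fraction(sauropod_adductor_forces("Camarasaurus"), grp$external_adductor)
#' @export
sauropod_adductor_forces <- function(taxon = c("Camarasaurus", "Diplodocus")) {
  taxon <- match.arg(taxon)
  muscles <- c("AMES", "AMEP", "AMEM", "PSTs", "AMP", "PTd", "PTv")
  groups <- c(rep("temporal", 4), rep("palatal", 3))
  force <- switch(taxon,
    Camarasaurus = c(592, 227.4, 312.49, 154.8, 493.9, 611.5, 584.1),
    Diplodocus = c(175.22, 40.77, 95.65, 103.1, 146.6, 407.7, 355.9)
  )
  tibble(taxon = taxon, muscle = muscles, group = groups, force_N = force)
}

#' Published craniocervical muscle force estimates for two Morrison sauropods
#'
#' Maximum contractile force estimates (N) for the seven craniocervical
#' muscles (forces from occipital insertion areas at 392 kPa): dorsiflexors
#' s.c. (m. splenius capitis), t.c. (m. transversospinalis capitis);
#' lateroflexors c. (m. complexus), l.c.s. (m. longissimus capitis
#' superficialis), i.c. (m. iliocostalis capitis); ventriflexors l.c.p.
#' (m. longissimus capitis profundus), r.c.v. (m. rectus capitis ventralis).
#'
#' @inheritParams sauropod_adductor_forces
#' @return A tibble with columns `taxon`, `muscle`, `group`, `force_N`.
#' @export
sauropod_craniocervical_forces <- function(taxon = c("Camarasaurus", "Diplodocus")) {
  taxon <- match.arg(taxon)
  muscles <- c("s.c.", "t.c.", "c.", "l.c.s.", "i.c.", "l.c.p.", "r.c.v.")
  groups <- c("dorsiflexor", "dorsiflexor", "lateroflexor", "lateroflexor",
              "lateroflexor", "ventriflexor", "ventriflexor")
  force <- switch(taxon,
    Camarasaurus = c(415.5, 403.76, 134.5, 344.2, 302.2, 154.8, 143.5),
    Diplodocus = c(218.0, 254.0, 200.3, 163.1, 255.2, 94.86, 104.3)
  )
  tibble(taxon = taxon, muscle = muscles, group = groups, force_N = force)
}

#' Reference cranial tissue material properties
#'
#' Isotropic linear-elastic properties commonly used for vertebrate cranial
#' FE models, in the package unit system (MPa): enamel E = 80 GPa, nu = 0.30;
#' dentine E = 21 GPa, nu = 0.31; (bovine Haversian) bone E = 23.1 GPa,
#' nu = 0.29.
#'
#' @return Named list of [material()] objects (`enamel`, `dentine`, `bone`).
#' @export
cranial_materials <- function() {
  list(
    enamel = material("enamel", young_modulus = 80000, poisson_ratio = 0.30),
    dentine = material("dentine", young_modulus = 21000, poisson_ratio = 0.31),
    bone = material("bone", young_modulus = 23100, poisson_ratio = 0.29)
  )
}
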
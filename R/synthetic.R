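#' Simulate a two-grade craniodental character matrix
#'
#' Emulates the structure of an empirical craniodental functional-character
#' matrix: two functional grades ("broad" vs "narrow"), continuous
#' characters drawn from group-offset Gaussians (means +delta/2 and
#' -delta/2), binary characters drawn with group-dependent probabilities,
#' and a fixed number of cells — `round(missing_fraction * n_cells)`, so the
#' realised completeness is deterministic — masked missing completely at
#' random (set `biased_columns = TRUE` to concentrate missingness in a
#' random half of the characters instead, mimicking poorly preserved taxa).
#'
#' Defaults mirror the study conditions this generator stands in for:
#' 35 taxa, 20 characters (17 continuous + 3 binary), missing fraction
#' 0.247, within-group sd 1 and a grade offset of 2.5 sd.
#'
#' @param n_taxa Number of taxa (>= 4).
#' @param n_continuous,n_binary Character counts.
#' @param delta Between-grade offset of continuous characters, in
#'   within-group sd units (>= 0).
#' @param sd Within-group standard deviation (> 0).
#' @param p_binary Length-2 probabilities of state 1 for the two grades.
#' @param missing_fraction Fraction of cells masked missing, in [0, 1).
#' @param seed Mandatory RNG seed.
#' @param biased_columns Concentrate missingness in half the characters.
#' @return A [character_matrix()] with a `grade` group column.
#' @export
make_two_grade_matrix <- function(n_taxa = 35, n_continuous = 17, n_binary = 3,
                                  delta = 2.5, sd = 1, p_binary = c(0.2, 0.8),
                                  missing_fraction = 0.247, seed,
                                  biased_columns = FALSE) {
  if (missing(seed)) stop_input("`seed` is required")
  if (n_taxa < 4) stop_input("`n_taxa` must be >= 4")
  if (delta < 0 || sd <= 0) stop_input("`delta` must be >= 0 and `sd` > 0")
  if (missing_fraction < 0 || missing_fraction >= 1) stop_input("`missing_fraction` must be in [0, 1)")
  set.seed(seed)
  n_broad <- ceiling(n_taxa / 2)
  grade <- c(rep("broad", n_broad), rep("narrow", n_taxa - n_broad))
  sign_g <- ifelse(grade == "broad", 1, -1)
  p <- n_continuous + n_binary
  vals <- matrix(NA_real_, n_taxa, p)
  for (j in seq_len(n_continuous)) {
    vals[, j] <- rnorm(n_taxa, mean = sign_g * delta / 2, sd = sd)
  }
  for (j in seq_len(n_binary)) {
    pr <- ifelse(grade == "broad", p_binary[1], p_binary[2])
    vals[, n_continuous + j] <- rbinom(n_taxa, 1, pr)
  }
  rownames(vals) <- sprintf("taxon_%02d", seq_len(n_taxa))
  colnames(vals) <- c(sprintf("cont_%02d", seq_len(n_continuous)),
                      sprintf("bin_%02d", seq_len(n_binary)))
  n_mask <- round(missing_fraction * base::length(vals))
  if (n_mask > 0) {
    # redraw the mask (deterministically, from the same stream) if it would
    # leave a taxon pair with no shared characters or a character with < 2
    # scored cells — the generated matrices must always be analysable
    for (try in 1:100) {
      cells <- if (biased_columns) {
        cols <- sample(p, ceiling(p / 2))
        pool <- as.vector(outer(seq_len(n_taxa), (cols - 1) * n_taxa, "+"))
        sample(pool, min(n_mask, base::length(pool)))
      } else {
        sample(base::length(vals), n_mask)
      }
      masked <- vals
      masked[cells] <- NA_real_
      scored <- !is.na(masked)
      ok_cols <- all(colSums(scored) >= 2)
      ok_pairs <- all(tcrossprod(scored * 1) >= 1)
      if (ok_cols && ok_pairs) break
      if (try == 100) stop_input("could not draw an analysable missingness mask; lower `missing_fraction`")
    }
    vals <- masked
  }
  character_matrix(vals,
                   kind = c(rep("continuous", n_continuous), rep("binary", n_binary)),
                   groups = tibble(taxon = rownames(vals), grade = grade))
}

#' Simulate a time-scaled tree with Brownian tip values
#'
#' Draws a random bifurcating topology, assigns tip first-appearance ages
#' uniformly on `age_range`, time-scales with the minimum-branch-length
#' rule, then simulates Brownian motion along the resulting branch lengths.
#' The generating truth (root state and rate) is returned for recovery
#' tests.
#'
#' @param n_tips Number of tips (>= 3).
#' @param age_range Interval (Ma) from which tip ages are drawn.
#' @param rate Brownian rate sigma^2 (per Myr; >= 0; 0 gives constant tips).
#' @param root_state True root state.
#' @param mbl Minimum branch length for time-scaling, Myr.
#' @param seed Mandatory RNG seed.
#' @return List: `tree` (a `timed_tree`), `tip_values` (named vector),
#'   `ages`, `root_state`, `rate`.
#' @export
make_bm_tree_data <- function(n_tips = 20, age_range = c(145, 170), rate = 1,
                              root_state = 0, mbl = 1, seed) {
  if (missing(seed)) stop_input("`seed` is required")
  if (n_tips < 3) stop_input("`n_tips` must be >= 3")
  if (rate < 0) stop_input("`rate` must be >= 0")
  set.seed(seed)
  topo <- ape::rtree(n_tips, br = NULL)
  ages <- setNames(runif(n_tips, age_range[1], age_range[2]), topo$tip.label)
  tree <- time_scale(topo, ages, mode = "mbl", mbl = mbl)
  tip_values <- if (rate == 0) {
    setNames(rep(root_state, n_tips), tree$tip.label)
  } else {
    x <- phytools::fastBM(tree, a = root_state, sig2 = rate)
    x[tree$tip.label]
  }
  list(tree = tree, tip_values = tip_values, ages = ages,
       root_state = root_state, rate = rate)
}
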
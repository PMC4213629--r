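#' Read a rooted tree topology from Newick
#'
#' Parses Newick text or a file via `ape`, discards any input branch lengths
#' (node ages are recomputed from occurrence data by [time_scale()]),
#' requires unique tip labels, and flags polytomies (treated as hard).
#'
#' @param source Newick string (containing `(`) or a file path.
#' @return An `ape::phylo` topology without branch lengths.
#' @export
read_tree_topology <- function(source) {
  phy <- if (grepl("(", source, fixed = TRUE)) {
    tryCatch(ape::read.tree(text = source),
             error = function(e) stop_input("Newick parse error: %s", conditionMessage(e)))
  } else {
    tryCatch(ape::read.tree(source),
             error = function(e) stop_input("Newick parse error in %s: %s", source,
                                            conditionMessage(e)))
  }
  if (is.null(phy)) stop_input("Newick parse error: no tree found")
  if (anyDuplicated(phy$tip.label)) {
    stop_input("duplicate tip labels: %s",
               paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  }
  if (!ape::is.binary(phy) || !ape::is.rooted(phy)) {
    inform("tree contains polytomies (treated as hard); interpreted as rooted at the basal node")
  }
  phy$edge.length <- NULL
  phy
}

#' Time-scale a topology from taxon first-appearance ages
#'
#' Re-implements occurrence-based time-scaling of a palaeontological tree:
#' tips are dated at their first-appearance age (Ma); in `basic` mode each
#' node's age is the oldest age among its descendant tips (which can yield
#' zero-length branches, flagged); in `mbl` mode node ages are additionally
#' pushed rootward just enough that every branch is at least `mbl` Myr long,
#' leaving tip ages untouched.
#'
#' @param phy A rooted `ape::phylo` topology.
#' @param ages Named numeric vector of ages (Ma), or data frame with columns
#'   `taxon`, `age_ma`. Every tip must be dated.
#' @param mode `"basic"` or `"mbl"`.
#' @param mbl Minimum branch length, Myr (used in `mbl` mode; default 1).
#' @return A `timed_tree` (also `phylo`): branch lengths in Myr,
#'   `$node_ages` for all nodes (tips first, `ape` numbering), and
#'   `$root.time` set to the root age.
#' @export
time_scale <- function(phy, ages, mode = c("basic", "mbl"), mbl = 1) {
  mode <- match.arg(mode)
  if (is.data.frame(ages)) ages <- setNames(ages$age_ma, ages$taxon)
  missing_tips <- setdiff(phy$tip.label, names(ages))
  if (base::length(missing_tips) > 0) {
    stop_input("no age for tip(s): %s", paste(missing_tips, collapse = ", "))
  }
  ntip <- base::length(phy$tip.label)
  nnode <- phy$Nnode
  age <- numeric(ntip + nnode)
  age[seq_len(ntip)] <- ages[phy$tip.label]
  # postorder: children before parents
  po <- ape::reorder.phylo(phy, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    need <- if (mode == "mbl") age[ch] + mbl else age[ch]
    age[p] <- max(age[p], need)
  }
  phy$edge.length <- age[phy$edge[, 1]] - age[phy$edge[, 2]]
  if (mode == "basic" && any(phy$edge.length <= 1e-12)) {
    inform(sprintf("%d zero-length branch(es) under basic time-scaling; consider mode = \"mbl\"",
                   sum(phy$edge.length <= 1e-12)))
  }
  phy$node_ages <- age
  phy$root.time <- age[ntip + 1]
  class(phy) <- c("timed_tree", class(phy))
  phy
}

#' Ancestral states by branch-length-weighted squared-change parsimony
#'
#' Internal-node values minimise the sum over branches of (change along the
#' branch)^2 / branch length — the maximum-likelihood ancestral states under
#' Brownian motion. Solved exactly as a sparse linear system over the tree's
#' weighted Laplacian. Requires strictly positive branch lengths (use
#' [time_scale()] with `mode = "mbl"` upstream).
#'
#' @param tree A `phylo`/`timed_tree` with positive branch lengths.
#' @param tip_values Named numeric vector (one value per tip), or a matrix
#'   with one column per axis (rownames = tips).
#' @return A tibble with `node` (ape node number), `label` (tip label or
#'   `node<N>`), `type`, and one column per axis.
#' @export
ancestral_states <- function(tree, tip_values) {
  if (is.null(tree$edge.length)) stop_input("tree has no branch lengths; run time_scale() first")
  if (any(tree$edge.length <= 0)) {
    stop_input("non-positive branch length(s); re-run time_scale() with mode = \"mbl\"")
  }
  X <- if (is.null(dim(tip_values))) {
    matrix(tip_values, ncol = 1, dimnames = list(names(tip_values), "axis1"))
  } else as.matrix(tip_values)
  missing_tips <- setdiff(tree$tip.label, rownames(X))
  if (base::length(missing_tips) > 0) {
    stop_input("no tip value for: %s", paste(missing_tips, collapse = ", "))
  }
  X <- X[tree$tip.label, , drop = FALSE]
  ntip <- base::length(tree$tip.label)
  nn <- ntip + tree$Nnode
  w <- 1 / tree$edge.length
  # weighted graph Laplacian over all nodes
  i <- c(tree$edge[, 1], tree$edge[, 2], tree$edge[, 1], tree$edge[, 2])
  j <- c(tree$edge[, 1], tree$edge[, 2], tree$edge[, 2], tree$edge[, 1])
  x <- c(w, w, -w, -w)
  L <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(nn, nn))
  internal <- (ntip + 1):nn
  tipsq <- seq_len(ntip)
  rhs <- -L[internal, tipsq, drop = FALSE] %*% X
  states <- as.matrix(Matrix::solve(L[internal, internal, drop = FALSE], rhs))
  if (any(!is.finite(states))) stop_input("ancestral-state solve produced non-finite values")
  all_states <- rbind(X, states)
  colnames(all_states) <- colnames(X)
  out <- tibble(
    node = seq_len(nn),
    label = c(tree$tip.label, paste0("node", internal)),
    type = c(rep("tip", ntip), rep("internal", tree$Nnode))
  )
  dplyr::bind_cols(out, as_tibble(all_states))
}

#' Phylomorphospace edge segments on two ordination axes
#'
#' Reconstructs ancestral positions on two score axes and returns one
#' parent-to-child segment per branch, for drawing the phylogeny inside the
#' functionspace. Tips absent from the score matrix are dropped from the
#' tree with a warning, and tips lie exactly at their observed scores.
#'
#' @param tree A `timed_tree` (positive branch lengths).
#' @param scores Matrix of ordination scores (rownames = taxa), e.g.
#'   `pco_fit$scores`.
#' @param axes Two axes to project onto (default 1:2).
#' @return A tibble of segments: `parent`, `child`, `parent_x`, `parent_y`,
#'   `child_x`, `child_y`, `child_is_tip`.
#' @export
project_phylomorphospace <- function(tree, scores, axes = c(1, 2)) {
  stopifnot(base::length(axes) == 2)
  sc <- as.matrix(scores)
  drop <- setdiff(tree$tip.label, rownames(sc))
  if (base::length(drop) > 0) {
    warn(sprintf("dropping %d tip(s) without scores: %s", base::length(drop),
                 paste(drop, collapse = ", ")))
    tree <- ape::drop.tip(tree, drop)
  }
  ntip <- base::length(tree$tip.label)
  tipvals <- sc[tree$tip.label, axes, drop = FALSE]
  colnames(tipvals) <- c("x", "y")
  st <- ancestral_states(tree, tipvals)
  xy <- as.matrix(st[, c("x", "y")])
  lab <- st$label
  tibble(
    parent = lab[tree$edge[, 1]],
    child = lab[tree$edge[, 2]],
    parent_x = xy[tree$edge[, 1], 1], parent_y = xy[tree$edge[, 1], 2],
    child_x = xy[tree$edge[, 2], 1], child_y = xy[tree$edge[, 2], 2],
    child_is_tip = tree$edge[, 2] <= ntip
  )
}

#' Write a timed tree as Newick with branch lengths in Myr
#'
#' @param tree A `timed_tree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timed_tree <- function(tree, path) {
  cls <- class(tree)
  class(tree) <- "phylo"
  ape::write.tree(tree, file = path)
  class(tree) <- cls
  invisible(path)
}
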
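#' Construct a craniodental character matrix
#'
#' Taxa-by-characters data mixing continuous biomechanical metrics and
#' binary (0/1) tooth characters, with missing cells allowed, plus optional
#' per-taxon group labels (e.g. functional grade and clade).
#'
#' @param values Numeric matrix (taxa x characters, rownames = taxa,
#'   colnames = characters) or a data frame whose first column is the taxon
#'   name.
#' @param kind Character vector (`"continuous"`/`"binary"`) named by
#'   character, or unnamed in column order.
#' @param groups Optional data frame with a `taxon` column plus label
#'   columns (e.g. `grade`, `clade`).
#' @return A `char_matrix` object.
#' @export
character_matrix <- function(values, kind, groups = NULL) {
  if (is.data.frame(values)) {
    taxa <- as.character(values[[1]])
    values <- as.matrix(values[, -1, drop = FALSE])
    rownames(values) <- taxa
  }
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_input("`values` needs taxon rownames and character colnames")
  }
  if (is.null(names(kind))) names(kind) <- colnames(values)
  kind <- kind[colnames(values)]
  if (any(is.na(kind)) || !all(kind %in% c("continuous", "binary"))) {
    stop_input("`kind` must label every character as continuous or binary")
  }
  bin <- values[, kind == "binary", drop = FALSE]
  if (!all(is.na(bin) | bin %in% c(0, 1))) stop_input("binary cells must be 0, 1 or missing")
  if (!is.null(groups)) {
    groups <- as_tibble(groups)
    if (!"taxon" %in% names(groups)) stop_input("`groups` needs a `taxon` column")
  }
  structure(list(values = values, kind = kind, groups = groups), class = "char_matrix")
}

#' @export
print.char_matrix <- function(x, ...) {
  cat(sprintf("<char_matrix> %d taxa x %d characters (%d continuous, %d binary), completeness %.1f%%\n",
              nrow(x$values), ncol(x$values), sum(x$kind == "continuous"),
              sum(x$kind == "binary"), completeness(x)))
  invisible(x)
}

#' Matrix completeness
#'
#' @param cm A [character_matrix()].
#' @return Percentage of scored (non-missing) cells.
#' @export
completeness <- function(cm) {
  v <- cm$values
  if (base::length(v) == 0) stop_input("empty character matrix")
  100 * sum(!is.na(v)) / base::length(v)
}

#' z-transform the continuous characters
#'
#' Standardises every continuous character to mean 0, sample (n-1) standard
#' deviation 1 over its scored cells; binary characters and missing cells
#' are untouched.
#'
#' @param cm A [character_matrix()].
#' @return A `char_matrix` with standardised continuous columns.
#' @export
z_transform <- function(cm) {
  v <- cm$values
  for (j in which(cm$kind == "continuous")) {
    x <- v[, j]
    ok <- !is.na(x)
    if (sum(ok) < 2) stop_input("character `%s` has fewer than 2 scored values", colnames(v)[j])
    s <- sd(x[ok])
    if (!is.finite(s) || s == 0) stop_input("character `%s` has zero variance", colnames(v)[j])
    v[, j] <- (x - mean(x[ok])) / s
  }
  cm$values <- v
  cm
}

#' Pairwise taxon distances from an incomplete character matrix
#'
#' Default (`"scaled_euclidean"`): Euclidean distance over the characters
#' both taxa score, rescaled by `sqrt(p_total / p_shared)` so that sparsely
#' shared pairs are not biased short — the standard pairwise-deletion
#' treatment for ordination of incomplete matrices. Alternatives:
#' `"euclidean"` (pairwise deletion, no rescaling) and `"gower"`
#' (range-normalised mean character distance). Binary characters enter as
#' raw 0/1.
#'
#' @param cm A [character_matrix()] (z-transform first for mixed scales).
#' @param method Distance option (see above).
#' @return Symmetric taxa x taxa distance matrix with zero diagonal.
#' @export
fs_distance <- function(cm, method = c("scaled_euclidean", "euclidean", "gower")) {
  method <- match.arg(method)
  v <- cm$values
  n <- nrow(v); p <- ncol(v)
  rng <- apply(v, 2, function(x) diff(range(x, na.rm = TRUE)))
  rng[!is.finite(rng) | rng == 0] <- 1
  d <- matrix(0, n, n, dimnames = list(rownames(v), rownames(v)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    shared <- !is.na(v[i, ]) & !is.na(v[j, ])
    ps <- sum(shared)
    if (ps == 0) stop_input("taxa `%s` and `%s` share no scored characters",
                            rownames(v)[i], rownames(v)[j])
    diffs <- v[i, shared] - v[j, shared]
    d[i, j] <- d[j, i] <- switch(method,
      scaled_euclidean = sqrt(sum(diffs^2) * p / ps),
      euclidean = sqrt(sum(diffs^2)),
      gower = mean(abs(diffs) / rng[shared])
    )
  }
  d
}

#' Principal coordinate analysis
#'
#' Classical metric scaling: the squared-distance matrix is double-centred
#' (Gower) and eigendecomposed. Axes are ordered by eigenvalue; variance
#' fractions are computed over the positive eigenvalues only; negative
#' eigenvalues (possible for semi-metric inputs) are counted and reported
#' but not corrected.
#'
#' @param d Symmetric distance matrix (e.g. from [fs_distance()]).
#' @param groups Optional per-taxon group tibble carried to the scores.
#' @return A `pco` object: `eigenvalues`, `scores` (taxa x axes),
#'   `variance_fraction`, `n_negative`, `taxa`, `groups`.
#' @export
pco <- function(d, groups = NULL) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop_input("distance matrix must be symmetric")
  n <- nrow(d)
  A <- -0.5 * d^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  tol <- 1e-9 * max(abs(eig$values), 1)
  pos <- eig$values > tol
  scores <- eig$vectors[, pos, drop = FALSE] %*% diag(sqrt(eig$values[pos]), sum(pos))
  rownames(scores) <- rownames(d)
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  structure(list(
    eigenvalues = eig$values,
    scores = scores,
    variance_fraction = eig$values[pos] / sum(eig$values[pos]),
    n_negative = sum(eig$values < -tol),
    taxa = rownames(d),
    groups = groups,
    metric = attr(d, "metric") %||% "euclidean"
  ), class = "pco")
}

#' @export
print.pco <- function(x, ...) {
  vf <- x$variance_fraction
  cat(sprintf("<pco> %d taxa, %d positive axes (%d negative eigenvalues)\n",
              base::length(x$taxa), ncol(x$scores), x$n_negative))
  cat(sprintf("  PC1 %.1f%%, PC2 %.1f%%, PC3 %.1f%% of positive-eigenvalue variance\n",
              100 * vf[1], 100 * (vf[2] %||% NA), 100 * (vf[3] %||% NA)))
  invisible(x)
}

# sums of squared Euclidean distances decomposition for the pseudo-F
pseudo_f_stat <- function(d2, grp_idx, n_per, n, g) {
  ss_t <- sum(d2) / (2 * n) # d2 is full symmetric, each pair counted twice
  ss_w <- 0
  for (k in seq_len(g)) {
    idx <- grp_idx[[k]]
    ss_w <- ss_w + sum(d2[idx, idx]) / (2 * n_per[k])
  }
  ss_b <- ss_t - ss_w
  if (ss_w <= 1e-12 * max(ss_t, 1e-300)) {
    if (ss_t <= 1e-12) return(NA_real_) # no variation at all
    return(Inf)
  }
  (ss_b / (g - 1)) / (ss_w / (n - g))
}

#' Permutational (non-parametric) MANOVA
#'
#' Pseudo-F on Euclidean distances among ordination-score rows, with a
#' permutation null obtained by relabelling rows. With a single variable and
#' two groups the statistic reduces to the classical one-way ANOVA F. The
#' p-value is `(number of permuted F >= observed + 1) / (n_perm + 1)` and is
#' never exactly 0; with `exact = TRUE` (two groups only) all distinct label
#' assignments are enumerated instead and p is the exact proportion with
#' `F >= observed`.
#'
#' @param scores Numeric matrix or data frame of ordination scores (rows =
#'   taxa); use e.g. `ord$scores[, 1:18]` for the first 18 axes.
#' @param groups Group label per row (>= 2 groups, each with >= 2 members).
#' @param n_perm Number of permutations (default 9999).
#' @param seed Mandatory RNG seed for the permutation null.
#' @param exact Enumerate all assignments (2 groups only).
#' @return An `npmanova` object: `F`, `p`, `n_perm`, `seed`, `method`.
#' @export
npmanova <- function(scores, groups, n_perm = 9999, seed, exact = FALSE) {
  if (missing(seed) && !exact) stop_input("`seed` is required for the permutation null")
  X <- as.matrix(scores)
  storage.mode(X) <- "double"
  groups <- as.character(groups)
  if (base::length(groups) != nrow(X)) stop_input("one group label per score row required")
  tab <- table(groups)
  if (base::length(tab) < 2) stop_input("need at least 2 groups")
  if (any(tab < 2)) stop_input("singleton group(s): %s", paste(names(tab)[tab < 2], collapse = ", "))
  n <- nrow(X); g <- base::length(tab)
  d2 <- as.matrix(dist(X))^2
  split_idx <- function(lab) split(seq_len(n), lab)
  n_per <- as.integer(tab)
  f_obs <- pseudo_f_stat(d2, split_idx(groups), n_per, n, g)
  if (is.na(f_obs)) {
    return(structure(list(F = NA_real_, p = 1, n_perm = 0L,
                          seed = if (missing(seed)) NA_integer_ else seed,
                          method = "degenerate", pairwise = NULL), class = "npmanova"))
  }
  if (exact) {
    if (g != 2) stop_input("`exact = TRUE` supports two groups only")
    n1 <- n_per[1]
    combs <- combn(n, n1)
    fs <- apply(combs, 2, function(idx) {
      pseudo_f_stat(d2, list(idx, setdiff(seq_len(n), idx)), n_per, n, g)
    })
    p <- mean(fs >= f_obs - 1e-12)
    return(structure(list(F = f_obs, p = p, n_perm = ncol(combs),
                          seed = NA_integer_, method = "exact", pairwise = NULL),
                     class = "npmanova"))
  }
  set.seed(seed)
  count <- 0L
  for (b in seq_len(n_perm)) {
    lab <- sample(groups)
    fb <- pseudo_f_stat(d2, split_idx(lab), n_per, n, g)
    if (!is.na(fb) && fb >= f_obs - 1e-12) count <- count + 1L
  }
  structure(list(F = f_obs, p = (count + 1) / (n_perm + 1), n_perm = n_perm,
                 seed = seed, method = "permutation", pairwise = NULL),
            class = "npmanova")
}

#' @export
print.npmanova <- function(x, ...) {
  cat(sprintf("<npmanova> pseudo-F = %.4g, p = %.4g (%s, %d permutations)\n",
              x$F, x$p, x$method, x$n_perm))
  invisible(x)
}

#' Pairwise permutational MANOVA with Bonferroni correction
#'
#' Runs [npmanova()] on every pair of groups and reports raw and
#' Bonferroni-corrected p-values.
#'
#' @inheritParams npmanova
#' @return Tibble with `group1`, `group2`, `F`, `p_raw`, `p_bonferroni`,
#'   sorted by group names.
#' @export
pairwise_npmanova <- function(scores, groups, n_perm = 9999, seed) {
  if (missing(seed)) stop_input("`seed` is required")
  groups <- as.character(groups)
  X <- as.matrix(scores)
  gl <- sort(unique(groups))
  if (base::length(gl) < 3) warn("fewer than 3 groups; pairwise table is trivial")
  pairs <- combn(gl, 2)
  n_pairs <- ncol(pairs)
  rows <- lapply(seq_len(n_pairs), function(q) {
    keep <- groups %in% pairs[, q]
    res <- npmanova(X[keep, , drop = FALSE], groups[keep], n_perm = n_perm,
                    seed = seed + q)
    tibble(group1 = pairs[1, q], group2 = pairs[2, q], F = res$F, p_raw = res$p)
  })
  out <- dplyr::bind_rows(rows)
  out$p_bonferroni <- pmin(1, out$p_raw * n_pairs)
  dplyr::arrange(out, .data$group1, .data$group2)
}

#' Spearman correlation of characters with ordination axes
#'
#' Rank-order correlation of each character with the given PCO axes over the
#' taxa scored for that character (ties mid-ranked). Characters with fewer
#' than 3 scored taxa on an axis are skipped with a warning.
#'
#' @param cm A [character_matrix()].
#' @param ordination A [pco()] result on the same taxa.
#' @param axes Integer axes to correlate against (default 1:2).
#' @return Tibble with `character`, `axis`, `rho`, `p_value`, `n`.
#' @export
character_axis_correlation <- function(cm, ordination, axes = c(1, 2)) {
  sc <- ordination$scores
  taxa <- intersect(rownames(cm$values), rownames(sc))
  rows <- list()
  for (ch in colnames(cm$values)) {
    x <- cm$values[taxa, ch]
    for (ax in axes) {
      ok <- !is.na(x)
      if (sum(ok) < 3) {
        warn(sprintf("character `%s`: fewer than 3 scored taxa; skipped", ch))
        next
      }
      ct <- suppressWarnings(cor.test(x[ok], sc[taxa, ax][ok], method = "spearman",
                                      exact = FALSE))
      rows[[base::length(rows) + 1]] <- tibble(character = ch, axis = colnames(sc)[ax],
                                               rho = unname(ct$estimate),
                                               p_value = ct$p.value, n = sum(ok))
    }
  }
  dplyr::bind_rows(rows)
}

#' Read a character matrix with a metadata sidecar
#'
#' The main CSV has the taxon in the first column and one column per
#' character; empty cells or `?` mean missing. The sidecar CSV has columns
#' `character`, `kind` and optionally rows with `taxon`-level labels is a
#' separate file: pass `groups_path` with columns `taxon` plus labels.
#'
#' @param path Character matrix CSV.
#' @param kind_path Sidecar CSV with columns `character`, `kind`.
#' @param groups_path Optional CSV with columns `taxon`, labels.
#' @return A [character_matrix()].
#' @export
read_character_matrix <- function(path, kind_path, groups_path = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                 na.strings = c("", "?", "NA"))
  kinds <- read.csv(kind_path, stringsAsFactors = FALSE)
  groups <- if (!is.null(groups_path)) as_tibble(read.csv(groups_path, stringsAsFactors = FALSE)) else NULL
  character_matrix(df, setNames(kinds$kind, kinds$character), groups)
}

#' Write ordination outputs as CSV
#'
#' Writes per-taxon scores (`<stem>_scores.csv`) and the eigenvalue /
#' variance-fraction table (`<stem>_eigenvalues.csv`).
#'
#' @param ordination A [pco()] result.
#' @param stem Output path stem.
#' @return The two paths, invisibly.
#' @export
write_ordination <- function(ordination, stem) {
  sp <- paste0(stem, "_scores.csv")
  ep <- paste0(stem, "_eigenvalues.csv")
  sc <- data.frame(taxon = rownames(ordination$scores),
                   signif(ordination$scores, 6), check.names = FALSE)
  write.csv(sc, sp, row.names = FALSE)
  ev <- data.frame(axis = seq_along(ordination$eigenvalues),
                   eigenvalue = signif(ordination$eigenvalues, 6))
  ev$variance_fraction <- NA
  pos <- which(ordination$eigenvalues > 0)[seq_along(ordination$variance_fraction)]
  ev$variance_fraction[pos] <- signif(ordination$variance_fraction, 6)
  write.csv(ev, ep, row.names = FALSE)
  invisible(c(sp, ep))
}
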
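toy_matrix <- function(values, kind = NULL, taxa = NULL) {
  if (is.null(taxa)) taxa <- paste0("t", seq_len(nrow(values)))
  rownames(values) <- taxa
  if (is.null(colnames(values))) colnames(values) <- paste0("c", seq_len(ncol(values)))
  character_matrix(values, kind %||% rep("continuous", ncol(values)))
}
`%||%` <- rlang::`%||%`

test_that("z-transform standardises continuous columns and skips binary/missing", {
  cm <- toy_matrix(cbind(a = c(1, 2, 3), b = c(5, 5, NA, 7)[c(1, 2, 4)]))
  z <- z_transform(cm)
  expect_equal(unname(z$values[, "a"]), c(-1, 0, 1))
  cm2 <- toy_matrix(matrix(c(5, 5, NA, 7), ncol = 1), taxa = paste0("t", 1:4))
  z2 <- z_transform(cm2)
  expect_equal(unname(z2$values[, 1]), c(-0.5773503, -0.5773503, NA, 1.1547005),
               tolerance = 1e-6)
  cmb <- toy_matrix(cbind(x = c(1, 2, 3), bin = c(0, 1, 0)),
                    kind = c("continuous", "binary"))
  zb <- z_transform(cmb)
  expect_equal(unname(zb$values[, "bin"]), c(0, 1, 0))
  const <- toy_matrix(cbind(flat = c(2, 2, 2)))
  expect_error(z_transform(const), "flat")
})

test_that("pairwise-deletion distances match hand calculations", {
  cm <- toy_matrix(rbind(c(0, 0), c(3, 4)))
  d <- fs_distance(cm, method = "scaled_euclidean")
  expect_equal(d[1, 2], 5)
  expect_equal(diag(d), c(t1 = 0, t2 = 0))
  # identical rows at distance zero
  cm0 <- toy_matrix(rbind(c(1, 2), c(1, 2)))
  expect_equal(fs_distance(cm0)[1, 2], 0)
  # one of 2 characters missing: difference 3 rescaled by sqrt(2/1)
  cmm <- toy_matrix(rbind(c(0, NA), c(3, 4)))
  expect_equal(fs_distance(cmm, "scaled_euclidean")[1, 2], 3 * sqrt(2))
  expect_equal(fs_distance(cmm, "euclidean")[1, 2], 3)
  # no shared characters is an error naming the pair
  cmn <- toy_matrix(rbind(c(1, NA), c(NA, 2)))
  expect_error(fs_distance(cmn), "t1.*t2")
  expect_true(isSymmetric(fs_distance(make_two_grade_matrix(n_taxa = 8, seed = 4)$values |>
                                        toy_matrix())))
})

test_that("PCO recovers collinear and equilateral geometry", {
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3,
              dimnames = list(letters[1:3], letters[1:3]))
  fit <- pco(d)
  expect_equal(length(fit$variance_fraction), 1) # one positive axis: 100%
  expect_equal(fit$variance_fraction, 1)
  expect_equal(sort(fit$scores[, 1]), c(-1, 0, 1), ignore_attr = TRUE,
               tolerance = 1e-9)
  expect_lt(abs(sum(fit$scores[, 1])), 1e-9) # centred at the origin

  dq <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(dq) <- 0
  fq <- pco(dq)
  expect_equal(fq$variance_fraction, c(0.5, 0.5), tolerance = 1e-9)
  expect_error(pco(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("PCO on complete Euclidean data reproduces PCA exactly", {
  set.seed(11)
  X <- matrix(rnorm(15 * 6), 15, 6,
              dimnames = list(paste0("t", 1:15), paste0("c", 1:6)))
  fit <- pco(fs_distance(toy_matrix(X), method = "euclidean"))
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  vf_pca <- (pc$sdev^2 / sum(pc$sdev^2))[seq_along(fit$variance_fraction)]
  expect_equal(fit$variance_fraction, vf_pca, tolerance = 1e-9)
  for (ax in 1:3) {
    expect_equal(abs(fit$scores[, ax]), abs(pc$x[, ax]), ignore_attr = TRUE,
                 tolerance = 1e-8)
  }
  # independent classical-scaling cross-check
  cs <- cmdscale(dist(X), k = 4, eig = TRUE)
  expect_equal(fit$eigenvalues[1:4], cs$eig[1:4], tolerance = 1e-9)
})

test_that("ordination is invariant to taxon relabelling up to sign", {
  cm <- make_two_grade_matrix(n_taxa = 12, n_continuous = 6, n_binary = 2, seed = 9)
  fit <- fs_fit(cm)
  perm <- sample(seq_len(nrow(cm$values)))
  cmp <- cm
  cmp$values <- cm$values[perm, ]
  fitp <- fs_fit(cmp)
  expect_equal(fitp$variance_fraction, fit$variance_fraction, tolerance = 1e-9)
  for (ax in 1:2) {
    a <- fit$scores[rownames(cmp$values), ax]
    b <- fitp$scores[, ax]
    expect_true(max(abs(a - b)) < 1e-8 || max(abs(a + b)) < 1e-8)
  }
})

test_that("pseudo-F equals classical one-way ANOVA F for univariate data", {
  set.seed(21)
  for (rep in 1:3) {
    y <- rnorm(14)
    g <- rep(c("a", "b"), times = c(6, 8))
    f_classic <- summary(aov(y ~ g))[[1]]$`F value`[1]
    res <- npmanova(matrix(y, ncol = 1), g, n_perm = 19, seed = rep)
    expect_equal(res$F, f_classic, tolerance = 1e-10)
  }
})

test_that("npmanova handles the no-signal and separable toy cases", {
  x <- matrix(rep(1, 6), ncol = 1)
  res <- npmanova(x, rep(c("a", "b"), each = 3), n_perm = 99, seed = 1)
  expect_equal(res$p, 1)
  # exhaustive enumeration: two extreme assignments out of C(6,3)=20
  ex <- npmanova(matrix(c(0, 0, 0, 1, 1, 1), ncol = 1),
                 rep(c("a", "b"), each = 3), exact = TRUE)
  expect_equal(ex$p, 0.1)
  expect_equal(ex$n_perm, 20)
  expect_error(npmanova(x, c("a", rep("b", 5)), n_perm = 9, seed = 1), "singleton")
  expect_error(npmanova(x, rep("a", 6), n_perm = 9, seed = 1), "2 groups")
  # p resolution and reproducibility under a fixed seed
  set.seed(99)
  y <- matrix(rnorm(20), ncol = 2)
  g <- rep(c("a", "b"), each = 5)
  r1 <- npmanova(y, g, n_perm = 49, seed = 12)
  r2 <- npmanova(y, g, n_perm = 49, seed = 12)
  expect_equal(r1$p, r2$p)
  expect_equal((r1$p * 50) %% 1, 0)
  expect_gt(r1$p, 0)
})

test_that("pseudo-F agrees with an independent permutational MANOVA implementation", {
  skip_if_not_installed("vegan")
  cm <- make_two_grade_matrix(n_taxa = 16, n_continuous = 8, n_binary = 2,
                              missing_fraction = 0, seed = 5)
  fit <- fs_fit(cm)
  grade <- grade_of(fit, cm)
  k <- min(6, ncol(fit$scores))
  ours <- npmanova(fit$scores[, 1:k], grade, n_perm = 99, seed = 2)
  df <- data.frame(grade = grade)
  ref <- vegan::adonis2(dist(fit$scores[, 1:k]) ~ grade, data = df,
                        permutations = 99)
  expect_equal(ours$F, ref$F[1], tolerance = 1e-8)
})

test_that("pairwise npMANOVA enumerates pairs with Bonferroni correction", {
  set.seed(31)
  X <- rbind(matrix(rnorm(10), 5), matrix(rnorm(10, 3), 5), matrix(rnorm(10, 6), 5))
  g <- rep(c("a", "b", "c"), each = 5)
  tab <- pairwise_npmanova(X, g, n_perm = 49, seed = 3)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$p_bonferroni, pmin(1, tab$p_raw * 3))
  # sorted table invariant to label order in the input
  tab2 <- pairwise_npmanova(X[15:1, ], g[15:1], n_perm = 49, seed = 3)
  expect_equal(tab2$group1, tab$group1)
  expect_equal(tab2$group2, tab$group2)
})

test_that("Spearman loadings respect monotone transforms and skip sparse characters", {
  cm <- make_two_grade_matrix(n_taxa = 15, n_continuous = 6, n_binary = 2,
                              missing_fraction = 0, seed = 8)
  fit <- fs_fit(cm)
  # plant characters equal to / transformed from the axis scores
  v <- cm$values
  v <- cbind(v, same = fit$scores[rownames(v), 1],
             cubed = fit$scores[rownames(v), 1]^3,
             anti = -fit$scores[rownames(v), 1])
  cm2 <- character_matrix(v, c(cm$kind, same = "continuous", cubed = "continuous",
                               anti = "continuous"))
  tab <- character_axis_correlation(cm2, fit, axes = 1)
  expect_equal(tab$rho[tab$character == "same"], 1)
  expect_equal(tab$rho[tab$character == "cubed"], 1)
  expect_equal(tab$rho[tab$character == "anti"], -1)
  # a character scored for <3 taxa is skipped with a warning
  v2 <- cm$values
  v2[, 1] <- NA
  v2[1:2, 1] <- c(1, 2)
  cm3 <- character_matrix(v2, cm$kind)
  expect_warning(tab3 <- character_axis_correlation(cm3, fit, axes = 1), "skipped")
  expect_false(colnames(v2)[1] %in% tab3$character)
})

test_that("completeness counts scored cells", {
  cm <- toy_matrix(rbind(c(1, NA), c(2, 3)))
  expect_equal(completeness(cm), 75)
  cm2 <- toy_matrix(rbind(c(1, 2), c(2, 3)))
  expect_equal(completeness(cm2), 100)
})

test_that("character matrix CSV + sidecar round-trips with ? as missing", {
  cm <- make_two_grade_matrix(n_taxa = 6, n_continuous = 3, n_binary = 1, seed = 13)
  dir <- withr::local_tempdir()
  main <- file.path(dir, "matrix.csv")
  kind <- file.path(dir, "kinds.csv")
  grp <- file.path(dir, "groups.csv")
  df <- data.frame(taxon = rownames(cm$values), cm$values, check.names = FALSE)
  df[2, 3] <- "?"
  write.csv(df, main, row.names = FALSE, quote = FALSE, na = "")
  write.csv(data.frame(character = colnames(cm$values), kind = cm$kind),
            kind, row.names = FALSE)
  write.csv(cm$groups, grp, row.names = FALSE)
  back <- read_character_matrix(main, kind, grp)
  expect_true(is.na(back$values[2, 2]))
  expect_equal(back$kind, cm$kind)
  expect_equal(back$groups$grade, cm$groups$grade)
})

test_that("npMANOVA power rises with the generator's grade offset", {
  n_sim <- 40
  rates <- vapply(c(0.5, 1.5, 3), function(delta) {
    mean(vapply(seq_len(n_sim), function(r) {
      cm <- make_two_grade_matrix(n_taxa = 16, n_continuous = 8, n_binary = 2,
                                  delta = delta, seed = 5000 + 97 * r + round(delta * 7))
      fit <- fs_fit(cm)
      k <- min(6, ncol(fit$scores))
      res <- npmanova(fit$scores[, 1:k, drop = FALSE], grade_of(fit, cm),
                      n_perm = 99, seed = r)
      res$p <= 0.05
    }, logical(1)))
  }, double(1))
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[3], 0.9)
})
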
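test_that("PERMANOVA partition matches brute-force sums and vegan", {
  m4 <- cassian_ppd()
  grouping <- cassian_depth_split()
  pm <- permanova(m4, grouping, permutations = 499, seed = 7)

  # brute-force partition oracle: explicit double loops
  d <- unclass(m4); n <- nrow(d); g <- grouping[rownames(d)]
  sst <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) sst <- sst + d[i, j]^2
  sst <- sst / n
  ssw <- 0
  for (grp in unique(g)) {
    idx <- which(g == grp); ng <- length(idx); s <- 0
    for (a in 1:(ng - 1)) for (b in (a + 1):ng) s <- s + d[idx[a], idx[b]]^2
    ssw <- ssw + s / ng
  }
  expect_equal(pm$ss_total, sst, tolerance = 1e-12)
  expect_equal(pm$ss_within, ssw, tolerance = 1e-12)
  expect_equal(pm$ss_between + pm$ss_within, pm$ss_total, tolerance = 1e-12)
  expect_equal(pm$r_squared, 1 - pm$ss_within / pm$ss_total, tolerance = 1e-12)

  # independent implementation: vegan::adonis2
  ad <- vegan::adonis2(stats::as.dist(unclass(m4)) ~ g, permutations = 99)
  expect_equal(pm$r_squared, ad$R2[1], tolerance = 1e-10)
  expect_equal(pm$pseudo_F, ad$F[1], tolerance = 1e-10)

  # published value: R2 = 0.21 for the two depth groups
  expect_equal(round_half_up(pm$r_squared, 2), 0.21)
  expect_gte(pm$p_value, 1 / 500)
})

test_that("PERMANOVA degenerate designs behave correctly", {
  m4 <- cassian_ppd()
  expect_error(permanova(m4, setNames(rep("g", 8), rownames(m4))),
               "degenerate")
  # constant dissimilarity: every permutation gives the identical F = 1
  cm <- matrix(1, 8, 8) - diag(1, 8)
  dimnames(cm) <- dimnames(m4)
  pmc <- permanova(diss_matrix(cm), cassian_depth_split(),
                   permutations = 199, seed = 1)
  expect_equal(pmc$pseudo_F, 1, tolerance = 1e-12)
  expect_equal(pmc$p_value, 1)
})

test_that("PERMANOVA p is approximately uniform under exchangeable labels", {
  tab <- random_table(n_samples = 10, n_taxa = 12, size = 120)
  d <- dissimilarity_matrix(tab)
  set.seed(55)
  pvals <- vapply(1:200, function(r) {
    g <- setNames(sample(rep(c("a", "b"), each = 5)), rownames(d))
    permanova(d, g, permutations = 99, seed = 900 + r)$p_value
  }, numeric(1))
  expect_true(all(pvals >= 1 / 100 & pvals <= 1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_lt(unname(ks$statistic), 0.15)
  expect_lte(mean(pvals <= 0.05), 0.12)
})

test_that("PCoA recovers Euclidean configurations and flags semimetric input", {
  # three mutually equidistant points: two equal positive eigenvalues
  eq <- matrix(1, 3, 3) - diag(1, 3)
  dimnames(eq) <- list(letters[1:3], letters[1:3])
  emb <- pcoa(diss_matrix(eq))
  ev <- emb$eigenvalues[emb$eigenvalues > 1e-9]
  expect_equal(length(ev), 2)
  expect_equal(ev[1], ev[2], tolerance = 1e-9)
  expect_equal(as.matrix(stats::dist(emb$coordinates)), unname(eq) + diag(0, 3),
               tolerance = 1e-9, ignore_attr = TRUE)

  # generate-from-coordinates oracle
  set.seed(4)
  pts <- matrix(rnorm(14), 7, 2)
  dmat <- as.matrix(stats::dist(pts))
  emb2 <- pcoa(diss_matrix(dmat, "euclidean"))
  expect_false(emb2$negative_eigenvalues)
  expect_equal(as.matrix(stats::dist(emb2$coordinates)), dmat,
               tolerance = 1e-9, ignore_attr = TRUE)
  # cross-check against classical MDS
  ref <- stats::cmdscale(dmat, k = 2)
  expect_equal(abs(cor(emb2$coordinates[, 1], ref[, 1])), 1, tolerance = 1e-9)

  # proportional dissimilarity is a semimetric: such matrices can carry
  # negative eigenvalues, which are flagged, not an error (the published
  # 2-dp matrix happens to be positive semidefinite, so a computed PPD
  # matrix is used here)
  semi <- abundance_table(matrix(
    c(1, 3, 2, 1, 5, 0,
      0, 2, 1, 0, 3, 3,
      2, 2, 1, 2, 1, 0,
      4, 3, 6, 4, 2, 2,
      3, 2, 2, 2, 1, 2), 5, 6, byrow = TRUE,
    dimnames = list(paste0("s", 1:5), paste0("t", 1:6))))
  emb3 <- pcoa(dissimilarity_matrix(semi))
  expect_true(emb3$negative_eigenvalues)
  expect_false(pcoa(cassian_ppd())$negative_eigenvalues)
})

test_that("NMDS minimises stress-1 and is consistent across k", {
  # perfect embedding: 4 metric points in 3 dimensions
  set.seed(8)
  pts <- matrix(rnorm(12), 4, 3)
  dmat <- as.matrix(stats::dist(pts))
  fit3 <- nmds(diss_matrix(dmat, "euclidean"), k = 3, restarts = 5, seed = 2)
  expect_lt(fit3$stress, 1e-4)

  m4 <- cassian_ppd()
  stress <- vapply(1:3, function(k)
    nmds(m4, k = k, restarts = 20, seed = 10)$stress, numeric(1))
  expect_lte(stress[1] + 0.01, 1)           # stress-1 scale
  expect_true(all(diff(stress) < 0.01))     # non-increasing in k (tolerating local optima)
  expect_lte(stress[2], 0.10)               # published configuration: stress 0.06

  # stress is invariant under rotation/reflection of the configuration,
  # checked with an independent stress-1 oracle (isotonic regression)
  stress1_oracle <- function(diss, coords) {
    dv <- diss[lower.tri(diss)]
    ev <- as.matrix(stats::dist(coords))[lower.tri(diss)]
    ord <- order(dv, ev)  # primary tie treatment: untie in favour of the fit
    dhat <- stats::isoreg(ev[ord])$yf
    sqrt(sum((ev[ord] - dhat)^2) / sum(ev[ord]^2))
  }
  fit <- nmds(m4, k = 2, restarts = 20, seed = 10)
  theta <- 0.7
  rot <- fit$coordinates %*% matrix(c(cos(theta), sin(theta),
                                      -sin(theta), cos(theta)), 2, 2)
  s_orig <- stress1_oracle(unclass(m4), fit$coordinates)
  s_rot <- stress1_oracle(unclass(m4), rot)
  expect_equal(s_rot, s_orig, tolerance = 1e-10)
  expect_equal(s_orig, fit$stress, tolerance = 0.02)

  expect_error(nmds(m4, k = 8), "smaller")
})

test_that("dispersion distances match coordinate-space centroids and vegan", {
  # Euclidean toy data: centroid distances computable directly
  set.seed(12)
  pts <- matrix(rnorm(16), 8, 2)
  rownames(pts) <- paste0("s", 1:8)
  g <- setNames(rep(c("A", "B"), each = 4), rownames(pts))
  dmat <- as.matrix(stats::dist(pts))
  disp <- dispersion_of_homogeneity(diss_matrix(dmat, "euclidean"), g)
  oracle <- vapply(rownames(pts), function(s) {
    cen <- colMeans(pts[names(g)[g == g[s]], , drop = FALSE])
    sqrt(sum((pts[s, ] - cen)^2))
  }, numeric(1))
  expect_equal(disp$distances, oracle, tolerance = 1e-9)

  # identical samples collapse to zero dispersion
  zero <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(unname(dispersion_of_homogeneity(
    diss_matrix(zero), setNames(rep("g", 3), letters[1:3]))$distances),
    rep(0, 3))

  # agree with the independent vegan implementation on the published matrix
  m4 <- cassian_ppd()
  grouping <- cassian_depth_split()
  disp4 <- dispersion_of_homogeneity(m4, grouping)
  bd <- vegan::betadisper(stats::as.dist(unclass(m4)),
                          grouping[rownames(m4)], type = "centroid")
  expect_equal(unname(disp4$distances), unname(bd$distances), tolerance = 1e-6)
  # and on a semimetric matrix, exercising the imaginary-axis correction
  semi <- abundance_table(matrix(
    c(1, 3, 2, 1, 5, 0,
      0, 2, 1, 0, 3, 3,
      2, 2, 1, 2, 1, 0,
      4, 3, 6, 4, 2, 2,
      3, 2, 2, 2, 1, 2), 5, 6, byrow = TRUE,
    dimnames = list(paste0("s", 1:5), paste0("t", 1:6))))
  ds <- dissimilarity_matrix(semi)
  gs <- setNames(c("A", "A", "B", "B", "B"), rownames(semi))
  disp_s <- dispersion_of_homogeneity(ds, gs)
  bd_s <- vegan::betadisper(stats::as.dist(unclass(ds)), gs, type = "centroid")
  expect_equal(unname(disp_s$distances), unname(bd_s$distances),
               tolerance = 1e-6)

  # two groups of duplicated points: zero within, separated centroids
  dup <- abundance_table(rbind(a1 = c(x = 5, y = 0), a2 = c(x = 5, y = 0),
                               b1 = c(x = 0, y = 5), b2 = c(x = 0, y = 5)))
  dd <- dissimilarity_matrix(dup)
  dg <- setNames(c("A", "A", "B", "B"), rownames(dup))
  disp_dup <- dispersion_of_homogeneity(dd, dg)
  expect_equal(unname(disp_dup$distances), rep(0, 4), tolerance = 1e-9)
  expect_gt(sum((disp_dup$centroids["A", ] - disp_dup$centroids["B", ])^2), 0.5)
})
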
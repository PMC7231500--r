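test_that("proportional dissimilarity reproduces the published pairwise values", {
  tab <- cassian_new4()
  d <- dissimilarity_matrix(tab, "ppd")
  r2 <- function(a, b) round_half_up(d[a, b], 2)
  expect_equal(r2("Costalaresc", "Picolbach"), 0.83)
  expect_equal(r2("Costalaresc", "Rumerlo cliff"), 1.00)
  expect_equal(r2("Costalaresc", "Rumerlo ski slope"), 0.99)
  expect_equal(r2("Picolbach", "Rumerlo cliff"), 0.93)
  expect_equal(r2("Picolbach", "Rumerlo ski slope"), 1.00)
  expect_equal(r2("Rumerlo cliff", "Rumerlo ski slope"), 0.67)
})

test_that("proportional dissimilarity has its limiting values and bounds", {
  expect_equal(proportional_dissimilarity(c(3, 1), c(6, 2)), 0)
  expect_equal(proportional_dissimilarity(c(1, 0), c(0, 5)), 1)
  expect_equal(proportional_dissimilarity(c(4, 0), c(1, 1)), 0.5)
  expect_error(proportional_dissimilarity(c(0, 0), c(1, 1)), "zero-total")
  expect_error(proportional_dissimilarity(c(1, 2), c(1, 2, 3)), "aligned")
})

test_that("PPD is scale-invariant and equals Bray-Curtis on proportions", {
  set.seed(21)
  for (rep in 1:15) {
    tab <- random_table(n_samples = 4, n_taxa = 10)
    d <- dissimilarity_matrix(tab, "ppd")
    expect_true(all(d >= 0 & d <= 1))
    # scaling one sample's counts changes nothing
    m <- unclass(tab) * 1L
    m[1, ] <- m[1, ] * 7L
    d_scaled <- dissimilarity_matrix(abundance_table(m), "ppd")
    expect_equal(unclass(d_scaled), unclass(d), tolerance = 1e-12)
    # independent route: vegan Bray-Curtis on proportion-normalised rows
    p <- unclass(tab) / rowSums(unclass(tab))
    ref <- as.matrix(vegan::vegdist(p, method = "bray"))
    expect_lt(max(abs(unclass(d) - ref)), 1e-12)
  }
})

test_that("modified Gower follows the log-transform definition", {
  expect_equal(modified_gower_dissimilarity(c(4, 0), c(1, 1)), 1.5)
  expect_equal(modified_gower_dissimilarity(c(1, 0), c(0, 1)), 1)
  expect_equal(modified_gower_dissimilarity(c(8, 2), c(8, 2)), 0)
  # double zeros are excluded from the divisor
  expect_equal(modified_gower_dissimilarity(c(4, 0, 0), c(1, 1, 0)), 1.5)
  expect_error(modified_gower_dissimilarity(c(1, 1), c(1, 1), log_base = 1), "log_base")
  mg <- dissimilarity_matrix(cassian_new4(), "modified_gower")
  expect_true(all(mg >= 0))
  expect_equal(attr(mg, "metric"), "modified_gower")
})

test_that("dissimilarity matrices are symmetric with zero diagonal", {
  dup <- abundance_table(rbind(s1 = c(a = 2, b = 3), s2 = c(a = 2, b = 3)))
  expect_equal(unname(unclass(dissimilarity_matrix(dup))), matrix(0, 2, 2),
               ignore_attr = TRUE)
  disjoint <- abundance_table(diag(5, 3, 3) + 0)
  dd <- dissimilarity_matrix(disjoint)
  expect_equal(unname(lower_vals <- dd[lower.tri(dd)]), rep(1, 3))
  expect_error(dissimilarity_matrix(dup[1, , drop = FALSE]), "two samples")
})

test_that("mean dissimilarity summaries reproduce the published beta diversity", {
  m4 <- cassian_ppd()
  all4 <- mean_dissimilarity(m4, "all")
  expect_equal(round_half_up(all4$mean, 2), 0.91)
  expect_equal(all4$n_pairs, 28)
  expect_equal(round_half_up(all4$se, 2), 0.02)
  cost <- mean_dissimilarity(m4, "per-sample", sample = "Costalaresc")
  expect_equal(round_half_up(cost$mean, 2), 0.91)
  expect_equal(cost$n_pairs, 7)
  m5 <- safaga_ppd()
  expect_equal(round_half_up(mean_dissimilarity(m5, "all")$mean, 2), 0.89)

  const <- diss_matrix(matrix(0.4, 3, 3) - diag(0.4, 3), "ppd")
  cm <- mean_dissimilarity(const, "all")
  expect_equal(cm$mean, 0.4)
  expect_equal(cm$se, 0)
})

test_that("overall mean equals the pair-count-weighted within/between combination", {
  grouping <- cassian_depth_split()
  m4 <- cassian_ppd()
  w <- mean_dissimilarity(m4, "within-group", grouping = grouping)
  b <- mean_dissimilarity(m4, "between-group", grouping = grouping)
  a <- mean_dissimilarity(m4, "all")
  expect_equal((w$mean * w$n_pairs + b$mean * b$n_pairs) / (w$n_pairs + b$n_pairs),
               a$mean, tolerance = 1e-12)
  expect_equal(w$n_pairs + b$n_pairs, a$n_pairs)
})

test_that("pooled group compositions combine counts before comparison", {
  tab <- toy_table()
  singletons <- pooled_group_dissimilarity(tab, c(s1 = "g1", s2 = "g2"))
  expect_equal(singletons["g1", "g2"],
               proportional_dissimilarity(tab["s1", ], tab["s2", ]))

  same <- abundance_table(rbind(a1 = c(x = 2, y = 2), a2 = c(x = 1, y = 1),
                                b1 = c(x = 3, y = 3)))
  d0 <- pooled_group_dissimilarity(same, c(a1 = "A", a2 = "A", b1 = "B"))
  expect_equal(d0["A", "B"], 0)

  hand <- abundance_table(rbind(s1 = c(A = 4, B = 0), s2 = c(A = 1, B = 1),
                                s3 = c(A = 1, B = 1)))
  dh <- pooled_group_dissimilarity(hand, c(s1 = "g1", s2 = "g2", s3 = "g2"))
  expect_equal(dh["g1", "g2"], 0.5)
  expect_error(pooled_group_dissimilarity(hand, c(s1 = "g", s2 = "g", s3 = "g")),
               "two groups")
})

test_that("dissimilarity matrices round-trip through CSV, upper triangle accepted", {
  m4 <- cassian_ppd()
  path <- tempfile(fileext = ".csv")
  write_dissimilarity_matrix(m4, path)
  back <- read_dissimilarity_matrix(path)
  expect_equal(unclass(back), unclass(m4), tolerance = 1e-12)
  # the packaged fixture itself is upper-triangle-only and symmetrises on read
  expect_equal(m4["Stuores", "Costalaresc"], 1.00)
  expect_equal(max(abs(unclass(m4) - t(unclass(m4)))), 0)
})
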
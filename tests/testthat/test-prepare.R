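test_that("top-n reduction keeps ties at the cutoff rank", {
  tab <- cassian_new4()
  red <- top_n_reduce(tab, 10)
  # published tables: two taxa tied at 3 specimens (Costalaresc) and three
  # tied at 5 (Rumerlo cliff) are all retained under "ten most abundant"
  expect_equal(sum(red["Costalaresc", ] > 0), 11)
  expect_equal(sum(red["Costalaresc", ]), 315)
  expect_equal(sum(red["Rumerlo cliff", ] > 0), 12)
  expect_equal(sum(red["Rumerlo cliff", ]), 229)

  tied <- abundance_table(rbind(s = c(a = 5, b = 3, c = 3, d = 1)))
  expect_equal(colnames(top_n_reduce(tied, 2)), c("a", "b", "c"))
  expect_error(top_n_reduce(tied, 0), ">= 1")
})

test_that("top-n reduction is idempotent, rank-respecting, and a no-op for small samples", {
  set.seed(101)
  for (rep in 1:10) {
    tab <- random_table(n_samples = 3, n_taxa = 15, size = 80)
    n <- sample(2:6, 1)
    once <- top_n_reduce(tab, n)
    expect_equal(top_n_reduce(once, n), once)
    # no retained count may be smaller than a dropped count in the same sample
    for (s in rownames(tab)) {
      kept <- tab[s, intersect(colnames(once), colnames(tab))]
      kept <- kept[once[s, intersect(colnames(once), colnames(tab))] > 0]
      dropped_ids <- setdiff(colnames(tab)[tab[s, ] > 0],
                             colnames(once)[once[s, ] > 0])
      if (length(kept) && length(dropped_ids))
        expect_gte(min(kept), max(tab[s, dropped_ids]))
    }
  }
  small <- abundance_table(rbind(s = c(a = 2, b = 1)))
  expect_equal(top_n_reduce(small, 10), small)
})

test_that("taxon exclusion adjusts totals and is logged", {
  raw <- rumerlo_ski_raw()
  expect_equal(sum(raw), 44)
  cleaned <- exclude_taxa(raw, "Pragsoconulus robustus")
  expect_equal(sum(cleaned), 33)
  expect_equal(attr(cleaned, "exclusion_log")$removed, 11L)

  tab <- toy_table()
  same <- exclude_taxa(tab, "not there")
  expect_equal(unclass(same), unclass(tab), ignore_attr = "exclusion_log")

  two <- abundance_table(rbind(s = c(a = 9, b = 1)))
  expect_equal(berger_parker(exclude_taxa(two, "a")["s", ]), 1.0)
  expect_error(exclude_taxa(two, c("a", "b")), "empty")
})

test_that("site merging sums counts, conserves specimens, and merges metadata", {
  grouping <- safaga_site_grouping()
  # per-sample index columns legitimately differ within a site; merging
  # applies to the field metadata
  md13 <- safaga_metadata()[, c("sample_id", "latitude", "longitude",
                                "depth_m", "environment", "n_specimens")]
  # synthetic counts for the 13 Safaga samples (real counts unpublished)
  set.seed(7)
  counts <- t(vapply(md13$n_specimens,
                     function(n) as.numeric(rmultinom(1, n, runif(12))),
                     numeric(12)))
  dimnames(counts) <- list(md13$sample_id, paste0("t", 1:12))
  tab <- abundance_table(counts)
  merged <- merge_by_site(tab, grouping, metadata = md13)
  expect_equal(nrow(merged$table), 8)
  expect_equal(sum(merged$table), sum(tab))
  expect_equal(merged$metadata$n_specimens[merged$metadata$sample_id == "94-1"],
               sum(md13$n_specimens[grouping == "94-1"]))
  expect_equal(merged$metadata$depth_m[merged$metadata$sample_id == "94-4"], 39)

  # identity grouping leaves the table untouched
  ident <- merge_by_site(tab, setNames(rownames(tab), rownames(tab)))
  expect_equal(unclass(ident), unclass(tab))

  # additivity
  two <- abundance_table(rbind(x = c(A = 1), y = c(A = 2)))
  expect_equal(unname(unclass(merge_by_site(two, c(x = "s", y = "s")))[1, 1]), 3L)

  # conflicting depth raises under rule = error
  md_bad <- md13
  md_bad$depth_m[md_bad$sample_id == "94-1-b"] <- 11
  expect_error(merge_by_site(tab, grouping, metadata = md_bad), "conflicting 'depth_m'")
  ok <- merge_by_site(tab, grouping, metadata = md_bad, conflict = "first")
  expect_equal(ok$metadata$depth_m[ok$metadata$sample_id == "94-1"], 10)
})

test_that("depth-rank inference orients, centres, and matches a rank-sum oracle", {
  attrs <- c("suspension_deposit_ratio", "gastropod_abundance",
             "articulated_bivalves")
  # sample "deep" maximal on deep-pointing attributes, minimal on shallow ones
  profiles <- rbind(deep = c(0.1, 1, 0.9), shallow = c(2.0, 10, 0.1))
  colnames(profiles) <- attrs
  score <- infer_depth_rank(profiles)
  expect_gt(score[["deep"]], 0)
  expect_lt(score[["shallow"]], 0)
  expect_equal(sum(score), 0)

  equal <- matrix(1, 2, 3, dimnames = list(c("a", "b"), attrs))
  expect_warning(s0 <- infer_depth_rank(equal), "constant")
  expect_equal(unname(s0), c(0, 0))

  # three monotone profiles: brute-force weighted oriented rank sums
  prof3 <- rbind(p1 = c(3, 30, 0.1), p2 = c(2, 20, 0.5), p3 = c(1, 10, 0.9))
  colnames(prof3) <- attrs
  w <- c(suspension_deposit_ratio = 2, gastropod_abundance = 1,
         articulated_bivalves = 0.5)
  dirs <- depth_attribute_directions()[attrs]
  oracle <- sapply(1:3, function(i)
    sum(sapply(attrs, function(a)
      w[[a]] * dirs[[a]] * rank(prof3[, a])[i])))
  oracle <- oracle - mean(oracle)
  got <- infer_depth_rank(prof3, weights = w)
  expect_equal(unname(got), unname(oracle))
  expect_equal(order(got), order(oracle))
})
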
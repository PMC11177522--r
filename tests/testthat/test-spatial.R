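test_that("CoG matches hand-computed examples", {
  expect_equal(cog(point_map(base = 1)), list(i = 4.5, j = 4.5))
  expect_equal(cog(point_map(c(3, 7, 0.4))), list(i = 3, j = 7))
  expect_equal(cog(point_map(c(2, 2, 1), c(6, 6, 3))), list(i = 5, j = 5))
  expect_error(cog(point_map()), "CoG")
})

test_that("CoG shifts with the pattern (translation consistency)", {
  set.seed(51)
  v <- matrix(0, 8, 8)
  v[3:5, 2:4] <- runif(9)
  shifted <- matrix(0, 8, 8)
  shifted[3:5, 3:5] <- v[3:5, 2:4]
  expect_equal(cog(shifted)$j, cog(v)$j + 1, tolerance = 1e-12)
  expect_equal(cog(shifted)$i, cog(v)$i, tolerance = 1e-12)
})

test_that("h-dome transform equals the fixed-point reconstruction oracle", {
  # a constant map is one regional-maximum plateau spanning the whole
  # domain, so its dome height is exactly h everywhere (and segmentation
  # treats zero-range maps as clusterless upstream)
  expect_equal(hdome(matrix(1, 8, 8), 0.2), matrix(0.2, 8, 8))
  expect_equal(naive_hdome(matrix(1, 8, 8), 0.2), matrix(0.2, 8, 8))

  # single peak on a flat background: dome = h at the peak
  v <- matrix(0.1, 8, 8); v[4, 6] <- 0.9
  expect_equal(hdome(v, 0.3)[4, 6], 0.3)
  expect_equal(hdome(v, 0.3), naive_hdome(v, 0.3))

  # random maps: exact agreement with the oracle, bounded by h
  set.seed(52)
  for (r in 1:25) {
    v <- matrix(runif(64), 8, 8)
    h <- runif(1, 0.05, 0.5)
    conn <- sample(c(4, 8), 1)
    d <- hdome(v, h, conn)
    expect_equal(d, naive_hdome(v, h, conn), tolerance = 1e-12)
    expect_true(all(d >= -1e-12 & d <= h + 1e-12))
  }
})

test_that("segmentation keeps the cluster with the highest nRMS", {
  s <- segmentation_settings(h = 0.2)
  # one 2x2 block of ones on zero background
  v <- matrix(0, 8, 8); v[3:4, 5:6] <- 1
  m <- segment_relevant_channels(v, s)
  expect_equal(m$n_channels, 4)
  expect_true(all(m$mask[3:4, 5:6]))

  # two separated blocks: only the taller survives
  v2 <- matrix(0, 8, 8); v2[1:2, 1:2] <- 1; v2[6:7, 6:7] <- 0.6
  m2 <- segment_relevant_channels(v2, s)
  expect_true(all(m2$mask[1:2, 1:2]) && m2$n_channels == 4)

  # all-zero map: empty mask
  expect_equal(segment_relevant_channels(matrix(0, 8, 8), s)$n_channels, 0)

  # equal peaks: tie broken by summed nRMS
  v3 <- matrix(0, 8, 8); v3[1:2, 1:2] <- 1; v3[5:7, 5:7] <- 1
  m3 <- segment_relevant_channels(v3, s)
  expect_true(all(m3$mask[5:7, 5:7]) && m3$n_channels == 9)
})

test_that("segmentation is covariant under map scaling", {
  set.seed(53)
  for (r in 1:10) {
    v <- profile_gains(spatial_profile(
      data.frame(ci = runif(1, 3, 6), cj = runif(1, 3, 6),
                 si = 1.2, sj = 1.2, gain = 1), floor_gain = 0.2)) +
      matrix(rnorm(64, 0, 0.01), 8, 8)
    v <- pmax(v, 0)
    m1 <- suppressWarnings(segment_relevant_channels(v))
    m2 <- suppressWarnings(segment_relevant_channels(v * 7.3))  # h relative to range
    expect_identical(m1$mask, m2$mask)
  }
})

test_that("overlap degree follows the set formula", {
  a <- mask_from_cells(list(c(1, 1), c(1, 2), c(2, 1)))
  b <- mask_from_cells(list(c(2, 1), c(2, 2)))
  expect_equal(overlap_degree(a, b), 100 * 1 / 3, tolerance = 1e-6)
  expect_equal(overlap_degree(a, a), 100)
  expect_equal(overlap_degree(a, mask_from_cells(list(c(8, 8)))), 0)
  expect_warning(z <- overlap_degree(cluster_mask(matrix(FALSE, 8, 8)),
                                     cluster_mask(matrix(FALSE, 8, 8))), "empty")
  expect_equal(z, 0)
  # symmetry and monotonicity when the intersection shrinks
  expect_equal(overlap_degree(a, b), overlap_degree(b, a))
  b_small <- mask_from_cells(list(c(2, 2)))
  expect_lte(overlap_degree(a, b_small), overlap_degree(a, b))
})

test_that("within- and between-task overlaps aggregate pairwise values", {
  a <- mask_from_cells(list(c(1, 1), c(1, 2)))
  expect_equal(within_task_overlap(list(a, a, a)), 100)
  b <- mask_from_cells(list(c(1, 1), c(1, 2)))   # = a
  c_ <- mask_from_cells(list(c(5, 5), c(5, 6)))  # disjoint
  d <- mask_from_cells(list(c(1, 1), c(5, 5)))   # half of each
  # pairwise: (a,b)=100, (a,c)=0, (b,c)=0
  expect_equal(within_task_overlap(list(a, b, c_)), 100 / 3, tolerance = 1e-9)
  expect_equal(within_task_overlap(list(a, c_, d)), (0 + 50 + 50) / 3)
  empty <- cluster_mask(matrix(FALSE, 8, 8))
  expect_warning(w <- within_task_overlap(list(a, empty, empty)), "non-empty")
  expect_true(is.na(w))
  expect_equal(between_task_overlap(a, b), 100)
  expect_equal(between_task_overlap(a, c_), 0)
})
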
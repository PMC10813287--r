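geom <- specimen_geometry("circ") # 10.1 mm wide, 20 mm gauge

test_that("rendered frames honour incompressible thinning and the seed", {
  fr1 <- render_frame(geom, stretch = 1, scale_mm_px = 0.1, noise_sd = 0)
  expect_equal(attr(fr1, "truth")$width_px, round(10.1 / 0.1))

  fr <- render_frame(geom, stretch = 1.2, scale_mm_px = 0.1, noise_sd = 0)
  expect_lte(
    abs(attr(fr, "truth")$width_px - 10.1 / sqrt(1.2) / 0.1), 1
  )
  a <- render_frame(geom, 1.1, noise_sd = 0.05, seed = 3)
  b <- render_frame(geom, 1.1, noise_sd = 0.05, seed = 3)
  expect_identical(a$pixels, b$pixels)
})

test_that("binarization recovers the silhouette and respects polarity", {
  fr <- render_frame(geom, 1, scale_mm_px = 0.2, noise_sd = 0)
  mask <- binarize(fr)
  expect_equal(sum(mask), attr(fr, "truth")$width_px * attr(fr, "truth")$length_px)

  noisy <- render_frame(geom, 1, scale_mm_px = 0.2, noise_sd = 0.05, seed = 1)
  nmask <- binarize(noisy)
  # mismatches against the clean silhouette stay within 1 px of its border
  diff_px <- which(nmask != mask, arr.ind = TRUE)
  if (nrow(diff_px) > 0) {
    on_border <- apply(diff_px, 1, function(rc) {
      r <- rc[1]
      co <- rc[2]
      nb <- mask[
        max(1, r - 1):min(nrow(mask), r + 1),
        max(1, co - 1):min(ncol(mask), co + 1)
      ]
      any(nb) && !all(nb)
    })
    expect_true(all(on_border))
  }

  inverted <- tissue_frame(1 - noisy$pixels, noisy$scale_mm_px)
  expect_identical(binarize(inverted, polarity = "dark"), nmask)

  flat <- tissue_frame(matrix(0, 50, 50), 0.1)
  expect_error(binarize(flat), "segmentation failed")
})

test_that("edge extraction partitions a rectangle into four sensible groups", {
  mask <- matrix(FALSE, 120, 60)
  mask[11:110, 16:45] <- TRUE # 100 rows x 30 cols
  edges <- extract_edges(mask)
  expect_s3_class(edges, "edge_groups")
  expect_equal(nrow(edges$left), nrow(edges$right))
  expect_true(abs(nrow(edges$left) - 100) <= 4)
  expect_true(abs(nrow(edges$top) - 30) <= 4)
  # exact partition of the boundary pixel set
  n_boundary <- 2 * 100 + 2 * 30 - 4
  all_pts <- dplyr::bind_rows(edges$left, edges$right, edges$top, edges$bottom)
  expect_equal(nrow(all_pts), n_boundary)
  expect_equal(nrow(dplyr::distinct(all_pts)), n_boundary)
})

test_that("edge extraction partitions a rotated silhouette with no orphans", {
  # rectangle rotated by 5 degrees, built from coordinates
  th <- 5 * pi / 180
  mask <- matrix(FALSE, 140, 80)
  ctr <- c(70, 40)
  for (r in 1:140) {
    for (co in 1:80) {
      u <- cos(th) * (r - ctr[1]) + sin(th) * (co - ctr[2])
      v <- -sin(th) * (r - ctr[1]) + cos(th) * (co - ctr[2])
      mask[r, co] <- abs(u) <= 50 && abs(v) <= 15
    }
  }
  edges <- extract_edges(mask)
  groups <- dplyr::bind_rows(edges$left, edges$right, edges$top, edges$bottom)
  # recompute the boundary independently
  pad <- matrix(FALSE, 142, 82)
  pad[2:141, 2:81] <- mask
  interior <- pad[1:140, 2:81] & pad[3:142, 2:81] &
    pad[2:141, 1:80] & pad[2:141, 3:82]
  want <- which(mask & !interior, arr.ind = TRUE)
  expect_equal(nrow(groups), nrow(want))
  expect_equal(nrow(dplyr::distinct(groups)), nrow(want))
  expect_true(all(nrow(edges$left) > 0, nrow(edges$right) > 0))

  expect_error(extract_edges(matrix(FALSE, 5, 5)), "foreground")
  lone <- matrix(FALSE, 9, 9)
  lone[5, 5] <- TRUE
  expect_error(extract_edges(lone), "degenerate")
})

test_that("width tracking measures rendered specimens to pixel accuracy", {
  # 100 px wide rectangle at 0.1 mm/px reads 10.0 mm
  g10 <- specimen_geometry("circ", width_mm = 10)
  fr <- render_frame(g10, 1, scale_mm_px = 0.1, noise_sd = 0)
  series <- track_width(list(fr))
  expect_equal(series$min_width_mm, 10.0, tolerance = 0.1)
  expect_equal(series$extension_mm, 0)

  # identical frames give identical series rows
  two <- track_width(list(fr, fr))
  expect_equal(two$min_width_mm[1], two$min_width_mm[2])

  # a waisted (necked) specimen reports the neck width: carve both flanks
  # inward over a band of central rows
  px <- fr$pixels
  neck_rows <- 150:170
  px[neck_rows, 1:95] <- 0.15
  px[neck_rows, 156:ncol(px)] <- 0.15
  waisted <- tissue_frame(px, 0.1)
  expect_equal(track_width(list(waisted))$min_width_mm, 6.0, tolerance = 0.02)
})

test_that("tracked width stays within 2 px of ground truth under noise", {
  # a reduced randomized sweep; the full 50-case sweep runs in the
  # acceptance suite
  withr::with_seed(99, {
    for (i in 1:10) {
      g <- specimen_geometry("circ",
        width_mm = runif(1, 7, 13),
        gauge_length_mm = runif(1, 15, 25)
      )
      stretch <- runif(1, 1, 1.2)
      fr <- render_frame(g, stretch,
        scale_mm_px = 0.1,
        noise_sd = runif(1, 0, 0.08), seed = i
      )
      got <- track_width(list(fr))$min_width_mm
      expect_lte(abs(got - attr(fr, "truth")$width_mm), 2 * 0.1)
    }
  })
})
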
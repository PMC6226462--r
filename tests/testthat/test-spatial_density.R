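make_map <- function(cells, width = 1000, height = 1000, border_x = NULL) {
  border <- if (!is.null(border_x))
    data.frame(x_um = c(border_x, border_x), y_um = c(0, height))
  cell_map(cells, c(0, width, 0, height), border = border, tumor_side = 1)
}

uniform_cells <- function(n, width = 1000, height = 1000, seed = 1) {
  set.seed(seed)
  data.frame(x_um = runif(n, 0, width), y_um = runif(n, 0, height),
             neun = 1L, pv = 0L, wfa = 0L)
}

test_that("grid labelling: sham has no border, vertical border geometry", {
  sham <- make_map(uniform_cells(100))
  g <- grid_boxes(sham)
  expect_true(all(g$label == "parenchyma"))
  expect_equal(nrow(g), 100)

  m <- make_map(uniform_cells(100), border_x = 450)
  g2 <- grid_boxes(m)
  expect_equal(sum(g2$label == "border"), 10)   # one 10-box column band
  expect_true(all(g2$x0[g2$label == "border"] == 400))
  expect_true(all(g2$label[g2$x0 < 400] == "tumor"))
  # first parenchymal column sits one box step away -> 0.1 mm -> first bin
  first_col <- g2[g2$x0 == 500, ]
  expect_true(all(first_col$steps == 1))
  expect_equal(unique(first_col$dist_mm), 0.1)
  next_col <- g2[g2$x0 == 600, ]
  expect_true(all(next_col$steps == 2))
  expect_error(grid_boxes(make_map(uniform_cells(10), border_x = 2000)),
               "bounds|border")
})

test_that("box counts partition the cells exactly (no double counting)", {
  m <- make_map(uniform_cells(500, seed = 3), border_x = 450)
  g <- box_counts(m, grid_boxes(m), "neun")
  expect_equal(sum(g$count), 500L)
  # boundary cells obey the half-open convention
  cells <- data.frame(x_um = c(100, 99.999), y_um = c(50, 50),
                      neun = 1L, pv = 0L, wfa = 0L)
  m2 <- make_map(cells)
  g2 <- box_counts(m2, grid_boxes(m2), "neun")
  expect_equal(g2$count[g2$x0 == 100 & g2$y0 == 0], 1L)
  expect_equal(g2$count[g2$x0 == 0 & g2$y0 == 0], 1L)
})

test_that("homogeneous fields give unbiased densities within Poisson error", {
  m <- gen_cell_map("sham_map", seed = 5)
  g <- grid_boxes(m)
  d <- density_per_bin(m, g, "neun")
  expect_equal(d$bin, "overall")
  sigma <- sqrt(26.12 / d$n_boxes)
  expect_lt(abs(d$mean_density - 26.12), 3 * sigma)

  # near-unbiasedness over seeds
  dens <- vapply(1:100, function(s) {
    mm <- gen_cell_map("sham_map", seed = s)
    density_per_bin(mm, grid_boxes(mm), "neun")$mean_density
  }, numeric(1))
  expect_lt(abs(mean(dens) - 26.12) / 26.12, 0.01)
})

test_that("implanted maps recover the planted density gradient per bin", {
  m <- gen_cell_map("gbm22_map", seed = 8)
  g <- grid_boxes(m)
  truth <- attr(m, "truth")
  for (mk in c("neun", "pv")) {
    d <- density_per_bin(m, g, mk)
    expect_equal(nrow(d), 3)
    lam <- truth$intensities[[mk]]
    for (b in 1:3) {
      sigma <- sqrt(lam[b] / d$n_boxes[b])
      expect_lt(abs(d$mean_density[b] - lam[b]), 3 * sigma + 1e-9)
    }
  }
  # PV is a subset of NeuN, so PV density can never exceed NeuN density
  dn <- density_per_bin(m, g, "neun")
  dp <- density_per_bin(m, g, "pv")
  expect_true(all(dp$mean_density <= dn$mean_density))
  expect_true(all(m$cells$neun[m$cells$pv == 1] == 1))
})

test_that("subsampling boxes is seeded and bounded", {
  m <- gen_cell_map("gbm22_map", seed = 2)
  g <- grid_boxes(m)
  d1 <- density_per_bin(m, g, "neun", subsample = 4, seed = 11)
  d2 <- density_per_bin(m, g, "neun", subsample = 4, seed = 11)
  expect_identical(d1, d2)
  expect_true(all(d1$n_boxes == 4))
})

test_that("sham normalization: identity, linearity, degenerate sham", {
  m <- gen_cell_map("gbm22_map", seed = 4)
  g <- grid_boxes(m)
  d <- density_per_bin(m, g, "pv")
  self <- d
  norm_self <- normalize_to_sham(self, self)
  expect_equal(norm_self$pct_of_sham, rep(100, 3))

  sham <- gen_cell_map("sham_map", seed = 4)
  ds <- density_per_bin(sham, grid_boxes(sham), "pv")
  halved <- ds
  halved$mean_density <- ds$mean_density / 2
  expect_equal(normalize_to_sham(halved, ds)$pct_of_sham, 50)

  zero <- ds; zero$mean_density <- 0
  expect_error(normalize_to_sham(ds, zero), "zero")
  dn <- density_per_bin(sham, grid_boxes(sham), "neun")
  expect_error(normalize_to_sham(d, dn), "marker")
})

test_that("empty maps yield zero densities", {
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      neun = integer(0), pv = integer(0), wfa = integer(0))
  m <- make_map(empty, border_x = 450)
  d <- density_per_bin(m, grid_boxes(m), "neun")
  expect_true(all(d$mean_density == 0))
})
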
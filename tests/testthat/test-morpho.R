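test_that("biovolume formulas match their closed forms and agree at the limit", {
  expect_equal(cell_volume(1.0, 1.0, "sphere"), pi / 6)
  expect_equal(cell_volume(0.92, 0.28, "rod"),
               pi / 4 * 0.28^2 * (0.92 - 0.28 / 3))
  # the rod formula degenerates continuously to the sphere at l = w
  w <- 0.7
  expect_equal(cell_volume(w, w, "rod"), cell_volume(w, w, "sphere"))
  expect_error(cell_volume(0.5, 0.8, "rod"), "width")
  expect_error(cell_volume(-1, 1, "sphere"), "positive")
})

test_that("volume grows with each dimension and scales as the cube", {
  expect_gt(cell_volume(1.2, 0.3, "rod"), cell_volume(1.0, 0.3, "rod"))
  expect_gt(cell_volume(1.0, 0.4, "rod"), cell_volume(1.0, 0.3, "rod"))
  c3 <- 1.7^3
  expect_equal(cell_volume(1.7 * 1.0, 1.7 * 0.3, "rod"),
               c3 * cell_volume(1.0, 0.3, "rod"))
})

test_that("population percentiles use linear order-statistic interpolation", {
  cells <- data.frame(cell_id = sprintf("c%03d", 1:100), population = "p",
                      shape = "sphere",
                      length_um = (6 / pi * (1:100))^(1 / 3),
                      width_um = (6 / pi * (1:100))^(1 / 3))
  s <- population_summary(cells, "p")
  expect_equal(s$volume_p5, 5.95, tolerance = 1e-6)
  expect_equal(s$volume_median, 50.5, tolerance = 1e-6)
  expect_equal(s$volume_p95, 95.05, tolerance = 1e-6)
  # a single cell: all percentiles equal its volume
  one <- population_summary(cells[1, ], "p")
  expect_equal(one$volume_p5, one$volume_median)
  expect_equal(one$volume_median, one$volume_p95)
  # row order is irrelevant
  set.seed(101)
  s2 <- population_summary(cells[sample(100), ], "p")
  expect_equal(s2[c("volume_p5", "volume_median", "volume_p95")],
               s[c("volume_p5", "volume_median", "volume_p95")])
  # empty population is an explicit empty result
  expect_equal(population_summary(cells, "nope")$n, 0L)
})

test_that("an all-focal table gives 100/100 and ratio 1", {
  cells <- data.frame(cell_id = c("a", "b"), population = "f",
                      shape = "sphere", length_um = c(0.5, 0.7),
                      width_um = c(0.5, 0.7))
  bm <- biomass_share(cells, "f")
  expect_equal(bm$abundance_pct, 100)
  expect_equal(bm$biomass_pct, 100)
  expect_equal(bm$ratio, 1)
})

test_that("large focal spheres at 10% abundance reach ~20% of biomass", {
  cells <- rbind(
    data.frame(cell_id = sprintf("f%03d", 1:100), population = "focal",
               shape = "sphere", length_um = 0.52416, width_um = 0.52416),
    data.frame(cell_id = sprintf("b%03d", 1:900), population = "background",
               shape = "sphere", length_um = 0.40, width_um = 0.40))
  bm <- biomass_share(cells, "focal")
  expect_equal(bm$abundance_pct, 10)
  expect_equal(round(bm$ratio, 2), 2.0)
  expect_equal(round(bm$biomass_pct), 20)
})

test_that("the ratio identity holds on arbitrary tables", {
  set.seed(102)
  for (k in 1:10) {
    n <- sample(20:60, 1)
    cells <- data.frame(cell_id = sprintf("c%03d", seq_len(n)),
                        population = sample(c("f", "x", "y"), n, TRUE,
                                            prob = c(0.3, 0.4, 0.3)),
                        shape = sample(c("rod", "sphere"), n, TRUE),
                        length_um = runif(n, 0.4, 1.6))
    cells$width_um <- ifelse(cells$shape == "sphere", cells$length_um,
                             cells$length_um * runif(n, 0.2, 0.9))
    if (!any(cells$population == "f")) cells$population[1] <- "f"
    bm <- biomass_share(cells, "f")
    v <- cell_volume(cells$length_um, cells$width_um, cells$shape)
    expect_equal(bm$ratio, mean(v[cells$population == "f"]) / mean(v))
    expect_equal(bm$ratio * bm$abundance_pct, bm$biomass_pct)
    # percentiles are ordered
    expect_true(bm$focal$volume_p5 <= bm$focal$volume_median)
    expect_true(bm$focal$volume_median <= bm$focal$volume_p95)
    # rescaling all dimensions leaves shares and ratio unchanged
    scaled <- cells
    scaled$length_um <- 2 * scaled$length_um
    scaled$width_um <- 2 * scaled$width_um
    bm2 <- biomass_share(scaled, "f")
    expect_equal(bm2$ratio, bm$ratio)
    expect_equal(bm2$biomass_pct, bm$biomass_pct)
    expect_equal(bm2$focal$volume_median, 8 * bm$focal$volume_median)
  }
})
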
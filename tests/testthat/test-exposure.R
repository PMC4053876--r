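two_cell_fixture <- function(pm_vals = c(10, 100), pop_vals = c(3, 1)) {
  tr <- grid_transform(0, 1, 1)
  list(pm = grid_field(matrix(pm_vals, 1), transform = tr),
       pop = grid_field(matrix(pop_vals, 1), transform = tr),
       zones = zone_mask(matrix(c(1L, 1L), 1), transform = tr))
}

random_fixture <- function(seed, rows = 12, cols = 12, n_zones = 3) {
  withr::with_seed(seed, {
    tr <- grid_transform(0, rows, 1)
    pm <- grid_field(matrix(stats::runif(rows * cols, 5, 150), rows),
                     transform = tr)
    pop <- grid_field(matrix(stats::rlnorm(rows * cols, 3, 1), rows),
                      transform = tr)
    labels <- matrix(sample.int(n_zones, rows * cols, replace = TRUE), rows)
    list(pm = pm, pop = pop,
         zones = zone_mask(matrix(as.integer(labels), rows),
                           transform = tr))
  })
}

test_that("hand-computed two-cell examples reproduce exactly", {
  fx <- two_cell_fixture()
  expect_equal(pw_pm25(fx$pm, fx$pop, fx$zones)$pw_pm25, 32.5)
  expect_equal(pc_pm25(fx$pm, fx$pop, fx$zones)$pc_pm25, 65)
  expect_equal(pc_pm25(fx$pm, fx$pop, fx$zones,
                       form = "simple_mean")$pc_pm25, 55)
})

test_that("degenerate weighting patterns behave as weighted means must", {
  # uniform PM: PW equals the constant regardless of population
  fx <- two_cell_fixture(pm_vals = c(42, 42), pop_vals = c(9, 1))
  expect_equal(pw_pm25(fx$pm, fx$pop, fx$zones)$pw_pm25, 42)
  # all population in one cell: PW is that cell's PM
  fx2 <- two_cell_fixture(pm_vals = c(10, 100), pop_vals = c(0, 7))
  expect_equal(pw_pm25(fx2$pm, fx2$pop, fx2$zones)$pw_pm25, 100)
  # zero population everywhere: PC is 0, PW undefined (never 0)
  fx3 <- two_cell_fixture(pop_vals = c(0, 0))
  expect_warning(res <- zonal_report(fx3$pm, fx3$pop, fx3$zones),
                 "zero population")
  expect_equal(res$pc_pm25, 0)
  expect_true(is.na(res$pw_pm25))
})

test_that("PW is population-scale invariant and PC population-linear", {
  fx <- random_fixture(5)
  base <- zonal_report(fx$pm, fx$pop, fx$zones)
  pop2 <- grid_field(fx$pop$values * 2, transform = fx$pop$transform)
  doubled <- zonal_report(fx$pm, pop2, fx$zones)
  expect_equal(doubled$pw_pm25, base$pw_pm25)
  expect_equal(doubled$pc_pm25, 2 * base$pc_pm25)
  expect_equal(doubled$total_population, 2 * base$total_population)
})

test_that("PW stays within the zone's PM range and merges between zones", {
  fx <- random_fixture(6)
  rep <- zonal_report(fx$pm, fx$pop, fx$zones)
  for (z in rep$zone) {
    in_zone <- fx$zones$labels == z
    expect_gte(rep$pw_pm25[rep$zone == z], min(fx$pm$values[in_zone]))
    expect_lte(rep$pw_pm25[rep$zone == z], max(fx$pm$values[in_zone]))
  }
  # merging zones 1 and 2 lands between their PW values
  merged_labels <- fx$zones$labels
  merged_labels[merged_labels == 2L] <- 1L
  merged <- zone_mask(merged_labels, transform = fx$zones$transform)
  pw_m <- pw_pm25(fx$pm, fx$pop, merged)
  pw12 <- rep$pw_pm25[rep$zone %in% 1:2]
  expect_gte(pw_m$pw_pm25[pw_m$zone == 1], min(pw12))
  expect_lte(pw_m$pw_pm25[pw_m$zone == 1], max(pw12))
})

test_that("uniform population reduces PW to the plain zonal mean", {
  fx <- random_fixture(8)
  upop <- grid_field(matrix(7, 12, 12), transform = fx$pop$transform)
  rep <- pw_pm25(fx$pm, upop, fx$zones)
  for (z in rep$zone) {
    expect_equal(rep$pw_pm25[rep$zone == z],
                 mean(fx$pm$values[fx$zones$labels == z]),
                 tolerance = 1e-12)
  }
})

test_that("masked cells are excluded and label permutation only relabels", {
  fx <- random_fixture(9)
  m <- matrix(TRUE, 12, 12); m[1, ] <- FALSE
  pm_m <- grid_field(fx$pm$values, mask = m, transform = fx$pm$transform)
  rep <- zonal_report(pm_m, fx$pop, fx$zones)
  expect_equal(sum(rep$n_valid_cells), sum(m & fx$zones$labels > 0))
  # permute labels 1<->3
  perm <- fx$zones$labels
  perm[fx$zones$labels == 1L] <- 3L
  perm[fx$zones$labels == 3L] <- 1L
  zp <- zone_mask(perm, transform = fx$zones$transform)
  rep_a <- zonal_report(fx$pm, fx$pop, fx$zones)
  rep_b <- zonal_report(fx$pm, fx$pop, zp)
  expect_equal(rep_b$pw_pm25[rep_b$zone == 3],
               rep_a$pw_pm25[rep_a$zone == 1])
  expect_equal(rep_b$pc_pm25[rep_b$zone == 1],
               rep_a$pc_pm25[rep_a$zone == 3])
})

test_that("a dense high-PM zone ranks first on population-weighted exposure", {
  tr <- grid_transform(0, 4, 1)
  pm <- grid_field(matrix(c(rep(150, 8), rep(20, 8)), 4, byrow = TRUE),
                   transform = tr)
  pop <- grid_field(matrix(c(rep(1000, 8), rep(10, 8)), 4, byrow = TRUE),
                    transform = tr)
  zones <- zone_mask(matrix(c(rep(1L, 8), rep(2L, 8)), 4, byrow = TRUE),
                     transform = tr)
  rep <- zonal_report(pm, pop, zones)
  expect_equal(rep$rank_pw[rep$zone == 1], 1)
  expect_equal(rep$rank_pc[rep$zone == 1], 1)
})

test_that("density rasters convert to counts with latitude-dependent area", {
  d <- grid_field(matrix(1, 2, 2), transform = grid_transform(100, 60, 1))
  cnt <- density_to_count(d)
  # all-ones density: counts equal cell areas; higher latitude -> smaller
  expect_true(all(cnt$values[1, ] < cnt$values[2, ]))
  expect_equal(cnt$units, "persons/cell")
})
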
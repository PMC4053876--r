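test_that("breakpoint tables validate their ladder", {
  expect_error(breakpoint_table("x", c(0, 10), c(5, 50)), "\\(0, 0\\)")
  expect_error(breakpoint_table("x", c(0, 10, 10), c(0, 50, 100)),
               "strictly increasing")
  expect_error(breakpoint_table("x", 0, 0), "at least 2")
  tb <- default_breakpoints("PM2.5")
  expect_equal(attr(tb, "cap_index"), 500)
  path <- withr::local_tempfile(fileext = ".json")
  write_breakpoints(tb, path)
  tb2 <- read_breakpoints(path)
  expect_equal(tb2$concentration, tb$concentration)
  expect_equal(attr(tb2, "pollutant"), "PM2.5")
})

test_that("iaqi hits every breakpoint node exactly and interpolates midpoints", {
  for (poll in c("PM2.5", "PM10")) {
    tb <- default_breakpoints(poll)
    expect_equal(iaqi(tb$concentration, tb), tb$index, info = poll)
    mids <- (head(tb$concentration, -1) + tail(tb$concentration, -1)) / 2
    mid_idx <- (head(tb$index, -1) + tail(tb$index, -1)) / 2
    expect_equal(iaqi(mids, tb), mid_idx, info = poll)
  }
  tb <- default_breakpoints("PM2.5")
  expect_equal(iaqi(0, tb), 0)
  expect_equal(iaqi(700, tb), 500) # beyond the table: capped
  expect_equal(iaqi(54.9, tb, integer_ceiling = TRUE),
               ceiling(iaqi(54.9, tb)))
  expect_error(iaqi(-1, tb), "non-negative")
})

test_that("iaqi is continuous and non-decreasing over the table range", {
  tb <- default_breakpoints("PM10")
  x <- seq(0, 600, by = 0.1)
  v <- iaqi(x, tb)
  expect_true(all(diff(v) >= 0))
  expect_lt(max(abs(diff(v))), 1.1 * 0.1 * max(diff(tb$index) /
                                                 diff(tb$concentration)))
})

test_that("raw weights are index shares on the simplex", {
  expect_equal(raw_weights(c(100, 100)), c(0.5, 0.5))
  expect_equal(raw_weights(c(300, 100)), c(0.75, 0.25))
  expect_equal(raw_weights(c(100, 0)), c(1, 0))
  expect_error(raw_weights(c(0, 0)), "all individual indexes are zero")
  expect_error(raw_weights(c(-1, 2)), "non-negative")
})

test_that("extreme-value modification truncates only dominance configurations", {
  even <- modify_weights(c(0.5, 0.5))
  expect_equal(even$P, c(0.5, 0.5))
  expect_equal(c(even$s, even$t), c(0L, 0L))
  dust <- modify_weights(c(0.96, 0.04))
  expect_equal(dust$P, c(1, 0))
  expect_equal(c(dust$s, dust$t), c(1L, 1L))
  skew <- modify_weights(c(0.7, 0.3))
  expect_equal(skew$P, c(0.7, 0.3)) # t = 1 but s = 0: unchanged
  expect_equal(c(skew$s, skew$t), c(0L, 1L))
  expect_error(modify_weights(c(0.5, 0.4)), "sum to 1")
  # idempotence over random simplex draws
  withr::with_seed(99, {
    for (i in 1:50) {
      k <- sample(2:4, 1)
      Q <- raw_weights(stats::runif(k, 0, 500))
      P1 <- modify_weights(Q)$P
      expect_equal(modify_weights(P1)$P, P1)
    }
  })
})

test_that("the composite index composes weights and indexes", {
  expect_equal(paqi(c(150, 150))$paqi, 150)
  expect_equal(paqi(c(300, 100))$paqi, 250)
  b <- paqi(c(480, 20))
  expect_equal(b$Q, c(0.96, 0.04))
  expect_equal(b$paqi, 480)
  td <- tidy(paqi(c(PM10 = 300, PM2.5 = 100)))
  expect_equal(td$pollutant, c("PM10", "PM2.5"))
  expect_equal(td$Q, c(0.75, 0.25))
  expect_equal(glance(b)$s, 1L)
  expect_error(paqi(150), "at least 2")
})

test_that("composite index properties hold over random draws", {
  withr::with_seed(7, {
    for (i in 1:500) {
      k <- sample(2:4, 1)
      I <- stats::runif(k, 1, 500)
      b <- paqi(I)
      expect_gte(b$paqi, min(I))
      expect_lte(b$paqi, max(I))
      expect_equal(sum(b$P), 1)
      perm <- sample(k)
      expect_equal(paqi(I[perm])$paqi, b$paqi)
      if (b$s == 0 || b$t == 0) { # unmodified: mean-square identity
        expect_equal(b$paqi, sum(I^2) / sum(I))
        expect_gte(b$paqi, mean(I))
      }
    }
  })
})

test_that("gridded composite equals the scalar operation cell by cell", {
  withr::with_seed(15, {
    i10 <- matrix(stats::runif(100, 0, 500), 10, 10)
    i25 <- matrix(stats::runif(100, 0, 500), 10, 10)
  })
  m <- matrix(TRUE, 10, 10); m[3, 7] <- FALSE
  f10 <- make_field(i10)
  f25 <- grid_field(i25, mask = m, transform = unit_transform(10))
  out <- paqi_grid(list(PM10 = f10, PM2.5 = f25))
  for (i in 1:10) for (j in 1:10) {
    if (i == 3 && j == 7) {
      expect_false(out$mask[i, j])
    } else {
      expect_equal(out$values[i, j], paqi(c(i10[i, j], i25[i, j]))$paqi)
    }
  }
  # constant equal inputs pass through
  cst <- paqi_grid(list(a = make_field(matrix(150, 4, 4)),
                        b = make_field(matrix(150, 4, 4))))
  expect_true(all(cst$values == 150))
  expect_error(paqi_grid(list(f10)), "at least 2")
})

test_that("classification uses half-open categories with severity ordered", {
  expect_equal(as.character(classify(0)), "excellent")
  expect_equal(as.character(classify(150)), "moderately polluted")
  expect_equal(as.character(classify(200)), "heavily polluted")
  expect_equal(as.character(classify(199.99)), "moderately polluted")
  labs <- classify(0:500)
  expect_true(!is.unsorted(labs)) # non-decreasing severity
  expect_error(classify(-5), "non-negative")
})
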
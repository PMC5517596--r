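test_that("trapezoid reproduces the fitted threshold semantics", {
  # temperature trapezoid 10/18/30/35
  expect_equal(trapezoid(24, 10, 18, 30, 35), 1)
  expect_equal(trapezoid(14, 10, 18, 30, 35), 0.5)
  expect_equal(trapezoid(35, 10, 18, 30, 35), 0)
  expect_equal(trapezoid(10, 10, 18, 30, 35), 0)
  expect_equal(trapezoid(32.5, 10, 18, 30, 35), 0.5)
  # moisture trapezoid 0.1/0.7/0.9/1.3
  expect_equal(trapezoid(0.8, 0.1, 0.7, 0.9, 1.3), 1)
  expect_equal(trapezoid(0.4, 0.1, 0.7, 0.9, 1.3), 0.5)
  expect_equal(trapezoid(1.3, 0.1, 0.7, 0.9, 1.3), 0)
  expect_error(trapezoid(1, 5, 4, 6, 7), "a < b")
})

test_that("temperature index is the trapezoid applied pointwise", {
  w <- weekly_series(tmin = rep(19, 52), tmax = rep(29, 52))
  expect_equal(temperature_index(w), rep(1, 52))
  w <- weekly_series(tmin = rep(3, 52), tmax = rep(13, 52))   # tavg 8
  expect_equal(temperature_index(w), rep(0, 52))
  # sinusoidal year: pointwise oracle
  tavg <- 20 + 10 * sin(2 * pi * (1:52) / 52)
  w <- weekly_series(tmin = tavg - 5, tmax = tavg + 5)
  ti <- temperature_index(w)
  expect_equal(ti, vapply(tavg, oracle_trap, numeric(1), 10, 18, 30, 35))
})

test_that("moisture index thresholds", {
  expect_equal(moisture_index(sm_trace(rep(0.8, 52))), rep(1, 52))
  expect_equal(moisture_index(sm_trace(rep(0.4, 52))), rep(0.5, 52))
  expect_equal(moisture_index(sm_trace(rep(1.3, 52))), rep(0, 52))
  bad <- sm_trace(rep(0.5, 52)); bad$converged <- FALSE
  expect_warning(moisture_index(bad), "non-converged")
})

test_that("annual growth index integrates TI * MI", {
  expect_equal(annual_growth_index(rep(1, 52), rep(1, 52)), 100)
  expect_equal(annual_growth_index(rep(1, 52), rep(0, 52)), 0)
  expect_equal(annual_growth_index(rep(1, 52),
                                   c(rep(1, 26), rep(0, 26))), 50)
})

test_that("stress accumulation: exceedance, compounding and cap", {
  # no week beyond threshold
  expect_equal(accumulate_stress(rep(10, 52), 7, -0.00007, "below"), 0)
  # single cold week, exceedance 1: one-term sum
  v <- rep(10, 52); v[20] <- 6
  expect_equal(accumulate_stress(v, 7, -0.00007, "below"),
               100 * 0.00007 * 1 * 1)
  # 10 consecutive heat weeks at exceedance 5: arithmetic series, capped
  v <- rep(35, 52); v[11:20] <- 45
  expect_equal(accumulate_stress(v, 40, 0.01, "above"),
               min(100, 100 * 0.01 * 5 * sum(1:10)))
  # same run shorter so the cap does not bind: 4 weeks
  v <- rep(35, 52); v[11:14] <- 45
  expect_equal(accumulate_stress(v, 40, 0.01, "above"),
               100 * 0.01 * 5 * (1 + 2 + 3 + 4))
})

test_that("stress runs wrap across the year boundary", {
  # stressed weeks 51, 52, 1, 2: counts must be 1,2,3,4 across the wrap
  v <- rep(45, 52); v[c(51, 52, 1, 2)] <- 30
  s_wrap <- accumulate_stress(v, 40, 0.001, "below")
  expect_equal(s_wrap, 100 * 0.001 * 10 * (3 + 4 + 1 + 2))
  # identical run in mid-year gives the same accumulation
  v2 <- rep(45, 52); v2[21:24] <- 30
  expect_equal(accumulate_stress(v2, 40, 0.001, "below"), s_wrap)
})

test_that("linear accumulation drops the consecutive-week compounding", {
  v <- rep(35, 52); v[11:14] <- 45
  expect_equal(accumulate_stress(v, 40, 0.01, "above", "linear"),
               100 * 0.01 * 5 * 4)
})

test_that("stress is monotone in exceedance and run length", {
  set.seed(21)
  for (i in 1:10) {
    v <- runif(52, 20, 45)
    s0 <- accumulate_stress(v, 40, 0.01, "above")
    s1 <- accumulate_stress(v + runif(52, 0, 3), 40, 0.01, "above")
    expect_gte(s1, s0)
  }
  base <- rep(35, 52)
  s <- vapply(1:12, function(k) {
    v <- base; v[1:k] <- 42
    accumulate_stress(v, 40, 0.01, "above")
  }, numeric(1))
  expect_true(all(diff(s) >= 0))
})

test_that("EI combines growth and stress per the index equation", {
  p <- maize_parameters()
  # ideal year: TI = MI = 1, no stress -> EI = 100
  w <- weekly_series(tmin = rep(19, 52), tmax = rep(29, 52))
  r <- compute_ei(w, sm_trace(rep(0.8, 52)), p)
  expect_equal(r$gi_a, 100)
  expect_equal(r$ei, 100)
  expect_equal(as.character(r$category), "optimal")
  expect_equal(c(r$cs, r$hs, r$ds, r$ws), rep(0, 4))

  # GI_A = 80 (MI = 0.8), CS = 50 via one cold week at a rate of 0.5
  pc <- maize_parameters(thcs = -0.5)
  tmin <- rep(19, 52); tmin[10] <- 6   # exceedance 1 below TTCS = 7
  tmax <- rep(29, 52); tmax[10] <- 30  # keeps tavg on the optimal plateau
  w <- weekly_series(tmin = tmin, tmax = tmax)
  r <- compute_ei(w, sm_trace(rep(0.58, 52)), pc)
  expect_equal(r$gi_a, 80)
  expect_equal(r$cs, 50)
  expect_equal(r$ei, 40)

  # any stress at 100 forces EI = 0, category unsuitable
  # (tavg 15.5 degC still grows, so GI alone would allow persistence)
  w <- weekly_series(tmin = rep(2, 52), tmax = rep(29, 52))
  r <- compute_ei(w, sm_trace(rep(0.8, 52)), p)
  expect_equal(r$cs, 100)
  expect_equal(r$ei, 0)
  expect_equal(as.character(r$category), "unsuitable")
  expect_gt(r$gi_a, 0)          # growth alone would have allowed persistence
  expect_lte(r$ei, r$gi_a)
})

test_that("EI is non-increasing in each stress, holding others fixed", {
  # drive CS up progressively via colder single weeks at a large rate
  p <- maize_parameters(thcs = -0.05)
  ei <- vapply(seq(0, 10, by = 2), function(drop) {
    tmin <- rep(19, 52); tmin[5] <- 7 - drop
    r <- compute_ei(weekly_series(tmin = tmin, tmax = rep(29, 52)),
                    sm_trace(rep(0.8, 52)), p)
    r$ei
  }, numeric(1))
  expect_true(all(diff(ei) <= 0))
})

test_that("classification bins are left-open right-closed", {
  expect_equal(as.character(classify_ei(0)), "unsuitable")
  expect_equal(as.character(classify_ei(0.5)), "marginal")  # (0,1) folded in
  expect_equal(as.character(classify_ei(10)), "marginal")
  expect_equal(as.character(classify_ei(10.001)), "medium")
  expect_equal(as.character(classify_ei(20)), "medium")
  expect_equal(as.character(classify_ei(20.5)), "optimal")
  expect_true(is.na(classify_ei(NA)))
  expect_error(classify_ei(-1), "0, 100")
  expect_error(classify_ei(101), "0, 100")
})

test_that("run_grid on one cell equals the single-cell pipeline", {
  set.seed(22)
  cell <- random_cell()
  g <- grid_from_cells(list(cell))
  res <- run_grid(g)
  w <- monthly_to_weekly(cell$tmin, cell$tmax, cell$precip,
                         cell$rh09, cell$rh15)
  tr <- suppressWarnings(run_bucket(w))
  r <- compute_ei(w, tr)
  expect_equal(res$ei[1, 1], r$ei, tolerance = 1e-12)
  expect_equal(res$gi_a[1, 1], r$gi_a, tolerance = 1e-12)
  expect_equal(res$cs[1, 1], r$cs, tolerance = 1e-12)
  expect_equal(res$ws[1, 1], r$ws, tolerance = 1e-12)
})

test_that("vectorized grid equals the straight-loop oracle", {
  set.seed(23)
  cells <- replicate(50, random_cell(), simplify = FALSE)
  g <- grid_from_cells(cells)
  res <- run_grid(g)
  for (i in seq_along(cells)) {
    ref <- do.call(oracle_cell, cells[[i]])
    expect_equal(res$ei[1, i], ref$ei, tolerance = 1e-9)
    expect_equal(res$gi_a[1, i], ref$gi_a, tolerance = 1e-9)
    for (s in c("cs", "hs", "ds", "ws"))
      expect_equal(res[[s]][1, i], ref[[s]], tolerance = 1e-9)
  }
})

test_that("run_grid masks and bounds", {
  set.seed(24)
  g <- uniform_grid(random_cell(), nlat = 3, nlon = 3)
  mask <- g$land_mask; mask[2, 2] <- FALSE
  g <- climate_grid(g$lons, g$lats, g$tmin, g$tmax, g$precip, g$rh09,
                    g$rh15, land_mask = mask)
  res <- run_grid(g)
  expect_true(is.na(res$ei[2, 2]))
  expect_true(all(is.na(res$category[2, 2])))
  vals <- res$ei[!is.na(res$ei)]
  expect_true(all(vals >= 0 & vals <= 100))
  # determinism
  res2 <- run_grid(g)
  expect_equal(res$ei, res2$ei)
})

test_that("constructed polar and hyperarid bands are excluded", {
  # polar: tavg below freezing all year -> CS = 100
  polar <- list(tmin = rep(-25, 12), tmax = rep(-15, 12),
                precip = rep(30, 12), rh09 = rep(0.8, 12),
                rh15 = rep(0.7, 12))
  # hyperarid: warm, zero precipitation -> DS = 100, MI = 0
  arid <- list(tmin = rep(20, 12), tmax = rep(34, 12),
               precip = rep(0, 12), rh09 = rep(0.3, 12),
               rh15 = rep(0.1, 12))
  g <- grid_from_cells(list(polar, arid))
  res <- run_grid(g)
  expect_equal(res$cs[1, 1], 100)
  expect_equal(res$ei[1, 1], 0)
  expect_equal(res$ds[1, 2], 100)
  expect_equal(res$ei[1, 2], 0)
})
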
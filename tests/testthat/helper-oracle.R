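# Independent straight-loop single-cell oracle. Everything here is scalar
# code written directly from the model definition: its own cyclic
# interpolation, weekly precipitation split, bucket recursion, trapezoid
# and stress loop. It shares no code path with the vectorized package
# implementation it is used to check.

oracle_interp12 <- function(v) {
  mm <- ((1:12) - 0.5) * 364 / 12
  out <- numeric(52)
  for (i in 1:52) {
    t <- 3.5 + 7 * (i - 1)
    j <- findInterval(t, mm)
    if (j == 0) { j <- 12; t <- t + 364 }
    jn <- if (j == 12) 1 else j + 1
    x1 <- mm[j]
    x2 <- if (j == 12) mm[1] + 364 else mm[jn]
    w <- (t - x1) / (x2 - x1)
    out[i] <- (1 - w) * v[j] + w * v[jn]
  }
  out
}

oracle_precip_weekly <- function(p_monthly) {
  dpm <- 364 / 12
  day_month <- floor(((0:363) + 0.5) / dpm) + 1
  month_len <- tabulate(day_month, nbins = 12)
  rate <- p_monthly[day_month] / month_len[day_month]
  out <- numeric(52)
  for (k in 1:52) out[k] <- sum(rate[((k - 1) * 7 + 1):(k * 7)])
  out
}

oracle_bucket <- function(precip_w, et_w, capacity = 100, cap = 2,
                          tol = 1e-6, max_years = 50, sm0 = 0.5) {
  sm <- numeric(52)
  prev <- rep(Inf, 52)
  state <- sm0
  for (y in 1:max_years) {
    for (w in 1:52) {
      state <- state + (precip_w[w] - et_w[w]) / capacity
      if (state < 0) state <- 0
      if (state > cap) state <- cap
      sm[w] <- state
    }
    if (max(abs(sm - prev)) < tol) return(list(sm = sm, converged = TRUE))
    prev <- sm
  }
  list(sm = sm, converged = FALSE)
}

oracle_trap <- function(x, a, b, c, d) {
  if (x <= a || x >= d) return(0)
  if (x < b) return((x - a) / (b - a))
  if (x <= c) return(1)
  (d - x) / (d - c)
}

oracle_stress <- function(v, thr, rate, side) {
  d <- numeric(52)
  for (w in 1:52)
    d[w] <- max(0, if (side == "below") thr - v[w] else v[w] - thr)
  st <- d > 0
  if (!any(st)) return(0)
  cc <- numeric(52)
  run <- 0
  for (pass in 1:2) {
    for (w in 1:52) {
      run <- if (st[w]) run + 1 else 0
      cc[w] <- run
    }
  }
  min(100, 100 * abs(rate) * sum(d * cc))
}

# full per-cell pipeline from 12 monthly values of each variable
oracle_cell <- function(tmin, tmax, precip, rh09, rh15,
                        p = maize_parameters(), e_coeff = 0.8) {
  tmin_w <- oracle_interp12(tmin)
  tmax_w <- oracle_interp12(tmax)
  tavg_w <- (tmin_w + tmax_w) / 2
  rh_w <- oracle_interp12((rh09 + rh15) / 2)
  precip_w <- oracle_precip_weekly(precip)
  et_w <- numeric(52)
  for (w in 1:52) et_w[w] <- e_coeff * max(tavg_w[w], 0) * (1 - rh_w[w]) * 7
  bk <- oracle_bucket(precip_w, et_w)
  ti <- mi <- numeric(52)
  for (w in 1:52) {
    ti[w] <- oracle_trap(tavg_w[w], p$dv0, p$dv1, p$dv2, p$dv3)
    mi[w] <- oracle_trap(bk$sm[w], p$sm0, p$sm1, p$sm2, p$sm3)
  }
  gi <- 100 * sum(ti * mi) / 52
  cs <- oracle_stress(tmin_w, p$ttcs, p$thcs, "below")
  hs <- oracle_stress(tmax_w, p$tths, p$thhs, "above")
  ds <- oracle_stress(bk$sm, p$smds, p$hds, "below")
  ws <- oracle_stress(bk$sm, p$smws, p$hws, "above")
  ei <- gi * (1 - cs / 100) * (1 - ds / 100) * (1 - hs / 100) * (1 - ws / 100)
  list(gi_a = gi, cs = cs, hs = hs, ds = ds, ws = ws, ei = ei,
       sm = bk$sm)
}
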
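# sensor-array simulator: specs, exposure profiles, response dynamics, drift

test_that("gas roster has the eight regulated gases with their ppm ranges", {
  g <- enose_gases()
  expect_equal(nrow(g), 8)
  expect_equal(g$conc_max[g$name == "hydrogen_sulfide"], 14)
  expect_equal(g$conc_max[g$name == "ammonia"], 20)
  expect_equal(g$conc_max[g$name == "trimethylamine"], 20)
  expect_equal(sum(g$conc_max == 14), 6)
  expect_true(all(g$conc_min == 0))
  g2 <- enose_gases(list(ammonia = list(conc_max = 30)))
  expect_equal(g2$conc_max[g2$name == "ammonia"], 30)
  expect_error(enose_gases(list(nope = list(conc_max = 1))), "unknown gas")
})

test_that("default array has 23 channels with env channels gas-blind", {
  arr <- default_array()
  expect_equal(arr$sensors$id, paste0("S", 1:23))
  expect_equal(nrow(arr$sensitivity), 23)
  # environment channels carry no gas sensitivity
  expect_true(all(arr$sensitivity["S22", ] == 0))
  expect_true(all(arr$sensitivity["S23", ] == 0))
  # each EC cell's largest gain sits on its nominal target
  expect_equal(which.max(arr$sensitivity["S2", ]), c(hydrogen_sulfide = 1))
  expect_equal(which.max(arr$sensitivity["S1", ]), c(ammonia = 7))
  # global field override
  arr0 <- default_array(noise_sd = 0)
  expect_true(all(arr0$sensors$noise_sd == 0))
  # per-channel override and validation
  arr2 <- default_array(overrides = list(S4 = list(noise_sd = 9)))
  expect_equal(arr2$sensors["S4", "noise_sd"], 9)
  expect_error(default_array(overrides = list(S99 = list(noise_sd = 1))),
               "unknown channel")
  expect_error(default_array(frobnicate = 1), "unknown sensor field")
})

test_that("intermittent protocol yields 600 recorded points per cycle", {
  p <- gen_intermittent(3, seed = 1)
  expect_equal(length(p$time), 1800)
  gas_seg <- p$segments[p$segments$mode == "gas", ]
  expect_equal(nrow(gas_seg), 3)
  expect_true(all(gas_seg$end - gas_seg$start + 1 == 180))
  # single-gas mode: only the requested gas column is nonzero
  ph <- gen_intermittent(2, gases = "hydrogen_sulfide", seed = 2)
  expect_true(all(ph$conc[, -1] == 0))
  expect_true(any(ph$conc[, 1] > 0))
  # determinism
  expect_identical(gen_intermittent(2, seed = 5), gen_intermittent(2, seed = 5))
  # protocol that cannot tile 600 points
  expect_error(gen_intermittent(1, protocol = list(pre = 100, gas = 180,
                                                   post = 120)),
               "600")
})

test_that("continuous protocol starts clean and respects ranges", {
  p <- gen_continuous(5, seed = 1,
                      opts = list(hold = c(180, 180), clean = 1200))
  expect_equal(length(p$time), 1200 + 5 * 180)
  expect_true(all(p$conc[1:1200, ] == 0))
  gmax <- enose_gases()$conc_max
  expect_true(all(sweep(p$conc, 2, gmax, `<=`)))
  expect_true(all(p$conc >= 0))
  expect_true(all(p$temp >= 15 & p$temp <= 36))
  expect_true(all(p$rh >= 30 & p$rh <= 84))
  # degenerate all-clean option
  p0 <- gen_continuous(3, seed = 1, opts = list(all_zero = TRUE))
  expect_true(all(p0$conc == 0))
})

test_that("two seeds give different conditions with the same uniform marginals", {
  draw_concs <- function(seed) {
    p <- gen_continuous(150, seed = seed, opts = list(clean = 60, p_zero = 0))
    # one drawn level per (gas segment, active gas)
    gs <- p$segments[p$segments$mode == "gas", ]
    unlist(lapply(seq_len(nrow(gs)), function(i) {
      v <- p$conc[gs$start[i], ]
      v[v > 0]
    }))
  }
  c1 <- draw_concs(11)
  c2 <- draw_concs(12)
  expect_gt(length(c1), 100)
  expect_false(isTRUE(all.equal(c1[1:50], c2[1:50])))
  # KS check of drawn levels against the uniform range (gas 1, 0-14 ppm)
  p <- gen_continuous(400, seed = 13, opts = list(clean = 60, p_zero = 0,
                                                  max_active = 1))
  gs <- p$segments[p$segments$mode == "gas", ]
  lv <- vapply(seq_len(nrow(gs)), function(i) {
    v <- p$conc[gs$start[i], ]
    if (v[1] > 0) v[1] else NA_real_
  }, numeric(1))
  lv <- lv[!is.na(lv)]
  expect_gt(length(lv), 25)
  expect_gt(suppressWarnings(ks.test(lv, "punif", 0, 14)$p.value), 0.01)
})

test_that("clean air with noise and drift off stays at baseline", {
  p <- gen_continuous(2, seed = 1,
                      opts = list(all_zero = TRUE, clean = 300,
                                  hold = c(60, 60)))
  arr <- default_array(noise_sd = 0, env_temp = 0, env_rh = 0, env_press = 0)
  rec <- simulate_response(p, arr, seed = 1, drift = FALSE)
  for (i in c(1, 5, 12, 20)) {
    expect_true(all(rec$channels[, i] == arr$sensors$baseline[i]))
  }
})

test_that("step response follows first-order kinetics within 2%", {
  # single 8-ppm hydrogen sulfide step; S2 is linear with tau_resp = 20 s
  n <- 900
  cm <- matrix(0, n, 8); colnames(cm) <- enose_gases()$name
  cm[301:n, 1] <- 8
  prof <- structure(list(time = seq_len(n) - 1, conc = cm,
                         temp = rep(25, n), rh = rep(50, n),
                         press = rep(101.3, n),
                         segments = data.frame(start = c(1, 301),
                                               end = c(300, n),
                                               mode = c("clean", "gas"))),
                    class = "enose_profile")
  arr <- default_array(noise_sd = 0, env_temp = 0, env_rh = 0, env_press = 0)
  rec <- simulate_response(prof, arr, seed = 1, drift = FALSE)
  s2 <- as.numeric(rec$channels[, "S2"])
  base <- arr$sensors["S2", "baseline"]
  tau <- arr$sensors["S2", "tau_resp"]
  step_height <- arr$sensitivity["S2", 1] * 8
  reached <- s2[300 + tau] - base
  expect_lt(abs(reached - (1 - exp(-1)) * step_height),
            0.02 * step_height + 1)  # +1 AD for integer quantization
  # settles to steady state
  expect_lt(abs(s2[n] - (base + step_height)), 0.01 * step_height + 1)
})

test_that("steady-state response is monotone in concentration per channel", {
  arr <- default_array(noise_sd = 0, env_temp = 0, env_rh = 0, env_press = 0)
  grid <- c(0, 1, 3, 7, 12)
  final <- sapply(grid, function(cc) {
    n <- 600
    cm <- matrix(0, n, 8); colnames(cm) <- enose_gases()$name
    cm[, 2] <- cc  # methyl sulfide
    prof <- structure(list(time = seq_len(n) - 1, conc = cm,
                           temp = rep(25, n), rh = rep(50, n),
                           press = rep(101.3, n),
                           segments = data.frame(start = 1, end = n,
                                                 mode = "gas")),
                      class = "enose_profile")
    rec <- simulate_response(prof, arr, seed = 1, drift = FALSE)
    rec$channels[n, ]
  })
  for (i in 1:21) expect_true(all(diff(final[i, ]) >= 0))
})

test_that("recovery returns to baseline after a long clean period", {
  prof <- two_pulse_profile(conc = 8, pre = 100, pulse = 120, gap = 700,
                            post = 100)
  arr <- default_array(noise_sd = 0, env_temp = 0, env_rh = 0, env_press = 0)
  rec <- simulate_response(prof, arr, seed = 1, drift = FALSE)
  # inspect just before the second pulse: gap 700 s > 7 * max tau_rec (70)
  t_check <- 100 + 120 + 700
  for (i in 1:21) {
    base <- arr$sensors$baseline[i]
    expect_lt(abs(rec$channels[t_check - 1, i] - base), 0.01 * base + 1.5)
  }
})

test_that("recordings are reproducible, integer and non-negative", {
  p <- gen_intermittent(2, seed = 3)
  r1 <- simulate_response(p, seed = 9, drift = TRUE)
  r2 <- simulate_response(p, seed = 9, drift = TRUE)
  expect_identical(r1$channels, r2$channels)
  expect_true(all(r1$channels >= 0))
  expect_true(all(r1$channels == round(r1$channels)))
  expect_identical(r1$truth, p$conc)
})

test_that("carry-over makes identical pulses after a short clean unequal", {
  prof <- two_pulse_profile(conc = 8, gap = 100)
  arr <- default_array(env_temp = 0, env_rh = 0, env_press = 0)
  peak <- function(rec, ch, s1, s2) {
    base <- arr$sensors[ch, "baseline"]
    c(max(rec$channels[s1, ch]) - base, max(rec$channels[s2, ch]) - base)
  }
  s1 <- 151:270; s2 <- 371:490
  rec_on <- simulate_response(prof, arr, seed = 2, drift = TRUE)
  rec_off <- simulate_response(prof, arr, seed = 2, drift = FALSE)
  # MOS channel S10: strong carry-over (frac 0.25)
  p_on <- peak(rec_on, "S10", s1, s2)
  p_off <- peak(rec_off, "S10", s1, s2)
  noise_sd <- arr$sensors["S10", "noise_sd"]
  expect_gt(abs(p_on[1] - p_on[2]), 5 * noise_sd)
  expect_lt(abs(p_off[1] - p_off[2]), 5 * noise_sd)
})

test_that("recording CSV round-trips through the documented schema", {
  p <- gen_intermittent(1, seed = 4)
  rec <- simulate_response(p, seed = 4)
  path <- tempfile(fileext = ".csv")
  write_recording(rec, path)
  hdr <- strsplit(readLines(path, n = 1), ",")[[1]]
  hdr <- gsub('"', "", hdr)
  expect_equal(hdr[1:2], c("time_s", "ch_S1"))
  expect_true(all(c("ch_S23", "temp_C", "rh_pct", "press_kPa",
                    "c_hydrogen_sulfide", "c_trimethylamine") %in% hdr))
  back <- read_recording(path)
  expect_equal(back$channels, rec$channels)
  expect_equal(back$truth, rec$truth)
  expect_equal(back$temp, rec$temp, tolerance = 1e-12)
})
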
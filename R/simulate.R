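# Synthetic electronic-nose recordings: gas exposure profiles and
# sensor-array responses with configurable short-term drift.

#' Specifications of the eight regulated malodor gases
#'
#' Returns the gas roster used throughout the package: six sulfur/aromatic
#' compounds spanning 0--14 ppm and two nitrogenous compounds (ammonia,
#' trimethylamine) spanning 0--20 ppm.
#'
#' @param overrides optional named list; each element is a list with
#'   `conc_min` and/or `conc_max` replacing the defaults for that gas.
#' @return data.frame with columns `name`, `conc_min`, `conc_max` (ppm).
#' @export
enose_gases <- function(overrides = NULL) {
  g <- data.frame(
    name = GAS_NAMES,
    conc_min = rep(0, N_GASES),
    conc_max = c(14, 14, 14, 14, 14, 14, 20, 20),
    stringsAsFactors = FALSE
  )
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), g$name)
    if (length(bad)) stop("unknown gas name(s): ", paste(bad, collapse = ", "))
    for (nm in names(overrides)) {
      for (fld in names(overrides[[nm]])) {
        if (!fld %in% c("conc_min", "conc_max")) {
          stop("unknown gas field: ", fld)
        }
        g[g$name == nm, fld] <- overrides[[nm]][[fld]]
      }
    }
  }
  if (any(g$conc_min < 0) || any(g$conc_max <= g$conc_min)) {
    stop("gas ranges must satisfy 0 <= conc_min < conc_max")
  }
  g
}

# Default per-principle dynamic / noise / drift parameters.
.principle_defaults <- function(principle) {
  switch(principle,
    EC   = list(baseline = 200,  tau_resp = 20, tau_rec = 45,  noise_sd = 3,
                drift_rw_sd = 0.10, carry_frac = 0.10, carry_tau = 240,
                env_temp = 1.5, env_rh = 0.3, env_press = 0),
    MOS  = list(baseline = 800,  tau_resp = 15, tau_rec = 70,  noise_sd = 4,
                drift_rw_sd = 0.25, carry_frac = 0.25, carry_tau = 300,
                env_temp = 4.0, env_rh = 1.0, env_press = 0),
    PID  = list(baseline = 150,  tau_resp = 5,  tau_rec = 12,  noise_sd = 3,
                drift_rw_sd = 0.08, carry_frac = 0.05, carry_tau = 150,
                env_temp = 0.8, env_rh = 0.2, env_press = 0),
    NDIR = list(baseline = 400,  tau_resp = 10, tau_rec = 20,  noise_sd = 2,
                drift_rw_sd = 0.05, carry_frac = 0.02, carry_tau = 120,
                env_temp = 0.5, env_rh = 0.1, env_press = 0),
    RC   = list(baseline = 0,    tau_resp = 3,  tau_rec = 3,   noise_sd = 1,
                drift_rw_sd = 0.02, carry_frac = 0.00, carry_tau = 60,
                env_temp = 0, env_rh = 0, env_press = 0),
    stop("unknown sensing principle: ", principle)
  )
}

# Default sensitivity matrix (AD counts per ppm at reference conditions).
# Electrochemical cells carry their nominal target (largest gain) plus small
# cross-sensitivities to chemically related compounds; MOS elements are
# broadly responsive with sublinear (power-law) response; PIDs respond to
# ionizable organics; the NDIR channel is weakly cross-sensitive; the two
# environment channels (pressure, temperature/humidity) have no gas response.
.default_sensitivity <- function() {
  S <- matrix(0, nrow = 23, ncol = N_GASES,
              dimnames = list(paste0("S", 1:23), GAS_NAMES))
  # gas column shorthand
  h2s <- 1; dms <- 2; dmds <- 3; mm <- 4; cs2 <- 5; sty <- 6; nh3 <- 7; tma <- 8
  # EC cells: nominal target per Table of sensor models (S1 NH3, S2 H2S,
  # S3 CH3SH, S4 C2H6S, S5 CS2, S6 C2H6S2, S7 CS2, S8 styrene, S9 SO2).
  S["S1", nh3] <- 110; S["S1", tma] <- 12
  S["S2", h2s] <- 120; S["S2", mm] <- 15; S["S2", dms] <- 6
  S["S3", mm] <- 115; S["S3", h2s] <- 18; S["S3", dms] <- 8
  S["S4", dms] <- 110; S["S4", dmds] <- 14; S["S4", mm] <- 8
  S["S5", cs2] <- 105; S["S5", dms] <- 5
  S["S6", dmds] <- 115; S["S6", dms] <- 12; S["S6", mm] <- 5
  S["S7", cs2] <- 95; S["S7", h2s] <- 4
  S["S8", sty] <- 100; S["S8", tma] <- 4
  # S9 is an SO2 cell: weak cross-response to reduced sulfur compounds only.
  S["S9", c(h2s, mm, dms)] <- c(8, 6, 4)
  # MOS elements: broad, sublinear; TGS2602/2603 amine-heavy.
  S["S10", ] <- c(60, 55, 45, 50, 20, 35, 25, 30)
  S["S11", ] <- c(45, 50, 40, 45, 25, 40, 20, 25)
  S["S12", ] <- c(35, 30, 25, 30, 10, 20, 55, 90)
  S["S13", ] <- c(55, 40, 35, 50, 15, 25, 30, 40)
  S["S14", ] <- c(40, 45, 35, 40, 30, 45, 15, 20)
  # PIDs: ionizable organics (sulfides, styrene, TMA); H2S/NH3 weak.
  S["S15", ] <- c(5, 60, 70, 45, 25, 75, 2, 55)
  S["S16", ] <- c(4, 55, 65, 40, 20, 70, 2, 80)
  S["S17", ] <- c(6, 50, 60, 40, 22, 65, 3, 45)
  S["S18", ] <- c(5, 45, 55, 35, 20, 60, 2, 40)
  S["S19", ] <- c(5, 55, 62, 42, 24, 68, 2, 50)
  S["S20", ] <- c(4, 40, 50, 32, 18, 55, 2, 35)
  # NDIR: weak broad cross-sensitivity.
  S["S21", ] <- c(3, 4, 4, 3, 12, 5, 2, 3)
  # S22 (pressure), S23 (temperature/humidity): zero gas sensitivity.
  S
}

#' Default 23-channel sensor array specification
#'
#' Builds the default array: 21 gas-sensing channels (S1--S9 electrochemical,
#' S10--S14 metal-oxide, S15--S20 photoionization, S21 NDIR) plus two
#' environment channels (S22 pressure, S23 temperature/humidity). Each spec
#' carries a sensitivity vector over the eight gases, power-law response
#' exponents, asymmetric response/recovery time constants, baseline, noise,
#' drift (random-walk step sd, carry-over fraction and decay time) and linear
#' temperature/humidity/pressure coupling gains.
#'
#' @param overrides named list keyed by channel id (e.g. `list(S4 =
#'   list(noise_sd = 0))`); unknown ids are an error.
#' @param ... scalar field overrides applied to every channel, e.g.
#'   `noise_sd = 0` or `drift_rw_sd = 0`.
#' @return object of class `enose_array`: list with `sensors` (data.frame of
#'   scalar fields), `sensitivity` (23 x 8), `exponent` (23 x 8).
#' @export
default_array <- function(overrides = NULL, ...) {
  principle <- c(rep("EC", 9), rep("MOS", 5), rep("PID", 6), "NDIR", "RC", "RC")
  ids <- paste0("S", 1:23)
  rows <- lapply(principle, .principle_defaults)
  sensors <- do.call(rbind, lapply(rows, as.data.frame))
  sensors <- cbind(data.frame(id = ids, principle = principle,
                              stringsAsFactors = FALSE), sensors)
  rownames(sensors) <- ids
  # environment channel readouts: S22 tracks chamber pressure, S23 humidity
  # (with a temperature component)
  sensors["S22", c("baseline", "env_press")] <- c(4000, 40)
  sensors["S23", c("baseline", "env_rh", "env_temp")] <- c(200, 30, 2)

  sens <- .default_sensitivity()
  expo <- matrix(1, 23, N_GASES, dimnames = dimnames(sens))
  expo[principle == "MOS", ] <- 0.6  # canonical MOS sublinearity

  global <- list(...)
  for (fld in names(global)) {
    if (!fld %in% names(sensors)) stop("unknown sensor field: ", fld)
    sensors[[fld]] <- global[[fld]]
  }
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), ids)
    if (length(bad)) stop("unknown channel id(s): ", paste(bad, collapse = ", "))
    for (id in names(overrides)) {
      ov <- overrides[[id]]
      for (fld in names(ov)) {
        if (fld == "sensitivity") {
          sens[id, ] <- ov[[fld]]
        } else if (fld == "exponent") {
          expo[id, ] <- ov[[fld]]
        } else if (fld %in% names(sensors)) {
          sensors[id, fld] <- ov[[fld]]
        } else stop("unknown sensor field: ", fld)
      }
    }
  }
  stopifnot(all(sensors$tau_resp > 0), all(sensors$tau_rec > 0),
            all(sensors$noise_sd >= 0),
            all(sensors$carry_frac >= 0 & sensors$carry_frac < 1))
  structure(list(sensors = sensors, sensitivity = sens, exponent = expo),
            class = "enose_array")
}

#' @export
print.enose_array <- function(x, ...) {
  cat("<enose_array> ", nrow(x$sensors), " channels (",
      sum(rowSums(abs(x$sensitivity)) > 0), " gas-sensitive, ",
      sum(rowSums(abs(x$sensitivity)) == 0), " environment)\n", sep = "")
  print(table(x$sensors$principle))
  invisible(x)
}

# Smooth bounded environment series: slow sinusoid plus AR(1) jitter,
# clamped to [lo, hi]. Mimics the diurnal cycle of chamber conditions.
.env_series <- function(n, lo, hi, period = 86400, ar_sd = 0.01) {
  mid <- (lo + hi) / 2
  amp <- (hi - lo) / 2 * 0.8
  phase <- runif(1, 0, 2 * pi)
  base <- mid + amp * sin(2 * pi * (seq_len(n) - 1) / period + phase)
  e <- numeric(n)
  z <- 0
  innov <- rnorm(n, 0, ar_sd * (hi - lo))
  for (t in seq_len(n)) {
    z <- 0.999 * z + innov[t]
    e[t] <- z
  }
  pmin(hi, pmax(lo, base + e))
}

.make_env <- function(n, temp_range = c(15, 36), rh_range = c(30, 84)) {
  temp <- .env_series(n, temp_range[1], temp_range[2])
  # humidity anticorrelated with temperature, plus its own wander
  rh0 <- .env_series(n, rh_range[1], rh_range[2])
  rh <- pmin(rh_range[2], pmax(rh_range[1],
        mean(rh_range) - 0.6 * (temp - mean(temp_range)) / diff(temp_range) *
          diff(rh_range) + (rh0 - mean(rh_range)) * 0.5))
  press <- 101.3 + cumsum(rnorm(n, 0, 2e-4))
  press <- 101.3 + (press - mean(press))
  list(temp = temp, rh = rh, press = press)
}

.new_profile <- function(time, conc, env, segments) {
  colnames(conc) <- GAS_NAMES
  structure(list(time = time, conc = conc, temp = env$temp, rh = env$rh,
                 press = env$press, segments = segments),
            class = "enose_profile")
}

#' @export
print.enose_profile <- function(x, ...) {
  cat("<enose_profile> ", length(x$time), " s, ",
      sum(x$segments$mode == "gas"), " gas segment(s)\n", sep = "")
  invisible(x)
}

#' Intermittent (purge / expose / purge) exposure profile
#'
#' Generates the cyclic sampling protocol: each recorded cycle is 600 points
#' at 1 Hz, split into a pre-exposure clean phase, a 3-minute gas phase and a
#' post-exposure clean phase. Per cycle the exposed gas (or mixture) and its
#' concentration are drawn uniformly within the gas ranges.
#'
#' @param n_cycles number of 600-point cycles (>= 1).
#' @param gases character vector of candidate gas names (default all eight).
#' @param seed integer RNG seed.
#' @param protocol list with `pre`, `gas`, `post` phase durations in seconds;
#'   must sum to 600.
#' @param mixture if `TRUE` each cycle exposes 1--3 gases simultaneously;
#'   if `FALSE` (default) a single gas per cycle.
#' @param conc_floor lower bound of the drawn concentration as a fraction of
#'   the gas range (default 0: the full range is sampled).
#' @return `enose_profile` of length `600 * n_cycles`.
#' @export
gen_intermittent <- function(n_cycles, gases = GAS_NAMES, seed = 1,
                             protocol = list(pre = 300, gas = 180, post = 120),
                             mixture = FALSE, conc_floor = 0) {
  stopifnot(n_cycles >= 1)
  gases <- match.arg(gases, GAS_NAMES, several.ok = TRUE)
  pre <- protocol$pre; gas_d <- protocol$gas; post <- protocol$post
  if (pre + gas_d + post != 600) {
    stop("protocol durations must tile the 600-point recorded cycle window ",
         "(pre + gas + post == 600), got ", pre + gas_d + post)
  }
  set.seed(seed)
  n <- 600L * as.integer(n_cycles)
  gspec <- enose_gases()
  conc <- matrix(0, n, N_GASES)
  seg <- list()
  for (cyc in seq_len(n_cycles)) {
    off <- (cyc - 1L) * 600L
    g_start <- off + pre + 1L
    g_end <- off + pre + gas_d
    active <- if (mixture) {
      sample(gases, sample(seq_len(min(3L, length(gases))), 1L))
    } else sample(gases, 1L)
    for (g in active) {
      j <- match(g, GAS_NAMES)
      lo <- gspec$conc_min[j] + conc_floor * (gspec$conc_max[j] - gspec$conc_min[j])
      conc[g_start:g_end, j] <- runif(1, lo, gspec$conc_max[j])
    }
    seg[[length(seg) + 1L]] <- data.frame(start = off + 1L, end = off + pre,
                                          mode = "clean")
    seg[[length(seg) + 1L]] <- data.frame(start = g_start, end = g_end,
                                          mode = "gas")
    seg[[length(seg) + 1L]] <- data.frame(start = g_end + 1L, end = off + 600L,
                                          mode = "clean")
  }
  env <- .make_env(n)
  .new_profile(seq_len(n) - 1L, conc, env, do.call(rbind, seg))
}

#' Non-intermittent (continuous random-step) exposure profile
#'
#' Starts with a clean-air period (default 20 min), then applies
#' `n_conditions` random step conditions without purging in between: each
#' condition holds a randomly drawn gas mixture for a random duration.
#'
#' @param n_conditions number of step conditions (>= 1).
#' @param seed integer RNG seed.
#' @param opts list: `hold` = c(min, max) hold-time bounds in s (default
#'   60--300), `clean` = initial clean duration in s (default 1200),
#'   `max_active` = max gases simultaneously present (default 3),
#'   `p_zero` = probability a condition is clean air (default 0.1),
#'   `all_zero` = if TRUE every condition is clean air.
#' @return `enose_profile`.
#' @export
gen_continuous <- function(n_conditions, seed = 1, opts = list()) {
  stopifnot(n_conditions >= 1)
  o <- utils::modifyList(list(hold = c(60, 300), clean = 1200,
                              max_active = 3, p_zero = 0.1,
                              all_zero = FALSE), opts)
  set.seed(seed)
  gspec <- enose_gases()
  holds <- if (o$hold[1] == o$hold[2]) rep(o$hold[1], n_conditions) else
    round(runif(n_conditions, o$hold[1], o$hold[2]))
  n <- as.integer(o$clean + sum(holds))
  conc <- matrix(0, n, N_GASES)
  seg <- list(data.frame(start = 1L, end = as.integer(o$clean), mode = "clean"))
  pos <- as.integer(o$clean)
  for (k in seq_len(n_conditions)) {
    idx <- (pos + 1L):(pos + holds[k])
    if (!o$all_zero && runif(1) > o$p_zero) {
      n_act <- sample(seq_len(o$max_active), 1L)
      active <- sample(GAS_NAMES, n_act)
      for (g in active) {
        j <- match(g, GAS_NAMES)
        conc[idx, j] <- runif(1, gspec$conc_min[j], gspec$conc_max[j])
      }
    }
    seg[[length(seg) + 1L]] <- data.frame(start = min(idx), end = max(idx),
                                          mode = "gas")
    pos <- pos + holds[k]
  }
  env <- .make_env(n)
  .new_profile(seq_len(n) - 1L, conc, env, do.call(rbind, seg))
}

#' Simulate the sensor-array response to an exposure profile
#'
#' Each channel relaxes toward its steady-state response
#' `R_ss = baseline + sum_j gain_j * c_j^exponent_j + env coupling` with an
#' asymmetric first-order law: time constant `tau_resp` when the target lies
#' above the current state and `tau_rec` when below (discretized exactly for
#' piecewise-constant input at 1 Hz). With `drift = TRUE` two short-term
#' drift mechanisms are added: a per-channel random-walk baseline and a
#' carry-over term -- at each gas-to-clean transition a fraction of the
#' channel's excess response is latched and decays with time constant
#' `carry_tau`, so identical pulses after short cleans read unequal.
#' Gaussian measurement noise is added and values are quantized to
#' non-negative integer AD counts.
#'
#' @param profile an `enose_profile`.
#' @param sensors an `enose_array` (default `default_array()`).
#' @param seed integer RNG seed for noise and drift.
#' @param drift logical: enable random-walk baseline drift and carry-over.
#' @return object of class `enose_recording`: `time`, `channels` (T x 23
#'   integer AD matrix), `truth` (T x 8 ppm), `temp`, `rh`, `press`,
#'   `provenance`.
#' @export
simulate_response <- function(profile, sensors = default_array(), seed = 1,
                              drift = TRUE) {
  stopifnot(inherits(profile, "enose_profile"), inherits(sensors, "enose_array"))
  sp <- sensors$sensors
  if (any(!is.finite(sp$tau_resp)) || any(!is.finite(sp$tau_rec))) {
    stop("non-finite dynamics parameters")
  }
  n <- length(profile$time)
  nc <- nrow(sp)
  set.seed(seed)

  # steady-state response matrix (T x channels)
  dtemp <- profile$temp - 25
  drh <- profile$rh - 50
  dpress <- profile$press - 101.3
  Rss <- matrix(rep(sp$baseline, each = n), n, nc)
  for (i in seq_len(nc)) {
    gains <- sensors$sensitivity[i, ]
    active <- which(gains != 0)
    if (length(active)) {
      cm <- profile$conc[, active, drop = FALSE]
      em <- sensors$exponent[i, active]
      resp <- sweep(cm, 2, em, `^`)
      Rss[, i] <- Rss[, i] + as.vector(resp %*% gains[active])
    }
    Rss[, i] <- Rss[, i] + sp$env_temp[i] * dtemp +
      sp$env_rh[i] * drh + sp$env_press[i] * dpress
  }

  # asymmetric first-order relaxation (exact update per 1 s step)
  a_up <- 1 - exp(-1 / sp$tau_resp)
  a_dn <- 1 - exp(-1 / sp$tau_rec)
  state <- Rss[1, ]
  S <- matrix(0, n, nc)
  for (t in seq_len(n)) {
    target <- Rss[t, ]
    alpha <- ifelse(target >= state, a_up, a_dn)
    state <- state + alpha * (target - state)
    S[t, ] <- state
  }

  if (drift) {
    # random-walk baseline drift
    rw <- apply(matrix(rnorm(n * nc), n, nc), 2, cumsum)
    rw <- sweep(rw, 2, sp$drift_rw_sd, `*`)
    # carry-over: latch a fraction of the excess response at each
    # gas->clean boundary, decaying thereafter
    gas_end <- profile$segments$end[profile$segments$mode == "gas"]
    gas_end <- gas_end[gas_end < n]
    carry <- matrix(0, n, nc)
    z <- numeric(nc)
    decay <- exp(-1 / sp$carry_tau)
    is_end <- logical(n)
    is_end[sort(unique(gas_end))] <- TRUE
    for (t in seq_len(n)) {
      z <- z * decay
      if (is_end[t]) {
        z <- z + sp$carry_frac * pmax(0, S[t, ] - sp$baseline)
      }
      carry[t, ] <- z
    }
    S <- S + rw + carry
  }

  noise <- matrix(rnorm(n * nc), n, nc)
  noise <- sweep(noise, 2, sp$noise_sd, `*`)
  channels <- round(pmax(S + noise, 0))
  colnames(channels) <- sp$id

  structure(list(
    time = profile$time,
    channels = channels,
    truth = profile$conc,
    temp = profile$temp, rh = profile$rh, press = profile$press,
    provenance = list(seed = seed, drift = drift,
                      n_channels = nc, generated = TRUE)
  ), class = "enose_recording")
}

#' @export
print.enose_recording <- function(x, ...) {
  cat("<enose_recording> ", nrow(x$channels), " s x ", ncol(x$channels),
      " channels; drift ", if (isTRUE(x$provenance$drift)) "on" else "off",
      "\n", sep = "")
  invisible(x)
}

#' Write / read a recording as CSV
#'
#' Schema: `time_s, ch_S1..ch_S23, temp_C, rh_pct, press_kPa,
#' c_<gas1>..c_<gas8>`, one header row, UTF-8.
#'
#' @param recording an `enose_recording`.
#' @param path output CSV path.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "enose_recording"))
  df <- data.frame(time_s = recording$time)
  ch <- as.data.frame(recording$channels)
  names(ch) <- paste0("ch_", colnames(recording$channels))
  df <- cbind(df, ch,
              temp_C = recording$temp, rh_pct = recording$rh,
              press_kPa = recording$press)
  tr <- as.data.frame(recording$truth)
  names(tr) <- paste0("c_", colnames(recording$truth))
  df <- cbind(df, tr)
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_recording
#' @param path CSV path produced by [write_recording()].
#' @export
read_recording <- function(path) {
  df <- read.csv(path, fileEncoding = "UTF-8", check.names = FALSE)
  ch_cols <- grep("^ch_", names(df), value = TRUE)
  c_cols <- grep("^c_", names(df), value = TRUE)
  channels <- as.matrix(df[, ch_cols])
  colnames(channels) <- sub("^ch_", "", ch_cols)
  truth <- as.matrix(df[, c_cols])
  colnames(truth) <- sub("^c_", "", c_cols)
  structure(list(
    time = df$time_s, channels = channels, truth = truth,
    temp = df$temp_C, rh = df$rh_pct, press = df$press_kPa,
    provenance = list(path = path)
  ), class = "enose_recording")
}
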
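# Shared fixtures, built in code.

sheep_props <- function(mua = 0.015, musp = 1.0, wl = c(751, 839)) {
  lapply(wl, function(w) optical_properties(mua, musp, w))
}

sheep_medium <- function(mua = 0.015, musp = 1.0, s = 10) {
  p <- sheep_props(mua, musp)
  layered_medium(s, p, p)
}

# A delta_od_series with channels computed from known absorption perturbations
# via the package's forward models (short channel homogeneous by default so
# the two-step inversion round trip is exact).
make_dod_series <- function(dmua_up, dmua_down, baseline = sheep_medium(),
                            hemi = "left", short_model = "homogeneous",
                            fs = 10, task = "motor") {
  n <- max(length(dmua_up), length(dmua_down))
  cols <- NULL
  cn <- character(0)
  for (dist in c("short", "long")) {
    rho <- if (dist == "short") 10 else 30
    model <- if (dist == "short") short_model else "two_layer"
    for (wl in c(751, 839)) {
      cols <- cbind(cols, delta_od_forward(rho, model, baseline,
                                           dmua_up, dmua_down, wavelength = wl))
      cn <- c(cn, sprintf("%s_%s_%g", hemi, dist, wl))
    }
  }
  colnames(cols) <- cn
  structure(list(block = 1L, subject_id = "s1", task = task, onset = 0,
                 time_rel = seq(-5, by = 1 / fs, length.out = n),
                 delta_od = cols, baseline_window = c(-5, 0),
                 phases = list(baseline = c(-5, 0)),
                 channels = NULL, sampling_rate = fs, flags = list()),
            class = "delta_od_series")
}

# Minimal hemoglobin_series stand-in for aggregation/statistics tests.
make_hb_series <- function(subject, block, do2hb_down, dhhb_down = -0.3 * do2hb_down,
                           time = seq(-5, 62.9, by = 0.1), hemisphere = "left",
                           task = "startle") {
  n <- length(time)
  z <- rep(0, n)
  structure(list(block = block, subject_id = subject, task = task, onset = 0,
                 hemisphere = hemisphere, time_rel = time,
                 o2hb = cbind(up = z, down = do2hb_down),
                 hhb = cbind(up = z, down = dhhb_down),
                 do2hb = cbind(up = z, down = do2hb_down),
                 dhhb = cbind(up = z, down = dhhb_down),
                 baseline_window = c(-5, 0),
                 phases = list(baseline = c(-5, 0), stimulus = c(0, 3),
                               reaction = c(3, 63)),
                 flags = list()),
            class = "hemoglobin_series")
}

# Minimal od_block for exclusion tests (no optical data needed).
make_block <- function(subject, block, onset, task = "startle") {
  phases <- if (task == "startle")
    list(baseline = c(-5, 0), stimulus = c(0, 3), reaction = c(3, 63))
  else list(baseline = c(-5, 0), walk = c(0, 30), recovery = c(30, 35))
  w <- range(unlist(phases))
  structure(list(block = block, subject_id = subject, task = task,
                 onset = onset, window = onset + w, phases = phases),
            class = "od_block")
}
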
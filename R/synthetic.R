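# Ground-truthed synthetic experiments: OD recordings + schedules + behavior
# annotations with the statistical structure the analysis assumes, so every
# pipeline stage is testable without animal recordings.
#
# To avoid an inverse crime, generation always uses the full two-layer forward
# model at BOTH distances; the analysis's short-channel homogeneous
# approximation is therefore genuinely exercised and its bias measured.

#' Ground-truth parameters for the synthetic generator
#'
#' The stated world of the simulations: a canonical cortical hemodynamic
#' response confined to the lower layer, superficial systemic activity
#' (Mayer-wave oscillation and slow drift) confined to the upper layer, and
#' white measurement noise on the optical density.
#'
#' @param peak_do2hb,peak_dhhb cortical response peak amplitudes, uM
#'   (defaults +1 and -0.3).
#' @param onset,time_to_peak,fwhm response onset delay, time to peak and
#'   width, s (defaults 1, 6, 6).
#' @param undershoot post-stimulus undershoot fraction (default 0.2).
#' @param mayer_amp Mayer-wave amplitude on upper-layer O2Hb, uM (default
#'   0.2); the HHb oscillation is a quarter of it.
#' @param mayer_freq Mayer-wave frequency, Hz (default 0.1).
#' @param drift upper-layer O2Hb drift, uM per minute (default 0.05).
#' @param noise_od Gaussian OD noise standard deviation per sample (default
#'   1e-3 OD).
#' @param od0 baseline optical density offset added to every channel.
#' @return A list of class `ground_truth`.
#' @export
ground_truth <- function(peak_do2hb = 1.0, peak_dhhb = -0.3,
                         onset = 1, time_to_peak = 6, fwhm = 6,
                         undershoot = 0.2,
                         mayer_amp = 0.2, mayer_freq = 0.1, drift = 0.05,
                         noise_od = 1e-3, od0 = 1.0) {
  if (time_to_peak <= 0 || fwhm <= 0)
    stop("time_to_peak and fwhm must be positive", call. = FALSE)
  structure(list(peak_do2hb = peak_do2hb, peak_dhhb = peak_dhhb,
                 onset = onset, time_to_peak = time_to_peak, fwhm = fwhm,
                 undershoot = undershoot, mayer_amp = mayer_amp,
                 mayer_freq = mayer_freq, drift = drift,
                 noise_od = noise_od, od0 = od0),
            class = "ground_truth")
}

# gamma-variate normalized to peak 1 at its mode tp, shape from (tp, fwhm):
# sqrt(a) - 1/sqrt(a) = 2.355 tp / fwhm (Gaussian-width matching), b = tp/(a-1).
gamma_variate <- function(t, tp, fwhm) {
  cc <- 2 * sqrt(2 * log(2)) * tp / fwhm
  u <- (cc + sqrt(cc^2 + 4)) / 2
  a <- u^2
  b <- tp / (a - 1)
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- (t[pos] / tp)^(a - 1) * exp(-(t[pos] - tp) / b)
  out
}

#' Canonical hemodynamic response waveform
#'
#' Difference of two gamma-variates: a main lobe peaking `time_to_peak`
#' seconds after `onset` and an undershoot lobe peaking at twice that, scaled
#' by the undershoot fraction. The waveform is zero before `onset` and
#' normalized so its maximum equals `peak` exactly (the effective time to
#' peak is the argmax of the combined waveform, within a fraction of a second
#' of the nominal one).
#'
#' @param t time, s (vector); the response starts at `t = onset`.
#' @param peak peak amplitude, uM (may be negative for a deoxy-hemoglobin
#'   response).
#' @param onset,time_to_peak,fwhm,undershoot shape parameters, s / fraction.
#' @return Concentration change, uM, same length as `t`.
#' @examples
#' t <- seq(0, 40, 0.1)
#' h <- canonical_hrf(t, peak = 1)
#' max(h) # 1
#' @export
canonical_hrf <- function(t, peak, onset = 1, time_to_peak = 6, fwhm = 6,
                          undershoot = 0.2) {
  if (time_to_peak <= 0 || fwhm <= 0 || undershoot < 0)
    stop("non-positive HRF shape parameters", call. = FALSE)
  if (peak == 0) return(numeric(length(t)))
  shape <- function(tt)
    gamma_variate(tt, time_to_peak, fwhm) -
      undershoot * gamma_variate(tt, 2 * time_to_peak, 1.6 * fwhm)
  # normalization: maximum of the combined waveform
  mx <- stats::optimize(shape, c(0, 2 * time_to_peak), maximum = TRUE)$objective
  peak * shape(t - onset) / mx
}

# Per-layer truth concentration time courses (uM) over an absolute time grid
# with responses at each block onset. Upper layer carries only systemics,
# lower layer only the cortical response.
truth_concentrations <- function(time, onsets, truth, mayer_phase = 0) {
  n <- length(time)
  lower_o2 <- numeric(n); lower_hh <- numeric(n)
  for (on in onsets) {
    tt <- time - on
    lower_o2 <- lower_o2 + canonical_hrf(tt, truth$peak_do2hb, truth$onset,
                                         truth$time_to_peak, truth$fwhm,
                                         truth$undershoot)
    lower_hh <- lower_hh + canonical_hrf(tt, truth$peak_dhhb, truth$onset,
                                         truth$time_to_peak, truth$fwhm,
                                         truth$undershoot)
  }
  mayer <- truth$mayer_amp * sin(2 * pi * truth$mayer_freq * time + mayer_phase)
  drift <- truth$drift * time / 60
  list(upper_o2hb = mayer + drift,
       upper_hhb = -0.25 * mayer,
       lower_o2hb = lower_o2,
       lower_hhb = lower_hh)
}

# concentrations (uM) -> absorption change (mm^-1) at both wavelengths
conc_to_dmua <- function(o2hb, hhb, eps) {
  # eps in cm^-1 mM^-1; uM -> mM is /1000; cm^-1 -> mm^-1 is /10
  cbind((eps[1, "o2hb"] * o2hb + eps[1, "hhb"] * hhb) / 1e4,
        (eps[2, "o2hb"] * o2hb + eps[2, "hhb"] * hhb) / 1e4)
}

# OD channel matrix for one hemisphere over an absolute time grid.
simulate_hemisphere_od <- function(time, conc, baseline, probe, eps,
                                   truth, hemi) {
  dmua_up <- conc_to_dmua(conc$upper_o2hb, conc$upper_hhb, eps)
  dmua_dn <- conc_to_dmua(conc$lower_o2hb, conc$lower_hhb, eps)
  wls <- probe$wavelengths
  od <- matrix(NA_real_, length(time), 4L)
  cn <- character(4L)
  k <- 0L
  for (dist in c("short", "long")) {
    rho <- if (dist == "short") probe$rho_short else probe$rho_long
    for (j in seq_along(wls)) {
      k <- k + 1L
      # truth forward: full two-layer model at both distances
      dod <- delta_od_forward(rho, "two_layer", baseline,
                              dmua_up[, j], dmua_dn[, j], wavelength = wls[j])
      od[, k] <- truth$od0 + dod + rnorm(length(time), 0, truth$noise_od)
      cn[k] <- sprintf("%s_%s_%g", hemi, dist, wls[j])
    }
  }
  colnames(od) <- cn
  od
}

#' Generate one synthetic task block
#'
#' Converts the ground-truth concentration time courses of one block into OD
#' recordings at both distances and wavelengths through the full two-layer
#' forward model, adds systemic components and Gaussian OD noise, and returns
#' the recording slice together with the planted truth.
#'
#' @param truth a [ground_truth()].
#' @param baseline [layered_medium()] with baseline properties per wavelength.
#' @param probe [probe_config()].
#' @param seed integer seed.
#' @param task `"motor"` or `"startle"` (sets the analysis window).
#' @param hemispheres channels to generate.
#' @param eps extinction matrix.
#' @return A list with `recording` (an [od_recording()] covering one block:
#'   onset at 30 s), `schedule` (single-block [block_schedule()]) and `truth`
#'   (the input parameters plus the planted per-layer concentration series).
#' @export
generate_block <- function(truth = ground_truth(), baseline, probe = probe_config(),
                           seed = 1, task = "motor",
                           hemispheres = c("left", "right"),
                           eps = sheep_extinction()) {
  sched <- block_schedule(task, block_starts = 30)
  dur <- 30 + sched$window[2] + 5
  with_seed(seed, {
    time <- seq(0, dur - 1 / probe$sampling_rate, by = 1 / probe$sampling_rate)
    phase <- runif(1, 0, 2 * pi)
    conc <- truth_concentrations(time, 30, truth, phase)
    od <- do.call(cbind, lapply(hemispheres, function(h)
      simulate_hemisphere_od(time, conc, baseline, probe, eps, truth, h)))
    list(recording = od_recording(time, od, "synthetic"),
         schedule = sched,
         truth = list(params = truth, time = time, concentrations = conc,
                      block_onset = 30))
  })
}

# run code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Block plan for a synthetic startle cohort
#'
#' Deterministic allocation of per-block reaction labels and planted
#' artifacts. Blocks are assigned round-robin across subjects in the order
#' flight, freezing, artifact (alternating chewing / head shake, each with a
#' flight reaction so only the artifact causes the exclusion), no-reaction.
#' The defaults mirror a 10-subject, 5-block startle cohort in which 39 of 50
#' blocks survive exclusion and split 28 Move / 11 Stand.
#'
#' @param n_subjects,blocks_per_subject cohort shape.
#' @param n_flight,n_freeze retained blocks with a flight / freezing reaction.
#' @param n_artifact blocks excluded for chewing or head shaking.
#' @param n_noreaction blocks excluded for showing neither flight nor
#'   freezing.
#' @return Data frame `subject, block, label, artifact, reaction`.
#' @export
startle_block_plan <- function(n_subjects = 10, blocks_per_subject = 5,
                               n_flight = 28, n_freeze = 11,
                               n_artifact = 8, n_noreaction = 3) {
  total <- n_subjects * blocks_per_subject
  if (n_flight + n_freeze + n_artifact + n_noreaction != total)
    stop("plan counts must sum to n_subjects * blocks_per_subject", call. = FALSE)
  kind <- c(rep("flight", n_flight), rep("freezing", n_freeze),
            rep("artifact", n_artifact), rep("noreaction", n_noreaction))
  # enumerate block 1 of every subject, then block 2, ... so the categories
  # spread round-robin across subjects
  subject <- sprintf("sheep%02d", rep(seq_len(n_subjects), times = blocks_per_subject))
  block <- rep(seq_len(blocks_per_subject), each = n_subjects)
  art <- character(total)
  art[kind == "artifact"] <- rep_len(c("chewing", "head_shake"),
                                     sum(kind == "artifact"))
  art[kind != "artifact"] <- "none"
  data.frame(subject = subject, block = block,
             label = ifelse(kind == "freezing", "freezing",
                            ifelse(kind == "noreaction", "none", "flight")),
             artifact = art,
             reaction = kind != "noreaction")
}

#' Generate a seeded synthetic cohort
#'
#' Produces per-subject OD recordings (10 motor or 5 startle blocks each, the
#' tasks' block designs), behavior annotations driving the planned exclusions
#' and Move/Stand labels, and the full ground truth. Deterministic given the
#' seed.
#'
#' @param n_subjects number of sheep.
#' @param task `"motor"` or `"startle"`.
#' @param truth a [ground_truth()].
#' @param seed integer seed.
#' @param baseline [layered_medium()]; default sheep-like baseline via
#'   [default_baseline()].
#' @param probe [probe_config()].
#' @param eps extinction matrix.
#' @param n_frequent_shakers motor task: this many subjects get head-shake
#'   annotations on more than half of their blocks and are excluded at the
#'   subject level.
#' @param plan startle task: block plan, see [startle_block_plan()]. Default
#'   `startle_block_plan(n_subjects)` (requires `n_subjects * 5` to match its
#'   counts; pass an explicit plan otherwise).
#' @param hemispheres channels to generate.
#' @return An object of class `synthetic_cohort`: `subjects`, `recordings`
#'   (named list of [od_recording()]), `schedule`, `annotations`, `truth`,
#'   `plan` (startle), `seed`.
#' @export
generate_cohort <- function(n_subjects, task = c("motor", "startle"),
                            truth = ground_truth(), seed = 1,
                            baseline = default_baseline(),
                            probe = probe_config(),
                            eps = sheep_extinction(),
                            n_frequent_shakers = 0,
                            plan = NULL,
                            hemispheres = c("left", "right")) {
  task <- match.arg(task)
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  fs <- probe$sampling_rate
  if (task == "motor") {
    n_blocks <- 10L
    onsets <- 30 + (seq_len(n_blocks) - 1) * 60
    dur <- 30 + n_blocks * 60
  } else {
    if (is.null(plan)) plan <- startle_block_plan(n_subjects)
    n_blocks <- max(plan$block)
    onsets <- 30 + (seq_len(n_blocks) - 1) * 100
    dur <- 30 + n_blocks * 100
  }
  subjects <- sprintf("sheep%02d", seq_len(n_subjects))
  sched <- block_schedule(task, onsets)

  with_seed(seed, {
    time <- seq(0, dur - 1 / fs, by = 1 / fs)
    recordings <- list()
    ann <- list()
    truths <- list()
    for (si in seq_along(subjects)) {
      s <- subjects[si]
      phase <- runif(1, 0, 2 * pi)
      if (task == "startle") {
        rows <- plan[plan$subject == s, , drop = FALSE]
        # the cortical response is planted only in blocks with a reaction
        active <- onsets[rows$block[rows$reaction]]
      } else {
        active <- onsets
      }
      conc <- truth_concentrations(time, active, truth, phase)
      od <- do.call(cbind, lapply(hemispheres, function(h)
        simulate_hemisphere_od(time, conc, baseline, probe, eps, truth, h)))
      recordings[[s]] <- od_recording(time, od, s)
      truths[[s]] <- list(concentrations = conc, mayer_phase = phase,
                          active_onsets = active)

      if (task == "motor") {
        if (si <= n_frequent_shakers) {
          # head shake on 60% of the blocks: subject-level exclusion
          for (b in seq_len(ceiling(0.6 * n_blocks))) {
            ann[[length(ann) + 1L]] <- data.frame(
              subject = s, behavior = "head_shake",
              start = onsets[b] + 10, end = onsets[b] + 12)
          }
        }
      } else {
        for (k in seq_len(nrow(rows))) {
          on <- onsets[rows$block[k]]
          if (rows$label[k] == "flight")
            ann[[length(ann) + 1L]] <- data.frame(
              subject = s, behavior = "flight", start = on + 4, end = on + 12)
          if (rows$label[k] == "freezing")
            ann[[length(ann) + 1L]] <- data.frame(
              subject = s, behavior = "freezing", start = on + 3.5, end = on + 25)
          if (rows$artifact[k] != "none")
            ann[[length(ann) + 1L]] <- data.frame(
              subject = s, behavior = rows$artifact[k],
              start = on + 20, end = on + 24)
        }
      }
    }
    annotations <- if (length(ann)) do.call(rbind, ann) else
      data.frame(subject = character(), behavior = character(),
                 start = numeric(), end = numeric())
    structure(list(subjects = subjects, task = task, recordings = recordings,
                   schedule = sched, annotations = annotations,
                   truth = list(params = truth, per_subject = truths),
                   plan = if (task == "startle") plan else NULL,
                   baseline = baseline, probe = probe, eps = eps,
                   seed = seed),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %s task, %d subjects, %d blocks each, seed %s\n",
              x$task, length(x$subjects), length(x$schedule$block_starts),
              format(x$seed)))
  invisible(x)
}

#' Write a synthetic cohort to disk in the pipeline's input formats
#'
#' One OD CSV per subject, an annotation CSV, and a JSON file holding the
#' schedule, probe/baseline configuration and the ground-truth parameters.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$subjects)
    write_od_csv(cohort$recordings[[s]], file.path(dir, paste0(s, ".csv")))
  write_annotations(cohort$annotations, file.path(dir, "annotations.csv"))
  up <- resolve_props(cohort$baseline$upper, cohort$probe$wavelengths[1])
  cfg <- list(
    task = cohort$task,
    subjects = as.list(stats::setNames(
      file.path(dir, paste0(cohort$subjects, ".csv")), cohort$subjects)),
    annotations = file.path(dir, "annotations.csv"),
    block_starts = cohort$schedule$block_starts,
    probe = list(rho_short = cohort$probe$rho_short,
                 rho_long = cohort$probe$rho_long,
                 wavelengths = cohort$probe$wavelengths,
                 sampling_rate = cohort$probe$sampling_rate),
    baseline = list(s = cohort$baseline$s,
                    mua0 = up$mua, musp0 = up$musp,
                    n_tissue = cohort$baseline$n_tissue,
                    n_external = cohort$baseline$n_external),
    extinction = list(wavelengths = as.numeric(rownames(cohort$eps)),
                      o2hb = as.numeric(cohort$eps[, "o2hb"]),
                      hhb = as.numeric(cohort$eps[, "hhb"])),
    truth = unclass(cohort$truth$params),
    seed = cohort$seed)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Default sheep-like baseline medium
#'
#' Placeholder baseline optical properties (mua0 = 0.015 mm^-1, musp0' = 1.0
#' mm^-1 at both wavelengths, s = 10 mm, n = 1.4/1.0), configurable per
#' wavelength.
#'
#' @param mua0,musp0 baseline coefficients, mm^-1.
#' @param s upper-layer thickness, mm.
#' @param wavelengths wavelengths, nm.
#' @param n_tissue,n_external refractive indices.
#' @return A [layered_medium()].
#' @export
default_baseline <- function(mua0 = 0.015, musp0 = 1.0, s = 10,
                             wavelengths = c(751, 839),
                             n_tissue = 1.4, n_external = 1.0) {
  props <- lapply(wavelengths, function(w) optical_properties(mua0, musp0, w))
  layered_medium(s, props, props, n_tissue, n_external)
}
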
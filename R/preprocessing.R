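# Ingestion of OD recordings, block segmentation, baseline-referenced delta-OD,
# and ethogram-driven exclusion / Move-Stand classification.
#
# All time intervals are half-open [start, end) in seconds.

#' Default ethogram vocabulary
#'
#' Behavior codes recognized by [apply_exclusion()] and [classify_reaction()].
#' `head_shake`, `chewing`, `running` and `jumping` interfere with the optical
#' recording; `flight` and `freezing` describe the reaction to the startle
#' stimulus. The vocabulary is config-extensible.
#' @return Character vector of codes.
#' @export
ethogram_codes <- function() {
  c("head_shake", "chewing", "running", "jumping",
    "flight", "freezing", "walking", "standing", "vocalization")
}

#' Default exclusion rules
#'
#' @param exclude_codes behaviors whose overlap with a block's analysis window
#'   excludes the block.
#' @param frequent_fraction subject-level threshold: a subject is dropped when
#'   one excluding behavior overlaps more than this fraction of their blocks
#'   ("frequent" head shaking).
#' @param require_reaction for the startle task, exclude blocks with neither
#'   flight nor freezing in the stimulus + reaction window.
#' @param vocabulary recognized behavior codes.
#' @return A list of rules for [apply_exclusion()].
#' @export
exclusion_rules <- function(exclude_codes = c("head_shake", "chewing",
                                              "running", "jumping"),
                            frequent_fraction = 0.5,
                            require_reaction = TRUE,
                            vocabulary = ethogram_codes()) {
  list(exclude_codes = exclude_codes, frequent_fraction = frequent_fraction,
       require_reaction = require_reaction, vocabulary = vocabulary)
}

# channel name convention: <hemisphere>_<distance>_<wavelength>, e.g.
# left_short_751.
parse_channels <- function(nms) {
  parts <- strsplit(nms, "_", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 3L
  if (any(bad))
    stop("channel names must be <hemi>_<dist>_<wavelength>: ",
         paste(nms[bad], collapse = ", "), call. = FALSE)
  data.frame(channel = nms,
             hemisphere = vapply(parts, `[`, "", 1L),
             distance = vapply(parts, `[`, "", 2L),
             wavelength = as.numeric(vapply(parts, `[`, "", 3L)))
}

#' Construct an OD recording
#'
#' @param time sample times, s; strictly increasing uniform grid.
#' @param od numeric matrix of decadic optical densities, one column per
#'   channel, column names `<hemi>_<dist>_<wavelength>` (e.g. `left_short_751`).
#' @param subject_id subject label.
#' @return An object of class `od_recording`.
#' @export
od_recording <- function(time, od, subject_id = "subject") {
  od <- as.matrix(od)
  if (length(time) != nrow(od)) stop("time/od length mismatch", call. = FALSE)
  dt <- diff(time)
  if (any(dt <= 0)) stop("time must be strictly increasing", call. = FALSE)
  if (length(dt) && (max(dt) > 1.5 * stats::median(dt)))
    stop("gaps larger than one sample in the time grid", call. = FALSE)
  channels <- parse_channels(colnames(od))
  structure(list(time = as.numeric(time), od = od, channels = channels,
                 subject_id = subject_id,
                 sampling_rate = 1 / stats::median(dt)),
            class = "od_recording")
}

#' @export
print.od_recording <- function(x, ...) {
  cat(sprintf("<od_recording> %s: %d samples @ %g Hz, %d channels\n",
              x$subject_id, length(x$time), round(x$sampling_rate, 3),
              ncol(x$od)))
  invisible(x)
}

#' Read / write OD recordings as delimited text
#'
#' CSV with a `time` column followed by one column per channel.
#'
#' @param path file path.
#' @param subject_id subject label for the returned recording.
#' @return [read_od_csv()] returns an `od_recording`.
#' @export
read_od_csv <- function(path, subject_id = sub("\\.csv$", "", basename(path))) {
  d <- read.csv(path, check.names = FALSE)
  if (!"time" %in% names(d)) stop("OD csv must have a `time` column", call. = FALSE)
  od_recording(d$time, as.matrix(d[setdiff(names(d), "time")]), subject_id)
}

#' @rdname read_od_csv
#' @param rec an `od_recording`.
#' @export
write_od_csv <- function(rec, path) {
  d <- data.frame(time = rec$time, check.names = FALSE)
  d <- cbind(d, as.data.frame(rec$od, check.names = FALSE))
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read / write behavior annotations
#'
#' CSV with columns `subject, behavior, start, end` (seconds, half-open).
#' @param path file path.
#' @export
read_annotations <- function(path) {
  d <- read.csv(path)
  need <- c("subject", "behavior", "start", "end")
  if (!all(need %in% names(d)))
    stop("annotation csv needs columns subject, behavior, start, end", call. = FALSE)
  if (any(d$start >= d$end)) stop("annotation with start >= end", call. = FALSE)
  d[need]
}

#' @rdname read_annotations
#' @param annotations data frame of annotations.
#' @export
write_annotations <- function(annotations, path) {
  write.csv(annotations[c("subject", "behavior", "start", "end")], path,
            row.names = FALSE)
  invisible(path)
}

#' Task block schedule
#'
#' `block_starts` mark the task-phase onset (walk onset for the motor task,
#' umbrella opening for the startle test). Phases (relative to onset, s):
#' motor `baseline [-5, 0), walk [0, 30), recovery [30, 35)`; startle
#' `baseline [-5, 0), stimulus [0, 3), reaction [3, 63)`. The baseline is the
#' last 5 s before onset. The analysis window spans all phases.
#'
#' @param task `"motor"` or `"startle"`.
#' @param block_starts onset times, s.
#' @param phases optional named list of `c(start, end)` phase intervals
#'   relative to onset, overriding the task defaults.
#' @return An object of class `block_schedule`.
#' @export
block_schedule <- function(task = c("motor", "startle"), block_starts,
                           phases = NULL) {
  task <- match.arg(task)
  if (is.null(phases)) {
    phases <- if (task == "motor") {
      list(baseline = c(-5, 0), walk = c(0, 30), recovery = c(30, 35))
    } else {
      list(baseline = c(-5, 0), stimulus = c(0, 3), reaction = c(3, 63))
    }
  }
  win <- range(unlist(phases))
  starts <- sort(as.numeric(block_starts))
  if (length(starts) > 1L && any(diff(starts) < diff(win)))
    stop("blocks overlap: starts closer than the analysis window", call. = FALSE)
  structure(list(task = task, block_starts = starts, phases = phases,
                 window = win), class = "block_schedule")
}

#' Cut a recording into per-block analysis windows
#'
#' One slice per block covering the analysis window (baseline through the end
#' of the task-specific span), with half-open sample selection
#' `start <= t < end`. Blocks extending past the recording are dropped with a
#' reason recorded in the `"dropped"` attribute.
#'
#' @param rec an [od_recording()].
#' @param sched a [block_schedule()].
#' @return List of `od_block` slices; each holds `time_rel` (s relative to
#'   onset), `od`, the absolute `window`, `phases`, `block` index and
#'   `subject_id`.
#' @export
segment_blocks <- function(rec, sched) {
  slices <- list()
  dropped <- data.frame(block = integer(), reason = character())
  for (b in seq_along(sched$block_starts)) {
    onset <- sched$block_starts[b]
    w0 <- onset + sched$window[1]
    w1 <- onset + sched$window[2]
    if (w0 < rec$time[1] - 1e-9 ||
        w1 > rec$time[length(rec$time)] + 1 / rec$sampling_rate + 1e-9) {
      dropped <- rbind(dropped, data.frame(block = b,
                                           reason = "outside recording"))
      message(sprintf("block %d dropped: analysis window [%g, %g) outside recording",
                      b, w0, w1))
      next
    }
    idx <- which(rec$time >= w0 - 1e-9 & rec$time < w1 - 1e-9)
    slices[[length(slices) + 1L]] <-
      structure(list(block = b, subject_id = rec$subject_id,
                     task = sched$task,
                     onset = onset,
                     time_rel = rec$time[idx] - onset,
                     od = rec$od[idx, , drop = FALSE],
                     channels = rec$channels,
                     window = c(w0, w1),
                     phases = sched$phases,
                     sampling_rate = rec$sampling_rate),
                class = "od_block")
  }
  attr(slices, "dropped") <- dropped
  slices
}

#' Baseline-referenced change in optical density for one block
#'
#' `delta OD(t) = OD(t) - mean(OD over the baseline window)` per channel, so
#' the mean over the baseline window is zero by construction. A zero-variance
#' (flat-line) channel is flagged, not dropped.
#'
#' @param block an `od_block` from [segment_blocks()].
#' @return An object of class `delta_od_series`: `time_rel`, `delta_od`
#'   matrix, `baseline_window`, `channels`, `flags$flat_channels`.
#' @export
compute_delta_od <- function(block) {
  bw <- block$phases$baseline
  sel <- block$time_rel >= bw[1] - 1e-9 & block$time_rel < bw[2] - 1e-9
  if (!any(sel)) stop("baseline window contains no samples", call. = FALSE)
  base <- colMeans(block$od[sel, , drop = FALSE])
  dod <- sweep(block$od, 2L, base)
  flat <- apply(block$od, 2L, function(x) stats::var(x) == 0)
  if (any(flat))
    warning("flat-line channel(s): ", paste(colnames(block$od)[flat], collapse = ", "),
            call. = FALSE)
  structure(list(block = block$block, subject_id = block$subject_id,
                 task = block$task, onset = block$onset,
                 time_rel = block$time_rel, delta_od = dod,
                 baseline_window = bw, phases = block$phases,
                 channels = block$channels,
                 sampling_rate = block$sampling_rate,
                 flags = list(flat_channels = colnames(block$od)[flat])),
            class = "delta_od_series")
}

# half-open interval overlap
overlaps <- function(a0, a1, b0, b1) a0 < b1 & a1 > b0

annotations_for <- function(annotations, subject_id) {
  if (is.null(annotations) || nrow(annotations) == 0L)
    return(annotations[0, , drop = FALSE])
  annotations[annotations$subject == subject_id, , drop = FALSE]
}

#' Ethogram-driven block and subject exclusion
#'
#' A block is excluded iff an annotation with an excluding code overlaps its
#' analysis window (half-open interval overlap). A subject is excluded
#' entirely when one excluding behavior overlaps more than
#' `rules$frequent_fraction` of their blocks (frequent head shaking). For the
#' startle task, a block with neither `flight` nor `freezing` annotated in the
#' stimulus + reaction window is excluded (`no_reaction`).
#'
#' @param blocks list of `od_block` or `delta_od_series` objects.
#' @param annotations data frame `subject, behavior, start, end` (absolute s).
#' @param rules see [exclusion_rules()].
#' @return List with `retained` (blocks) and `excluded`
#'   (data frame `subject, block, reason`).
#' @export
apply_exclusion <- function(blocks, annotations, rules = exclusion_rules()) {
  if (is.null(annotations)) {
    annotations <- data.frame(subject = character(), behavior = character(),
                              start = numeric(), end = numeric())
  }
  unknown <- setdiff(unique(annotations$behavior), rules$vocabulary)
  if (length(unknown))
    stop("unknown behavior code(s): ", paste(unknown, collapse = ", "),
         "; vocabulary: ", paste(rules$vocabulary, collapse = ", "),
         call. = FALSE)
  excluded <- data.frame(subject = character(), block = integer(),
                         reason = character())
  reason_of <- rep(NA_character_, length(blocks))

  for (i in seq_along(blocks)) {
    blk <- blocks[[i]]
    ann <- annotations_for(annotations, blk$subject_id)
    w <- if (!is.null(blk$window)) blk$window else blk$onset + range(unlist(blk$phases))
    hit <- ann$behavior %in% rules$exclude_codes &
      overlaps(ann$start, ann$end, w[1], w[2])
    if (any(hit)) {
      reason_of[i] <- paste0("behavior:", ann$behavior[which(hit)[1]])
      next
    }
    if (blk$task == "startle" && isTRUE(rules$require_reaction)) {
      rw <- blk$onset + c(blk$phases$stimulus[1], blk$phases$reaction[2])
      rx <- ann$behavior %in% c("flight", "freezing") &
        overlaps(ann$start, ann$end, rw[1], rw[2])
      if (!any(rx)) reason_of[i] <- "no_reaction"
    }
  }

  # subject-level: frequent excluding behavior across that subject's blocks
  subj <- vapply(blocks, function(b) b$subject_id, character(1))
  for (s in unique(subj)) {
    idx <- which(subj == s)
    ann <- annotations_for(annotations, s)
    for (code in rules$exclude_codes) {
      code_ann <- ann[ann$behavior == code, , drop = FALSE]
      if (nrow(code_ann) == 0L) next
      n_hit <- sum(vapply(idx, function(i) {
        w <- blocks[[i]]$window
        any(overlaps(code_ann$start, code_ann$end, w[1], w[2]))
      }, logical(1)))
      if (n_hit / length(idx) > rules$frequent_fraction) {
        reason_of[idx] <- paste0("frequent_", code)
      }
    }
  }

  keep <- is.na(reason_of)
  if (any(!keep)) {
    excluded <- data.frame(
      subject = subj[!keep],
      block = vapply(blocks[!keep], function(b) b$block, numeric(1)),
      reason = reason_of[!keep])
  }
  list(retained = blocks[keep], excluded = excluded)
}

#' Classify the startle reaction of a retained block
#'
#' `Move` iff a flight annotation overlaps the stimulus-or-reaction window;
#' `Stand` iff freezing is annotated and no flight. When both are present,
#' flight dominates (Move). A retained block with neither is a consistency
#' error: it should have been excluded.
#'
#' @param block an `od_block` or `delta_od_series` (startle task).
#' @param annotations annotation data frame.
#' @return `"Move"` or `"Stand"`.
#' @export
classify_reaction <- function(block, annotations) {
  if (block$task != "startle") stop("reaction classification is for the startle task",
                                    call. = FALSE)
  ann <- annotations_for(annotations, block$subject_id)
  rw <- block$onset + c(block$phases$stimulus[1], block$phases$reaction[2])
  in_win <- function(code) any(ann$behavior == code &
                               overlaps(ann$start, ann$end, rw[1], rw[2]))
  if (in_win("flight")) return("Move")
  if (in_win("freezing")) return("Stand")
  stop(sprintf("block %s/%d has neither flight nor freezing: should have been excluded",
               block$subject_id, block$block), call. = FALSE)
}
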
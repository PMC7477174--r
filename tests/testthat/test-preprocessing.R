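# Block segmentation, baseline referencing, ethogram exclusion and
# Move/Stand classification.

motor_recording <- function(n_blocks = 10, fs = 10, value = 1.0) {
  dur <- 30 + n_blocks * 60
  time <- seq(0, dur - 1 / fs, by = 1 / fs)
  od <- matrix(value, length(time), 2,
               dimnames = list(NULL, c("left_short_751", "left_long_751")))
  od_recording(time, od, "s1")
}

test_that("motor blocks segment into 400-sample analysis windows", {
  rec <- motor_recording()
  sched <- block_schedule("motor", 30 + (0:9) * 60)
  sl <- segment_blocks(rec, sched)
  expect_length(sl, 10)
  expect_true(all(vapply(sl, function(s) nrow(s$od), numeric(1)) == 400))
  expect_equal(sl[[1]]$time_rel[1], -5)
  expect_equal(sl[[1]]$time_rel[400], 34.9)
})

test_that("startle blocks are 680 samples and out-of-bounds blocks drop", {
  fs <- 10
  time <- seq(0, 529.9, by = 1 / fs)
  od <- matrix(rnorm(length(time)), ncol = 1,
               dimnames = list(NULL, "left_short_751"))
  rec <- od_recording(time, od, "s1")
  sched <- block_schedule("startle", 30 + (0:4) * 100)
  sl <- segment_blocks(rec, sched)
  expect_length(sl, 5)
  expect_true(all(vapply(sl, function(s) nrow(s$od), numeric(1)) == 680))
  # a block whose baseline starts before the recording is dropped, rest kept
  sched_bad <- block_schedule("startle", c(3, 130, 230, 330, 430))
  expect_message(sl2 <- segment_blocks(rec, sched_bad), "dropped")
  expect_length(sl2, 4)
  expect_equal(attr(sl2, "dropped")$block, 1L)
})

test_that("delta-OD referencing: constant input, step response, zero baseline mean", {
  rec <- motor_recording(n_blocks = 1)
  sched <- block_schedule("motor", 30)
  blk <- segment_blocks(rec, sched)[[1]]
  dod <- expect_warning(compute_delta_od(blk), "flat-line")
  expect_true(all(dod$delta_od == 0))
  # step of +0.01 at onset
  od <- matrix(1, 400, 1, dimnames = list(NULL, "left_short_751"))
  od[blk$time_rel >= 0, ] <- 1.01
  blk2 <- blk
  blk2$od <- od
  dod2 <- suppressWarnings(compute_delta_od(blk2))
  expect_equal(unname(dod2$delta_od[blk2$time_rel >= 0, 1]),
               rep(0.01, sum(blk2$time_rel >= 0)))
  base_sel <- dod2$time_rel >= -5 & dod2$time_rel < 0
  expect_equal(mean(dod2$delta_od[base_sel, 1]), 0)
  # flat-line channel is flagged with a warning, not an error
  expect_warning(compute_delta_od(blk), "flat-line")
})

test_that("exclusion follows half-open overlap and matches a brute-force oracle", {
  blocks <- lapply(1:20, function(b) make_block("s1", b, onset = b * 100))
  set.seed(7)
  ann <- data.frame(subject = "s1",
                    behavior = sample(c("chewing", "head_shake", "flight"),
                                      30, replace = TRUE),
                    start = runif(30, 0, 2100))
  ann$end <- ann$start + runif(30, 1, 40)
  # every block gets a reaction so only artifact exclusions fire
  ann <- rbind(ann, data.frame(subject = "s1", behavior = "flight",
                               start = (1:20) * 100 + 5, end = (1:20) * 100 + 10))
  res <- apply_exclusion(blocks, ann, exclusion_rules())
  # brute-force oracle: direct interval overlap per block
  exp_excl <- vapply(blocks, function(blk) {
    any(ann$behavior %in% c("chewing", "head_shake") &
          ann$start < blk$window[2] & ann$end > blk$window[1])
  }, logical(1))
  got_excl <- !(vapply(blocks, function(b) b$block, numeric(1)) %in%
                  vapply(res$retained, function(b) b$block, numeric(1)))
  frequent <- mean(exp_excl) > 0.5  # subject-level rule may widen the set
  if (!frequent) expect_equal(got_excl, exp_excl)
  expect_equal(length(res$retained) + nrow(res$excluded), length(blocks))
  # order-independence under annotation permutation
  res2 <- apply_exclusion(blocks, ann[sample(nrow(ann)), ], exclusion_rules())
  expect_equal(vapply(res2$retained, function(b) b$block, numeric(1)),
               vapply(res$retained, function(b) b$block, numeric(1)))
})

test_that("edge cases: no annotations, abutting interval, unknown code", {
  blocks <- lapply(1:3, function(b) make_block("s1", b, onset = b * 100,
                                               task = "motor"))
  res <- apply_exclusion(blocks, NULL, exclusion_rules())
  expect_length(res$retained, 3)
  expect_equal(nrow(res$excluded), 0)
  # annotation starting exactly at the window end does not overlap
  w_end <- blocks[[1]]$window[2]
  ann <- data.frame(subject = "s1", behavior = "chewing",
                    start = w_end, end = w_end + 5)
  res2 <- apply_exclusion(blocks, ann, exclusion_rules())
  expect_length(res2$retained, 3)
  # one sample earlier it does
  ann$start <- w_end - 0.1
  res3 <- apply_exclusion(blocks, ann, exclusion_rules())
  expect_length(res3$retained, 2)
  expect_error(apply_exclusion(blocks, data.frame(subject = "s1",
                                                  behavior = "grazing",
                                                  start = 0, end = 1),
                               exclusion_rules()),
               "unknown behavior")
})

test_that("startle blocks without a reaction are excluded; frequent shaking drops the subject", {
  blocks <- lapply(1:4, function(b) make_block("s1", b, onset = b * 100))
  ann <- data.frame(subject = "s1", behavior = "flight",
                    start = c(105, 205, 305), end = c(110, 210, 310))
  res <- apply_exclusion(blocks, ann, exclusion_rules())
  expect_length(res$retained, 3)
  expect_equal(res$excluded$reason, "no_reaction")
  # head shaking in 3 of 4 block windows: subject-level exclusion
  shake <- data.frame(subject = "s1", behavior = "head_shake",
                      start = c(110, 210, 310), end = c(112, 212, 312))
  res2 <- apply_exclusion(blocks, rbind(ann, shake), exclusion_rules())
  expect_length(res2$retained, 0)
  expect_true(all(res2$excluded$reason == "frequent_head_shake"))
})

test_that("reaction classification: flight wins, freezing alone stands", {
  blk <- make_block("s1", 1, onset = 100)
  flight <- data.frame(subject = "s1", behavior = "flight",
                       start = 105, end = 110)
  freeze <- data.frame(subject = "s1", behavior = "freezing",
                       start = 104, end = 120)
  expect_equal(classify_reaction(blk, flight), "Move")
  expect_equal(classify_reaction(blk, freeze), "Stand")
  expect_equal(classify_reaction(blk, rbind(flight, freeze)), "Move")
  none <- data.frame(subject = "s1", behavior = "chewing",
                     start = 105, end = 110)
  expect_error(classify_reaction(blk, none), "should have been excluded")
})

test_that("OD and annotation files round-trip through CSV", {
  rec <- motor_recording(n_blocks = 1)
  f <- tempfile(fileext = ".csv")
  write_od_csv(rec, f)
  back <- read_od_csv(f, "s1")
  expect_equal(back$od, rec$od)
  expect_equal(back$time, rec$time)
  ann <- data.frame(subject = "s1", behavior = "flight", start = 1, end = 2)
  fa <- tempfile(fileext = ".csv")
  write_annotations(ann, fa)
  expect_equal(read_annotations(fa), ann)
  unlink(c(f, fa))
})
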
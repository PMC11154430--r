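make_rec <- function(tensor, ...) pressure_recording(tensor, ...)

test_that("text frame files round-trip losslessly", {
  set.seed(1)
  tensor <- array(sample(0:50, 3 * 2 * 2, replace = TRUE), c(3, 2, 2))
  rec <- make_rec(tensor, dt = 0.02, cell_size = 0.005)
  path <- withr::local_tempfile(fileext = ".txt")
  write_frames_text(rec, path)
  back <- read_frames_text(path)
  expect_identical(back$tensor, rec$tensor + 0)
  expect_equal(back$dt, 0.02)
  expect_equal(back$cell_size, 0.005)
})

test_that("malformed frame files fail with informative errors", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# dt=0.02 cell=0.005 rows=2 cols=2 frames=1",
               "Frame 1", "1,2", "3"), path)
  expect_error(read_frames_text(path), "frame 1")
  writeLines(character(0), path)
  expect_error(read_frames_text(path), "empty")
  writeLines(c("1,2", "3,4"), path)
  expect_error(read_frames_text(path), "header")
})

test_that("pass segmentation splits on zero gaps of at least min_gap", {
  blk <- function(n, v) array(v, c(n, 2, 2))
  tensor <- abind_frames(list(blk(5, 1), blk(10, 0), blk(7, 2)))
  p <- segment_passes(make_rec(tensor), min_gap = 5)
  expect_equal(p$n_frames, c(5, 7))
  expect_equal(p$start, c(0, 15))
  # gap shorter than min_gap stays inside one pass
  p2 <- segment_passes(make_rec(tensor), min_gap = 12)
  expect_equal(nrow(p2), 1)
  # no zero frames: a single pass spanning everything
  p3 <- segment_passes(make_rec(blk(8, 3)), min_gap = 5)
  expect_equal(p3$start, 0)
  expect_equal(p3$end, 8)
  # all-zero recording: no passes, not an error
  expect_equal(nrow(segment_passes(make_rec(blk(6, 0)))), 0)
})

test_that("direction normalization flips odd passes and only them", {
  f1 <- matrix(c(1, 3, 2, 4), 2, 2)  # [[1,2],[3,4]]
  tensor <- array(0, c(7, 2, 2))
  tensor[1, , ] <- f1
  tensor[7, , ] <- f1
  rec <- make_rec(tensor)
  passes <- segment_passes(rec, min_gap = 5)
  expect_equal(nrow(passes), 2)
  norm <- normalize_direction(rec, passes)
  # pass index 0: unchanged
  expect_equal(norm$recording$tensor[1, , ], f1)
  # pass index 1: rows and columns reversed
  expect_equal(norm$recording$tensor[7, , ], matrix(c(4, 2, 3, 1), 2, 2))
  # total pressure conserved per frame
  expect_equal(apply(norm$recording$tensor, 1, sum),
               apply(tensor, 1, sum))
  # flip twice restores the original (involution)
  p2 <- norm$passes
  p2$normalized <- FALSE
  again <- normalize_direction(norm$recording, p2)
  expect_equal(again$recording$tensor, tensor)
  # double normalization with the flag honoured is an error
  expect_error(normalize_direction(norm$recording, norm$passes),
               "already normalized")
})

test_that("step detection recovers generator layout exactly", {
  co <- make_cohort(n_persons = 2, seed = 1)
  prof <- person_profile(co, "P01")
  rec <- simulate_recording(prof, n_passes = 4, steps_per_pass = 8,
                            seed = 7)
  truth <- attr(rec, "truth")
  steps <- extract_steps(rec)
  expect_equal(nrow(steps), 32)
  expect_equal(unname(table(steps$foot)["l"]), 16L)
  expect_equal(unname(table(steps$foot)["r"]), 16L)
  m <- dplyr::inner_join(
    dplyr::select(truth, foot, cycle, t_frame0 = frame0, t_frame1 = frame1),
    dplyr::select(steps, foot, cycle, frame0, frame1),
    by = c("foot", "cycle"))
  expect_equal(nrow(m), 32)
  expect_lte(max(abs(m$t_frame0 - m$frame0)), 1)
  expect_lte(max(abs(m$t_frame1 - m$frame1)), 1)
  # blank pass: no detections
  blank <- pressure_recording(array(0, c(10, 8, 8)))
  expect_equal(nrow(detect_steps(blank, segment_passes(blank))), 0)
})

test_that("step signals integrate pressure over the region box", {
  # uniform pressure P over A cells for one frame -> P * A * cell^2
  tensor <- array(0, c(3, 6, 6))
  tensor[2, 2:4, 3:5] <- 50
  rec <- make_rec(tensor, cell_size = 0.01)
  region <- tibble::tibble(pass = 1L, foot = "r", cycle = 1L,
                           row0 = 1L, row1 = 4L, col0 = 2L, col1 = 5L,
                           frame0 = 1L, frame1 = 2L, area = 9L)
  st <- extract_step_signal(rec, region, pad_to = 10)
  expect_equal(st$values[1], 50 * 9 * 0.01^2)
  expect_equal(st$values[2:10], rep(0, 9))
  expect_equal(st$stance_len, 1)
  # stance longer than pad_to is an error
  region_long <- region
  region_long$frame1 <- 30L
  expect_error(extract_step_signal(rec, region_long, pad_to = 10),
               "pad_to")
})

test_that("padding zeroes the tail and respects the stance", {
  st <- step_signal(c(5, 4, 3, 2, 1e-6, 1e-7), dt = 0.02)
  expect_equal(st$stance_len, 4)
  padded <- pad_step_signal(st, pad_to = 12)
  expect_equal(length(padded$values), 12)
  expect_identical(padded$values[5:12], rep(0, 8))
  st45 <- step_signal(c(seq(1, 45), rep(0, 10)), stance_len = 45)
  expect_error(pad_step_signal(st45, pad_to = 40), "pad_to")
})

test_that("detected step signals match the rendered ground truth", {
  co <- make_cohort(n_persons = 2, seed = 1)
  prof <- person_profile(co, "P02")
  rec <- simulate_recording(prof, n_passes = 2, steps_per_pass = 4,
                            seed = 11)
  truth <- attr(rec, "truth")
  steps <- extract_steps(rec)
  m <- dplyr::inner_join(
    dplyr::select(truth, foot, cycle, start_frame, t0 = frame0,
                  t1 = frame1, force),
    dplyr::select(steps, foot, cycle, frame0, signal),
    by = c("foot", "cycle"))
  for (i in seq_len(nrow(m))) {
    off <- m$frame0[i] - m$start_frame[i]
    tr <- m$force[[i]][(off + 1):length(m$force[[i]])]
    dv <- m$signal[[i]]$values[seq_along(tr)]
    expect_lt(sqrt(sum((tr - dv)^2) / sum(tr^2)), 0.01)
  }
})
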
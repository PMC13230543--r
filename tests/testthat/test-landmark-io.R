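# Pose CSV parsing, frame adequacy, the video quality gate and
# best-frame selection.

test_that("a three-header pose CSV parses into a tracked video", {
  sch <- one_point_schema()
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "scorer,net,net,net,net,net,net,net,net,net",
    "bodyparts,epiglottis_1,epiglottis_1,epiglottis_1,arytenoids_1,arytenoids_1,arytenoids_1,vocal_folds_1,vocal_folds_1,vocal_folds_1",
    "coords,x,y,likelihood,x,y,likelihood,x,y,likelihood",
    "0,10.5,20.5,0.91,30,40,0.85,50,60,0.99",
    "1,11.5,21.5,0.72,31,41,0.66,51,61,0.98"), path)
  v <- read_pose_csv(path, sch)
  expect_s3_class(v, "tracked_video")
  expect_equal(n_frames(v), 2)
  lm <- tidy(v)
  expect_equal(sort(unique(lm$structure)),
               c("arytenoids", "epiglottis", "vocal_folds"))
  expect_equal(lm$likelihood[lm$frame == 0 & lm$structure == "epiglottis"], 0.91)
  expect_equal(lm$x[lm$frame == 1 & lm$structure == "vocal_folds"], 51)
  expect_equal(lm$likelihood[lm$frame == 1 & lm$structure == "arytenoids"], 0.66)
})

test_that("non-numeric cells become missing points with likelihood 0", {
  sch <- one_point_schema()
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "scorer,net,net,net,net,net,net,net,net,net",
    "bodyparts,epiglottis_1,epiglottis_1,epiglottis_1,arytenoids_1,arytenoids_1,arytenoids_1,vocal_folds_1,vocal_folds_1,vocal_folds_1",
    "coords,x,y,likelihood,x,y,likelihood,x,y,likelihood",
    "0,nan,20.5,0.91,30,40,0.85,50,60,0.99"), path)
  v <- read_pose_csv(path, sch)
  lm <- tidy(v)
  epi <- lm[lm$structure == "epiglottis", ]
  expect_true(is.na(epi$x))
  expect_equal(epi$likelihood, 0)
})

test_that("empty data section yields a valid zero-frame video", {
  sch <- one_point_schema()
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "scorer,net,net,net,net,net,net,net,net,net",
    "bodyparts,epiglottis_1,epiglottis_1,epiglottis_1,arytenoids_1,arytenoids_1,arytenoids_1,vocal_folds_1,vocal_folds_1,vocal_folds_1",
    "coords,x,y,likelihood,x,y,likelihood,x,y,likelihood"), path)
  v <- read_pose_csv(path, sch)
  expect_equal(n_frames(v), 0)
  expect_error(video_passes_quality_gate(v), "at least one frame")
})

test_that("malformed headers and ragged rows raise informative errors", {
  sch <- one_point_schema()
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "scorer,net,net,net,net,net,net",
    "bodyparts,epiglottis_1,epiglottis_1,epiglottis_1,arytenoids_1,arytenoids_1,arytenoids_1",
    "coords,x,y,likelihood,x,y,likelihood",
    "0,1,2,0.5,3,4,0.5"), path)
  expect_error(read_pose_csv(path, sch), "vocal_folds_1")

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "scorer,net,net,net,net,net,net,net,net,net",
    "bodyparts,epiglottis_1,epiglottis_1,epiglottis_1,arytenoids_1,arytenoids_1,arytenoids_1,vocal_folds_1,vocal_folds_1,vocal_folds_1",
    "coords,x,y,likelihood,x,y,likelihood,x,y,likelihood",
    "0,1,2,0.5,3,4,0.5,5,6,0.5",
    "1,1,2,0.5,3,4"), path2)
  expect_error(read_pose_csv(path2, sch), "row 2")
})

test_that("write_pose_csv round-trips through read_pose_csv", {
  set.seed(11)
  lik <- replicate(4, runif(12, 0.3, 1), simplify = FALSE)
  v <- video_with_likelihoods(lik)
  # perturb coordinates so the round trip is non-trivial
  v$landmarks$x <- v$landmarks$x + runif(nrow(v$landmarks), -0.4, 0.4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pose_csv(v, path)
  v2 <- read_pose_csv(path)
  expect_equal(tidy(v2)$x, tidy(v)$x, tolerance = 1e-6)
  expect_equal(tidy(v2)$y, tidy(v)$y, tolerance = 1e-6)
  expect_equal(tidy(v2)$likelihood, tidy(v)$likelihood, tolerance = 1e-6)

  # zero-frame video writes a header-only file
  v0 <- read_pose_csv(path, fps = 30)
  empty <- v0
  empty$landmarks <- empty$landmarks[0, ]
  p0 <- withr::local_tempfile(fileext = ".csv")
  write_pose_csv(empty, p0)
  expect_length(readLines(p0), 3)
  expect_equal(n_frames(read_pose_csv(p0)), 0)
})

test_that("frame adequacy follows the all-points criterion", {
  lm <- demo_frame_landmarks()
  expect_true(frame_is_adequate(lm, 0.70))
  lm$likelihood[5] <- 0.69
  expect_false(frame_is_adequate(lm, 0.70))
  expect_true(frame_is_adequate(lm, 0))
  # mean aggregation tolerates a single weak point
  expect_true(frame_is_adequate(lm, 0.70, method = "mean"))
})

test_that("quality gate excludes videos with a majority of poor frames", {
  good <- rep(0.99, 12)
  bad <- rep(0.50, 12)
  v5 <- video_with_likelihoods(c(replicate(5, bad, simplify = FALSE),
                                 replicate(5, good, simplify = FALSE)))
  v6 <- video_with_likelihoods(c(replicate(6, bad, simplify = FALSE),
                                 replicate(4, good, simplify = FALSE)))
  expect_true(video_passes_quality_gate(v5))   # exactly 50% still passes
  expect_false(video_passes_quality_gate(v6))  # more than 50% fails
  expect_true(video_passes_quality_gate(
    video_with_likelihoods(replicate(10, good, simplify = FALSE))))
})

test_that("quality gate is monotone in both thresholds", {
  set.seed(42)
  for (rep in 1:20) {
    lik <- replicate(8, runif(12, 0.2, 1), simplify = FALSE)
    v <- video_with_likelihoods(lik)
    thr <- sort(runif(2))
    frac <- sort(runif(2))
    # raising the likelihood threshold can only lose the pass
    expect_true(video_passes_quality_gate(v, thr[2], frac[1]) <=
                  video_passes_quality_gate(v, thr[1], frac[1]))
    # raising the tolerated fraction can only gain the pass
    expect_true(video_passes_quality_gate(v, thr[1], frac[1]) <=
                  video_passes_quality_gate(v, thr[1], frac[2]))
  }
})

test_that("best-frame selection maximizes mean likelihood with early ties", {
  mk <- function(m) rep(m, 12)
  v <- video_with_likelihoods(lapply(c(0.5, 0.9, 0.7), mk))
  expect_equal(select_best_frame(v, 0, 3 / 30), 1)
  v_tie <- video_with_likelihoods(lapply(c(0.8, 0.8, 0.8), mk))
  expect_equal(select_best_frame(v_tie, 0, 3 / 30), 0)
  expect_error(select_best_frame(v, 10, 11), "no frame")
})

test_that("best-frame selection is invariant to likelihood rescaling and
           matches a brute-force argmax", {
  set.seed(7)
  for (rep in 1:10) {
    lik <- replicate(9, runif(12, 0.1, 0.9), simplify = FALSE)
    v <- video_with_likelihoods(lik)
    best <- select_best_frame(v, 0, 9 / 30)
    means <- vapply(lik, mean, numeric(1))
    expect_equal(best, which.max(means) - 1L)
    v_scaled <- v
    v_scaled$landmarks$likelihood <- v$landmarks$likelihood * 0.5
    expect_equal(select_best_frame(v_scaled, 0, 9 / 30), best)
  }
})

test_that("interval files round-trip and are validated", {
  iv <- tibble::tibble(swallow_id = c("s1", "s2"),
                       t_start = c(0, 2), t_end = c(1.5, 3.5),
                       t_whiteout = c(0.8, 2.6))
  path <- withr::local_tempfile(fileext = ".csv")
  write_intervals(iv, path)
  expect_equal(read_intervals(path), iv)

  ypath <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("swallows:",
               "- swallow_id: s1", "  t_start: 0", "  t_end: 1.5",
               "  t_whiteout: 0.8"), ypath)
  expect_equal(read_intervals(ypath)$t_whiteout, 0.8)

  bad <- iv
  bad$t_whiteout[1] <- 2.0
  bpath <- withr::local_tempfile(fileext = ".csv")
  write_intervals(bad, bpath)
  expect_error(read_intervals(bpath), "t_start <= t_whiteout <= t_end")
})
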
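# Residue fractions, YPR-SRS severity mapping, the 3x3 invasion rule and
# per-swallow orchestration.

test_that("severity mapping reproduces the published cut points", {
  expect_equal(as.character(severity_from_fraction(0)), "absence")
  expect_equal(as.character(severity_from_fraction(0.009)), "absence")
  expect_equal(as.character(severity_from_fraction(0.01)), "trace")
  expect_equal(as.character(severity_from_fraction(0.03)), "trace")
  expect_equal(as.character(severity_from_fraction(0.05)), "mild")
  expect_equal(as.character(severity_from_fraction(0.25)), "moderate")
  expect_equal(as.character(severity_from_fraction(0.30)), "moderate")
  expect_equal(as.character(severity_from_fraction(0.50)), "moderate")
  expect_equal(as.character(severity_from_fraction(0.51)), "severe")
  expect_equal(as.character(severity_from_fraction(0.75)), "severe")
  # alternative closure at the 50% tie
  expect_equal(as.character(severity_from_fraction(0.50, TRUE)), "severe")
  expect_error(severity_from_fraction(1.2), "\\[0, 1\\]")
  expect_error(severity_from_fraction(-0.1), "\\[0, 1\\]")
})

test_that("severity mapping is total, single-valued and monotone on a
           fine sweep", {
  f <- seq(0, 1, by = 1e-4)
  lv <- severity_from_fraction(f)
  expect_false(anyNA(lv))
  expect_true(all(diff(as.integer(lv)) >= 0))
  expect_equal(length(unique(lv)), 5)
})

test_that("residue_fraction counts pixels exactly over the half-open box", {
  ones <- EBImage::Image(1, dim = c(12, 12))
  zeros <- EBImage::Image(0, dim = c(12, 12))
  roi <- rect_roi(1, 1, 11, 11)
  expect_equal(residue_fraction(ones, roi)$fraction, 1)
  expect_equal(residue_fraction(zeros, roi)$fraction, 0)

  set.seed(33)
  mask <- EBImage::Image(0, dim = c(10, 10))
  on <- sample(100, 25)
  mask[on] <- 1
  full <- rect_roi(0, 0, 10, 10)
  rf <- residue_fraction(mask, full)
  expect_equal(rf$blue_pixels, 25L)
  expect_equal(rf$total_pixels, 100L)
  expect_equal(rf$fraction, 0.25)

  expect_error(residue_fraction(mask, rect_roi(0, 0, 11, 10)), "bounds")
})

test_that("residue_fraction equals the brute-force per-pixel loop", {
  set.seed(12)
  for (rep in 1:5) {
    w <- sample(20:64, 1); h <- sample(20:64, 1)
    mask <- EBImage::Image(matrix(rbinom(w * h, 1, 0.3), w, h))
    x0 <- sample(0:(w - 5), 1); y0 <- sample(0:(h - 5), 1)
    x1 <- sample((x0 + 1):w, 1); y1 <- sample((y0 + 1):h, 1)
    roi <- rect_roi(x0, y0, x1, y1)
    expect_equal(residue_fraction(mask, roi)$blue_pixels,
                 oracle_residue_count(mask, x0, y0, x1, y1))
  }
})

test_that("classify_region recovers planted severities through the full
           image chain", {
  targets <- list(c(0, "absence"), c(0.03, "trace"), c(0.30, "moderate"))
  for (tg in targets) {
    f <- as.numeric(tg[1])
    pf <- make_phantom_frame(phantom_spec(
      residue_fractions = c(vallecula = f, pyriform = f), seed = 77))
    img <- enhance_frame(pf$image)
    meas <- classify_region(img, pf$rois$vallecula, region = "vallecula")
    expect_equal(as.character(meas$severity), tg[2])
    expect_lt(abs(meas$fraction - f), 0.01)
  }
})

test_that("the invasion rule flags central cells as aspiration and
           peripheral cells as penetration", {
  sq <- rect_roi(0, 0, 30, 30)
  grid <- glottis_grid(sq)
  mk_mask <- function(cells) {
    m <- EBImage::Image(0, dim = c(30, 30))
    for (cc in cells) {
      cell <- grid$cells[[cc[1], cc[2]]]
      m[(cell$x0 + 3):(cell$x1 - 2), (cell$y0 + 3):(cell$y1 - 2)] <- 1
    }
    m
  }
  centre_only <- detect_invasion(NULL, grid, mask = mk_mask(list(c(2, 2))))
  expect_true(centre_only$aspiration)
  expect_false(centre_only$penetration)
  expect_equal(centre_only$argmax_cell, c(2L, 2L))

  corner_only <- detect_invasion(NULL, grid, mask = mk_mask(list(c(1, 3))))
  expect_true(corner_only$penetration)
  expect_false(corner_only$aspiration)

  both <- detect_invasion(NULL, grid,
                          mask = mk_mask(list(c(2, 2), c(3, 1))))
  expect_true(both$penetration && both$aspiration)

  none <- detect_invasion(NULL, grid, mask = EBImage::Image(0, dim = c(30, 30)))
  expect_false(none$penetration || none$aspiration)

  # the centre-column reading of the glottic entry is configurable
  cfg_col <- geometry_config(central_cells = list(c(1, 2), c(2, 2), c(3, 2)))
  top_mid <- detect_invasion(NULL, grid, cfg = cfg_col,
                             mask = mk_mask(list(c(1, 2))))
  expect_true(top_mid$aspiration)
  expect_false(top_mid$penetration)
})

test_that("invasion flags are monotone: adding residue never clears a
           flag", {
  set.seed(55)
  grid <- glottis_grid(rect_roi(0, 0, 30, 30))
  for (rep in 1:20) {
    m1 <- EBImage::Image(matrix(rbinom(900, 1, 0.05), 30, 30))
    extra <- matrix(rbinom(900, 1, 0.1), 30, 30)
    m2 <- EBImage::Image(pmax(as.array(m1), extra))
    c1 <- detect_invasion(NULL, grid, mask = m1)
    c2 <- detect_invasion(NULL, grid, mask = m2)
    expect_true(c2$penetration >= c1$penetration)
    expect_true(c2$aspiration >= c1$aspiration)
  }
})

test_that("analyze_swallow recovers planted labels and respects the
           whiteout frame ordering", {
  cells <- matrix(0, 3, 3); cells[2, 2] <- 0.25
  clean <- phantom_spec()
  loaded <- phantom_spec(residue_fractions = c(vallecula = 0.30,
                                               pyriform = 0.03),
                         glottis_cell_fractions = cells)
  white <- phantom_spec(whiteout = TRUE)
  gen <- make_tracked_video(list(clean, clean, white, loaded, loaded),
                            seed = 99)
  interval <- tibble::tibble(swallow_id = "s1", t_start = 0,
                             t_whiteout = 2.5 / 30, t_end = 4.9 / 30)
  sa <- analyze_swallow(gen$video, gen$images, interval)

  expect_lt(sa$pre_frame, sa$whiteout_frame)
  expect_gte(sa$post_frame, sa$whiteout_frame)
  expect_true(sa$post_frame > 2 && sa$pre_frame < 2)

  m <- sa$measurements
  expect_equal(as.character(m$severity[m$region == "vallecula"]), "moderate")
  expect_equal(as.character(m$severity[m$region == "pyriform"]), "trace")
  expect_true(sa$invasion$aspiration)
  expect_false(sa$invasion$penetration)
  # the pre-whiteout baseline is clean
  expect_true(all(sa$baseline$severity == "absence"))

  # clean swallow: everything absent, no flags
  gen0 <- make_tracked_video(list(clean, clean, white, clean, clean),
                             seed = 100)
  sa0 <- analyze_swallow(gen0$video, gen0$images, interval)
  expect_true(all(sa0$measurements$severity == "absence"))
  expect_false(sa0$invasion$penetration || sa0$invasion$aspiration)

  # a window with no frame on one side names the failing side
  bad <- tibble::tibble(swallow_id = "s2", t_start = 0,
                        t_whiteout = 0.2 / 30, t_end = 4.9 / 30)
  expect_error(analyze_swallow(gen$video, gen$images, bad),
               "before the whiteout")
})

test_that("tidiers expose swallow results as tibbles", {
  clean <- phantom_spec()
  white <- phantom_spec(whiteout = TRUE)
  loaded <- phantom_spec(residue_fractions = c(vallecula = 0.10,
                                               pyriform = 0))
  gen <- make_tracked_video(list(clean, clean, white, loaded, loaded),
                            seed = 101)
  interval <- tibble::tibble(swallow_id = "s1", t_start = 0,
                             t_whiteout = 2.5 / 30, t_end = 4.9 / 30)
  sa <- analyze_swallow(gen$video, gen$images, interval)
  td <- tidy(sa)
  expect_equal(nrow(td), 4)
  expect_setequal(unique(td$phase), c("pre", "post"))
  gl <- glance(sa)
  expect_equal(as.character(gl$vallecula_severity), "mild")
  inv <- tidy(sa$invasion)
  expect_equal(nrow(inv), 9)
  expect_equal(sum(inv$central), 1)
  expect_s3_class(autoplot(sa$invasion), "ggplot")
})
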
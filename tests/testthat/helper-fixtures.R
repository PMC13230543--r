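# Shared fixtures. The two 60-case validation cohorts used by the
# end-to-end recovery tests are expensive, so they are built once per
# session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

cohort_clean_60 <- function() {
  cached("cohort_clean_60", function() {
    make_validation_cohort(60, seed = 20260901)
  })
}

cohort_jittered_60 <- function() {
  cached("cohort_jittered_60", function() {
    make_validation_cohort(60, seed = 20260902, jitter_sd = 2, glare_count = 3)
  })
}

# a small landmark table where every structure has well-separated points
demo_frame_landmarks <- function() {
  lm <- default_phantom_landmarks()
  lm$likelihood <- 0.99
  lm
}

# build a tracked_video with one row per schema point per frame, constant
# coordinates, and the given per-frame likelihood vectors
video_with_likelihoods <- function(lik_per_frame, fps = 30) {
  base <- default_phantom_landmarks()
  landmarks <- dplyr::bind_rows(lapply(seq_along(lik_per_frame), function(i) {
    dplyr::mutate(base, frame = i - 1L, likelihood = lik_per_frame[[i]],
                  .before = 1)
  }))
  tracked_video(landmarks, fps = fps)
}

# a 1-point-per-structure schema for compact CSV parsing fixtures
one_point_schema <- function() {
  mk <- function(structs) {
    stats::setNames(lapply(structs, function(s) list(structure = s, point = 1L)),
                    paste0("P", seq_along(structs)))
  }
  landmark_schema(
    structures = c("epiglottis", "arytenoids", "vocal_folds"),
    points_per_structure = 1L,
    role_map = list(
      glottis = mk(c("vocal_folds", "arytenoids", "epiglottis")),
      pyriform = mk(c("arytenoids", "vocal_folds", "epiglottis", "arytenoids")),
      vallecula = mk(c("epiglottis", "vocal_folds", "arytenoids", "epiglottis"))
    ))
}
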
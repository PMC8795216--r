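test_that("TAC extraction carries geometry and matches the render", {
  spec <- straight_tube_spec(5, noise_sigma = 0)
  r <- rasterize_tree(spec)
  dyn <- render_dynamic(spec, r)
  path <- data.frame(i = 10:20, j = 5, k = 5, arclength_mm = 0:10)
  tacs <- extract_tacs(dyn, path)
  expect_length(tacs, 11L)
  expect_true(all(diff(vapply(tacs, function(t) t$arclength_mm, 1)) > 0))
  ## raw TAC equals the sampled gamma-variate at that voxel
  arr <- attr(dyn, "arrival")
  tt <- (0:29) * spec$dt
  expect_equal(tacs[[1]]$values,
               40 + gamma_variate(tt - arr[10, 5, 5], 400, 6, 3))
  expect_error(extract_tacs(dyn, data.frame(i = 99, j = 5, k = 5,
                                            arclength_mm = 0)),
               "outside")
})

test_that("conditioning is zero-phase and reduces noise", {
  tt <- (0:29) * 2
  ## a constant TAC becomes all zeros after baseline subtraction
  cst <- condition_tac(tac(tt, rep(120, 30)))
  expect_equal(max(abs(cst$values)), 0)
  expect_equal(cst$state, "conditioned")
  ## exact 4 s shifted copies stay shifted copies on the upsampled grid
  a <- tac(tt, 40 + gamma_variate(tt - 10, 400, 6, 3))
  b <- tac(tt, 40 + gamma_variate(tt - 14, 400, 6, 3))
  ca <- condition_tac(a); cb <- condition_tac(b)
  k <- 4 / (ca$times[2] - ca$times[1])  # samples per 4 s on the fine grid
  n <- length(ca$values)
  core <- 30:(n - 30)                   # away from the record edges
  expect_lt(max(abs(cb$values[core + k] - ca$values[core])), 1e-3 * 400)
  ## the induced differential delay is far below the 0.1 s budget
  d <- xcorr_delay(cb, ca)
  expect_lt(abs(d$delay_s - 4), 0.1)
  ## low-pass contract: white noise loses variance
  set.seed(1)
  wn <- tac(tt, rnorm(30, 0, 50))
  cw <- condition_tac(wn, cutoff_hz = 0.1)
  expect_lt(var(cw$values), var(wn$values))
  ## cutoff at or above the upsampled Nyquist is rejected
  expect_error(condition_tac(wn, upsample_factor = 1, cutoff_hz = 0.3),
               "Nyquist")
})

test_that("the 5% QC rule discards weak TACs with a strict inequality", {
  tt <- seq(0, 58, by = 2)
  shape <- gamma_variate(tt - 10, 1, 6, 3)
  mk <- function(peak) tac(tt, shape / max(shape) * peak, state = "conditioned")
  ref <- mk(400)
  tacs <- lapply(c(8, 19.9, 20, 400), mk)
  flagged <- qc_discard(tacs, ref)
  expect_equal(vapply(flagged, function(t) attr(t, "valid"), TRUE),
               c(FALSE, FALSE, TRUE, TRUE))
  expect_match(attr(flagged[[1]], "qc_reason"), "5%")
  ## identical TACs are all kept
  same <- qc_discard(list(ref, ref), ref)
  expect_true(all(vapply(same, function(t) attr(t, "valid"), TRUE)))
  ## a non-positive reference is an error
  expect_error(qc_discard(tacs, tac(tt, -shape, state = "conditioned")),
               "non-positive")
})

test_that("cross-correlation delays behave like a metric on shifts", {
  tt <- seq(0, 58, by = 2)
  a <- tac(tt, gamma_variate(tt - 10, 400, 6, 3), state = "conditioned")
  b <- tac(tt, gamma_variate(tt - 14, 400, 6, 3), state = "conditioned")
  ## identity
  d0 <- xcorr_delay(a, a)
  expect_equal(d0$delay_s, 0)
  expect_equal(d0$correlation_peak, 1)
  ## integer-multiple shift
  dab <- xcorr_delay(b, a, refine = FALSE)
  expect_equal(dab$delay_s, 4)
  ## antisymmetry within one time step
  dba <- xcorr_delay(a, b, refine = FALSE)
  expect_lte(abs(dab$delay_s + dba$delay_s), 2)
  ## amplitude invariance
  b5 <- tac(tt, 5 * b$values, state = "conditioned")
  expect_equal(xcorr_delay(b5, a)$delay_s, xcorr_delay(b, a)$delay_s)
  ## zero-variance input is flagged invalid, not an error
  z <- xcorr_delay(tac(tt, rep(0, 30), state = "conditioned"), a)
  expect_false(z$valid)
  expect_match(z$reason, "zero-variance")
})

test_that("sub-sample refinement reaches 0.2 s accuracy on fractional shifts", {
  tt <- (0:29) * 2
  for (shift in c(3.0, 1.4, 5.7)) {
    a <- condition_tac(tac(tt, 40 + gamma_variate(tt - 10, 400, 6, 3)))
    b <- condition_tac(tac(tt, 40 + gamma_variate(tt - 10 - shift, 400, 6, 3)))
    est <- xcorr_delay(b, a)$delay_s
    oracle <- oracle_dense_delay(
      function(t) gamma_variate(t - 10, 400, 6, 3),
      function(t) gamma_variate(t - 10 - shift, 400, 6, 3),
      duration = 58, lag_max = 10)
    expect_lt(abs(est - oracle), 0.2)
    expect_lt(abs(oracle - shift), 0.02)  # the oracle itself is near-exact
  }
})

test_that("delay profiles group valid points by segment", {
  path <- data.frame(segment_id = c(rep("proximal", 3), "thrombus",
                                    rep("mother", 4), rep("daughter1", 5)),
                     arclength_mm = 0:12)
  delays <- data.frame(arclength_mm = 0:12, delay_s = 0.1 * (0:12),
                       valid = TRUE)
  prof <- delay_profile(path, delays)
  expect_named(prof$series, c("mother", "daughter1"))
  expect_equal(nrow(prof$series$mother) + nrow(prof$series$daughter1), 9L)
  ## all-discarded distal points leave an empty flagged series
  delays$valid[path$segment_id == "daughter1"] <- FALSE
  prof2 <- delay_profile(path, delays)
  expect_named(prof2$series, "mother")
  expect_match(prof2$flags, "daughter1")
})

test_that("segment velocity fits invert the delay slope with a dead-band", {
  ## exact anterograde line: slope 0.2 s/mm -> +5 mm/s
  s1 <- data.frame(arclength_mm = c(0, 20, 40), delay_s = c(0, 4, 8))
  f1 <- fit_segment_velocity(s1)
  expect_equal(f1$slope_s_per_mm, 0.2)
  expect_equal(f1$velocity_mm_s, 5)
  expect_equal(f1$direction, "anterograde")
  ## exact retrograde line: slope -0.1 -> -10 mm/s
  f2 <- fit_segment_velocity(data.frame(arclength_mm = c(0, 20, 40),
                                        delay_s = c(4, 2, 0)))
  expect_equal(f2$velocity_mm_s, -10)
  expect_equal(f2$direction, "retrograde")
  ## all-zero delays (flow too fast for the frame interval): unresolved
  f3 <- fit_segment_velocity(data.frame(arclength_mm = seq(0, 40, 10),
                                        delay_s = rep(0, 5)))
  expect_equal(f3$direction, "unresolved")
  ## fewer than 3 points: unresolved with NA velocity
  f4 <- fit_segment_velocity(data.frame(arclength_mm = c(0, 10),
                                        delay_s = c(0, 1)))
  expect_equal(f4$direction, "unresolved")
  expect_true(is.na(f4$velocity_mm_s))
  ## Theil-Sen shrugs off a gross outlier that flips the OLS slope
  s5 <- data.frame(arclength_mm = seq(0, 40, 5),
                   delay_s = 0.2 * seq(0, 40, 5))
  s5$delay_s[9] <- -40
  f5 <- fit_segment_velocity(s5, method = "theilsen")
  expect_equal(f5$velocity_mm_s, 5, tolerance = 0.2)
})

test_that("pattern classification follows the daughter-direction vote", {
  row <- function(seg, dir) data.frame(path_id = 1, segment_id = seg,
    slope_s_per_mm = 0.1, velocity_mm_s = 10, direction = dir, n_points = 5,
    r_squared = 0.99, residual_sd_s = 0.1)
  expect_equal(classify_pattern(rbind(row("daughter1", "anterograde"),
                                      row("daughter2", "anterograde")))$pattern, "I")
  expect_equal(classify_pattern(rbind(row("daughter1", "retrograde"),
                                      row("daughter2", "retrograde")))$pattern, "II")
  expect_equal(classify_pattern(rbind(row("daughter1", "anterograde"),
                                      row("daughter2", "retrograde"),
                                      row("daughter3", "retrograde")))$pattern, "III")
  ## unresolved daughters are excluded from the vote but reported
  p <- classify_pattern(rbind(row("daughter1", "anterograde"),
                              row("daughter2", "unresolved")))
  expect_equal(p$pattern, "I")
  expect_match(p$notes, "daughter2")
  ## the mother segment does not vote
  expect_equal(classify_pattern(rbind(row("mother", "retrograde"),
                                      row("daughter1", "anterograde")))$pattern, "I")
  ## no resolved daughters: indeterminate, not an error
  expect_equal(classify_pattern(row("daughter1", "unresolved"))$pattern,
               "indeterminate")
})
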
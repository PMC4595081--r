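# Posture analytics: angles, coils, locomotion, eigenworms, clustering,
# event statistics, transition summaries.

test_that("relative angles capture curvature with the documented conventions", {
  straight <- cbind(seq(0, 180, length.out = 25), 40)
  a <- midline_angles(straight)
  expect_length(a$angles, 18)
  expect_equal(a$angles, rep(0, 18), tolerance = 1e-10)

  # constant-curvature arc with total turning Theta: every relative angle
  # (two intervals per pair) equals Theta / 10
  for (theta in c(0.8, -1.4, 2.5)) {
    arc <- arc_midline(theta, n = 201)
    a <- midline_angles(arc)$angles
    expect_equal(a, rep(theta / 10, 18), tolerance = 0.01)
  }

  # rigid rotation leaves all angles unchanged
  arc <- arc_midline(1.2, n = 201)
  phi <- 0.83
  rot <- cbind(arc[, 1] * cos(phi) - arc[, 2] * sin(phi),
               arc[, 1] * sin(phi) + arc[, 2] * cos(phi))
  expect_equal(midline_angles(rot)$angles, midline_angles(arc)$angles,
               tolerance = 1e-8)

  expect_error(midline_angles(cbind(1:3, 1)), "at least 5")
})

test_that("the posterior body angle is the most posterior relative angle", {
  expect_equal(posterior_body_angle(midline_angles(cbind(1:25, 3))), 0)
  arc <- arc_midline(1.5, n = 201)
  expect_equal(posterior_body_angle(midline_angles(arc)), 0.15,
               tolerance = 0.01)
  mirrored <- cbind(arc[, 1], -arc[, 2])
  expect_equal(posterior_body_angle(midline_angles(mirrored)),
               -posterior_body_angle(midline_angles(arc)), tolerance = 1e-8)
})

test_that("coil detection matches closed-form geometries", {
  straight <- cbind(seq(0, 180, length.out = 41), 10)
  cs <- detect_coils(straight)
  expect_false(cs$anterior); expect_false(cs$posterior)

  # closed circle: head adjacent to the tail region -> both coils
  th <- seq(0, 2 * pi * 0.99, length.out = 101)
  r <- 180 / (2 * pi)
  circle <- cbind(r * sin(th), r * (1 - cos(th)))
  cc <- detect_coils(circle)
  expect_true(cc$anterior); expect_true(cc$posterior)

  # omega fixture: head near mid-body, tail free
  sp <- sample_posture("omega", seed = 7)
  co <- detect_coils(posture_midline(sp))
  expect_true(co$anterior); expect_false(co$posterior)

  # invariance under rigid motion and uniform scaling
  for (fac in c(0.5, 3)) {
    sc <- circle * fac
    sc <- cbind(sc[, 1] * cos(1) - sc[, 2] * sin(1) + 17,
                sc[, 1] * sin(1) + sc[, 2] * cos(1) - 4)
    c2 <- detect_coils(sc)
    expect_equal(c2$anterior, cc$anterior)
    expect_equal(c2$posterior, cc$posterior)
  }

  # direction is reported only when a chirality convention is supplied
  expect_equal(cc$direction, "unknown")
  expect_true(detect_coils(circle, ventral_sign = 1)$direction
              %in% c("ventral", "dorsal"))
})

test_that("locomotion states recover traveling-wave direction across speeds", {
  fps <- 10
  for (freq in c(0.15, 0.4, 1.2)) {
    fwd <- wave_angles(200, fps, dir = 1, freq = freq)
    st <- classify_locomotion(fwd, fps)
    inner <- st[30:170]
    expect_gt(mean(inner == "forward"), 0.9,
              label = sprintf("forward recovery at %.2f Hz", freq))
    # time reversal swaps the direction
    st_rev <- classify_locomotion(fwd[200:1, ], fps)
    expect_gt(mean(st_rev[30:170] == "backward"), 0.9)
  }
  # constant angles are quiescent
  const <- matrix(0.3, 120, 18)
  expect_true(all(classify_locomotion(const, fps) == "quiescent"))
  expect_error(classify_locomotion(matrix(0, 3, 18), fps), "window")
})

test_that("eigenworm decompositions are orthonormal, exact and ordered", {
  # ensemble drawn from exactly two orthogonal modes
  set.seed(11)
  m1 <- sin(2 * pi * (1:18) / 18) / sqrt(sum(sin(2 * pi * (1:18) / 18)^2))
  m2 <- cos(2 * pi * (1:18) / 18) / sqrt(sum(cos(2 * pi * (1:18) / 18)^2))
  amps <- cbind(rnorm(200, sd = 2), rnorm(200, sd = 1))
  X <- amps %*% rbind(m1, m2)
  eg <- eigenworms(X)
  expect_equal(sum(eg$explained_variance[1:2]), 1, tolerance = 1e-9)
  # orthonormality and completeness
  expect_equal(unname(crossprod(eg$modes)), diag(18), tolerance = 1e-9)
  cum <- cumsum(eg$explained_variance)
  expect_true(all(diff(cum) >= -1e-12))
  expect_equal(cum[18], 1, tolerance = 1e-12)
  # projection then reconstruction is the identity
  rec <- eg$amplitudes %*% t(eg$modes) +
    matrix(eg$center, nrow(X), 18, byrow = TRUE)
  expect_equal(rec, X, tolerance = 1e-9)
  # predict() projects new postures consistently
  expect_equal(predict(eg, X[3, ]), eg$amplitudes[3, , drop = FALSE],
               ignore_attr = TRUE, tolerance = 1e-9)
  expect_error(eigenworms(X[1:10, ]), "19")
})

test_that("band-limited ensembles concentrate variance in the leading modes", {
  ang <- generate_posture_ensemble(400, seed = 3, noise_rel = 0.05)
  eg <- eigenworms(ang)
  expect_gt(sum(eg$explained_variance[1:6]), 1 - 0.05 - 0.02)
})

test_that("spool classification follows the amplitude-product thresholds", {
  expect_equal(as.character(classify_spool(1.5, 1.5)), "spool")
  expect_equal(as.character(classify_spool(3, 2)), "severe_spool")
  expect_equal(as.character(classify_spool(3, -2)), "figure8")
  expect_equal(as.character(classify_spool(0.5, 1)), "neither")
  expect_equal(as.character(classify_spool(c(1.5, 3), c(1.5, -2))),
               c("spool", "figure8"))
})

test_that("posture clustering keeps the best of redundant restarts", {
  set.seed(8)
  blobs <- rbind(matrix(rnorm(100, 0, 0.3), ncol = 2),
                 matrix(rnorm(100, 6, 0.3), ncol = 2),
                 cbind(rnorm(50, -6, 0.3), rnorm(50, 6, 0.3)))
  cl <- cluster_postures(blobs, k = 3, redundancy = 5, seed = 2)
  expect_equal(sort(cl$sizes), c(50L, 50L, 50L))
  # assignments are pure within blobs
  expect_equal(length(unique(cl$assignments[1:50])), 1)

  # k = n gives zero inertia
  small <- blobs[1:8, ]
  cl2 <- cluster_postures(small, k = 8, redundancy = 2, seed = 1)
  expect_equal(cl2$inertia, 0, tolerance = 1e-9)

  # more restarts can only lower the kept inertia
  i1 <- cluster_postures(blobs, k = 5, redundancy = 1, seed = 7)$inertia
  i5 <- cluster_postures(blobs, k = 5, redundancy = 5, seed = 7)$inertia
  expect_lte(i5, i1 + 1e-9)

  expect_error(cluster_postures(blobs[1:2, ], k = 3), "at least k")
})

test_that("Weibull fits recover parameters and reduce to the exponential", {
  x <- wormtrace:::with_seed(21, rweibull(500, shape = 1.5, scale = 10))
  f <- fit_weibull(x)
  expect_lt(abs(f$shape - 1.5) / 1.5, 0.1)
  expect_lt(abs(f$scale - 10) / 10, 0.1)
  # fixed shape 1: closed-form exponential, scale = sample mean
  f1 <- fit_weibull(x, shape = 1)
  expect_equal(f1$scale, mean(x), tolerance = 1e-12)
  # agrees with the reference maximum-likelihood fit
  ref <- MASS::fitdistr(x, "weibull")
  expect_equal(f$shape, unname(ref$estimate["shape"]), tolerance = 1e-3)
  expect_equal(f$scale, unname(ref$estimate["scale"]), tolerance = 1e-3)
})

test_that("coil events partition coil-positive frames exactly", {
  fps <- 10
  flags <- list(anterior = rep(c(TRUE, FALSE), 30),
                posterior = rep(FALSE, 60))
  st <- coil_event_stats(flags, fps)
  ev <- st$events[st$events$type == "anterior", ]
  expect_equal(nrow(ev), 30)
  expect_equal(unique(ev$duration), 1 / fps)
  # partition: every flagged frame in exactly one event
  covered <- unlist(mapply(seq, ev$start, ev$end))
  expect_setequal(covered, which(flags$anterior))
  expect_equal(anyDuplicated(covered), 0)
  # frequency = events per second
  expect_equal(unname(st$frequency["anterior"]), 30 / 6)
  # too few durations above the censoring floor: fit skipped with a flag
  expect_false(st$fits$anterior$fitted)

  # simulated Weibull durations are recovered by the event fit
  set.seed(3)
  durations <- pmax(2, round(rweibull(200, 1.5, 10) * fps))
  vec <- logical(0)
  for (d in durations) vec <- c(vec, rep(TRUE, d), FALSE, FALSE)
  st2 <- coil_event_stats(list(anterior = vec,
                               posterior = rep(FALSE, length(vec))), fps)
  expect_true(st2$fits$anterior$fitted)
  expect_lt(abs(st2$fits$anterior$scale - 10) / 10, 0.12)
})

test_that("transition summaries align events and measure propensities", {
  fps <- 10
  T_ <- 600
  states <- factor(rep("dwell", T_),
                   levels = c("forward", "backward", "dwell", "quiescent"))
  ant <- logical(T_)
  # every coil starts exactly 2 s after a forward initiation
  starts <- seq(50, 550, by = 100)
  for (s in starts) {
    states[s:(s + 40)] <- "forward"
    ant[(s + 20):(s + 25)] <- TRUE
  }
  ts <- transition_summaries(states, list(anterior = ant,
                                          posterior = logical(T_)), fps)
  expect_equal(ts$fraction_within, 1)
  expect_equal(ts$n_events$anterior, length(starts))
  # aligned probabilities are proper probabilities
  probs <- ts$aligned$anterior_entry
  expect_true(all(probs[is.finite(probs)] >= 0 & probs[is.finite(probs)] <= 1))

  # coil flags independent of states: during-coil propensities match the
  # baselines within binomial error
  set.seed(5)
  states2 <- factor(sample(c("forward", "backward", "dwell"), 4000, TRUE,
                           prob = c(0.5, 0.2, 0.3)),
                    levels = c("forward", "backward", "dwell", "quiescent"))
  coil2 <- sample(c(TRUE, FALSE), 4000, TRUE, prob = c(0.2, 0.8))
  ts2 <- transition_summaries(states2, list(anterior = coil2,
                                            posterior = logical(4000)), fps)
  for (s in c("forward", "backward", "dwell")) {
    p <- ts2$propensity[, s]
    se <- 3 * sqrt(0.25 / sum(coil2))
    expect_lt(abs(p["during_coil"] - p["baseline"]), se + 0.02)
  }

  # no events: flagged, baseline-only output
  ts3 <- transition_summaries(states2, list(anterior = logical(4000),
                                            posterior = logical(4000)), fps)
  expect_false(ts3$has_events)
  expect_true(is.na(ts3$fraction_within))
})
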
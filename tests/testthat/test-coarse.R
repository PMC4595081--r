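# Coarse MAP search: admissibility, scoring, clustering, beam search.

test_that("admissible extensions follow the 45-degree turn constraint", {
  gd <- c(20L, 20L)
  # heading east: the three continuations are E, NE, SE of the endpoint
  pts <- rbind(c(10L, 9L), c(10L, 10L))
  ext <- admissible_extensions(pts, gd)
  expect_setequal(paste(ext[, 1], ext[, 2]),
                  c("10 11", "9 11", "11 11"))
  # a visited point is excluded
  pts2 <- rbind(c(9L, 11L), c(10L, 9L), c(10L, 10L))
  # (9,11) is further than one step from older points? build an actual
  # self-avoidance case instead: path that already contains (10,11)
  pts3 <- rbind(c(10L, 12L), c(10L, 11L), c(10L, 10L))
  # heading west now; extensions are W, NW, SW of (10,10)
  ext3 <- admissible_extensions(pts3, gd)
  expect_setequal(paste(ext3[, 1], ext3[, 2]),
                  c("10 9", "9 9", "11 9"))
  # a corner heading into the corner can have no extensions
  ptsc <- rbind(c(2L, 2L), c(1L, 1L))
  extc <- admissible_extensions(ptsc, gd)
  expect_equal(nrow(extc), 0)
  expect_error(admissible_extensions(matrix(c(1L, 1L), 1), gd), "at least 2")
})

test_that("the hard-core exclusion bans returns next to the path", {
  gd <- c(20L, 20L)
  # a long straight path; extensions of its continuation may not touch it
  pts <- cbind(10L, 3:10)
  pts <- rbind(pts, c(9L, 11L), c(9L, 12L)) # step away and forward
  ext <- admissible_extensions(pts, gd)
  # returning to row 10 next to the old path (cells 10,11..13 are adjacent
  # to visited (10,10) or within one cell of the path) is forbidden
  expect_false(any(ext[, 1] == 10 & ext[, 2] <= 11))
  # a maximal-curvature U-turn over >= 3 cells separation stays admissible
  u <- rbind(c(5L, 5L), c(5L, 6L), c(6L, 7L), c(7L, 7L), c(8L, 6L))
  extu <- admissible_extensions(u, gd)
  expect_gt(nrow(extu), 0)
})

test_that("the length prior and DIFF follow their closed forms", {
  p <- worm_config(lambda = 10, A = 0.1)
  expect_equal(log_length_prior(10, p), 0)
  expect_equal(log_length_prior(12, p), -0.4)
  p0 <- worm_config(A = 0)
  expect_equal(log_length_prior(37, p0), 0)
  expect_error(log_length_prior(1, p), "n >= 2")

  # DIFF identity with alpha = 3
  d <- diff_value(p)
  manual <- 3 * ((log(p$p_high) + 2 * log(p$p_med) - 3 * log(p$p_low)) -
                   (log(1 - p$p_high) + 2 * log(1 - p$p_med) -
                      3 * log(1 - p$p_low)))
  expect_equal(d, manual)
  expect_gt(d, 0)
})

test_that("point log-likelihood ratios match direct substitution", {
  p <- worm_config()
  fmap <- array(FALSE, dim = c(9, 9, 4))
  # feature on at the point and both orthogonal neighbors, horizontal
  fmap[5, 5, 1] <- fmap[4, 5, 1] <- fmap[6, 5, 1] <- TRUE
  expect_equal(point_log_lr(0L, c(5L, 5L), fmap, p),
               log(p$p_high / p$p_low) + 2 * log(p$p_med / p$p_low))
  # off at all three
  expect_equal(point_log_lr(0L, c(5L, 2L), fmap, p),
               log((1 - p$p_high) / (1 - p$p_low)) +
                 2 * log((1 - p$p_med) / (1 - p$p_low)))
  # the difference between the two cases, times alpha, is DIFF
  on <- point_log_lr(0L, c(5L, 5L), fmap, p)
  off <- point_log_lr(0L, c(5L, 2L), fmap, p)
  expect_equal(p$alpha * (on - off), diff_value(p))
  expect_error(point_log_lr(0L, c(0L, 5L), fmap, p), "outside")
})

test_that("head candidates cluster by connectivity, largest first", {
  feats <- structure(list(arrays = array(FALSE, dim = c(16, 16, 12)),
                          coarse_unit = 2L, dim = c(16L, 16L)),
                     class = "worm_features")
  expect_error(find_head_candidates(feats), class = "worm_no_head")

  feats$arrays[5, 5:8, 1] <- TRUE                 # cluster of 4
  cl <- find_head_candidates(feats)
  expect_length(cl, 1)
  expect_gt(length(cl[[1]]$seeds), 0)

  feats$arrays[12, 12:13, 2] <- TRUE              # distant cluster of 2
  cl2 <- find_head_candidates(feats)
  expect_length(cl2, 2)
  expect_equal(cl2[[1]]$size, 4L)                 # ordered by size
  expect_equal(cl2[[2]]$size, 2L)
})

test_that("beam search equals exhaustive enumeration on small instances", {
  for (sd in 1:8) {
    fmap <- random_fmap(10, 10, p = 0.25, seed = sd)
    params <- tiny_config(head_stop = 50L, body_stop = 50L)
    params$lambda <- 8
    seeds <- list(make_seed(c(5, 5), c(5, 6), fmap, params))
    for (stage in c("body", "head")) {
      bb <- beam_search(seeds, fmap, params, stage = stage, max_len = 9,
                        diff_override = Inf)
      ob <- oracle_best(list(rbind(c(5L, 5L), c(5L, 6L))), fmap, params,
                        stage, max_len = 9)
      expect_equal(bb$log_post, ob, tolerance = 1e-9,
                   info = sprintf("seed %d stage %s", sd, stage))
    }
  }
})

test_that("an empty feature map terminates the search after the stop count", {
  fmap <- array(FALSE, dim = c(12, 12, 4))
  params <- tiny_config()
  seeds <- list(make_seed(c(6, 4), c(6, 5), fmap, params))
  res <- beam_search(seeds, fmap, params, stage = "head")
  # every step scores negatively, so the best never improves and the head
  # search stops after head_stop iterations: the seed itself is returned
  expect_equal(nrow(res$points), 2)
})

test_that("shrinking DIFF never improves the returned posterior", {
  for (sd in c(2, 9)) {
    fmap <- random_fmap(12, 12, p = 0.3, seed = sd)
    params <- tiny_config(body_stop = 5L)
    params$lambda <- 10
    seeds <- list(make_seed(c(6, 4), c(6, 5), fmap, params))
    posts <- vapply(c(Inf, 40, 10, 2, 0.5), function(dv)
      beam_search(seeds, fmap, params, max_len = 12,
                  diff_override = dv)$log_post, 0)
    expect_true(all(diff(posts) <= 1e-9))
  }
})

test_that("a strong prior pins the detected length to lambda", {
  # features along a full row admit paths of any length; with large A the
  # returned arc length approaches lambda
  fmap <- array(FALSE, dim = c(16, 30, 4))
  fmap[8, , 1] <- TRUE
  params <- tiny_config(A = 5)
  params$lambda <- 12
  seeds <- list(make_seed(c(8, 10), c(8, 11), fmap, params))
  res <- beam_search(seeds, fmap, params, stage = "body", max_len = 40)
  expect_equal(nrow(res$points), 12, tolerance = 1)
})

test_that("beam search is deterministic", {
  fmap <- random_fmap(12, 12, p = 0.3, seed = 4)
  params <- tiny_config()
  params$lambda <- 10
  seeds <- list(make_seed(c(6, 4), c(6, 5), fmap, params))
  r1 <- beam_search(seeds, fmap, params)
  r2 <- beam_search(seeds, fmap, params)
  expect_identical(r1$points, r2$points)
  expect_identical(r1$log_post, r2$log_post)
})

test_that("coarse detection recovers rendered midlines", {
  cfg <- worm_config()
  sc <- fixture_scene("straight")
  co <- detect_coarse(sc$image, cfg)
  expect_true(wormtrace:::coarse_inst_valid(co$points))
  # every detected point within ~1 coarse cell of the true midline
  px <- wormtrace:::coarse_to_px(co$points, co$coarse_unit)
  d <- vapply(seq_len(nrow(px)), function(i)
    min(sqrt((sc$truth$midline[, 1] - px[i, 1])^2 +
               (sc$truth$midline[, 2] - px[i, 2])^2)), 0)
  expect_lt(max(d) / cfg$coarse_unit, 1.6)

  # omega: self-avoiding with length near the prior expectation
  sco <- fixture_scene("omega")
  coo <- detect_coarse(sco$image, cfg)
  expect_true(wormtrace:::coarse_inst_valid(coo$points))
  steps <- diff(coo$points)
  eff <- 1 + sum(ifelse(steps[, 1] != 0 & steps[, 2] != 0, sqrt(2), 1))
  expect_lt(abs(eff - cfg$lambda) / cfg$lambda, 0.2)
})

test_that("an injected false head cluster loses to the true head", {
  cfg <- worm_config()
  sc <- fixture_scene("sinuous")
  masks <- build_masks(cfg$worm_width, cfg$feature_threshold_frac)
  edges <- detect_edges(sc$image, cfg$edge_threshold)
  feats <- detect_features(edges, masks, cfg$coarse_unit)
  # plant a compact fake head cluster in empty background
  feats$arrays[10:11, 10:12, 1] <- TRUE
  co <- detect_coarse(sc$image, cfg, masks = masks, features = feats)
  head_px <- wormtrace:::coarse_to_px(co$points[1, , drop = FALSE],
                                      co$coarse_unit)
  d_true <- sqrt(sum((head_px - sc$truth$head)^2))
  d_fake <- sqrt(sum((head_px - c(20, 22))^2))
  expect_lt(d_true, d_fake)
  expect_gt(co$n_clusters, 1)
})
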
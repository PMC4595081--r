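# Fine boundary model: search space, objective, dynamic program, midline.

make_straight_coarse <- function(cfg) {
  # a straight horizontal coarse midline through the middle of a frame
  pts <- cbind(24L, 40:10)   # head first, as detect_coarse returns
  structure(list(points = pts, head_len = 5L, log_post = 0,
                 head_cluster = 1L, n_clusters = 1L, status = "ok",
                 coarse_unit = cfg$coarse_unit, grid_dim = c(48L, 48L)),
            class = "worm_coarse")
}

test_that("the search space hypothesizes two offset boundary bands", {
  cfg <- worm_config()
  co <- make_straight_coarse(cfg)
  sp <- build_search_space(co, cfg, dims = c(144L, 160L))
  m <- length(sp$admissible)
  expect_equal(m %% 2, 1)            # 2n + 1 points
  expect_equal(sp$tip_index, (m + 1) / 2)
  # boundary hypotheses split into a band above and a band below the
  # midline row, about one worm width apart
  hyp <- sp$hyp
  n <- sp$tip_index - 1
  above <- hyp[2:(n - 2), 1]
  below <- hyp[(m - 1):(n + 3), 1]
  expect_equal(mean(below) - mean(above), cfg$worm_width, tolerance = 1.5)
  expect_error(build_search_space(
    structure(list(points = cbind(5L, 5:6), coarse_unit = 3L),
              class = "worm_coarse"), cfg, c(100L, 100L)),
    "too short")
})

test_that("a zero corridor makes the DP return the hypothesized boundary", {
  cfg <- worm_config(corridor_halfwidth = 0)
  co <- make_straight_coarse(cfg)
  sp <- build_search_space(co, cfg, dims = c(144L, 160L))
  expect_true(all(vapply(sp$admissible, nrow, 0L) == 1))
  edges <- detect_edges(matrix(100, 144, 160), 10)
  fine <- dp_solve(edges, sp, cfg)
  expect_equal(unname(fine$boundary),
               unname(do.call(rbind, sp$admissible)))
})

test_that("doubling the segment count refines sampling, not geometry", {
  cfg <- worm_config()
  co <- make_straight_coarse(cfg)
  s1 <- build_search_space(co, cfg, dims = c(144L, 160L))
  n1 <- s1$tip_index - 1
  s2 <- build_search_space(co, cfg, dims = c(144L, 160L), n_segments = 2 * n1)
  expect_equal(length(s2$admissible), 2 * length(s1$admissible) - 1)
  expect_equal(range(s2$hyp[, 1]), range(s1$hyp[, 1]), tolerance = 1)
})

test_that("segment edge types agree with the detector's polarity on a stripe", {
  img <- stripe_image(rows = 18:25)
  e <- detect_edges(img, 30)
  # top boundary: horizontal segment with the body below it; bright-to-dark
  # downwards is negative polarity under the detector's convention
  et_top <- segment_edge_type(0L, body_dir = c(1, 0))
  expect_true(any(e$arrays[17, , et_top]))
  # same segment with the body above: opposite polarity
  et_bot <- segment_edge_type(0L, body_dir = c(-1, 0))
  expect_true(any(e$arrays[25, , et_bot]))
  expect_false(et_top == et_bot)
  # left vs right boundary of a vertical body: opposite polarities
  expect_false(segment_edge_type(2L, c(0, 1)) ==
                 segment_edge_type(2L, c(0, -1)))
})

test_that("the fine objective matches direct substitution", {
  cfg <- worm_config()
  # tiny space: 3 points in a row, orientation east, edge type chosen
  space <- structure(list(
    admissible = list(matrix(c(5L, 5L), 1), matrix(c(5L, 8L), 1),
                      matrix(c(5L, 11L), 1)),
    hyp = rbind(c(5, 5), c(5, 8), c(5, 11)),
    beta = c(0L, 0L), edge_type = c(5L, 5L),
    tip_index = 2L, dims = c(20L, 20L)), class = "worm_finespace")
  arr <- array(FALSE, dim = c(20, 20, 8),
               dimnames = list(NULL, NULL, wormtrace:::edge_type_names()))
  edges0 <- structure(list(arrays = arr, threshold = 1, dim = c(20L, 20L)),
                      class = "worm_edges")
  boundary <- rbind(c(5L, 5L), c(5L, 8L), c(5L, 11L))
  # no edges anywhere: every rasterized pixel carries the off term and the
  # orientations match exactly (no prior penalty)
  n_px <- 7  # pixels 5..11 in the row, joins counted once
  off <- log((1 - cfg$p_obj) / (1 - cfg$p_bg))
  expect_equal(fine_objective(boundary, edges0, space, cfg), n_px * off)
  # all pixels carry the matching edge
  arr[5, 5:11, 5] <- TRUE
  edges1 <- structure(list(arrays = arr, threshold = 1, dim = c(20L, 20L)),
                      class = "worm_edges")
  on <- log(cfg$p_obj / cfg$p_bg)
  expect_equal(fine_objective(boundary, edges1, space, cfg), n_px * on)
  # an orientation deviation costs B per 45-degree step, nothing at B = 0
  bound2 <- rbind(c(5L, 5L), c(8L, 8L), c(5L, 11L))
  obj_b <- fine_objective(bound2, edges1, space, cfg)
  cfg0 <- worm_config(B = 0)
  obj_0 <- fine_objective(bound2, edges1, space, cfg0)
  expect_gt(obj_0, obj_b)
})

test_that("the dynamic program equals brute force on small instances", {
  set.seed(31)
  for (rep in 1:4) {
    m <- 5
    admissible <- lapply(seq_len(m), function(i) {
      ctr <- c(6 + i, 4 + 2 * i)
      cbind(ctr[1] + sample(-1:1, 3, TRUE), ctr[2] + sample(-1:1, 3, TRUE))
    })
    admissible <- lapply(admissible, function(g) unique(g)[1:min(3, nrow(unique(g))), , drop = FALSE])
    space <- structure(list(admissible = admissible,
                            hyp = t(vapply(admissible, function(g) colMeans(g), numeric(2))),
                            beta = sample(0:7, m - 1, TRUE),
                            edge_type = sample(1:8, m - 1, TRUE),
                            tip_index = 3L, dims = c(30L, 30L)),
                      class = "worm_finespace")
    arr <- array(runif(30 * 30 * 8) < 0.2, dim = c(30, 30, 8))
    dimnames(arr) <- list(NULL, NULL, wormtrace:::edge_type_names())
    edges <- structure(list(arrays = arr, threshold = 1, dim = c(30L, 30L)),
                       class = "worm_edges")
    cfg <- worm_config()
    fine <- dp_solve(edges, space, cfg)
    expect_equal(fine$log_post, oracle_dp(edges, space, cfg),
                 tolerance = 1e-9, info = paste("instance", rep))
    # objective consistency: re-scoring the returned boundary reproduces
    # the optimum the DP reports
    expect_equal(fine_objective(fine$boundary, edges, space, cfg),
                 fine$log_post, tolerance = 1e-9)
  }
})

test_that("a dominant orientation prior pins segments to their expected directions", {
  cfg <- worm_config(B = 1e4)
  co <- make_straight_coarse(cfg)
  sp <- build_search_space(co, cfg, dims = c(144L, 160L))
  edges <- detect_edges(matrix(100, 144, 160), 10)
  fine <- dp_solve(edges, sp, cfg)
  b <- fine$boundary
  codes <- vapply(2:nrow(b), function(i) {
    d <- b[i, ] - b[i - 1, ]
    if (all(d == 0)) return(NA_integer_)
    wormtrace:::dir_code(d[1], d[2])
  }, 0L)
  dev <- wormtrace:::dir_circ_dist(codes[!is.na(codes)],
                                   sp$beta[!is.na(codes)])
  expect_lt(mean(dev), 0.35)
})

test_that("boundary refinement lands on true intensity boundaries", {
  cfg <- worm_config()
  sc <- fixture_scene("straight")
  fit <- fixture_detection("straight")
  # distance from each detected boundary point to the true boundary polygon
  tb <- sc$truth$boundary
  d <- vapply(seq_len(nrow(fit$boundary)), function(i)
    min(sqrt((tb[, 1] - fit$boundary[i, 1])^2 +
               (tb[, 2] - fit$boundary[i, 2])^2)), 0)
  expect_lt(sqrt(mean(d^2)), 2)
})

test_that("midlines derive from boundary midpoints and resample evenly", {
  # two parallel boundary lines -> the central line
  n <- 10
  lb <- cbind(10, 5:(5 + n - 1))
  rb <- cbind(18, 5:(5 + n - 1))
  tip <- c(14, 5 + n)
  fine <- structure(list(boundary = rbind(lb, tip, rb[n:1, ]),
                         head_tip_index = n + 1L, log_post = 0),
                    class = "worm_fine")
  mid <- boundaries_to_midline(fine, 21L)
  expect_equal(unique(round(mid[-21, 1], 6)), 14)
  expect_equal(nrow(mid), 21)
  seg <- sqrt(rowSums(diff(mid)^2))
  expect_lt(diff(range(seg)), 1e-6)

  # circular arcs of radii r +- w/2 -> midline of radius r
  th <- seq(0, pi, length.out = 41)
  r <- 30; w <- 8
  outer_b <- cbind(50 - (r + w / 2) * sin(th), 50 + (r + w / 2) * cos(th))
  inner_b <- cbind(50 - (r - w / 2) * sin(th), 50 + (r - w / 2) * cos(th))
  tip2 <- c(50 - r * sin(pi), 50 + r * cos(pi))
  fine2 <- structure(list(boundary = rbind(outer_b, tip2, inner_b[41:1, ]),
                          head_tip_index = 42L, log_post = 0),
                     class = "worm_fine")
  mid2 <- boundaries_to_midline(fine2, 41L)
  rad <- sqrt((mid2[, 1] - 50)^2 + (mid2[, 2] - 50)^2)
  expect_equal(mean(rad), r, tolerance = 0.5)

  # degenerate boundary rejected
  degen <- structure(list(boundary = rbind(c(3L, 3L), c(3L, 3L), c(3L, 3L)),
                          head_tip_index = 2L, log_post = 0),
                     class = "worm_fine")
  expect_error(boundaries_to_midline(degen), "degenerate")
})

test_that("midline accuracy and length hold on rendered scenes", {
  cfg <- worm_config()
  # non-coiled: mean Hausdorff under half a worm width
  hds <- c(); lens <- c()
  for (fam in c("straight", "sinuous")) {
    for (s in c(5, 9)) {
      sp <- sample_posture(fam, seed = s)
      sc <- render_scene(scene_spec(sp))
      fit <- detect_posture(sc$image, cfg)
      hds <- c(hds, wormtrace:::hausdorff_dist(
        wormtrace:::resample_polyline(fit$midline, 100),
        wormtrace:::resample_polyline(sc$truth$midline21, 100)))
      lens <- c(lens, fit$length / sc$truth$length)
    }
  }
  expect_lt(mean(hds), cfg$worm_width / 2)
  # coiled: under one worm width
  hdc <- c()
  for (fam in c("omega", "spool")) {
    for (s in c(5, 9)) {
      sp <- sample_posture(fam, seed = s)
      sc <- render_scene(scene_spec(sp))
      fit <- detect_posture(sc$image, cfg)
      hdc <- c(hdc, wormtrace:::hausdorff_dist(
        wormtrace:::resample_polyline(fit$midline, 100),
        wormtrace:::resample_polyline(sc$truth$midline21, 100)))
      lens <- c(lens, fit$length / sc$truth$length)
    }
  }
  expect_lt(mean(hdc), cfg$worm_width)
  # arc length within 10% of ground truth
  expect_true(all(abs(lens - 1) < 0.1))
})
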
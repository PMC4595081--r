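# Independent oracles for the search stages, implemented by brute force.

# score a full coarse path from scratch under the set-based data model:
# locations claimed once, on-path locations take p_high terms with the
# orientation of the step that reaches them (later steps upgrade neighbor
# claims), orthogonal neighbors take p_med terms with the orientation of
# the first step that claims them
oracle_score_path <- function(points, fmap, params, stage = "body") {
  Hr <- dim(fmap)[1]; Hc <- dim(fmap)[2]
  hi_on <- log(params$p_high / params$p_low)
  hi_off <- log((1 - params$p_high) / (1 - params$p_low))
  md_on <- log(params$p_med / params$p_low)
  md_off <- log((1 - params$p_med) / (1 - params$p_low))
  claimed <- list() # key -> list(role, value)
  total <- 0
  orient_of_step <- function(i) {
    if (i == 1) d <- points[2, ] - points[1, ] else d <- points[i, ] - points[i - 1, ]
    wormtrace:::dir_code(d[1], d[2]) %% 4L
  }
  orths <- function(o) wormtrace:::orth_offsets(o)
  for (i in seq_len(nrow(points))) {
    o <- orient_of_step(i)
    p <- points[i, ]
    key <- paste(p, collapse = ",")
    on <- fmap[p[1], p[2], o + 1L]
    term <- if (on) hi_on else hi_off
    prev <- claimed[[key]]
    if (is.null(prev)) {
      claimed[[key]] <- list(role = 1L, value = term)
      total <- total + term
    } else if (prev$role == 2L) {
      total <- total + term - prev$value
      claimed[[key]] <- list(role = 1L, value = term)
    }
    for (k in 1:2) {
      q <- p + orths(o)[k, ]
      if (q[1] < 1 || q[1] > Hr || q[2] < 1 || q[2] > Hc) next
      qkey <- paste(q, collapse = ",")
      if (!is.null(claimed[[qkey]])) next
      qterm <- if (fmap[q[1], q[2], o + 1L]) md_on else md_off
      claimed[[qkey]] <- list(role = 2L, value = qterm)
      total <- total + qterm
    }
  }
  if (stage == "body") {
    steps <- diff(points)
    eff <- 1 + sum(ifelse(steps[, 1] != 0 & steps[, 2] != 0, sqrt(2), 1))
    total <- total - params$A * (eff - params$lambda)^2
  }
  total
}

# admissibility identical to the search: 45-degree turns, self-avoidance,
# and the hard-core exclusion against all but the last two points
oracle_extensions <- function(points, grid_dim) {
  wormtrace::admissible_extensions(points, grid_dim)
}

# exhaustive enumeration: best posterior over all admissible paths from the
# seed pairs, any length up to max_len
oracle_best <- function(seeds, fmap, params, stage = "body", max_len = 10) {
  grid_dim <- dim(fmap)[1:2]
  best <- -Inf
  recurse <- function(points) {
    sc <- oracle_score_path(points, fmap, params, stage)
    if (sc > best) best <<- sc
    if (nrow(points) >= max_len) return()
    ext <- oracle_extensions(points, grid_dim)
    for (k in seq_len(nrow(ext)))
      recurse(rbind(points, ext[k, ]))
  }
  for (sd in seeds) recurse(sd)
  best
}

# exhaustive DP oracle: best fine objective over all corridor paths
oracle_dp <- function(edges, space, params) {
  m <- length(space$admissible)
  best <- -Inf
  maps <- wormtrace:::edge_llr_maps(edges, params)
  recurse <- function(i, boundary) {
    if (i > m) {
      sc <- wormtrace:::fine_objective_maps(boundary, maps, space, params)
      if (sc > best) best <<- sc
      return()
    }
    G <- space$admissible[[i]]
    for (k in seq_len(nrow(G)))
      recurse(i + 1, rbind(boundary, G[k, , drop = FALSE]))
  }
  recurse(1, matrix(numeric(0), 0, 2))
  best
}

# random small feature map for search tests
random_fmap <- function(Hr, Hc, p = 0.2, seed = 1) {
  with_seed <- wormtrace:::with_seed
  with_seed(seed, array(runif(Hr * Hc * 4) < p, dim = c(Hr, Hc, 4)))
}

# small config for search-level tests
tiny_config <- function(...) {
  wormtrace::worm_config(worm_width = 8, worm_length = 40, ...)
}

# build a seed instantiation the way the search does
make_seed <- function(p1, p2, fmap, params) {
  wormtrace:::seed_inst(as.integer(p1), as.integer(p2), fmap, params)
}
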
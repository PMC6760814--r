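# small deterministic inputs shared across test files

# straight-line walkers: individual i moves with constant velocity; handy for
# exact kinematics checks
straight_ts <- function(t_n = 50, n = 3, fps = 32, radius = 100) {
  pos <- array(0, dim = c(t_n, n, 2))
  for (i in seq_len(n)) {
    v <- c(cos(i), sin(i)) * i      # BL per frame
    pos[, i, 1] <- (i - 1) * 5 + (seq_len(t_n) - 1) * v[1] / fps
    pos[, i, 2] <- (seq_len(t_n) - 1) * v[2] / fps
  }
  trajectory_set(pos, fps = fps, arena_radius = radius)
}

# random smooth-ish trajectories for property tests
random_ts <- function(t_n = 60, n = 6, fps = 32, radius = 50, seed = 1) {
  set.seed(seed)
  pos <- array(0, dim = c(t_n, n, 2))
  for (i in seq_len(n)) {
    for (k in 1:2) {
      steps <- stats::rnorm(t_n, sd = 0.3)
      pos[, i, k] <- cumsum(steps) + stats::runif(1, -5, 5)
    }
  }
  trajectory_set(pos, fps = fps, arena_radius = radius)
}

# a tiny preprocessed simulation shared by feature/network tests
small_sim_dataset <- function(seed = 3, topo_index = FALSE, stride = 2L,
                              duration = 12, n = 5L, n_agents = 12L) {
  config <- zonal_config(n_agents = n_agents, arena_radius = 15)
  sim <- simulate_zonal(config, duration, seed = seed, burn_in = 2)
  prep <- preprocess_trajectories(sim$ts)
  split <- split_frames(dim(prep$kin$velocity)[1], c(0.8, 0.1, 0.1))
  ds <- build_dataset(prep$kin, prep$ts, split, prep$border_mask, n = n,
                      horizon = 4L, stride = stride, topo_index = topo_index)
  list(ds = ds, sim = sim, prep = prep, split = split)
}

# hand-built dataset whose label is perfectly predicted by the side of the
# nearest neighbour (the one of minimal distance; its x > 0 => right);
# separable by a permutation-invariant model by construction
separable_dataset <- function(m = 3000, n = 4, seed = 42) {
  set.seed(seed)
  mn <- m * n
  x <- stats::rnorm(mn)
  pair <- cbind(v = stats::rnorm(mn %/% n)[rep(seq_len(m), each = n)],
                a_perp = stats::rnorm(mn), x = x, y = stats::rnorm(mn),
                vx = stats::rnorm(mn), vy = stats::rnorm(mn))
  d <- matrix(sqrt(pair[, "x"]^2 + pair[, "y"]^2), nrow = n)
  nearest <- (seq_len(m) - 1L) * n + apply(d, 2, which.min)
  label <- as.integer(pair[nearest, "x"] > 0)
  first <- seq(1, mn, by = n)
  ds <- list(
    x_pair = pair,
    x_alpha = pair[first, c("v", "a_perp"), drop = FALSE],
    x_w = cbind(v = pair[first, "v"][rep(seq_len(m), each = n)],
                vi = sqrt(pair[, "vx"]^2 + pair[, "vy"]^2),
                absx = abs(x), y = pair[, "y"]),
    label = label,
    turn_angle = stats::runif(m, 0, 180),
    frame = seq_len(m), focal = rep(1L, m),
    split = rep(c("train", "validation", "test"),
                times = c(m - 2 * (m %/% 10), m %/% 10, m %/% 10)),
    m = m, n = as.integer(n),
    vars = list(alpha = c("v", "a_perp"), social = c("x", "y", "vx", "vy")),
    odd_pair = c(2L, 3L, 5L), odd_alpha = 2L)
  odd <- stats::setNames(seq_len(ncol(ds$x_pair)) %in% ds$odd_pair,
                         colnames(ds$x_pair))
  fishrules:::standardize_dataset(ds, odd)
}

# smallest angular distance between two angles
ang_dist <- function(a, b) abs(atan2(sin(a - b), cos(a - b)))

# random MLP parameter list for direct kernel tests
rand_mlp <- function(sizes, seed = 1, sd = 0.3) {
  set.seed(seed)
  lapply(seq_len(length(sizes) - 1), function(l)
    list(W = matrix(stats::rnorm(sizes[l] * sizes[l + 1], sd = sd),
                    sizes[l], sizes[l + 1]),
         b = stats::rnorm(sizes[l + 1], sd = 0.1)))
}
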
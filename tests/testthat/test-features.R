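test_that("focal frame: ahead is +y, the focal's right is +x", {
  # neighbour dead ahead moving parallel
  out <- focal_frame_transform(c(0, 0), c(0, 2), c(0, 3), c(0, 1))
  expect_equal(c(out$x, out$y), c(0, 3))
  expect_equal(out$theta, 0)
  # focal heading east, neighbour to its south => x > 0, y = 0
  out2 <- focal_frame_transform(c(0, 0), c(1, 0), c(0, -2), c(1, 0))
  expect_equal(c(out2$x, out2$y), c(2, 0))
  expect_error(focal_frame_transform(c(0, 0), c(0, 0), c(1, 1), c(1, 0)),
               "zero")
})

test_that("focal frame transform round-trips to world coordinates", {
  set.seed(8)
  for (k in 1:20) {
    fp <- rnorm(2); fv <- rnorm(2); op <- rnorm(2); ov <- rnorm(2)
    if (sum(fv^2) < 1e-4) next
    out <- focal_frame_transform(fp, fv, op, ov)
    sp <- sqrt(sum(fv^2))
    f <- fv / sp; r <- c(f[2], -f[1])
    # invert: world = focal + x * r + y * f
    expect_equal(fp + out$x * r + out$y * f, op)
    expect_equal(out$vx * r + out$vy * f, ov)
    expect_equal(out$v, sqrt(sum(ov^2)))
  }
})

test_that("nearest neighbours sorted by distance with index tie-break", {
  pos <- rbind(c(0, 0), c(1, 0), c(2, 0), c(3, 0))
  expect_equal(nearest_neighbours(pos, 1, 2), c(2, 3))
  # exact tie: lower id first
  pos_tie <- rbind(c(0, 0), c(0, 1), c(1, 0), c(-1, 0))
  expect_equal(nearest_neighbours(pos_tie, 1, 3), c(2, 3, 4))
  expect_error(nearest_neighbours(pos, 1, 5), "available")
  # agrees with a brute-force full sort on random points
  set.seed(9)
  posr <- matrix(rnorm(200), 100, 2)
  d <- sqrt(rowSums(sweep(posr, 2, posr[17, ])^2)); d[17] <- Inf
  expect_equal(nearest_neighbours(posr, 17, 10), order(d)[1:10])
})

test_that("turn labels: side convention, zero-turn tie, mirror symmetry", {
  fps <- 32
  make_kin <- function(rot_deg) {
    # heading north at t, rotated by rot_deg (positive = counterclockwise,
    # i.e. toward the focal's left) at t + 4
    pos <- array(0, dim = c(10, 1, 2))
    v0 <- c(0, 1); ang <- rot_deg * pi / 180
    rot <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
    v1 <- as.vector(rot %*% v0)
    for (t in 2:6) pos[t, 1, ] <- pos[t - 1, 1, ] + v0 / fps
    for (t in 7:10) pos[t, 1, ] <- pos[t - 1, 1, ] + v1 / fps
    differentiate(trajectory_set(pos, fps = fps, arena_radius = 10))
  }
  lab <- turn_label(make_kin(-30), 1, 5, 4)  # clockwise => right
  expect_equal(lab$side, "right")
  expect_equal(lab$turn_angle, 30, tolerance = 1e-6)
  lab2 <- turn_label(make_kin(30), 1, 5, 4)
  expect_equal(lab2$side, "left")
  expect_equal(lab2$turn_angle, 30, tolerance = 1e-6)
  lab0 <- turn_label(make_kin(0), 1, 5, 4)   # exact tie labelled right
  expect_equal(lab0$side, "right")
  expect_equal(lab0$turn_angle, 0)
})

test_that("reflected worlds give reflected labels", {
  ts <- random_ts(t_n = 30, n = 2, seed = 12)
  tsm <- ts
  tsm$positions[, , 1] <- -tsm$positions[, , 1]
  kin <- differentiate(ts); kinm <- differentiate(tsm)
  n_lab <- 0
  for (t in 5:20) {
    a <- turn_label(kin, 1, t, 4); b <- turn_label(kinm, 1, t, 4)
    if (is.null(a)) next
    n_lab <- n_lab + 1
    expect_equal(a$turn_angle, b$turn_angle)
    if (a$turn_angle > 1e-9)
      expect_true(a$side != b$side)
  }
  expect_gt(n_lab, 5)
})

test_that("datasets have sorted neighbours and the documented layout", {
  out <- small_sim_dataset(seed = 3)
  ds <- out$ds
  expect_s3_class(ds, "turn_dataset")
  expect_equal(colnames(ds$x_pair), c("v", "a_perp", "x", "y", "vx", "vy"))
  expect_equal(nrow(ds$x_pair), ds$m * ds$n)
  # neighbour distance ordering non-decreasing within every sample (on the
  # de-standardized coordinates)
  xs <- sweep(ds$x_pair[, c("x", "y")], 2, ds$stats$pair$sd[c("x", "y")], "*")
  xs <- sweep(xs, 2, ds$stats$pair$mean[c("x", "y")], "+")
  d <- matrix(sqrt(rowSums(xs^2)), nrow = ds$n)
  expect_true(all(diff(d) >= -1e-9))
  # standardization statistics fitted on train rows only: train mean of even
  # features ~ 0, sd ~ 1; odd features scaled but not centred
  tr_rows <- fishrules:::pair_rows(which(ds$split == "train"), ds$n)
  expect_equal(unname(colMeans(ds$x_pair[tr_rows, c("v", "y", "vy")])),
               c(0, 0, 0), tolerance = 1e-8)
  expect_equal(unname(apply(ds$x_pair[tr_rows, ], 2,
                            function(z) sqrt(mean((z - mean(z) *
                              0)^2))))[c(1, 3)], c(1, 1), tolerance = 0.3)
  expect_equal(ds$stats$pair$mean[["x"]], 0)
  expect_equal(ds$stats$pair$mean[["a_perp"]], 0)
})

test_that("one frame of fully valid individuals yields one sample each", {
  # individuals on a circle, all moving, far from the border
  n_ind <- 30
  t_n <- 12
  pos <- array(0, dim = c(t_n, n_ind, 2))
  ang <- 2 * pi * (seq_len(n_ind) - 1) / n_ind
  for (t in seq_len(t_n)) {
    pos[t, , 1] <- 10 * cos(ang) + 0.2 * t
    pos[t, , 2] <- 10 * sin(ang) + 0.1 * t
  }
  ts <- trajectory_set(pos, fps = 32, arena_radius = 100)
  kin <- differentiate(ts)
  split <- list(train = 1:6, validation = 7L, test = 8L)
  ds <- build_dataset(kin, ts, split, n = 25L, horizon = 4L)
  # frames 3..8 are usable (valid kinematics from frame 3, horizon 4 <= 12)
  expect_equal(ds$m, 6 * n_ind)
  expect_equal(ds$n, 25L)
  expect_equal(ncol(ds$x_pair) - 2L + 2L, 6)  # 6 pair variables
  expect_equal(ds$n * ncol(ds$x_pair), 150)   # 25 x 6 inputs per decision
})

test_that("border-masked focals produce no samples but remain neighbours", {
  out <- small_sim_dataset(seed = 4)
  prep <- out$prep
  masked <- which(prep$border_mask, arr.ind = TRUE)
  skip_if(nrow(masked) == 0, "no border-masked points in this fixture")
  key_ds <- paste(out$ds$frame, out$ds$focal)
  key_masked <- paste(masked[, 1], masked[, 2])
  expect_length(intersect(key_ds, key_masked), 0)
})

test_that("the feature pipeline is reflection-equivariant end to end", {
  config <- zonal_config(n_agents = 10L, arena_radius = 15)
  sim <- simulate_zonal(config, 10, seed = 21, burn_in = 2)
  tsm <- sim$ts
  tsm$positions[, , 1] <- -tsm$positions[, , 1]  # mirrored world
  build <- function(ts) {
    prep <- preprocess_trajectories(ts)
    split <- split_frames(dim(prep$kin$velocity)[1], c(0.8, 0.1, 0.1))
    build_dataset(prep$kin, prep$ts, split, prep$border_mask, n = 4L,
                  horizon = 4L, stride = 3L)
  }
  ds <- build(sim$ts)
  dsm <- build(tsm)
  ref <- reflect_dataset(ds)
  expect_equal(dsm$x_pair, ref$x_pair, tolerance = 1e-10)
  expect_equal(dsm$x_w, ref$x_w, tolerance = 1e-10)
  # labels match wherever the side is numerically well defined; exact and
  # near-exact zero turns are tie-labelled right in both worlds
  decided <- ds$turn_angle > 1e-4
  expect_gt(mean(decided), 0.5)
  expect_equal(dsm$label[decided], ref$label[decided])
  expect_equal(dsm$turn_angle, ds$turn_angle, tolerance = 1e-10)
  # reflecting twice is the identity
  expect_equal(reflect_dataset(ref), ds)
})

test_that("topological index is appended and reflection-invariant", {
  out <- small_sim_dataset(seed = 5, topo_index = TRUE)
  ds <- out$ds
  expect_true("topo" %in% colnames(ds$x_pair))
  expect_true("topo" %in% names(ds$stats$w$mean))
  expect_false(which(colnames(ds$x_pair) == "topo") %in% ds$odd_pair)
  ref <- reflect_dataset(ds)
  expect_equal(ref$x_pair[, "topo"], ds$x_pair[, "topo"])
})

test_that("pooling datasets refits consistent standardization", {
  a <- small_sim_dataset(seed = 6)$ds
  b <- small_sim_dataset(seed = 7)$ds
  pooled <- bind_datasets(list(a, b), run_id = c("a", "b"))
  expect_equal(pooled$m, a$m + b$m)
  expect_equal(pooled$run, c(rep("a", a$m), rep("b", b$m)))
  tr_rows <- fishrules:::pair_rows(which(pooled$split == "train"), pooled$n)
  expect_equal(unname(colMeans(pooled$x_pair[tr_rows, "v", drop = FALSE])), 0,
               tolerance = 1e-8)
  expect_equal(unname(sqrt(mean(pooled$x_pair[tr_rows, "x"]^2))), 1,
               tolerance = 1e-6)
})
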
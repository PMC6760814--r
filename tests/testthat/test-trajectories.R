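test_that("csv-long round trip preserves positions, metadata and gaps", {
  ts <- random_ts(t_n = 20, n = 3, seed = 5)
  ts$positions[7, 2, ] <- NA_real_
  ts <- trajectory_set(ts$positions, fps = ts$fps, arena_radius = 50)
  path <- file.path(tempdir(), "traj.csv")
  write_trajectories(ts, path)
  back <- read_trajectories(path)
  expect_equal(back$positions, ts$positions)
  expect_equal(back$fps, ts$fps)
  expect_equal(back$arena_radius, ts$arena_radius)
  expect_true(back$missing_mask[7, 2])
  expect_equal(sum(back$missing_mask), 1)
})

test_that("malformed or empty trajectory files raise format errors", {
  path <- file.path(tempdir(), "empty.csv")
  writeLines(character(0), path)
  expect_error(read_trajectories(path, meta = list(fps = 32)),
               "malformed")
  writeLines(c("a,b", "1,2"), path)
  expect_error(read_trajectories(path, meta = list(fps = 32)),
               "frame,id,x,y")
  expect_error(read_trajectories("no-such-file.csv"), "not found")
  expect_error(read_trajectories(path, dialect = "npz"), "dialect")
})

test_that("short gaps are interpolated linearly, long gaps left missing", {
  pos <- array(NA_real_, dim = c(12, 2, 2))
  pos[, 1, 1] <- 0:11; pos[, 1, 2] <- 0
  pos[, 2, 1] <- 2 * (0:11); pos[, 2, 2] <- 1
  pos[2, 1, ] <- NA          # single-frame gap: (0,0) at t1, (2,0) at t3
  pos[5:10, 2, ] <- NA       # 6-frame gap > max_gap
  ts <- trajectory_set(pos, fps = 32, arena_radius = 100)
  out <- interpolate_gaps(ts, max_gap = 5, quiet = TRUE)
  expect_equal(out$positions[2, 1, ], c(1, 0))
  expect_false(any(out$missing_mask[, 1]))
  expect_equal(out$missing_mask[, 2], c(rep(FALSE, 4), rep(TRUE, 6),
                                        FALSE, FALSE))
})

test_that("interpolated fraction is reported", {
  ts <- random_ts(t_n = 100, n = 10, seed = 2)  # 1000 points
  ts$positions[50, 4, ] <- NA
  ts <- trajectory_set(ts$positions, fps = 32, arena_radius = 50)
  expect_message(interpolate_gaps(ts, max_gap = 5), "1 of 1000 .*0\\.100%")
})

test_that("normalization centres the arena and flags the border", {
  pos <- array(0, dim = c(2, 3, 2))
  center <- c(10, -5); radius <- 8
  pos[, 1, ] <- rep(center, each = 2)                      # at the centre
  pos[, 2, 1] <- center[1] + 0.9 * radius; pos[, 2, 2] <- center[2]
  pos[, 3, 1] <- center[1] + 0.5 * radius; pos[, 3, 2] <- center[2]
  ts <- trajectory_set(pos, fps = 32, arena_center = center,
                       arena_radius = radius)
  nm <- normalize_and_mask(ts, border_fraction = 0.8)
  expect_equal(nm$ts$positions[1, 1, ], c(0, 0))
  expect_false(nm$border_mask[1, 1])
  expect_true(all(nm$border_mask[, 2]))   # at 0.9 x radius
  expect_false(any(nm$border_mask[, 3]))  # at 0.5 x radius
  # idempotent on already-normalized data
  again <- normalize_and_mask(nm$ts, border_fraction = 0.8)
  expect_equal(again$ts$positions, nm$ts$positions)
  expect_equal(again$border_mask, nm$border_mask)
})

test_that("border mask fraction matches the area ratio for uniform points", {
  set.seed(11)
  n_pts <- 20000
  r <- sqrt(runif(n_pts)); a <- runif(n_pts, 0, 2 * pi)
  pos <- array(c(r * cos(a), r * sin(a)), dim = c(n_pts %/% 2, 2, 2))
  pos <- array(NA_real_, dim = c(n_pts, 1, 2))
  pos[, 1, 1] <- r * cos(a); pos[, 1, 2] <- r * sin(a)
  ts <- trajectory_set(pos, fps = 32, arena_radius = 1)
  nm <- normalize_and_mask(ts, border_fraction = 0.8)
  expect_equal(mean(nm$border_mask), 1 - 0.8^2, tolerance = 0.02)
})

test_that("pixel-unit recordings are rescaled to body lengths", {
  pos <- array(80, dim = c(2, 1, 2))  # 80 px = 1 BL from centre on each axis
  ts <- trajectory_set(pos, fps = 32, arena_center = c(0, 0),
                       arena_radius = 800, body_length_px = 80)
  nm <- normalize_and_mask(ts)
  expect_equal(nm$ts$positions[1, 1, ], c(1, 1))
  expect_equal(nm$ts$arena_radius, 10)
})

test_that("causal smoothing: unit mass, causality, and ramp lag", {
  w <- fishrules:::causal_kernel(5, 1)
  expect_equal(sum(w), 1)
  expect_true(all(w > 0))
  # constant trajectory unchanged
  pos <- array(3, dim = c(30, 1, 2))
  ts <- trajectory_set(pos, fps = 32, arena_radius = 10)
  expect_equal(smooth_causal(ts)$positions, pos)
  # impulse response strictly causal
  pos0 <- array(0, dim = c(30, 1, 2)); pos0[15, 1, ] <- 1
  sm <- smooth_causal(trajectory_set(pos0, fps = 32, arena_radius = 10))
  expect_true(all(sm$positions[1:14, 1, 1] == 0))
  expect_true(all(sm$positions[15:19, 1, 1] > 0))
  # ramp: output is t minus the kernel's mean lag (beyond the warm-up)
  posr <- array(0, dim = c(30, 1, 2)); posr[, 1, 1] <- 0:29
  smr <- smooth_causal(trajectory_set(posr, fps = 32, arena_radius = 100))
  lag <- sum((0:4) * w)
  expect_equal(smr$positions[10:30, 1, 1], (9:29) - lag)
})

test_that("first frames use a truncated, renormalized kernel", {
  pos <- array(0, dim = c(10, 1, 2)); pos[, 1, 1] <- 5
  sm <- smooth_causal(trajectory_set(pos, fps = 32, arena_radius = 10))
  expect_equal(sm$positions[1:4, 1, 1], rep(5, 4))  # constant stays constant
})

test_that("backward differences give exact velocity and zero acceleration", {
  fps <- 32
  pos <- array(0, dim = c(20, 1, 2))
  pos[, 1, 1] <- (0:19) * 0.25  # 0.25 BL per frame => 8 BL/s
  kin <- differentiate(trajectory_set(pos, fps = fps, arena_radius = 100))
  expect_false(any(kin$valid_mask[1:2, ]))
  expect_true(all(kin$valid_mask[3:20, ]))
  expect_equal(kin$velocity[3:20, 1, 1], rep(8, 18))
  expect_equal(kin$acceleration[3:20, 1, 1], rep(0, 18))
  expect_equal(kin$speed[3:20, 1], rep(8, 18))
})

test_that("kinematics are causal: future positions do not matter", {
  ts <- random_ts(t_n = 40, n = 2, seed = 7)
  kin1 <- differentiate(ts)
  ts2 <- ts
  ts2$positions[30:40, , ] <- ts2$positions[30:40, , ] + 100
  kin2 <- differentiate(ts2)
  expect_equal(kin1$velocity[1:29, , ], kin2$velocity[1:29, , ])
  expect_equal(kin1$acceleration[1:29, , ], kin2$acceleration[1:29, , ])
  # same for smoothing
  sm1 <- smooth_causal(ts); sm2 <- smooth_causal(ts2)
  expect_equal(sm1$positions[1:29, , ], sm2$positions[1:29, , ])
})

test_that("circular motion recovers the centripetal acceleration", {
  fps <- 100; radius <- 2; speed <- 3
  omega <- speed / radius
  t <- (0:599) / fps
  pos <- array(0, dim = c(600, 1, 2))
  pos[, 1, 1] <- radius * cos(omega * t)
  pos[, 1, 2] <- radius * sin(omega * t)
  kin <- differentiate(trajectory_set(pos, fps = fps, arena_radius = 10))
  a_mag <- sqrt(kin$acceleration[, 1, 1]^2 + kin$acceleration[, 1, 2]^2)
  expect_equal(mean(a_mag[10:600]), speed^2 / radius, tolerance = 0.02)
})

test_that("shuffle control: offsets, marginals, and bijection", {
  # 10-minute, 100-individual recording at 32 fps
  t_n <- 600 * 32; n <- 100
  offs <- shuffle_offsets(t_n, n)
  circ <- pmin(offs, t_n - offs)
  expect_equal(min(circ[circ > 0]) / 32, 6)      # minimum nonzero shift 6 s
  expect_equal(mean(circ) / 32, 150)             # mean circular shift 150 s
  # marginals unchanged, shuffle of shuffles returns the original
  ts <- random_ts(t_n = 40, n = 4, seed = 3)
  sh <- shuffle_shift(ts)
  for (i in 1:4)
    expect_equal(sort(sh$positions[, i, 1]), sort(ts$positions[, i, 1]))
  # N applications of a T/N circular shift are the identity
  cur <- ts$positions[, 2, 1]
  k <- 40 / 4
  for (r in 1:4) cur <- cur[c((40 - k + 1):40, 1:(40 - k))]
  expect_equal(cur, ts$positions[, 2, 1])
  expect_error(shuffle_shift(random_ts(t_n = 3, n = 4)), "individuals")
})

test_that("frame splits are contiguous, disjoint and correctly sized", {
  sp <- split_frames(1000)
  expect_equal(lengths(sp), c(train = 970, validation = 20, test = 10))
  expect_equal(sort(unlist(sp, use.names = FALSE)), 1:1000)
  sp2 <- split_frames(4, c(0.5, 0.25, 0.25))
  expect_equal(lengths(sp2), c(train = 2, validation = 1, test = 1))
  # rotation moves the validation+test block but keeps a partition
  for (r in 0:2) {
    spr <- split_frames(1000, rotate = r)
    expect_equal(sort(unlist(spr, use.names = FALSE)), 1:1000)
    expect_equal(length(spr$validation), 20)
    vt <- sort(c(spr$validation, spr$test))
    expect_equal(vt, seq(min(vt), max(vt)))  # val+test contiguous
  }
  expect_false(identical(split_frames(1000, rotate = 1)$validation,
                         split_frames(1000)$validation))
  expect_error(split_frames(10, c(0.98, 0.01, 0.01)), "too short")
})
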
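test_that("logistic link and cross-entropy match closed forms", {
  expect_equal(logit_to_probability(0), 0.5)
  expect_equal(logit_to_probability(100), 1, tolerance = 1e-12)
  z <- c(-3, 0.5, 2)
  expect_equal(logit_to_probability(-z), 1 - logit_to_probability(z))
  # hand-computed 3-sample batch
  p <- c(0.9, 0.2, 0.6); y <- c(1, 0, 1)
  expect_equal(cross_entropy_loss(p, y),
               -(log(0.9) + log(0.8) + log(0.6)) / 3)
  expect_equal(cross_entropy_loss(rep(0.5, 10), rep(c(0, 1), 5)), log(2))
  expect_lt(cross_entropy_loss(c(1, 0), c(1, 0)), 1e-10)
})

test_that("analytic gradients match finite differences for all kernels", {
  set.seed(31)
  m <- 6L; n <- 3L
  Xp <- matrix(rnorm(m * n * 4), m * n, 4)
  Xw <- matrix(rnorm(m * n * 3), m * n, 3)
  Xa <- matrix(rnorm(m * 2), m, 2)
  y <- sample(0:1, m, TRUE)
  odd <- c(1L, 3L)
  h <- 1e-2
  fd_check <- function(loss_fun, grads, params, top, n_checks = 12) {
    set.seed(99)
    for (k in seq_len(n_checks)) {
      l <- sample(length(params), 1)
      W <- params[[l]]$W
      ij <- sample(length(W), 1)
      pp <- params; pm <- params
      pp[[l]]$W[ij] <- W[ij] + h
      pm[[l]]$W[ij] <- W[ij] - h
      num <- (loss_fun(pp) - loss_fun(pm)) / (2 * h)
      ana <- grads[[l]]$W[ij]
      expect_equal(ana, num, tolerance = 0.02,
                   label = sprintf("%s layer %d grad", top, l))
    }
  }
  # attention: check both subnetworks
  pi_p <- rand_mlp(c(4, 8, 8, 8, 1), seed = 1)
  w_p <- rand_mlp(c(3, 8, 8, 8, 1), seed = 2)
  g <- fishrules:::cpp_attn_grad(Xp, Xw, odd, n, y, pi_p, w_p)
  fd_check(function(p) fishrules:::cpp_attn_grad(Xp, Xw, odd, n, y, p,
                                                 w_p)$loss,
           g$g_pi, pi_p, "attn pi")
  fd_check(function(p) fishrules:::cpp_attn_grad(Xp, Xw, odd, n, y, pi_p,
                                                 p)$loss,
           g$g_w, w_p, "attn w")
  # interaction: pair embedding and aggregator
  pe <- rand_mlp(c(4, 8, 8, 8, 8), seed = 3)
  ga <- rand_mlp(c(8, 8, 1), seed = 4)
  gi <- fishrules:::cpp_inter_grad(Xp, odd, n, y, pe, ga)
  fd_check(function(p) fishrules:::cpp_inter_grad(Xp, odd, n, y, p, ga)$loss,
           gi$g_pi, pe, "inter pi")
  fd_check(function(p) fishrules:::cpp_inter_grad(Xp, odd, n, y, pe, p)$loss,
           gi$g_gamma, ga, "inter gamma")
  # focal baseline
  fp <- rand_mlp(c(2, 8, 8, 1), seed = 5)
  gf <- fishrules:::cpp_focal_grad(Xa, 2L, y, fp)
  fd_check(function(p) fishrules:::cpp_focal_grad(Xa, 2L, y, p)$loss,
           gf$g, fp, "focal")
})

test_that("both social models are exactly odd under body-axis reflection", {
  ds <- separable_dataset(m = 200)
  ref <- reflect_dataset(ds)
  for (kind in c("attention", "interaction")) {
    model <- build_model(kind, ds, seed = 2)
    z <- predict_logit(model, ds)
    zr <- predict_logit(model, ref)
    expect_equal(zr, -z, tolerance = 1e-5)
  }
  model <- build_model("focal", ds, seed = 2)
  expect_equal(predict_logit(model, ref), -predict_logit(model, ds),
               tolerance = 1e-5)
})

test_that("logits are invariant under neighbour permutation", {
  ds <- separable_dataset(m = 150)
  set.seed(77)
  perm_ds <- ds
  for (s in seq_len(ds$m)) {
    rows <- (s - 1) * ds$n + seq_len(ds$n)
    p <- sample(ds$n)
    perm_ds$x_pair[rows, ] <- ds$x_pair[rows[p], ]
    perm_ds$x_w[rows, ] <- ds$x_w[rows[p], ]
  }
  for (kind in c("attention", "interaction")) {
    model <- build_model(kind, ds, seed = 5)
    expect_equal(predict_logit(model, perm_ds), predict_logit(model, ds),
                 tolerance = 1e-4)
  }
})

test_that("attention weights are positive, normalized, and drive the logit", {
  ds <- separable_dataset(m = 100)
  model <- build_model("attention", ds, seed = 7)
  out <- attention_logit(model, ds)
  expect_true(all(out$omega > 0))
  expect_equal(colSums(out$omega), rep(1, ds$m), tolerance = 1e-6)
  expect_equal(out$z, colSums(out$pi * out$omega), tolerance = 1e-5)
  # equal weights reduce the logit to the mean pair logit
  z_uniform <- colMeans(out$pi)
  eq <- abs(apply(out$omega, 2, max) - 1 / ds$n) < 1e-6
  expect_equal(out$z[eq], z_uniform[eq])
  # a dominant weight pins the logit to that neighbour's pair logit
  ds1 <- ds
  rows1 <- seq(1, ds$m * ds$n, by = ds$n)
  ds1$x_w[rows1, ] <- ds1$x_w[rows1, ] + 50  # push one neighbour's weight up
  out1 <- attention_logit(model, ds1)
  dom <- which(out1$omega[1, ] > 0.999)
  expect_gt(length(dom), 0)
  expect_equal(out1$z[dom], out1$pi[1, dom], tolerance = 1e-2)
})

test_that("a separable rule is learned to high accuracy by both models", {
  # the label is the x-side of the closest neighbour: recoverable only by a
  # model that can single out one neighbour from the permutation-invariant set
  ds <- separable_dataset(m = 40000, n = 3)
  for (kind in c("attention", "interaction")) {
    model <- build_model(kind, ds, seed = 11)
    cfg <- train_config(kind, batch_size = 100L, lr_start = 1e-3,
                        lr_end = 1e-4, max_epochs = 30L, seed = 11)
    model <- train_network(model, ds, cfg)
    acc <- evaluate_accuracy(model, ds, c(0, 180))
    expect_gt(acc, 0.95)
  }
})

test_that("label-free noise trains to chance accuracy", {
  ds <- separable_dataset(m = 1500, seed = 13)
  set.seed(13)
  ds$label <- sample(0:1, ds$m, TRUE)  # labels independent of inputs
  model <- build_model("attention", ds, seed = 3)
  model <- train_network(model, ds, train_config("attention",
                                                 max_epochs = 8L, seed = 3))
  acc <- evaluate_accuracy(model, ds, c(0, 180))
  expect_gt(acc, 0.38)
  expect_lt(acc, 0.62)
})

test_that("the early-stopping rule fires on stalled-and-risen loss only", {
  expect_false(fishrules:::should_stop(c(1, 0.9, 0.8), 10, 0.25))
  # stalled 10 epochs but not risen 25%
  expect_false(fishrules:::should_stop(c(0.8, rep(0.85, 10)), 10, 0.25))
  # stalled and risen
  expect_true(fishrules:::should_stop(c(0.8, rep(0.85, 9), 1.01), 10, 0.25))
  # risen early but patience not exhausted
  expect_false(fishrules:::should_stop(c(0.8, 1.1, 1.1), 10, 0.25))
})

test_that("training is deterministic given the seed", {
  ds <- separable_dataset(m = 800)
  run <- function() {
    model <- build_model("attention", ds, seed = 9)
    train_network(model, ds, train_config("attention", max_epochs = 3L,
                                          seed = 9))
  }
  m1 <- run(); m2 <- run()
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
})

test_that("angle filtering partitions accuracy consistently", {
  ds <- separable_dataset(m = 600)
  model <- build_model("attention", ds, seed = 1)
  idx <- which(ds$split == "test")
  n_low <- sum(ds$turn_angle[idx] <= 90)
  acc_low <- evaluate_accuracy(model, ds, c(0, 90))
  acc_high <- evaluate_accuracy(model, ds, c(90.0000001, 180))
  acc_all <- evaluate_accuracy(model, ds, c(0, 180))
  expect_equal(acc_all, (acc_low * n_low + acc_high * (length(idx) - n_low)) /
                 length(idx))
  expect_error(evaluate_accuracy(model, ds, c(200, 300)), "no samples")
})

test_that("model checkpoints round-trip with their manifest", {
  ds <- separable_dataset(m = 100)
  model <- build_model("attention", ds, seed = 2)
  path <- file.path(tempdir(), "model.rds")
  save_model(model, path)
  back <- load_model(path)
  expect_identical(back$params, model$params)
  expect_equal(predict_logit(back, ds), predict_logit(model, ds))
  saveRDS(list(), path)
  expect_error(load_model(path), "checkpoint")
})

test_that("mismatched manifests are refused", {
  ds <- separable_dataset(m = 100)
  model <- build_model("attention", ds, seed = 1)
  ds2 <- ds
  ds2$vars$social <- c(ds2$vars$social, "topo")
  expect_error(attention_logit(model, ds2), "manifest")
  expect_error(train_network(build_model("attention", ds, seed = 1), ds,
                             train_config("interaction")), "model_kind")
})
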
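#' Apply the circular-shift shuffle control to preprocessed kinematics
#'
#' Shifts each individual's positions, velocities, accelerations and masks
#' together by the [shuffle_offsets()] of the recording. Because every
#' per-individual series moves as one block, focal (asocial) kinematics
#' remain genuine and internally consistent; only the temporal alignment
#' between individuals -- hence every social relation -- is destroyed.
#'
#' @param prep output of [preprocess_trajectories()].
#' @return the shuffled preprocessing output.
#' @export
shuffle_preprocessed <- function(prep) {
  t_n <- dim(prep$kin$velocity)[1]
  n <- dim(prep$kin$velocity)[2]
  offs <- shuffle_offsets(t_n, n)
  shift1 <- function(x, k) if (k == 0) x else
    x[c((t_n - k + 1L):t_n, 1L:(t_n - k))]
  for (i in seq_len(n)) {
    k <- offs[i]
    for (d in 1:2) {
      prep$ts$positions[, i, d] <- shift1(prep$ts$positions[, i, d], k)
      prep$kin$velocity[, i, d] <- shift1(prep$kin$velocity[, i, d], k)
      prep$kin$acceleration[, i, d] <- shift1(prep$kin$acceleration[, i, d], k)
    }
    prep$kin$speed[, i] <- shift1(prep$kin$speed[, i], k)
    prep$kin$valid_mask[, i] <- shift1(prep$kin$valid_mask[, i], k)
    prep$ts$missing_mask[, i] <- shift1(prep$ts$missing_mask[, i], k)
    prep$border_mask[, i] <- shift1(prep$border_mask[, i], k)
  }
  prep
}

#' Preprocess a trajectory set with the standard chain
#'
#' Gap interpolation, arena normalization with border masking, causal
#' smoothing and causal differentiation, in that order.
#'
#' @param ts a [trajectory_set()].
#' @param border_fraction border-mask radius fraction (default 0.8).
#' @param max_gap longest interpolated gap in frames (default 5).
#' @param kernel_len,sigma causal smoothing kernel (defaults 5 frames,
#'   sigma 1 frame).
#' @return list with `ts` (normalized, smoothed), `kin`
#'   (a `kinematics_set`) and `border_mask`.
#' @export
preprocess_trajectories <- function(ts, border_fraction = 0.8, max_gap = 5L,
                                    kernel_len = 5L, sigma = 1) {
  ts <- interpolate_gaps(ts, max_gap = max_gap, quiet = TRUE)
  nm <- normalize_and_mask(ts, border_fraction = border_fraction)
  sm <- smooth_causal(nm$ts, kernel_len = kernel_len, sigma = sigma)
  list(ts = sm, kin = differentiate(sm), border_mask = nm$border_mask)
}

#' Build a turn dataset from a zonal simulation
#'
#' Simulates the zonal model, runs the standard preprocessing and builds
#' decision samples with a 125 ms horizon (4 frames at 32 fps) by default,
#' the horizon used when training on simulated trajectories.
#'
#' @param config a [zonal_config()].
#' @param duration recorded duration in seconds.
#' @param seed simulation seed.
#' @param n neighbours per sample (default 25).
#' @param horizon_s prediction horizon in seconds (default 0.125).
#' @param stride keep every `stride`-th frame.
#' @param fractions split fractions (default `c(0.97, 0.02, 0.01)`).
#' @param topo_index append the topological index to the social vectors.
#' @param shuffle apply the circular-shift shuffle control before
#'   building samples.
#' @return list with `dataset` (a `turn_dataset`), `sim` (the
#'   [simulate_zonal()] result) and `prep` (the preprocessing output).
#' @export
sim_turn_dataset <- function(config, duration, seed = 1L, n = 25L,
                             horizon_s = 0.125, stride = 1L,
                             fractions = c(0.97, 0.02, 0.01),
                             topo_index = FALSE, shuffle = FALSE) {
  sim <- simulate_zonal(config, duration, seed = seed)
  prep <- preprocess_trajectories(sim$ts)
  if (shuffle) prep <- shuffle_preprocessed(prep)
  horizon <- round(horizon_s * prep$kin$fps)
  split <- split_frames(dim(prep$kin$velocity)[1], fractions)
  ds <- build_dataset(prep$kin, prep$ts, split, prep$border_mask,
                      n = n, horizon = horizon, stride = stride,
                      topo_index = topo_index)
  list(dataset = ds, sim = sim, prep = prep)
}

#' Zone-wise score summary of a recovery map
#'
#' Evaluates the trained pair-interaction subnetwork on a dense spatial
#' grid, classifies every point, and summarises the scores inside each
#' true interaction zone of the generating configuration: the mean
#' attraction-repulsion score in the repulsion and attraction zones and
#' the fraction of orientation-zone points classified as alignment.
#'
#' @param model a trained attention `fish_model`.
#' @param config the generating [zonal_config()].
#' @param focal_speed,neighbour_speed evaluation speeds in BL/s (defaults:
#'   the simulator's constant speed).
#' @param step spatial grid step in BL (default 0.5).
#' @param extent half-width of the evaluated square in BL (default 10.5).
#' @param theta_n orientation samples (default 64).
#' @return list with the per-zone summaries and the underlying point
#'   classification (`points`).
#' @export
recovery_scores <- function(model, config, focal_speed = config$speed,
                            neighbour_speed = config$speed, step = 0.25,
                            extent = 10.5, theta_n = 64L) {
  ax <- seq(-extent, extent, by = step)
  ax <- ax[ax != 0]  # x = 0 has score 0 by convention; skip the axis
  map <- pair_logit_map(model, x = ax, y = ax,
                        theta = seq(-pi, pi, length.out = theta_n + 1L)[seq_len(theta_n)],
                        v_i = neighbour_speed, focal_speed = focal_speed)
  pts <- classify_regions(map)
  pts$zone <- true_zone(pts$x, pts$y, config)
  rep_pts <- pts[!is.na(pts$zone) & pts$zone == "repulsion", ]
  att_pts <- pts[!is.na(pts$zone) & pts$zone == "attraction", ]
  ori_pts <- pts[!is.na(pts$zone) & pts$zone == "orientation", ]
  list(repulsion_mean_score = mean(rep_pts$ar_score),
       attraction_mean_score = mean(att_pts$ar_score),
       orientation_alignment_fraction = mean(ori_pts$class == "alignment"),
       points = pts)
}

#' Compare estimated and ground-truth neighbour counts
#'
#' Computes the run-averaged effective number of interacting neighbours
#' `N_total` from a trained attention model and the run-averaged
#' ground-truth count over the same (frame, focal) pairs.
#'
#' @param model a trained attention `fish_model`.
#' @param dataset the matching `turn_dataset`.
#' @param sim the [simulate_zonal()] result the dataset was built from.
#' @return list with `estimated` (mean `N_total`), `truth` (mean
#'   ground-truth count), `ratio`, and the per-sample `series`.
#' @export
count_recovery <- function(model, dataset, sim) {
  ser <- neighbour_count_series(model, dataset)
  truth <- sim$counts[cbind(ser$frame, ser$focal)]
  list(estimated = mean(ser$n_total), truth = mean(truth),
       ratio = mean(ser$n_total) / mean(truth),
       series = cbind(ser, truth = truth))
}

#' Ground-truth recovery experiment for one configuration
#'
#' End-to-end validation run: simulate the zonal model, build the 125-ms
#' decision dataset, train the attention network, and score the learned
#' maps against the generating geometry (and, for finite topological caps,
#' the estimated against the true neighbour counts).
#'
#' @param config a [zonal_config()].
#' @param duration simulated recording length in seconds.
#' @param seed seed for simulation, initialization and training.
#' @param n neighbours per sample.
#' @param stride dataset frame stride.
#' @param fractions split fractions.
#' @param topo_index include the topological index input.
#' @param max_epochs,batch_size training-schedule overrides.
#' @param anneal_epochs learning-rate annealing horizon (default 100, the
#'   reference schedule, so short runs keep the schedule's early-epoch
#'   rates).
#' @param verbose print training progress.
#' @return list of class `"recovery_report"`: `scores` (from
#'   [recovery_scores()]), `counts` (from [count_recovery()], `NULL` for an
#'   uncapped run), `accuracy` (all angles and 20-160 degrees, test
#'   split), the trained `model` and the `dataset`.
#' @export
run_recovery <- function(config, duration = 60, seed = 1L, n = 25L,
                         stride = 4L, fractions = c(0.85, 0.05, 0.10),
                         topo_index = FALSE, max_epochs = 20L,
                         batch_size = 500L, anneal_epochs = 100L,
                         verbose = FALSE) {
  sd <- sim_turn_dataset(config, duration, seed = seed, n = n,
                         stride = stride, fractions = fractions,
                         topo_index = topo_index)
  model <- build_model("attention", sd$dataset, seed = seed)
  cfg <- train_config("attention", batch_size = batch_size,
                      max_epochs = max_epochs,
                      anneal_epochs = anneal_epochs, seed = seed)
  model <- train_network(model, sd$dataset, cfg, verbose = verbose)
  counts <- if (is.finite(config$topological_cap))
    count_recovery(model, sd$dataset, sd$sim) else NULL
  out <- list(scores = recovery_scores(model, config),
              counts = counts,
              accuracy = c(
                all = evaluate_accuracy(model, sd$dataset, c(0, 180)),
                large = evaluate_accuracy(model, sd$dataset, c(20, 160))),
              model = model, dataset = sd$dataset, config = config,
              seed = as.integer(seed))
  class(out) <- "recovery_report"
  out
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report: preset '%s', cap %s>\n", x$config$preset,
              format(x$config$topological_cap)))
  cat(sprintf("  test accuracy: %.1f%% (all angles), %.1f%% (20-160 deg)\n",
              100 * x$accuracy["all"], 100 * x$accuracy["large"]))
  s <- x$scores
  cat(sprintf("  mean score: repulsion zone %+.3f, attraction zone %+.3f\n",
              s$repulsion_mean_score, s$attraction_mean_score))
  cat(sprintf("  orientation zone classified alignment: %.0f%%\n",
              100 * s$orientation_alignment_fraction))
  if (!is.null(x$counts))
    cat(sprintf("  N_total: estimated %.2f vs ground truth %.2f\n",
                x$counts$estimated, x$counts$truth))
  invisible(x)
}

#' Small deterministic fixture
#'
#' A seconds-scale zonal simulation (10 agents by default) with a few
#' injected tracking gaps, for exercising the preprocessing chain.
#'
#' @param seed integer seed.
#' @param n_agents number of agents (default 10).
#' @param duration seconds (default 20).
#' @param n_gaps number of injected single-point gaps (default 5).
#' @return a [trajectory_set()] with missing points.
#' @export
make_fixture <- function(seed = 1L, n_agents = 10L, duration = 20,
                         n_gaps = 5L) {
  config <- zonal_config(n_agents = n_agents, arena_radius = 15)
  sim <- simulate_zonal(config, duration, seed = seed, burn_in = 2)
  pos <- sim$ts$positions
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed + 1L)
  t_n <- dim(pos)[1]
  gt <- sample(3:(t_n - 3L), n_gaps)
  gi <- sample(n_agents, n_gaps, replace = TRUE)
  for (k in seq_len(n_gaps)) pos[gt[k], gi[k], ] <- NA_real_
  trajectory_set(pos, fps = sim$ts$fps, arena_center = c(0, 0),
                 arena_radius = config$arena_radius)
}

#' Analyse an experimental trajectory recording
#'
#' The observational arm of the pipeline: preprocess, build the decision
#' dataset at a 1-s horizon (the horizon used for recordings of real
#' groups), train the attention network, and return angle-filtered
#' accuracies, interaction maps and neighbour-count statistics. The same
#' entry point accepts simulator output, which uses the identical
#' container.
#'
#' @param ts a [trajectory_set()] (e.g. from [read_trajectories()]).
#' @param n neighbours per sample (default 25).
#' @param horizon_s prediction horizon in seconds (default 1).
#' @param stride dataset frame stride.
#' @param fractions split fractions (default `c(0.97, 0.02, 0.01)`).
#' @param angle_bands turning-angle bands (degrees) to report accuracy
#'   for, in addition to all angles.
#' @param max_epochs,seed training-schedule settings.
#' @param shuffle analyse the circular-shift shuffle control instead.
#' @param verbose print training progress.
#' @return list with `accuracy`, `map` (a [pair_logit_map()]),
#'   `regions`, `counts` (per-sample `N_total`/`N_important`), the
#'   trained `model` and the `dataset`.
#' @export
run_fish_analysis <- function(ts, n = 25L, horizon_s = 1, stride = 1L,
                              fractions = c(0.97, 0.02, 0.01),
                              angle_bands = list(c(20, 160), c(30, 100)),
                              max_epochs = 20L, seed = 1L, shuffle = FALSE,
                              verbose = FALSE) {
  prep <- preprocess_trajectories(ts)
  if (shuffle) prep <- shuffle_preprocessed(prep)
  horizon <- round(horizon_s * prep$kin$fps)
  split <- split_frames(dim(prep$kin$velocity)[1], fractions)
  ds <- build_dataset(prep$kin, prep$ts, split, prep$border_mask, n = n,
                      horizon = horizon, stride = stride)
  model <- build_model("attention", ds, seed = seed)
  model <- train_network(model, ds,
                         train_config("attention", max_epochs = max_epochs,
                                      seed = seed), verbose = verbose)
  acc <- c(all = evaluate_accuracy(model, ds, c(0, 180)))
  for (band in angle_bands)
    acc[sprintf("%g-%g", band[1], band[2])] <-
      evaluate_accuracy(model, ds, band)
  map <- pair_logit_map(model)
  counts <- neighbour_count_series(model, ds)
  list(accuracy = acc, map = map, regions = classify_regions(map),
       counts = counts, model = model, dataset = ds)
}
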
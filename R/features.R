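#' Transform a neighbour into the focal's egocentric frame
#'
#' Coordinates are expressed in an instantaneous, non-moving frame centred
#' on the focal with the +y axis along the focal's velocity; +x points to
#' the focal's right. `theta` is the neighbour's heading relative to the
#' focal's, in `[-pi, pi)`, 0 = parallel, positive = heading to the focal's
#' right.
#'
#' @param focal_pos,focal_vel length-2 focal position and velocity.
#' @param other_pos,other_vel length-2 neighbour position and absolute
#'   velocity (same world frame).
#' @return list with `x`, `y`, `vx`, `vy`, `v` (neighbour speed), `theta`.
#' @export
focal_frame_transform <- function(focal_pos, focal_vel, other_pos, other_vel) {
  sp <- sqrt(sum(focal_vel^2))
  if (sp <= 0) stop("focal speed is zero; frame undefined", call. = FALSE)
  f <- focal_vel / sp             # forward (+y)
  r <- c(f[2], -f[1])             # right (+x)
  rel <- other_pos - focal_pos
  vx <- sum(other_vel * r); vy <- sum(other_vel * f)
  th <- atan2(vx, vy)
  if (th >= pi) th <- th - 2 * pi
  list(x = sum(rel * r), y = sum(rel * f), vx = vx, vy = vy,
       v = sqrt(sum(other_vel^2)), theta = th)
}

#' Indices of the n nearest neighbours
#'
#' @param positions numeric `[individuals x 2]` positions at one frame;
#'   rows with `NA` are ignored.
#' @param focal focal row index.
#' @param n number of neighbours.
#' @return integer vector of `n` indices ordered by increasing Euclidean
#'   distance, ties broken by lower index.
#' @export
nearest_neighbours <- function(positions, focal, n = 25L) {
  d <- sqrt((positions[, 1] - positions[focal, 1])^2 +
            (positions[, 2] - positions[focal, 2])^2)
  d[focal] <- Inf
  d[is.na(d)] <- Inf
  if (sum(is.finite(d)) < n)
    stop(sprintf("only %d neighbours available, %d requested",
                 sum(is.finite(d)), n), call. = FALSE)
  order(d)[seq_len(n)]
}

#' Turning side and turning angle after a horizon
#'
#' The turning angle is the unsigned angle (degrees) between the focal's
#' velocity at `t` and at `t + horizon`. The side is right when the future
#' velocity has a positive x-component in the focal frame at `t` (i.e. the
#' heading moved clockwise); the measure-zero exact tie is labelled right.
#'
#' @param kin a `kinematics_set` from [differentiate()].
#' @param focal individual index.
#' @param t frame index (1-based).
#' @param horizon horizon in frames.
#' @return list with `side` (`"right"` or `"left"`) and `turn_angle`
#'   (degrees in `[0, 180]`), or `NULL` when either heading is undefined.
#' @export
turn_label <- function(kin, focal, t, horizon) {
  t2 <- t + horizon
  if (t2 > dim(kin$velocity)[1]) stop("horizon beyond recording", call. = FALSE)
  v1 <- kin$velocity[t, focal, ]
  v2 <- kin$velocity[t2, focal, ]
  if (anyNA(c(v1, v2)) || sum(v1^2) == 0 || sum(v2^2) == 0) return(NULL)
  f <- v1 / sqrt(sum(v1^2))
  r <- c(f[2], -f[1])
  xc <- sum(v2 * r)
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  list(side = if (xc >= 0) "right" else "left", turn_angle = ang)
}

# feature tables: which variables exist, whether each flips sign under
# body-axis reflection (odd), and which feed the weighting subnetwork
ALPHA_VARS <- c(v = FALSE, a_perp = TRUE, a_par = FALSE)
SOCIAL_VARS <- c(x = TRUE, y = FALSE, vx = TRUE, vy = FALSE,
                 ax = TRUE, ay = FALSE, topo = FALSE)

#' Build focal-frame decision samples from kinematics
#'
#' Produces one sample per (valid focal, selected frame): the asocial
#' vector of the focal, the social vectors of its `n` nearest neighbours
#' (sorted by increasing distance, expressed in the focal frame), and the
#' turning side/angle after `horizon` frames. A focal is valid at frame t
#' when its kinematics are defined at t and t + horizon, its speed is
#' positive at both, and it is not border-masked at t; border-masked or
#' missing individuals still serve as neighbours when tracked.
#'
#' Features are z-scored with statistics fitted on the training split
#' only; variables that flip sign under body-axis reflection are scaled
#' but not centred, so reflection remains an exact sign flip in feature
#' space. The weighting subnetwork receives the reflection-invariant
#' subset (focal speed, neighbour speed, |x|, y, plus the topological
#' index when enabled), standardized with its own training statistics.
#'
#' @param kin a `kinematics_set` from [differentiate()].
#' @param ts the matching normalized [trajectory_set()] (positions in BL).
#' @param split frame split from [split_frames()].
#' @param border_mask logical `[frames x individuals]` from
#'   [normalize_and_mask()], or `NULL`.
#' @param n number of neighbours per sample (default 25).
#' @param horizon prediction horizon in frames.
#' @param stride keep every `stride`-th frame (default 1).
#' @param alpha_vars asocial variables (default `c("v", "a_perp")`).
#' @param social_vars social variables per neighbour
#'   (default `c("x", "y", "vx", "vy")`).
#' @param topo_index append each neighbour's distance rank to its social
#'   vector (and to the weighting inputs).
#' @return an object of class `"turn_dataset"`: standardized feature
#'   matrices `x_pair` (`[m*n x d]`, sample-major), `x_w`, `x_alpha`,
#'   labels (1 = right), turning angles, provenance (`frame`, `focal`) and
#'   the standardization statistics.
#' @export
build_dataset <- function(kin, ts, split, border_mask = NULL, n = 25L,
                          horizon, stride = 1L,
                          alpha_vars = c("v", "a_perp"),
                          social_vars = c("x", "y", "vx", "vy"),
                          topo_index = FALSE) {
  stopifnot(inherits(kin, "kinematics_set"), inherits(ts, "trajectory_set"))
  stopifnot(all(alpha_vars %in% names(ALPHA_VARS)),
            all(social_vars %in% setdiff(names(SOCIAL_VARS), "topo")))
  t_n <- dim(kin$velocity)[1]
  n_ind <- dim(kin$velocity)[2]
  if (n_ind <= n)
    stop(sprintf("need more than n = %d individuals, got %d", n, n_ind),
         call. = FALSE)
  if (is.null(border_mask)) border_mask <- matrix(FALSE, t_n, n_ind)
  if (topo_index) social_vars <- c(social_vars, "topo")

  frames_by_split <- lapply(split, function(fr) {
    fr <- fr[fr + horizon <= t_n & fr >= 3L]
    fr[seq_along(fr) %% stride == 0L]
  })
  if (any(!lengths(frames_by_split)))
    stop("a split is empty after horizon/stride filtering", call. = FALSE)

  chunks <- list(); ci <- 0L
  for (sp in names(frames_by_split)) {
    for (t in frames_by_split[[sp]]) {
      smp <- frame_samples(kin, ts, border_mask, t, n, horizon,
                           alpha_vars, social_vars)
      if (is.null(smp)) next
      smp$split <- sp
      ci <- ci + 1L
      chunks[[ci]] <- smp
    }
  }
  if (!ci) stop("no valid samples", call. = FALSE)

  m <- sum(vapply(chunks, function(ch) length(ch$label), integer(1)))
  ds <- list(
    x_pair = do.call(rbind, lapply(chunks, `[[`, "pair")),
    x_alpha = do.call(rbind, lapply(chunks, `[[`, "alpha")),
    x_w = do.call(rbind, lapply(chunks, `[[`, "w")),
    label = unlist(lapply(chunks, `[[`, "label"), use.names = FALSE),
    turn_angle = unlist(lapply(chunks, `[[`, "angle"), use.names = FALSE),
    frame = unlist(lapply(chunks, `[[`, "frame"), use.names = FALSE),
    focal = unlist(lapply(chunks, `[[`, "focal"), use.names = FALSE),
    split = unlist(lapply(chunks, function(ch)
      rep(ch$split, length(ch$label))), use.names = FALSE),
    m = m, n = as.integer(n),
    vars = list(alpha = alpha_vars, social = social_vars))

  pair_cols <- c(alpha_vars, social_vars)
  odd <- c(ALPHA_VARS[alpha_vars], SOCIAL_VARS[social_vars])
  ds$odd_pair <- which(unname(odd))
  ds$odd_alpha <- which(unname(ALPHA_VARS[alpha_vars]))
  colnames(ds$x_pair) <- pair_cols
  colnames(ds$x_alpha) <- alpha_vars
  standardize_dataset(ds, odd)
}

# samples for one frame, vectorized over focals; returns raw features
frame_samples <- function(kin, ts, border_mask, t, n, horizon,
                          alpha_vars, social_vars) {
  pos <- ts$positions[t, , ]
  vel <- kin$velocity[t, , ]
  acc <- kin$acceleration[t, , ]
  sp <- kin$speed[t, ]
  sp2 <- kin$speed[t + horizon, ]
  ok_focal <- kin$valid_mask[t, ] & kin$valid_mask[t + horizon, ] &
    !border_mask[t, ] & !is.na(sp) & sp > 0 & !is.na(sp2) & sp2 > 0
  ok_nb <- !ts$missing_mask[t, ] & is.finite(vel[, 1])
  focals <- which(ok_focal)
  if (!length(focals)) return(NULL)
  if (sum(ok_nb) - 1L < n) return(NULL)

  fx <- vel[, 1] / sp; fy <- vel[, 2] / sp   # forward unit
  rx <- fy; ry <- -fx                        # right unit
  # future-velocity side and turning angle per focal
  v2 <- kin$velocity[t + horizon, , ]
  xc <- v2[, 1] * rx + v2[, 2] * ry
  cosang <- (vel[, 1] * v2[, 1] + vel[, 2] * v2[, 2]) / (sp * sp2)
  angle <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi

  nf <- length(focals)
  dx <- matrix(pos[, 1], nf, length(sp), byrow = TRUE) - pos[focals, 1]
  dy <- matrix(pos[, 2], nf, length(sp), byrow = TRUE) - pos[focals, 2]
  dist <- sqrt(dx^2 + dy^2)
  dist[cbind(seq_len(nf), focals)] <- Inf
  dist[, !ok_nb] <- Inf
  ord <- t(apply(dist, 1L, function(d) order(d)[seq_len(n)]))

  rows_f <- rep(seq_len(nf), each = n)
  nb <- as.vector(t(ord))
  foc <- focals[rows_f]
  xl <- dx[cbind(rows_f, nb)] * rx[foc] + dy[cbind(rows_f, nb)] * ry[foc]
  yl <- dx[cbind(rows_f, nb)] * fx[foc] + dy[cbind(rows_f, nb)] * fy[foc]
  vxl <- vel[nb, 1] * rx[foc] + vel[nb, 2] * ry[foc]
  vyl <- vel[nb, 1] * fx[foc] + vel[nb, 2] * fy[foc]

  social <- sapply(social_vars, function(vn) switch(vn,
    x = xl, y = yl, vx = vxl, vy = vyl,
    ax = acc[nb, 1] * rx[foc] + acc[nb, 2] * ry[foc],
    ay = acc[nb, 1] * fx[foc] + acc[nb, 2] * fy[foc],
    topo = rep(seq_len(n), times = nf)))
  alpha <- sapply(alpha_vars, function(vn) switch(vn,
    v = sp[focals],
    a_perp = acc[focals, 1] * rx[focals] + acc[focals, 2] * ry[focals],
    a_par = acc[focals, 1] * fx[focals] + acc[focals, 2] * fy[focals]))
  if (!is.matrix(alpha)) alpha <- matrix(alpha, nrow = nf)
  if (!is.matrix(social)) social <- matrix(social, nrow = nf * n)

  pair <- cbind(alpha[rows_f, , drop = FALSE], social)
  wmat <- cbind(v = sp[foc], vi = sqrt(vxl^2 + vyl^2), absx = abs(xl), y = yl)
  if ("topo" %in% social_vars)
    wmat <- cbind(wmat, topo = rep(seq_len(n), times = nf))
  list(pair = pair, alpha = alpha, w = wmat,
       label = as.integer(xc[focals] >= 0), angle = angle[focals],
       frame = rep(t, nf), focal = focals)
}

# z-score features with train-split statistics; odd features keep mean 0
standardize_dataset <- function(ds, odd) {
  tr <- ds$split == "train"
  tr_rows <- pair_rows(which(tr), ds$n)
  std <- function(x, rows, force_zero_mean) {
    mu <- colMeans(x[rows, , drop = FALSE])
    mu[force_zero_mean] <- 0
    sd <- sqrt(colMeans(sweep(x[rows, , drop = FALSE], 2, mu)^2))
    sd[sd < 1e-12] <- 1
    list(mean = mu, sd = sd)
  }
  st_pair <- std(ds$x_pair, tr_rows, unname(odd))
  st_alpha <- std(ds$x_alpha, which(tr),
                  unname(ALPHA_VARS[ds$vars$alpha]))
  st_w <- std(ds$x_w, tr_rows, rep(FALSE, ncol(ds$x_w)))
  apply_std <- function(x, st) sweep(sweep(x, 2, st$mean), 2, st$sd, "/")
  ds$x_pair <- apply_std(ds$x_pair, st_pair)
  ds$x_alpha <- apply_std(ds$x_alpha, st_alpha)
  ds$x_w <- apply_std(ds$x_w, st_w)
  ds$stats <- list(pair = st_pair, alpha = st_alpha, w = st_w)
  class(ds) <- "turn_dataset"
  ds
}

#' Reflect a dataset along the focal body axis
#'
#' Flips the sign of every reflection-odd feature (`x`, `vx`, `ax`,
#' `a_perp`) and the turn labels; the weighting inputs are
#' reflection-invariant and unchanged.
#'
#' @param ds a `turn_dataset`.
#' @return the reflected `turn_dataset`.
#' @export
reflect_dataset <- function(ds) {
  ds$x_pair[, ds$odd_pair] <- -ds$x_pair[, ds$odd_pair]
  if (length(ds$odd_alpha))
    ds$x_alpha[, ds$odd_alpha] <- -ds$x_alpha[, ds$odd_alpha]
  ds$label <- 1L - ds$label
  ds
}

#' Subset a turn dataset by sample index
#'
#' @param ds a `turn_dataset`.
#' @param idx sample indices to keep.
#' @return a `turn_dataset` with `length(idx)` samples.
#' @export
subset_dataset <- function(ds, idx) {
  rows <- pair_rows(idx, ds$n)
  ds$x_pair <- ds$x_pair[rows, , drop = FALSE]
  ds$x_w <- ds$x_w[rows, , drop = FALSE]
  ds$x_alpha <- ds$x_alpha[idx, , drop = FALSE]
  for (f in c("label", "turn_angle", "frame", "focal", "split"))
    ds[[f]] <- ds[[f]][idx]
  ds$m <- length(idx)
  ds
}

#' Concatenate turn datasets with identical layouts
#'
#' Used to pool samples across recordings (e.g. simulations with different
#' topological caps). The datasets must share variable subsets. Each input
#' is de-standardized with its own statistics and the pooled features are
#' re-standardized on the pooled training split, so the result is a
#' consistently scaled dataset.
#'
#' @param ds_list list of `turn_dataset` objects.
#' @param run_id optional labels, recycled per dataset, stored as `run`.
#' @return a pooled `turn_dataset`.
#' @export
bind_datasets <- function(ds_list, run_id = seq_along(ds_list)) {
  stopifnot(length(ds_list) >= 1)
  v0 <- ds_list[[1]]$vars
  for (ds in ds_list)
    if (!identical(ds$vars, v0) || ds$n != ds_list[[1]]$n)
      stop("datasets have mismatched layouts", call. = FALSE)
  unstd <- function(x, st) sweep(sweep(x, 2, st$sd, "*"), 2, st$mean, "+")
  out <- ds_list[[1]]
  out$x_pair <- do.call(rbind, lapply(ds_list, function(ds)
    unstd(ds$x_pair, ds$stats$pair)))
  out$x_w <- do.call(rbind, lapply(ds_list, function(ds)
    unstd(ds$x_w, ds$stats$w)))
  out$x_alpha <- do.call(rbind, lapply(ds_list, function(ds)
    unstd(ds$x_alpha, ds$stats$alpha)))
  for (f in c("label", "turn_angle", "frame", "focal", "split"))
    out[[f]] <- unlist(lapply(ds_list, `[[`, f), use.names = FALSE)
  out$run <- unlist(mapply(function(ds, id) rep(id, ds$m), ds_list, run_id,
                           SIMPLIFY = FALSE), use.names = FALSE)
  out$m <- length(out$label)
  odd <- stats::setNames(seq_len(ncol(out$x_pair)) %in% out$odd_pair,
                         colnames(out$x_pair))
  standardize_dataset(unclass(out), odd)
}

#' @export
print.turn_dataset <- function(x, ...) {
  cat(sprintf("<turn_dataset: %d samples x %d neighbours>\n", x$m, x$n))
  cat(sprintf("  pair vars: %s (input dim %d x %d = %d)\n",
              paste(colnames(x$x_pair), collapse = ", "), x$n,
              ncol(x$x_pair), x$n * ncol(x$x_pair)))
  cat(sprintf("  splits: %s\n",
              paste(sprintf("%s %d", names(table(x$split)), table(x$split)),
                    collapse = ", ")))
  cat(sprintf("  right turns: %.1f%%; median turn angle %.1f deg\n",
              100 * mean(x$label), stats::median(x$turn_angle)))
  invisible(x)
}
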
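#' Multi-individual trajectory container
#'
#' Holds per-frame 2-D positions for all individuals of a recording together
#' with the recording metadata needed downstream: frame rate, arena centre
#' and radius, and (for pixel-unit recordings) the pixel length of one body
#' length (BL). Untracked points are marked in `missing_mask` and stored as
#' `NA` in `positions`.
#'
#' @param positions numeric array `[frames x individuals x 2]`.
#' @param fps frames per second (recordings analysed here use 32).
#' @param arena_center numeric length-2, same units as `positions`.
#' @param arena_radius positive scalar, same units as `positions`.
#' @param body_length_px pixels per body length, or `NULL` when positions
#'   are already expressed in BL.
#' @param missing_mask logical `[frames x individuals]`; inferred from
#'   non-finite positions when `NULL`.
#' @return an object of class `"trajectory_set"`.
#' @export
trajectory_set <- function(positions, fps = 32,
                           arena_center = c(0, 0), arena_radius,
                           body_length_px = NULL, missing_mask = NULL) {
  stopifnot(is.array(positions), length(dim(positions)) == 3,
            dim(positions)[3] == 2)
  if (dim(positions)[1] < 2) stop("need at least 2 frames", call. = FALSE)
  if (dim(positions)[2] < 1) stop("need at least 1 individual", call. = FALSE)
  stopifnot(fps > 0, arena_radius > 0, length(arena_center) == 2)
  inferred <- !is.finite(positions[, , 1]) | !is.finite(positions[, , 2])
  if (!is.matrix(inferred)) inferred <- matrix(inferred, dim(positions)[1])
  if (is.null(missing_mask)) missing_mask <- inferred
  stopifnot(identical(dim(missing_mask), dim(positions)[1:2]))
  positions[, , 1][missing_mask] <- NA_real_
  positions[, , 2][missing_mask] <- NA_real_
  structure(list(positions = positions, fps = fps,
                 arena_center = as.numeric(arena_center),
                 arena_radius = arena_radius,
                 body_length_px = body_length_px,
                 missing_mask = missing_mask),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  d <- dim(x$positions)
  cat(sprintf("<trajectory_set: %d frames x %d individuals @ %g fps>\n",
              d[1], d[2], x$fps))
  cat(sprintf("  arena: center (%g, %g), radius %g; missing %.3f%%\n",
              x$arena_center[1], x$arena_center[2], x$arena_radius,
              100 * mean(x$missing_mask)))
  invisible(x)
}

n_frames <- function(ts) dim(ts$positions)[1]
n_individuals <- function(ts) dim(ts$positions)[2]

#' Read trajectories from disk
#'
#' Reads the long CSV dialect with columns `frame,id,x,y` (frames 0-based;
#' ids arbitrary labels mapped to columns in sorted order). Cells absent
#' from the file, or with blank/NaN coordinates, become missing points.
#' Recording metadata comes from a YAML sidecar (keys `fps`, `arena_center`,
#' `arena_radius`, optional `body_length_px`) or an equivalent named list.
#'
#' @param path CSV file path.
#' @param meta path to a YAML metadata file, or a named list. Defaults to
#'   `paste0(path, ".yaml")` when that file exists.
#' @param dialect input dialect; only `"csv-long"` is supported by this
#'   implementation.
#' @return a [trajectory_set()].
#' @export
read_trajectories <- function(path, meta = NULL, dialect = "csv-long") {
  if (!identical(dialect, "csv-long"))
    stop(sprintf("unsupported trajectory dialect '%s'; use 'csv-long'",
                 dialect), call. = FALSE)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(utils::read.csv(path), error = function(e)
    stop("malformed trajectory file (expected columns frame,id,x,y): ",
         conditionMessage(e), call. = FALSE))
  need <- c("frame", "id", "x", "y")
  if (!all(need %in% names(df)) || nrow(df) == 0)
    stop("malformed trajectory file: expected non-empty columns frame,id,x,y",
         call. = FALSE)
  if (is.null(meta)) {
    side <- paste0(path, ".yaml")
    if (file.exists(side)) meta <- side
    else stop("no metadata given and no sidecar found at ", side,
              call. = FALSE)
  }
  if (is.character(meta)) meta <- yaml::read_yaml(meta)
  ids <- sort(unique(df$id))
  t_max <- max(df$frame)
  pos <- array(NA_real_, dim = c(t_max + 1L, length(ids), 2))
  row <- cbind(df$frame + 1L, match(df$id, ids))
  pos[cbind(row, 1L)] <- df$x
  pos[cbind(row, 2L)] <- df$y
  trajectory_set(pos, fps = meta$fps,
                 arena_center = unlist(meta$arena_center),
                 arena_radius = meta$arena_radius,
                 body_length_px = meta$body_length_px)
}

#' Write trajectories to disk
#'
#' Writes the long CSV dialect (`frame,id,x,y`, frames 0-based, missing
#' points omitted) and a YAML metadata sidecar at `paste0(path, ".yaml")`.
#'
#' @param ts a [trajectory_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(ts, path) {
  t_n <- n_frames(ts); n <- n_individuals(ts)
  df <- data.frame(frame = rep(seq_len(t_n) - 1L, times = n),
                   id = rep(seq_len(n) - 1L, each = t_n),
                   x = as.vector(ts$positions[, , 1]),
                   y = as.vector(ts$positions[, , 2]))
  df <- df[!is.na(df$x) & !is.na(df$y), ]
  df <- df[order(df$frame, df$id), ]
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(fps = ts$fps, arena_center = ts$arena_center,
               arena_radius = ts$arena_radius)
  if (!is.null(ts$body_length_px)) meta$body_length_px <- ts$body_length_px
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' Linearly interpolate short tracking gaps
#'
#' Runs of missing frames of length at most `max_gap` are filled by
#' per-coordinate linear interpolation between the flanking tracked points.
#' Longer gaps, and leading/trailing missing runs (which have no flanking
#' values), are left missing.
#'
#' @param ts a [trajectory_set()].
#' @param max_gap longest gap (frames) that is filled (default 5).
#' @param quiet suppress the message reporting the interpolated fraction.
#' @return a [trajectory_set()] with the short gaps filled.
#' @export
interpolate_gaps <- function(ts, max_gap = 5L, quiet = FALSE) {
  pos <- ts$positions
  before <- sum(ts$missing_mask)
  for (i in seq_len(n_individuals(ts))) {
    for (k in 1:2) {
      pos[, i, k] <- zoo::na.approx(pos[, i, k], maxgap = max_gap,
                                    na.rm = FALSE)
    }
  }
  mask <- is.na(pos[, , 1]) | is.na(pos[, , 2])
  if (!is.matrix(mask)) mask <- matrix(mask, n_frames(ts))
  filled <- before - sum(mask)
  if (!quiet)
    message(sprintf("interpolated %d of %d points (%.3f%%)", filled,
                    length(mask), 100 * filled / length(mask)))
  if (any(mask[1, ] | mask[n_frames(ts), ]) && !quiet)
    warning("leading/trailing missing runs cannot be interpolated",
            call. = FALSE)
  trajectory_set(pos, fps = ts$fps, arena_center = ts$arena_center,
                 arena_radius = ts$arena_radius,
                 body_length_px = ts$body_length_px, missing_mask = mask)
}

#' Normalize trajectories and mask the arena border
#'
#' Translates positions so the arena centre sits at the origin and, when
#' `body_length_px` is known, rescales them to body-length (BL) units --
#' the unit in which all model inputs are expressed. Points further from
#' the centre than `border_fraction` times the arena radius are flagged in
#' `border_mask`; downstream, such points are excluded as focal samples but
#' still usable as neighbours.
#'
#' @param ts a [trajectory_set()].
#' @param border_fraction radius fraction beyond which points are masked
#'   (default 0.8).
#' @return list with `ts` (normalized trajectories) and `border_mask`
#'   (logical `[frames x individuals]`; `FALSE` at missing points).
#' @export
normalize_and_mask <- function(ts, border_fraction = 0.8) {
  if (ts$arena_radius <= 0) stop("arena radius must be positive", call. = FALSE)
  scale <- if (is.null(ts$body_length_px)) 1 else ts$body_length_px
  pos <- ts$positions
  pos[, , 1] <- (pos[, , 1] - ts$arena_center[1]) / scale
  pos[, , 2] <- (pos[, , 2] - ts$arena_center[2]) / scale
  radius <- ts$arena_radius / scale
  out <- trajectory_set(pos, fps = ts$fps, arena_center = c(0, 0),
                        arena_radius = radius, body_length_px = NULL,
                        missing_mask = ts$missing_mask)
  r <- sqrt(pos[, , 1]^2 + pos[, , 2]^2)
  border <- !is.na(r) & r > border_fraction * radius
  if (!is.matrix(border)) border <- matrix(border, n_frames(ts))
  list(ts = out, border_mask = border)
}

# truncated-and-renormalized half-Gaussian weights for lags 0..len-1
causal_kernel <- function(kernel_len, sigma) {
  k <- 0:(kernel_len - 1L)
  w <- exp(-k^2 / (2 * sigma^2))
  w / sum(w)
}

#' Causal half-Gaussian smoothing
#'
#' Convolves each coordinate with a causal kernel spanning the current
#' frame and `kernel_len - 1` past frames, with weights proportional to
#' `exp(-k^2 / (2 sigma^2))` at lag `k`, normalized to sum to one. The
#' output at frame t never depends on frames after t. For the first
#' `kernel_len - 1` frames the kernel is truncated to the available past
#' and renormalized.
#'
#' @param ts a [trajectory_set()]; smoothing propagates `NA` through any
#'   remaining missing points, so interpolate first.
#' @param kernel_len kernel length in frames (default 5).
#' @param sigma kernel width in frames (default 1).
#' @return a smoothed [trajectory_set()].
#' @export
smooth_causal <- function(ts, kernel_len = 5L, sigma = 1) {
  stopifnot(kernel_len >= 1, sigma > 0)
  w <- causal_kernel(kernel_len, sigma)
  t_n <- n_frames(ts)
  pos <- ts$positions
  for (i in seq_len(n_individuals(ts))) {
    for (k in 1:2) {
      x <- ts$positions[, i, k]
      sm <- as.numeric(stats::filter(x, w, sides = 1))
      head_n <- min(kernel_len - 1L, t_n)
      for (t in seq_len(head_n)) {
        wt <- w[seq_len(t)]
        sm[t] <- sum(wt * x[t:1]) / sum(wt)
      }
      pos[, i, k] <- sm
    }
  }
  trajectory_set(pos, fps = ts$fps, arena_center = ts$arena_center,
                 arena_radius = ts$arena_radius,
                 body_length_px = ts$body_length_px,
                 missing_mask = ts$missing_mask)
}

#' Causal finite-difference kinematics
#'
#' Backward differences using only current and past frames:
#' `v(t) = (x(t) - x(t-1)) * fps` and `a(t) = (v(t) - v(t-1)) * fps`.
#' The first two frames carry no acceleration and are invalidated, as is
#' any frame whose three-frame support touches a missing point.
#'
#' @param ts a smoothed, gap-free [trajectory_set()] in BL units.
#' @return a list of class `"kinematics_set"` with `velocity` and
#'   `acceleration` (`[frames x individuals x 2]`, BL/s and BL/s^2),
#'   `speed` (`[frames x individuals]`), `valid_mask`, `fps`.
#' @export
differentiate <- function(ts) {
  t_n <- n_frames(ts); n <- n_individuals(ts); fps <- ts$fps
  vel <- array(NA_real_, dim = dim(ts$positions))
  acc <- array(NA_real_, dim = dim(ts$positions))
  vel[-1, , ] <- (ts$positions[-1, , , drop = FALSE] -
                  ts$positions[-t_n, , , drop = FALSE]) * fps
  acc[-(1:2), , ] <- (vel[-(1:2), , , drop = FALSE] -
                      vel[-c(1, t_n), , , drop = FALSE]) * fps
  speed <- sqrt(vel[, , 1]^2 + vel[, , 2]^2)
  if (!is.matrix(speed)) speed <- matrix(speed, t_n)
  valid <- is.finite(acc[, , 1]) & is.finite(acc[, , 2]) &
    is.finite(vel[, , 1]) & is.finite(vel[, , 2])
  if (!is.matrix(valid)) valid <- matrix(valid, t_n)
  structure(list(velocity = vel, acceleration = acc, speed = speed,
                 valid_mask = valid, fps = fps),
            class = "kinematics_set")
}

#' Circular-shift shuffle control
#'
#' Destroys genuine social interactions while preserving every
#' single-individual statistic: individual i's trajectory is circularly
#' shifted in time by `(i - 1) * T / N` frames, so one individual is
#' unshifted and all pairwise relative shifts are at least `T / N` frames.
#' For a 10-minute, 100-individual recording at 32 fps this guarantees a
#' minimum nonzero circular shift of 6 s and a mean circular shift of
#' 150 s.
#'
#' @param ts a [trajectory_set()].
#' @return a shuffled [trajectory_set()].
#' @export
shuffle_shift <- function(ts) {
  t_n <- n_frames(ts); n <- n_individuals(ts)
  if (n > t_n) stop("more individuals than frames; cannot shuffle",
                    call. = FALSE)
  offs <- shuffle_offsets(t_n, n)
  pos <- ts$positions
  mask <- ts$missing_mask
  for (i in seq_len(n)) {
    k <- offs[i]
    if (k == 0) next
    ord <- c((t_n - k + 1L):t_n, 1L:(t_n - k))
    pos[, i, ] <- pos[ord, i, ]
    mask[, i] <- mask[ord, i]
  }
  trajectory_set(pos, fps = ts$fps, arena_center = ts$arena_center,
                 arena_radius = ts$arena_radius,
                 body_length_px = ts$body_length_px, missing_mask = mask)
}

#' Shuffle offsets in frames
#'
#' Offsets applied by [shuffle_shift()]: individual i is shifted by
#' `round((i - 1) * T / N)` frames.
#'
#' @param t_n number of frames.
#' @param n number of individuals.
#' @return integer vector of length `n`.
#' @export
shuffle_offsets <- function(t_n, n) {
  as.integer(round((seq_len(n) - 1L) * t_n / n))
}

#' Contiguous train/validation/test frame split
#'
#' Divides `1:t_n` into three contiguous, disjoint blocks. `rotate`
#' selects which part of the recording holds the validation and test
#' blocks: 0 places them at the end, 1 at the start, 2 in the middle of
#' the recording.
#'
#' @param t_n number of frames.
#' @param fractions length-3 fractions summing to 1
#'   (default `c(0.97, 0.02, 0.01)`).
#' @param rotate 0, 1 or 2; see above.
#' @return list with integer frame vectors `train`, `validation`, `test`.
#' @export
split_frames <- function(t_n, fractions = c(0.97, 0.02, 0.01), rotate = 0L) {
  stopifnot(length(fractions) == 3, all(fractions > 0),
            abs(sum(fractions) - 1) < 1e-8)
  n_val <- floor(t_n * fractions[2])
  n_test <- floor(t_n * fractions[3])
  n_train <- t_n - n_val - n_test
  if (n_val < 1 || n_test < 1 || n_train < 1)
    stop("recording too short for the requested split fractions",
         call. = FALSE)
  sizes <- switch(as.character(rotate %% 3L),
    "0" = list(train = n_train, validation = n_val, test = n_test),
    "1" = list(validation = n_val, test = n_test, train = n_train),
    "2" = list(train = n_train %/% 2L, validation = n_val, test = n_test,
               train2 = n_train - n_train %/% 2L))
  out <- list()
  at <- 1L
  for (nm in names(sizes)) {
    block <- seq.int(at, length.out = sizes[[nm]])
    key <- sub("2$", "", nm)
    out[[key]] <- c(out[[key]], block)
    at <- at + sizes[[nm]]
  }
  out[c("train", "validation", "test")]
}
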
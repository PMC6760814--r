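#' Normalize raw aggregation weights
#'
#' @param w vector of positive raw weights `W_i`.
#' @return weights `omega_i = W_i / sum(W)`, positive and summing to 1.
#' @export
normalized_weights <- function(w) {
  if (any(w <= 0)) stop("raw weights must be strictly positive",
                        call. = FALSE)
  w / sum(w)
}

#' Effective number of interacting neighbours
#'
#' The inverse of the typical weight: `N_total = 1 / omega_t =
#' exp(-sum(omega_i log omega_i))`, the perplexity (exponential of the
#' Shannon entropy, natural log) of the normalized weights. It equals the
#' number of neighbours for uniform weights and 1 for a one-hot weight
#' vector.
#'
#' @param omega normalized weights (non-negative, summing to 1);
#'   zero entries contribute `0 log 0 = 0`.
#' @return scalar in `[1, length(omega)]`.
#' @export
n_total <- function(omega) {
  stopifnot(all(omega >= 0), abs(sum(omega) - 1) < 1e-6)
  nz <- omega[omega > 0]
  exp(-sum(nz * log(nz)))
}

#' Number of important neighbours
#'
#' Counts the neighbours whose normalized weight reaches the typical
#' weight `omega_t = 1 / N_total`: with uniform weights every neighbour is
#' exactly typical and all count; with a one-hot vector only one does.
#' `definition = "below-typical"` instead counts the strictly
#' below-typical neighbours.
#'
#' @param omega normalized weights.
#' @param definition `"at-least-typical"` (default) or `"below-typical"`.
#' @return integer count.
#' @export
n_important <- function(omega, definition = c("at-least-typical",
                                              "below-typical")) {
  definition <- match.arg(definition)
  omega_t <- 1 / n_total(omega)
  if (definition == "at-least-typical") sum(omega >= omega_t - 1e-12)
  else sum(omega < omega_t - 1e-12)
}

#' Per-sample neighbour-count series from a trained attention model
#'
#' Applies the attention network to every sample, extracts the normalized
#' weights and computes `N_total` and `N_important` per (frame, focal).
#'
#' @param model a trained attention `fish_model`.
#' @param dataset a `turn_dataset`.
#' @param idx sample indices (default all).
#' @param chunk evaluation chunk size.
#' @return data frame with `frame`, `focal`, `n_total`, `n_important`.
#' @export
neighbour_count_series <- function(model, dataset, idx = NULL,
                                   chunk = 4096L) {
  if (is.null(idx)) idx <- seq_len(dataset$m)
  nt <- numeric(length(idx)); ni <- integer(length(idx))
  for (start in seq(1L, length(idx), by = chunk)) {
    sel <- idx[start:min(start + chunk - 1L, length(idx))]
    om <- attention_logit(model, dataset, sel)$omega
    h <- -colSums(ifelse(om > 0, om * log(om), 0))
    ntc <- exp(h)
    at <- start:(start + length(sel) - 1L)
    nt[at] <- ntc
    ni[at] <- colSums(om >= rep(1 / ntc, each = nrow(om)) - 1e-12)
  }
  data.frame(frame = dataset$frame[idx], focal = dataset$focal[idx],
             n_total = nt, n_important = ni)
}

#' Averaged-periodogram power spectrum
#'
#' Welch-style estimate: the series is cut into segments of `segment`
#' points with 50% overlap, each segment is mean-detrended, and the
#' per-segment periodograms are averaged (no taper). The one-sided
#' spectrum satisfies `sum(power) * df ~ var(series)` for a stationary
#' series.
#'
#' @param series uniformly sampled numeric series.
#' @param fps sampling rate (frames per second of the series).
#' @param segment segment length in points (default 256); when the series
#'   is shorter, a single full-length periodogram is returned with a
#'   warning.
#' @return data frame with `frequency` (Hz, up to `fps / 2`) and `power`.
#' @export
power_spectrum <- function(series, fps, segment = 256L) {
  stopifnot(length(series) >= 8, fps > 0)
  if (length(series) < segment) {
    warning("series shorter than one segment; single periodogram",
            call. = FALSE)
    segment <- length(series)
  }
  segment <- as.integer(segment)
  hop <- max(1L, segment %/% 2L)
  starts <- seq(1L, length(series) - segment + 1L, by = hop)
  nfreq <- segment %/% 2L
  acc <- numeric(nfreq)
  for (s in starts) {
    x <- series[s:(s + segment - 1L)]
    x <- x - mean(x)
    ft <- stats::fft(x)
    p <- (Mod(ft)^2) / (segment * fps)     # two-sided density
    half <- p[2:(nfreq + 1L)]
    half <- 2 * half                       # fold negative frequencies
    if (segment %% 2L == 0L) half[nfreq] <- half[nfreq] / 2  # Nyquist
    acc <- acc + half
  }
  data.frame(frequency = (1:nfreq) * fps / segment,
             power = acc / length(starts))
}
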
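#' Interaction-zone geometry
#'
#' One zone is an annular region in the agent's egocentric frame (origin at
#' the agent, +y along its heading): a point at local coordinates (x, y)
#' belongs to the zone when `inner <= r_eff < outer` with
#' `r_eff = hypot(x, (y - offset) / axis_ratio)`, and when it is not inside
#' the rear blind cone of half-angle `blind` (radians, measured from the
#' backward direction).
#'
#' @param inner,outer radii in BL.
#' @param offset forward displacement of the zone centre in BL.
#' @param axis_ratio fore-aft semi-axis relative to the lateral one
#'   (1 = circular).
#' @param blind rear blind half-angle in radians (0 = full field of view).
#' @return a list describing the zone.
#' @export
zone_spec <- function(inner, outer, offset = 0, axis_ratio = 1, blind = 0) {
  stopifnot(inner >= 0, outer > inner, axis_ratio > 0, blind >= 0,
            blind <= pi)
  list(inner = inner, outer = outer, offset = offset,
       axis_ratio = axis_ratio, blind = blind)
}

#' Zonal-model configuration
#'
#' Parameters of the repulsion/orientation/attraction agent model used to
#' generate ground-truth trajectories: 50 agents moving at a constant
#' 3 BL/s in a circular arena of radius 25 BL; at each 1/32 s step an agent
#' keeps its heading with probability 2/3 and otherwise rotates it toward
#' the zone-determined desired direction -- perturbed by Gaussian
#' directional error of 0.2 rad -- by at most the turning rate of 0.2 rad. Neighbours in the repulsion zone override all
#' others; otherwise the agent aligns with orientation-zone neighbours and
#' is attracted toward attraction-zone neighbours. A finite
#' `topological_cap` restricts candidate neighbours to the cap nearest.
#'
#' Geometry presets (defaults in BL; the repulsion radius is 1, orientation
#' annulus 1-5, attraction annulus 5-10 unless varied):
#' * `"circular"` -- the default concentric zones;
#' * `"large-repulsion"` -- repulsion radius enlarged to 2;
#' * `"displaced"` -- orientation zone displaced 2 BL forward;
#' * `"elliptical"` -- orientation zone elongated fore-aft (axis ratio 2);
#' * `"blind-angle"` -- a rear blind cone of half-angle pi/4 on all zones.
#'
#' @param preset geometry preset name.
#' @param n_agents number of agents (default 50).
#' @param speed constant speed in BL/s (default 3).
#' @param dt time step in s (default 1/32).
#' @param p_keep probability of not updating the heading at a step
#'   (default 2/3).
#' @param turning_rate maximum heading rotation per update event, rad
#'   (default 0.2).
#' @param noise_sd heading noise SD per update event, rad (default 0.2).
#' @param arena_radius arena radius in BL (default 25).
#' @param topological_cap maximum number of nearest neighbours considered
#'   (`Inf` = no cap).
#' @param zones optional list with `repulsion`, `orientation`, `attraction`
#'   [zone_spec()]s overriding the preset.
#' @return a list of class `"zonal_config"`.
#' @export
zonal_config <- function(preset = c("circular", "large-repulsion",
                                    "displaced", "elliptical", "blind-angle"),
                         n_agents = 50L, speed = 3, dt = 1 / 32,
                         p_keep = 2 / 3, turning_rate = 0.2, noise_sd = 0.2,
                         arena_radius = 25, topological_cap = Inf,
                         zones = NULL) {
  preset <- match.arg(preset)
  stopifnot(n_agents >= 1, speed > 0, dt > 0, p_keep >= 0, p_keep <= 1,
            turning_rate >= 0, noise_sd >= 0, arena_radius > 0,
            topological_cap >= 1)
  if (is.null(zones)) {
    zones <- switch(preset,
      "circular" = list(repulsion = zone_spec(0, 1),
                        orientation = zone_spec(1, 5),
                        attraction = zone_spec(5, 10)),
      "large-repulsion" = list(repulsion = zone_spec(0, 2),
                               orientation = zone_spec(2, 5),
                               attraction = zone_spec(5, 10)),
      "displaced" = list(repulsion = zone_spec(0, 1),
                         orientation = zone_spec(1, 5, offset = 2),
                         attraction = zone_spec(5, 10)),
      "elliptical" = list(repulsion = zone_spec(0, 1),
                          orientation = zone_spec(1, 5, axis_ratio = 2),
                          attraction = zone_spec(5, 10)),
      "blind-angle" = list(repulsion = zone_spec(0, 1, blind = pi / 4),
                           orientation = zone_spec(1, 5, blind = pi / 4),
                           attraction = zone_spec(5, 10, blind = pi / 4)))
  }
  stopifnot(setequal(names(zones), c("repulsion", "orientation",
                                     "attraction")))
  structure(list(preset = preset, n_agents = as.integer(n_agents),
                 speed = speed, dt = dt, p_keep = p_keep,
                 turning_rate = turning_rate, noise_sd = noise_sd,
                 arena_radius = arena_radius,
                 topological_cap = topological_cap, zones = zones),
            class = "zonal_config")
}

wrap_pi <- function(a) atan2(sin(a), cos(a))

# zone membership in the agent frame; x right, y forward
in_zone <- function(x, y, zone) {
  r_eff <- sqrt(x^2 + ((y - zone$offset) / zone$axis_ratio)^2)
  inside <- r_eff >= zone$inner & r_eff < zone$outer
  if (zone$blind > 0) {
    bearing <- atan2(x, y)  # 0 = ahead, +-pi = behind
    inside <- inside & abs(bearing) <= pi - zone$blind
  }
  inside
}

# desired directions and ground-truth neighbour sets for all agents.
# Returns desired heading components (unnormalized; zero when no neighbour
# drives the decision), ground-truth counts and repulsion flags.
zonal_decisions <- function(positions, headings, config) {
  n <- nrow(positions)
  dxm <- matrix(positions[, 1], n, n, byrow = TRUE) - positions[, 1]
  dym <- matrix(positions[, 2], n, n, byrow = TRUE) - positions[, 2]
  dist <- sqrt(dxm^2 + dym^2)
  diag(dist) <- Inf
  candidate <- matrix(TRUE, n, n)
  diag(candidate) <- FALSE
  if (is.finite(config$topological_cap) && config$topological_cap < n - 1) {
    rk <- t(apply(dist, 1L, rank, ties.method = "first"))
    candidate <- candidate & rk <= config$topological_cap
  }
  cs <- cos(headings); sn <- sin(headings)
  # local frame of agent i (rows): x right, y forward
  xl <- dxm * sn - dym * cs
  yl <- dxm * cs + dym * sn
  memb <- lapply(config$zones, function(z) candidate & in_zone(xl, yl, z))
  with_unit <- dist > 0
  ux <- ifelse(with_unit, dxm / dist, 0)
  uy <- ifelse(with_unit, dym / dist, 0)
  rep_count <- rowSums(memb$repulsion)
  rep_x <- -rowSums(ux * memb$repulsion)
  rep_y <- -rowSums(uy * memb$repulsion)
  ori_x <- memb$orientation %*% cs
  ori_y <- memb$orientation %*% sn
  att_x <- rowSums(ux * memb$attraction)
  att_y <- rowSums(uy * memb$attraction)
  use_rep <- rep_count > 0
  des_x <- ifelse(use_rep, rep_x, ori_x + att_x)
  des_y <- ifelse(use_rep, rep_y, ori_y + att_y)
  count <- ifelse(use_rep, rep_count,
                  rowSums(memb$orientation | memb$attraction))
  list(des_x = des_x, des_y = des_y, count = as.integer(count),
       repulsion_flag = use_rep)
}

#' Desired direction of a single agent under the zonal rules
#'
#' Exposes the decision rule for inspection: if any neighbour occupies the
#' repulsion zone, the desired direction is the negative sum of unit
#' vectors toward those neighbours and everything else is ignored;
#' otherwise it is the normalized sum of orientation-zone neighbours' unit
#' headings and of unit vectors toward attraction-zone neighbours; with no
#' zone neighbour the agent keeps its heading.
#'
#' @param agent agent index.
#' @param positions `[n x 2]` agent positions (BL).
#' @param headings agent headings (rad, world frame).
#' @param config a [zonal_config()].
#' @return list with `heading` (desired heading, rad) and `count`
#'   (ground-truth interacting-neighbour count) and `repulsion_flag`.
#' @export
desired_direction <- function(agent, positions, headings, config) {
  dec <- zonal_decisions(positions, headings, config)
  nrm <- sqrt(dec$des_x[agent]^2 + dec$des_y[agent]^2)
  heading <- if (nrm < 1e-12) headings[agent]
             else atan2(dec$des_y[agent], dec$des_x[agent])
  list(heading = heading, count = dec$count[agent],
       repulsion_flag = dec$repulsion_flag[agent])
}

# one simulation step; returns the new state plus the per-agent ground
# truth evaluated at the *current* frame
step_zonal <- function(positions, headings, config) {
  n <- config$n_agents
  dec <- zonal_decisions(positions, headings, config)
  update <- stats::runif(n) >= config$p_keep
  nrm <- sqrt(dec$des_x^2 + dec$des_y^2)
  target <- ifelse(nrm < 1e-12, headings, atan2(dec$des_y, dec$des_x))
  # directional error perturbs the desired direction; the realized turn is
  # then clamped to the turning rate, so |heading change| <= turning_rate
  noisy <- target + stats::rnorm(n, sd = config$noise_sd)
  delta <- pmin(pmax(wrap_pi(noisy - headings), -config$turning_rate),
                config$turning_rate)
  headings <- ifelse(update, headings + delta, headings)
  positions <- positions + config$speed * config$dt *
    cbind(cos(headings), sin(headings))
  r <- sqrt(rowSums(positions^2))
  out <- r > config$arena_radius
  if (any(out)) {
    nx <- positions[out, 1] / r[out]
    ny <- positions[out, 2] / r[out]
    vx <- cos(headings[out]); vy <- sin(headings[out])
    vn <- vx * nx + vy * ny
    headings[out] <- atan2(vy - 2 * vn * ny, vx - 2 * vn * nx)
    positions[out, 1] <- nx * config$arena_radius
    positions[out, 2] <- ny * config$arena_radius
  }
  list(positions = positions, headings = wrap_pi(headings),
       count = dec$count, repulsion_flag = dec$repulsion_flag)
}

#' Simulate zonal-model trajectories with ground truth
#'
#' Runs the agent-based model for `duration` seconds (after discarding a
#' `burn_in` transient) and returns the trajectories in the standard
#' container, with per-frame ground-truth interacting-neighbour counts.
#' Deterministic given `seed`.
#'
#' @param config a [zonal_config()].
#' @param duration recorded duration in seconds.
#' @param seed integer seed.
#' @param burn_in discarded initial transient in seconds (default 10).
#' @return list with `ts` (a [trajectory_set()], fps = 1/dt, positions in
#'   BL centred on the arena), `counts` (integer `[frames x agents]`
#'   ground-truth interacting-neighbour counts) and `repulsion_flag`
#'   (logical, same shape: decision driven by the repulsion override).
#' @export
simulate_zonal <- function(config, duration, seed = 1L, burn_in = 10) {
  stopifnot(inherits(config, "zonal_config"), duration > 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- config$n_agents
  n_rec <- round(duration / config$dt)
  n_burn <- round(burn_in / config$dt)
  r0 <- config$arena_radius * 0.9 * sqrt(stats::runif(n))
  a0 <- stats::runif(n, 0, 2 * pi)
  positions <- cbind(r0 * cos(a0), r0 * sin(a0))
  headings <- stats::runif(n, -pi, pi)
  pos_out <- array(NA_real_, dim = c(n_rec, n, 2))
  counts <- matrix(NA_integer_, n_rec, n)
  repflag <- matrix(NA, n_rec, n)
  for (t in seq_len(n_burn + n_rec)) {
    st <- step_zonal(positions, headings, config)
    if (t > n_burn) {
      k <- t - n_burn
      pos_out[k, , ] <- positions  # positions at the decision frame
      counts[k, ] <- st$count
      repflag[k, ] <- st$repulsion_flag
    }
    positions <- st$positions
    headings <- st$headings
  }
  ts <- trajectory_set(pos_out, fps = 1 / config$dt, arena_center = c(0, 0),
                       arena_radius = config$arena_radius)
  list(ts = ts, counts = counts, repulsion_flag = repflag, config = config,
       seed = as.integer(seed))
}

#' True interaction zone of a point in the agent frame
#'
#' Classifies egocentric coordinates against a configuration's geometry,
#' honouring the repulsion-first precedence and blind cones.
#'
#' @param x,y egocentric coordinates in BL (recyclable vectors).
#' @param config a [zonal_config()].
#' @return character vector: `"repulsion"`, `"orientation"`,
#'   `"attraction"` or `NA` (outside every zone or inside a blind cone).
#' @export
true_zone <- function(x, y, config) {
  out <- rep(NA_character_, length(x))
  for (nm in c("attraction", "orientation", "repulsion"))
    out[in_zone(x, y, config$zones[[nm]])] <- nm
  out
}
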
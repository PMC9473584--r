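# Coarse-grained slab simulation of sticker-spacer chains plus ATP.
#
# Bead types are coded 0 = neutral spacer, 1 = Tyr, 2 = Arg, 3 = ATP.
# Lengths in nm, energies in the CG unit eps0, mass = 1, friction and
# temperature in reduced units (see the methods vignette for the
# nominal mapping to the full-scale run).

#' Coarse-grained force field
#'
#' Three potentials: a harmonic bond `k (r - r_b)^2`, a smooth cosine
#' sticker attraction `U0 (1 + cos(pi r / r0))` for r < r0 (Tyr-Arg
#' depth `U0_YR`, ATP-Arg depth `U0_AR`), and a softened, truncated
#' Lennard-Jones repulsion
#' `4 eps lambda * (((1-lambda)^2 + (r/sigma)^6)^-2 - ((1-lambda)^2 +
#' (r/sigma)^6)^-1)` for r < r_c, shifted so it vanishes at the
#' cutoff.  The repulsion acts between beads of the same type only --
#' it exists to prevent same-type aggregation, and its range (sigma =
#' 3.5 nm) exceeds the sticker attraction range (2 nm), so a
#' cross-type repulsion would suppress sticker binding altogether.
#' Bonded neighbours feel only the spring.
#'
#' @param r_b mean bond length (nm).
#' @param k_bond bond stiffness (eps0/nm^2); default `20/r_b^2`.
#' @param r0 sticker attraction range (nm).
#' @param U0_YR,U0_AR Tyr-Arg and ATP-Arg attraction depths (eps0).
#' @param lambda_lj softening parameter of the repulsion.
#' @param sigma repulsion length scale (nm).
#' @param r_c repulsion cutoff (nm).
#' @param eps_Y,eps_R,eps_N,eps_ATP per-type repulsion strengths
#'   (eps0): reference values for Tyr and Arg; spacers default to
#'   phantom (0 -- a spacer-spacer repulsion of sticker magnitude
#'   overwhelms the sparse sticker attraction and dissolves the slab);
#'   ATP-ATP defaults to the Tyr value to keep ATP from clumping.
#' @return A list of class `cg_forcefield`.
#' @export
cg_forcefield <- function(r_b = 4.5, k_bond = 20 / r_b^2, r0 = 2.0,
                          U0_YR = -20, U0_AR = -75, lambda_lj = 0.68,
                          sigma = 3.5, r_c = 5.0,
                          eps_Y = 0.621, eps_R = 0.15,
                          eps_N = 0, eps_ATP = 0.621) {
  stopifnot(r_b > 0, r0 > 0, sigma > 0, r_c > 0)
  structure(list(r_b = r_b, k_bond = k_bond, r0 = r0,
                 U0_YR = U0_YR, U0_AR = U0_AR, lambda_lj = lambda_lj,
                 sigma = sigma, r_c = r_c,
                 eps_type = c(eps_N, eps_Y, eps_R, eps_ATP)),
            class = "cg_forcefield")
}

#' Pair energy and radial force
#'
#' Reference R implementation of the three CG potentials, used both as
#' user-facing API and as the oracle the compiled force loop is tested
#' against.  The radial force is `-dU/dr` (positive = repulsive).
#'
#' @param kind `"bond"`, `"sticker_attraction"` or `"soft_repulsion"`.
#' @param r distance (nm), scalar or vector.
#' @param ff a [cg_forcefield()].
#' @param U0 attraction depth for `"sticker_attraction"` (defaults to
#'   the Tyr-Arg depth).
#' @param eps repulsion strength for `"soft_repulsion"` (defaults to
#'   the Tyr value).
#' @return A list with vectors `energy` and `force`.
#' @export
pair_energy_force <- function(kind = c("bond", "sticker_attraction",
                                       "soft_repulsion"),
                              r, ff = cg_forcefield(),
                              U0 = ff$U0_YR, eps = ff$eps_type[2]) {
  kind <- match.arg(kind)
  stopifnot(all(r >= 0))
  switch(kind,
    bond = {
      dr <- r - ff$r_b
      list(energy = ff$k_bond * dr^2, force = -2 * ff$k_bond * dr)
    },
    sticker_attraction = {
      inside <- r < ff$r0
      e <- ifelse(inside, U0 * (1 + cos(pi * r / ff$r0)), 0)
      f <- ifelse(inside, U0 * (pi / ff$r0) * sin(pi * r / ff$r0), 0)
      list(energy = e, force = f)
    },
    soft_repulsion = {
      A <- (1 - ff$lambda_lj)^2
      rep_raw <- function(x) {
        d <- A + (x / ff$sigma)^6
        4 * ff$lambda_lj * (d^-2 - d^-1)
      }
      shift <- rep_raw(ff$r_c)
      inside <- r < ff$r_c
      d <- A + (r / ff$sigma)^6
      e <- ifelse(inside, eps * (4 * ff$lambda_lj * (d^-2 - d^-1) - shift), 0)
      ds6dr <- ifelse(r > 0, 6 * (r / ff$sigma)^6 / r, 0)
      f <- ifelse(inside,
                  -eps * 4 * ff$lambda_lj * (-2 * d^-3 + d^-2) * ds6dr, 0)
      list(energy = e, force = f)
    })
}

#' Build a slab initial configuration
#'
#' Chains are grown as fixed-bond-length random walks starting inside a
#' central slab of the elongated box (so both phases and their
#' interface are sampled once the dynamics equilibrate); ATP beads are
#' scattered uniformly over the whole box.  Deterministic for a given
#' seed.
#'
#' @param config list with any of: `n_chains` (default 50),
#'   `chain_length` (default 50 beads), `sticker_fraction` (per-type,
#'   default 0.06), `sticker_placement` (`"random"` or `"even"`),
#'   `n_atp` (default 0), `box` (nm, default `c(50, 50, 250)`),
#'   `slab_fraction` (fraction of the long axis initially occupied,
#'   default 0.3).
#' @param seed integer seed.
#' @param ff a [cg_forcefield()].
#' @return A list of class `cg_system`: `coords` (N x 3), `type`,
#'   `chain_id`, `box`, `ff`, `config`.
#' @export
build_slab_system <- function(config = list(), seed = 1,
                              ff = cg_forcefield()) {
  cfg <- utils::modifyList(
    list(n_chains = 50, chain_length = 50, sticker_fraction = 0.06,
         sticker_placement = "random", n_atp = 0,
         box = c(50, 50, 250), slab_fraction = 0.3), config)
  stopifnot(cfg$n_chains >= 1, cfg$chain_length >= 2,
            length(cfg$box) == 3, all(cfg$box > 0))
  n_st <- round(cfg$sticker_fraction * cfg$chain_length)
  if (2 * n_st > cfg$chain_length)
    stop("sticker fraction infeasible for this chain length")
  if (cfg$n_chains * cfg$chain_length * ff$r_b^3 * 0.1 >
      prod(cfg$box))
    stop("density too high to place chains")
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()),
          add = TRUE)
  set.seed(seed)
  Lz <- cfg$box[3]
  half <- cfg$slab_fraction * Lz / 2
  n_beads <- cfg$n_chains * cfg$chain_length + cfg$n_atp
  coords <- matrix(0, n_beads, 3)
  type <- integer(n_beads)
  chain_id <- integer(n_beads)
  idx <- 1
  for (ch in seq_len(cfg$n_chains)) {
    pos <- c(runif(1, 0, cfg$box[1]), runif(1, 0, cfg$box[2]),
             runif(1, Lz / 2 - half, Lz / 2 + half))
    sticker_pos <- if (cfg$sticker_placement == "even") {
      round(seq(1, cfg$chain_length, length.out = 2 * n_st))
    } else {
      sort(sample.int(cfg$chain_length, 2 * n_st))
    }
    ty <- integer(cfg$chain_length)
    if (n_st > 0) {
      lab <- sample(rep(1:2, n_st))  # interleave Tyr/Arg assignments
      ty[sticker_pos] <- lab
    }
    for (b in seq_len(cfg$chain_length)) {
      if (b > 1) {
        u <- rnorm(3)
        step <- ff$r_b * u / sqrt(sum(u^2))
        pos <- pos + step
        # keep the walk near the slab along z
        if (abs(pos[3] - Lz / 2) > half)
          pos[3] <- pos[3] - 2 * step[3]
      }
      coords[idx, ] <- pos
      type[idx] <- ty[b]
      chain_id[idx] <- ch
      idx <- idx + 1
    }
  }
  if (cfg$n_atp > 0) {
    for (a in seq_len(cfg$n_atp)) {
      coords[idx, ] <- runif(3) * cfg$box
      type[idx] <- 3L
      chain_id[idx] <- cfg$n_chains + a  # each ATP is its own molecule
      idx <- idx + 1
    }
  }
  structure(list(coords = coords, type = type, chain_id = chain_id,
                 box = cfg$box, ff = ff, config = cfg),
            class = "cg_system")
}

#' Run Langevin dynamics on a CG system
#'
#' BAOAB integration in the NVT ensemble with a Langevin thermostat and
#' minimum-image periodic boundaries.  Fully reproducible for a given
#' seed.
#'
#' @param system a [build_slab_system()] result.
#' @param n_steps number of time steps.
#' @param dt time step (reduced units).
#' @param temperature thermostat kT in eps0.
#' @param friction Langevin friction (1/reduced time).
#' @param mass bead mass (reduced).
#' @param seed integer seed for the thermostat noise.
#' @param sample_every store a frame every this many steps.
#' @return A list of class `cg_trajectory` with `times`, `frames`
#'   (list of N x 3 coordinate matrices, unwrapped), `energies`,
#'   `type`, `chain_id`, `box`, `ff` and the run settings.
#' @export
run_langevin <- function(system, n_steps = 2000, dt = 0.02,
                         temperature = 1, friction = 1, mass = 1,
                         seed = 1, sample_every = 20) {
  stopifnot(inherits(system, "cg_system"), n_steps >= 1, dt > 0)
  out <- cg_run_langevin(system$coords, system$type, system$chain_id,
                         system$box, unclass(system$ff),
                         as.integer(n_steps), dt, temperature, friction,
                         mass, as.integer(seed), as.integer(sample_every))
  structure(list(times = out$times, frames = out$frames,
                 energies = out$energies, type = system$type,
                 chain_id = system$chain_id, box = system$box,
                 ff = system$ff,
                 settings = list(n_steps = n_steps, dt = dt,
                                 temperature = temperature,
                                 friction = friction, mass = mass,
                                 seed = seed,
                                 sample_every = sample_every)),
            class = "cg_trajectory")
}

#' Total potential energy of a configuration
#'
#' @param system a `cg_system`, or a `cg_trajectory` together with a
#'   frame index through `frame`.
#' @param coords optional explicit N x 3 coordinate matrix overriding
#'   the system coordinates.
#' @param frame frame index when `system` is a trajectory.
#' @return Potential energy in eps0.
#' @export
cg_energy <- function(system, coords = NULL, frame = NULL) {
  if (inherits(system, "cg_trajectory")) {
    coords <- system$frames[[if (is.null(frame)) length(system$frames) else frame]]
    return(cg_total_energy(coords, system$type, system$chain_id,
                           system$box, unclass(system$ff)))
  }
  stopifnot(inherits(system, "cg_system"))
  if (is.null(coords)) coords <- system$coords
  cg_total_energy(coords, system$type, system$chain_id, system$box,
                  unclass(system$ff))
}

# wrap values into [0, L)
.wrap <- function(x, L) x - L * floor(x / L)

# circular mean of positions on [0, L)
.circ_center <- function(z, L) {
  th <- 2 * pi * z / L
  ang <- atan2(mean(sin(th)), mean(cos(th)))
  .wrap(ang * L / (2 * pi), L)
}

#' Density profile along the slab axis
#'
#' Time-averaged bead density along the long axis.  Each retained frame
#' is recentred so the condensate (circular mean of all bead positions)
#' sits at the box centre, removing slab drift.  The condensate bounds
#' are where the smoothed profile exceeds half its plateau (maximum)
#' value.
#'
#' @param traj a `cg_trajectory`.
#' @param axis axis index (3 = the long axis of the default box).
#' @param n_bins number of histogram bins.
#' @param discard_frac fraction of initial frames dropped as
#'   equilibration.
#' @param min_contrast error out when the peak density is below this
#'   multiple of the mean (no condensate present).
#' @return A list of class `cg_density_profile` with `z` (bin
#'   centres), `density` (beads/nm^3), `bounds` (condensate interval
#'   on the recentred axis), `dense_density`, `dilute_density`, and
#'   `shifts` (per-frame recentring offsets).
#' @export
density_profile <- function(traj, axis = 3, n_bins = 60,
                            discard_frac = 0.3, min_contrast = 2) {
  stopifnot(inherits(traj, "cg_trajectory"))
  nf <- length(traj$frames)
  keep <- seq.int(max(1, floor(discard_frac * nf) + 1), nf)
  if (length(keep) < 2) stop("too few frames after equilibration discard")
  L <- traj$box[axis]
  edges <- seq(0, L, length.out = n_bins + 1)
  counts <- numeric(n_bins)
  shifts <- numeric(nf)
  for (i in keep) {
    z <- .wrap(traj$frames[[i]][, axis], L)
    ctr <- .circ_center(z, L)
    shifts[i] <- L / 2 - ctr
    z <- .wrap(z + shifts[i], L)
    counts <- counts + tabulate(pmin(n_bins, floor(z / L * n_bins) + 1),
                                n_bins)
  }
  bin_vol <- prod(traj$box[-axis]) * L / n_bins
  dens <- counts / (length(keep) * bin_vol)
  # light smoothing for the plateau estimate
  sm <- stats::filter(c(dens[n_bins], dens, dens[1]), rep(1 / 3, 3))[2:(n_bins + 1)]
  sm <- as.numeric(sm)
  peak <- max(sm)
  if (peak < min_contrast * mean(dens))
    stop("no dense region detected: density profile is uniform")
  thr <- peak / 2
  above <- sm >= thr
  # contiguous region containing the peak (profile is recentred)
  i0 <- which.max(sm)
  lo <- i0; while (lo > 1 && above[lo - 1]) lo <- lo - 1
  hi <- i0; while (hi < n_bins && above[hi + 1]) hi <- hi + 1
  mid <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  inside <- seq(lo, hi)
  structure(list(z = mid, density = dens,
                 bounds = c(edges[lo], edges[hi + 1]),
                 dense_density = mean(dens[inside]),
                 dilute_density = if (length(inside) < n_bins)
                   mean(dens[-inside]) else NA_real_,
                 shifts = shifts, axis = axis, frames_used = keep),
            class = "cg_density_profile")
}

#' Chain exchange statistics between condensate and dilute phase
#'
#' A chain is "inside" when at least half of its beads lie within the
#' condensate bounds.  State changes are debounced: a transition counts
#' as an exchange event only when the new state persists for at least
#' `dwell` sampled frames, and the bounds are widened/narrowed by
#' `hysteresis` nm depending on the current state to suppress boundary
#' flicker.
#'
#' @param traj a `cg_trajectory` (protein chains only are analysed;
#'   ATP beads are ignored).
#' @param bounds condensate interval along the axis; defaults to the
#'   [density_profile()] bounds (with its per-frame recentring).
#' @param profile optional precomputed [density_profile()].
#' @param axis slab axis.
#' @param dwell debounce length in frames.
#' @param hysteresis boundary hysteresis (nm).
#' @return A list with `total_events`, `n_exchanged_chains`,
#'   `events_per_chain`, and the `inside` state matrix
#'   (frames x chains).
#' @export
exchange_statistics <- function(traj, bounds = NULL, profile = NULL,
                                axis = 3, dwell = 5, hysteresis = 1) {
  stopifnot(inherits(traj, "cg_trajectory"))
  L <- traj$box[axis]
  shifts <- NULL
  if (is.null(bounds)) {
    if (is.null(profile)) profile <- density_profile(traj, axis = axis)
    bounds <- profile$bounds
    shifts <- profile$shifts
    frames_used <- profile$frames_used
  } else {
    frames_used <- seq_along(traj$frames)
  }
  chains <- sort(unique(traj$chain_id[traj$type != 3L]))
  n_ch <- length(chains)
  inside <- matrix(NA, length(frames_used), n_ch)
  for (fi in seq_along(frames_used)) {
    fr <- frames_used[fi]
    z <- .wrap(traj$frames[[fr]][, axis] +
                 if (is.null(shifts)) 0 else shifts[fr], L)
    for (ci in seq_len(n_ch)) {
      zb <- z[traj$chain_id == chains[ci] & traj$type != 3L]
      frac_in <- mean(zb >= bounds[1] & zb <= bounds[2])
      frac_in_wide <- mean(zb >= bounds[1] - hysteresis &
                             zb <= bounds[2] + hysteresis)
      prev <- if (fi == 1) NA else inside[fi - 1, ci]
      inside[fi, ci] <- if (isTRUE(prev)) frac_in_wide >= 0.5
                        else frac_in >= 0.5
    }
  }
  events_per_chain <- integer(n_ch)
  for (ci in seq_len(n_ch)) {
    s <- inside[, ci]
    state <- s[1]
    run <- rle(s)
    # committed state changes: runs of the new state lasting >= dwell
    if (length(run$lengths) > 1) {
      cur <- run$values[1]
      for (k in 2:length(run$lengths)) {
        if (run$values[k] != cur && run$lengths[k] >= dwell) {
          events_per_chain[ci] <- events_per_chain[ci] + 1L
          cur <- run$values[k]
        }
      }
    }
  }
  list(total_events = sum(events_per_chain),
       n_exchanged_chains = sum(events_per_chain > 0),
       events_per_chain = stats::setNames(events_per_chain,
                                          paste0("chain", chains)),
       inside = inside)
}

#' Write a trajectory in XYZ format with a JSON sidecar
#'
#' @param traj a `cg_trajectory`.
#' @param path output `.xyz` path; the sidecar is written next to it
#'   with extension `.json`.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path) {
  stopifnot(inherits(traj, "cg_trajectory"))
  lab <- c("N", "Y", "R", "A")[traj$type + 1]
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(traj$frames)) {
    writeLines(c(as.character(length(lab)),
                 sprintf("t= %g", traj$times[i])), con)
    fr <- traj$frames[[i]]
    writeLines(sprintf("%s %.6f %.6f %.6f", lab, fr[, 1], fr[, 2],
                       fr[, 3]), con)
  }
  sidecar <- sub("\\.xyz$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    list(box = traj$box, types = traj$type, chain_id = traj$chain_id,
         forcefield = unclass(traj$ff), settings = traj$settings),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
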
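#' Pore trajectory container
#'
#' Per-frame ion (and optionally water) coordinates around a channel pore,
#' together with the landmark positions that define the analysis geometry
#' (selectivity-filter backbone-oxygen centers and residue centers-of-mass
#' along the pore axis) and optional per-frame opposing-chain minimum
#' distances.
#'
#' @param ions Data frame with columns `frame`, `time_ps`, `id`, `x`, `y`,
#'   `z` (Angstrom).
#' @param landmarks Data frame with columns `name`, `x`, `y`, `z`. Expected
#'   names include `T143`, `G145`, `Y146`, `G147` (SF backbone-O centers),
#'   `T143sc`, and residue centers `D173`, `I177`, `M181`, `M302`, `M308`.
#' @param waters Optional data frame like `ions`.
#' @param chain_min_distances Optional data frame with columns `frame`,
#'   `residue`, `pair` (`"1-3"` or `"2-4"`), `dist` (Angstrom).
#' @param box_length_z Periodic box length along the pore axis, Angstrom.
#' @param event_log Optional generator ground-truth conduction events
#'   (data frame `ion`, `frame`, `time_ps`).
#' @return Object of class `pore_trajectory`.
#' @export
pore_trajectory <- function(ions, landmarks, waters = NULL,
                            chain_min_distances = NULL, box_length_z,
                            event_log = NULL) {
  need <- c("frame", "time_ps", "id", "x", "y", "z")
  if (!all(need %in% names(ions))) {
    stop("'ions' needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!all(c("name", "x", "y", "z") %in% names(landmarks))) {
    stop("'landmarks' needs columns name, x, y, z", call. = FALSE)
  }
  tms <- unique(ions[order(ions$frame), c("frame", "time_ps")])
  if (anyDuplicated(tms$frame) || any(diff(tms$time_ps) <= 0)) {
    stop("frame times must be strictly increasing", call. = FALSE)
  }
  gz <- function(n) landmarks$z[match(n, landmarks$name)]
  if (all(c("T143", "I177", "M302") %in% landmarks$name)) {
    if (!(gz("T143") > gz("I177") && gz("I177") > gz("M302"))) {
      stop("landmark ordering inconsistent with the pore axis ",
           "(need SF above HBC above G-loop in z)", call. = FALSE)
    }
  }
  structure(list(ions = ions, waters = waters, landmarks = landmarks,
                 chain_min_distances = chain_min_distances,
                 box_length_z = box_length_z, frames = tms,
                 event_log = event_log),
            class = "pore_trajectory")
}

#' @export
print.pore_trajectory <- function(x, ...) {
  cat(sprintf("pore_trajectory: %d frames, %d ion records%s, box_z %.1f A\n",
              nrow(x$frames), nrow(x$ions),
              if (!is.null(x$waters)) sprintf(", %d water records",
                                              nrow(x$waters)) else "",
              x$box_length_z))
  invisible(x)
}

landmark_xyz <- function(traj, name) {
  i <- match(name, traj$landmarks$name)
  if (is.na(i)) stop("landmark '", name, "' not present", call. = FALSE)
  unlist(traj$landmarks[i, c("x", "y", "z")])
}

## minimal-image z relative to a reference, in [-L/2, L/2)
rel_z <- function(z, z_ref, L) {
  ((z - z_ref + L / 2) %% L) - L / 2
}

#' Cylinder selection of pore species in one frame
#'
#' Selects particle ids whose radial distance from the vertical axis through
#' a landmark is at most `radius` and whose axial offset from the landmark
#' is at most `height / 2`. Defaults follow the analysis geometry: a
#' 110 Angstrom tall cylinder centered on the M181 center-of-mass, radius
#' 25 Angstrom for K+ and 10 Angstrom for water.
#'
#' @param traj A [pore_trajectory()].
#' @param frame Frame number.
#' @param center_landmark Landmark name (default `"M181"`).
#' @param radius Cylinder radius, Angstrom (default 25 for ions, 10 for
#'   water).
#' @param height Cylinder height, Angstrom (default 110).
#' @param species `"ion"` or `"water"`.
#' @return Vector of selected particle ids.
#' @export
cylinder_select <- function(traj, frame, center_landmark = "M181",
                            radius = if (species == "ion") 25 else 10,
                            height = 110, species = c("ion", "water")) {
  species <- match.arg(species)
  stopifnot(inherits(traj, "pore_trajectory"))
  if (radius <= 0 || height <= 0) {
    stop("'radius' and 'height' must be > 0", call. = FALSE)
  }
  ctr <- landmark_xyz(traj, center_landmark)
  tab <- if (species == "ion") traj$ions else traj$waters
  if (is.null(tab)) stop("trajectory has no ", species, " records",
                         call. = FALSE)
  f <- tab[tab$frame == frame, ]
  r <- sqrt((f$x - ctr["x"])^2 + (f$y - ctr["y"])^2)
  dz <- abs(rel_z(f$z, ctr["z"], traj$box_length_z))
  f$id[r <= radius & dz <= height / 2]
}

#' Selectivity-filter cylinder selection
#'
#' Ids within the narrow selectivity-filter cylinder: radius 2.5 Angstrom,
#' spanning in z from the T143 to the Y146 backbone-oxygen centers.
#'
#' @param traj A [pore_trajectory()].
#' @param frame Frame number.
#' @param radius Cylinder radius, Angstrom.
#' @param species `"ion"` or `"water"`.
#' @return Vector of selected particle ids.
#' @export
sf_cylinder_select <- function(traj, frame, radius = 2.5,
                               species = c("ion", "water")) {
  species <- match.arg(species)
  stopifnot(inherits(traj, "pore_trajectory"))
  lo <- landmark_xyz(traj, "T143")
  hi <- landmark_xyz(traj, "Y146")
  if (hi["z"] <= lo["z"]) {
    stop("selectivity-filter landmarks are inverted (Y146 must lie above T143)",
         call. = FALSE)
  }
  tab <- if (species == "ion") traj$ions else traj$waters
  if (is.null(tab)) stop("trajectory has no ", species, " records",
                         call. = FALSE)
  f <- tab[tab$frame == frame, ]
  ax <- (lo[c("x", "y")] + hi[c("x", "y")]) / 2
  r <- sqrt((f$x - ax["x"])^2 + (f$y - ax["y"])^2)
  f$id[r <= radius & f$z >= lo["z"] & f$z <= hi["z"]]
}

#' Count selectivity-filter conduction events
#'
#' A conduction event is recorded at the first frame at which an ion that
#' previously occupied the selectivity filter appears above the S1 exit
#' plane (extracellular side). An ion can contribute another event only
#' after re-entering from the intracellular side (below the filter).
#' Coordinates are reduced modulo the periodic box around the pore center
#' before tracking, so boundary wraps do not create spurious crossings.
#'
#' @param traj A [pore_trajectory()].
#' @param exit_landmark Landmark defining the S1 exit plane (default
#'   `"G147"`, the outermost backbone-oxygen center; a convention — the
#'   plane is configurable).
#' @param sf_radius Selectivity-filter cylinder radius, Angstrom.
#' @return Object of class `conduction_report`: `event_count`,
#'   `event_times` (ps), `rate_per_us`, `per_ion` (events per ion id).
#' @export
count_conduction_events <- function(traj, exit_landmark = "G147",
                                    sf_radius = 2.5) {
  stopifnot(inherits(traj, "pore_trajectory"))
  if (nrow(traj$frames) < 2L) stop("need >= 2 frames", call. = FALSE)
  L <- traj$box_length_z
  ctr <- landmark_xyz(traj, "M181")
  z_exit <- rel_z(landmark_xyz(traj, exit_landmark)["z"], ctr["z"], L)
  lo <- landmark_xyz(traj, "T143"); hi <- landmark_xyz(traj, "Y146")
  z_sf_lo <- rel_z(lo["z"], ctr["z"], L)
  z_sf_hi <- rel_z(hi["z"], ctr["z"], L)
  ax <- (lo[c("x", "y")] + hi[c("x", "y")]) / 2

  ions <- traj$ions[order(traj$ions$id, traj$ions$frame), ]
  zr <- rel_z(ions$z, ctr["z"], L)
  rr <- sqrt((ions$x - ax["x"])^2 + (ions$y - ax["y"])^2)
  in_sf <- rr <= sf_radius & zr >= z_sf_lo & zr <= z_sf_hi
  below <- zr < z_sf_lo
  above_exit <- zr > z_exit

  ev_time <- numeric(0)
  ev_ion <- numeric(0)
  for (sub in split(seq_len(nrow(ions)), ions$id)) {
    armed <- FALSE   # has been below the filter
    primed <- FALSE  # has occupied the filter since last arming
    for (i in sub) {
      if (primed && above_exit[i]) {
        ev_time <- c(ev_time, ions$time_ps[i])
        ev_ion <- c(ev_ion, ions$id[i])
        armed <- FALSE; primed <- FALSE
      }
      if (below[i]) { armed <- TRUE; primed <- FALSE }
      if (armed && in_sf[i]) primed <- TRUE
    }
  }
  dur_us <- diff(range(traj$frames$time_ps)) / 1e6
  ord <- order(ev_time)
  structure(list(event_count = length(ev_time),
                 event_times = ev_time[ord],
                 rate_per_us = length(ev_time) / dur_us,
                 per_ion = table(ev_ion)),
            class = "conduction_report")
}

#' @export
print.conduction_report <- function(x, ...) {
  cat(sprintf("conduction_report: %d events (%.2f per us)\n",
              x$event_count, x$rate_per_us))
  invisible(x)
}

#' Potassium z-occupancy histogram of the pore
#'
#' Histogram of ion z positions (0.5 Angstrom bins by default) between two
#' landmarks, pooled over all frames, and the mean simultaneous ion count in
#' the region (total in-region observations / number of frames). Default
#' region: selectivity filter (T143) down to M308 of the G-loop.
#'
#' @param traj A [pore_trajectory()].
#' @param from Upper landmark (default `"T143"`).
#' @param to Lower landmark (default `"M308"`).
#' @param bin Bin width, Angstrom (default 0.5).
#' @param radius Radial cutoff from the M181 axis, Angstrom (default 25).
#' @return List with `breaks`, `mids` (relative to the M181 center),
#'   `counts`, `mean_count`, `per_frame_counts`.
#' @export
occupancy_histogram <- function(traj, from = "T143", to = "M308", bin = 0.5,
                                radius = 25) {
  stopifnot(inherits(traj, "pore_trajectory"))
  if (bin <= 0) stop("'bin' must be > 0", call. = FALSE)
  L <- traj$box_length_z
  ctr <- landmark_xyz(traj, "M181")
  z_hi <- rel_z(landmark_xyz(traj, from)["z"], ctr["z"], L)
  z_lo <- rel_z(landmark_xyz(traj, to)["z"], ctr["z"], L)
  if (z_lo >= z_hi) stop("empty region: '", to, "' must lie below '", from,
                         "'", call. = FALSE)
  zr <- rel_z(traj$ions$z, ctr["z"], L)
  rr <- sqrt((traj$ions$x - ctr["x"])^2 + (traj$ions$y - ctr["y"])^2)
  inside <- zr >= z_lo & zr <= z_hi & rr <= radius
  n_frames <- nrow(traj$frames)
  breaks <- seq(z_lo, z_hi + bin - 1e-12, by = bin)
  if (breaks[length(breaks)] < z_hi) breaks <- c(breaks, z_hi)
  counts <- if (any(inside)) {
    tabulate(findInterval(zr[inside], breaks, rightmost.closed = TRUE,
                          all.inside = TRUE),
             nbins = length(breaks) - 1L)
  } else integer(length(breaks) - 1L)
  pf <- tabulate(match(traj$ions$frame[inside], traj$frames$frame),
                 nbins = n_frames)
  list(breaks = breaks,
       mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
       counts = counts,
       mean_count = sum(inside) / n_frames,
       per_frame_counts = pf)
}

#' Pore solvation profile and dewetting report
#'
#' For every frame and z-bin between the helix-bundle-crossing (I177) and
#' G-loop (M302) landmarks, records whether any water lies in the bin
#' (within the 10 Angstrom water cylinder). Contiguous runs of frames in
#' which at least one bin is empty are reported as dewetted intervals.
#'
#' @param traj A [pore_trajectory()] with water records.
#' @param z_bin Bin height, Angstrom (default 2).
#' @param radius Water cylinder radius, Angstrom (default 10).
#' @param from Upper landmark (default `"I177"`).
#' @param to Lower landmark (default `"M302"`).
#' @return List with `occupancy` (frames x bins logical matrix),
#'   `dewetted_frames` (logical), `intervals` (data frame `start_frame`,
#'   `end_frame`), `dewetted_fraction`.
#' @export
solvation_profile <- function(traj, z_bin = 2, radius = 10, from = "I177",
                              to = "M302") {
  stopifnot(inherits(traj, "pore_trajectory"))
  if (is.null(traj$waters) || nrow(traj$waters) == 0L) {
    warning("no waters in trajectory; reporting all frames as dewetted")
    n <- nrow(traj$frames)
    return(list(occupancy = matrix(FALSE, n, 1),
                dewetted_frames = rep(TRUE, n),
                intervals = data.frame(start_frame = traj$frames$frame[1],
                                       end_frame = traj$frames$frame[n]),
                dewetted_fraction = 1))
  }
  L <- traj$box_length_z
  ctr <- landmark_xyz(traj, "M181")
  z_hi <- rel_z(landmark_xyz(traj, from)["z"], ctr["z"], L)
  z_lo <- rel_z(landmark_xyz(traj, to)["z"], ctr["z"], L)
  breaks <- seq(z_lo, z_hi, by = z_bin)
  if (breaks[length(breaks)] < z_hi) breaks <- c(breaks, z_hi)
  n_bins <- length(breaks) - 1L
  w <- traj$waters
  zr <- rel_z(w$z, ctr["z"], L)
  rr <- sqrt((w$x - ctr["x"])^2 + (w$y - ctr["y"])^2)
  inside <- zr >= z_lo & zr <= z_hi & rr <= radius
  fr_idx <- match(w$frame[inside], traj$frames$frame)
  bin_idx <- findInterval(zr[inside], breaks, rightmost.closed = TRUE,
                          all.inside = TRUE)
  n_frames <- nrow(traj$frames)
  occ <- matrix(FALSE, n_frames, n_bins)
  occ[cbind(fr_idx, bin_idx)] <- TRUE
  dew <- !apply(occ, 1, all)
  r <- rle(dew)
  ends <- cumsum(r$lengths)
  starts <- c(1, ends[-length(ends)] + 1)
  iv <- data.frame(start_frame = traj$frames$frame[starts[r$values]],
                   end_frame = traj$frames$frame[ends[r$values]])
  list(occupancy = occ, dewetted_frames = dew, intervals = iv,
       dewetted_fraction = mean(dew))
}

#' Opposing-chain minimum-distance histogram
#'
#' Pools the per-frame minimum distances of the two opposing chain pairs
#' (1-3 and 2-4) for a residue and reports the distribution and its mode
#' (most frequently sampled distance at the bin resolution).
#'
#' @param traj A [pore_trajectory()] with `chain_min_distances`.
#' @param residue Residue name, e.g. `"M181"`.
#' @param bin Bin width, Angstrom (default 0.5).
#' @param pool_pairs Pool the two chain pairs (default `TRUE`) or keep them
#'   separate.
#' @return For pooled input, a list with `breaks`, `mids`, `counts`,
#'   `modal_distance`, `modes` (local maxima); otherwise a named list of
#'   such lists per pair.
#' @export
min_distance_histogram <- function(traj, residue, bin = 0.5,
                                   pool_pairs = TRUE) {
  stopifnot(inherits(traj, "pore_trajectory"))
  cmd <- traj$chain_min_distances
  if (is.null(cmd) || !residue %in% cmd$residue) {
    stop("no chain distances for residue '", residue, "'", call. = FALSE)
  }
  sub <- cmd[cmd$residue == residue, ]
  one <- function(d) {
    lo <- floor(min(d) / bin) * bin
    breaks <- seq(lo, max(d) + bin, by = bin)
    counts <- tabulate(findInterval(d, breaks, rightmost.closed = TRUE,
                                    all.inside = TRUE),
                       nbins = length(breaks) - 1L)
    mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
    # local maxima above 10% of the peak, for multimodal distributions
    pk <- which(counts >= 0.1 * max(counts) &
                  counts >= c(-Inf, counts[-length(counts)]) &
                  counts >= c(counts[-1], -Inf))
    list(breaks = breaks, mids = mids, counts = counts,
         modal_distance = mids[which.max(counts)],
         modes = mids[pk])
  }
  if (pool_pairs) one(sub$dist)
  else lapply(split(sub$dist, sub$pair), one)
}

#' Synthetic pore-trajectory specification
#'
#' Generator configuration for [synth_trajectory()]. The geometry emulates
#' the analysed channel: a z-stack of landmarks (selectivity filter at the
#' top, then the rectification controller D173, the HBC residues I177 and
#' M181, and the G-loop residues M308 and M302), permeating ions planted as
#' complete pore crossings, a pool of confined cavity ions setting the mean
#' regional K+ occupancy, waters as Poisson scatter in the pore cylinder
#' with optional dewetting windows, and opposing-chain distances drawn from
#' Gaussian mixtures.
#'
#' @param n_frames Frames per run (default 1001, one frame per 1000 ps).
#' @param dt_ps Time between frames, ps.
#' @param box_length_z Periodic box length, Angstrom (default 145).
#' @param permeation_rate_per_us Mean planted conduction events per
#'   microsecond (Poisson; default 12.7, the most conductive condition).
#'   Set `n_permeations` to plant an exact count instead.
#' @param n_permeations Exact number of planted permeations (overrides the
#'   rate if not `NULL`).
#' @param mean_pool_ions Mean simultaneous K+ count between the selectivity
#'   filter and M308 (default 9.3).
#' @param water_density Waters per Angstrom of pore column (default 10,
#'   bulk-like for a 10 Angstrom cylinder).
#' @param dewetting_windows List of `c(start_frame, end_frame)` windows in
#'   which waters are removed around the HBC.
#' @param chain_distance_spec Named list: residue -> list(means, sds,
#'   weights) for the opposing-chain minimum distances.
#' @return List of class `synth_traj_spec`.
#' @export
synth_traj_spec <- function(n_frames = 1001L, dt_ps = 1000,
                            box_length_z = 145,
                            permeation_rate_per_us = 12.7,
                            n_permeations = NULL,
                            mean_pool_ions = 9.3,
                            water_density = 10,
                            dewetting_windows = list(),
                            chain_distance_spec = list(
                              I177 = list(means = 8.2, sds = 0.5,
                                          weights = 1),
                              M181 = list(means = 10.6, sds = 0.7,
                                          weights = 1),
                              M308 = list(means = 9.4, sds = 0.6,
                                          weights = 1),
                              M302 = list(means = 6.0, sds = 0.4,
                                          weights = 1))) {
  if (n_frames < 2L) stop("'n_frames' must be >= 2", call. = FALSE)
  if (water_density < 0) stop("'water_density' must be >= 0", call. = FALSE)
  if (mean_pool_ions < 0) stop("'mean_pool_ions' must be >= 0",
                               call. = FALSE)
  if (!is.null(n_permeations) && n_permeations < 0) {
    stop("'n_permeations' must be >= 0", call. = FALSE)
  }
  if (permeation_rate_per_us < 0) {
    stop("'permeation_rate_per_us' must be >= 0", call. = FALSE)
  }
  structure(as.list(environment()), class = "synth_traj_spec")
}

default_landmarks <- function() {
  data.frame(
    name = c("G147", "Y146", "G145", "T143", "T143sc",
             "D173", "I177", "M181", "M308", "M302"),
    x = 0, y = 0,
    z = c(25, 23, 21, 18, 17, 5, 0, -4, -16, -22)
  )
}

#' Generate a synthetic pore trajectory
#'
#' Builds a [pore_trajectory()] with known ground truth: every planted
#' permeation produces exactly one selectivity-filter exit event (logged in
#' `event_log`), pool ions perform reflected random walks spanning the
#' occupancy region plus a calibrated overshoot so their mean in-region
#' count equals `mean_pool_ions`, waters are Poisson scatter with optional
#' dewetting windows, and chain distances are Gaussian-mixture draws.
#'
#' @param spec A [synth_traj_spec()].
#' @param seed Integer RNG seed.
#' @return A [pore_trajectory()] with `event_log` filled in.
#' @export
synth_trajectory <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "synth_traj_spec"))
  set.seed(seed)
  lm <- default_landmarks()
  gz <- function(n) lm$z[match(n, lm$name)]
  n_fr <- spec$n_frames
  times <- (seq_len(n_fr) - 1) * spec$dt_ps
  dur_us <- (n_fr - 1) * spec$dt_ps / 1e6

  ion_rows <- list()
  next_id <- 1L
  events <- list()

  # --- planted permeations -------------------------------------------------
  n_perm <- if (!is.null(spec$n_permeations)) spec$n_permeations
            else stats::rpois(1, spec$permeation_rate_per_us * dur_us)
  transit <- 40L  # frames from below the G-loop to above the exit plane
  if (n_perm > 0) {
    z_path <- seq(gz("M302") - 12, gz("G147") + 12, length.out = transit)
    max_start <- max(1L, n_fr - transit - 5L)
    starts <- sort(sample.int(max_start, n_perm, replace = TRUE))
    for (p in seq_len(n_perm)) {
      f0 <- starts[p]
      frames <- f0:min(n_fr, f0 + transit - 1L)
      zs <- z_path[seq_along(frames)]
      ion_rows[[length(ion_rows) + 1L]] <- data.frame(
        frame = frames, time_ps = times[frames], id = next_id,
        x = stats::runif(length(frames), -1, 1),
        y = stats::runif(length(frames), -1, 1),
        z = zs)
      f_exit <- frames[which(zs > gz("G147"))[1]]
      events[[length(events) + 1L]] <- data.frame(
        ion = next_id, frame = f_exit, time_ps = times[f_exit])
      next_id <- next_id + 1L
    }
  }

  # --- cavity pool ions ----------------------------------------------------
  if (spec$mean_pool_ions > 0) {
    region_len <- gz("T143") - gz("M308")
    n_pool <- max(ceiling(spec$mean_pool_ions * 1.3),
                  ceiling(spec$mean_pool_ions))
    p_in <- spec$mean_pool_ions / n_pool
    span <- region_len / p_in
    z_top <- gz("T143")
    z_bot <- z_top - span
    for (j in seq_len(n_pool)) {
      z <- numeric(n_fr)
      z[1] <- stats::runif(1, z_bot, z_top)  # stationary (uniform) start
      steps <- stats::rnorm(n_fr - 1, 0, 6)
      for (t in 2:n_fr) {
        zt <- z[t - 1] + steps[t - 1]
        # reflect into [z_bot, z_top]
        while (zt > z_top || zt < z_bot) {
          if (zt > z_top) zt <- 2 * z_top - zt
          if (zt < z_bot) zt <- 2 * z_bot - zt
        }
        z[t] <- zt
      }
      theta <- stats::runif(n_fr, 0, 2 * pi)
      rad <- stats::runif(n_fr, 3, 20)  # clear of the 2.5 A SF cylinder
      ion_rows[[length(ion_rows) + 1L]] <- data.frame(
        frame = seq_len(n_fr), time_ps = times, id = next_id,
        x = rad * cos(theta), y = rad * sin(theta), z = z)
      next_id <- next_id + 1L
    }
  }
  ions <- do.call(rbind, ion_rows)
  if (is.null(ions)) {
    ions <- data.frame(frame = seq_len(n_fr), time_ps = times, id = 0L,
                       x = 0, y = 0, z = gz("M302") - 30)
  }

  # --- waters --------------------------------------------------------------
  waters <- NULL
  if (spec$water_density > 0) {
    col_lo <- gz("M302") - 2
    col_hi <- gz("I177") + 2
    col_len <- col_hi - col_lo
    n_w <- stats::rpois(n_fr, spec$water_density * col_len)
    tot <- sum(n_w)
    fr <- rep(seq_len(n_fr), n_w)
    theta <- stats::runif(tot, 0, 2 * pi)
    rad <- 9 * sqrt(stats::runif(tot))
    waters <- data.frame(frame = fr, time_ps = times[fr],
                         id = seq_len(tot) + 1e6,
                         x = rad * cos(theta), y = rad * sin(theta),
                         z = stats::runif(tot, col_lo, col_hi))
    for (w in spec$dewetting_windows) {
      zwin <- c(gz("I177") - 3, gz("I177") + 3)
      drop <- waters$frame >= w[1] & waters$frame <= w[2] &
        waters$z >= zwin[1] & waters$z <= zwin[2]
      waters <- waters[!drop, ]
    }
  }

  # --- chain distances -----------------------------------------------------
  cmd <- NULL
  if (length(spec$chain_distance_spec)) {
    rows <- lapply(names(spec$chain_distance_spec), function(res) {
      cs <- spec$chain_distance_spec[[res]]
      draw <- function() {
        comp <- sample.int(length(cs$means), n_fr, replace = TRUE,
                           prob = cs$weights)
        stats::rnorm(n_fr, cs$means[comp], cs$sds[comp])
      }
      rbind(data.frame(frame = seq_len(n_fr), residue = res, pair = "1-3",
                       dist = draw()),
            data.frame(frame = seq_len(n_fr), residue = res, pair = "2-4",
                       dist = draw()))
    })
    cmd <- do.call(rbind, rows)
  }

  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(ion = integer(0), frame = integer(0), time_ps = numeric(0))
  pore_trajectory(ions, lm, waters = waters, chain_min_distances = cmd,
                  box_length_z = spec$box_length_z, event_log = ev)
}
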
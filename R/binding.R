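## AFP binding detection from centre-of-mass height tracks: an unchanging
## z-coordinate at the ice-front height indicates ice binding.

#' Binding state from a centre-of-mass height series
#'
#' A window is "bound" when the rolling standard deviation of the
#' centre-of-mass height is below `z_sd_threshold` and the window-mean
#' height lies within `proximity` of the ice-front height. The bind time is
#' the start of the first bound window of the final bound stretch sustained
#' to the end of the track (transient low-mobility episodes that end in
#' detachment do not count as binding).
#'
#' @param com_z Centre-of-mass z series, angstroms.
#' @param time Frame times, ps.
#' @param window_frames Rolling window length in frames.
#' @param z_sd_threshold Rolling SD threshold, angstroms (default 1.5).
#' @param front_z Ice-front height: scalar or per-frame vector, angstroms.
#' @param proximity Maximum |mean height - front| for binding, A (default 10).
#' @return Object of class `binding_track`: data.frame `windows` (window
#'   start `time`, `com_z_mean`, `com_z_sd`, `bound`), `bind_time` (ps, or
#'   `NA` when never bound to the end), plus the inputs.
#' @export
binding_state <- function(com_z, time, window_frames, z_sd_threshold = 1.5,
                          front_z, proximity = 10) {
  nf <- length(com_z)
  w <- as.integer(window_frames)
  if (w < 2) stop("window_frames must be >= 2")
  if (nf < w) stop("track shorter than one analysis window")
  if (length(front_z) == 1) front_z <- rep(front_z, nf)
  if (length(front_z) != nf) stop("front_z must be scalar or per-frame")
  # rolling mean and sd via cumulative sums
  c1 <- cumsum(c(0, com_z)); c2 <- cumsum(c(0, com_z^2))
  cf <- cumsum(c(0, front_z))
  starts <- seq_len(nf - w + 1L)
  m <- (c1[starts + w] - c1[starts]) / w
  v <- pmax(0, (c2[starts + w] - c2[starts]) / w - m^2) * w / (w - 1)
  fz <- (cf[starts + w] - cf[starts]) / w
  s <- sqrt(v)
  bound <- s < z_sd_threshold & abs(m - fz) <= proximity
  bind_time <- NA_real_
  if (bound[length(bound)]) {
    run_start <- length(bound)
    while (run_start > 1 && bound[run_start - 1L]) run_start <- run_start - 1L
    bind_time <- time[starts[run_start]]
  }
  structure(list(
    windows = data.frame(time = time[starts], com_z_mean = m, com_z_sd = s,
                         front_z = fz, bound = bound),
    bind_time = bind_time, com_z = com_z, time = time,
    window_frames = w, z_sd_threshold = z_sd_threshold,
    proximity = proximity), class = "binding_track")
}

#' Track AFP binding in a trajectory
#'
#' Computes the protein centre-of-mass height per frame (all protein atoms,
#' equal weights) and applies [binding_state()]. The ice-front height can
#' be supplied directly or derived per frame from phase labels via
#' [front_height_series()].
#'
#' @param traj An `md_trajectory` containing protein atoms.
#' @param window_ns Analysis window, ns (default 20).
#' @param z_sd_threshold Rolling SD threshold, angstroms (default 1.5).
#' @param front_z Scalar or per-frame front height; if `NULL`, derived from
#'   `labels`.
#' @param labels Optional `phase_labels` used to derive the front height.
#' @param proximity Front-proximity cutoff, angstroms (default 10).
#' @return A `binding_track` (see [binding_state()]); the centre-of-mass
#'   series is in `$com_z`.
#' @export
track_afp <- function(traj, window_ns = 20, z_sd_threshold = 1.5,
                      front_z = NULL, labels = NULL, proximity = 10) {
  stopifnot(inherits(traj, "md_trajectory"))
  pidx <- which(traj$roles == "protein")
  if (!length(pidx)) stop("no protein atoms in trajectory")
  com_z <- colMeans(traj$coords[pidx, 3, , drop = FALSE][, 1, ])
  if (length(pidx) == 1)
    com_z <- traj$coords[pidx, 3, ]
  if (is.null(front_z)) {
    if (is.null(labels))
      stop("supply front_z or labels to locate the ice front")
    front_z <- front_height_series(labels, traj)
    # extend trailing NA (incomplete classification windows) with the last
    # defined value
    ok <- which(!is.na(front_z))
    if (!length(ok)) stop("front height undefined for all frames")
    front_z[seq_len(ok[1] - 1)] <- front_z[ok[1]]
    last <- ok[length(ok)]
    if (last < length(front_z))
      front_z[(last + 1):length(front_z)] <- front_z[last]
  }
  w <- max(2L, as.integer(round(window_ns * 1000 / traj$dt_frame)))
  binding_state(com_z, traj$time, w, z_sd_threshold, front_z, proximity)
}

#' @export
print.binding_track <- function(x, ...) {
  nb <- sum(x$windows$bound)
  cat(sprintf("binding track: %d windows (%d frames each), %d bound\n",
              nrow(x$windows), x$window_frames, nb))
  cat(if (is.na(x$bind_time)) "no sustained binding\n"
      else sprintf("bound from t = %g ps to trajectory end\n", x$bind_time))
  invisible(x)
}
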
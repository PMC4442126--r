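## Mobility-based ice/water classification and ice-fraction statistics.
##
## A water is immobile ("ice") at frame t when its oxygen stays within the
## displacement threshold over a short window of successive frames (default
## 0.8 A over 3 frames, i.e. 200 ps at the 100 ps capture interval).

#' Classify waters as ice or liquid by oxygen mobility
#'
#' A water oxygen is labelled ice at frame `t` when, over the window of
#' `window_frames` successive frames starting at `t`, its maximum deviation
#' from the window-mean position (periodic boundaries unwrapped) is below
#' `disp_threshold`; otherwise liquid. The alternative `"endpoint"` mode
#' uses the first-to-last-frame displacement instead of the deviation from
#' the mean; the mean-based form is the default because it is stable
#' against single-frame vibrational excursions. Labels are only defined at
#' frames with a complete window (the final `window_frames - 1` frames are
#' `NA`). Windows overlap (one per starting frame).
#'
#' @param traj An `md_trajectory`.
#' @param disp_threshold Displacement threshold, angstroms (default 0.8).
#' @param window_frames Window length in frames (default 3).
#' @param mode `"mean"` (default) or `"endpoint"`.
#' @param pbc Periodic dimensions used for unwrapping (default x, y).
#' @return Object of class `phase_labels`: logical matrix `ice`
#'   (`n_waters x n_frames`, `NA` for incomplete windows), `water_idx`
#'   (atom indices of the classified waters), and the parameters.
#' @export
classify_ice <- function(traj, disp_threshold = 0.8, window_frames = 3,
                         mode = c("mean", "endpoint"),
                         pbc = c(TRUE, TRUE, FALSE)) {
  stopifnot(inherits(traj, "md_trajectory"))
  mode <- match.arg(mode)
  if (disp_threshold <= 0) stop("disp_threshold must be positive")
  w <- as.integer(window_frames)
  if (w < 2) stop("window_frames must be >= 2")
  if (traj$n_frames < w)
    stop("trajectory has ", traj$n_frames, " frames; the classification ",
         "window needs at least ", w)
  widx <- which(traj$roles %in% c("water", "seed", "barrier"))
  if (!length(widx)) stop("no water atoms in trajectory")
  U <- .unwrap_coords(traj$coords[widx, , , drop = FALSE], traj$box, pbc)
  n <- length(widx)
  nf <- traj$n_frames
  ice <- matrix(NA, n, nf)
  # cumulative sums over frames for O(1) window means
  CS <- array(0, c(n, 3, nf + 1L))
  for (f in seq_len(nf))
    CS[, , f + 1L] <- matrix(CS[, , f], ncol = 3) + .frame_mat(U, f)
  for (t0 in seq_len(nf - w + 1L)) {
    if (mode == "mean") {
      m <- (matrix(CS[, , t0 + w], ncol = 3) -
              matrix(CS[, , t0], ncol = 3)) / w
      maxdev2 <- rep(0, n)
      for (k in t0:(t0 + w - 1L)) {
        dev2 <- rowSums((.frame_mat(U, k) - m)^2)
        maxdev2 <- pmax(maxdev2, dev2)
      }
      ice[, t0] <- sqrt(maxdev2) < disp_threshold
    } else {
      d <- .frame_mat(U, t0 + w - 1L) - .frame_mat(U, t0)
      ice[, t0] <- sqrt(rowSums(d * d)) < disp_threshold
    }
  }
  structure(list(ice = ice, water_idx = widx,
                 disp_threshold = disp_threshold, window_frames = w,
                 mode = mode, time = traj$time),
            class = "phase_labels")
}

#' Ice fraction above the seed crystal over time
#'
#' Fraction of waters in the region (by default everything above the
#' topmost constrained seed oxygen) that are ice-labelled, per frame.
#'
#' @param labels A `phase_labels` from [classify_ice()].
#' @param traj The trajectory the labels were computed from.
#' @param region `c(zmin, zmax)` in angstroms; default
#'   `c(<top seed oxygen z>, Inf)`. Required if the trajectory has no seed
#'   atoms.
#' @return Object of class `ice_fraction_series`: data.frame with `time`
#'   (ps), `fraction` and `n_region` (waters in the region), one row per
#'   labelled frame; the region is stored as attribute `region`.
#' @export
ice_fraction <- function(labels, traj, region = NULL) {
  stopifnot(inherits(labels, "phase_labels"),
            inherits(traj, "md_trajectory"))
  if (is.null(region)) {
    sidx <- which(traj$roles == "seed")
    if (!length(sidx))
      stop("no seed atoms in trajectory; supply region = c(zmin, zmax)")
    region <- c(max(traj$coords[sidx, 3, 1]), Inf)
  }
  if (region[1] >= region[2]) stop("empty region")
  frames <- which(colSums(!is.na(labels$ice)) > 0)
  out <- data.frame(time = labels$time[frames], fraction = NA_real_,
                    n_region = NA_integer_)
  for (k in seq_along(frames)) {
    f <- frames[k]
    z <- traj$coords[labels$water_idx, 3, f]
    inr <- z > region[1] & z <= region[2]
    if (!any(inr)) stop("no waters in the region at frame ", f)
    out$fraction[k] <- mean(labels$ice[inr, f])
    out$n_region[k] <- sum(inr)
  }
  attr(out, "region") <- region
  class(out) <- c("ice_fraction_series", "data.frame")
  out
}

#' Equilibration statistics of an ice-fraction series
#'
#' Mean and standard deviation over a time window plus an ordinary
#' least-squares regression of fraction on time; the window is judged
#' equilibrated when the slope confidence interval covers zero (no
#' appreciable growth or melting).
#'
#' @param series An `ice_fraction_series` (or data.frame with `time`,
#'   `fraction`).
#' @param t_start,t_end Window limits, ps.
#' @param level Confidence level for the slope interval (default 0.95).
#' @return List of class `equilibrium_stats`: `mean`, `sd`, `slope` (per
#'   ps), `slope_ci`, `equilibrated`, `n`.
#' @export
equilibrium_stats <- function(series, t_start = -Inf, t_end = Inf,
                              level = 0.95) {
  d <- series[series$time >= t_start & series$time <= t_end, ]
  if (nrow(d) < 10)
    stop("need at least 10 points in the window; got ", nrow(d))
  fit <- stats::lm(fraction ~ time, data = d)
  ci <- suppressWarnings(stats::confint(fit, "time", level = level))
  slope <- unname(stats::coef(fit)["time"])
  structure(list(mean = mean(d$fraction), sd = stats::sd(d$fraction),
                 slope = slope, slope_ci = unname(ci[1, ]),
                 equilibrated = is.finite(ci[1, 1]) && is.finite(ci[1, 2]) &&
                   ci[1, 1] <= 0 && ci[1, 2] >= 0,
                 n = nrow(d), level = level),
            class = "equilibrium_stats")
}

#' @export
print.equilibrium_stats <- function(x, ...) {
  cat(sprintf("ice fraction %.4f +/- %.4f (n = %d)\n", x$mean, x$sd, x$n))
  cat(sprintf("slope %.3g per ps, %g%% CI [%.3g, %.3g] -> %s\n",
              x$slope, 100 * x$level, x$slope_ci[1], x$slope_ci[2],
              if (x$equilibrated) "equilibrated" else "growing/melting"))
  invisible(x)
}

#' Per-frame ice-front height from phase labels
#'
#' A robust per-frame front estimate: the given quantile (default 0.98) of
#' the z coordinates of ice-labelled waters above `zmin`.
#'
#' @param labels A `phase_labels`.
#' @param traj The trajectory.
#' @param zmin Lower bound of the region considered (default the top seed
#'   oxygen, or 0 with no seed atoms).
#' @param probs Quantile used (default 0.98).
#' @return Numeric vector, one height per frame (`NA` where undefined).
#' @export
front_height_series <- function(labels, traj, zmin = NULL, probs = 0.98) {
  stopifnot(inherits(labels, "phase_labels"))
  if (is.null(zmin)) {
    sidx <- which(traj$roles == "seed")
    zmin <- if (length(sidx)) max(traj$coords[sidx, 3, 1]) else 0
  }
  out <- rep(NA_real_, traj$n_frames)
  for (f in seq_len(traj$n_frames)) {
    lab <- labels$ice[, f]
    if (all(is.na(lab))) next
    z <- traj$coords[labels$water_idx, 3, f]
    zi <- z[!is.na(lab) & lab & z > zmin]
    if (length(zi)) out[f] <- stats::quantile(zi, probs, names = FALSE)
  }
  out
}
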
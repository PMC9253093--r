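#' Per-frame speed series from a tracked trial
#'
#' Uses the midpoint of the two tracking points. Mode `"3d"` is the full
#' three-dimensional speed between successive frames; mode `"2d"` drops the
#' vertical term, nullifying the influence of imperfect buoyancy on the
#' reported speeds.
#'
#' @param trial a `tracked_trial` (see [simulate_linear_trial()],
#'   [read_trial()]).
#' @param mode `"2d"` (horizontal, default) or `"3d"`.
#' @return data.frame with `t_s` (time of the later frame of each pair) and
#'   `v` (m/s).
#' @export
velocity_series <- function(trial, mode = c("2d", "3d")) {
  mode <- match.arg(mode)
  if (nrow(trial) < 2L) stop("need at least 2 frames")
  if (any(diff(trial$t_s) <= 0)) stop("timestamps must be strictly increasing")
  mid <- cbind((trial$p1x + trial$p2x) / 2,
               (trial$p1y + trial$p2y) / 2,
               (trial$p1z + trial$p2z) / 2)
  d <- diff(mid)
  if (mode == "2d") d[, 3] <- 0
  data.frame(t_s = trial$t_s[-1],
             v = sqrt(rowSums(d^2)) / diff(trial$t_s))
}

motor_windows <- function(trial) {
  on <- trial$motor_on > 0
  if (!any(on)) return(NULL)
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = trial$t_s[starts[r$values]],
        end = trial$t_s[ends[r$values]])
}

#' Linear acceleration fit over the pulse window(s)
#'
#' Ordinary least squares of the horizontal speed against time over the
#' motor-on window(s), as an operational acceleration-from-rest measure.
#'
#' @param trial a `tracked_trial`.
#' @param windows optional matrix of `(start, end)` times (s); defaults to
#'   the motor-on windows of the trial.
#' @param mode speed mode passed to [velocity_series()].
#' @return List with `slope` (m/s^2), `slope_cm_s2`, `intercept`,
#'   `r_squared` and `n`.
#' @export
fit_acceleration <- function(trial, windows = NULL, mode = "2d") {
  vs <- velocity_series(trial, mode)
  if (is.null(windows)) windows <- motor_windows(trial)
  if (is.null(windows)) stop("no motor-on window in trial and none supplied")
  windows <- matrix(windows, ncol = 2)
  sel <- rep(FALSE, nrow(vs))
  for (i in seq_len(nrow(windows)))
    sel <- sel | (vs$t_s >= windows[i, 1] & vs$t_s <= windows[i, 2])
  if (sum(sel) < 3L) stop("fewer than 3 frames in the fit window")
  fit <- stats::lm(v ~ t_s, data = vs[sel, ])
  rss <- sum(stats::resid(fit)^2)
  tss <- sum((vs$v[sel] - mean(vs$v[sel]))^2)
  list(slope = unname(stats::coef(fit)[2]),
       slope_cm_s2 = unname(stats::coef(fit)[2]) * 100,
       intercept = unname(stats::coef(fit)[1]),
       r_squared = if (tss > 0) 1 - rss / tss else 1,
       n = sum(sel))
}

#' Rocking (pitch) angle series
#'
#' Angle of the tracking-point pair away from true vertical, minus the
#' static angle of the pair `theta_tp`:
#' `theta_dv = acos((z2 - z1) / |p2 - p1|) - theta_tp`, with point 1
#' anterior and point 2 posterior.
#'
#' @param trial a `tracked_trial`.
#' @param theta_tp static tracking-point angle from vertical, degrees.
#' @return data.frame with `t_s` and `theta_dv` (degrees).
#' @export
rocking_angle <- function(trial, theta_tp = 0) {
  d <- cbind(trial$p2x - trial$p1x, trial$p2y - trial$p1y,
             trial$p2z - trial$p1z)
  len <- sqrt(rowSums(d^2))
  if (any(len < 1e-12)) stop("coincident tracking points")
  data.frame(t_s = trial$t_s,
             theta_dv = acos(pmin(1, pmax(-1, d[, 3] / len))) * 180 / pi -
               theta_tp)
}

#' Yaw angle and angular velocity
#'
#' Bearing of the horizontal component of the tracking-point pair, unwrapped
#' to a continuous net angle from the starting angle (counter-clockwise
#' positive viewed from above); angular velocity by frame differencing.
#'
#' @param trial a top-down `tracked_trial`.
#' @param smooth_frames moving-average window (frames) used for
#'   `peak_omega` only; the raw `omega` series is retained.
#' @return A `yaw_result`: list with `t_s`, `net_angle` (deg), `omega`
#'   (deg/s, length n-1, at the later frame of each pair), `peak_omega`
#'   (deg/s, from the smoothed series) and `revolutions`.
#' @export
yaw_series <- function(trial, smooth_frames = 5L) {
  dx <- trial$p2x - trial$p1x
  dy <- trial$p2y - trial$p1y
  if (any(dx^2 + dy^2 < 1e-16))
    stop("tracking points vertically stacked: bearing undefined")
  bearing <- atan2(dy, dx)
  dwrap <- diff(bearing)
  dwrap <- (dwrap + pi) %% (2 * pi) - pi # unwrap: steps into (-pi, pi]
  net <- c(0, cumsum(dwrap)) * 180 / pi
  omega <- diff(net) / diff(trial$t_s)
  structure(list(t_s = trial$t_s, net_angle = net, omega = omega,
                 peak_omega = max(abs(moving_average(omega, smooth_frames))),
                 revolutions = max(abs(net)) / 360),
            class = "yaw_result")
}

#' @export
print.yaw_result <- function(x, ...) {
  cat(sprintf(
    "yaw: net angle %.1f deg (%.2f revolutions), peak |omega| %.1f deg/s\n",
    x$net_angle[length(x$net_angle)], x$revolutions, x$peak_omega))
  invisible(x)
}

moving_average <- function(x, k = 5L) {
  if (k <= 1L) return(x)
  n <- length(x)
  out <- stats::filter(x, rep(1 / k, k), sides = 2)
  # shrink the window at the edges instead of dropping frames
  half <- (k - 1L) %/% 2L
  for (i in seq_len(half)) {
    out[i] <- mean(x[1:(i + half)])
    out[n - i + 1L] <- mean(x[(n - i + 1L - half):n])
  }
  as.numeric(out)
}

#' Summarize a linear trial: peak velocity, coasting distance, duration
#'
#' Peak velocity is the maximum of the 5-frame moving average of the
#' horizontal speed (tracking points sit far from the body center, so raw
#' speeds oscillate with rocking). Coasting distance is the horizontal path
#' length of the midpoint from motor-off until rest; rest is speed below
#' `rest_speed` sustained for `rest_hold` seconds (or track end).
#'
#' @param trial a `tracked_trial`.
#' @param smooth_frames moving-average window (frames).
#' @param rest_speed rest threshold, m/s.
#' @param rest_hold time the threshold must hold, s.
#' @return List with `peak_velocity` (m/s), `coasting_distance` (m),
#'   `duration` (s) and `motor_off` time.
#' @export
trial_summary <- function(trial, smooth_frames = 5L, rest_speed = 0.01,
                          rest_hold = 0.5) {
  vs <- velocity_series(trial, "2d")
  vsm <- moving_average(vs$v, smooth_frames)
  mw <- motor_windows(trial)
  motor_off <- if (is.null(mw)) trial$t_s[1] else max(mw[, 2])
  # rest: first time the smoothed speed stays below threshold for rest_hold
  fps <- attr(trial, "fps") %||% (1 / stats::median(diff(trial$t_s)))
  hold_n <- max(1L, round(rest_hold * fps))
  below <- vsm < rest_speed & vs$t_s > motor_off
  rest_i <- NA_integer_
  run <- 0L
  for (i in seq_along(below)) {
    run <- if (below[i]) run + 1L else 0L
    if (run >= hold_n) {
      rest_i <- i - hold_n + 1L
      break
    }
  }
  t_rest <- if (is.na(rest_i)) vs$t_s[length(vs$t_s)] else vs$t_s[rest_i]
  mid <- cbind((trial$p1x + trial$p2x) / 2, (trial$p1y + trial$p2y) / 2)
  seg <- sqrt(rowSums(diff(mid)^2))
  coast_sel <- vs$t_s > motor_off & vs$t_s <= t_rest
  list(peak_velocity = max(vsm),
       coasting_distance = sum(seg[coast_sel]),
       duration = t_rest - trial$t_s[1],
       motor_off = motor_off)
}

#' Group summary of trial metrics
#'
#' @param trials list of `tracked_trial`s.
#' @param conf confidence level of the t-based interval.
#' @return data.frame with one row per metric: mean, sd, and confidence
#'   bounds over trials.
#' @export
trial_group_summary <- function(trials, conf = 0.95) {
  if (!length(trials)) stop("empty trial group")
  s <- lapply(trials, trial_summary)
  met <- c("peak_velocity", "coasting_distance", "duration")
  do.call(rbind, lapply(met, function(m) {
    x <- vapply(s, `[[`, numeric(1), m)
    n <- length(x)
    se <- stats::sd(x) / sqrt(n)
    q <- if (n > 1) stats::qt(1 - (1 - conf) / 2, n - 1) else NA_real_
    data.frame(metric = m, n = n, mean = mean(x), sd = stats::sd(x),
               lower = mean(x) - q * se, upper = mean(x) + q * se)
  }))
}
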
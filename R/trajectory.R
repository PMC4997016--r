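#' Trajectory objects
#'
#' A trajectory is the universal currency of the pipeline: a time-ordered
#' series of 2D localizations on a uniform frame grid. It is stored as a
#' `data.frame` with columns `frame` (0-based integer index), `t_s` (seconds),
#' `x_um`, `y_um` (microns) and, for simulated data, `true_x_um`, `true_y_um`
#' and `state` (one of `"LD"`, `"LO_FREE"`, `"LO_TRAPPED"`), plus a
#' `frame_interval_s` attribute.
#'
#' @param x A data frame with at least columns `frame`, `t_s`, `x_um`, `y_um`.
#' @param frame_interval_s Frame interval in seconds; inferred from `t_s`
#'   when omitted.
#' @return An object of class `trajectory` (a data frame).
#' @examples
#' tr <- as_trajectory(data.frame(frame = 0:3, t_s = (0:3) * 2e-5,
#'                                x_um = c(0, .1, .2, .3), y_um = 0))
#' frame_interval(tr)
#' @export
as_trajectory <- function(x, frame_interval_s = NULL) {
  stopifnot(is.data.frame(x))
  need <- c("frame", "t_s", "x_um", "y_um")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("trajectory is missing column(s): ", paste(miss, collapse = ", "))
  }
  x <- as.data.frame(x)
  if (nrow(x) < 2L) stop("a trajectory needs at least 2 frames")
  if (any(!is.finite(x$x_um)) || any(!is.finite(x$y_um))) {
    stop("trajectory coordinates must be finite")
  }
  df <- diff(x$frame)
  if (any(df <= 0)) stop("frame indices must be strictly increasing")
  if (any(df != df[1])) stop("frame spacing must be uniform")
  if (is.null(frame_interval_s)) {
    dts <- diff(x$t_s)
    frame_interval_s <- stats::median(dts)
    if (any(abs(dts - frame_interval_s) > 1e-9 * max(frame_interval_s, 1e-12))) {
      stop("time stamps are not uniformly spaced; pass frame_interval_s explicitly")
    }
  }
  stop_if_not_scalar_num(frame_interval_s, "frame_interval_s", 0, strict = TRUE)
  attr(x, "frame_interval_s") <- frame_interval_s
  class(x) <- c("trajectory", "data.frame")
  x
}

new_trajectory <- function(frame, t_s, x_um, y_um, frame_interval_s,
                           true_x_um = NULL, true_y_um = NULL, state = NULL) {
  df <- data.frame(frame = frame, t_s = t_s, x_um = x_um, y_um = y_um)
  if (!is.null(true_x_um)) df$true_x_um <- true_x_um
  if (!is.null(true_y_um)) df$true_y_um <- true_y_um
  if (!is.null(state)) df$state <- state
  as_trajectory(df, frame_interval_s = frame_interval_s)
}

#' @rdname as_trajectory
#' @param traj A `trajectory`.
#' @export
frame_interval <- function(traj) {
  attr(traj, "frame_interval_s") %||% stats::median(diff(traj$t_s))
}

#' @export
print.trajectory <- function(x, ...) {
  dt <- frame_interval(x)
  cat(sprintf("Trajectory: %d frames, dt = %.3g s (%.3g s total)\n",
              nrow(x), dt, (nrow(x) - 1) * dt))
  if ("state" %in% names(x)) {
    tab <- table(x$state)
    cat("  states:", paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n")
  }
  print(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat(sprintf("  ... %d more rows\n", nrow(x) - 4L))
  invisible(x)
}

#' @export
plot.trajectory <- function(x, ..., asp = 1, type = "l") {
  graphics::plot(x$x_um, x$y_um, asp = asp, type = type,
                 xlab = expression(x ~ (mu * m)), ylab = expression(y ~ (mu * m)), ...)
  invisible(x)
}

#' Read and write trajectory CSV files
#'
#' The on-disk format has a mandatory header
#' `frame,t_s,x_um,y_um[,true_x_um,true_y_um,state]` with `.` as the decimal
#' separator.
#'
#' @param path File path.
#' @param traj A `trajectory`.
#' @return `read_trajectory_csv()` returns a `trajectory`;
#'   `write_trajectory_csv()` returns `path` invisibly.
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_trajectory(df)
}

#' @rdname read_trajectory_csv
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Downsample a trajectory in time
#'
#' Keeps every `factor`-th frame, emulating acquisition at a lower frame rate
#' (e.g. 50 kHz data re-analysed at 1 kHz with `factor = 50`). True positions
#' and state labels, when present, are carried along; observed positions are
#' simply subsampled (no re-blurring).
#'
#' @param traj A `trajectory`.
#' @param factor Integer >= 1.
#' @return A `trajectory` with frame interval `factor * frame_interval(traj)`.
#' @export
downsample_trajectory <- function(traj, factor) {
  stopifnot(factor >= 1, factor == round(factor))
  idx <- seq(1L, nrow(traj), by = as.integer(factor))
  out <- as.data.frame(traj)[idx, , drop = FALSE]
  out$frame <- seq_len(nrow(out)) - 1L
  out$t_s <- out$frame * frame_interval(traj) * factor
  rownames(out) <- NULL
  as_trajectory(out, frame_interval_s = frame_interval(traj) * factor)
}
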
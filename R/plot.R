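# Base-graphics helpers: force curve, processed retract with events,
# rupture-force histogram, velocity series.

#' @export
plot.force_curve <- function(x, ...) {
  k <- x$metadata$spring_constant_k
  app <- x$segment == "approach"; ret <- x$segment == "retract"
  graphics::plot(x$z_position[app], k * x$deflection[app], type = "l",
                 col = "firebrick", xlab = "piezo position (nm)",
                 ylab = "force (pN)",
                 main = x$metadata$curve_id,
                 xlim = range(x$z_position),
                 ylim = range(k * x$deflection), ...)
  graphics::lines(x$z_position[ret], k * x$deflection[ret], col = "steelblue")
  graphics::legend("topleft", c("approach", "retract"), lty = 1,
                   col = c("firebrick", "steelblue"), bty = "n")
  invisible(x)
}

#' @export
plot.processed_curve <- function(x, events = NULL, ...) {
  if (is.null(x$separation))
    stop("plot.processed_curve: separation axis missing; use process_curve()")
  graphics::plot(x$separation, x$force, type = "l", col = "steelblue",
                 xlab = "tip-sample separation (nm)", ylab = "force (pN)",
                 main = x$metadata$curve_id, ...)
  graphics::abline(h = 0, col = "grey60", lty = 3)
  if (!is.null(events) && nrow(events)) {
    cols <- ifelse(events$class == "jump", "firebrick", "darkorange")
    graphics::points(events$separation_nm,
                     -events$force_pN, pch = 19, col = cols)
    graphics::legend("bottomright", c("jump", "tether"), pch = 19,
                     col = c("firebrick", "darkorange"), bty = "n")
  }
  invisible(x)
}

#' @export
plot.condition_summary <- function(x, ...) {
  if (x$n == 0) stop("plot.condition_summary: empty summary")
  graphics::barplot(x$histogram$counts,
                    names.arg = utils::head(x$histogram$breaks, -1),
                    space = 0, col = "indianred",
                    xlab = "rupture force (pN)", ylab = "count",
                    main = sprintf("%s / %s @ %s um/s (n = %d)",
                                   x$condition_label, x$treatment_label,
                                   format(x$velocity_v), x$n), ...)
  invisible(x)
}

#' @export
plot.velocity_series <- function(x, ...) {
  graphics::plot(x$velocities, x$medians, pch = 19,
                 xlab = "pulling velocity (um/s)",
                 ylab = "median rupture force (pN)", ...)
  graphics::abline(x$intercept, x$slope, col = "steelblue")
  invisible(x)
}
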
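#' @title Angular coverage ("suckerotopy") statistics
#' @name coverage
#' @description
#' The fraction of the circle around a sucker attributable to each group
#' of nerve tips (ExA vs InA). Tips are centered on their centroid,
#' projected to the transverse plane, normalized to the unit circle, and
#' the circle is partitioned among groups with boundaries at the circular
#' midpoints between adjacent differently-labelled tips. The partition is
#' equivalent to assigning every angle to the group of its nearest tip in
#' circular distance, so the per-group extents always sum to 360 degrees.
NULL

#' Center tips and normalize to the unit circle
#'
#' Translates the tips so their centroid is at the origin, drops the
#' projection-axis coordinate (proximal-distal by default), and scales
#' each remaining 2D vector to magnitude 1, creating a circle of tips.
#'
#' When the circle center is known independently (synthetic data, or an
#' anatomically determined sucker center), pass it as `center`; the
#' default is the tip centroid, which for strongly asymmetric tip clouds
#' sits away from the circle center and distorts the angular fractions.
#'
#' @param tips a `tip_set` (see [tip_set()] / [extract_tips()]).
#' @param center optional known 3D center; default `NULL` uses the tip
#'   centroid.
#' @return the `tip_set` with columns `px`, `py` (unit-circle positions)
#'   and `angle_deg` added; attribute `unit_circle` set.
#' @export
center_and_normalize <- function(tips, center = NULL) {
  stopifnot(inherits(tips, "tip_set"))
  if (nrow(tips) < 2L) stop("need at least 2 tips to form a circle")
  axis <- attr(tips, "projection_axis")
  keep <- setdiff(c("x", "y", "z"), axis)
  c3 <- if (is.null(center)) c(mean(tips$x), mean(tips$y), mean(tips$z))
        else { stopifnot(length(center) == 3L); as.numeric(center) }
  u <- tips[[keep[1]]] - c3[match(keep[1], c("x", "y", "z"))]
  v <- tips[[keep[2]]] - c3[match(keep[2], c("x", "y", "z"))]
  mag <- sqrt(u^2 + v^2)
  if (all(mag == 0)) stop("all tips coincide with their centroid")
  if (any(mag == 0)) {
    bad <- which(mag == 0)[1L]
    stop("tip ", bad, " (trace '", tips$trace[bad], "') coincides with ",
         "the tip centroid in the projection plane; its angle is undefined")
  }
  tips$px <- u / mag
  tips$py <- v / mag
  tips$angle_deg <- (atan2(tips$py, tips$px) * 180 / pi) %% 360
  attr(tips, "unit_circle") <- TRUE
  tips
}

#' Partition the circle among tip groups
#'
#' Sorts tip angles on `[0, 360)` and places a group boundary at the
#' circular midpoint between each adjacent pair of differently-labelled
#' tips. Each group's angular extent is the total arc it owns; extents sum
#' to 360 degrees and, divided by 360, give the fraction of the sucker
#' each ANC side covers.
#'
#' @param tips a `tip_set` in unit-circle form (see
#'   [center_and_normalize()]); a plain `tip_set` is converted first.
#' @return object of class `coverage_result`: data.frames `extents`
#'   (group, extent_deg, fraction, n_tips), `tip_angles` and the sorted
#'   `boundaries` in degrees.
#' @export
angular_coverage <- function(tips) {
  stopifnot(inherits(tips, "tip_set"))
  if (nrow(tips) == 0L) stop("empty tip set")
  if (!isTRUE(attr(tips, "unit_circle"))) tips <- center_and_normalize(tips)
  ord <- order(tips$angle_deg)
  ang <- tips$angle_deg[ord]
  grp <- as.character(tips$group[ord])
  n <- length(ang)
  groups <- unique(grp)
  if (length(groups) == 1L) {
    warning("only one tip group present; it covers the whole circle")
    res <- data.frame(group = groups, extent_deg = 360, fraction = 1,
                      n_tips = n, stringsAsFactors = FALSE)
    return(structure(list(extents = res, boundaries = numeric(0),
                          tip_angles = data.frame(angle_deg = ang,
                                                  group = grp)),
                     class = "coverage_result"))
  }
  ## arc owned by tip i: from the midpoint toward its predecessor to the
  ## midpoint toward its successor (circular)
  nxt <- c(2:n, 1L)
  gap_after <- (ang[nxt] - ang) %% 360        # gap i -> i+1
  ## a full-circle ambiguity only when all tips share one angle
  if (all(gap_after == 0)) gap_after[] <- 360 / n
  owned <- (c(gap_after[n], gap_after[-n]) + gap_after) / 2
  extents <- tapply(owned, grp, sum)
  boundaries <- ((ang + gap_after / 2) %% 360)[grp[nxt] != grp]
  res <- data.frame(group = names(extents),
                    extent_deg = as.numeric(extents),
                    fraction = as.numeric(extents) / 360,
                    n_tips = as.integer(table(grp)[names(extents)]),
                    stringsAsFactors = FALSE)
  res <- res[order(-res$extent_deg), ]
  rownames(res) <- NULL
  structure(
    list(extents = res, boundaries = sort(boundaries),
         tip_angles = data.frame(angle_deg = ang, group = grp,
                                 stringsAsFactors = FALSE)),
    class = "coverage_result"
  )
}

#' @export
print.coverage_result <- function(x, ...) {
  cat("<coverage_result>\n")
  e <- x$extents
  for (i in seq_len(nrow(e))) {
    cat(sprintf("  %s: %.1f%% (%.1f deg, %d tips)\n", e$group[i],
                100 * e$fraction[i], e$extent_deg[i], e$n_tips[i]))
  }
  if (length(x$boundaries) > 0L) {
    cat("  boundaries (deg):",
        paste(format(x$boundaries, digits = 4), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Summary record of a coverage partition
#'
#' Formats a `coverage_result` the way the sucker-coverage figures report
#' it: per-group percentage of the circle rounded to 0.1, boundary angles
#' and tip counts, plus a one-line text summary such as
#' `"ExA 68.0%, InA 32.0%"`.
#'
#' @param result a `coverage_result`.
#' @return list with `percent` (named, rounded to 0.1), `extent_deg`,
#'   `n_tips`, `boundaries_deg`, `text`.
#' @export
coverage_report <- function(result) {
  stopifnot(inherits(result, "coverage_result"))
  e <- result$extents
  pct <- round(100 * e$fraction, 1)
  names(pct) <- e$group
  list(
    percent = pct,
    extent_deg = stats::setNames(e$extent_deg, e$group),
    n_tips = stats::setNames(e$n_tips, e$group),
    boundaries_deg = result$boundaries,
    text = paste(sprintf("%s %.1f%%", e$group, pct), collapse = ", ")
  )
}

#' Polar scatter of tip angles
#'
#' Draws the unit-circle tip distribution colored by group, with the
#' group boundaries, using base graphics.
#'
#' @param result a `coverage_result`.
#' @param ... passed to [graphics::plot()].
#' @return `result`, invisibly.
#' @export
plot_coverage <- function(result, ...) {
  stopifnot(inherits(result, "coverage_result"))
  ta <- result$tip_angles
  th <- ta$angle_deg * pi / 180
  cols <- stats::setNames(seq_along(unique(ta$group)) + 1,
                          unique(ta$group))
  graphics::plot(cos(th), sin(th), col = cols[ta$group], pch = 19,
                 asp = 1, xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3),
                 xlab = "", ylab = "", axes = FALSE, ...)
  phi <- seq(0, 2 * pi, length.out = 256)
  graphics::lines(cos(phi), sin(phi), col = "grey70")
  for (b in result$boundaries) {
    graphics::segments(0, 0, 1.2 * cos(b * pi / 180),
                       1.2 * sin(b * pi / 180), lty = 2, col = "grey40")
  }
  graphics::legend("topright", legend = names(cols), col = cols, pch = 19,
                   bty = "n")
  invisible(result)
}
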
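#' @title Average nerve trajectory
#' @name trajectory
#' @description
#' The average trajectory of a nerve summarizes its exit direction: a
#' vector from the root of the trace (the nerve's ANC exit point) to the
#' center of the traced process.
NULL

#' Average trajectory vector of a trace
#'
#' With `weighting = "nodes"` (default) the center is the unweighted mean
#' of all node coordinates, root included, matching a centroid taken over
#' the tracer's point list. With `weighting = "arc_length"` the center is
#' the line-density centroid of the polyline (each edge contributes its
#' midpoint weighted by its length), which is robust to uneven node
#' density in manual traces.
#'
#' @param trace a `neurite_trace` with at least 2 nodes.
#' @param weighting `"nodes"` or `"arc_length"`.
#' @return object of class `trajectory_vector` with fields `origin`,
#'   `vector`, `magnitude`, `group`, `trace`, `norm_length`.
#' @export
average_trajectory <- function(trace, weighting = c("nodes", "arc_length")) {
  validate_trace(trace)
  weighting <- match.arg(weighting)
  nd <- trace$nodes
  if (nrow(nd) < 2L) {
    stop("trace '", trace$name, "' has fewer than 2 nodes; the average ",
         "trajectory is degenerate")
  }
  ri <- which(nd$parent_id == -1L)
  origin <- c(nd$x[ri], nd$y[ri], nd$z[ri])
  if (weighting == "nodes") {
    center <- c(mean(nd$x), mean(nd$y), mean(nd$z))
  } else {
    pidx <- match(nd$parent_id, nd$node_id)
    child <- which(!is.na(pidx))
    par <- pidx[child]
    mx <- (nd$x[child] + nd$x[par]) / 2
    my <- (nd$y[child] + nd$y[par]) / 2
    mz <- (nd$z[child] + nd$z[par]) / 2
    w <- sqrt((nd$x[child] - nd$x[par])^2 + (nd$y[child] - nd$y[par])^2 +
                (nd$z[child] - nd$z[par])^2)
    if (sum(w) == 0) {
      stop("trace '", trace$name, "' has zero total edge length; ",
           "arc-length centroid is undefined")
    }
    center <- c(sum(w * mx), sum(w * my), sum(w * mz)) / sum(w)
  }
  v <- center - origin
  structure(
    list(origin = origin, vector = v, magnitude = sqrt(sum(v^2)),
         group = trace$group, trace = trace$name, norm_length = NA_real_),
    class = "trajectory_vector"
  )
}

#' @export
print.trajectory_vector <- function(x, ...) {
  cat("<trajectory_vector> trace '", x$trace, "' (", x$group, ")\n",
      sep = "")
  cat("  vector: (", paste(format(x$vector, digits = 5), collapse = ", "),
      "), |v| = ", format(x$magnitude, digits = 5),
      if (is.na(x$norm_length)) " um" else " (normalized)", "\n", sep = "")
  invisible(x)
}

#' Normalize trajectory vectors by a reference length
#'
#' Divides each vector by the reference length (the cable length of the
#' longest, skin-reaching nerve), so trajectories are comparable across
#' specimens on a 0-1 scale.
#'
#' @param vs list of `trajectory_vector` objects (or a single one).
#' @param norm_length positive reference length in um; alternatively a
#'   `trace_set`, in which case the reference is taken from its
#'   skin-reaching (else longest) trace.
#' @return list of normalized vectors.
#' @export
normalize_trajectories <- function(vs, norm_length) {
  if (inherits(vs, "trajectory_vector")) vs <- list(vs)
  if (inherits(norm_length, "trace_set")) {
    norm_length <- norm_length_of(norm_length)
  }
  if (!is.numeric(norm_length) || length(norm_length) != 1L ||
      norm_length <= 0) {
    stop("norm_length must be a single positive length in um")
  }
  lapply(vs, function(v) {
    v$vector <- v$vector / norm_length
    v$magnitude <- v$magnitude / norm_length
    v$norm_length <- norm_length
    v
  })
}

#' Tidy table of trajectory vectors
#'
#' @param vs list of `trajectory_vector` objects.
#' @return data.frame with columns `trace`, `group`, `vx`, `vy`, `vz`,
#'   `magnitude`.
#' @export
trajectory_table <- function(vs) {
  if (inherits(vs, "trajectory_vector")) vs <- list(vs)
  do.call(rbind, lapply(vs, function(v) {
    data.frame(trace = v$trace, group = v$group, vx = v$vector[1],
               vy = v$vector[2], vz = v$vector[3], magnitude = v$magnitude,
               stringsAsFactors = FALSE)
  }))
}
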
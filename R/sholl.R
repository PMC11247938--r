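#' @title Three-dimensional Sholl analysis
#' @name sholl
#' @description
#' Branching profiles of traced nerves: the number of intersections between
#' the nerve fiber and a series of concentric spheres centered at the nerve
#' exit point, with 10 um radius spacing by default. Crossings are counted
#' exactly from the quadratic of the squared distance along each
#' parent-child edge, so re-entrant edges contribute two crossings and
#' tangential touches contribute none.
NULL

## Edge geometry relative to a center: for an edge p -> q the squared
## distance along the segment is f(t) = a t^2 + b t + c, t in [0, 1].
edge_quadratics <- function(trace, center) {
  nd <- trace$nodes
  pidx <- match(nd$parent_id, nd$node_id)
  child <- which(!is.na(pidx))
  par <- pidx[child]
  px <- nd$x[par] - center[1]; py <- nd$y[par] - center[2]
  pz <- nd$z[par] - center[3]
  dx <- nd$x[child] - nd$x[par]; dy <- nd$y[child] - nd$y[par]
  dz <- nd$z[child] - nd$z[par]
  list(child = child, parent = par,
       a = dx^2 + dy^2 + dz^2,
       b = 2 * (px * dx + py * dy + pz * dz),
       c = px^2 + py^2 + pz^2)
}

## distance of every node from the center
node_distances <- function(trace, center) {
  nd <- trace$nodes
  sqrt((nd$x - center[1])^2 + (nd$y - center[2])^2 + (nd$z - center[3])^2)
}

## Crossings of the sphere of radius r:
##  * each simple root of f(t) - r^2 strictly inside (0,1) counts 1
##    (a re-entrant edge has two such roots and counts 2; a tangency has
##    a double root and counts 0);
##  * a node lying exactly on the sphere counts once iff the sign of
##    (distance - r) strictly before the node differs from its sign
##    immediately after along at least one child edge.
count_crossings <- function(eq, dists, node_rows, r) {
  tol <- shell_tol(r)
  on_shell <- abs(dists - r) <= tol    # indexed by node table row
  cc <- eq$c - r^2
  n <- 0L
  disc <- eq$b^2 - 4 * eq$a * cc
  pos <- which(disc > 0 & eq$a > 0)
  if (length(pos) > 0L) {
    sq <- sqrt(disc[pos])
    t1 <- (-eq$b[pos] - sq) / (2 * eq$a[pos])
    t2 <- (-eq$b[pos] + sq) / (2 * eq$a[pos])
    ## roots belonging to an endpoint that sits on the shell are handled
    ## by the node rule below, not as interior crossings
    lo <- ifelse(on_shell[eq$parent[pos]], 1e-9, 0)
    hi <- ifelse(on_shell[eq$child[pos]], 1 - 1e-9, 1)
    n <- n + sum(t1 > lo & t1 < hi) + sum(t2 > lo & t2 < hi)
  }
  ## node-on-sphere events: one crossing iff the sign strictly before the
  ## node differs from the sign immediately after along some child edge
  for (v in which(on_shell)) {
    ei <- which(eq$child == v)          # edge arriving at v
    if (length(ei) != 1L) next          # root: distance 0, never on a shell
    g <- 2 * eq$a[ei] + eq$b[ei]        # f'(1) on the incoming edge
    s_before <- if (g != 0) -sign(g) else 1
    kids <- which(eq$parent == v)       # edges leaving v
    if (length(kids) == 0L) next        # leaf touch: no sign change
    s_after <- ifelse(eq$b[kids] != 0, sign(eq$b[kids]), 1)
    if (any(s_after == -s_before)) n <- n + 1L
  }
  n
}

## absolute distance tolerance for deciding a node sits on a shell
shell_tol <- function(r) 1e-9 * (1 + abs(r))

#' Sholl intersection profile of a trace
#'
#' Counts, for each sphere radius, the crossings of that sphere by the
#' polyline edges of the trace. Radii are `step, 2*step, ...` extending to
#' the smallest multiple of `step` at or beyond the most distant node.
#'
#' @param trace a `neurite_trace`.
#' @param step shell spacing in um (default 10, the standard spacing).
#' @param center 3D point of the sphere centers; defaults to the trace
#'   root (the nerve's ANC exit point).
#' @return object of class `sholl_profile` with fields `radii`, `counts`,
#'   `center`, `step`, `trace`, `group`, `normalized`, `norm_length`.
#' @export
sholl_profile <- function(trace, step = 10, center = NULL) {
  validate_trace(trace)
  if (!is.numeric(step) || length(step) != 1L || step <= 0) {
    stop("step must be a single positive number of um")
  }
  nd <- trace$nodes
  if (is.null(center)) {
    ri <- which(nd$parent_id == -1L)
    center <- c(nd$x[ri], nd$y[ri], nd$z[ri])
  }
  stopifnot(length(center) == 3L)
  dists <- node_distances(trace, center)
  rmax <- max(dists)
  nshell <- max(1L, ceiling(rmax / step - 1e-12))
  radii <- step * seq_len(nshell)
  if (nrow(nd) == 1L) {
    counts <- integer(nshell)
  } else {
    eq <- edge_quadratics(trace, center)
    counts <- vapply(radii, function(r) count_crossings(eq, dists, NULL, r),
                     integer(1))
  }
  structure(
    list(radii = radii, counts = counts, center = center, step = step,
         trace = trace$name, group = trace$group, normalized = FALSE,
         norm_length = NA_real_),
    class = "sholl_profile"
  )
}

#' @export
print.sholl_profile <- function(x, ...) {
  cat("<sholl_profile> trace '", x$trace, "', ", length(x$radii),
      " shells, step ", x$step, if (x$normalized) " (normalized)" else " um",
      "\n", sep = "")
  print(data.frame(radius = x$radii, count = x$counts), row.names = FALSE)
  invisible(x)
}

#' Polynomial fit of a Sholl profile
#'
#' Ordinary (unweighted) least squares of intersection count on shell
#' radius with a degree-5 polynomial by default. Requires at least
#' `degree + 1` shells; the degree is never silently reduced.
#'
#' @param profile a `sholl_profile`.
#' @param degree polynomial degree (default 5).
#' @return object of class `sholl_fit` with ascending `coefficients`
#'   (intercept first), `degree`, `domain`, `fitted`, `residuals`.
#' @export
fit_profile <- function(profile, degree = 5L) {
  stopifnot(inherits(profile, "sholl_profile"))
  degree <- as.integer(degree)
  if (degree < 0L) stop("degree must be non-negative")
  ns <- length(profile$radii)
  if (ns < degree + 1L) {
    stop("profile has ", ns, " shells; a degree-", degree,
         " polynomial needs at least ", degree + 1L,
         " (degenerate fit refused)")
  }
  X <- outer(profile$radii, 0:degree, `^`)
  fit <- stats::lsfit(X, profile$counts, intercept = FALSE)
  coefs <- unname(fit$coefficients)
  fitted <- drop(X %*% coefs)
  structure(
    list(coefficients = coefs, degree = degree,
         domain = c(0, max(profile$radii)), radii = profile$radii,
         fitted = fitted, residuals = profile$counts - fitted,
         trace = profile$trace),
    class = "sholl_fit"
  )
}

#' Evaluate a Sholl polynomial fit
#'
#' @param object a `sholl_fit`.
#' @param newdata radii at which to evaluate (defaults to the fitted radii).
#' @param ... unused.
#' @return fitted intersection counts.
#' @export
predict.sholl_fit <- function(object, newdata = NULL, ...) {
  r <- if (is.null(newdata)) object$radii else newdata
  drop(outer(r, 0:object$degree, `^`) %*% object$coefficients)
}

#' @export
print.sholl_fit <- function(x, ...) {
  cat("<sholl_fit> degree", x$degree, "for trace '", x$trace, "'\n")
  cat("  coefficients (ascending):",
      paste(format(x$coefficients, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

#' Normalize Sholl radii to the longest nerve
#'
#' Divides each profile's radii by a common reference length so the
#' longest nerve, the nerve that reaches the skin, spans radius 1. Counts
#' are unchanged. If no trace carries the `reaches_skin` flag the maximum
#' cable length in the set is used instead, with a warning.
#'
#' @param profiles list of `sholl_profile` objects (one per trace in `ts`).
#' @param ts the `trace_set` the profiles came from.
#' @return list of normalized profiles, same order.
#' @export
normalize_profiles <- function(profiles, ts) {
  if (inherits(profiles, "sholl_profile")) profiles <- list(profiles)
  stopifnot(inherits(ts, "trace_set"))
  L <- norm_length_of(ts)
  lapply(profiles, function(p) {
    p$radii <- p$radii / L
    p$normalized <- TRUE
    p$norm_length <- L
    p
  })
}

#' Undo Sholl radius normalization
#'
#' @param profiles list of normalized `sholl_profile` objects.
#' @return profiles with radii restored to um.
#' @export
denormalize_profiles <- function(profiles) {
  if (inherits(profiles, "sholl_profile")) profiles <- list(profiles)
  lapply(profiles, function(p) {
    if (!isTRUE(p$normalized)) return(p)
    p$radii <- p$radii * p$norm_length
    p$normalized <- FALSE
    p$norm_length <- NA_real_
    p
  })
}

## reference length for normalization: the flagged skin-reaching nerve
## (longest of them if several), else the longest nerve overall
norm_length_of <- function(ts) {
  lens <- vapply(ts$traces, path_length, numeric(1))
  skin <- vapply(ts$traces, function(t) isTRUE(t$reaches_skin), logical(1))
  if (any(skin)) {
    L <- max(lens[skin])
  } else {
    warning("no trace flagged reaches_skin; normalizing by the longest ",
            "path length in the set")
    L <- max(lens)
  }
  if (L <= 0) stop("normalization length is zero")
  L
}

#' Tidy table of Sholl profiles
#'
#' @param profiles list of `sholl_profile` objects.
#' @return data.frame with columns `trace`, `group`, `radius`, `count`.
#' @export
sholl_table <- function(profiles) {
  if (inherits(profiles, "sholl_profile")) profiles <- list(profiles)
  do.call(rbind, lapply(profiles, function(p) {
    data.frame(trace = p$trace, group = p$group, radius = p$radii,
               count = p$counts, stringsAsFactors = FALSE)
  }))
}
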
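#' @title Synthetic data generators
#' @name synthetic
#' @description
#' Generators for every input the pipeline consumes: rooted branching
#' trees with oracle Sholl profiles, labelled tip sets drawn from known
#' angular arcs, segment-measurement tables with a proximal-distal taper
#' and an ExA-InA width offset, and blob images with known nuclei counts.
#' Each generator is a pure function of its parameters and a single
#' integer seed, threaded through a named pseudo-random stream so adding
#' a generator never perturbs existing fixtures, and each emits
#' machine-readable ground truth.
NULL

## run expr under a deterministic per-stream seed, restoring the caller's
## RNG state afterwards
with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  codes <- utf8ToInt(stream)
  offset <- sum(codes * seq_along(codes)) %% 100000L
  set.seed((abs(as.integer(seed)) %% 100000L) * 19937L + offset)
  force(expr)
}

runit3 <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

#' Dense-resampling Sholl oracle
#'
#' Reference implementation of the intersection profile by brute force:
#' each edge is sampled every `sample_step` um and crossings are counted
#' as sign changes of (distance - radius) between consecutive samples
#' within an edge. Nodes lying exactly on a shell are resolved by the
#' sign of the nearest samples on the incoming and outgoing edges (one
#' crossing iff some outgoing side has the opposite sign). Slow but
#' independent of the quadratic-root computation in [sholl_profile()].
#'
#' @param trace a `neurite_trace`.
#' @param step shell spacing in um.
#' @param center sphere center; defaults to the trace root.
#' @param sample_step resampling interval in um (default 0.01).
#' @return a `sholl_profile`.
#' @export
sholl_profile_dense <- function(trace, step = 10, center = NULL,
                                sample_step = 0.01) {
  validate_trace(trace)
  nd <- trace$nodes
  if (is.null(center)) {
    ri <- which(nd$parent_id == -1L)
    center <- c(nd$x[ri], nd$y[ri], nd$z[ri])
  }
  dists <- node_distances(trace, center)
  rmax <- max(dists)
  nshell <- max(1L, ceiling(rmax / step - 1e-12))
  radii <- step * seq_len(nshell)
  pidx <- match(nd$parent_id, nd$node_id)
  child <- which(!is.na(pidx))
  if (length(child) == 0L) {
    counts <- integer(nshell)
  } else {
    par <- pidx[child]
    samp_d <- vector("list", length(child))
    for (e in seq_along(child)) {
      p <- c(nd$x[par[e]], nd$y[par[e]], nd$z[par[e]])
      q <- c(nd$x[child[e]], nd$y[child[e]], nd$z[child[e]])
      len <- sqrt(sum((q - p)^2))
      m <- max(2L, as.integer(ceiling(len / sample_step)) + 1L)
      t <- seq(0, 1, length.out = m)
      samp_d[[e]] <- sqrt((p[1] + t * (q[1] - p[1]) - center[1])^2 +
                            (p[2] + t * (q[2] - p[2]) - center[2])^2 +
                            (p[3] + t * (q[3] - p[3]) - center[3])^2)
    }
    d <- unlist(samp_d, use.names = FALSE)
    eid <- rep.int(seq_along(child), lengths(samp_d))
    counts <- vapply(radii, function(r) {
      tol <- shell_tol(r)
      s <- sign(d - r)
      s[abs(d - r) <= tol] <- 0          # samples at node-on-shell events
      nz <- s != 0
      sv <- s[nz]; ev <- eid[nz]
      nfl <- length(sv)
      flips <- if (nfl > 1L) {
        sum(sv[-1L] != sv[-nfl] & ev[-1L] == ev[-nfl])
      } else 0L
      ## node-on-shell events, resolved from the nearest off-shell samples
      on_shell <- which(abs(dists - r) <= tol)
      for (v in on_shell) {
        ein <- which(child == v)
        if (length(ein) != 1L) next       # root, never on a shell (r > 0)
        sin_ <- samp_d[[ein]] - r
        sin_ <- sign(sin_[abs(sin_) > tol])
        if (length(sin_) == 0L) next
        s_before <- sin_[length(sin_)]
        eouts <- which(par == v)
        if (length(eouts) == 0L) next     # leaf touch
        crossed <- FALSE
        for (eo in eouts) {
          so <- samp_d[[eo]] - r
          so <- sign(so[abs(so) > tol])
          if (length(so) > 0L && so[1L] == -s_before) crossed <- TRUE
        }
        if (crossed) flips <- flips + 1L
      }
      as.integer(flips)
    }, integer(1))
  }
  structure(
    list(radii = radii, counts = counts, center = center, step = step,
         trace = trace$name, group = trace$group, normalized = FALSE,
         norm_length = NA_real_),
    class = "sholl_profile"
  )
}

#' Generate a synthetic neurite trace with oracle Sholl ground truth
#'
#' Four kinds of rooted trees:
#' * `"straight"`: an unbranched path of total length `length` along +z;
#' * `"y_tree"`: a stem to radial distance `branch_radius`, bifurcating
#'   into two branches whose tips lie at radial distance `tip_radius`;
#' * `"random_tree"`: edges attached to uniformly chosen existing nodes,
#'   directions biased radially outward by `outward_bias`, lengths
#'   uniform on `edge_len`;
#' * `"radial_cone"`: `n_paths` unbranched paths whose every step
#'   direction is drawn uniformly within a cone of `half_angle` degrees
#'   about `axis` (so the whole trace, and its average trajectory, lies
#'   inside the cone).
#'
#' @param kind tree kind.
#' @param length total length (um) of a straight path.
#' @param n_nodes nodes in a straight path.
#' @param branch_radius,tip_radius,branch_angle y-tree geometry (um, um,
#'   degrees from the stem axis).
#' @param n_edges edges of a random tree.
#' @param edge_len `c(min, max)` edge length range (um).
#' @param outward_bias 0-1, radial bias of random-tree growth.
#' @param axis,half_angle,n_paths,steps_per_path radial-cone parameters.
#' @param step Sholl shell spacing for the emitted ground truth.
#' @param seed integer seed.
#' @param truth compute the dense-oracle ground-truth profile (default
#'   TRUE; disable for speed when only the geometry is needed).
#' @param name,group passed to [neurite_trace()].
#' @return list with `trace` (a `neurite_trace`), `sholl_truth` (a
#'   `sholl_profile` from [sholl_profile_dense()], or NULL) and `params`.
#' @export
gen_trace <- function(kind = c("random_tree", "straight", "y_tree",
                               "radial_cone"),
                      length = 95, n_nodes = 20,
                      branch_radius = 50, tip_radius = 100,
                      branch_angle = 30,
                      n_edges = 30, edge_len = c(5, 15),
                      outward_bias = 0.7,
                      axis = c(0, 0, 1), half_angle = 30, n_paths = 3,
                      steps_per_path = 8,
                      step = 10, seed = 0, truth = TRUE,
                      name = NULL, group = "untagged") {
  kind <- match.arg(kind)
  if (any(c(length, branch_radius, tip_radius, n_edges, edge_len,
            half_angle, steps_per_path) <= 0)) {
    stop("lengths, radii, counts and angles must be positive")
  }
  xyz <- with_stream(seed, paste0("trace/", kind), {
    switch(kind,
      straight = {
        z <- seq(0, length, length.out = max(2L, n_nodes))
        cbind(0, 0, z)
      },
      y_tree = {
        al <- branch_angle * pi / 180
        rbind(c(0, 0, 0),
              c(0, 0, branch_radius),
              tip_radius * c(sin(al), 0, cos(al)),
              tip_radius * c(-sin(al), 0, cos(al)))
      },
      random_tree = {
        pts <- matrix(0, nrow = n_edges + 1L, ncol = 3)
        parent <- integer(n_edges + 1L)
        parent[1L] <- -1L
        for (i in seq_len(n_edges)) {
          pi_ <- sample.int(i, 1L)
          p <- pts[pi_, ]
          rnd <- runit3()
          if (sum(p^2) == 0) {
            dir <- rnd
          } else {
            radial <- p / sqrt(sum(p^2))
            dir <- outward_bias * radial + (1 - outward_bias) * rnd
            dir <- dir / sqrt(sum(dir^2))
          }
          len <- stats::runif(1, edge_len[1], edge_len[2])
          pts[i + 1L, ] <- p + len * dir
          parent[i + 1L] <- pi_
        }
        attr(pts, "parent") <- parent
        pts
      },
      radial_cone = {
        ax <- axis / sqrt(sum(axis^2))
        ## orthonormal frame around the cone axis
        tmp <- if (abs(ax[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
        e1 <- tmp - sum(tmp * ax) * ax
        e1 <- e1 / sqrt(sum(e1^2))
        e2 <- c(ax[2] * e1[3] - ax[3] * e1[2],
                ax[3] * e1[1] - ax[1] * e1[3],
                ax[1] * e1[2] - ax[2] * e1[1])
        pts <- matrix(0, nrow = 1L + n_paths * steps_per_path, ncol = 3)
        parent <- integer(nrow(pts))
        parent[1L] <- -1L
        k <- 1L
        for (p in seq_len(n_paths)) {
          prev <- 1L
          for (s in seq_len(steps_per_path)) {
            ## uniform in solid angle within the cone
            cth <- stats::runif(1, cos(half_angle * pi / 180), 1)
            sth <- sqrt(1 - cth^2)
            phi <- stats::runif(1, 0, 2 * pi)
            dir <- cth * ax + sth * (cos(phi) * e1 + sin(phi) * e2)
            len <- stats::runif(1, edge_len[1], edge_len[2])
            k <- k + 1L
            pts[k, ] <- pts[prev, ] + len * dir
            parent[k] <- prev
            prev <- k
          }
        }
        attr(pts, "parent") <- parent
        pts
      }
    )
  })
  parent <- attr(xyz, "parent")
  n <- nrow(xyz)
  if (is.null(parent)) {
    if (kind == "y_tree") parent <- c(-1L, 1L, 2L, 2L)
    else parent <- c(-1L, seq_len(n - 1L))
  }
  parent_id <- ifelse(parent == -1L, -1L, parent)
  nodes <- data.frame(node_id = seq_len(n), type_code = 0L,
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      radius = 0.5, parent_id = as.integer(parent_id))
  if (is.null(name)) name <- paste0(kind, "_seed", seed)
  tr <- neurite_trace(nodes, name = name, group = group)
  truth_profile <- if (isTRUE(truth)) {
    sholl_profile_dense(tr, step = step)
  } else NULL
  list(trace = tr, sholl_truth = truth_profile,
       params = list(kind = kind, seed = seed, step = step))
}

#' Generate a labelled tip set from known angular arcs
#'
#' Tips for each group are drawn uniformly within that group's arc on the
#' circle, at unit-ish radius with Gaussian radial jitter, plus Gaussian
#' jitter along the projection axis. The emitted ground-truth fraction of
#' each group is its arc width plus half of each adjacent inter-group
#' gap, over 360 -- the large-sample limit of the midpoint partition.
#'
#' @param arcs named list of `c(start, end)` arcs in degrees with
#'   `0 <= start < end <= 360`, non-overlapping across groups; names are
#'   group labels. Default: ExA covering 65% of the circle, InA 35%.
#' @param n_per_group tips per group (default 200).
#' @param radial_jitter sd of the radius about 1.
#' @param axial_jitter sd along the projection axis.
#' @param projection_axis `"x"`, `"y"` or `"z"` (default `"z"`).
#' @param seed integer seed.
#' @return list with `tips` (a `tip_set`), `truth` (named fractions) and
#'   `params`.
#' @export
gen_tipset <- function(arcs = list(ExA = c(0, 234), InA = c(234, 360)),
                       n_per_group = 200, radial_jitter = 0.05,
                       axial_jitter = 0.1, projection_axis = "z",
                       seed = 0) {
  if (is.null(names(arcs)) || any(names(arcs) == "")) {
    stop("arcs must be a named list (names are group labels)")
  }
  am <- do.call(rbind, arcs)
  if (any(am[, 1] < 0) || any(am[, 2] > 360) || any(am[, 1] >= am[, 2])) {
    stop("each arc must satisfy 0 <= start < end <= 360")
  }
  ord <- order(am[, 1])
  am <- am[ord, , drop = FALSE]
  grp <- names(arcs)[ord]
  k <- nrow(am)
  for (i in seq_len(k)) {
    j <- if (i == k) 1L else i + 1L
    gap <- if (i == k) (am[j, 1] + 360 - am[i, 2]) else am[j, 1] - am[i, 2]
    if (gap < 0) {
      stop("arcs for groups '", grp[i], "' and '", grp[j],
           "' overlap on the circle")
    }
  }
  ## truth: arc width + half of each flanking gap, over 360
  widths <- am[, 2] - am[, 1]
  gap_after <- vapply(seq_len(k), function(i) {
    j <- if (i == k) 1L else i + 1L
    (am[j, 1] - am[i, 2]) %% 360
  }, numeric(1))
  gap_before <- gap_after[c(k, seq_len(k - 1L))]
  share <- widths + gap_before / 2 + gap_after / 2
  tt <- tapply(share, grp, sum) / 360
  truth <- stats::setNames(as.numeric(tt), names(tt))
  df <- with_stream(seed, "tipset", {
    rows <- lapply(seq_len(k), function(i) {
      th <- stats::runif(n_per_group, am[i, 1], am[i, 2]) * pi / 180
      r <- 1 + stats::rnorm(n_per_group, 0, radial_jitter)
      ax <- stats::rnorm(n_per_group, 0, axial_jitter)
      u <- r * cos(th); v <- r * sin(th)
      switch(projection_axis,
        z = data.frame(x = u, y = v, z = ax, group = grp[i]),
        y = data.frame(x = u, y = ax, z = v, group = grp[i]),
        x = data.frame(x = ax, y = u, z = v, group = grp[i]))
    })
    do.call(rbind, rows)
  })
  list(tips = tip_set(df, projection_axis = projection_axis),
       truth = truth[unique(grp)],
       params = list(arcs = arcs, n_per_group = n_per_group, seed = seed))
}

#' Generate a synthetic segment-measurement table
#'
#' Emulates the measured structure of the ANC cell body layer: segment
#' widths taper from proximal to distal, ExA segments are wider than InA,
#' cell density rises distally and is higher on InA, and segment counts
#' per sucker hold a constant target. Widths are
#' `base_width - taper * position + exa_offset * 1[ExA] + N(0, noise_sd)`
#' with position coded 0, 1, 2 for proximal, intermediate, distal.
#' Draws that would produce non-positive widths are resampled with a
#' warning. Generating parameters are returned for recovery tests.
#'
#' @param replicates measurements per (position, side, territory) cell;
#'   default 12, giving the standard n = 24 per (position, territory)
#'   condition after pooling sides.
#' @param base_width proximal ExA-free baseline width (um).
#' @param taper width decrease per position step (um).
#' @param exa_offset extra width of ExA segments (um).
#' @param noise_sd measurement noise sd (um).
#' @param n_suckers suckers spanned by each segment count (default 6).
#' @param segs_per_sucker target segments per sucker (default 7.5).
#' @param count_noise_sd sd of the segment-count noise (default 0).
#' @param density_base,density_pos_step,density_ina_offset nuclei per
#'   um^2: baseline, increase per position step, extra density on InA.
#' @param acetabulum_base,acetabulum_taper sucker width baseline and
#'   taper (um).
#' @param arm_id arm identifier.
#' @param seed integer seed.
#' @return list with `segments` (a `segment_table`), `suckers`
#'   (data.frame of sucker records) and `params`.
#' @export
gen_segment_table <- function(replicates = 12, base_width = 50, taper = 10,
                              exa_offset = 8, noise_sd = 4,
                              n_suckers = 6, segs_per_sucker = 7.5,
                              count_noise_sd = 0,
                              density_base = 0.008,
                              density_pos_step = 0.002,
                              density_ina_offset = 0.001,
                              acetabulum_base = 400,
                              acetabulum_taper = 100,
                              arm_id = "arm1", seed = 0) {
  if (replicates < 1) stop("replicates must be at least 1")
  with_stream(seed, "segment_table", {
    grid <- expand.grid(position = POSITIONS,
                        side = c("anterior", "posterior"),
                        territory = c("ExA", "InA"),
                        rep = seq_len(replicates),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    posi <- match(grid$position, POSITIONS) - 1L
    mu <- base_width - taper * posi + exa_offset * (grid$territory == "ExA")
    w <- mu + stats::rnorm(nrow(grid), 0, noise_sd)
    bad <- which(w <= 0)
    if (length(bad) > 0L) {
      warning(length(bad), " width draw(s) were non-positive and were ",
              "resampled")
      for (i in bad) {
        while (w[i] <= 0) w[i] <- mu[i] + stats::rnorm(1, 0, noise_sd)
      }
    }
    height <- w * 1.2 + stats::rnorm(nrow(grid), 0, noise_sd)
    height[height <= 0] <- w[height <= 0]
    dens <- density_base + density_pos_step * posi +
      density_ina_offset * (grid$territory == "InA")
    patch_area <- w * 20                       # rectangle spanning the width
    nuclei <- stats::rpois(nrow(grid), dens * patch_area)
    segments <- segment_table(
      arm_id = arm_id, position = grid$position, side = grid$side,
      territory = grid$territory, width = w, height = height,
      nuclei_count = nuclei, patch_area = patch_area)
    target_total <- segs_per_sucker * n_suckers
    suckers <- do.call(rbind, lapply(seq_along(POSITIONS), function(pi_) {
      data.frame(
        arm_id = arm_id, position = POSITIONS[pi_],
        sucker_index = seq_len(n_suckers),
        acetabulum_width = pmax(
          1, acetabulum_base - acetabulum_taper * (pi_ - 1L) +
            stats::rnorm(n_suckers, 0, count_noise_sd * 10)),
        count_anterior = pmax(0, round(
          target_total + stats::rnorm(n_suckers, 0, count_noise_sd))),
        count_posterior = pmax(0, round(
          target_total + stats::rnorm(n_suckers, 0, count_noise_sd))),
        stringsAsFactors = FALSE)
    }))
    list(segments = segments, suckers = suckers,
         params = list(replicates = replicates, base_width = base_width,
                       taper = taper, exa_offset = exa_offset,
                       noise_sd = noise_sd, n_suckers = n_suckers,
                       segs_per_sucker = segs_per_sucker, seed = seed))
  })
}

#' Generate an image of disjoint bright blobs with known count
#'
#' Gaussian blobs of peak intensity 1 on a zero background, placed by
#' rejection sampling so that centers are at least `min_separation`
#' pixels apart (and `margin` pixels from the border), guaranteeing the
#' thresholded components stay disjoint. Ground-truth centers are
#' emitted in um.
#'
#' @param n_blobs number of blobs.
#' @param blob_sigma Gaussian sd in pixels (default 3).
#' @param image_size `c(rows, cols)` in pixels.
#' @param pixel_size um per pixel.
#' @param min_separation minimum center distance in pixels (default
#'   `8 * blob_sigma`).
#' @param margin border margin in pixels (default `4 * blob_sigma`).
#' @param seed integer seed.
#' @return list with `image` (a `nuclei_image`), `truth` (data.frame of
#'   centers, um) and `params`.
#' @export
gen_nuclei_image <- function(n_blobs = 5, blob_sigma = 3,
                             image_size = c(128, 128), pixel_size = 1,
                             min_separation = 8 * blob_sigma,
                             margin = 4 * blob_sigma, seed = 0) {
  if (n_blobs < 0) stop("n_blobs must be non-negative")
  nr <- image_size[1]; nc <- image_size[2]
  with_stream(seed, "nuclei_image", {
    centers <- matrix(numeric(0), ncol = 2)
    attempts <- 0L
    while (nrow(centers) < n_blobs) {
      attempts <- attempts + 1L
      if (attempts > 10000L) {
        stop("could not place ", n_blobs, " blobs with separation ",
             min_separation, " px in 10,000 attempts")
      }
      cand <- c(stats::runif(1, margin, nc - margin),
                stats::runif(1, margin, nr - margin))  # (x=col, y=row), px
      if (nrow(centers) > 0L) {
        dd <- sqrt((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2)
        if (min(dd) < min_separation) next
      }
      centers <- rbind(centers, cand)
    }
    px <- matrix(0, nr, nc)
    if (n_blobs > 0L) {
      xs <- matrix(rep(seq_len(nc) - 0.5, each = nr), nr, nc)
      ys <- matrix(rep(seq_len(nr) - 0.5, times = nc), nr, nc)
      for (i in seq_len(n_blobs)) {
        px <- px + exp(-((xs - centers[i, 1])^2 + (ys - centers[i, 2])^2) /
                         (2 * blob_sigma^2))
      }
      px <- pmin(px, 1)
    }
    truth <- data.frame(x = centers[, 1] * pixel_size,
                        y = centers[, 2] * pixel_size)
    list(image = nuclei_image(px, pixel_size = pixel_size),
         truth = truth,
         params = list(n_blobs = n_blobs, blob_sigma = blob_sigma,
                       image_size = image_size, seed = seed))
  })
}
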
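# fixtures and independent oracles shared across the suite; everything is
# built in code, nothing is read from disk

# trace from a coordinate matrix and parent vector (parent -1 = root)
make_trace <- function(xyz, parent, name = "fix", group = "untagged",
                       reaches_skin = FALSE) {
  if (!is.matrix(xyz)) xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  neurite_trace(
    data.frame(node_id = seq_len(nrow(xyz)), type_code = 0L,
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], radius = 0.5,
               parent_id = as.integer(parent)),
    name = name, group = group, reaches_skin = reaches_skin)
}

straight_trace <- function(zs = c(0, 5, 10), name = "straight") {
  make_trace(cbind(0, 0, zs), c(-1L, seq_along(zs)[-length(zs)]),
             name = name)
}

# Y-tree: root -> (0,0,50), then children at (+-30, 0, 90); edges 50 + 2*50
y150_trace <- function(name = "y150") {
  make_trace(rbind(c(0, 0, 0), c(0, 0, 50), c(30, 0, 90), c(-30, 0, 90)),
             c(-1L, 1L, 2L, 2L), name = name)
}

# random rotation matrix (det +1) and translation
random_rigid <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = stats::rnorm(3, sd = 50))
}

transform_trace <- function(trace, R, t) {
  xyz <- as.matrix(trace$nodes[, c("x", "y", "z")]) %*% t(R)
  trace$nodes$x <- xyz[, 1] + t[1]
  trace$nodes$y <- xyz[, 2] + t[2]
  trace$nodes$z <- xyz[, 3] + t[3]
  trace
}

# independent leaf count: scan of the parent table by node degree
leaf_count_by_degree <- function(trace) {
  nd <- trace$nodes
  if (nrow(nd) == 1L) return(1L)
  outdeg <- table(factor(nd$parent_id, levels = nd$node_id))
  sum(outdeg == 0 & nd$parent_id != -1L)
}

# brute-force coverage oracle: assign grid angles to the nearest tip's
# group by circular distance; returns extents in degrees per group
grid_coverage <- function(angles, groups, n_grid = 36000L) {
  th <- (seq_len(n_grid) - 0.5) * 360 / n_grid
  dmat <- abs(outer(th, angles, `-`))
  dmat <- pmin(dmat %% 360, (-dmat) %% 360)
  nearest <- groups[apply(dmat, 1L, which.min)]
  counts <- table(factor(nearest, levels = unique(groups)))
  stats::setNames(as.numeric(counts) * 360 / n_grid, names(counts))
}

# unit-circle tip set straight from angles (degrees) and labels
tips_from_angles <- function(angles, groups) {
  ts <- tip_set(data.frame(x = cos(angles * pi / 180),
                           y = sin(angles * pi / 180),
                           z = 0, group = groups))
  center_and_normalize(ts, center = c(0, 0, 0))
}
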
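#' @title SWC neurite reconstructions
#' @name swc_io
#' @description
#' Readers, writers and validators for SWC-format neurite traces. One SWC
#' file holds one rooted tree: the reconstruction of a single nerve traced
#' from the axial nerve cord (ANC) outward. Group labels (ExA/InA for oral
#' nerves, aboral/central/oral for brachial nerves) are not part of SWC and
#' are attached from a sidecar mapping or a function argument.
NULL

#' Known group labels for traced nerves
#'
#' ExA/InA mark oral nerves by the external/internal side of the ANC they
#' arise from; aboral/central/oral classify nerves by exit position.
#' @export
TRACE_GROUPS <- c("ExA", "InA", "aboral", "central", "oral", "untagged")

#' Construct a neurite trace from a node table
#'
#' A `neurite_trace` is a rooted tree of 3D points with radii, the unit of
#' all nerve-level analysis. Coordinates are micrometres.
#'
#' @param nodes data.frame with columns `node_id`, `type_code`, `x`, `y`,
#'   `z`, `radius`, `parent_id` (parent `-1` marks the root).
#' @param name trace name (defaults to `"trace"`).
#' @param group one of [TRACE_GROUPS].
#' @param reaches_skin logical; whether this nerve reaches the skin (the
#'   longest nerve, used as the normalization reference).
#' @return object of class `neurite_trace`.
#' @export
neurite_trace <- function(nodes, name = "trace", group = "untagged",
                          reaches_skin = FALSE) {
  group <- match.arg(group, TRACE_GROUPS)
  required <- c("node_id", "type_code", "x", "y", "z", "radius", "parent_id")
  missing_cols <- setdiff(required, names(nodes))
  if (length(missing_cols) > 0L) {
    stop("node table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  nodes <- as.data.frame(nodes)[required]
  tr <- structure(
    list(name = as.character(name), nodes = nodes, group = group,
         reaches_skin = isTRUE(reaches_skin)),
    class = "neurite_trace"
  )
  validate_trace(tr)
  tr
}

#' Validate the tree structure of a neurite trace
#'
#' Checks node id uniqueness, the single-root condition, parent references,
#' and that the parent graph is one connected rooted tree (no cycles).
#' Child-before-parent node order is permitted.
#'
#' @param trace a `neurite_trace`.
#' @return the trace, invisibly; stops with a structural error otherwise.
#' @export
validate_trace <- function(trace) {
  nd <- trace$nodes
  if (nrow(nd) == 0L) stop("trace '", trace$name, "' has no nodes")
  if (anyDuplicated(nd$node_id)) {
    dup <- nd$node_id[duplicated(nd$node_id)][1L]
    stop("duplicate node_id ", dup, " in trace '", trace$name, "'")
  }
  if (any(nd$node_id <= 0)) stop("node_id values must be positive integers")
  if (any(nd$radius < 0)) stop("negative radius in trace '", trace$name, "'")
  roots <- which(nd$parent_id == -1L)
  if (length(roots) != 1L) {
    stop("trace '", trace$name, "' has ", length(roots),
         " roots; exactly one node must have parent_id -1")
  }
  nonroot <- nd$parent_id != -1L
  bad <- nonroot & !(nd$parent_id %in% nd$node_id)
  if (any(bad)) {
    stop("node ", nd$node_id[which(bad)[1L]], " in trace '", trace$name,
         "' references missing parent ", nd$parent_id[which(bad)[1L]])
  }
  if (any(nonroot & nd$parent_id == nd$node_id)) {
    stop("node ", nd$node_id[which(nd$parent_id == nd$node_id)[1L]],
         " is its own parent")
  }
  ## connectivity: BFS from the root over the child adjacency must reach all
  idx <- match(nd$parent_id, nd$node_id)  # NA for root
  children <- split(seq_len(nrow(nd)), idx)
  seen <- logical(nrow(nd))
  queue <- roots
  seen[queue] <- TRUE
  while (length(queue) > 0L) {
    kids <- unlist(children[as.character(queue)], use.names = FALSE)
    kids <- kids[!seen[kids]]
    seen[kids] <- TRUE
    queue <- kids
  }
  if (!all(seen)) {
    stop("trace '", trace$name, "' is not a single connected tree: node ",
         nd$node_id[which(!seen)[1L]], " is unreachable from the root ",
         "(cycle or disconnected component)")
  }
  invisible(trace)
}

#' @export
print.neurite_trace <- function(x, ...) {
  cat("<neurite_trace> '", x$name, "' (", x$group, ")\n", sep = "")
  cat("  nodes:", nrow(x$nodes),
      " tips:", length(tip_indices(x)),
      " path length:", format(path_length(x), digits = 6), "um\n")
  if (x$reaches_skin) cat("  reaches skin (normalization reference)\n")
  invisible(x)
}

#' Read an SWC reconstruction
#'
#' Accepts space- or tab-delimited 7-column SWC with `#` comment lines and
#' blank lines. Node ids need not be consecutive and nodes may appear
#' child-before-parent (two-pass parse). Coordinates are read at full
#' precision and assumed to be micrometres.
#'
#' @param path path to an SWC file.
#' @param group optional group label, one of [TRACE_GROUPS].
#' @param name trace name; defaults to the file name without extension.
#' @param reaches_skin logical flag, see [neurite_trace()].
#' @return a validated `neurite_trace`.
#' @export
read_swc <- function(path, group = "untagged", name = NULL,
                     reaches_skin = FALSE) {
  if (!file.exists(path)) stop("SWC file not found: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  body <- lines[keep]
  lineno <- which(keep)
  if (length(body) == 0L) stop("no data lines in SWC file: ", path)
  fields <- strsplit(trimws(body), "[ \t]+")
  nfield <- lengths(fields)
  if (any(nfield != 7L)) {
    i <- which(nfield != 7L)[1L]
    stop("malformed SWC line ", lineno[i], " in ", path, ": expected 7 ",
         "whitespace-separated fields, got ", nfield[i])
  }
  m <- suppressWarnings(
    matrix(as.numeric(unlist(fields)), ncol = 7L, byrow = TRUE))
  if (anyNA(m)) {
    i <- which(apply(is.na(m), 1L, any))[1L]
    stop("malformed SWC line ", lineno[i], " in ", path,
         ": non-numeric field")
  }
  nodes <- data.frame(
    node_id = as.integer(m[, 1L]), type_code = as.integer(m[, 2L]),
    x = m[, 3L], y = m[, 4L], z = m[, 5L], radius = m[, 6L],
    parent_id = as.integer(m[, 7L])
  )
  neurite_trace(nodes, name = name, group = group,
                reaches_skin = reaches_skin)
}

#' Write a trace to SWC
#'
#' Emits standard 7-column whitespace-delimited SWC. Coordinates are
#' written with enough digits that `read_swc(write_swc(t))` reproduces the
#' node table exactly.
#'
#' @param trace a `neurite_trace`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(trace, path) {
  validate_trace(trace)
  nd <- trace$nodes
  lines <- sprintf("%d %d %s %s %s %s %d",
                   nd$node_id, nd$type_code,
                   format(nd$x, digits = 17, trim = TRUE, scientific = FALSE),
                   format(nd$y, digits = 17, trim = TRUE, scientific = FALSE),
                   format(nd$z, digits = 17, trim = TRUE, scientific = FALSE),
                   format(nd$radius, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   nd$parent_id)
  ok <- tryCatch({
    writeLines(c(paste0("# SWC export: ", trace$name), lines), path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write SWC to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Bundle traces sharing an axis convention
#'
#' @param traces list of `neurite_trace` objects with unique names.
#' @param proximal_distal,oral_aboral which coordinate axis ("x","y","z")
#'   runs proximal-to-distal along the arm / oral-to-aboral across the ANC.
#' @return object of class `trace_set`.
#' @export
trace_set <- function(traces, proximal_distal = "z", oral_aboral = "y") {
  if (inherits(traces, "neurite_trace")) traces <- list(traces)
  stopifnot(all(vapply(traces, inherits, logical(1), "neurite_trace")))
  nms <- vapply(traces, function(t) t$name, character(1))
  if (anyDuplicated(nms)) {
    stop("trace names must be unique; duplicated: ",
         nms[duplicated(nms)][1L])
  }
  names(traces) <- nms
  structure(
    list(traces = traces,
         axis_convention = list(
           proximal_distal = match.arg(proximal_distal, c("x", "y", "z")),
           oral_aboral = match.arg(oral_aboral, c("x", "y", "z"))),
         units = "um"),
    class = "trace_set"
  )
}

#' @export
print.trace_set <- function(x, ...) {
  cat("<trace_set>", length(x$traces), "traces; proximal-distal axis:",
      x$axis_convention$proximal_distal, "\n")
  invisible(x)
}

#' Attach group labels and skin flags from a sidecar table
#'
#' SWC has no label field, so group membership travels in a sidecar CSV
#' with columns `trace`, `group` and optionally `reaches_skin`.
#'
#' @param ts a `trace_set`.
#' @param labels data.frame or path to a CSV.
#' @return the `trace_set` with labels applied.
#' @export
apply_labels <- function(ts, labels) {
  if (is.character(labels)) {
    labels <- utils::read.csv(labels, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("trace", "group") %in% names(labels)))
  for (i in seq_len(nrow(labels))) {
    nm <- labels$trace[i]
    if (!nm %in% names(ts$traces)) {
      warning("label row for unknown trace '", nm, "' ignored")
      next
    }
    ts$traces[[nm]]$group <- match.arg(labels$group[i], TRACE_GROUPS)
    if ("reaches_skin" %in% names(labels)) {
      ts$traces[[nm]]$reaches_skin <- isTRUE(as.logical(labels$reaches_skin[i]))
    }
  }
  ts
}

## row indices of leaf nodes; the root counts as a leaf only in a
## single-node trace
tip_indices <- function(trace) {
  nd <- trace$nodes
  if (nrow(nd) == 1L) return(1L)
  is_parent <- nd$node_id %in% nd$parent_id
  root <- nd$parent_id == -1L
  which(!is_parent & !root)
}

#' Total cable length of a trace
#'
#' Sum of Euclidean parent-child edge lengths, in micrometres. This is the
#' quantity used to identify the longest nerve for length normalization.
#'
#' @param trace a `neurite_trace`.
#' @return length in um (0 for a root-only trace).
#' @export
path_length <- function(trace) {
  nd <- trace$nodes
  pidx <- match(nd$parent_id, nd$node_id)
  has_parent <- !is.na(pidx)
  if (!any(has_parent)) return(0)
  dx <- nd$x[has_parent] - nd$x[pidx[has_parent]]
  dy <- nd$y[has_parent] - nd$y[pidx[has_parent]]
  dz <- nd$z[has_parent] - nd$z[pidx[has_parent]]
  sum(sqrt(dx^2 + dy^2 + dz^2))
}

#' Extract termination points of traced nerves
#'
#' Returns every leaf node of every trace, labelled with its trace's group.
#' These are the tips whose circular distribution around a sucker defines
#' the coverage statistic.
#'
#' @param ts a `trace_set` (or a single `neurite_trace`).
#' @param projection_axis axis dropped when the tips are later projected to
#'   a circle; defaults to the set's proximal-distal axis.
#' @return a `tip_set`: data.frame with columns `x`, `y`, `z`, `group`,
#'   `trace` and attribute `projection_axis`.
#' @export
extract_tips <- function(ts, projection_axis = NULL) {
  if (inherits(ts, "neurite_trace")) ts <- trace_set(list(ts))
  if (is.null(projection_axis)) {
    projection_axis <- ts$axis_convention$proximal_distal
  }
  rows <- lapply(ts$traces, function(tr) {
    idx <- tip_indices(tr)
    if (length(idx) == 0L) return(NULL)
    data.frame(x = tr$nodes$x[idx], y = tr$nodes$y[idx],
               z = tr$nodes$z[idx], group = tr$group, trace = tr$name,
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) {
    out <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      group = character(0), trace = character(0))
  } else {
    out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }
  tip_set(out, projection_axis = projection_axis)
}

#' Construct a tip set
#'
#' @param tips data.frame with columns `x`, `y`, `z`, `group` (and
#'   optionally `trace`).
#' @param projection_axis coordinate dropped when forming the sucker
#'   circle; default `"z"` (the proximal-distal axis).
#' @return object of classes `tip_set`/`data.frame`.
#' @export
tip_set <- function(tips, projection_axis = "z") {
  projection_axis <- match.arg(projection_axis, c("x", "y", "z"))
  tips <- as.data.frame(tips)
  stopifnot(all(c("x", "y", "z", "group") %in% names(tips)))
  if (!"trace" %in% names(tips)) {
    tips$trace <- rep(NA_character_, nrow(tips))
  }
  attr(tips, "projection_axis") <- projection_axis
  class(tips) <- c("tip_set", "data.frame")
  tips
}

#' Per-file SWC diagnostics
#'
#' Parses and validates each file, reporting node/tip counts and path
#' length or the parse/structural error. Backs `ancmorph validate`.
#'
#' @param paths character vector of SWC paths.
#' @return data.frame with one row per file.
#' @export
validate_swc_files <- function(paths) {
  rows <- lapply(paths, function(p) {
    res <- tryCatch(read_swc(p), error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(file = p, valid = FALSE, nodes = NA_integer_,
                 tips = NA_integer_, path_length = NA_real_,
                 message = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      data.frame(file = p, valid = TRUE, nodes = nrow(res$nodes),
                 tips = length(tip_indices(res)),
                 path_length = path_length(res), message = "",
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
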
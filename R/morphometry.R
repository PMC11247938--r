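#' @title Segment and sucker morphometry
#' @name morphometry
#' @description
#' Segment- and sucker-level measurements of the axial nerve cord cell
#' body layer: segments per sucker, segment widths with the two-step
#' ExA/InA averaging, cell density, cross-sectional area, and the
#' two-way ANOVA + Tukey post-hoc stage applied along the proximal-distal
#' axis and between ANC sides.
NULL

#' Positions along the proximal-distal axis
#' @export
POSITIONS <- c("proximal", "intermediate", "distal")

#' Build a table of segment measurements
#'
#' One row per measured segment with its factorial labels.
#'
#' @param arm_id,position,side,territory,width vectors of equal length:
#'   arm identifier; position in [POSITIONS]; side `"anterior"` or
#'   `"posterior"`; territory `"ExA"` or `"InA"`; width in um (> 0).
#' @param height optional segment height in um.
#' @param nuclei_count,patch_area optional DAPI nuclei count and patch
#'   area (um^2) for density.
#' @return data.frame of class `segment_table`.
#' @export
segment_table <- function(arm_id, position, side, territory, width,
                          height = NA_real_, nuclei_count = NA_integer_,
                          patch_area = NA_real_) {
  df <- data.frame(
    arm_id = as.character(arm_id),
    position = factor(position, levels = POSITIONS),
    side = factor(side, levels = c("anterior", "posterior")),
    territory = factor(territory, levels = c("ExA", "InA")),
    width = as.numeric(width), height = as.numeric(height),
    nuclei_count = as.integer(nuclei_count),
    patch_area = as.numeric(patch_area)
  )
  if (anyNA(df$position) || anyNA(df$side) || anyNA(df$territory)) {
    stop("position/side/territory contain values outside their levels")
  }
  if (any(df$width <= 0)) stop("segment widths must be positive")
  if (any(!is.na(df$nuclei_count) & is.na(df$patch_area))) {
    stop("patch_area required wherever nuclei_count is present")
  }
  if (any(!is.na(df$patch_area) & df$patch_area <= 0)) {
    stop("patch_area must be positive")
  }
  class(df) <- c("segment_table", "data.frame")
  df
}

#' Segments per sucker
#'
#' Segment counts taken along a run of suckers on the anterior and
#' posterior sides of the ANC are averaged together, then divided by the
#' number of suckers spanned (six in the standard protocol).
#'
#' @param count_anterior,count_posterior non-negative segment counts.
#' @param n_suckers number of suckers the counts span (default 6).
#' @return segments per sucker, `((anterior + posterior)/2) / n_suckers`.
#' @export
segments_per_sucker <- function(count_anterior, count_posterior,
                                n_suckers = 6) {
  if (any(n_suckers < 1)) stop("n_suckers must be at least 1")
  if (any(count_anterior < 0) || any(count_posterior < 0)) {
    stop("segment counts must be non-negative")
  }
  ((count_anterior + count_posterior) / 2) / n_suckers
}

#' Two-step width summary per position and territory
#'
#' Measurements on the anterior and posterior side are pooled (averaged
#' together) to get one mean per (position, territory); the total per
#' position is the mean of the ExA and InA means — not the pooled grand
#' mean, so an unbalanced territory does not tilt the total.
#'
#' @param records a `segment_table` (or data.frame with `position`,
#'   `territory`, `width`).
#' @param response measurement column to summarize (default `"width"`).
#' @return data.frame with columns `position`, `territory` (including the
#'   `"total"` rows), `mean`, `sem`, `n`. sem is sd/sqrt(n) with the n-1
#'   denominator; for `"total"` rows `mean` is the mean of the two
#'   territory means and `sem`/`n` are `NA`.
#' @export
summarize_widths <- function(records, response = "width") {
  stopifnot(all(c("position", "territory", response) %in% names(records)))
  v <- records[[response]]
  keep <- !is.na(v)
  records <- records[keep, , drop = FALSE]
  v <- v[keep]
  out <- list()
  for (pos in levels(factor(records$position))) {
    cell_means <- c()
    for (terr in c("ExA", "InA")) {
      sel <- records$position == pos & records$territory == terr
      if (!any(sel)) {
        warning("no ", response, " records for (", pos, ", ", terr,
                "); cell omitted")
        next
      }
      x <- v[sel]
      m <- mean(x)
      s <- if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        position = pos, territory = terr, mean = m, sem = s,
        n = length(x), stringsAsFactors = FALSE)
      cell_means[terr] <- m
    }
    if (length(cell_means) == 2L) {
      out[[length(out) + 1L]] <- data.frame(
        position = pos, territory = "total", mean = mean(cell_means),
        sem = NA_real_, n = NA_integer_, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$position <- factor(res$position, levels = POSITIONS)
  res[order(res$position), ]
}

#' Cell density from a nuclei count and patch area
#'
#' @param nuclei_count non-negative count of DAPI nuclei in the patch.
#' @param patch_area patch area in um^2 (> 0).
#' @return density in nuclei per um^2.
#' @export
cell_density <- function(nuclei_count, patch_area) {
  if (any(patch_area <= 0)) stop("patch_area must be positive")
  if (any(nuclei_count < 0)) stop("nuclei_count must be non-negative")
  nuclei_count / patch_area
}

#' Cross-sectional area of a segment
#'
#' Width is the extent along the proximal-distal axis, height the extent
#' perpendicular to it; the cross-section is treated as their product.
#'
#' @param width,height positive extents in um.
#' @return area in um^2.
#' @export
cross_sectional_area <- function(width, height) {
  if (any(width <= 0) || any(height <= 0)) {
    stop("width and height must be positive")
  }
  width * height
}

#' Two-way ANOVA with Tukey post-hoc comparisons
#'
#' Fits `response ~ factor_a * factor_b` and reports per-factor and
#' interaction F statistics and p-values, followed by Tukey HSD pairwise
#' comparisons using the pooled error term. Sums of squares are Type II,
#' which coincide with the classical balanced-design ANOVA when cell
#' counts are equal. If any factor cell has fewer than 2 replicates the
#' interaction term is refused (additive model fitted) with a warning.
#'
#' @param records data.frame of tidy measurements.
#' @param response name of the numeric response column.
#' @param factor_a,factor_b names of the two factor columns (e.g.
#'   `"position"` and `"territory"`).
#' @param alpha significance level (default 0.05).
#' @return object of class `anova_result`: `table` (term, df, F, p,
#'   significant), `tukey` (factor, contrast, diff, lwr, upr, p_adj,
#'   significant), `alpha`, `interaction_included`.
#' @export
two_way_anova_tukey <- function(records, response, factor_a, factor_b,
                                alpha = 0.05) {
  stopifnot(all(c(response, factor_a, factor_b) %in% names(records)))
  d <- data.frame(
    y = as.numeric(records[[response]]),
    A = factor(records[[factor_a]]),
    B = factor(records[[factor_b]])
  )
  d <- d[stats::complete.cases(d), , drop = FALSE]
  d$A <- droplevels(d$A); d$B <- droplevels(d$B)
  if (nlevels(d$A) < 2L || nlevels(d$B) < 2L) {
    stop("both factors need at least 2 observed levels")
  }
  cell_n <- table(d$A, d$B)
  interaction_ok <- all(cell_n >= 2L)
  if (!interaction_ok) {
    warning("some factor cells have fewer than 2 replicates; the ",
            "interaction term is refused and main effects only are tested")
    fml <- y ~ A + B
  } else {
    fml <- y ~ A * B
  }
  fit <- stats::aov(fml, data = d)
  a2 <- car::Anova(stats::lm(fml, data = d), type = 2)
  terms_map <- c(A = factor_a, B = factor_b, `A:B` = paste0(factor_a, ":",
                                                            factor_b))
  rn <- trimws(rownames(a2))
  keep <- rn %in% names(terms_map)
  tab <- data.frame(
    term = unname(terms_map[rn[keep]]),
    df = a2$Df[keep],
    F = a2$`F value`[keep],
    p = a2$`Pr(>F)`[keep],
    stringsAsFactors = FALSE
  )
  tab$significant <- tab$p < alpha
  tk <- stats::TukeyHSD(fit)
  tukey <- do.call(rbind, lapply(names(tk), function(w) {
    m <- tk[[w]]
    data.frame(factor = unname(terms_map[w]), contrast = rownames(m),
               diff = m[, "diff"], lwr = m[, "lwr"], upr = m[, "upr"],
               p_adj = m[, "p adj"], stringsAsFactors = FALSE,
               row.names = NULL)
  }))
  tukey$significant <- tukey$p_adj < alpha
  structure(
    list(table = tab, tukey = tukey, alpha = alpha,
         interaction_included = interaction_ok,
         factors = c(factor_a, factor_b), response = response),
    class = "anova_result"
  )
}

#' @export
print.anova_result <- function(x, ...) {
  cat("<anova_result> ", x$response, " ~ ", x$factors[1], " x ",
      x$factors[2], " (Type II SS, alpha = ", x$alpha, ")\n", sep = "")
  print(x$table, row.names = FALSE, digits = 4)
  cat("Tukey HSD:\n")
  print(x$tukey, row.names = FALSE, digits = 4)
  invisible(x)
}
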
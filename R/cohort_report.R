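# Cohort-level summaries: printed-percentage arithmetic, per-plate relative
# abundances, box statistics, pairwise diameter tests, and
# cumulative-completeness effective-genome estimates.

#' Percentage with half-away-from-zero rounding
#'
#' `100 * numerator / denominator`, rounded half away from zero to
#' `decimals` places (the convention of printed cohort figures; banker's
#' rounding is deliberately not used).
#'
#' @param numerator,denominator Counts; `denominator` must be positive.
#' @param decimals Number of decimal places.
#' @return The rounded percentage.
#' @export
pct <- function(numerator, denominator, decimals = 0) {
  if (any(denominator <= 0)) stop("denominator must be positive", call. = FALSE)
  x <- 100 * numerator / denominator
  f <- 10^decimals
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Per-plate group relative abundance
#'
#' Fractions of each group on one sort plate, optionally after a seeded
#' subsample without replacement (for rarefaction-style randomized sets).
#'
#' @param taxonomy Data frame with `sag_id`, `plate_id`, `group`.
#' @param plate_id Plate to summarize.
#' @param subsample_n Subsample size (`NULL` = no subsampling; must not
#'   exceed the plate size).
#' @param seed Integer seed for the subsample.
#' @return Named numeric vector of group fractions (over all groups present
#'   in `taxonomy`), summing to 1.
#' @export
plate_abundance <- function(taxonomy, plate_id, subsample_n = NULL, seed = 1) {
  rows <- taxonomy[taxonomy$plate_id == plate_id, , drop = FALSE]
  if (!nrow(rows)) stop("empty plate: ", plate_id, call. = FALSE)
  groups <- sort(unique(taxonomy$group))
  g <- rows$group
  if (!is.null(subsample_n)) {
    if (subsample_n > nrow(rows)) {
      stop("subsample_n exceeds plate size", call. = FALSE)
    }
    g <- with_seed(split_seed(seed, "plate", plate_id), {
      g[sample.int(length(g), subsample_n)]
    })
  }
  tab <- table(factor(g, levels = groups))
  stats::setNames(as.numeric(tab) / sum(tab), groups)
}

#' Box-plot statistics
#'
#' Quartiles by linear interpolation (type 7), whiskers at
#' `Q1 - 1.5 * IQR` and `Q3 + 1.5 * IQR`, and the values falling outside
#' the whiskers as outliers.
#'
#' @param values Numeric vector (n >= 1, `NA`s dropped).
#' @param group Label carried into the output.
#' @return List of class `box_stats`: `group`, `n`, `median`, `q1`, `q3`,
#'   `iqr`, `whisker_low`, `whisker_high`, `outliers`.
#' @export
boxstats <- function(values, group = "all") {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no values", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  structure(list(
    group = group, n = length(values), median = q[2], q1 = q[1], q3 = q[3],
    iqr = iqr, whisker_low = lo, whisker_high = hi,
    outliers = values[values < lo | values > hi]
  ), class = "box_stats")
}

#' @export
print.box_stats <- function(x, ...) {
  cat(sprintf("<box_stats> %s (n=%d): median %.3g [Q1 %.3g, Q3 %.3g], whiskers [%.3g, %.3g], %d outlier(s)\n",
              x$group, x$n, x$median, x$q1, x$q3, x$whisker_low,
              x$whisker_high, length(x$outliers)))
  invisible(x)
}

#' Cumulative-completeness effective genome count
#'
#' The sum of per-genome completeness fractions: how many randomly sampled
#' complete genomes a cohort of partial assemblies amounts to.
#'
#' @param completeness_pcts Completeness values in percent, each in
#'   `[0, 100]`.
#' @return The effective genome count (sum / 100).
#' @export
cumulative_complete_genomes <- function(completeness_pcts) {
  if (!length(completeness_pcts)) return(0)
  if (any(completeness_pcts < 0 | completeness_pcts > 100)) {
    stop("completeness values must lie in [0, 100]", call. = FALSE)
  }
  sum(completeness_pcts) / 100
}

#' Pairwise diameter tests across phyla
#'
#' Two-sided rank-sum test of cell diameters for every group pair (the
#' machinery behind "smaller than k of m phyla" statements), with the count
#' of pairs below `alpha`.
#'
#' @param diameter Numeric vector of cell diameters.
#' @param group Group label per cell.
#' @param alpha Significance level for the pair count.
#' @return List with `pairs` (data frame from [group_separation()]),
#'   `n_pairs`, `n_significant`.
#' @export
diameter_tests <- function(diameter, group, alpha = 0.05) {
  pairs <- group_separation(diameter, group)
  list(pairs = pairs, n_pairs = nrow(pairs),
       n_significant = sum(pairs$p_value < alpha))
}

#' Cohort summary table
#'
#' Per-group SAG counts, percent of the cohort, co-sort rates per detector,
#' and the cumulative-completeness effective genome count.
#'
#' @param truth Community truth table (needs `sag_id`, `group`,
#'   `completeness`; the first source's completeness is used).
#' @param flags Per-SAG flag table from [flag_cosorts()] rows (optional).
#' @return Data frame, one row per group plus a `total` row.
#' @export
cohort_summary <- function(truth, flags = NULL) {
  comp1 <- 100 * as.numeric(vapply(strsplit(truth$completeness, ","),
                                   function(x) x[1], ""))
  N <- nrow(truth)
  mk <- function(rows, label) {
    sid <- truth$sag_id[rows]
    f <- if (!is.null(flags)) flags[match(sid, flags$sag_id), ] else NULL
    data.frame(
      group = label,
      n_sags = length(sid),
      pct_of_total = pct(length(sid), N, 1),
      pct_cosort_markers = if (!is.null(f)) pct(sum(f$by_markers), length(sid), 1) else NA_real_,
      pct_cosort_ssu = if (!is.null(f)) pct(sum(f$by_ssu), length(sid), 1) else NA_real_,
      effective_complete_genomes = round(cumulative_complete_genomes(comp1[rows]), 1),
      stringsAsFactors = FALSE
    )
  }
  groups <- sort(unique(truth$group))
  out <- do.call(rbind, lapply(groups, function(g) mk(which(truth$group == g), g)))
  rbind(out, mk(seq_len(N), "total"))
}
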
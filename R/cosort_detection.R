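# Detection of heterogeneous DNA sources in SAGs: single-copy marker census
# (completeness/contamination), dual co-sort flags, and chi-square
# decomposition of cohort screen tables into per-group percent contributions.

#' Single-copy marker census
#'
#' Counts distinct and duplicated markers in a genome's annotated gene set.
#' Completeness is the percent of the marker universe found at least once;
#' contamination is the percent of extra copies relative to the universe
#' size (a simplification of lineage-aware collocation-based estimates, with
#' the same 10% threshold semantics downstream).
#'
#' @param marker_ids Character vector (multiset) of observed marker ids;
#'   `NA`s are ignored. Ids outside `marker_set` are dropped with a warning.
#' @param marker_set The marker universe (default: the 56-gene set).
#' @param genome_id Label carried into the output.
#' @return One-row data frame: `genome_id`, `found`, `duplicated`,
#'   `total_copies`, `completeness_pct`, `contamination_pct`.
#' @export
marker_census <- function(marker_ids, marker_set = marker_universe(),
                          genome_id = "genome") {
  marker_ids <- marker_ids[!is.na(marker_ids)]
  unknown <- setdiff(unique(marker_ids), marker_set)
  if (length(unknown)) {
    warning("ignoring marker ids outside the marker set: ",
            paste(unknown, collapse = ", "), call. = FALSE)
    marker_ids <- marker_ids[marker_ids %in% marker_set]
  }
  tab <- table(marker_ids)
  found <- length(tab)
  total <- sum(tab)
  data.frame(
    genome_id = genome_id,
    found = found,
    duplicated = sum(tab >= 2),
    total_copies = as.integer(total),
    completeness_pct = 100 * found / length(marker_set),
    contamination_pct = 100 * (total - found) / length(marker_set),
    stringsAsFactors = FALSE
  )
}

#' Flag a SAG as a putative co-sort
#'
#' Two independent detectors: `by_markers` fires when marker contamination
#' is at or above `contam_threshold` percent; `by_ssu` fires when the SAG
#' carries two near-full-length 16S genes (length strictly greater than
#' `min_ssu_len`, classifier confidence at or above `conf_floor`) assigned
#' to different phyla.
#'
#' @param census One-row data frame from [marker_census()].
#' @param ssu Data frame of classified 16S hits for this SAG (needs columns
#'   `length_nt`, `phylum`, `confidence`); may be empty or `NULL`.
#' @param min_ssu_len Length threshold in nt (hits must exceed it).
#' @param conf_floor Minimum bootstrap confidence (percent).
#' @param contam_threshold Marker contamination threshold (percent).
#' @param group Cohort group label for the SAG.
#' @return One-row data frame: `sag_id`, `group`, `by_markers`, `by_ssu`.
#' @export
flag_cosorts <- function(census, ssu = NULL, min_ssu_len = 1000,
                         conf_floor = 80, contam_threshold = 10,
                         group = "all") {
  by_markers <- census$contamination_pct >= contam_threshold
  by_ssu <- FALSE
  if (!is.null(ssu) && nrow(ssu)) {
    eligible <- ssu[ssu$length_nt > min_ssu_len & ssu$confidence >= conf_floor, ,
                    drop = FALSE]
    by_ssu <- nrow(eligible) >= 2 && length(unique(eligible$phylum)) >= 2
  }
  data.frame(sag_id = census$genome_id, group = group,
             by_markers = by_markers, by_ssu = by_ssu,
             stringsAsFactors = FALSE)
}

#' Chi-square decomposition of a cohort screen table
#'
#' Pearson chi-square test of independence with no continuity correction,
#' decomposed into per-cell Pearson residuals and percent contributions to
#' the statistic (`100 * residual^2 / X2`).
#'
#' @param observed Matrix of nonnegative integer counts, at least 2x2, with
#'   all row and column margins positive (groups x outcome, e.g. co-sort vs
#'   single).
#' @return An object of class `chisq_decomposition`: list with `observed`,
#'   `expected`, `statistic`, `df`, `p_value`, `residuals` (Pearson),
#'   `pct_contribution`.
#' @export
chisq_decomposition <- function(observed) {
  observed <- as.matrix(observed)
  if (nrow(observed) < 2 || ncol(observed) < 2) {
    stop("observed must have at least 2 rows and 2 columns", call. = FALSE)
  }
  if (any(observed < 0) || any(observed != round(observed))) {
    stop("observed must contain nonnegative integers", call. = FALSE)
  }
  rs <- rowSums(observed)
  cs <- colSums(observed)
  if (any(rs == 0) || any(cs == 0)) {
    stop("all row and column margins must be positive", call. = FALSE)
  }
  N <- sum(observed)
  expected <- outer(rs, cs) / N
  resid <- (observed - expected) / sqrt(expected)
  stat <- sum(resid^2)
  df <- (nrow(observed) - 1) * (ncol(observed) - 1)
  pct <- if (stat > 0) 100 * resid^2 / stat else resid * 0
  structure(list(
    observed = observed,
    expected = expected,
    statistic = stat,
    df = df,
    p_value = stats::pchisq(stat, df, lower.tail = FALSE),
    residuals = resid,
    pct_contribution = pct
  ), class = "chisq_decomposition")
}

#' @export
print.chisq_decomposition <- function(x, ...) {
  cat(sprintf("Chi-square decomposition: X2 = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  cat("Percent contribution per cell:\n")
  print(round(x$pct_contribution, 2))
  invisible(x)
}

#' Cohort-level co-sort screen
#'
#' Runs the marker census and both co-sort detectors over every SAG of a
#' community, and decomposes the resulting group x {co-sort, single} table
#' for each detector.
#'
#' @param community A `sag_community`.
#' @param detector `"by_markers"` or `"by_ssu"` for the decomposition table.
#' @param ssu Optional precomputed classified 16S table (as from
#'   [classify_assembly_ssu()] rbound over SAGs, with a `sag_id` column);
#'   if `NULL` the 16S detector runs from scratch.
#' @param min_ssu_len,conf_floor,contam_threshold Passed to [flag_cosorts()].
#' @param seed Seed for the 16S classifier bootstrap.
#' @return List with `census` (per-SAG), `flags` (per-SAG), `table`
#'   (groups x {cosort, single}), `decomposition` (or `NULL` when a margin is
#'   zero).
#' @export
cosort_screen <- function(community, detector = c("by_markers", "by_ssu"),
                          ssu = NULL, min_ssu_len = 1000, conf_floor = 80,
                          contam_threshold = 10, seed = 1) {
  detector <- match.arg(detector)
  ann <- community$annotations
  truth <- community$truth

  if (is.null(ssu) && detector == "by_ssu") {
    ssu <- do.call(rbind, lapply(community$sags, function(s) {
      classify_assembly_ssu(s, community$refdb, min_len = min_ssu_len,
                            seed = split_seed(seed, "ssu", s$sag_id))
    }))
  }

  rows <- lapply(truth$sag_id, function(sid) {
    mk <- ann$marker_id[ann$sag_id == sid]
    cen <- marker_census(mk, genome_id = sid)
    shits <- if (!is.null(ssu)) ssu[ssu$sag_id == sid, , drop = FALSE] else NULL
    fl <- flag_cosorts(cen, shits, min_ssu_len = min_ssu_len,
                       conf_floor = conf_floor,
                       contam_threshold = contam_threshold,
                       group = truth$group[truth$sag_id == sid])
    list(census = cen, flags = fl)
  })
  census <- do.call(rbind, lapply(rows, `[[`, "census"))
  flags <- do.call(rbind, lapply(rows, `[[`, "flags"))

  flag <- flags[[detector]]
  tab <- table(flags$group, factor(flag, levels = c(TRUE, FALSE),
                                   labels = c("cosort", "single")))
  tab <- unclass(as.matrix(tab))
  dec <- if (all(rowSums(tab) > 0) && all(colSums(tab) > 0) && nrow(tab) >= 2) {
    chisq_decomposition(tab)
  } else NULL
  list(census = census, flags = flags, table = tab, decomposition = dec)
}
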
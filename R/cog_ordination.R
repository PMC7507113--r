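# COG-category relative-abundance profiles, genome filtering, classical
# scaling ordination, and rank-sum group separation tests.

#' Build a COG-category relative-abundance matrix
#'
#' Per genome, the percent of assigned COGs falling in each of the 25
#' categories (rows sum to 100). Genomes with zero assigned COGs are dropped
#' with a warning.
#'
#' @param annotations Annotation table with a grouping column (`by`) and
#'   `cog_category`; unknown category letters raise an error.
#' @param metadata Optional data frame keyed by the grouping column with
#'   `group` and/or `completeness_pct` columns to carry along.
#' @param by Grouping column name (default `"genome_id"`).
#' @return An object of class `cog_matrix`: data frame with `genome_id`,
#'   `group`, `completeness_pct`, then the 25 category columns in fixed
#'   order.
#' @export
build_cog_matrix <- function(annotations, metadata = NULL, by = "genome_id") {
  cats <- cog_categories()
  ann <- annotations[!is.na(annotations$cog_category), , drop = FALSE]
  bad <- setdiff(unique(ann$cog_category), cats)
  if (length(bad)) {
    stop("unknown COG category letter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  all_ids <- unique(annotations[[by]])
  counts <- table(factor(ann[[by]], levels = all_ids),
                  factor(ann$cog_category, levels = cats))
  counts <- unclass(as.matrix(counts))
  tot <- rowSums(counts)
  if (any(tot == 0)) {
    warning(sum(tot == 0), " genome(s) with zero assigned COGs excluded",
            call. = FALSE)
    counts <- counts[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  pct <- 100 * counts / tot
  out <- data.frame(genome_id = rownames(pct),
                    group = NA_character_,
                    completeness_pct = NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(metadata)) {
    key <- if (!is.null(metadata[[by]])) metadata[[by]] else metadata$genome_id
    ix <- match(out$genome_id, key)
    if ("group" %in% names(metadata)) out$group <- metadata$group[ix]
    if ("completeness_pct" %in% names(metadata)) {
      out$completeness_pct <- metadata$completeness_pct[ix]
    }
  }
  out <- cbind(out, as.data.frame(pct))
  rownames(out) <- NULL
  structure(out, class = c("cog_matrix", "data.frame"))
}

#' Filter genomes for ordination eligibility
#'
#' Keeps genomes with marker completeness at or above `min_completeness`
#' percent and at least one 16S gene of length at or above `min_ssu_len`.
#'
#' @param matrix A `cog_matrix`.
#' @param census Data frame from [marker_census()] rows (per genome).
#' @param ssu 16S hit table with `sag_id` (or `genome_id`) and `length_nt`.
#' @param min_completeness Completeness threshold in percent (inclusive).
#' @param min_ssu_len 16S length threshold in nt (inclusive).
#' @return The filtered `cog_matrix`.
#' @export
filter_genomes <- function(matrix, census, ssu, min_completeness = 30,
                           min_ssu_len = 1200) {
  comp <- census$completeness_pct[match(matrix$genome_id, census$genome_id)]
  sid <- ssu[[if ("sag_id" %in% names(ssu)) "sag_id" else "genome_id"]]
  has_ssu <- vapply(matrix$genome_id, function(g) {
    any(sid == g & ssu$length_nt >= min_ssu_len)
  }, NA)
  keep <- !is.na(comp) & comp >= min_completeness & has_ssu
  out <- matrix[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = class(matrix))
}

cog_values <- function(m) {
  as.matrix(m[, cog_categories(), drop = FALSE])
}

#' Ordinate COG profiles by classical scaling
#'
#' Eigen-decomposition of the centered Gram matrix of the percent profiles
#' (classical multidimensional scaling of Euclidean distances, equivalent to
#' PCA of the centered matrix). Axes are ordered by eigenvalue; the sign
#' convention makes the first nonzero loading of each axis positive.
#'
#' @param matrix A `cog_matrix` (>= 3 genomes) or plain numeric matrix.
#' @param n_axes Number of axes to return; axes beyond the rank are
#'   zero-filled with a warning.
#' @param transform `"none"` (default; Euclidean distances on the raw
#'   percentages) or `"hellinger"` (square-root of row-normalized profiles
#'   before ordination).
#' @return An object of class `ordination_result`: list with `coordinates`
#'   (genomes x axes), `eigenvalues` (nonincreasing), `variance_explained`,
#'   `loadings` (categories x axes), `group` (if present in the input).
#' @export
ordinate_profiles <- function(matrix, n_axes = 2, transform = c("none", "hellinger")) {
  transform <- match.arg(transform)
  X <- if (inherits(matrix, "cog_matrix")) cog_values(matrix) else as.matrix(matrix)
  if (nrow(X) < 3) stop("ordination requires >= 3 genomes", call. = FALSE)
  if (transform == "hellinger") X <- sqrt(X / rowSums(X))
  Xc <- scale(X, center = TRUE, scale = FALSE)
  G <- tcrossprod(Xc)
  eig <- eigen(G, symmetric = TRUE)
  lam <- pmax(eig$values, 0)
  rank <- sum(lam > max(lam, 0) * 1e-12)
  if (n_axes > rank) {
    warning("n_axes exceeds the rank; extra axes zero-filled", call. = FALSE)
  }
  k <- n_axes
  coords <- matrix(0, nrow(X), k)
  loads <- matrix(0, ncol(X), k)
  for (a in seq_len(min(k, rank))) {
    u <- eig$vectors[, a]
    coords[, a] <- u * sqrt(lam[a])
    v <- crossprod(Xc, u) / sqrt(lam[a])
    nz <- which(abs(v) > 1e-12)[1]
    if (!is.na(nz) && v[nz] < 0) {
      v <- -v
      coords[, a] <- -coords[, a]
    }
    loads[, a] <- v
  }
  dimnames(coords) <- list(rownames(X), paste0("PC", seq_len(k)))
  dimnames(loads) <- list(colnames(X), paste0("PC", seq_len(k)))
  structure(list(
    coordinates = coords,
    eigenvalues = lam[seq_len(k)],
    variance_explained = lam[seq_len(k)] / sum(lam),
    loadings = loads,
    group = if (inherits(matrix, "cog_matrix")) matrix$group else NULL,
    genome_id = if (inherits(matrix, "cog_matrix")) matrix$genome_id else NULL
  ), class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf("<ordination_result> %d genomes x %d axes; variance explained: %s\n",
              nrow(x$coordinates), ncol(x$coordinates),
              paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = ", ")))
  invisible(x)
}

# two-sided rank-sum test; exact enumeration (midranks) when both groups are
# small, tie-corrected normal approximation via wilcox.test otherwise
ranksum_test <- function(x, y, exact_max = 8) {
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  if (n1 <= exact_max && n2 <= exact_max) {
    mu <- n1 * (n1 + n2 + 1) / 2
    combs <- utils::combn(n1 + n2, n1)
    Ws <- colSums(matrix(r[combs], nrow = n1))
    p <- mean(abs(Ws - mu) >= abs(W - mu) - 1e-12)
    method <- "exact enumeration"
  } else {
    p <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    method <- "normal approximation"
  }
  list(statistic = W, p_value = p, method = method, n1 = n1, n2 = n2)
}

#' Test group separation along an ordination axis
#'
#' Two-sided rank-sum test per group pair on one axis. Ties are handled by
#' midranks; the null distribution is enumerated exactly when both groups
#' have at most 8 members, and approximated normally (with tie-corrected
#' variance and continuity correction) otherwise. Singleton groups are
#' skipped with a warning.
#'
#' @param coords An `ordination_result`, or a numeric vector of values.
#' @param groups Group label per genome (defaults to the ordination's).
#' @param axis Axis number (ignored for plain numeric input).
#' @return Data frame: `group1`, `group2`, `n1`, `n2`, `statistic`
#'   (rank-sum of group1), `p_value`, `method`.
#' @export
group_separation <- function(coords, groups = NULL, axis = 1) {
  if (inherits(coords, "ordination_result")) {
    values <- coords$coordinates[, axis]
    if (is.null(groups)) groups <- coords$group
  } else {
    values <- as.numeric(coords)
  }
  stopifnot(length(values) == length(groups))
  glev <- unique(groups[!is.na(groups)])
  sizes <- vapply(glev, function(g) sum(groups == g, na.rm = TRUE), 0L)
  if (any(sizes < 2)) {
    warning("singleton group(s) skipped: ",
            paste(glev[sizes < 2], collapse = ", "), call. = FALSE)
    glev <- glev[sizes >= 2]
  }
  if (length(glev) < 2) stop("need >= 2 groups with >= 2 members", call. = FALSE)
  pairs <- utils::combn(glev, 2)
  out <- lapply(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1, i]
    g2 <- pairs[2, i]
    t <- ranksum_test(values[which(groups == g1)], values[which(groups == g2)])
    data.frame(group1 = g1, group2 = g2, n1 = t$n1, n2 = t$n2,
               statistic = t$statistic, p_value = t$p_value,
               method = t$method, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
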
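# Respiratory coding potential: KO score-threshold rule, electron-transport
# complex census, oxygen-reductase homolog search (Smith-Waterman +
# Karlin-Altschul e-values), and oxidoreductase (EC1) fraction.

#' BLOSUM62 substitution matrix
#'
#' The standard BLOSUM62 amino-acid substitution matrix (from Biostrings).
#'
#' @return Numeric matrix with amino-acid row/column names.
#' @export
blosum62 <- function() {
  if (is.null(.sagcensus_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .sagcensus_cache$blosum62 <- e$BLOSUM62
  }
  .sagcensus_cache$blosum62
}

#' Smith-Waterman local alignment
#'
#' Optimal local alignment score under affine gap penalties (a gap of length
#' L costs `gap_open + L * gap_extend`), with the number of aligned columns
#' of the optimal traceback; ties on score are broken toward the longest
#' alignment. Empty sequences score 0 with alignment length 0.
#'
#' @param query,subject Peptide sequences (characters must appear in the
#'   substitution matrix).
#' @param matrix Substitution matrix (default [blosum62()]).
#' @param gap_open,gap_extend Positive gap penalties.
#' @return List with `score` and `aln_len`.
#' @export
smith_waterman <- function(query, subject, matrix = blosum62(),
                           gap_open = 11, gap_extend = 1) {
  if (gap_open <= 0 || gap_extend <= 0) {
    stop("gap penalties must be positive", call. = FALSE)
  }
  if (!nchar(query) || !nchar(subject)) return(list(score = 0, aln_len = 0L))
  enc <- function(x) {
    idx <- match(strsplit(x, "")[[1]], rownames(matrix))
    if (anyNA(idx)) stop("sequence contains letters absent from the matrix",
                         call. = FALSE)
    idx
  }
  res <- sw_align_cpp(enc(query), enc(subject), matrix, gap_open, gap_extend)
  list(score = res$score, aln_len = as.integer(res$aln_len))
}

#' Karlin-Altschul e-value
#'
#' `E = K * m * n * exp(-lambda * S)` for raw score `S`, query length `m`
#' and database length `n`. Defaults are the conventional gapped BLOSUM62
#' constants.
#'
#' @param score Raw alignment score.
#' @param query_len,db_len Positive lengths in residues.
#' @param K,lambda Positive Karlin-Altschul parameters.
#' @return The e-value.
#' @export
karlin_evalue <- function(score, query_len, db_len, K = 0.041, lambda = 0.267) {
  if (K <= 0 || lambda <= 0) stop("K and lambda must be positive", call. = FALSE)
  if (query_len <= 0 || db_len <= 0) {
    stop("query_len and db_len must be positive", call. = FALSE)
  }
  K * query_len * db_len * exp(-lambda * score)
}

#' Detect oxygen-reductase homologs
#'
#' Aligns every query protein against a reference database of oxygen-binding
#' subunits (heme-copper oxidase subunit I, family `HCO_A`; bd-ubiquinol
#' oxidase subunit A, family `bd`) with Smith-Waterman, converts scores to
#' Karlin-Altschul e-values, and reports proteins whose best reference
#' e-value passes the cutoff. Family and oxygen-affinity class are inherited
#' from the best reference (ties on e-value broken by higher raw score, then
#' lexicographic reference id). The reference database is de-replicated
#' (100% identical sequences removed) before the search. The tree-eligible
#' subset additionally requires protein length strictly greater than
#' `min_len_for_tree` amino acids.
#'
#' @param proteins Named character vector of query peptides.
#' @param refdb Data frame with `id`, `family`, `affinity`, `seq` (default:
#'   the packaged synthetic reference, [o2red_reference()]).
#' @param evalue_cutoff Maximum e-value for a hit.
#' @param min_len_for_tree Length filter (aa) for the tree-eligible subset.
#' @param matrix,gap_open,gap_extend,K,lambda Alignment/statistics settings.
#' @return List with `hits` (data frame: `protein_id`, `family`, `affinity`,
#'   `score`, `aln_len`, `evalue`, `length_aa`, `tree_eligible`, `ref_id`)
#'   and `tree_eligible` (named character vector of peptides).
#' @export
detect_o2red <- function(proteins, refdb = o2red_reference(),
                         evalue_cutoff = 1e-10, min_len_for_tree = 400,
                         matrix = blosum62(), gap_open = 11, gap_extend = 1,
                         K = 0.041, lambda = 0.267) {
  if (is.null(refdb) || !nrow(refdb)) stop("empty refdb", call. = FALSE)
  keep <- !duplicated(refdb$seq)
  refdb <- refdb[keep, , drop = FALSE]
  db_len <- sum(nchar(refdb$seq))
  if (is.null(names(proteins))) {
    names(proteins) <- sprintf("protein%d", seq_along(proteins))
  }

  rows <- list()
  for (p in names(proteins)) {
    pep <- proteins[[p]]
    if (!nchar(pep)) next
    al <- lapply(refdb$seq, function(r) {
      smith_waterman(pep, r, matrix = matrix,
                     gap_open = gap_open, gap_extend = gap_extend)
    })
    sc <- vapply(al, `[[`, 0, "score")
    ev <- karlin_evalue(sc, nchar(pep), db_len, K = K, lambda = lambda)
    ord <- order(ev, -sc, refdb$id)
    b <- ord[1]
    if (ev[b] <= evalue_cutoff) {
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = p, family = refdb$family[b], affinity = refdb$affinity[b],
        score = sc[b], aln_len = al[[b]]$aln_len, evalue = ev[b],
        length_aa = nchar(pep),
        tree_eligible = nchar(pep) > min_len_for_tree,
        ref_id = refdb$id[b],
        stringsAsFactors = FALSE
      )
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else data.frame(
    protein_id = character(0), family = character(0), affinity = character(0),
    score = numeric(0), aln_len = integer(0), evalue = numeric(0),
    length_aa = integer(0), tree_eligible = logical(0), ref_id = character(0)
  )
  list(hits = hits,
       tree_eligible = proteins[hits$protein_id[hits$tree_eligible]])
}

#' Apply the KO acceptance rule
#'
#' A protein counts as a KEGG-ortholog hit when its profile score reaches
#' `rule_frac` (default 50%) of the family's curated score threshold. Rows
#' with missing or nonpositive thresholds are rejected with a warning.
#'
#' @param raw Data frame with columns `protein_id` (or `protein`), `ko_id`
#'   (or `ko`), `ko_score` (or `score`), `ko_threshold` (or `threshold`);
#'   extra columns are preserved.
#' @param rule_frac Fraction of the threshold a score must reach.
#' @return The input with an `accepted` logical column, invalid rows dropped.
#' @export
apply_ko_rule <- function(raw, rule_frac = 0.5) {
  nm <- names(raw)
  score <- raw[[if ("ko_score" %in% nm) "ko_score" else "score"]]
  thr <- raw[[if ("ko_threshold" %in% nm) "ko_threshold" else "threshold"]]
  bad <- is.na(thr) | thr <= 0 | is.na(score)
  if (any(bad)) {
    warning(sum(bad), " row(s) with missing or nonpositive threshold rejected",
            call. = FALSE)
    raw <- raw[!bad, , drop = FALSE]
    score <- score[!bad]
    thr <- thr[!bad]
  }
  raw$accepted <- score >= rule_frac * thr
  raw
}

#' Electron-transport-chain profile of one genome
#'
#' Counts accepted KO hits per respiratory complex, records which complexes
#' are present (count >= 1) and whether the chain is complete (all of I-IV),
#' and computes the oxidoreductase fraction
#' `100 * ec1_count / protein_count`.
#'
#' @param ko_hits Data frame from [apply_ko_rule()] (needs `ko_id`/`ko` and
#'   `accepted`); may be empty or `NULL`.
#' @param complex_map Data frame mapping `ko` to `complex` (default
#'   [default_complex_map()]); must cover all accepted ETC KOs in use.
#' @param o2red_hits Optional hit table from [detect_o2red()].
#' @param protein_count Total predicted proteins (> 0).
#' @param ec1_count Number of proteins with a top-level EC 1 annotation.
#' @param genome_id Label.
#' @return An object of class `etc_profile`: one-row data frame with
#'   per-complex counts `complex_I`..`complex_IV`, `n_complexes`,
#'   `complete_etc`, `n_o2red`, `ec1_fraction`.
#' @export
etc_profile <- function(ko_hits, complex_map = default_complex_map(),
                        o2red_hits = NULL, protein_count, ec1_count,
                        genome_id = "genome") {
  if (protein_count <= 0) stop("protein_count must be positive", call. = FALSE)
  counts <- stats::setNames(integer(4), c("I", "II", "III", "IV"))
  if (!is.null(ko_hits) && nrow(ko_hits)) {
    ko <- ko_hits[[if ("ko_id" %in% names(ko_hits)) "ko_id" else "ko"]]
    acc <- ko_hits$accepted
    cx <- complex_map$complex[match(ko[acc], complex_map$ko)]
    if (anyNA(cx)) {
      warning("accepted KO id(s) not covered by complex_map ignored",
              call. = FALSE)
    }
    tab <- table(factor(cx[!is.na(cx)], levels = names(counts)))
    counts[] <- as.integer(tab)
  }
  present <- names(counts)[counts >= 1]
  structure(data.frame(
    genome_id = genome_id,
    complex_I = counts[["I"]], complex_II = counts[["II"]],
    complex_III = counts[["III"]], complex_IV = counts[["IV"]],
    n_complexes = length(present),
    complete_etc = length(present) == 4L,
    n_o2red = if (is.null(o2red_hits)) 0L else nrow(o2red_hits),
    ec1_fraction = 100 * ec1_count / protein_count,
    stringsAsFactors = FALSE
  ), class = c("etc_profile", "data.frame"))
}

#' Cohort respiratory summary
#'
#' Percent of genomes per group carrying each respiratory complex, a
#' complete chain, and at least two complexes; mean oxidoreductase fraction.
#'
#' @param profiles Data frame of rbound [etc_profile()] rows.
#' @param groups Group label per row.
#' @return Data frame, one row per group.
#' @export
energy_summary <- function(profiles, groups) {
  stopifnot(nrow(profiles) == length(groups))
  do.call(rbind, lapply(split(seq_len(nrow(profiles)), groups), function(ix) {
    p <- profiles[ix, , drop = FALSE]
    data.frame(
      group = groups[ix[1]],
      n = nrow(p),
      pct_complex_I = 100 * mean(p$complex_I >= 1),
      pct_complex_II = 100 * mean(p$complex_II >= 1),
      pct_complex_III = 100 * mean(p$complex_III >= 1),
      pct_complex_IV = 100 * mean(p$complex_IV >= 1),
      pct_complete_etc = 100 * mean(p$complete_etc),
      pct_two_plus = 100 * mean(p$n_complexes >= 2),
      mean_ec1_fraction = mean(p$ec1_fraction),
      stringsAsFactors = FALSE
    )
  }))
}

#' Respiratory scan of a simulated community
#'
#' Applies the KO rule to every genome's (or SAG's) annotation rows and
#' builds per-genome [etc_profile()]s.
#'
#' @param annotations Annotation table (truth rows of a community or
#'   genome); must carry `genome_id` or `sag_id`, KO columns, and
#'   `ec_top_class`.
#' @param by `"genome_id"` or `"sag_id"` grouping column.
#' @param complex_map Passed to [etc_profile()].
#' @param rule_frac Passed to [apply_ko_rule()].
#' @return Data frame of per-genome profiles.
#' @export
energy_scan <- function(annotations, by = "genome_id",
                        complex_map = default_complex_map(), rule_frac = 0.5) {
  ids <- unique(annotations[[by]])
  do.call(rbind, lapply(ids, function(g) {
    ann <- annotations[annotations[[by]] == g, , drop = FALSE]
    prot <- unique(ann$protein_id)
    ec1 <- sum(!is.na(ann$ec_top_class) & ann$ec_top_class == 1 &
                 !duplicated(ann$protein_id))
    ko <- ann[!is.na(ann$ko_id), , drop = FALSE]
    hits <- if (nrow(ko)) apply_ko_rule(ko, rule_frac = rule_frac) else NULL
    etc_profile(hits, complex_map = complex_map, protein_count = length(prot),
                ec1_count = ec1, genome_id = g)
  }))
}
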
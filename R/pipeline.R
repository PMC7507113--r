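# End-to-end pipeline: simulate -> coding density -> 16S classification ->
# co-sort screen -> respiratory scan -> COG ordination -> cohort report,
# written as deterministic TSVs from one (config, seed).

#' Run the full SAG analysis pipeline on a simulated community
#'
#' Chains every stage of the package over one simulated cohort and writes
#' all stage outputs as TSV files. Identical `(config, seed)` pairs produce
#' byte-identical outputs.
#'
#' @param outdir Output directory.
#' @param seed Integer seed driving every stage.
#' @param n_taxa,n_sags,cosort_rate,completeness_range,n_plates,phyla Passed
#'   to [simulate_community()].
#' @param min_orf_len,rt_factor Passed to [coding_density()].
#' @param min_ssu_len 16S length threshold (nt) for the co-sort screen.
#' @param ordination_min_ssu_len 16S length threshold (nt) for ordination
#'   eligibility.
#' @param min_completeness Completeness threshold (%) for ordination.
#' @return Invisibly, a list with all in-memory stage results.
#' @export
run_pipeline <- function(outdir, seed = 1, n_taxa = 8, n_sags = 40,
                         cosort_rate = 0.02,
                         completeness_range = c(0.06, 0.60),
                         n_plates = 5, phyla = default_phyla(),
                         min_orf_len = 300, rt_factor = 2,
                         min_ssu_len = 1000, ordination_min_ssu_len = 1200,
                         min_completeness = 30) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  comm <- simulate_community(n_taxa = n_taxa, n_sags = n_sags,
                             cosort_rate = cosort_rate,
                             completeness_range = completeness_range,
                             n_plates = n_plates, phyla = phyla,
                             seed = seed, outdir = outdir)

  density <- do.call(rbind, lapply(comm$sags, function(s) {
    coding_density(s, min_orf_len = min_orf_len, rt_factor = rt_factor)
  }))
  rownames(density) <- NULL
  write_tsv(density, file.path(outdir, "coding_density.tsv"))

  ssu <- do.call(rbind, lapply(comm$sags, function(s) {
    classify_assembly_ssu(s, comm$refdb, min_len = min_ssu_len,
                          seed = split_seed(seed, "classify", s$sag_id))
  }))
  if (is.null(ssu)) {
    ssu <- data.frame(sag_id = character(0), contig_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), length_nt = integer(0),
                      sequence = character(0), phylum = character(0),
                      confidence = numeric(0))
  }
  rownames(ssu) <- NULL
  write_tsv(ssu[, setdiff(names(ssu), "sequence")],
            file.path(outdir, "ssu_classifications.tsv"))

  screen <- cosort_screen(comm, detector = "by_markers", ssu = ssu,
                          min_ssu_len = min_ssu_len, seed = seed)
  write_tsv(screen$census, file.path(outdir, "marker_census.tsv"))
  write_tsv(screen$flags, file.path(outdir, "cosort_flags.tsv"))
  if (!is.null(screen$decomposition)) {
    d <- screen$decomposition
    cells <- expand.grid(group = rownames(d$observed),
                         outcome = colnames(d$observed),
                         stringsAsFactors = FALSE)
    dec_df <- data.frame(
      cells,
      observed = as.vector(d$observed),
      expected = as.vector(d$expected),
      residual = as.vector(d$residuals),
      pct_contribution = as.vector(d$pct_contribution)
    )
    write_tsv(dec_df, file.path(outdir, "chisq_decomposition.tsv"))
  }

  energy <- energy_scan(comm$annotations, by = "sag_id")
  rownames(energy) <- NULL
  write_tsv(energy, file.path(outdir, "energy_profiles.tsv"))
  esum <- energy_summary(energy,
                         comm$truth$group[match(energy$genome_id, comm$truth$sag_id)])
  rownames(esum) <- NULL
  write_tsv(esum, file.path(outdir, "energy_summary.tsv"))

  meta <- data.frame(genome_id = comm$truth$sag_id, group = comm$truth$group,
                     stringsAsFactors = FALSE)
  cogm <- build_cog_matrix(comm$annotations, metadata = meta, by = "sag_id")
  names(cogm)[1] <- "genome_id"
  cogm <- filter_genomes(cogm, screen$census, ssu,
                         min_completeness = min_completeness,
                         min_ssu_len = ordination_min_ssu_len)
  write_tsv(cogm, file.path(outdir, "cog_matrix.tsv"))
  ord_report <- NULL
  if (nrow(cogm) >= 3) {
    ord <- ordinate_profiles(cogm, n_axes = 2)
    coords <- data.frame(genome_id = ord$genome_id, group = ord$group,
                         ord$coordinates)
    write_tsv(coords, file.path(outdir, "ordination_coords.tsv"))
    write_tsv(data.frame(axis = seq_along(ord$eigenvalues),
                         eigenvalue = ord$eigenvalues,
                         variance_explained = ord$variance_explained),
              file.path(outdir, "ordination_eigenvalues.tsv"))
    ok_groups <- names(which(table(ord$group) >= 2))
    if (length(ok_groups) >= 2) {
      keep <- ord$group %in% ok_groups
      ord_report <- group_separation(ord$coordinates[keep, 1], ord$group[keep])
      write_tsv(ord_report, file.path(outdir, "ordination_tests.tsv"))
    }
  }

  summ <- cohort_summary(comm$truth, screen$flags)
  write_tsv(summ, file.path(outdir, "cohort_summary.tsv"))
  box <- do.call(rbind, lapply(split(comm$truth$diameter_um, comm$truth$group),
                               function(v) {
    b <- boxstats(v)
    data.frame(n = b$n, median = b$median, q1 = b$q1, q3 = b$q3,
               whisker_low = b$whisker_low, whisker_high = b$whisker_high,
               n_outliers = length(b$outliers))
  }))
  box <- cbind(group = rownames(box), box)
  rownames(box) <- NULL
  write_tsv(box, file.path(outdir, "diameter_boxstats.tsv"))

  invisible(list(community = comm, density = density, ssu = ssu,
                 screen = screen, energy = energy, energy_summary = esum,
                 cog_matrix = cogm, ordination_tests = ord_report,
                 summary = summ))
}
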
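#' Locus and individual quality control
#'
#' Applies the panel QC used before any statistics: loci with a missing-call
#' fraction at or above `max_locus_missing` are removed; loci whose
#' major-allele frequency is at or above `max_major_allele_freq` in every
#' sample are removed as near-fixed; finally individuals whose missing
#' fraction (over the retained loci) is strictly above `max_ind_missing` are
#' removed. The boundary asymmetry (loci `>=`, individuals `>`) is
#' deliberate and documented in the methods vignette.
#'
#' @param gm a [genotype_matrix()].
#' @param sites per-individual sample labels used for the per-sample
#'   near-fixation rule; `NULL` treats the panel as one sample.
#' @param max_locus_missing,max_major_allele_freq,max_ind_missing thresholds
#'   in (0, 1].
#' @return list with `genotypes` (filtered matrix) and `report` (a
#'   `qc_report` recording every decision).
#' @export
apply_locus_and_individual_qc <- function(gm, sites = NULL,
                                          max_locus_missing = 0.25,
                                          max_major_allele_freq = 0.95,
                                          max_ind_missing = 0.25) {
  stopifnot(max_locus_missing > 0, max_locus_missing <= 1,
            max_major_allele_freq > 0, max_major_allele_freq <= 1,
            max_ind_missing > 0, max_ind_missing <= 1)
  d <- gm$dosage
  n0 <- nrow(d); l0 <- ncol(d)

  loc_miss <- colMeans(is.na(d))
  drop_missing <- loci(gm)[loc_miss >= max_locus_missing]

  freq <- allele_freq_by_sample(gm, sites)
  major <- pmax(freq, 1 - freq)
  # near-fixed only if at/above threshold in every sample where typed
  fixed <- apply(major, 2, function(f) all(f[is.finite(f)] >= max_major_allele_freq))
  drop_fixed <- setdiff(loci(gm)[fixed], drop_missing)

  keep_loci <- setdiff(loci(gm), c(drop_missing, drop_fixed))
  if (!length(keep_loci)) stop("QC removed every locus")
  gm2 <- gm[, keep_loci]

  ind_miss <- rowMeans(is.na(gm2$dosage))
  drop_inds <- individuals(gm2)[ind_miss > max_ind_missing]
  keep_inds <- setdiff(individuals(gm2), drop_inds)
  if (!length(keep_inds)) stop("QC removed every individual")
  gm2 <- gm2[keep_inds, ]

  report <- structure(list(
    loci_dropped_missing = drop_missing,
    loci_dropped_fixed = drop_fixed,
    individuals_dropped = drop_inds,
    thresholds = c(max_locus_missing = max_locus_missing,
                   max_major_allele_freq = max_major_allele_freq,
                   max_ind_missing = max_ind_missing),
    n_loci_before = l0, n_loci_after = length(keep_loci),
    n_ind_before = n0, n_ind_after = length(keep_inds)),
    class = "qc_report")
  list(genotypes = gm2, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report: loci", x$n_loci_before, "->", x$n_loci_after,
      sprintf("(%d high-missing, %d near-fixed);", length(x$loci_dropped_missing),
              length(x$loci_dropped_fixed)),
      "individuals", x$n_ind_before, "->", x$n_ind_after,
      sprintf("(%d high-missing)\n", length(x$individuals_dropped)))
  invisible(x)
}

#' Write a QC report as JSON
#' @param report a `qc_report`.
#' @param path output path.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a minimal variant table
#'
#' Tab-separated with header columns `CHROM`, `POS`, `QUAL`, `TYPE`
#' (`SNP`/`indel`) and one or more per-pool depth columns named `DP*`.
#'
#' @param path file path.
#' @return data.frame of variant records.
#' @export
read_variant_table <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("CHROM", "POS", "QUAL", "TYPE")
  if (!all(need %in% colnames(tab)))
    stop("variant table must have columns: ", paste(need, collapse = ", "))
  if (any(tab$POS < 1)) stop("variant positions must be >= 1")
  tab
}

#' Filter candidate SNPs for assay design
#'
#' Retains SNPs with quality strictly above `qual_min`, every per-pool depth
#' within `[cov_min, cov_max]`, and no other variant (SNP or indel, whether
#' or not it passes the other filters itself) within `min_spacing_bp` on the
#' same contig. Optionally keeps a single SNP per contig, choosing the
#' highest QUAL and breaking ties by lowest position.
#'
#' @param records data.frame as returned by [read_variant_table()].
#' @param qual_min,cov_min,cov_max,min_spacing_bp numeric filter settings.
#' @param one_per_contig keep at most one SNP per contig?
#' @return The retained rows of `records`.
#' @export
filter_candidate_snps <- function(records, qual_min = 600, cov_min = 10,
                                  cov_max = 50, min_spacing_bp = 200,
                                  one_per_contig = TRUE) {
  records <- records[order(records$CHROM, records$POS), , drop = FALSE]
  dp_cols <- grep("^DP", colnames(records), value = TRUE)
  keep <- records$TYPE == "SNP" & records$QUAL > qual_min
  if (length(dp_cols)) {
    dp <- as.matrix(records[, dp_cols, drop = FALSE])
    keep <- keep & apply(dp >= cov_min & dp <= cov_max, 1, all)
  }
  # spacing against every called variant on the same contig
  near <- vapply(seq_len(nrow(records)), function(i) {
    same <- records$CHROM == records$CHROM[i]
    dist <- abs(records$POS[same] - records$POS[i])
    any(dist > 0 & dist < min_spacing_bp) ||
      sum(same & records$POS == records$POS[i]) > 1
  }, logical(1))
  keep <- keep & !near
  out <- records[keep, , drop = FALSE]
  if (one_per_contig && nrow(out)) {
    out <- out[order(out$CHROM, -out$QUAL, out$POS), , drop = FALSE]
    out <- out[!duplicated(out$CHROM), , drop = FALSE]
    out <- out[order(out$CHROM, out$POS), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
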
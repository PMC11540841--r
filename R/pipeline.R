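#' Run the full analysis pipeline
#'
#' Orchestrates QC, per-sample diversity, linkage (pairwise LD and the
#' index of association), differentiation (pairwise FST and AMOVA),
#' ordination (PCA, DAPC), driver-locus discovery and karyotype
#' classification, haplotype reconstruction, admixture clustering with
#' K-selection, and the LD-pruned re-analysis (PCA, FST/AMOVA, admixture on
#' the pruned panel), driven by one configuration list.
#'
#' @param config list (or path to a YAML file) with elements:
#'   \describe{
#'     \item{input}{either `list(genepop=, metadata=)` paths, or
#'       `list(preset = TRUE, n_scale =, missing_rate =)` for synthetic
#'       data.}
#'     \item{stages}{character vector among `"qc"`, `"diversity"`,
#'       `"linkage"`, `"differentiation"`, `"ordination"`, `"karyotype"`,
#'       `"haplotypes"`, `"admixture"`, `"pruned"` (default: all).}
#'     \item{seed}{global seed, expanded per stage.}
#'     \item{n_perm}{permutation count for FST/AMOVA/IA.}
#'     \item{admixture}{list(k_range, n_runs, burn_in, n_iter).}
#'     \item{out_dir}{optional output directory for TSV/JSON/Newick files.}
#'   }
#' @return list of class `report_bundle` with one element per executed
#'   stage plus `provenance` (config hash, seed, stage wall times).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1
  n_perm <- config$n_perm %||% 199
  all_stages <- c("qc", "diversity", "linkage", "differentiation",
                  "ordination", "karyotype", "haplotypes", "admixture",
                  "pruned")
  stages <- config$stages %||% all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  adm <- config$admixture %||% list()
  adm_k <- adm$k_range %||% 1:5
  adm_runs <- adm$n_runs %||% 3
  adm_burn <- adm$burn_in %||% 500
  adm_iter <- adm$n_iter %||% 1500

  # --- load or simulate
  if (!is.null(config$input$preset)) {
    sim <- simulate_dataset(preset_three_habitats(
      seed = derive_seed(seed, "sim"),
      n_scale = config$input$n_scale %||% 1,
      missing_rate = config$input$missing_rate %||% 0.02))
    gm <- sim$genotypes; md <- sim$metadata
  } else {
    got <- read_genotypes(config$input$genotypes,
                          config$input$format %||% "genepop")
    gm <- got$genotypes
    md <- if (!is.null(config$input$metadata))
      read_metadata(config$input$metadata) else got$metadata
  }

  bundle <- list()
  times <- c()
  tick <- function(stage, expr) {
    t0 <- proc.time()[3]
    out <- expr
    times[stage] <<- round(proc.time()[3] - t0, 2)
    message(sprintf("[karyopop] stage %-16s %6.2fs", stage, times[stage]))
    out
  }

  if ("qc" %in% stages) {
    res <- tick("qc", apply_locus_and_individual_qc(
      gm, sites = align_metadata(gm, md)$site))
    gm <- res$genotypes
    md <- md[md$individual %in% individuals(gm), , drop = FALSE]
    bundle$qc <- res$report
  }
  sites <- align_metadata(gm, md)$site
  groups <- align_metadata(gm, md)$group

  if ("diversity" %in% stages) {
    bundle$diversity <- tick("diversity", {
      div <- per_sample_diversity(gm, md)
      kw <- kruskal_wallis_groups(div$uhe_mean, div$group)
      hwe <- hwe_tests(gm, md)
      hwe$q <- bh_fdr(hwe$p, hwe$site)$q
      list(table = div, kruskal_wallis_uhe = kw, hwe = hwe)
    })
  }

  ld <- NULL
  if ("linkage" %in% stages || "karyotype" %in% stages ||
      "pruned" %in% stages) {
    ld <- tick("ld_matrix", pairwise_ld_fisher(
      gm, seed = derive_seed(seed, "ld")))
  }
  if ("linkage" %in% stages) {
    bundle$linkage <- tick("linkage", list(
      ld = ld,
      ia = index_of_association(gm, n_perm = min(n_perm, 999),
                                seed = derive_seed(seed, "ia"))))
  }

  if ("differentiation" %in% stages) {
    bundle$differentiation <- tick("differentiation", {
      fst <- weir_cockerham_fst(gm, sites, n_perm = n_perm,
                                seed = derive_seed(seed, "fst"))
      list(fst = fst,
           amova_flat = amova(gm, sites, NULL, n_perm,
                              derive_seed(seed, "amova")),
           amova_hier = amova(gm, sites, groups, n_perm,
                              derive_seed(seed, "amovah")),
           dendrogram = fst_dendrogram(fst))
    })
  }

  pca <- NULL
  if ("ordination" %in% stages || "karyotype" %in% stages) {
    pca <- tick("pca", pca_genotypes(gm))
  }
  if ("ordination" %in% stages) {
    bundle$ordination <- tick("ordination", list(
      pca = pca,
      dapc = dapc_fit(gm, groups, n_pcs = config$dapc_n_pcs %||% "auto",
                      seed = derive_seed(seed, "dapc"))))
  }

  drivers <- NULL
  calls <- NULL
  if ("karyotype" %in% stages) {
    bundle$karyotype <- tick("karyotype", {
      drivers <- driver_loci_from_loadings(pca)
      calls <- classify_karyotypes(gm, drivers$locus, pca = pca,
                                   metadata = md,
                                   seed = derive_seed(seed, "karyo"))
      list(driver_loci = drivers,
           calls = calls,
           frequency_table = karyotype_frequency_table(gm, calls,
                                                       metadata = md),
           by_sample = haplogroup_frequencies_by_sample(calls, md))
    })
    drivers <- bundle$karyotype$driver_loci
    calls <- bundle$karyotype$calls
  }

  if ("haplotypes" %in% stages) {
    bundle$haplotypes <- tick("haplotypes", {
      loci_sel <- if (!is.null(calls)) {
        ft <- bundle$karyotype$frequency_table
        diag_loci <- unique(ft$locus[ft$scope == "Total" & ft$diagnostic])
        if (length(diag_loci) >= 2) diag_loci else head(drivers$locus, 5)
      } else head(loci(gm), 5)
      hs <- em_phase_haplotypes(gm, loci_sel,
                                seed = derive_seed(seed, "em"))
      list(haplotypes = hs,
           differentiation = haplotype_differentiation(
             hs, md, n_perm = min(n_perm, 500),
             seed = derive_seed(seed, "hapdiff")))
    })
  }

  if ("admixture" %in% stages) {
    bundle$admixture <- tick("admixture", {
      runs <- admixture_scan(gm, adm_k, adm_runs, adm_burn, adm_iter,
                             seed = derive_seed(seed, "admix"))
      Ks <- vapply(runs, `[[`, numeric(1), "K")
      ev <- tryCatch(evanno_delta_k(runs), error = function(e) NULL)
      best_k <- if (!is.null(ev)) attr(ev, "best_k") else max(adm_k)
      kmax_runs <- runs[Ks == max(adm_k)]
      list(runs = runs, evanno = ev, best_k = best_k,
           puechmaille = puechmaille_statistics(kmax_runs, sites),
           averaged = if (sum(Ks == best_k) >= 2)
             align_and_average_runs(runs[Ks == best_k]))
    })
  }

  if ("pruned" %in% stages) {
    bundle$pruned <- tick("pruned", {
      pr <- ld_prune(gm, ld)
      gmp <- gm[, pr$retained]
      out <- list(prune = pr, pca = pca_genotypes(gmp),
                  fst = weir_cockerham_fst(gmp, sites, n_perm = n_perm,
                                           seed = derive_seed(seed, "fstp")),
                  amova_hier = amova(gmp, sites, groups, n_perm,
                                     derive_seed(seed, "amovap")),
                  memberships = habitat_memberships(gmp, md,
                                                    seed = derive_seed(seed, "memb")))
      out$migrants <- detect_migrants(out$memberships, md, calls = calls)
      out
    })
  }

  bundle$provenance <- list(config_hash = config_hash(config), seed = seed,
                            stage_seconds = times,
                            package_version =
                              as.character(utils::packageVersion("karyopop")))
  class(bundle) <- "report_bundle"
  if (!is.null(config$out_dir)) write_report_bundle(bundle, config$out_dir)
  bundle
}

#' Write the tabular pieces of a report bundle to disk
#'
#' @param bundle a `report_bundle` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wtsv <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
                                     quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$qc)) write_qc_report(bundle$qc,
                                           file.path(dir, "qc_report.json"))
  if (!is.null(bundle$diversity)) wtsv(bundle$diversity$table,
                                       "diversity.tsv")
  if (!is.null(bundle$differentiation)) {
    f <- bundle$differentiation$fst
    m <- f$fst; m[upper.tri(m)] <- f$p[upper.tri(f$p)]
    wtsv(data.frame(sample = rownames(m), m, check.names = FALSE),
         "fst_matrix.tsv")
    ape::write.tree(bundle$differentiation$dendrogram,
                    file.path(dir, "fst_dendrogram.nwk"))
  }
  if (!is.null(bundle$karyotype)) {
    wtsv(bundle$karyotype$calls, "karyotype_calls.tsv")
    wtsv(bundle$karyotype$frequency_table, "karyotype_frequencies.tsv")
    wtsv(bundle$karyotype$by_sample, "haplogroups_by_sample.tsv")
  }
  if (!is.null(bundle$admixture) && !is.null(bundle$admixture$evanno))
    wtsv(bundle$admixture$evanno, "evanno.tsv")
  if (!is.null(bundle$pruned)) {
    writeLines(bundle$pruned$prune$retained,
               file.path(dir, "pruned_loci.txt"))
    if (nrow(bundle$pruned$migrants))
      wtsv(bundle$pruned$migrants, "migrants.tsv")
  }
  jsonlite::write_json(bundle$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
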
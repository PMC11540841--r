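# Small in-code fixtures shared across tests.

# genotype matrix from a plain dosage matrix
gm_from <- function(d, inds = NULL, locs = NULL) {
  d <- as.matrix(d)
  rownames(d) <- inds %||% paste0("i", seq_len(nrow(d)))
  colnames(d) <- locs %||% paste0("L", seq_len(ncol(d)))
  genotype_matrix(d)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# two-group background-only simulation config
two_group_config <- function(seed, n_per_site = 25, n_loci = 40,
                             fst_between = 0.15, fst_within = 0.005) {
  simulation_config(
    seed = seed,
    groups = data.frame(group = rep(c("G1", "G2"), each = 2),
                        site = paste0("s", 1:4),
                        n = n_per_site, stringsAsFactors = FALSE),
    n_background_loci = n_loci, n_inversion_loci = 0,
    fst_between = fst_between, fst_within = fst_within)
}

# small three-group inversion config (fast)
small_inversion_config <- function(seed, n_per_site = 30,
                                   missing_rate = 0) {
  kf <- rbind(Ocean = c(0.567, 0.372, 0.061) / 1,
              Fjords = c(0.185, 0.537, 0.279),
              Mediterranean = c(0, 0, 1))
  kf <- kf / rowSums(kf)
  colnames(kf) <- c("AA", "AB", "BB")
  simulation_config(
    seed = seed,
    groups = data.frame(group = c("Ocean", "Fjords", "Mediterranean"),
                        site = c("oc1", "fj1", "md1"), n = n_per_site,
                        stringsAsFactors = FALSE),
    n_background_loci = 30, n_inversion_loci = 6, n_diagnostic = 4,
    partial_freqs = cbind(pA_on_A = c(0.7, 0.74), pA_on_B = c(0, 0.02)),
    fst_between = 0.03, fst_within = 0.005,
    karyotype_freqs = kf, missing_rate = missing_rate)
}
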
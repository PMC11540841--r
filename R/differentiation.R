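# Per-locus Weir-Cockerham variance components (a, b, c) for biallelic
# dosages split by sample; returns 3 x L matrix. Samples with no typed
# calls at a locus drop that locus from the pair/panel estimate.
wc_components <- function(d, sites) {
  sites <- as.factor(sites)
  idx <- split(seq_len(nrow(d)), sites)
  r_all <- length(idx)
  out <- matrix(NA_real_, 3, ncol(d))
  for (l in seq_len(ncol(d))) {
    x <- d[, l]
    ni <- vapply(idx, function(i) sum(!is.na(x[i])), numeric(1))
    use <- ni >= 1
    r <- sum(use)
    if (r < 2) next
    n_i <- ni[use]
    p_i <- vapply(idx[use], function(i) mean(x[i], na.rm = TRUE) / 2,
                  numeric(1))
    h_i <- vapply(idx[use], function(i) mean(x[i] == 1, na.rm = TRUE),
                  numeric(1))
    nbar <- mean(n_i)
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    pbar <- sum(n_i * p_i) / (r * nbar)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    if (nbar <= 1 || nc <= 0) next
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    out[, l] <- c(a, b, cc)
  }
  out
}

wc_theta <- function(d, sites) {
  comp <- wc_components(d, sites)
  sa <- sum(comp[1, ], na.rm = TRUE)
  st <- sum(comp, na.rm = TRUE)
  if (st == 0) return(NaN)
  sa / st
}

#' Weir-Cockerham F-statistics
#'
#' Multi-locus theta is the ratio of summed among-sample variance components
#' to summed total components over loci. With `pairwise = TRUE`, every
#' sample pair gets an estimate plus a permutation p-value obtained by
#' shuffling individuals between the two samples; p-values are
#' FDR-corrected over the pairwise family.
#'
#' @param gm a [genotype_matrix()].
#' @param sites per-individual sample labels (character/factor).
#' @param pairwise compute the pairwise matrix (`TRUE`) or a single
#'   multi-locus estimate over all samples (`FALSE`).
#' @param n_perm permutations per pair (0 skips testing).
#' @param seed RNG seed.
#' @return For `pairwise = FALSE`, a single numeric theta. Otherwise an
#'   `fst_matrix`: list with symmetric `fst`, `p`, `q` matrices and
#'   `n_perm`.
#' @export
weir_cockerham_fst <- function(gm, sites, pairwise = TRUE, n_perm = 10000,
                               seed = 1) {
  d <- gm$dosage
  sites <- as.character(sites)
  stopifnot(length(sites) == nrow(d))
  if (!pairwise) return(wc_theta(d, sites))
  sn <- unique(sites)
  S <- length(sn)
  fst <- p <- matrix(NA_real_, S, S, dimnames = list(sn, sn))
  with_seed(derive_seed(seed, "fst_perm"), {
    for (i in seq_len(S - 1)) for (j in (i + 1):S) {
      idx <- which(sites %in% c(sn[i], sn[j]))
      dd <- d[idx, , drop = FALSE]
      lab <- sites[idx]
      th <- wc_theta(dd, lab)
      fst[i, j] <- fst[j, i] <- th
      if (n_perm > 0) {
        cnt <- 0L
        for (b in seq_len(n_perm)) {
          if (wc_theta(dd, sample(lab)) >= th) cnt <- cnt + 1L
        }
        p[i, j] <- p[j, i] <- (cnt + 1) / (n_perm + 1)
      }
    }
  })
  q <- p
  lt <- lower.tri(p)
  if (any(!is.na(p[lt]))) {
    q[lt] <- p.adjust(p[lt], method = "BH")
    q[upper.tri(q)] <- t(q)[upper.tri(q)]
  }
  structure(list(samples = sn, fst = fst, p = p, q = q, n_perm = n_perm),
            class = "fst_matrix")
}

# Squared inter-individual genetic distance: per-locus allele-difference
# counts |dosage_i - dosage_j| summed over loci typed in both individuals,
# rescaled by (total loci / typed loci).
genotype_dist2 <- function(d) {
  n <- nrow(d); L <- ncol(d)
  D <- matrix(0, n, n, dimnames = list(rownames(d), rownames(d)))
  for (l in seq_len(L)) {
    x <- d[, l]
    dif <- abs(outer(x, x, "-"))
    dif[is.na(dif)] <- NA
    D <- D + ifelse(is.na(dif), 0, dif)
  }
  typed <- !is.na(d)
  shared <- tcrossprod(typed * 1)
  scale <- ifelse(shared > 0, L / shared, NA)
  D * scale
}

amova_ss <- function(D2, idx_list) {
  # SS within each block of indices: sum of pairwise d2 / block size
  vapply(idx_list, function(idx) {
    if (length(idx) < 2) return(0)
    sum(D2[idx, idx][lower.tri(diag(length(idx)))]) / length(idx)
  }, numeric(1))
}

amova_components <- function(D2, sites, groups = NULL) {
  N <- nrow(D2)
  sites <- as.character(sites)
  sidx <- split(seq_len(N), sites)
  S <- length(sidx)
  ss_total <- sum(D2[lower.tri(D2)]) / N
  ss_ws <- sum(amova_ss(D2, sidx))
  if (is.null(groups)) {
    df_as <- S - 1; df_ws <- N - S
    ss_as <- ss_total - ss_ws
    ms_as <- ss_as / df_as; ms_ws <- ss_ws / df_ws
    n0 <- (N - sum(lengths(sidx)^2) / N) / (S - 1)
    sig_w <- ms_ws
    sig_a <- (ms_as - ms_ws) / n0
    tot <- sig_a + sig_w
    return(list(design = "flat",
                ss = c(among_samples = ss_as, within_samples = ss_ws),
                df = c(among_samples = df_as, within_samples = df_ws),
                sigma = c(among_samples = sig_a, within_samples = sig_w),
                pct = 100 * c(among_samples = sig_a,
                              within_samples = sig_w) / tot,
                fst = sig_a / tot))
  }
  groups <- as.character(groups)
  gof <- tapply(groups, sites, `[`, 1)        # group of each site
  gidx <- split(seq_len(N), groups)
  G <- length(gidx)
  ss_wg <- sum(amova_ss(D2, gidx))
  ss_ag <- ss_total - ss_wg
  ss_as_wg <- ss_wg - ss_ws
  df_ag <- G - 1; df_as <- S - G; df_ws <- N - S
  ms_ag <- ss_ag / df_ag; ms_as <- ss_as_wg / df_as; ms_ws <- ss_ws / df_ws
  n_s <- lengths(sidx)
  N_g <- lengths(gidx)
  sum_ns2_over_Ng <- sum(vapply(names(gidx), function(gn) {
    s_in_g <- names(gof)[gof == gn]
    sum(n_s[s_in_g]^2) / N_g[gn]
  }, numeric(1)))
  n1 <- (N - sum_ns2_over_Ng) / (S - G)
  n2 <- (sum_ns2_over_Ng - sum(n_s^2) / N) / (G - 1)
  n3 <- (N - sum(N_g^2) / N) / (G - 1)
  sig_c <- ms_ws
  sig_b <- (ms_as - sig_c) / n1
  sig_a <- (ms_ag - sig_c - n2 * sig_b) / n3
  tot <- sig_a + sig_b + sig_c
  list(design = "hierarchical",
       ss = c(among_groups = ss_ag, among_samples_within = ss_as_wg,
              within_samples = ss_ws),
       df = c(among_groups = df_ag, among_samples_within = df_as,
              within_samples = df_ws),
       sigma = c(among_groups = sig_a, among_samples_within = sig_b,
                 within_samples = sig_c),
       pct = 100 * c(among_groups = sig_a, among_samples_within = sig_b,
                     within_samples = sig_c) / tot,
       fct = sig_a / tot, fsc = sig_b / (sig_b + sig_c),
       fst = (sig_a + sig_b) / tot)
}

#' Analysis of molecular variance (AMOVA)
#'
#' Excoffier-style sums of squares computed from squared inter-individual
#' distances (per-locus allele-difference counts, missing-rescaled).
#' A flat design (samples only) yields FST; a hierarchical design
#' (samples nested in groups) yields FCT, FSC and overall FST, with
#' method-of-moments variance components. Permutation schemes: individuals
#' among samples (flat FST and FSC), whole samples among groups (FCT).
#'
#' @param gm a [genotype_matrix()].
#' @param sites per-individual sample labels.
#' @param groups optional per-individual group labels (must be constant
#'   within site).
#' @param n_perm permutations (0 skips p-values).
#' @param seed RNG seed.
#' @return list of class `amova_result` with sums of squares, degrees of
#'   freedom, variance components `sigma`, percentages of variation `pct`,
#'   F-statistics and permutation p-values.
#' @export
amova <- function(gm, sites, groups = NULL, n_perm = 10000, seed = 1) {
  d <- gm$dosage
  sites <- as.character(sites)
  stopifnot(length(sites) == nrow(d))
  if (!is.null(groups)) {
    groups <- as.character(groups)
    if (anyDuplicated(unique(cbind(sites, groups))[, 1]))
      stop("hierarchy not nested: a site appears in two groups")
    if (any(table(tapply(groups, sites, `[`, 1)) < 2))
      warning("a group contains a single sample: FCT permutation degenerate")
  }
  D2 <- genotype_dist2(d)
  amova_from_dist(D2, sites, groups, n_perm = n_perm, seed = seed)
}

#' AMOVA from a precomputed squared-distance matrix
#'
#' @param D2 symmetric matrix of squared inter-individual distances.
#' @param sites,groups,n_perm,seed as in [amova()].
#' @return An `amova_result` (see [amova()]).
#' @export
amova_from_dist <- function(D2, sites, groups = NULL, n_perm = 10000,
                            seed = 1) {
  obs <- amova_components(D2, sites, groups)
  pvals <- NULL
  if (n_perm > 0) {
    pvals <- with_seed(derive_seed(seed, "amova_perm"), {
      N <- nrow(D2)
      if (is.null(groups)) {
        cnt <- 0L
        for (b in seq_len(n_perm)) {
          perm <- amova_components(D2, sample(sites), NULL)
          if (perm$fst >= obs$fst) cnt <- cnt + 1L
        }
        c(p_fst = (cnt + 1) / (n_perm + 1))
      } else {
        cnt_fsc <- cnt_fct <- 0L
        sn <- unique(sites)
        gof <- tapply(groups, sites, `[`, 1)[sn]
        for (b in seq_len(n_perm)) {
          # FSC: individuals among samples within groups
          s2 <- sites
          for (gn in unique(groups)) {
            i <- which(groups == gn)
            s2[i] <- sites[i][sample.int(length(i))]
          }
          perm <- amova_components(D2, s2, groups)
          if (perm$fsc >= obs$fsc) cnt_fsc <- cnt_fsc + 1L
          # FCT: whole samples among groups
          g2of <- setNames(sample(gof), sn)
          perm <- amova_components(D2, sites, unname(g2of[sites]))
          if (perm$fct >= obs$fct) cnt_fct <- cnt_fct + 1L
        }
        c(p_fsc = (cnt_fsc + 1) / (n_perm + 1),
          p_fct = (cnt_fct + 1) / (n_perm + 1))
      }
    })
  }
  structure(c(obs, list(p = pvals, n_perm = n_perm)), class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (", x$design, " design)\n", sep = "")
  tab <- data.frame(df = x$df, SS = x$ss, sigma = x$sigma, pct = x$pct)
  print(round(tab, 4))
  if (x$design == "flat") cat("FST =", round(x$fst, 4), "\n")
  else cat(sprintf("FCT = %.4f  FSC = %.4f  FST = %.4f\n",
                   x$fct, x$fsc, x$fst))
  if (!is.null(x$p)) print(round(x$p, 5))
  invisible(x)
}

#' UPGMA dendrogram from a pairwise FST matrix
#'
#' Negative estimates are clamped to zero before clustering.
#'
#' @param fst_matrix an `fst_matrix` from [weir_cockerham_fst()] or a plain
#'   symmetric matrix.
#' @param method agglomeration method (`"average"` = UPGMA).
#' @return An [ape::as.phylo()] tree; leaf order stored in attribute
#'   `leaf_order`.
#' @export
fst_dendrogram <- function(fst_matrix, method = "average") {
  m <- if (inherits(fst_matrix, "fst_matrix")) fst_matrix$fst else fst_matrix
  if (any(is.na(m[lower.tri(m)]))) stop("FST matrix has missing entries")
  m <- pmax(m, 0)
  diag(m) <- 0
  hc <- hclust(as.dist(m), method = method)
  tr <- ape::as.phylo(hc)
  attr(tr, "leaf_order") <- hc$labels[hc$order]
  tr
}
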
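#' Pairwise Fisher exact tests of linkage disequilibrium
#'
#' For every pair of loci builds the joint genotype contingency table
#' (up to 3 x 3 over dosages; individuals missing either call are excluded)
#' and applies Fisher's exact test: full network enumeration when the table
#' total is at most `exact_max_n`, otherwise a seeded Monte-Carlo version.
#'
#' @param gm a [genotype_matrix()].
#' @param sites optional per-individual sample labels; when given, tests are
#'   run within each sample (`scope = "per-sample"` behaviour) and a list of
#'   matrices is returned, otherwise one pooled matrix.
#' @param exact_max_n largest table total for exact evaluation.
#' @param mc_reps Monte-Carlo replicates for larger tables.
#' @param seed RNG seed for the Monte-Carlo branch.
#' @return An `ld_matrix`: list with `loci`, symmetric `p` matrix (diagonal
#'   `NA`) and `method`; or a named list of these per sample.
#' @export
pairwise_ld_fisher <- function(gm, sites = NULL, exact_max_n = 200,
                               mc_reps = 1e4, seed = 1) {
  if (!is.null(sites)) {
    sites <- as.character(sites)
    res <- lapply(split(seq_len(nrow(gm$dosage)), sites), function(idx)
      pairwise_ld_fisher(gm[idx, ], NULL, exact_max_n, mc_reps, seed))
    return(res)
  }
  d <- gm$dosage
  L <- ncol(d)
  if (L < 2) stop("need at least two loci")
  p <- matrix(NA_real_, L, L, dimnames = list(colnames(d), colnames(d)))
  with_seed(seed, {
    for (j in seq_len(L - 1)) for (k in (j + 1):L) {
      ok <- !is.na(d[, j]) & !is.na(d[, k])
      if (sum(ok) < 2) next
      tab <- table(factor(d[ok, j], 0:2), factor(d[ok, k], 0:2))
      tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
      if (nrow(tab) < 2 || ncol(tab) < 2) { p[j, k] <- p[k, j] <- 1; next }
      pv <- if (sum(tab) <= exact_max_n)
        fisher.test(tab, workspace = 2e6)$p.value
      else fisher.test(tab, simulate.p.value = TRUE, B = mc_reps)$p.value
      p[j, k] <- p[k, j] <- min(1, pv)
    }
  })
  structure(list(loci = colnames(d), p = p,
                 method = sprintf("fisher-exact (MC above n=%d, B=%g)",
                                  exact_max_n, mc_reps)),
            class = "ld_matrix")
}

# Per-locus pairwise distance matrices: count of differing alleles between
# unordered genotype pairs, i.e. |dosage_i - dosage_j| in {0, 1, 2}.
# Missing dosages are mean-imputed per locus before distances are formed.
locus_pair_distances <- function(d) {
  lapply(seq_len(ncol(d)), function(j) {
    x <- d[, j]
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    abs(outer(x, x, "-"))[lower.tri(diag(length(x)))]
  })
}

ia_from_distances <- function(dists) {
  m <- length(dists[[1]])
  total <- Reduce(`+`, dists)
  pvar <- function(v) sum(v^2) / m - (sum(v) / m)^2
  v_o <- pvar(total)
  vars <- vapply(dists, pvar, numeric(1))
  v_e <- sum(vars)
  denom <- 0
  L <- length(dists)
  for (j in seq_len(L - 1)) for (k in (j + 1):L)
    denom <- denom + sqrt(vars[j] * vars[k])
  c(ia = v_o / v_e - 1, rbard = (v_o - v_e) / (2 * denom))
}

#' Multilocus index of association
#'
#' Computes the index of association `IA = V_O/V_E - 1` and its
#' locus-number-standardised form `rbar_d`, where `V_O` is the variance over
#' individual pairs of the summed per-locus allele-difference distances and
#' `V_E` the sum of the per-locus distance variances. Significance is
#' assessed by permuting genotypes independently within each locus.
#'
#' @param gm a [genotype_matrix()] (typically restricted to a locus subset).
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return list of class `ia_result`: `ia`, `rbard`, `p_ia`, `p_rbard`,
#'   `n_perm`, and the per-pair `rbard_range` over locus pairs.
#' @export
index_of_association <- function(gm, n_perm = 999, seed = 1) {
  d <- gm$dosage
  if (ncol(d) < 2) stop("need at least two loci")
  if (nrow(d) < 3) stop("need at least three individuals")
  poly <- apply(d, 2, function(x) length(unique(x[!is.na(x)])) > 1)
  if (!any(poly)) stop("all loci monomorphic: index of association undefined")
  d <- d[, poly, drop = FALSE]
  if (ncol(d) < 2) stop("need at least two polymorphic loci")
  dists <- locus_pair_distances(d)
  obs <- ia_from_distances(dists)
  # per-pair rbar_d across locus pairs (reported as a range)
  L <- ncol(d)
  pair_rb <- if (L <= 40) {
    cmb <- combn(L, 2)
    vapply(seq_len(ncol(cmb)), function(i)
      ia_from_distances(dists[cmb[, i]])["rbard"], numeric(1))
  } else NA_real_
  perm <- with_seed(derive_seed(seed, "ia_perm"), {
    vapply(seq_len(n_perm), function(r) {
      ds <- d
      for (j in seq_len(ncol(ds))) ds[, j] <- ds[sample.int(nrow(ds)), j]
      ia_from_distances(locus_pair_distances(ds))
    }, numeric(2))
  })
  structure(list(
    ia = unname(obs["ia"]), rbard = unname(obs["rbard"]),
    p_ia = (sum(perm["ia", ] >= obs["ia"]) + 1) / (n_perm + 1),
    p_rbard = (sum(perm["rbard", ] >= obs["rbard"]) + 1) / (n_perm + 1),
    n_perm = n_perm,
    rbard_range = if (all(is.na(pair_rb))) c(NA_real_, NA_real_) else
      range(pair_rb, na.rm = TRUE),
    rbard_pair_mean = mean(pair_rb, na.rm = TRUE)),
    class = "ia_result")
}

#' Benjamini-Hochberg FDR correction within test families
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param family optional grouping; the step-up correction is applied within
#'   each family separately.
#' @param alpha significance level for the returned flags.
#' @return data.frame with `p`, `family`, `q` and `significant`.
#' @export
bh_fdr <- function(p, family = NULL, alpha = 0.05) {
  if (!length(p)) return(data.frame(p = numeric(0), family = character(0),
                                    q = numeric(0), significant = logical(0)))
  if (is.null(family)) family <- rep("all", length(p))
  q <- ave(p, family, FUN = function(v) p.adjust(v, method = "BH"))
  data.frame(p = p, family = family, q = q, significant = q < alpha,
             stringsAsFactors = FALSE)
}

#' LD-prune a locus panel
#'
#' Builds a graph whose edges join locus pairs with FDR-corrected LD
#' p-values below `p_threshold` and keeps exactly one locus per connected
#' component: the one with least missing data, ties broken by highest
#' minor-allele frequency, then lexicographic ID.
#'
#' @param gm a [genotype_matrix()].
#' @param ld_matrix an `ld_matrix` from [pairwise_ld_fisher()] covering the
#'   same loci.
#' @param p_threshold threshold on the FDR-corrected p-values.
#' @return list with `retained` locus IDs (input order) and `components`
#'   (data.frame locus -> component id).
#' @export
ld_prune <- function(gm, ld_matrix, p_threshold = 1e-4) {
  lnames <- ld_matrix$loci
  stopifnot(identical(sort(lnames), sort(loci(gm))))
  pm <- ld_matrix$p
  lt <- which(lower.tri(pm), arr.ind = TRUE)
  pv <- pm[lt]
  ok <- !is.na(pv)
  q <- rep(NA_real_, length(pv))
  q[ok] <- p.adjust(pv[ok], method = "BH")
  edges <- lt[!is.na(q) & q < p_threshold, , drop = FALSE]
  gr <- igraph::make_empty_graph(n = length(lnames), directed = FALSE)
  gr <- igraph::add_edges(gr, t(edges))
  comp <- igraph::components(gr)$membership
  d <- gm$dosage[, lnames, drop = FALSE]
  miss <- colMeans(is.na(d))
  p_hat <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p_hat, 1 - p_hat)
  keep <- vapply(split(seq_along(lnames), comp), function(idx) {
    idx <- idx[order(miss[idx], -maf[idx], lnames[idx])]
    lnames[idx[1]]
  }, "")
  retained <- loci(gm)[loci(gm) %in% keep]
  list(retained = retained,
       components = data.frame(locus = lnames, component = as.integer(comp),
                               stringsAsFactors = FALSE))
}
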
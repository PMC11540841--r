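#' Per-sample genetic diversity summaries
#'
#' For every sample (site) computes, per locus: observed heterozygosity
#' `Ho` = heterozygote count / typed count; expected heterozygosity
#' `He = 1 - p^2 - q^2`; unbiased expected heterozygosity
#' `uHe = 2n/(2n - 1) * He` with `n` the typed individuals; and
#' `FIS = (He - Ho)/He` for loci polymorphic in that sample. Sample values
#' are means over loci with standard errors `sd/sqrt(#loci)`.
#'
#' @param gm a [genotype_matrix()].
#' @param metadata a [sample_metadata()] (its `site` column defines samples).
#' @param fis_denominator `"he"` (default, GenAlEx convention) or `"uhe"`:
#'   the expected-heterozygosity flavour used in the FIS ratio.
#' @return data.frame, one row per sample, of class `diversity_stats`.
#' @export
per_sample_diversity <- function(gm, metadata,
                                 fis_denominator = c("he", "uhe")) {
  fis_denominator <- match.arg(fis_denominator)
  md <- align_metadata(gm, metadata)
  d <- gm$dosage
  rows <- lapply(split(seq_len(nrow(d)), md$site), function(idx) {
    x <- d[idx, , drop = FALSE]
    n <- colSums(!is.na(x))
    used <- n >= 1
    p <- colMeans(x, na.rm = TRUE) / 2
    ho <- colMeans(x == 1, na.rm = TRUE)
    he <- 2 * p * (1 - p)
    uhe <- ifelse(n > 0, 2 * n / pmax(2 * n - 1, 1) * he, NA)
    poly <- used & p > 0 & p < 1
    he_f <- if (fis_denominator == "he") he else uhe
    fis <- ifelse(poly, (he_f - ho) / he_f, NA)
    se <- function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2) return(NA_real_)
      sd(v) / sqrt(length(v))
    }
    data.frame(
      site = md$site[idx][1], group = md$group[idx][1], n = length(idx),
      polymorphic_pct = 100 * mean(poly[used]),
      ho_mean = mean(ho[used]), ho_se = se(ho[used]),
      uhe_mean = mean(uhe[used]), uhe_se = se(uhe[used]),
      fis_mean = mean(fis, na.rm = TRUE), fis_se = se(fis),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[match(unique(md$site), out$site), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("diversity_stats", "data.frame")
  out
}

#' Exact Hardy-Weinberg test for one locus
#'
#' Enumerates every heterozygote count compatible with the observed allele
#' counts, weighting by the exact sampling distribution of genotype counts
#' given allele counts, and sums the probabilities of configurations no more
#' probable than the observed one (two-sided, probability ordering).
#'
#' @param n_aa,n_ab,n_bb genotype counts.
#' @return list with `p`, `direction` (`"deficit"`, `"excess"` or `NA` for
#'   monomorphic counts) and the counts.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n < 1) stop("need at least one genotype")
  na <- 2 * n_aa + n_ab
  nb <- 2 * n_bb + n_ab
  if (na == 0 || nb == 0)
    return(list(p = 1, direction = NA_character_,
                counts = c(n_aa = n_aa, n_ab = n_ab, n_bb = n_bb)))
  rare <- min(na, nb)
  hets <- seq(rare %% 2, rare, by = 2)
  # log P(n_ab | n, na) = log [ n! / (naa! nab! nbb!) 2^nab na! nb! / (2n)! ]
  logp <- vapply(hets, function(h) {
    aa <- (na - h) / 2; bb <- (nb - h) / 2
    lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
      h * log(2) + lfactorial(na) + lfactorial(nb) - lfactorial(2 * n)
  }, numeric(1))
  pr <- exp(logp - max(logp)); pr <- pr / sum(pr)
  obs <- pr[match(n_ab, hets)]
  p <- min(1, sum(pr[pr <= obs + 1e-12]))
  p_hat <- na / (2 * n)
  he <- 2 * p_hat * (1 - p_hat)
  ho <- n_ab / n
  list(p = p, direction = if (ho < he) "deficit" else "excess",
       counts = c(n_aa = n_aa, n_ab = n_ab, n_bb = n_bb))
}

#' Hardy-Weinberg exact tests per sample and locus
#'
#' @param gm a [genotype_matrix()].
#' @param metadata a [sample_metadata()]; `NULL` pools all individuals.
#' @return data.frame with one row per (sample, locus): counts, p-value and
#'   deviation direction. Monomorphic (sample, locus) combinations get
#'   `p = 1` and `direction = NA`.
#' @export
hwe_tests <- function(gm, metadata = NULL) {
  d <- gm$dosage
  sites <- if (is.null(metadata)) rep("all", nrow(d)) else
    align_metadata(gm, metadata)$site
  rows <- lapply(split(seq_len(nrow(d)), sites), function(idx) {
    x <- d[idx, , drop = FALSE]
    do.call(rbind, lapply(seq_len(ncol(x)), function(j) {
      naa <- sum(x[, j] == 0, na.rm = TRUE)
      nab <- sum(x[, j] == 1, na.rm = TRUE)
      nbb <- sum(x[, j] == 2, na.rm = TRUE)
      if (naa + nab + nbb == 0) return(NULL)
      r <- hwe_exact_test(naa, nab, nbb)
      data.frame(site = sites[idx][1], locus = colnames(x)[j],
                 n_aa = naa, n_ab = nab, n_bb = nbb, p = r$p,
                 direction = r$direction %||% NA_character_,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Genotype accumulation curve
#'
#' For subset sizes 1 .. `max_loci`, repeatedly samples that many loci
#' without replacement and counts distinct multilocus genotypes (missing
#' calls count as their own symbol).
#'
#' @param gm a [genotype_matrix()].
#' @param max_loci largest subset size (default: number of loci - 1).
#' @param reps resamples per subset size.
#' @param seed RNG seed.
#' @return matrix `reps x max_loci` of MLG counts, class
#'   `genotype_accumulation`.
#' @export
genotype_accumulation_curve <- function(gm, max_loci = ncol(gm$dosage) - 1,
                                        reps = 25, seed = 1) {
  stopifnot(reps >= 1, max_loci >= 1, max_loci <= ncol(gm$dosage))
  d <- gm$dosage
  ch <- matrix(as.character(d), nrow(d), ncol(d))
  ch[is.na(ch)] <- "."
  out <- with_seed(seed, {
    vapply(seq_len(max_loci), function(k) {
      vapply(seq_len(reps), function(r) {
        js <- sample.int(ncol(ch), k)
        length(unique(apply(ch[, js, drop = FALSE], 1, paste,
                            collapse = "")))
      }, numeric(1))
    }, numeric(reps))
  })
  out <- matrix(out, nrow = reps)
  colnames(out) <- seq_len(max_loci)
  class(out) <- c("genotype_accumulation", class(out))
  out
}

#' Kruskal-Wallis comparison of diversity estimates among groups
#'
#' @param values numeric vector (e.g. per-sample uHe).
#' @param grouping group label per value.
#' @return list with `H`, `df` and `p`.
#' @export
kruskal_wallis_groups <- function(values, grouping) {
  grouping <- as.factor(grouping)
  if (nlevels(droplevels(grouping)) < 2)
    stop("need at least two groups")
  if (length(unique(values)) == 1)  # complete ties: no evidence either way
    return(list(H = 0, df = nlevels(droplevels(grouping)) - 1, p = 1))
  kt <- kruskal.test(values, grouping)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}
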
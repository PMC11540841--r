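#' Simulation configuration
#'
#' Describes a synthetic SNP-panel dataset with hierarchical population
#' structure plus a non-recombining inversion block. Background loci follow a
#' Balding-Nichols model: each locus draws an ancestral B-allele frequency
#' uniformly on `maf_range` (random side), each group draws its frequency
#' from a Beta distribution centred on the ancestral value with dispersion
#' `fst_between`, and each site from a Beta centred on its group value with
#' dispersion `fst_within`; genotypes are Hardy-Weinberg draws within site.
#' Inversion loci are generated by first drawing each individual's karyotype
#' (pair of arrangements) from its group's `(fAA, fAB, fBB)` and then
#' drawing each allele copy from its arrangement's allele-frequency profile:
#' perfectly diagnostic loci carry the A allele with probability 1 on
#' arrangement A and 0 on arrangement B; partial loci use the rows of
#' `partial_freqs`.
#'
#' @param seed integer global seed; one RNG stream is derived per stage.
#' @param groups data.frame with columns `group`, `site`, `n` (individuals
#'   per site) and optionally `latitude`, `longitude`, `year`.
#' @param n_background_loci,n_inversion_loci,n_diagnostic locus counts;
#'   `n_diagnostic <= n_inversion_loci` are perfectly diagnostic.
#' @param fst_between,fst_within target differentiation levels of the
#'   Balding-Nichols hierarchy. `fst_between` may be a named vector with
#'   one drift level per group (a group's divergence from the ancestral
#'   frequencies); a scalar applies to every group.
#' @param drift_shape shape of the Gamma multiplier applied per locus to
#'   the group drift (mean 1, so `fst_between` stays the mean drift);
#'   small values give the right-skewed per-locus differentiation typical
#'   of real SNP panels, `Inf` (default) gives homogeneous drift.
#' @param maf_range range of ancestral minor-allele frequencies.
#' @param group_maf_factor named numeric; per-group multiplicative shrink of
#'   the minor-allele frequency toward 0 (models reduced diversity, e.g. in
#'   an enclosed sea). Unnamed groups default to 1.
#' @param karyotype_freqs matrix with one row per group (rownames = group
#'   names) and columns `AA`, `AB`, `BB`, each row summing to 1.
#' @param partial_freqs two-column matrix (`pA_on_A`, `pA_on_B`): A-allele
#'   frequency on each arrangement for partially diagnostic loci (rows
#'   recycled).
#' @param missing_rate fraction of calls masked uniformly at random.
#' @param migrants optional data.frame with columns `to_site`, `from_group`,
#'   `n`: individuals whose genotypes are drawn from `from_group`'s profile
#'   but who are sampled (and labelled) at `to_site`.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1, groups, n_background_loci = 50,
                              n_inversion_loci = 0, n_diagnostic = 0,
                              fst_between = 0.1, fst_within = 0.005,
                              maf_range = c(0.05, 0.5),
                              group_maf_factor = NULL,
                              karyotype_freqs = NULL,
                              partial_freqs = NULL,
                              missing_rate = 0, migrants = NULL,
                              drift_shape = Inf) {
  stopifnot(is.data.frame(groups), all(c("group", "site", "n") %in%
                                         colnames(groups)))
  if (anyDuplicated(groups$site)) stop("sites must be unique")
  gnames <- unique(groups$group)
  if (n_inversion_loci > 0) {
    if (is.null(karyotype_freqs))
      stop("karyotype_freqs required when n_inversion_loci > 0")
    karyotype_freqs <- as.matrix(karyotype_freqs)
    colnames(karyotype_freqs) <- c("AA", "AB", "BB")
    if (!all(gnames %in% rownames(karyotype_freqs)))
      stop("karyotype_freqs must have a row for every group")
    if (any(abs(rowSums(karyotype_freqs) - 1) > 1e-8))
      stop("karyotype frequencies must sum to 1 within each group")
    if (n_diagnostic < n_inversion_loci && is.null(partial_freqs))
      stop("partial_freqs required when some inversion loci are partial")
  }
  if (!is.null(names(fst_between))) {
    if (!all(gnames %in% names(fst_between)))
      stop("fst_between must name every group (or be a scalar)")
  } else fst_between <- setNames(rep(fst_between[1], length(gnames)), gnames)
  stopifnot(missing_rate >= 0, missing_rate <= 1,
            all(fst_between >= 0), all(fst_between < 1),
            fst_within >= 0, fst_within < 1,
            n_background_loci >= 0, n_inversion_loci >= 0,
            n_diagnostic <= n_inversion_loci)
  gmf <- setNames(rep(1, length(gnames)), gnames)
  if (!is.null(group_maf_factor))
    gmf[names(group_maf_factor)] <- group_maf_factor
  structure(list(seed = as.integer(seed), groups = groups,
                 n_background_loci = n_background_loci,
                 n_inversion_loci = n_inversion_loci,
                 n_diagnostic = n_diagnostic,
                 fst_between = fst_between, fst_within = fst_within,
                 maf_range = maf_range, group_maf_factor = gmf,
                 karyotype_freqs = karyotype_freqs,
                 partial_freqs = partial_freqs,
                 missing_rate = missing_rate, migrants = migrants,
                 drift_shape = drift_shape),
            class = "simulation_config")
}

# Balding-Nichols draw: frequencies around p with E = p, Var = F p (1 - p).
# p and F are recycled; each draw may use its own drift level.
rbalding_nichols <- function(n, p, F) {
  p <- rep_len(p, n); F <- rep_len(F, n)
  out <- p
  pos <- F > 0
  out[pos] <- rbeta(sum(pos), p[pos] * (1 - F[pos]) / F[pos],
                    (1 - p[pos]) * (1 - F[pos]) / F[pos])
  pmin(pmax(out, 1e-6), 1 - 1e-6)
}

#' Preset emulating a three-habitat, inversion-carrying study design
#'
#' Sixteen sites in three habitat groups (Ocean, Fjords, Mediterranean) with
#' low within-group and higher between-group background differentiation,
#' strongly reduced Mediterranean diversity, and a 12-locus inversion block
#' (5 perfectly diagnostic loci) with group-specific karyotype frequencies:
#' the Mediterranean fixed for BB, the Ocean AA-rich (56.7% AA, remainder in
#' Hardy-Weinberg ratio), and the Fjords near-Mendelian proportions
#' (18.5/53.7/27.9%).
#'
#' @param seed global seed.
#' @param n_scale multiplier applied to per-site sample sizes (minimum 4
#'   individuals per site), for desk-scale runs.
#' @param missing_rate fraction of calls masked at random.
#' @param migrants optional migrant specification (see
#'   [simulation_config()]).
#' @return A [simulation_config()].
#' @export
preset_three_habitats <- function(seed = 1, n_scale = 1, missing_rate = 0.02,
                                  migrants = NULL) {
  sites <- data.frame(
    group = rep(c("Ocean", "Fjords", "Mediterranean"), c(7, 5, 4)),
    site = c("BaffinBay", "Labrador", "NorwegianSea", "SIceland",
             "Atlantic59N", "BayOfBiscay", "NPortugal",
             "Osterfjorden", "Korsfjorden", "Bjornafjorden",
             "Hardangerfjorden", "Boknafjorden",
             "Alboran", "Balears", "IonianSea", "AegeanSea"),
    n = c(43, 37, 36, 87, 189, 81, 97, 156, 25, 210, 40, 89, 24, 51, 63, 60),
    latitude = c(65.93, 61.43, 63.65, 62.19, 59.58, 46.71, 41.53, 60.62,
                 60.16, 60.12, 60.03, 59.20, 36.00, 38.50, 38.09, 37.60),
    longitude = c(-58.12, -60.65, 4.10, -18.42, -15.68, -8.69, -12.92, 5.52,
                  5.09, 5.62, 5.93, 5.61, -3.96, 2.50, 22.74, 23.26),
    year = c(2021, 2022, 2020, 2020, 2020, 2020, 2020, 2018, 2017, 2018,
             2018, 2018, 2020, 2020, 2019, 2019),
    stringsAsFactors = FALSE)
  sites$n <- pmax(4L, as.integer(round(sites$n * n_scale)))
  kf <- rbind(Ocean = c(0.567, 0.372, 0.061) / sum(c(0.567, 0.372, 0.061)),
              Fjords = c(0.185, 0.537, 0.279) / sum(c(0.185, 0.537, 0.279)),
              Mediterranean = c(0, 0, 1))
  colnames(kf) <- c("AA", "AB", "BB")
  # arrangement-level A-allele frequencies for the 7 partially diagnostic
  # loci; values emulate the observed per-karyotype frequency spectrum
  pf <- cbind(pA_on_A = c(1.00, 0.70, 0.73, 0.74, 0.74, 0.74, 0.55),
              pA_on_B = c(0.08, 0.00, 0.00, 0.04, 0.00, 0.02, 0.00))
  simulation_config(seed = seed, groups = sites,
                    n_background_loci = 109, n_inversion_loci = 12,
                    n_diagnostic = 5,
                    fst_between = c(Ocean = 0.02, Fjords = 0.12,
                                    Mediterranean = 0.02),
                    fst_within = 0.004, maf_range = c(0.05, 0.35),
                    group_maf_factor = c(Mediterranean = 0.35),
                    karyotype_freqs = kf, partial_freqs = pf,
                    missing_rate = missing_rate, migrants = migrants)
}

#' Simulate a genotype dataset with ground truth
#'
#' @param config a [simulation_config()].
#' @return list with `genotypes` ([genotype_matrix()]), `metadata`
#'   ([sample_metadata()]) and `truth` (list with per-individual karyotypes,
#'   per-locus classes, simulated frequencies and migrant identities).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  g <- config$groups
  n_bg <- config$n_background_loci
  n_inv <- config$n_inversion_loci
  n_diag <- config$n_diagnostic
  gnames <- unique(g$group)

  ind <- data.frame(
    individual = unlist(lapply(seq_len(nrow(g)), function(i)
      sprintf("%s_%03d", g$site[i], seq_len(g$n[i])))),
    site = rep(g$site, g$n), group = rep(g$group, g$n),
    origin_group = rep(g$group, g$n), stringsAsFactors = FALSE)

  # migrants: appended individuals genotyped from their origin group
  if (!is.null(config$migrants)) {
    m <- config$migrants
    mi <- do.call(rbind, lapply(seq_len(nrow(m)), function(i) {
      to <- m$to_site[i]
      data.frame(individual = sprintf("%s_m%02d_%02d", to, i, seq_len(m$n[i])),
                 site = to, group = g$group[match(to, g$site)],
                 origin_group = m$from_group[i], stringsAsFactors = FALSE)
    }))
    ind <- rbind(ind, mi)
  }
  n_ind <- nrow(ind)

  bg_names <- sprintf("bg%03d", seq_len(n_bg))
  inv_names <- if (n_inv) sprintf("inv%02d", seq_len(n_inv)) else character(0)
  locus_class <- c(rep("background", n_bg),
                   rep(c("inversion-diagnostic", "inversion-partial"),
                       c(n_diag, n_inv - n_diag)))
  names(locus_class) <- c(bg_names, inv_names)

  # ancestral and hierarchical background frequencies (B allele)
  anc <- with_seed(derive_seed(config$seed, "ancestral"), {
    m <- runif(n_bg, config$maf_range[1], config$maf_range[2])
    ifelse(runif(n_bg) < 0.5, m, 1 - m)
  })
  shape <- config$drift_shape %||% Inf
  group_freq <- with_seed(derive_seed(config$seed, "group_freqs"), {
    gf <- t(vapply(gnames, function(gn) {
      Fg <- config$fst_between[[gn]]
      Fl <- if (is.finite(shape))
        pmin(Fg * rgamma(n_bg, shape, shape), 0.95) else rep(Fg, n_bg)
      rbalding_nichols(n_bg, anc, Fl)
    }, numeric(n_bg)))
    gf <- matrix(gf, nrow = length(gnames), dimnames = list(gnames, bg_names))
    for (gn in gnames) {               # diversity shrink: pull MAF toward 0
      f <- config$group_maf_factor[[gn]]
      if (f < 1) {
        p <- gf[gn, ]
        m <- pmin(p, 1 - p) * f
        gf[gn, ] <- ifelse(p <= 0.5, m, 1 - m)
      }
    }
    gf
  })
  site_freq <- with_seed(derive_seed(config$seed, "site_freqs"), {
    sf <- t(vapply(seq_len(nrow(g)), function(i)
      vapply(group_freq[g$group[i], ], function(p)
        rbalding_nichols(1, p, config$fst_within), numeric(1)),
      numeric(n_bg)))
    dimnames(sf) <- list(g$site, bg_names)
    sf
  })

  d <- matrix(NA_integer_, n_ind, n_bg + n_inv,
              dimnames = list(ind$individual, c(bg_names, inv_names)))
  with_seed(derive_seed(config$seed, "background"), {
    for (i in seq_len(n_ind)) {
      src <- if (ind$origin_group[i] == ind$group[i]) ind$site[i] else
        g$site[match(ind$origin_group[i], g$group)]   # first site of origin
      d[i, seq_len(n_bg)] <- rbinom(n_bg, 2, site_freq[src, ])
    }
  })

  karyo <- rep(NA_character_, n_ind)
  if (n_inv) {
    kf <- config$karyotype_freqs
    karyo <- with_seed(derive_seed(config$seed, "karyotype"), {
      vapply(ind$origin_group, function(gn)
        sample(c("AA", "AB", "BB"), 1, prob = kf[gn, ]), "")
    })
    # arrangement pair per individual: number of B arrangements
    n_arrB <- c(AA = 0L, AB = 1L, BB = 2L)[karyo]
    pA <- rbind(
      matrix(rep(c(1, 0), n_diag), ncol = 2, byrow = TRUE),
      if (n_inv > n_diag) {
        idx <- rep(seq_len(nrow(config$partial_freqs)),
                   length.out = n_inv - n_diag)
        config$partial_freqs[idx, , drop = FALSE]
      })
    with_seed(derive_seed(config$seed, "inversion"), {
      for (j in seq_len(n_inv)) {
        # each copy carries the A allele with its arrangement's frequency;
        # dosage counts B alleles
        nB_copy1 <- rbinom(n_ind, 1, 1 - ifelse(n_arrB >= 1, pA[j, 2], pA[j, 1]))
        nB_copy2 <- rbinom(n_ind, 1, 1 - ifelse(n_arrB == 2, pA[j, 2], pA[j, 1]))
        d[, n_bg + j] <- nB_copy1 + nB_copy2
      }
    })
  }

  if (config$missing_rate > 0) {
    with_seed(derive_seed(config$seed, "missing"), {
      mask <- runif(length(d)) < config$missing_rate
      d[mask] <- NA_integer_
    })
  }

  gm <- genotype_matrix(d)
  md <- sample_metadata(
    individual = ind$individual, site = ind$site, group = ind$group,
    latitude = g$latitude[match(ind$site, g$site)] %||% NA_real_,
    longitude = g$longitude[match(ind$site, g$site)] %||% NA_real_,
    year = g$year[match(ind$site, g$site)] %||% NA_integer_)
  truth <- list(karyotype = setNames(karyo, ind$individual),
                locus_class = locus_class,
                site_freq = site_freq, group_freq = group_freq,
                arrangement_freq_A = if (n_inv) {
                  pA <- rbind(matrix(rep(c(1, 0), n_diag), ncol = 2,
                                     byrow = TRUE),
                              if (n_inv > n_diag) {
                                idx <- rep(seq_len(nrow(config$partial_freqs)),
                                           length.out = n_inv - n_diag)
                                config$partial_freqs[idx, , drop = FALSE]
                              })
                  dimnames(pA) <- list(inv_names, c("arrA", "arrB"))
                  pA
                },
                migrant_ids = ind$individual[ind$origin_group != ind$group],
                origin_group = setNames(ind$origin_group, ind$individual))
  list(genotypes = gm, metadata = md, truth = truth)
}

#' Write or read a simulation config as YAML
#' @param config a [simulation_config()].
#' @param path file path.
#' @export
write_simulation_config <- function(config, path) {
  x <- unclass(config)
  x$groups <- as.list(x$groups)
  x$karyotype_freqs <- if (!is.null(x$karyotype_freqs))
    list(groups = rownames(x$karyotype_freqs),
         values = unname(split(x$karyotype_freqs, row(x$karyotype_freqs))))
  x$partial_freqs <- if (!is.null(x$partial_freqs))
    unname(split(x$partial_freqs, row(x$partial_freqs)))
  x$group_maf_factor <- as.list(x$group_maf_factor)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_simulation_config
#' @export
read_simulation_config <- function(path) {
  x <- yaml::read_yaml(path)
  kf <- if (!is.null(x$karyotype_freqs)) {
    m <- do.call(rbind, x$karyotype_freqs$values)
    rownames(m) <- x$karyotype_freqs$groups
    m
  }
  pf <- if (!is.null(x$partial_freqs)) do.call(rbind, x$partial_freqs)
  simulation_config(seed = x$seed, groups = as.data.frame(x$groups),
                    drift_shape = x$drift_shape %||% Inf,
                    n_background_loci = x$n_background_loci,
                    n_inversion_loci = x$n_inversion_loci,
                    n_diagnostic = x$n_diagnostic,
                    fst_between = x$fst_between, fst_within = x$fst_within,
                    maf_range = unlist(x$maf_range),
                    group_maf_factor = unlist(x$group_maf_factor),
                    karyotype_freqs = kf, partial_freqs = pf,
                    missing_rate = x$missing_rate,
                    migrants = if (!is.null(x$migrants))
                      as.data.frame(x$migrants))
}
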
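#' Genotype matrix container
#'
#' Stores diploid biallelic calls for a panel of individuals and loci. Calls
#' are kept internally as the dosage of each locus's B allele (0, 1, 2 or
#' `NA` for missing); because calls are unordered allele pairs over two
#' alleles, the dosage view is lossless. The per-locus allele codes are kept
#' alongside so genotypes can be rendered back as allele pairs.
#'
#' @param dosage integer matrix, individuals in rows and loci in columns,
#'   values in \{0, 1, 2, NA\}; 0 means two copies of the A allele.
#' @param locus_alleles data.frame with columns `locus`, `allele_a`,
#'   `allele_b`; defaults to codes "01"/"02" per locus.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, locus_alleles = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("ind", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage)))
    colnames(dosage) <- paste0("loc", seq_len(ncol(dosage)))
  storage.mode(dosage) <- "integer"
  if (is.null(locus_alleles)) {
    locus_alleles <- data.frame(locus = colnames(dosage),
                                allele_a = "01", allele_b = "02",
                                stringsAsFactors = FALSE)
  }
  gm <- structure(list(dosage = dosage, locus_alleles = locus_alleles),
                  class = "genotype_matrix")
  validate_genotype_matrix(gm)
  gm
}

validate_genotype_matrix <- function(gm) {
  d <- gm$dosage
  if (anyDuplicated(rownames(d)))
    stop("duplicated individual IDs in genotype matrix")
  if (anyDuplicated(colnames(d)))
    stop("duplicated locus IDs in genotype matrix")
  bad <- !is.na(d) & !(d %in% 0:2)
  if (any(bad))
    stop("dosage values must be 0, 1, 2 or NA (found e.g. ",
         d[which(bad)[1]], ")")
  la <- gm$locus_alleles
  if (!identical(la$locus, colnames(d)))
    stop("locus_alleles registry does not match dosage columns")
  invisible(gm)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  d <- x$dosage
  cat("genotype_matrix:", nrow(d), "individuals x", ncol(d), "loci;",
      sprintf("%.1f%% missing\n", 100 * mean(is.na(d))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Individual and locus IDs of a genotype matrix
#' @param gm a `genotype_matrix`.
#' @return Character vector of IDs.
#' @export
individuals <- function(gm) rownames(gm$dosage)

#' @rdname individuals
#' @export
loci <- function(gm) colnames(gm$dosage)

#' Dosage view of a genotype matrix
#'
#' @param gm a `genotype_matrix`.
#' @return Integer matrix of B-allele counts (individuals x loci).
#' @export
dosage <- function(gm) gm$dosage

#' Subset a genotype matrix
#' @param x a `genotype_matrix`.
#' @param i,j individual / locus index (numeric, logical or character).
#' @param ... ignored.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  d <- x$dosage[i, j, drop = FALSE]
  la <- x$locus_alleles[match(colnames(d), x$locus_alleles$locus), ,
                        drop = FALSE]
  rownames(la) <- NULL
  genotype_matrix(d, la)
}

#' Render calls as allele pairs
#'
#' @param gm a `genotype_matrix`.
#' @param sep separator between the two allele codes.
#' @param missing string used for missing calls.
#' @return Character matrix of unordered allele-pair strings.
#' @export
genotype_calls <- function(gm, sep = "/", missing = NA_character_) {
  d <- gm$dosage
  out <- matrix(missing, nrow(d), ncol(d), dimnames = dimnames(d))
  for (j in seq_len(ncol(d))) {
    a <- gm$locus_alleles$allele_a[j]
    b <- gm$locus_alleles$allele_b[j]
    gt <- c(paste(a, a, sep = sep), paste(a, b, sep = sep),
            paste(b, b, sep = sep))
    ok <- !is.na(d[, j])
    out[ok, j] <- gt[d[ok, j] + 1L]
  }
  out
}

#' Per-sample allele frequency of the B allele
#'
#' @param gm a `genotype_matrix`.
#' @param sites factor/character of per-individual sample labels (`NULL` =
#'   one pooled sample).
#' @return Matrix of B-allele frequencies, samples x loci (`NaN` where a
#'   sample has no typed calls at a locus).
#' @export
allele_freq_by_sample <- function(gm, sites = NULL) {
  d <- gm$dosage
  if (is.null(sites)) sites <- rep("all", nrow(d))
  sites <- as.character(sites)
  out <- t(vapply(split(seq_len(nrow(d)), sites), function(idx) {
    colMeans(d[idx, , drop = FALSE], na.rm = TRUE) / 2
  }, numeric(ncol(d))))
  colnames(out) <- colnames(d)
  out
}

#' Sample metadata constructor
#'
#' @param individual,site,group character vectors (recycled where length 1).
#' @param latitude,longitude,year,depth optional numeric vectors.
#' @return data.frame of class `sample_metadata`, one row per individual.
#' @export
sample_metadata <- function(individual, site, group,
                            latitude = NA_real_, longitude = NA_real_,
                            year = NA_integer_, depth = NA_real_) {
  md <- data.frame(individual = as.character(individual),
                   site = as.character(site), group = as.character(group),
                   latitude = latitude, longitude = longitude,
                   year = year, depth = depth, stringsAsFactors = FALSE)
  if (anyDuplicated(md$individual))
    stop("duplicated individual IDs in metadata")
  # habitat group must be a function of site
  bysite <- unique(md[, c("site", "group")])
  if (anyDuplicated(bysite$site))
    stop("each site must belong to exactly one group")
  class(md) <- c("sample_metadata", "data.frame")
  md
}

# Align metadata rows to a genotype matrix, erroring on unmatched individuals.
align_metadata <- function(gm, metadata) {
  idx <- match(individuals(gm), metadata$individual)
  if (anyNA(idx))
    stop("metadata missing for individuals: ",
         paste(head(individuals(gm)[is.na(idx)]), collapse = ", "))
  metadata[idx, , drop = FALSE]
}
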
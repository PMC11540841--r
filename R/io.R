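#' Read genotypes from Genepop or tabular files
#'
#' Two dialects are supported. `format = "genepop"` reads classic Genepop
#' files with 2- or 3-digit allele codes ("00"/"000" = missing allele); each
#' POP block becomes one site. `format = "table"` reads a tab-separated table
#' with individuals in rows, loci in columns and calls written as
#' `"01/02"`-style allele pairs (`"00/00"`, `"00"` or empty = missing).
#' Coordinates, years and habitat groups travel in a sidecar metadata table
#' (see [read_metadata()]); the metadata returned here records the site
#' (POP block) of each individual with the site name doubling as group.
#'
#' @param path file path.
#' @param format `"genepop"` or `"table"`.
#' @return list with elements `genotypes` (a [genotype_matrix()]) and
#'   `metadata` (a [sample_metadata()]).
#' @export
read_genotypes <- function(path, format = c("genepop", "table")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "genepop") read_genepop(path) else read_geno_table(path)
}

read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3) stop("malformed Genepop file: fewer than 3 lines")
  pop_idx <- grep("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  if (!length(pop_idx)) stop("malformed Genepop file: no POP line found")
  header <- lines[2:(pop_idx[1] - 1)]
  # locus names either one per line, or comma-separated on one line
  loci <- trimws(unlist(strsplit(header, ",")))
  loci <- loci[nzchar(loci)]
  pops <- split_pop_blocks(lines, pop_idx)
  inds <- character(0); sites <- character(0); rows <- list()
  for (p in seq_along(pops)) {
    for (ln in pops[[p]]) {
      line_no <- which(lines == ln)[1]
      parts <- strsplit(ln, ",")[[1]]
      if (length(parts) < 2)
        stop("Genepop parse error at line ", line_no, ": missing ',' separator")
      id <- trimws(parts[1])
      toks <- strsplit(trimws(paste(parts[-1], collapse = ",")), "\\s+")[[1]]
      if (length(toks) != length(loci))
        stop("Genepop parse error at line ", line_no, ": expected ",
             length(loci), " genotypes, found ", length(toks))
      w <- nchar(toks)
      if (!all(w %in% c(4L, 6L)) || length(unique(w)) != 1)
        stop("Genepop parse error at line ", line_no,
             ": genotype codes must be uniformly 4 or 6 digits")
      inds <- c(inds, id)
      sites <- c(sites, paste0("POP", p))
      rows[[length(rows) + 1L]] <- toks
    }
  }
  dg <- nchar(rows[[1]][1]) / 2
  a1 <- t(vapply(rows, function(r) substr(r, 1, dg), character(length(loci))))
  a2 <- t(vapply(rows, function(r) substr(r, dg + 1, 2 * dg),
                 character(length(loci))))
  build_gm_from_allele_pairs(a1, a2, inds, loci, sites,
                             missing_code = strrep("0", dg))
}

split_pop_blocks <- function(lines, pop_idx) {
  ends <- c(pop_idx[-1] - 1, length(lines))
  lapply(seq_along(pop_idx), function(i) {
    if (pop_idx[i] + 1 > ends[i]) character(0)
    else lines[(pop_idx[i] + 1):ends[i]]
  })
}

read_geno_table <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", colClasses = "character",
                    check.names = FALSE)
  if (ncol(tab) < 2) stop("malformed genotype table: need id column + loci")
  inds <- tab[[1]]
  loci <- colnames(tab)[-1]
  calls <- as.matrix(tab[, -1, drop = FALSE])
  miss <- is.na(calls) | calls %in% c("", "00", "000", "00/00", "000/000")
  a1 <- a2 <- matrix(NA_character_, nrow(calls), ncol(calls))
  sp <- strsplit(calls[!miss], "/", fixed = TRUE)
  if (length(sp) && any(lengths(sp) != 2))
    stop("malformed genotype table: calls must be 'a/b' pairs ",
         "(found '", calls[!miss][which(lengths(sp) != 2)[1]], "')")
  a1[!miss] <- vapply(sp, `[`, "", 1)
  a2[!miss] <- vapply(sp, `[`, "", 2)
  build_gm_from_allele_pairs(a1, a2, inds, loci, sites = rep("POP1",
                                                             length(inds)),
                             missing_code = NA)
}

build_gm_from_allele_pairs <- function(a1, a2, inds, loci, sites,
                                       missing_code) {
  if (!is.na(missing_code)) {
    a1[a1 == missing_code] <- NA
    a2[a2 == missing_code] <- NA
  }
  half <- xor(is.na(a1), is.na(a2))
  if (any(half))
    stop("validation error: half-missing call for individual ",
         inds[which(half, arr.ind = TRUE)[1, 1]])
  d <- matrix(NA_integer_, length(inds), length(loci),
              dimnames = list(inds, loci))
  la <- data.frame(locus = loci, allele_a = "01", allele_b = "02",
                   stringsAsFactors = FALSE)
  for (j in seq_along(loci)) {
    al <- sort(unique(c(a1[, j], a2[, j])))
    al <- al[!is.na(al)]
    if (length(al) > 2)
      stop("validation error: locus ", loci[j], " has ", length(al),
           " alleles; only biallelic loci are supported")
    if (length(al) == 0) al <- c("01", "02")
    if (length(al) == 1) al <- c(al, if (al == "01") "02" else "01")
    la$allele_a[j] <- al[1]; la$allele_b[j] <- al[2]
    d[, j] <- (a1[, j] == al[2]) + (a2[, j] == al[2])
  }
  gm <- genotype_matrix(d, la)
  md <- sample_metadata(individual = inds, site = sites, group = sites)
  list(genotypes = gm, metadata = md)
}

#' Write genotypes to Genepop or tabular files
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @param format `"genepop"` or `"table"`.
#' @param metadata optional [sample_metadata()]; for Genepop output its
#'   `site` column defines the POP blocks (default: one block).
#' @param title title line for Genepop output.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path, format = c("genepop", "table"),
                            metadata = NULL, title = "karyopop export") {
  format <- match.arg(format)
  if (format == "table") {
    calls <- genotype_calls(gm)
    calls[is.na(calls)] <- "00/00"
    tab <- data.frame(individual = individuals(gm), calls,
                      check.names = FALSE, stringsAsFactors = FALSE)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  la <- gm$locus_alleles
  dg <- max(nchar(c(la$allele_a, la$allele_b)), 2)
  pad <- function(x) formatC(x, width = dg, flag = "0")
  d <- gm$dosage
  sites <- if (is.null(metadata)) rep("POP1", nrow(d)) else
    align_metadata(gm, metadata)$site
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(loci(gm), con)
  for (s in unique(sites)) {
    writeLines("POP", con)
    for (i in which(sites == s)) {
      g <- vapply(seq_len(ncol(d)), function(j) {
        if (is.na(d[i, j])) return(strrep("0", 2 * dg))
        a <- pad(la$allele_a[j]); b <- pad(la$allele_b[j])
        c(paste0(a, a), paste0(a, b), paste0(b, b))[d[i, j] + 1L]
      }, "")
      writeLines(paste0(individuals(gm)[i], " ,  ", paste(g, collapse = " ")),
                 con)
    }
  }
  invisible(path)
}

#' Read / write a sample metadata table
#'
#' Tab-separated, columns `individual`, `site`, `group` and optionally
#' `latitude`, `longitude`, `year`, `depth`.
#'
#' @param path file path.
#' @return A [sample_metadata()] data.frame.
#' @export
read_metadata <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("individual", "site", "group")
  if (!all(need %in% colnames(tab)))
    stop("metadata table must have columns: ", paste(need, collapse = ", "))
  sample_metadata(individual = tab$individual, site = tab$site,
                  group = tab$group,
                  latitude = tab$latitude %||% NA_real_,
                  longitude = tab$longitude %||% NA_real_,
                  year = tab$year %||% NA_integer_,
                  depth = tab$depth %||% NA_real_)
}

#' @rdname read_metadata
#' @param metadata a [sample_metadata()].
#' @export
write_metadata <- function(metadata, path) {
  write.table(as.data.frame(metadata), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
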
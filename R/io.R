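# File formats: pedigree TSV, long-format phenotype CSV, PLINK-RAW-style
# additive dosage text (with a companion .map), VCF reading (GT-based
# dosages, flipped to minor-allele counting), BED-like window maps and JSON
# fit serializations.

#' Write / read a pedigree as tab-separated text
#'
#' Columns: id, sire, dam, sex, family, generation; unknown parents coded 0.
#'
#' @param pedigree Pedigree data frame.
#' @param path Output path.
#' @export
write_pedigree <- function(pedigree, path) {
  write.table(pedigree[, c("id", "sire", "dam", "sex", "family", "generation")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_pedigree
#' @return `read_pedigree()` returns the pedigree data frame.
#' @export
read_pedigree <- function(path) {
  ped <- read.table(path, header = TRUE, sep = "\t",
                    colClasses = c(sex = "character"))
  need <- c("id", "sire", "dam", "sex", "family", "generation")
  miss <- setdiff(need, names(ped))
  if (length(miss)) stop_famgp("pedigree file lacks columns: ",
                               paste(miss, collapse = ", "))
  ped
}

#' Write / read long-format phenotype records as CSV
#'
#' @param phenotypes Long-format phenotype data frame.
#' @param path Output path.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.csv(phenotypes, path, row.names = FALSE, quote = FALSE)
}

#' @rdname write_phenotypes
#' @return `read_phenotypes()` returns the records data frame.
#' @export
read_phenotypes <- function(path) {
  utils::read.csv(path)
}

#' Write genotypes as PLINK-RAW-style dosage text
#'
#' Header `FID IID PAT MAT SEX PHENOTYPE <marker>_A ...`, one row per
#' individual, dosages in 0/1/2 (counted allele "A" is the minor allele). A
#' companion `<path>.map` file (chrom, id, 0, pos) preserves marker
#' positions.
#'
#' @param genotypes `famgp_geno`.
#' @param path Output path for the RAW text; the map goes to `<path>.map`.
#' @param pedigree Optional pedigree supplying FID/PAT/MAT/SEX columns.
#' @export
write_genotypes_raw <- function(genotypes, path, pedigree = NULL) {
  D <- dosages(genotypes)
  ids <- rownames(D)
  if (!is.null(pedigree)) {
    i <- match(ids, as.character(pedigree$id))
    fid <- pedigree$family[i]; pat <- pedigree$sire[i]; mat <- pedigree$dam[i]
    sex <- ifelse(pedigree$sex[i] == "M", 1L, 2L)
  } else {
    fid <- ids; pat <- 0L; mat <- 0L; sex <- 0L
  }
  hdr <- data.frame(FID = fid, IID = ids, PAT = pat, MAT = mat, SEX = sex,
                    PHENOTYPE = -9L)
  out <- cbind(hdr, as.data.frame(D))
  names(out)[-(1:6)] <- paste0(colnames(D), "_A")
  write.table(out, path, sep = " ", quote = FALSE, row.names = FALSE)
  map <- genotypes$map
  write.table(data.frame(map$chrom, map$id, 0, map$pos),
              paste0(path, ".map"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

read_genotypes_raw <- function(path) {
  if (file.info(path)$size == 0) stop_famgp("empty genotype file: ", path)
  raw <- read.table(path, header = TRUE, check.names = FALSE)
  need <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(need %in% names(raw)[1:6]))
    stop_famgp("not a PLINK-RAW-style file (missing header columns): ", path)
  D <- as.matrix(raw[, -(1:6), drop = FALSE])
  bad <- which(!(D %in% c(0, 1, 2)))
  if (length(bad)) {
    row <- ((bad[1] - 1) %% nrow(D)) + 1
    stop_famgp("dosage outside {0,1,2} at data line ", row + 1L, " of ", path)
  }
  storage.mode(D) <- "integer"
  rownames(D) <- as.character(raw$IID)
  colnames(D) <- sub("_[ACGT0-9]+$", "", colnames(D))
  mappath <- paste0(path, ".map")
  map <- if (file.exists(mappath)) {
    mp <- read.table(mappath, sep = "\t",
                     col.names = c("chrom", "id", "cm", "pos"))
    data.frame(id = mp$id, chrom = mp$chrom, pos = mp$pos,
               stringsAsFactors = FALSE)
  } else {
    data.frame(id = colnames(D), chrom = 1L, pos = seq_len(ncol(D)),
               stringsAsFactors = FALSE)
  }
  mi <- match(colnames(D), map$id)
  if (anyNA(mi)) stop_famgp("marker ids in RAW and map files disagree")
  new_geno(D, map[mi, , drop = FALSE])
}

read_genotypes_vcf <- function(path, missing = c("reject", "mean")) {
  missing <- match.arg(missing)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  count_alt <- function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_integer_)
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == ".")) return(NA_integer_)
    sum(al != "0")
  }
  D <- apply(gt, c(1, 2), count_alt)
  if (anyNA(D)) {
    if (missing == "reject") {
      bad <- which(rowSums(is.na(D)) > 0)[1]
      stop_famgp("missing genotype at VCF record ", bad,
                 " (use missing = \"mean\" to impute)")
    }
    for (i in seq_len(nrow(D))) {
      nas <- is.na(D[i, ])
      if (any(nas)) D[i, nas] <- round(mean(D[i, !nas]))
    }
  }
  D <- t(D)  # individuals x markers
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[
    is.na(ids) | ids == "."]
  colnames(D) <- ids
  # flip to minor-allele counting per marker
  f <- colMeans(D) / 2
  flip <- f > 0.5
  D[, flip] <- 2L - D[, flip, drop = FALSE]
  counted <- ifelse(flip, fix[, "REF"], fix[, "ALT"])
  map <- data.frame(id = ids, chrom = fix[, "CHROM"],
                    pos = as.integer(fix[, "POS"]),
                    counted_allele = counted, flipped = flip,
                    stringsAsFactors = FALSE)
  storage.mode(D) <- "integer"
  new_geno(D, map)
}

#' Read a genotype matrix from VCF or PLINK-RAW-style text
#'
#' VCF genotypes (GT field, unphased or phased) are converted to ALT-allele
#' dosages and then flipped per marker so dosages count the minor allele;
#' flips are recorded in the map (`flipped`, `counted_allele`). RAW files are
#' taken as already minor-allele coded; a companion `<path>.map` provides
#' positions when present.
#'
#' @param path File path.
#' @param format "auto" (by extension), "vcf" or "raw".
#' @param missing Missing-genotype policy for VCF: "reject" (default) or
#'   "mean" imputation (rounded).
#' @return A `famgp_geno` object.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "raw"),
                           missing = c("reject", "mean")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_famgp("file not found: ", path)
  if (file.info(path)$size == 0) stop_famgp("empty genotype file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "raw"
  if (format == "vcf") read_genotypes_vcf(path, missing)
  else read_genotypes_raw(path)
}

#' Write a collapsed-SNP window map as BED-like text
#'
#' Columns: chrom, start, end (0-based half-open positions), window id,
#' member count, collapsed MAF.
#'
#' @param collapsed `famgp_collapsed` from [collapse_rare()].
#' @param path Output path.
#' @export
write_window_map <- function(collapsed, path) {
  w <- collapsed$windows
  bed <- data.frame(chrom = w$chrom, start = w$start - 1L, end = w$end,
                    name = w$window, n_members = w$n_members, maf = w$maf)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Serialize a variance-component or prediction fit to JSON
#'
#' @param fit `famgp_vc_fit` or `gp_fit`.
#' @param path Output path.
#' @export
write_fit_json <- function(fit, path) {
  x <- unclass(fit)
  x$trace <- NULL
  x$mcmc <- if (!is.null(x$mcmc)) unclass(x$mcmc)
  # keep names of per-individual / per-marker vectors (JSON objects)
  for (f in intersect(c("beta", "u_hat", "c_hat", "a_post_mean", "a_post_sd",
                        "inclusion_prob", "centers"), names(x)))
    if (!is.null(names(x[[f]]))) x[[f]] <- as.list(x[[f]])
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write the truth sidecar of a simulation (tests only)
#'
#' @param truth `truth` element of [simulate_phenotypes()].
#' @param path Output path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
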
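#' @useDynLib famgp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor kmeans lm optim rbinom rnorm rpois runif sd var
#' @importFrom utils read.table write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_famgp <- function(...) stop(..., call. = FALSE)

#' Extract the dosage matrix from a genotype object
#'
#' Accepts either a plain individuals-by-markers matrix or a `famgp_geno`
#' object and returns the dosage matrix.
#'
#' @param x A matrix or `famgp_geno` object.
#' @return Numeric matrix of allele dosages (rows = individuals).
#' @export
dosages <- function(x) {
  if (inherits(x, "famgp_geno")) x$dosages else as.matrix(x)
}

#' Subset a genotype object by markers and/or individuals
#'
#' @param geno A `famgp_geno` object.
#' @param marker_ids,individual_ids Ids to keep (NULL keeps all).
#' @return The subset `famgp_geno`.
#' @export
geno_subset <- function(geno, marker_ids = NULL, individual_ids = NULL) {
  stopifnot(inherits(geno, "famgp_geno"))
  d <- geno$dosages
  map <- geno$map
  if (!is.null(marker_ids)) {
    keep <- match(marker_ids, colnames(d))
    if (anyNA(keep)) stop_famgp("unknown marker ids: ",
                                paste(marker_ids[is.na(keep)][1:5], collapse = ", "))
    d <- d[, keep, drop = FALSE]
    map <- map[keep, , drop = FALSE]
  }
  if (!is.null(individual_ids)) {
    keep <- match(as.character(individual_ids), rownames(d))
    if (anyNA(keep)) stop_famgp("unknown individual ids in genotype matrix")
    d <- d[keep, , drop = FALSE]
  }
  new_geno(d, map)
}

new_geno <- function(dosages, map) {
  stopifnot(ncol(dosages) == nrow(map))
  structure(list(dosages = dosages, map = map), class = "famgp_geno")
}

#' @export
print.famgp_geno <- function(x, ...) {
  cat(sprintf("<famgp_geno> %d individuals x %d markers, %d chromosome(s)\n",
              nrow(x$dosages), ncol(x$dosages), length(unique(x$map$chrom))))
  invisible(x)
}
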
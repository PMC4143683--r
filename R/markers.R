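# Marker preparation: minor-allele frequencies, LD pruning on founders,
# common/rare stratification, and k-means collapsing of rare variants into
# three-level collapsed SNPs.

#' Per-marker minor allele frequency
#'
#' f = (sum of dosages) / (2 n); MAF = min(f, 1 - f).
#'
#' @param genotypes `famgp_geno` or dosage matrix.
#' @param subset_ids Optional individual ids to restrict the computation to.
#' @return Named numeric vector of MAFs.
#' @export
compute_maf <- function(genotypes, subset_ids = NULL) {
  M <- dosages(genotypes)
  if (!is.null(subset_ids)) {
    keep <- match(as.character(subset_ids), rownames(M))
    if (length(keep) == 0L || anyNA(keep))
      stop_famgp("subset_ids empty or not all present in the genotype matrix")
    M <- M[keep, , drop = FALSE]
  }
  if (nrow(M) == 0L) stop_famgp("no individuals to compute MAF over")
  f <- colSums(M) / (2 * nrow(M))
  pmin(f, 1 - f)
}

#' LD pruning on founders
#'
#' Greedy pairwise pruning within a sliding marker window, a dialect of
#' PLINK's `--indep-pairwise`: per chromosome, markers monomorphic on the
#' founders are removed first (their r2 is undefined), then windows of
#' `window` retained markers advance by `step`; within a window, while any
#' retained pair has squared genotypic correlation >= `r2_threshold`, the
#' member with the lower founder MAF is dropped (tie: the later position).
#' r2 is computed on founder dosages only.
#'
#' @param genotypes `famgp_geno`.
#' @param founder_ids Ids of the (unrelated) founders r2 is computed on.
#' @param r2_threshold Squared-correlation threshold in (0, 1].
#' @param window,step Window length (markers) and step.
#' @return Character vector of retained marker ids (map order).
#' @export
ld_prune <- function(genotypes, founder_ids, r2_threshold = 0.9,
                     window = 50L, step = 5L) {
  if (r2_threshold <= 0 || r2_threshold > 1)
    stop_famgp("r2_threshold must be in (0, 1]")
  stopifnot(inherits(genotypes, "famgp_geno"))
  if (length(founder_ids) == 0L) stop_famgp("founder_ids is empty")
  Fd <- dosages(geno_subset(genotypes, individual_ids = founder_ids))
  map <- genotypes$map
  maf_f <- compute_maf(Fd)
  kept <- character(0)
  for (ch in unique(map$chrom)) {
    ids <- map$id[map$chrom == ch][order(map$pos[map$chrom == ch])]
    ids <- ids[apply(Fd[, ids, drop = FALSE], 2, function(v) var(v) > 0)]
    if (length(ids) == 0L) next
    alive <- rep(TRUE, length(ids))
    pos_of <- map$pos[match(ids, map$id)]
    start <- 1L
    repeat {
      live_idx <- which(alive)
      if (start > length(live_idx)) break
      win <- live_idx[start:min(start + window - 1L, length(live_idx))]
      if (length(win) >= 2L) {
        repeat {
          w <- win[alive[win]]
          if (length(w) < 2L) break
          r2 <- suppressWarnings(cor(Fd[, ids[w], drop = FALSE]))^2
          r2[!is.finite(r2)] <- 0
          diag(r2) <- 0
          mx <- which(r2 >= r2_threshold, arr.ind = TRUE)
          if (nrow(mx) == 0L) break
          i <- w[mx[1, 1]]; j <- w[mx[1, 2]]
          drop_i <- if (maf_f[ids[i]] != maf_f[ids[j]])
            if (maf_f[ids[i]] < maf_f[ids[j]]) i else j
          else if (pos_of[i] > pos_of[j]) i else j
          alive[drop_i] <- FALSE
        }
      }
      if (start + window - 1L >= length(live_idx)) break
      start <- start + step
    }
    kept <- c(kept, ids[alive])
  }
  map$id[map$id %in% kept]
}

#' Stratify markers by minor allele frequency
#'
#' Partitions markers into common (MAF >= threshold) and rare
#' (0 < MAF < threshold); monomorphic markers (MAF = 0) are discarded and
#' counted.
#'
#' @param genotypes `famgp_geno`.
#' @param threshold MAF threshold (default 0.05; the boundary is common).
#' @param subset_ids Individuals MAF is computed over (default: all analysis
#'   individuals).
#' @return List with `common` and `rare` (`famgp_geno`, possibly 0 markers),
#'   `maf` (vector used), and `n_dropped` (monomorphic count).
#' @export
split_by_maf <- function(genotypes, threshold = 0.05, subset_ids = NULL) {
  maf <- compute_maf(genotypes, subset_ids)
  common <- names(maf)[maf >= threshold]
  rare <- names(maf)[maf > 0 & maf < threshold]
  n_dropped <- sum(maf == 0)
  list(common = geno_subset(genotypes, marker_ids = common),
       rare = geno_subset(genotypes, marker_ids = rare),
       maf = maf, n_dropped = n_dropped)
}

# k-means++ initial centers on the unique rows of x (returns row indices of ux)
kmpp_init <- function(ux, k) {
  n <- nrow(ux)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1L)
  d2 <- rowSums((ux - ux[rep(centers[1], n), , drop = FALSE])^2)
  for (j in seq_len(k - 1L)) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j + 1L] <- sample.int(n, 1L, prob = prob)
    d2n <- rowSums((ux - ux[rep(centers[j + 1L], n), , drop = FALSE])^2)
    d2 <- pmin(d2, d2n)
  }
  centers
}

# k-means with k-means++ initialization and restarts; returns the stats::kmeans
# fit with the lowest within-cluster SSE
kmeans_pp <- function(x, k, restarts = 10L, iter_max = 300L) {
  ux <- unique(x)
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- ux[kmpp_init(ux, k), , drop = FALSE]
    fit <- suppressWarnings(
      stats::kmeans(x, centers = init, iter.max = iter_max))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best
}

# size-rank coding: largest cluster -> 0, medium -> 1, smallest -> 2; ties in
# size broken by ascending centroid L2 norm (nearer the origin -> smaller code)
size_rank_codes <- function(cluster, centers) {
  sizes <- tabulate(cluster, nbins = nrow(centers))
  norms <- sqrt(rowSums(centers^2))
  rank_order <- order(-sizes, norms)
  code_of <- integer(nrow(centers))
  code_of[rank_order] <- seq_len(nrow(centers)) - 1L
  code_of[cluster]
}

#' Collapse rare variants into three-level collapsed SNPs by k-means
#'
#' Per chromosome, position-sorted rare markers are cut into consecutive
#' blocks of `window_size`; a final block with fewer than 2 markers is merged
#' into the preceding block (kept as-is if it is the only block). Within each
#' window, individuals are clustered on their dosage vectors by k-means with
#' k = 3 (k-means++ initialization, 10 restarts, 300-iteration cap,
#' minimizing within-cluster sums of squares). Individuals in the largest,
#' medium and smallest cluster are coded 0, 1 and 2 respectively (size ties
#' broken by ascending centroid norm), and the collapsed MAF is computed from
#' the codes. Windows with fewer than 3 distinct dosage vectors use as many
#' clusters as there are distinct vectors (a single cluster codes everyone 0).
#'
#' @param rare `famgp_geno` of rare markers.
#' @param window_size Markers per window (>= 2).
#' @param seed Integer seed making the clustering deterministic.
#' @return A `famgp_collapsed` object: `dosages` (individuals x windows codes
#'   in 0/1/2), `windows` (chrom, start/end position, member count, collapsed
#'   MAF, number of clusters used) and `members` (list of member marker ids).
#' @export
collapse_rare <- function(rare, window_size = 100L, seed = 1L) {
  stopifnot(inherits(rare, "famgp_geno"))
  if (ncol(rare$dosages) == 0L) stop_famgp("rare marker set is empty")
  if (window_size < 2L) stop_famgp("window_size must be >= 2")
  set.seed(seed)
  map <- rare$map
  D <- rare$dosages
  blocks <- list()
  for (ch in unique(map$chrom)) {
    ids <- map$id[map$chrom == ch][order(map$pos[map$chrom == ch])]
    nb <- ceiling(length(ids) / window_size)
    cut_idx <- split(ids, rep(seq_len(nb), each = window_size)[seq_along(ids)])
    if (nb >= 2L && length(cut_idx[[nb]]) < 2L) {
      cut_idx[[nb - 1L]] <- c(cut_idx[[nb - 1L]], cut_idx[[nb]])
      cut_idx[[nb]] <- NULL
    }
    blocks <- c(blocks, lapply(cut_idx, function(m) list(chrom = ch, ids = m)))
  }
  n <- nrow(D)
  codes <- matrix(0L, n, length(blocks),
                  dimnames = list(rownames(D), paste0("w", seq_along(blocks))))
  info <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    ids <- blocks[[b]]$ids
    x <- D[, ids, drop = FALSE]
    storage.mode(x) <- "double"
    k <- min(3L, nrow(unique(x)))
    if (k == 1L) {
      cl_codes <- rep(0L, n)
    } else {
      km <- kmeans_pp(x, k)
      cl_codes <- size_rank_codes(km$cluster, km$centers)
    }
    codes[, b] <- cl_codes
    pos <- map$pos[match(ids, map$id)]
    info[[b]] <- data.frame(window = colnames(codes)[b],
                            chrom = blocks[[b]]$chrom,
                            start = min(pos), end = max(pos),
                            n_members = length(ids), k_used = k)
  }
  windows <- do.call(rbind, info)
  windows$maf <- compute_maf(codes)
  rownames(windows) <- NULL
  structure(list(dosages = codes, windows = windows,
                 members = lapply(blocks, `[[`, "ids")),
            class = c("famgp_collapsed"))
}

#' Window-size sweep for rare-variant collapsing
#'
#' Runs [collapse_rare()] at each window size and tabulates how many collapsed
#' SNPs remain rare (MAF < `maf_threshold`) — the quantity used to choose the
#' operating window size (larger windows leave fewer rare collapsed SNPs, at
#' the cost of coarser information).
#'
#' @param rare `famgp_geno` of rare markers.
#' @param sizes Integer vector of window sizes (each >= 2).
#' @param seed Integer seed.
#' @param maf_threshold Rarity threshold for the count (default 0.05).
#' @return Data frame: `window_size`, `n_rare_collapsed`, `n_collapsed`.
#' @export
window_size_sweep <- function(rare, sizes, seed = 1L, maf_threshold = 0.05) {
  rows <- lapply(sizes, function(s) {
    cs <- collapse_rare(rare, window_size = s, seed = seed)
    data.frame(window_size = s,
               n_rare_collapsed = sum(cs$windows$maf < maf_threshold),
               n_collapsed = nrow(cs$windows))
  })
  do.call(rbind, rows)
}

#' Assemble the two analysis marker sets
#'
#' Set 1 holds the common SNPs only; set 2 appends the collapsed SNPs formed
#' from rare variants (column concatenation, provenance retained per column).
#'
#' @param common `famgp_geno` of common markers.
#' @param collapsed `famgp_collapsed` from [collapse_rare()], or NULL for no
#'   collapsing (set 2 then equals set 1).
#' @return List of two `famgp_geno` objects `set1`, `set2`; their `map` gains
#'   a `source` column ("common" or "collapsed").
#' @export
assemble_marker_sets <- function(common, collapsed = NULL) {
  stopifnot(inherits(common, "famgp_geno"))
  map1 <- common$map
  map1$source <- "common"
  set1 <- new_geno(common$dosages, map1)
  if (is.null(collapsed) || nrow(collapsed$windows) == 0L)
    return(list(set1 = set1, set2 = set1))
  if (!identical(rownames(common$dosages), rownames(collapsed$dosages)))
    stop_famgp("individual ordering differs between common and collapsed sets")
  map2 <- data.frame(id = collapsed$windows$window,
                     chrom = collapsed$windows$chrom,
                     pos = collapsed$windows$start,
                     founder_maf = NA_real_, class = "collapsed",
                     source = "collapsed", stringsAsFactors = FALSE)
  keep <- intersect(names(map1), names(map2))
  set2 <- new_geno(cbind(common$dosages, collapsed$dosages),
                   rbind(map1[, keep, drop = FALSE], map2[, keep, drop = FALSE]))
  list(set1 = set1, set2 = set2)
}
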
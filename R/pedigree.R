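# Pedigree data model: additive (numerator) relationship matrix by the
# tabular method, and the classical parent-average predictor.

# Topologically order a pedigree so parents precede offspring; errors on
# cycles, naming an individual involved.
topological_order <- function(pedigree) {
  ids <- pedigree$id
  idx <- seq_along(ids)
  names(idx) <- as.character(ids)
  parent_idx <- function(p) ifelse(p == 0, NA_integer_, idx[as.character(p)])
  si <- parent_idx(pedigree$sire)
  di <- parent_idx(pedigree$dam)
  if (any(pedigree$sire != 0 & is.na(si)))
    stop_famgp("sire id not found in pedigree for individual ",
               ids[which(pedigree$sire != 0 & is.na(si))[1]])
  if (any(pedigree$dam != 0 & is.na(di)))
    stop_famgp("dam id not found in pedigree for individual ",
               ids[which(pedigree$dam != 0 & is.na(di))[1]])
  n <- length(ids)
  placed <- logical(n)
  ord <- integer(n)
  k <- 0L
  repeat {
    ready <- !placed &
      (is.na(si) | placed[pmax(si, 1L)]) &
      (is.na(di) | placed[pmax(di, 1L)])
    # pmax guard is safe: is.na() short-circuits the subscript's meaning
    ready[is.na(ready)] <- FALSE
    if (!any(ready)) break
    w <- which(ready)
    ord[k + seq_along(w)] <- w
    placed[w] <- TRUE
    k <- k + length(w)
  }
  if (k < n)
    stop_famgp("pedigree contains a cycle involving individual ",
               ids[which(!placed)[1]])
  ord
}

#' Additive relationship matrix (tabular method)
#'
#' Builds the pedigree-based additive (numerator) relationship matrix A with
#' the standard tabular method: A_jj = 1 + F_j where F_j = 0.5 * A(sire, dam),
#' and A_ij = 0.5 * (A(i, sire_j) + A(i, dam_j)), unknown parents contributing
#' 0 (founders are taken as unrelated and non-inbred). The pedigree is sorted
#' topologically first; a cycle raises an error naming an individual on it.
#'
#' @param pedigree Data frame with columns `id`, `sire`, `dam` (0 = unknown).
#' @return Symmetric matrix with dimnames set to the individual ids, in the
#'   pedigree's original order. Diagonal entries are 1 + inbreeding
#'   coefficient.
#' @export
additive_relationship_matrix <- function(pedigree) {
  ord <- topological_order(pedigree)
  ped <- pedigree[ord, , drop = FALSE]
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- as.character(ped$id)
  si <- ifelse(ped$sire == 0, 0L, idx[as.character(ped$sire)])
  di <- ifelse(ped$dam == 0, 0L, idx[as.character(ped$dam)])
  A <- matrix(0, n, n)
  for (j in seq_len(n)) {
    s <- si[j]; d <- di[j]
    if (j > 1L) {
      prev <- seq_len(j - 1L)
      as_ <- if (s > 0L) A[prev, s] else numeric(j - 1L)
      ad_ <- if (d > 0L) A[prev, d] else numeric(j - 1L)
      A[prev, j] <- 0.5 * (as_ + ad_)
      A[j, prev] <- A[prev, j]
    }
    A[j, j] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  dimnames(A) <- list(names(idx), names(idx))
  # return in the caller's original id order
  orig <- as.character(pedigree$id)
  A[orig, orig]
}

#' Parent-average genetic contribution
#'
#' Classical pedigree-only predictor for a target individual from estimated
#' additive genetic contributions of training-set parents: the father's value
#' if only the father is in the training set, the mother's if only she is,
#' and their mean when both are.
#'
#' @param u_hat Named numeric vector of estimated additive genetic
#'   contributions for training individuals (names = ids).
#' @param pedigree Pedigree data frame.
#' @param target_id Id of the individual to predict.
#' @return The parent-average prediction (scalar).
#' @export
parent_average <- function(u_hat, pedigree, target_id) {
  row <- pedigree[pedigree$id == target_id, , drop = FALSE]
  if (nrow(row) != 1L) stop_famgp("target_id not found in pedigree")
  f <- as.character(row$sire); m <- as.character(row$dam)
  f_in <- f != "0" && f %in% names(u_hat)
  m_in <- m != "0" && m %in% names(u_hat)
  if (!f_in && !m_in)
    stop_famgp("neither parent of ", target_id, " is in the training set")
  if (f_in && !m_in) return(unname(u_hat[f]))
  if (!f_in && m_in) return(unname(u_hat[m]))
  unname(0.5 * u_hat[f] + 0.5 * u_hat[m])
}
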
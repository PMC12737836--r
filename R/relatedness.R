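#' Encode IUPAC calls as allele dosages
#'
#' For each biallelic marker the major allele (ties broken toward the
#' lexicographically smaller base) becomes the encoding reference;
#' dosages count its copies: homozygous reference = 2, heterozygous = 1,
#' homozygous alternate = 0, missing = NA. The reference choice only
#' relabels the axis: swapping it maps d to 2 - d and leaves all
#' pairwise Euclidean distances unchanged.
#'
#' @param matrix a `call_matrix` with biallelic markers.
#' @return numeric markers x samples matrix of class `dosage_matrix`
#'   with attribute `encoding_reference` (per-marker base).
#' @export
encode_dosage <- function(matrix) {
  m <- unclass(matrix)
  p <- iupac_to_pairs(m)
  refs <- character(nrow(m))
  d <- base::matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  for (i in seq_len(nrow(m))) {
    a <- c(p$a1[i, ], p$a2[i, ])
    tb <- table(a[!is.na(a)])
    if (length(tb) > 2L) {
      stop("marker ", rownames(m)[i], " has more than two alleles")
    }
    ref <- if (length(tb) == 0L) NA_character_ else {
      cand <- names(tb)[tb == max(tb)]
      sort(cand)[1L]
    }
    refs[i] <- ref
    if (!is.na(ref)) {
      d[i, ] <- (p$a1[i, ] == ref) + (p$a2[i, ] == ref)
    }
  }
  structure(d, encoding_reference = setNames(refs, rownames(m)),
            class = c("dosage_matrix", "matrix"))
}

#' Euclidean distances between samples from dosages
#'
#' Missing dosages are mean-imputed per marker before the distance
#' computation; markers missing in every sample are dropped with a
#' warning. Distances are the standard Euclidean metric over marker
#' dimensions.
#'
#' @param dosages a `dosage_matrix` (markers x samples).
#' @return a `dist` object over samples.
#' @export
euclidean_distances <- function(dosages) {
  d <- unclass(dosages)
  all_na <- rowSums(!is.na(d)) == 0L
  if (any(all_na)) {
    warning(sum(all_na), " marker(s) missing in all samples dropped")
    d <- d[!all_na, , drop = FALSE]
  }
  mu <- rowMeans(d, na.rm = TRUE)
  idx <- which(is.na(d), arr.ind = TRUE)
  if (nrow(idx)) d[idx] <- mu[idx[, 1L]]
  dist(t(d))
}

#' Principal coordinates analysis of a Euclidean distance matrix
#'
#' Classical scaling (double centering + eigendecomposition). For
#' distances computed with [euclidean_distances()] this coincides with a
#' PCA of the centered dosage matrix: scores match up to sign and the
#' reported eigenvalues equal the covariance eigenvalues (classical
#' scaling eigenvalues divided by n - 1).
#'
#' @param dst a `dist` object (Euclidean).
#' @return list of class `pcoa_result` with `coordinates` (samples x
#'   components), `eigenvalues` (covariance scale, non-increasing) and
#'   `variance_percent` (100 * lambda / sum of positive lambda).
#' @export
pcoa <- function(dst) {
  n <- attr(dst, "Size")
  if (is.null(n) || n < 2L) stop("need at least 2 samples")
  # cmdscale warns when fewer than k eigenvalues are positive; that is
  # the normal situation for rank-deficient dosage data
  sc <- withCallingHandlers(
    cmdscale(dst, k = n - 1L, eig = TRUE),
    warning = function(w) {
      if (grepl("eigenvalues", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  eig <- sc$eig / (n - 1L)
  pos <- eig > 0
  vp <- ifelse(pos, 100 * eig / sum(eig[pos]), 0)
  k <- ncol(sc$points)
  coords <- sc$points
  colnames(coords) <- paste0("PC", seq_len(k))
  structure(list(coordinates = coords,
                 eigenvalues = eig,
                 variance_percent = vp),
            class = "pcoa_result")
}

#' Number of components needed to explain a variance threshold
#'
#' The smallest k whose cumulative explained variance is strictly
#' greater than `threshold_percent`.
#'
#' @param result a `pcoa_result`.
#' @param threshold_percent percent of variance to exceed (default 80).
#' @return integer count of components.
#' @export
select_pcs <- function(result, threshold_percent = 80) {
  if (threshold_percent >= 100) stop("threshold must be < 100")
  cs <- cumsum(result$variance_percent)
  which(cs > threshold_percent)[1L]
}

#' Identity-by-state similarity matrix
#'
#' For each sample pair, over the markers where both calls are
#' non-missing, each site contributes the shared-allele count of the two
#' genotypes divided by two (1 for identical genotypes, 0.5 for one
#' shared allele as in homozygous `A` vs heterozygous `M`, 0 for
#' disjoint); the similarity is the mean site score. Both homozygous and
#' heterozygous calls enter the count; missing data are excluded
#' pairwise, never imputed.
#'
#' @param matrix a `call_matrix`.
#' @return list of class `ibs_matrix` with `values` (symmetric samples x
#'   samples, NA when a pair shares no comparable marker) and
#'   `n_compared` (markers used per pair).
#' @export
ibs_matrix <- function(matrix) {
  m <- unclass(matrix)
  p <- iupac_to_pairs(m)
  ns <- ncol(m)
  ids <- colnames(m)
  vals <- base::matrix(NA_real_, ns, ns, dimnames = list(ids, ids))
  ncmp <- base::matrix(0L, ns, ns, dimnames = list(ids, ids))
  for (i in seq_len(ns)) {
    for (j in i:ns) {
      ok <- !is.na(p$a1[, i]) & !is.na(p$a1[, j])
      n <- sum(ok)
      ncmp[i, j] <- ncmp[j, i] <- n
      if (n > 0L) {
        s <- shared_allele_count(p$a1[ok, i], p$a2[ok, i],
                                 p$a1[ok, j], p$a2[ok, j]) / 2
        vals[i, j] <- vals[j, i] <- mean(s)
      }
    }
  }
  structure(list(values = vals, n_compared = ncmp), class = "ibs_matrix")
}

#' Rank nearest neighbors by IBS similarity
#'
#' For each query sample, all non-query samples are ranked by descending
#' similarity, ties broken by sample id. This mechanizes the
#' closest-wild-relative readout for dissected subgenome call sets.
#'
#' @param sim an `ibs_matrix`.
#' @param query_samples sample ids to rank neighbors for; all queries
#'   are excluded from every neighbor list.
#' @return data frame with columns `query`, `neighbor`, `similarity`,
#'   `rank`.
#' @export
nearest_neighbors <- function(sim, query_samples) {
  ids <- rownames(sim$values)
  unknown <- setdiff(query_samples, ids)
  if (length(unknown)) stop("unknown query sample(s): ",
                            paste(unknown, collapse = ", "))
  pool <- setdiff(ids, query_samples)
  out <- lapply(query_samples, function(q) {
    v <- sim$values[q, pool]
    ord <- order(-v, pool)
    data.frame(query = q, neighbor = pool[ord], similarity = v[ord],
               rank = seq_along(pool), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
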
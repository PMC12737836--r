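# encode pseudosequences once into sorted allele-pair matrices
# (sites x samples) shared by the distance and bootstrap code
.encode_pseudo <- function(pseudo) {
  if (is.null(names(pseudo))) stop("pseudosequences must be named")
  lens <- nchar(pseudo)
  if (length(unique(lens)) != 1L) {
    stop("pseudosequences must have equal length")
  }
  m <- matrix(unlist(strsplit(pseudo, "", fixed = TRUE), use.names = FALSE),
              ncol = length(pseudo), dimnames = list(NULL, names(pseudo)))
  iupac_to_pairs(m)
}

# IUPAC-aware pairwise distances from encoded pairs over selected sites;
# same site scoring as the IBS similarity (distance = 1 - mean score)
.pdist_pairs <- function(p, idx = NULL, on_empty = c("error", "max")) {
  on_empty <- match.arg(on_empty)
  a1 <- p$a1; a2 <- p$a2
  if (!is.null(idx)) {
    a1 <- a1[idx, , drop = FALSE]
    a2 <- a2[idx, , drop = FALSE]
  }
  ids <- colnames(a1)
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  empty <- FALSE
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !is.na(a1[, i]) & !is.na(a1[, j])
      if (!any(ok)) {
        if (on_empty == "error") {
          stop("no comparable sites between ", ids[i], " and ", ids[j])
        }
        d[i, j] <- d[j, i] <- NA_real_
        empty <- TRUE
        next
      }
      s <- shared_allele_count(a1[ok, i], a2[ok, i], a1[ok, j], a2[ok, j]) / 2
      d[i, j] <- d[j, i] <- 1 - mean(s)
    }
  }
  if (empty) {
    mx <- max(d, na.rm = TRUE)
    d[is.na(d)] <- mx
  }
  stats::as.dist(d)
}

#' IUPAC-aware p-distance matrix over SNP pseudosequences
#'
#' For each sample pair, over the sites where both calls are
#' non-missing, the distance is one minus the mean per-site
#' shared-allele score (identical genotypes score 1, one shared allele
#' of two scores 0.5), i.e. the complement of the IBS similarity — so
#' tree distances and similarity rankings are mutually consistent.
#'
#' @param pseudo named character vector of equal-length pseudosequences
#'   (see [pseudosequences()]).
#' @return a `dist` object.
#' @export
pdistance_matrix <- function(pseudo) {
  .pdist_pairs(.encode_pseudo(pseudo))
}

#' Neighbor-joining tree
#'
#' Canonical neighbor joining (Q-criterion agglomeration with
#' Studier-Keppler distance updates). On additive distance matrices it
#' reconstructs the generating topology and branch lengths exactly.
#' Negative estimated branch lengths are clamped to zero; the number
#' clamped is recorded in attribute `"n_clamped"`.
#'
#' @param dst a `dist` object or symmetric matrix over >= 3 taxa.
#' @return an unrooted `phylo` tree.
#' @export
neighbor_joining <- function(dst) {
  d <- as.matrix(dst)
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  tr <- ape::nj(stats::as.dist(d))
  neg <- tr$edge.length < 0
  tr$edge.length[neg] <- 0
  attr(tr, "n_clamped") <- sum(neg)
  tr
}

#' Neighbor-joining tree with bootstrap support
#'
#' Builds the reference tree from the full pseudosequence data, then
#' resamples marker columns with replacement `n_resamples` times; the
#' support of each internal bipartition is the fraction of replicate
#' trees that contain it, stored in `node.label` (in `[0, 1]`; the root
#' entry is empty). In a replicate, the rare pair left with no
#' comparable sites is assigned the maximum distance observed in that
#' replicate.
#'
#' @param pseudo named character vector of equal-length pseudosequences.
#' @param n_resamples number of bootstrap replicates (default 1000).
#' @param seed RNG seed for the resampling.
#' @return an unrooted `phylo` tree with bootstrap supports as node
#'   labels.
#' @export
bootstrap_support <- function(pseudo, n_resamples = 1000, seed = 1) {
  if (length(pseudo) < 4L) stop("need at least 4 taxa")
  if (n_resamples < 1L) stop("n_resamples must be >= 1")
  p <- .encode_pseudo(pseudo)
  nsite <- nrow(p$a1)
  ref <- neighbor_joining(.pdist_pairs(p))
  set.seed(check_seed(seed))
  reps <- vector("list", n_resamples)
  for (b in seq_len(n_resamples)) {
    idx <- sample.int(nsite, nsite, replace = TRUE)
    reps[[b]] <- ape::nj(.pdist_pairs(p, idx, on_empty = "max"))
  }
  class(reps) <- "multiPhylo"
  cnt <- ape::prop.clades(ref, part = ape::prop.part(reps), rooted = FALSE)
  supp <- cnt / n_resamples
  supp[is.na(supp)] <- 0
  supp[1L] <- NA_real_  # root of the stored representation, not a split
  ref$node.label <- ifelse(is.na(supp), "", format(supp, trim = TRUE))
  attr(ref, "support") <- supp
  ref
}

# bootstrap support of the bipartition separating `tipset` from the
# rest, looked up from a tree labelled by bootstrap_support(); NA when
# the split is not in the tree or is a trivial (pendant) split
split_support <- function(tree, tipset) {
  ntip <- length(tree$tip.label)
  target <- sort(match(tipset, tree$tip.label))
  if (anyNA(target)) stop("unknown tip(s)")
  if (length(target) <= 1L || length(target) >= ntip - 1L) return(NA_real_)
  comp <- setdiff(seq_len(ntip), target)
  pp <- ape::prop.part(tree)
  supp <- attr(tree, "support") %||%
    suppressWarnings(as.numeric(tree$node.label))
  for (k in seq_along(pp)) {
    cl <- sort(pp[[k]])
    if (identical(cl, target) || identical(cl, comp)) {
      if (is.null(supp)) return(NA_real_)
      return(supp[k])
    }
  }
  NA_real_
}

#' Support of the clade containing exactly the given tips
#'
#' @param tree a `phylo` with supports from [bootstrap_support()].
#' @param tipset character vector of tip labels forming one side of a
#'   bipartition.
#' @return the bootstrap support in `[0, 1]`, or NA when the
#'   bipartition is absent or trivial.
#' @export
clade_support <- function(tree, tipset) split_support(tree, tipset)

#' Sister group of a focal clade
#'
#' The focal tips must form one side of some bipartition of the
#' unrooted tree (a clade under some rooting). The sister group is read
#' across the focal clade's stem edge: of the two clades adjacent at the
#' far end of that edge, the one with fewer tips is returned (ties
#' broken by lexicographic tip labels), which matches the conventional
#' rooted sister when the larger side holds the outgroup.
#'
#' @param tree a `phylo` (node labels, when present, are interpreted as
#'   supports).
#' @param focal_tips tip label(s) of the focal clade.
#' @return list with `sister` (tip labels), `support` (bootstrap
#'   support of the focal stem bipartition, NA for trivial splits).
#' @export
find_sister <- function(tree, focal_tips) {
  tips <- tree$tip.label
  if (!all(focal_tips %in% tips)) stop("unknown focal tip(s)")
  focal <- unique(focal_tips)
  rest <- setdiff(tips, focal)
  if (length(rest) == 0L) stop("focal tips cannot cover the whole tree")
  support <- split_support(tree, focal)
  if (length(rest) == 1L) return(list(sister = rest, support = support))
  if (length(focal) > 1L) {
    # focal must be one side of a bipartition
    pp <- ape::prop.part(tree)
    target <- sort(match(focal, tips))
    comp <- sort(match(rest, tips))
    ok <- any(vapply(pp, function(cl) {
      cl <- sort(cl)
      identical(cl, target) || identical(cl, comp)
    }, logical(1)))
    if (!ok) stop("focal tips do not form a clade under any rooting")
  }
  rt <- ape::root(ape::unroot(tree), outgroup = focal, resolve.root = TRUE)
  root_node <- length(tips) + 1L
  kids <- rt$edge[rt$edge[, 1L] == root_node, 2L]
  tipset <- function(node) {
    if (node <= length(rt$tip.label)) return(rt$tip.label[node])
    ape::extract.clade(rt, node)$tip.label
  }
  kid_sets <- lapply(kids, tipset)
  other <- kids[!vapply(kid_sets, function(s) setequal(s, focal), logical(1))]
  if (length(other) != 1L) stop("focal tips do not form a clade under any rooting")
  if (other <= length(rt$tip.label)) {
    return(list(sister = rt$tip.label[other], support = support))
  }
  gkids <- rt$edge[rt$edge[, 1L] == other, 2L]
  gsets <- lapply(gkids, tipset)
  sizes <- lengths(gsets)
  ord <- order(sizes, vapply(gsets, function(s) paste(sort(s), collapse = ","),
                             character(1)))
  list(sister = sort(gsets[[ord[1L]]]), support = support)
}

#' Read a Newick tree
#'
#' @param path file containing one Newick tree.
#' @return a `phylo`.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path), error = function(e) NULL)
  if (is.null(tr)) stop("malformed Newick file: ", path)
  tr
}

#' Write a tree as Newick
#'
#' Bootstrap supports, when present, are serialized as internal node
#' labels.
#'
#' @param tree a `phylo`.
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
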
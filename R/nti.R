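#' Phylogenetic clustering of response groups: MNTD and NTI
#'
#' Groups of incorporators sharing an interaction type are tested for
#' terminal phylogenetic clustering with the nearest taxon index (NTI):
#' the standardized effect size of the group's mean nearest taxon
#' distance (MNTD) against a null of equal-sized random tip sets drawn
#' from the full tip pool.
#'
#' @name phylo_clustering
NULL

#' Pairwise tip-to-tip path-length matrix
#'
#' @param tree an `ape` `phylo` object with branch lengths.
#' @return symmetric matrix of cophenetic (path-length) distances with
#'   tip labels as dimnames.
#' @export
cophenetic_matrix <- function(tree) {
  validate_tree(tree)
  ape::cophenetic.phylo(tree)
}

#' Mean nearest taxon distance of a tip group
#'
#' Mean, over the group's members, of each member's distance to its
#' nearest other member.
#'
#' @param group character vector of tip labels (>= 2).
#' @param dmat cophenetic distance matrix.
#' @return MNTD in branch-length units.
#' @export
mntd <- function(group, dmat) {
  if (length(group) < 2) stop("MNTD needs a group of >= 2 taxa")
  missing <- setdiff(group, rownames(dmat))
  if (length(missing))
    stop("taxa not in distance matrix: ", paste(missing, collapse = ", "))
  d <- dmat[group, group, drop = FALSE]
  diag(d) <- Inf
  mean(apply(d, 1, min))
}

#' Nearest taxon index with a random tip-set null
#'
#' The null distribution draws `n_null` random subsets of size
#' `length(group)` from `pool` (all tips of the tree by default) and
#' computes each subset's MNTD. When the pool admits no more than
#' `n_null` distinct subsets the null is enumerated exhaustively
#' instead, making the index exact for small problems. Then
#' NTI = -(MNTD_obs - null mean) / null sd (sample sd), and
#' p = (number of null MNTDs <= observed + 1) / (n draws + 1).
#' Verdicts follow the standard bands: clustered when NTI > 0 and
#' p < 0.05; overdispersed when NTI < 0 and p > 0.95; random
#' otherwise.
#'
#' @param group character vector of tip labels (>= 2).
#' @param tree an `ape` `phylo` object with branch lengths, or a
#'   precomputed cophenetic matrix.
#' @param n_null number of null draws.
#' @param pool tip pool for the null (defaults to all row names of the
#'   distance matrix).
#' @param seed integer seed for the null draws.
#' @return data.frame of class `nti_result`: `n_group`, `mntd_obs`,
#'   `null_mean`, `null_sd`, `nti`, `p_value`, `verdict`.
#' @export
nti <- function(group, tree, n_null = 999L, pool = NULL, seed = 1L) {
  dmat <- if (is.matrix(tree)) tree else cophenetic_matrix(tree)
  if (is.null(pool)) pool <- rownames(dmat)
  stopifnot(all(group %in% pool))
  obs <- mntd(group, dmat)
  k <- length(group)
  if (choose(length(pool), k) <= n_null) {
    null_mntd <- utils::combn(pool, k, FUN = mntd, dmat = dmat)
  } else {
    set.seed(seed)
    null_mntd <- vapply(seq_len(n_null), function(i) {
      mntd(sample(pool, k), dmat)
    }, numeric(1))
  }
  null_mean <- mean(null_mntd)
  null_sd <- stats::sd(null_mntd)
  if (is.na(null_sd) || null_sd == 0)
    stop("degenerate null distribution (sd = 0) for group of size ", k)
  val <- -(obs - null_mean) / null_sd
  p <- (sum(null_mntd <= obs) + 1) / (length(null_mntd) + 1)
  verdict <- if (val > 0 && p < 0.05) "clustered"
  else if (val < 0 && p > 0.95) "overdispersed"
  else "random"
  structure(
    data.frame(n_group = k, mntd_obs = obs, null_mean = null_mean,
               null_sd = null_sd, nti = val, p_value = p,
               verdict = verdict, stringsAsFactors = FALSE),
    class = c("nti_result", "data.frame")
  )
}

#' NTI for every scenario x interaction-type group of incorporators
#'
#' @param calls data.frame with columns `taxon`, `scenario`, `type`.
#' @param tree phylogeny covering (at least) the called taxa.
#' @param n_null null draws per group.
#' @param min_group smallest group size tested (smaller groups are
#'   skipped; MNTD needs >= 2 and tiny groups carry no power).
#' @param seed integer seed.
#' @return data.frame: one row per (scenario, type) group with the
#'   [nti()] columns.
#' @export
nti_by_group <- function(calls, tree, n_null = 999L, min_group = 2L,
                         seed = 1L) {
  dmat <- cophenetic_matrix(tree)
  calls <- calls[calls$taxon %in% rownames(dmat), , drop = FALSE]
  groups <- split(calls$taxon, list(calls$scenario, calls$type),
                  drop = TRUE)
  groups <- groups[lengths(groups) >= max(2L, min_group)]
  if (!length(groups)) return(NULL)
  res <- lapply(seq_along(groups), function(i) {
    r <- nti(unique(groups[[i]]), dmat, n_null = n_null,
             seed = seed + i)
    cbind(data.frame(group = names(groups)[i],
                     stringsAsFactors = FALSE), r)
  })
  do.call(rbind, res)
}
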
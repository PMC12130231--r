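# Cluster-coherence analysis: entropy, mutual information, variation of
# information (VI), normalized VI, and per-cluster contribution
# decomposition.

#' Joint distribution of two clusterings
#'
#' Builds the contingency table of cluster co-membership over the items
#' present in both clusterings; items missing from either side are dropped
#' and counted.
#'
#' @param c1,c2 named label vectors (item -> cluster label) or
#'   `slc_clustering` objects.
#' @return List of class `joint_distribution`: `counts` (contingency
#'   matrix), `p_ij`, `p_i`, `p_j`, `n` (common items) and `dropped`.
#' @export
joint_distribution <- function(c1, c2) {
  l1 <- if (inherits(c1, "slc_clustering")) c1$labels else c1
  l2 <- if (inherits(c2, "slc_clustering")) c2$labels else c2
  common <- intersect(names(l1), names(l2))
  if (length(common) == 0L) {
    stop("no common item between clusterings of sizes ", length(l1), " and ",
         length(l2))
  }
  dropped <- (length(l1) - length(common)) + (length(l2) - length(common))
  counts <- table(factor(l1[common]), factor(l2[common]))
  counts <- matrix(as.numeric(counts), nrow(counts), ncol(counts),
                   dimnames = dimnames(counts))
  p <- counts / sum(counts)
  structure(list(counts = counts, p_ij = p, p_i = rowSums(p),
                 p_j = colSums(p), n = length(common), dropped = dropped),
            class = "joint_distribution")
}

#' Coherence report: VI, NVI, MI and their decomposition
#'
#' Computes (in nats) the marginal entropies H1 and H2, joint entropy H12,
#' mutual information MI, and the variation of information VI = H12 - MI,
#' with its pairwise decomposition c_ij = p_ij log(p_i p_j / p_ij^2) summing
#' to VI. A cluster's contribution is the sum of its pairwise terms with
#' every cluster of the other clustering. The normalized VI divides by the
#' joint (shared) entropy, NVI = VI / H12, defined as 0 when H12 = 0; NVI is
#' invariant to the logarithm base.
#'
#' @param jd a [joint_distribution()].
#' @return List of class `coherence_report`: `H1`, `H2`, `H12`, `MI`, `VI`,
#'   `NVI`, `c_ij` (pairwise VI contributions), `mi_ij` (pairwise MI terms),
#'   `vi_by_cluster1`, `vi_by_cluster2`, `mi_by_cluster1`, `mi_by_cluster2`,
#'   `n`.
#' @export
coherence_report <- function(jd) {
  stopifnot(inherits(jd, "joint_distribution"))
  p <- jd$p_ij; pi_ <- jd$p_i; pj <- jd$p_j
  xlogx <- function(x) ifelse(x > 0, x * log(x), 0)
  H1 <- -sum(xlogx(pi_)); H2 <- -sum(xlogx(pj)); H12 <- -sum(xlogx(p))
  pp <- outer(pi_, pj)
  mi_ij <- ifelse(p > 0, p * log(p / pp), 0)
  c_ij <- ifelse(p > 0, p * log(pp / p^2), 0)
  MI <- sum(mi_ij); VI <- sum(c_ij)
  NVI <- if (H12 > 0) VI / H12 else 0
  structure(list(H1 = H1, H2 = H2, H12 = H12, MI = MI, VI = VI, NVI = NVI,
                 c_ij = c_ij, mi_ij = mi_ij,
                 vi_by_cluster1 = rowSums(c_ij),
                 vi_by_cluster2 = colSums(c_ij),
                 mi_by_cluster1 = rowSums(mi_ij),
                 mi_by_cluster2 = colSums(mi_ij),
                 n = jd$n),
            class = "coherence_report")
}

#' @export
print.coherence_report <- function(x, ...) {
  cat(sprintf("coherence_report (n = %d items)\n", x$n))
  cat(sprintf("  H1 = %.4f  H2 = %.4f  H12 = %.4f nats\n", x$H1, x$H2, x$H12))
  cat(sprintf("  MI = %.4f  VI = %.4f  NVI = %.4f\n", x$MI, x$VI, x$NVI))
  invisible(x)
}

#' Pairwise normalized-VI matrix across several groupings
#'
#' @param clusterings named list of two or more named label vectors (or
#'   `slc_clustering` objects); each pair is compared on its common items.
#' @return Symmetric numeric matrix of NVI values with zero diagonal.
#' @export
pairwise_nvi_matrix <- function(clusterings) {
  if (length(clusterings) < 2L) stop("need at least two clusterings")
  nm <- names(clusterings)
  if (is.null(nm) || any(nm == "")) stop("clusterings must be named")
  k <- length(clusterings)
  out <- matrix(0, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      rep_ <- coherence_report(joint_distribution(clusterings[[i]],
                                                  clusterings[[j]]))
      out[i, j] <- out[j, i] <- rep_$NVI
    }
  }
  out
}
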
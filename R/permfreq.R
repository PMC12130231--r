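# Pathway hit frequencies across analyses, with identity-shuffling
# permutation significance.

# analyses x features significance matrix and features x pathways membership
# matrix over a shared feature universe
.hit_matrices <- function(diff, fmap) {
  df <- as.data.frame(diff)
  universe <- names(fmap)
  measured <- sort(unique(df$feature))
  extra <- setdiff(measured, universe)
  if (length(extra)) {
    message(length(extra), " measured feature(s) absent from the pathway map; ",
            "mapped to no pathway")
    for (f in extra) fmap[[f]] <- character()
    universe <- sort(c(universe, extra))
    fmap <- fmap[universe]
  }
  pathways <- sort(unique(unlist(fmap, use.names = FALSE)))
  M <- matrix(0, length(universe), length(pathways),
              dimnames = list(universe, pathways))
  for (f in universe) M[f, fmap[[f]]] <- 1
  analyses <- sort(unique(df$analysis))
  S <- matrix(0, length(analyses), length(universe),
              dimnames = list(analyses, universe))
  sig <- df[!is.na(df$significant) & df$significant, , drop = FALSE]
  if (nrow(sig)) S[cbind(match(sig$analysis, analyses),
                         match(sig$feature, universe))] <- 1
  list(S = S, M = M)
}

#' Count per-pathway analysis hits
#'
#' For every pathway, counts the number of analyses that have at least one
#' significant feature mapped to that pathway (each analysis counts at most
#' once per pathway).
#'
#' @param diff cohort `diff_table` with `analysis`, `feature`, `significant`.
#' @param fmap a [feature_pathway_map()].
#' @return Data frame of class `pathway_hit_counts` with columns `pathway`
#'   and `observed`; attributes `n_analyses` and `kind`.
#' @export
count_pathway_hits <- function(diff, fmap) {
  hm <- .hit_matrices(diff, fmap)
  counts <- colSums((hm$S %*% hm$M) > 0)
  out <- data.frame(pathway = colnames(hm$M), observed = as.integer(counts),
                    stringsAsFactors = FALSE)
  structure(out, n_analyses = nrow(hm$S), kind = attr(fmap, "kind"),
            class = c("pathway_hit_counts", "data.frame"))
}

#' Permutation significance of pathway hit frequencies
#'
#' Each permutation draws one random relabeling of the quantified feature
#' identities — a permutation of the rows of the feature-to-pathway map —
#' shared across all analyses and pathways in that iteration, then recounts
#' pathway hits. The one-sided enrichment p value uses the add-one
#' correction: p = (#\{permuted count >= observed\} + 1) / (B + 1).
#'
#' @param diff cohort `diff_table`.
#' @param fmap a [feature_pathway_map()].
#' @param B number of permutations (default 200000, as used for the full
#'   cohort; tests and examples run far fewer).
#' @param seed integer seed; fixed seed gives identical p values.
#' @return Data frame of class `permutation_result` with columns `pathway`,
#'   `observed`, `p`, `B`, `seed`.
#' @export
permutation_pvalues <- function(diff, fmap, B = 200000L, seed = 1L) {
  if (B < 1L) stop("B must be >= 1")
  hm <- .hit_matrices(diff, fmap)
  S <- hm$S; M <- hm$M
  observed <- colSums((S %*% M) > 0)
  n_feat <- nrow(M)
  exceed <- numeric(ncol(M))
  with_seed(seed, {
    for (b in seq_len(B)) {
      perm <- sample.int(n_feat)
      cnt <- colSums((S %*% M[perm, , drop = FALSE]) > 0)
      exceed <- exceed + (cnt >= observed)
    }
  })
  out <- data.frame(pathway = colnames(M), observed = as.integer(observed),
                    p = (exceed + 1) / (B + 1), B = as.integer(B),
                    seed = as.integer(seed), stringsAsFactors = FALSE)
  class(out) <- c("permutation_result", "data.frame")
  out
}

#' Exact permutation p values by full enumeration
#'
#' Enumerates all factorial relabelings of the feature universe; feasible
#' only for tiny universes (<= 8 features). Serves as the exact reference
#' for [permutation_pvalues()].
#'
#' @inheritParams permutation_pvalues
#' @return Data frame with columns `pathway`, `observed`, `p_exact`.
#' @export
exact_permutation_pvalues <- function(diff, fmap) {
  hm <- .hit_matrices(diff, fmap)
  S <- hm$S; M <- hm$M
  n <- nrow(M)
  if (n > 8L) stop("exact enumeration limited to <= 8 features")
  observed <- colSums((S %*% M) > 0)
  perms <- .all_permutations(n)
  exceed <- numeric(ncol(M))
  for (i in seq_len(nrow(perms))) {
    cnt <- colSums((S %*% M[perms[i, ], , drop = FALSE]) > 0)
    exceed <- exceed + (cnt >= observed)
  }
  data.frame(pathway = colnames(M), observed = as.integer(observed),
             p_exact = exceed / nrow(perms), stringsAsFactors = FALSE)
}

.all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}
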
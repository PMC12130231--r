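# Categorize significant SLC-metabolite pairs: annotated substrate,
# metabolic conversion, novel (non-orphan), novel (orphan).

.DEFAULT_EXCLUDED_SUBSTRATES <- c("hydron", "hydroxide", "water")

# drop substrates whose id or display label is on the excluded list
.filter_substrates <- function(g, substrates, excluded) {
  keep <- !(substrates %in% excluded | g$labels[substrates] %in% excluded)
  substrates[keep]
}

#' Reactions converting an annotated substrate into a metabolite
#'
#' Searches reactions in which some annotated substrate matches an educt and
#' the metabolite matches a product — or, symmetrically, the metabolite
#' matches an educt and a substrate a product. Terms occurring on both sides
#' of the same reaction are disqualified as match anchors, and the ubiquitous
#' substrate annotations hydron, hydroxide and water are ignored.
#'
#' @param net a `pathway_network`.
#' @param g an `ontology_graph`.
#' @param substrates character vector of annotated substrate term ids.
#' @param metabolite the measured metabolite's term id.
#' @param policy a [match_policy()].
#' @param excluded substrate names/ids never used as anchors.
#' @param bidirectional if `FALSE`, only the substrate-as-educt /
#'   metabolite-as-product direction is searched.
#' @return Character vector of reaction ids (sorted), with a `directions`
#'   attribute (`"substrate_to_metabolite"` or `"metabolite_to_substrate"`
#'   per reaction).
#' @export
find_conversions <- function(net, g, substrates, metabolite,
                             policy = match_policy(),
                             excluded = .DEFAULT_EXCLUDED_SUBSTRATES,
                             bidirectional = TRUE) {
  substrates <- .filter_substrates(g, intersect(substrates, g$terms), excluded)
  if (length(substrates) == 0L || !metabolite %in% g$terms) {
    return(structure(character(), directions = character()))
  }
  matches_any <- function(q, terms) {
    any(vapply(terms, function(t) terms_match(g, q, t, policy)$matched,
               logical(1)))
  }
  hits <- character(); dirs <- character()
  for (rid in names(net$reactions)) {
    r <- net$reactions[[rid]]
    both <- intersect(r$educts, r$products)      # disqualified anchors
    ed <- setdiff(intersect(r$educts, g$terms), both)
    pr <- setdiff(intersect(r$products, g$terms), both)
    if (length(ed) == 0L || length(pr) == 0L) next
    sub_ed <- any(vapply(substrates, function(s) matches_any(s, ed), logical(1)))
    met_pr <- matches_any(metabolite, pr)
    if (sub_ed && met_pr) {
      hits <- c(hits, rid); dirs <- c(dirs, "substrate_to_metabolite")
      next
    }
    if (bidirectional) {
      sub_pr <- any(vapply(substrates, function(s) matches_any(s, pr), logical(1)))
      met_ed <- matches_any(metabolite, ed)
      if (sub_pr && met_ed) {
        hits <- c(hits, rid); dirs <- c(dirs, "metabolite_to_substrate")
      }
    }
  }
  ord <- order(hits)
  structure(hits[ord], directions = dirs[ord])
}

#' Categorize significant SLC-metabolite pairs
#'
#' Every pair with adjusted p below `fdr` is placed in exactly one category,
#' by precedence: `annotated_substrate` (the metabolite matches one of the
#' SLC's annotated substrate terms), then `metabolic_conversion`
#' ([find_conversions()] finds a linking reaction), then
#' `novel_non_orphan` (the SLC has annotated substrates), else
#' `novel_orphan`. SLCs absent from the annotation table are treated as
#' orphans with a warning.
#'
#' @param diff a cohort `diff_table` of metabolomics results (columns
#'   `analysis`, `feature`, `lfc`, `padj`).
#' @param ann annotation data frame with columns `slc` and `substrates`
#'   (list column of substrate term ids; empty means orphan).
#' @param g an `ontology_graph`.
#' @param net a `pathway_network`.
#' @param policy a [match_policy()].
#' @param analysis_to_slc named character vector mapping analysis id to SLC
#'   id; by default each analysis id is its SLC id.
#' @param fdr adjusted-p cutoff for a pair to be categorized.
#' @param excluded,bidirectional passed to [find_conversions()].
#' @return Data frame of class `pair_records`: `slc`, `metabolite`, `lfc`,
#'   `padj`, `category`, `witness_substrate`, `witness_reaction`,
#'   `direction`.
#' @export
categorize_pairs <- function(diff, ann, g, net, policy = match_policy(),
                             analysis_to_slc = NULL, fdr = 0.05,
                             excluded = .DEFAULT_EXCLUDED_SUBSTRATES,
                             bidirectional = TRUE) {
  df <- as.data.frame(diff)
  sig <- df[!is.na(df$padj) & df$padj < fdr, , drop = FALSE]
  subst_of <- stats::setNames(ann$substrates, ann$slc)
  out <- list()
  for (i in seq_len(nrow(sig))) {
    an <- sig$analysis[[i]]
    slc <- if (is.null(analysis_to_slc)) an else unname(analysis_to_slc[[an]])
    met <- sig$feature[[i]]
    rec <- data.frame(slc = slc, metabolite = met, lfc = sig$lfc[[i]],
                      padj = sig$padj[[i]], category = NA_character_,
                      witness_substrate = NA_character_,
                      witness_reaction = NA_character_,
                      direction = NA_character_, stringsAsFactors = FALSE)
    if (!slc %in% names(subst_of)) {
      warning("SLC ", slc, " absent from annotation table; treated as orphan")
      rec$category <- "novel_orphan"
      out[[length(out) + 1L]] <- rec
      next
    }
    subs <- intersect(subst_of[[slc]], g$terms)
    wit <- NA_character_
    if (met %in% g$terms) {
      for (s in subs) {
        if (terms_match(g, met, s, policy)$matched) { wit <- s; break }
      }
    }
    if (!is.na(wit)) {
      rec$category <- "annotated_substrate"
      rec$witness_substrate <- wit
    } else {
      conv <- if (met %in% g$terms) {
        find_conversions(net, g, subs, met, policy, excluded, bidirectional)
      } else character()
      if (length(conv)) {
        rec$category <- "metabolic_conversion"
        rec$witness_reaction <- conv[[1L]]
        rec$direction <- attr(conv, "directions")[[1L]]
      } else if (length(subst_of[[slc]])) {
        rec$category <- "novel_non_orphan"
      } else {
        rec$category <- "novel_orphan"
      }
    }
    out[[length(out) + 1L]] <- rec
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(slc = character(), metabolite = character(), lfc = numeric(),
               padj = numeric(), category = character(),
               witness_substrate = character(), witness_reaction = character(),
               direction = character(), stringsAsFactors = FALSE)
  class(res) <- c("pair_records", "data.frame")
  res
}

#' @export
print.pair_records <- function(x, ...) {
  cat("pair_records:", nrow(x), "significant pairs\n")
  print(table(x$category))
  invisible(x)
}

#' Compare fold-change magnitudes across pair categories
#'
#' Kruskal-Wallis test of |log2 fold change| across the four pair
#' categories, plus the per-category median |lfc|.
#'
#' @param pairs a `pair_records` data frame.
#' @return List with `kruskal` (htest) and `medians` (named numeric).
#' @export
compare_pair_categories <- function(pairs) {
  stopifnot(nrow(pairs) > 0L)
  med <- tapply(abs(pairs$lfc), pairs$category, stats::median)
  kw <- stats::kruskal.test(abs(pairs$lfc), factor(pairs$category))
  list(kruskal = kw, medians = med)
}
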
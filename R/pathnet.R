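# Pathway hierarchy + reaction network: feature-to-pathway mapping and
# per-pathway expression summaries.

#' Construct a pathway network
#'
#' A DAG of pathways with a single recorded root (the "Metabolism"-style
#' top pathway) plus reactions, each carrying educt/product chemical term
#' sets, participating proteins, and direct pathway memberships. A pathway's
#' reaction set is hierarchical: it includes the reactions of all its
#' descendants.
#'
#' @param root root pathway id.
#' @param pathways data frame with columns `id` and `parents` (list column of
#'   character vectors; the root has no parents).
#' @param reactions named list: reaction id -> list with elements `educts`,
#'   `products` (character vectors of ontology term ids, both non-empty),
#'   `proteins` (character, may be empty) and `pathways` (character,
#'   non-empty).
#' @return An object of class `pathway_network`.
#' @export
pathway_network <- function(root, pathways, reactions) {
  ids <- as.character(pathways$id)
  if (!root %in% ids) stop("root pathway not among pathway ids")
  parents <- pathways$parents
  if (is.null(parents)) parents <- rep(list(character()), length(ids))
  parents <- lapply(parents, as.character)
  names(parents) <- ids
  for (p in ids) {
    miss <- setdiff(parents[[p]], ids)
    if (length(miss)) stop("unknown parent pathway: ", miss[[1L]])
  }
  if (length(reactions) == 0L) stop("pathway network needs at least one reaction")
  if (is.null(names(reactions)) || anyDuplicated(names(reactions))) {
    stop("reactions must be a uniquely named list")
  }
  for (rid in names(reactions)) {
    r <- reactions[[rid]]
    if (length(r$educts) == 0L || length(r$products) == 0L) {
      stop("reaction ", rid, " has empty educts or products")
    }
    if (length(r$pathways) == 0L) stop("reaction ", rid, " has no pathway")
    miss <- setdiff(r$pathways, ids)
    if (length(miss)) stop("reaction ", rid, " references unknown pathway ", miss[[1L]])
  }
  net <- list(root = root, pathways = ids, parents = parents,
              reactions = reactions)
  class(net) <- "pathway_network"
  # every pathway must reach the root
  anc <- pathway_ancestors(net)
  for (p in setdiff(ids, root)) {
    if (!root %in% anc[[p]]) stop("pathway ", p, " is not connected to the root")
  }
  net
}

#' @export
print.pathway_network <- function(x, ...) {
  cat("pathway_network:", length(x$pathways), "pathways (root ", x$root, "), ",
      length(x$reactions), "reactions\n")
  invisible(x)
}

#' Ancestors of every pathway
#'
#' @param net a `pathway_network`.
#' @return Named list: pathway id -> character vector of strict ancestors
#'   (parents, grandparents, ... up to the root).
#' @export
pathway_ancestors <- function(net) {
  memo <- stats::setNames(vector("list", length(net$pathways)), net$pathways)
  get_anc <- function(p, seen = character()) {
    if (!is.null(memo[[p]])) return(memo[[p]])
    if (p %in% seen) stop("cycle among pathway parent edges at ", p)
    pars <- net$parents[[p]]
    out <- pars
    for (q in pars) out <- union(out, get_anc(q, c(seen, p)))
    memo[[p]] <<- out
    out
  }
  for (p in net$pathways) get_anc(p)
  memo
}

# pathway -> all reactions assigned to it or any descendant
.pathway_reaction_sets <- function(net) {
  anc <- pathway_ancestors(net)
  sets <- stats::setNames(rep(list(character()), length(net$pathways)),
                          net$pathways)
  for (rid in names(net$reactions)) {
    direct <- net$reactions[[rid]]$pathways
    all_p <- unique(c(direct, unlist(anc[direct], use.names = FALSE)))
    for (p in all_p) sets[[p]] <- c(sets[[p]], rid)
  }
  lapply(sets, unique)
}

#' Reactions involving a metabolite
#'
#' A reaction is hit when the metabolite matches (per [terms_match()]) any of
#' its educt or product terms as an identical, more generic, more specific or
#' equivalent chemical term.
#'
#' @param net a `pathway_network`.
#' @param g an `ontology_graph`.
#' @param m metabolite term id (registered in `g`).
#' @param policy a [match_policy()].
#' @return Character vector of reaction ids (sorted).
#' @export
reactions_for_metabolite <- function(net, g, m, policy = match_policy()) {
  if (!m %in% g$terms) stop("unknown term id: ", m)
  hits <- character()
  for (rid in names(net$reactions)) {
    r <- net$reactions[[rid]]
    cand <- intersect(unique(c(r$educts, r$products)), g$terms)
    for (term in cand) {
      if (terms_match(g, m, term, policy)$matched) { hits <- c(hits, rid); break }
    }
  }
  sort(hits)
}

#' Pathways associated with a feature
#'
#' Metabolites map via ontology matching against reaction educts/products;
#' genes map via a gene-to-protein table against reaction protein
#' annotations. The matched reactions' direct pathway memberships are
#' expanded to all ancestor pathways up to the root. A gene absent from the
#' mapping table maps to no pathway (with a message), not an error.
#'
#' @param net a `pathway_network`.
#' @param feature feature id (term id or gene id).
#' @param kind `"metabolite"` or `"gene"`.
#' @param g `ontology_graph`, required for metabolites.
#' @param gene_map data frame with columns `gene_id`, `protein_id`; required
#'   for genes. One-to-many mappings are allowed.
#' @param policy a [match_policy()].
#' @return Character vector of pathway ids (sorted; possibly empty).
#' @export
pathways_for_feature <- function(net, feature, kind = c("metabolite", "gene"),
                                 g = NULL, gene_map = NULL,
                                 policy = match_policy()) {
  kind <- match.arg(kind)
  if (kind == "metabolite") {
    if (is.null(g)) stop("ontology graph required for metabolite features")
    rids <- reactions_for_metabolite(net, g, feature, policy)
  } else {
    if (is.null(gene_map)) stop("gene_map required for gene features")
    prots <- gene_map$protein_id[gene_map$gene_id == feature]
    if (length(prots) == 0L) {
      message("gene ", feature, " absent from gene map; maps to no pathway")
      return(character())
    }
    rids <- names(net$reactions)[vapply(net$reactions, function(r) {
      length(intersect(r$proteins, prots)) > 0L
    }, logical(1))]
  }
  if (length(rids) == 0L) return(character())
  anc <- pathway_ancestors(net)
  direct <- unique(unlist(lapply(net$reactions[rids], `[[`, "pathways"),
                          use.names = FALSE))
  sort(unique(c(direct, unlist(anc[direct], use.names = FALSE))))
}

#' Map many features to pathways at once
#'
#' @inheritParams pathways_for_feature
#' @param features character vector of feature ids.
#' @return Named list (class `feature_pathway_map`): feature id -> character
#'   vector of pathway ids, with the feature kind stored as an attribute.
#' @export
feature_pathway_map <- function(net, features, kind = c("metabolite", "gene"),
                                g = NULL, gene_map = NULL,
                                policy = match_policy()) {
  kind <- match.arg(kind)
  features <- sort(unique(as.character(features)))
  out <- stats::setNames(lapply(features, function(f) {
    pathways_for_feature(net, f, kind, g = g, gene_map = gene_map,
                         policy = policy)
  }), features)
  structure(out, kind = kind, class = "feature_pathway_map")
}

#' Mean pathway log2 fold change
#'
#' Arithmetic mean of the log2 fold changes of all genes mapped to a pathway,
#' without any significance filter; duplicated (feature, lfc) rows are
#' deduplicated to one row per feature first.
#'
#' @param diff a `diff_table` or data frame with columns `feature` and `lfc`.
#' @param fmap a `feature_pathway_map`.
#' @param pathway pathway id.
#' @return The mean log2 fold change, or `NA_real_` when no measured feature
#'   maps to the pathway (flagged with a warning).
#' @export
mean_pathway_lfc <- function(diff, fmap, pathway) {
  df <- as.data.frame(diff)
  df <- df[!duplicated(df$feature), , drop = FALSE]
  mapped <- names(fmap)[vapply(fmap, function(p) pathway %in% p, logical(1))]
  use <- df$feature %in% mapped & is.finite(df$lfc)
  if (!any(use)) {
    warning("no mapped feature for pathway ", pathway, "; mean undefined")
    return(NA_real_)
  }
  mean(df$lfc[use])
}

#' Top-level pathways by mapped-feature count
#'
#' Ranks the direct children of the root by the number of distinct mapped
#' features and returns the top `k` (default nine), ties broken by pathway id.
#'
#' @param net a `pathway_network`.
#' @param fmap a `feature_pathway_map`.
#' @param k number of pathways to return.
#' @return Ordered character vector of pathway ids.
#' @export
top_level_pathways <- function(net, fmap, k = 9L) {
  children <- net$pathways[vapply(net$parents, function(p) net$root %in% p,
                                  logical(1))]
  if (length(children) < k) {
    message("root has only ", length(children), " children; returning all")
    k <- length(children)
  }
  counts <- vapply(children, function(p) {
    sum(vapply(fmap, function(pp) p %in% pp, logical(1)))
  }, numeric(1))
  ord <- order(-counts, children)
  children[ord][seq_len(k)]
}

#' Read a pathway network from JSON
#'
#' Expects `{"root": id, "pathways": [{"id", "parents": [...]}, ...],
#' "reactions": [{"id", "educts", "products", "proteins", "pathways"}, ...]}`.
#'
#' @param path JSON file path.
#' @return A `pathway_network`.
#' @export
read_pathway_network <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  pw <- data.frame(id = vapply(j$pathways, `[[`, character(1), "id"),
                   stringsAsFactors = FALSE)
  pw$parents <- lapply(j$pathways, function(p) {
    unlist(p$parents, use.names = FALSE) %||% character()
  })
  reacts <- stats::setNames(lapply(j$reactions, function(r) {
    list(educts = unlist(r$educts, use.names = FALSE),
         products = unlist(r$products, use.names = FALSE),
         proteins = unlist(r$proteins, use.names = FALSE) %||% character(),
         pathways = unlist(r$pathways, use.names = FALSE))
  }), vapply(j$reactions, `[[`, character(1), "id"))
  pathway_network(j$root, pw, reacts)
}

#' Write a pathway network to JSON
#'
#' @param net a `pathway_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pathway_network <- function(net, path) {
  j <- list(
    root = net$root,
    pathways = lapply(net$pathways, function(p) {
      list(id = p, parents = as.list(net$parents[[p]]))
    }),
    reactions = lapply(names(net$reactions), function(rid) {
      r <- net$reactions[[rid]]
      list(id = rid, educts = as.list(r$educts), products = as.list(r$products),
           proteins = as.list(r$proteins), pathways = as.list(r$pathways))
    })
  )
  jsonlite::write_json(j, path, auto_unbox = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
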
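# Chemical-term ontology: storage, parsing, and generic/specific matching.

.EQ_RELATIONS <- c("is_conjugate_base_of", "is_conjugate_acid_of",
                   "is_tautomer_of", "is_enantiomer_of")
.DIR_RELATIONS <- c("is_a", "has_role")
.ALL_RELATIONS <- c(.DIR_RELATIONS, .EQ_RELATIONS)

#' Construct a chemical-term ontology graph
#'
#' Builds the typed graph used to decide whether one chemical term is a more
#' generic or a more specific form of another. Directional edges (`is_a`,
#' `has_role`) point from the specific term to the generic term (or from a
#' chemical to its role); equivalence edges (conjugate acid/base, tautomer,
#' enantiomer) are stored once and traversed in both directions.
#'
#' @param terms character vector of term ids.
#' @param edges data frame with columns `source`, `relation`, `target`.
#'   Allowed relations: `is_a`, `has_role`, `is_conjugate_base_of`,
#'   `is_conjugate_acid_of`, `is_tautomer_of`, `is_enantiomer_of`.
#' @param labels optional named character vector mapping term id to a display
#'   name; unnamed terms fall back to their id.
#' @return An object of class `ontology_graph`.
#' @export
ontology_graph <- function(terms, edges, labels = NULL) {
  terms <- unique(as.character(terms))
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(source = character(), relation = character(),
                        target = character(), stringsAsFactors = FALSE)
  }
  edges <- data.frame(source = as.character(edges$source),
                      relation = as.character(edges$relation),
                      target = as.character(edges$target),
                      stringsAsFactors = FALSE)
  bad_rel <- setdiff(unique(edges$relation), .ALL_RELATIONS)
  if (length(bad_rel)) {
    stop("unknown relation type(s): ", paste(bad_rel, collapse = ", "))
  }
  endpoints <- unique(c(edges$source, edges$target))
  dangling <- setdiff(endpoints, terms)
  if (length(dangling)) {
    stop("edge endpoint(s) not registered as terms: ",
         paste(utils::head(dangling, 5L), collapse = ", "))
  }
  cyc <- .find_isa_cycle(terms, edges[edges$relation == "is_a", , drop = FALSE])
  if (!is.null(cyc)) {
    stop("cycle among is_a edges: ", paste(cyc, collapse = " -> "))
  }
  lab <- stats::setNames(terms, terms)
  if (!is.null(labels)) lab[names(labels)] <- labels
  g <- list(terms = terms, edges = edges, labels = lab)
  class(g) <- "ontology_graph"
  g
}

# Kahn's algorithm on the is_a subgraph; returns one cycle (term sequence) or
# NULL when acyclic.
.find_isa_cycle <- function(terms, isa) {
  if (nrow(isa) == 0L) return(NULL)
  out <- split(isa$target, factor(isa$source, levels = terms))
  indeg <- stats::setNames(integer(length(terms)), terms)
  tt <- table(factor(isa$target, levels = terms))
  indeg[names(tt)] <- as.integer(tt)
  queue <- terms[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (w in out[[v]]) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) queue <- c(queue, w)
    }
  }
  if (seen == length(terms)) return(NULL)
  # walk forward inside the residual subgraph until a repeat names the cycle
  resid <- names(indeg)[indeg > 0L]
  v <- resid[[1L]]; path <- character()
  repeat {
    path <- c(path, v)
    nxt <- intersect(out[[v]], resid)
    v <- nxt[[1L]]
    if (v %in% path) return(c(path[which(path == v):length(path)], v))
  }
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat("ontology_graph:", length(x$terms), "terms,", nrow(x$edges), "edges\n")
  rel <- table(x$edges$relation)
  if (length(rel)) {
    cat(paste0("  ", names(rel), ": ", as.integer(rel), collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Read an ontology from OBO or TSV
#'
#' The OBO dialect consumes only `id`, `name`, `is_a` and `relationship:`
#' lines of `[Term]` stanzas (OBO 1.2 line format); every other tag is
#' skipped. The TSV dialect expects a header and three columns
#' `source`, `relation`, `target`. Edges with relation types outside the
#' supported set are dropped with a single warning carrying their count.
#'
#' @param source path to the ontology file.
#' @param dialect `"obo_subset"` or `"tsv_edges"`.
#' @return An `ontology_graph`.
#' @export
load_ontology <- function(source, dialect = c("obo_subset", "tsv_edges")) {
  dialect <- match.arg(dialect)
  if (!file.exists(source)) stop("ontology file not found: ", source)
  if (dialect == "tsv_edges") {
    df <- utils::read.delim(source, stringsAsFactors = FALSE)
    names(df) <- tolower(names(df))
    if (!all(c("source", "relation", "target") %in% names(df))) {
      stop("TSV edge list must have columns source, relation, target")
    }
    keep <- df$relation %in% .ALL_RELATIONS
    if (any(!keep)) {
      warning(sum(!keep), " edge(s) with unsupported relation type ignored")
    }
    df <- df[keep, c("source", "relation", "target"), drop = FALSE]
    return(ontology_graph(unique(c(df$source, df$target)), df))
  }
  lines <- readLines(source, warn = FALSE)
  terms <- character(); labels <- character()
  src <- character(); rel <- character(); tgt <- character()
  cur <- NA_character_; in_term <- FALSE; n_ignored <- 0L
  for (ln in lines) {
    ln <- sub("!.*$", "", ln)            # strip trailing comments
    ln <- trimws(ln)
    if (ln == "[Term]") { in_term <- TRUE; cur <- NA_character_; next }
    if (grepl("^\\[", ln)) { in_term <- FALSE; next }
    if (!in_term || ln == "") next
    if (grepl("^id:", ln)) {
      cur <- trimws(sub("^id:", "", ln))
      terms <- c(terms, cur)
    } else if (grepl("^name:", ln) && !is.na(cur)) {
      labels[cur] <- trimws(sub("^name:", "", ln))
    } else if (grepl("^is_a:", ln) && !is.na(cur)) {
      src <- c(src, cur); rel <- c(rel, "is_a")
      tgt <- c(tgt, trimws(sub("^is_a:", "", ln)))
    } else if (grepl("^relationship:", ln) && !is.na(cur)) {
      parts <- strsplit(trimws(sub("^relationship:", "", ln)), "[[:space:]]+")[[1L]]
      if (length(parts) >= 2L && parts[[1L]] %in% .ALL_RELATIONS) {
        src <- c(src, cur); rel <- c(rel, parts[[1L]]); tgt <- c(tgt, parts[[2L]])
      } else {
        n_ignored <- n_ignored + 1L
      }
    }
  }
  if (n_ignored > 0L) {
    warning(n_ignored, " relationship line(s) with unsupported type ignored")
  }
  edges <- data.frame(source = src, relation = rel, target = tgt,
                      stringsAsFactors = FALSE)
  ontology_graph(unique(c(terms, src, tgt)), edges, labels = labels)
}

#' Matching policy for ontology traversal
#'
#' @param max_depth maximum number of edges in a match path (default
#'   unbounded).
#' @param allow_direction_mixing if `TRUE`, generalization direction may flip
#'   along the path (so siblings match through a shared parent). The default
#'   `FALSE` enforces a single consistent direction for `is_a`/`has_role`
#'   edges, with equivalence edges freely interleaved.
#' @return A list of class `match_policy`.
#' @export
match_policy <- function(max_depth = Inf, allow_direction_mixing = FALSE) {
  stopifnot(max_depth >= 1)
  structure(list(max_depth = max_depth,
                 allow_direction_mixing = isTRUE(allow_direction_mixing)),
            class = "match_policy")
}

# Adjacency lists keyed by term: $up (specific -> generic), $down (inverse),
# $eq (both orientations of equivalence edges). Each entry is a data frame of
# (to, source, relation, target) rows describing the traversed edge.
.ont_adjacency <- function(g) {
  mk <- function() stats::setNames(vector("list", length(g$terms)), g$terms)
  up <- mk(); down <- mk(); eq <- mk()
  add <- function(adj, from, to, s, r, t) {
    adj[[from]] <- rbind(adj[[from]],
                         data.frame(to = to, source = s, relation = r,
                                    target = t, stringsAsFactors = FALSE))
    adj
  }
  e <- g$edges
  for (i in seq_len(nrow(e))) {
    s <- e$source[[i]]; r <- e$relation[[i]]; t <- e$target[[i]]
    if (r %in% .DIR_RELATIONS) {
      up <- add(up, s, t, s, r, t)
      down <- add(down, t, s, s, r, t)
    } else {
      eq <- add(eq, s, t, s, r, t)
      eq <- add(eq, t, s, s, r, t)
    }
  }
  list(up = up, down = down, eq = eq)
}

# BFS from `from` to `to` using the union of the given adjacency lists;
# returns the traversed edge list (data frame) or NULL if unreachable.
.ont_bfs <- function(adjs, from, to, max_depth) {
  if (from == to) return(data.frame())
  prev <- list(); depth <- c(stats::setNames(0L, from))
  queue <- from
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    if (depth[[v]] >= max_depth) next
    nbr <- do.call(rbind, lapply(adjs, function(a) a[[v]]))
    if (is.null(nbr) || nrow(nbr) == 0L) next
    for (i in seq_len(nrow(nbr))) {
      w <- nbr$to[[i]]
      if (!is.null(prev[[w]]) || w == from) next
      prev[[w]] <- nbr[i, c("source", "relation", "target"), drop = FALSE]
      names(prev)[length(prev)] <- w
      prev[[w]]$from <- v
      depth[[w]] <- depth[[v]] + 1L
      if (w == to) {
        path <- NULL; cur <- to
        while (cur != from) {
          step <- prev[[cur]]
          path <- rbind(step[, c("source", "relation", "target")], path)
          cur <- step$from
        }
        return(path)
      }
      queue <- c(queue, w)
    }
  }
  NULL
}

#' Decide whether two terms match as generic/specific forms
#'
#' Two terms match when they are identical, connected purely by equivalence
#' edges, or connected by a path whose directional edges (`is_a`, `has_role`)
#' are all traversed in one consistent direction — i.e. one term is a more
#' specific or a more generic form of the other — with equivalence edges
#' freely interleaved.
#'
#' @param g an `ontology_graph`.
#' @param query,target registered term ids.
#' @param policy a [match_policy()].
#' @return A list of class `match_result` with fields `query`, `target`,
#'   `matched`, `direction` (one of `identity`, `equivalence_only`,
#'   `query_more_specific`, `query_more_generic`, or `mixed` when the policy
#'   allows direction mixing) and `path` (data frame of traversed edges,
#'   empty when unmatched).
#' @export
terms_match <- function(g, query, target, policy = match_policy()) {
  stopifnot(inherits(g, "ontology_graph"))
  for (id in c(query, target)) {
    if (!id %in% g$terms) stop("unknown term id: ", id)
  }
  res <- function(matched, direction, path) {
    structure(list(query = query, target = target, matched = matched,
                   direction = direction,
                   path = if (is.null(path)) data.frame() else path),
              class = "match_result")
  }
  if (query == target) return(res(TRUE, "identity", data.frame()))
  adj <- .ont_adjacency(g)
  p <- .ont_bfs(adj["eq"], query, target, policy$max_depth)
  if (!is.null(p)) return(res(TRUE, "equivalence_only", p))
  p <- .ont_bfs(adj[c("up", "eq")], query, target, policy$max_depth)
  if (!is.null(p)) return(res(TRUE, "query_more_specific", p))
  p <- .ont_bfs(adj[c("down", "eq")], query, target, policy$max_depth)
  if (!is.null(p)) return(res(TRUE, "query_more_generic", p))
  if (policy$allow_direction_mixing) {
    p <- .ont_bfs(adj, query, target, policy$max_depth)
    if (!is.null(p)) return(res(TRUE, "mixed", p))
  }
  res(FALSE, NA_character_, NULL)
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("%s ~ %s: %s%s\n", x$query, x$target,
              if (x$matched) "matched" else "not matched",
              if (x$matched) paste0(" (", x$direction, ")") else ""))
  invisible(x)
}

#' Match a metabolite panel against a compound set
#'
#' Applies [terms_match()] to every (panel term, compound term) pair and
#' collects, per panel term, the compounds it matches. Iteration order is
#' deterministic (sorted ids).
#'
#' @inheritParams terms_match
#' @param panel character vector of panel (measured metabolite) term ids.
#' @param compounds character vector of compound term ids.
#' @return Named list: panel term id -> character vector of matched compound
#'   term ids (possibly empty).
#' @export
match_panel <- function(g, panel, compounds, policy = match_policy()) {
  panel <- sort(unique(as.character(panel)))
  compounds <- sort(unique(as.character(compounds)))
  out <- stats::setNames(vector("list", length(panel)), panel)
  for (m in panel) {
    hits <- character()
    for (cpd in compounds) {
      if (terms_match(g, m, cpd, policy)$matched) hits <- c(hits, cpd)
    }
    out[[m]] <- hits
  }
  out
}
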
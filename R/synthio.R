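# Synthetic inputs with embedded ground truth: toy ontologies, pathway
# networks, MRM peak tables, and log2-fold-change cohorts.

#' Evaluate code under a local RNG seed
#'
#' Saves and restores the global RNG state so generators leave no trace in
#' the session's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

.new_truth <- function(seed, ...) {
  structure(c(list(seed = seed), list(...)), class = "synth_truth")
}

#' Generate a toy chemical-term ontology with its match closure
#'
#' Builds a forest of `is_a` trees (the generic/specific backbone), then with
#' probability `p_equivalence` per term attaches an equivalence partner
#' (conjugate acid/base, tautomer or enantiomer variant term) and, with the
#' same probability per leaf, a `has_role` edge to a shared role term. The
#' exact generic/specific match closure is computed alongside by
#' Floyd-Warshall transitive closure over the relation matrices — an
#' implementation independent of the package's breadth-first matcher, so it
#' can serve as its oracle.
#'
#' @param seed integer seed.
#' @param n_roots number of tree roots (>= 1).
#' @param depth tree depth (>= 1; root is depth 0).
#' @param branching children per internal node.
#' @param p_equivalence probability in \[0, 1\] of decorating a term with an
#'   equivalence partner / a leaf with a role.
#' @return List with elements `graph` (an [ontology_graph()]), `closure`
#'   (logical term x term matrix of matchability) and `truth` (a
#'   `synth_truth` carrying the seed and parameters).
#' @export
gen_ontology <- function(seed, n_roots = 1L, depth = 2L, branching = 2L,
                         p_equivalence = 0.1) {
  if (n_roots < 1L || depth < 1L || branching < 1L) {
    stop("n_roots, depth and branching must be >= 1")
  }
  if (p_equivalence < 0 || p_equivalence > 1) {
    stop("p_equivalence must lie in [0, 1]")
  }
  with_seed(seed, {
    terms <- character(); src <- character(); rel <- character(); tgt <- character()
    nid <- 0L
    new_term <- function(prefix = "T") {
      nid <<- nid + 1L
      sprintf("%s%03d", prefix, nid)
    }
    add_edge <- function(s, r, t) {
      src <<- c(src, s); rel <<- c(rel, r); tgt <<- c(tgt, t)
    }
    leaves <- character()
    for (ri in seq_len(n_roots)) {
      root <- new_term(); terms <- c(terms, root)
      level <- root
      for (d in seq_len(depth)) {
        nxt <- character()
        for (parent in level) {
          for (b in seq_len(branching)) {
            child <- new_term(); terms <- c(terms, child)
            add_edge(child, "is_a", parent)
            nxt <- c(nxt, child)
          }
        }
        level <- nxt
      }
      leaves <- c(leaves, level)
    }
    backbone <- terms
    eq_rels <- c("is_conjugate_base_of", "is_conjugate_acid_of",
                 "is_tautomer_of", "is_enantiomer_of")
    for (t in backbone) {
      if (stats::runif(1) < p_equivalence) {
        partner <- new_term("E"); terms <- c(terms, partner)
        add_edge(t, sample(eq_rels, 1L), partner)
      }
    }
    roles <- character()
    for (lf in leaves) {
      if (stats::runif(1) < p_equivalence) {
        if (length(roles) == 0L || stats::runif(1) < 0.5) {
          roles <- c(roles, new_term("R")); terms <- c(terms, roles[length(roles)])
        }
        add_edge(lf, "has_role", sample(roles, 1L))
      }
    }
    edges <- data.frame(source = src, relation = rel, target = tgt,
                        stringsAsFactors = FALSE)
    g <- ontology_graph(terms, edges)
    list(graph = g, closure = .closure_oracle(g),
         truth = .new_truth(seed, n_roots = n_roots, depth = depth,
                            branching = branching, p_equivalence = p_equivalence,
                            leaves = leaves))
  })
}

# Exhaustive match closure by boolean Floyd-Warshall over relation matrices:
# matched(q, t) iff q = t, or q and t are connected by equivalence edges
# alone, or one reaches the other through up-edges (is_a/has_role) with
# equivalence edges interleaved. Independent of the BFS in terms_match().
.closure_oracle <- function(g) {
  n <- length(g$terms)
  idx <- stats::setNames(seq_len(n), g$terms)
  up <- matrix(FALSE, n, n); eq <- matrix(FALSE, n, n)
  for (i in seq_len(nrow(g$edges))) {
    s <- idx[[g$edges$source[[i]]]]; t <- idx[[g$edges$target[[i]]]]
    if (g$edges$relation[[i]] %in% c("is_a", "has_role")) up[s, t] <- TRUE
    else { eq[s, t] <- TRUE; eq[t, s] <- TRUE }
  }
  tc <- function(adj) {                    # reflexive-transitive closure
    reach <- adj | diag(TRUE, n)
    for (k in seq_len(n)) {
      reach <- reach | (reach[, k] %o% reach[k, ])
    }
    reach
  }
  up_reach <- tc(up | eq)
  eq_reach <- tc(eq)
  m <- eq_reach | up_reach | t(up_reach)
  dimnames(m) <- list(g$terms, g$terms)
  m
}

#' Generate a toy pathway network over an ontology
#'
#' One root pathway with at least two direct children; remaining pathways
#' attach under random earlier pathways. Each reaction draws non-empty educt
#' and product term sets from the ontology's leaves (occasionally sharing a
#' term between the two sides, so the educt-also-product exclusion rule is
#' exercisable), one or two protein annotations, and at least one pathway
#' membership.
#'
#' @param seed integer seed.
#' @param n_pathways total pathway count including the root (>= 3).
#' @param n_reactions number of reactions (>= 1).
#' @param ontology output of [gen_ontology()] or an `ontology_graph`.
#' @return A [pathway_network()].
#' @export
gen_pathway_network <- function(seed, n_pathways = 6L, n_reactions = 8L,
                                ontology) {
  if (n_reactions < 1L) stop("n_reactions must be >= 1")
  if (n_pathways < 3L) stop("n_pathways must be >= 3 (root plus two children)")
  g <- if (inherits(ontology, "ontology_graph")) ontology else ontology$graph
  pool <- setdiff(g$terms, g$edges$target[g$edges$relation == "is_a"])
  if (length(pool) < 2L) pool <- g$terms
  with_seed(seed, {
    ids <- c("P_root", sprintf("P%02d", seq_len(n_pathways - 1L)))
    parents <- vector("list", n_pathways)
    parents[[1L]] <- character()
    for (i in seq_len(n_pathways - 1L)) {
      parents[[i + 1L]] <- if (i <= 2L) "P_root" else sample(ids[seq_len(i)], 1L)
    }
    pw <- data.frame(id = ids, stringsAsFactors = FALSE)
    pw$parents <- parents
    reactions <- stats::setNames(lapply(seq_len(n_reactions), function(i) {
      ed <- sample(pool, sample(1:2, 1L))
      pr <- sample(pool, sample(1:2, 1L))
      if (stats::runif(1) < 0.15) pr[1L] <- ed[1L]   # shared-species reaction
      list(educts = ed, products = unique(pr),
           proteins = sprintf("GENE_%03d", sample.int(3L * n_reactions, 2L)),
           pathways = sample(ids[-1L], sample(1:2, 1L)))
    }), sprintf("RX%03d", seq_len(n_reactions)))
    pathway_network("P_root", pw, reactions)
  })
}

#' Generate a synthetic targeted-metabolomics experiment
#'
#' Emulates the structure of MRM peak-area data: per analysis a balanced
#' plus/minus-doxycycline design (default four replicates per condition, two
#' clones for the two-way model), multiplicative run effects shared by
#' targets and internal standards, lognormal injection noise, a per-run
#' calibration dilution series, and an internal-standard panel in which each
#' metabolite co-varies with its true standard (so the true standard's
#' calibration regression is near-linear while decoys are degraded by
#' independent per-injection fluctuation).
#'
#' @param seed integer seed.
#' @param analyses character vector of analysis ids (one SLC cell line each).
#' @param model `"one_way"` or `"two_way_clone"` (applies to all analyses).
#' @param metabolites character vector of metabolite ids.
#' @param n_is number of internal standards (>= 2 so decoys exist).
#' @param n_replicates biological replicates per condition (per clone).
#' @param n_clones clones for the two-way model.
#' @param planted data frame with columns `analysis`, `metabolite`, `effect`
#'   (log2 induced-vs-uninduced effects); omitted metabolites are null.
#' @param noise_sd log2-scale injection noise SD for metabolite areas.
#' @param batch_effects named numeric vector of per-run area multipliers
#'   (names are run ids `run1`, `run2`, ...); default all 1. Analyses are
#'   assigned to runs round-robin.
#' @param n_runs number of runs.
#' @param calibration_concs calibration concentrations (default a 6-point
#'   two-fold dilution series, micromolar).
#' @param decoy_noise_sd log2 SD of the per-injection fluctuation that
#'   decouples a metabolite from non-matching standards.
#' @param structure_matched metabolite ids whose true standard is flagged
#'   structure-matched in the panel.
#' @return List with `peaks` (a [peak_table()]), `panel` (IS panel data
#'   frame), `designs` (list of [experiment_design()] per analysis) and
#'   `truth` (`synth_truth` with `true_is_map` and `planted_effects`).
#' @export
gen_metabolomics_experiment <- function(seed, analyses = "SLC1",
                                        model = c("one_way", "two_way_clone"),
                                        metabolites = sprintf("M%02d", 1:10),
                                        n_is = 3L, n_replicates = 4L,
                                        n_clones = 2L, planted = NULL,
                                        noise_sd = 0.1, batch_effects = NULL,
                                        n_runs = 1L,
                                        calibration_concs = 100 / 2^(0:5),
                                        decoy_noise_sd = 2.5,
                                        structure_matched = character()) {
  model <- match.arg(model)
  if (n_is < 1L) stop("need at least one internal standard")
  if (!is.null(planted)) {
    bad <- setdiff(planted$metabolite, metabolites)
    if (length(bad)) stop("planted effect for analyte(s) absent from the panel: ",
                          paste(bad, collapse = ", "))
    bad <- setdiff(planted$analysis, analyses)
    if (length(bad)) stop("planted effect for unknown analysis: ",
                          paste(bad, collapse = ", "))
  }
  runs <- sprintf("run%d", seq_len(n_runs))
  if (is.null(batch_effects)) batch_effects <- stats::setNames(rep(1, n_runs), runs)
  if (!all(runs %in% names(batch_effects))) {
    stop("batch_effects must name every run")
  }
  is_ids <- sprintf("IS%02d", seq_len(n_is))
  n_met <- length(metabolites)
  with_seed(seed, {
    true_is <- stats::setNames(is_ids[(seq_len(n_met) - 1L) %% n_is + 1L],
                               metabolites)
    ti <- match(true_is, is_ids)
    resp <- 2^stats::runif(n_met, -1, 1)
    is_amount <- 2^stats::runif(n_is, 3, 5)
    base_conc <- stats::runif(n_met, 5, 50)
    eff <- matrix(0, length(analyses), n_met,
                  dimnames = list(analyses, metabolites))
    if (!is.null(planted)) {
      for (i in seq_len(nrow(planted))) {
        eff[planted$analysis[[i]], planted$metabolite[[i]]] <- planted$effect[[i]]
      }
    }
    clones <- if (model == "two_way_clone") sprintf("c%d", seq_len(n_clones))
              else NA_character_
    sheet <- expand.grid(replicate = seq_len(n_replicates),
                         condition = c("uninduced", "induced"),
                         clone = clones, analysis = analyses,
                         stringsAsFactors = FALSE,
                         KEEP.OUT.ATTRS = FALSE)
    sheet$run <- runs[(match(sheet$analysis, analyses) - 1L) %% n_runs + 1L]
    sheet$sample <- paste(sheet$analysis,
                          ifelse(is.na(sheet$clone), "x", sheet$clone),
                          sheet$condition, sheet$replicate, sep = "_")
    sheet$noise <- noise_sd
    cal <- expand.grid(replicate = seq_along(calibration_concs), run = runs,
                       stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    cal_sheet <- data.frame(replicate = cal$replicate,
                            condition = "calibration",
                            clone = NA_character_, analysis = "calibration",
                            run = cal$run,
                            sample = paste(cal$run, "cal", cal$replicate,
                                           sep = "_"),
                            noise = 0.02, stringsAsFactors = FALSE)
    sheet <- rbind(sheet, cal_sheet)
    S <- nrow(sheet)
    is_cal <- sheet$condition == "calibration"
    # injection x metabolite expected concentration
    conc <- matrix(rep(base_conc, each = S), S, n_met)
    bio_idx <- which(!is_cal)
    induced <- sheet$condition == "induced"
    an_row <- match(sheet$analysis[bio_idx], analyses)
    conc[bio_idx, ] <- conc[bio_idx, ] *
      2^(eff[an_row, , drop = FALSE] * induced[bio_idx])
    conc[is_cal, ] <- calibration_concs[sheet$replicate[is_cal]]
    run_eff <- unname(batch_effects[sheet$run])
    # f: per-injection fluctuation of each IS, shared with the metabolites it
    # truly matches, so only the true standard's ratio is stable
    f <- matrix(2^stats::rnorm(S * n_is, 0, decoy_noise_sd), S, n_is)
    a_met <- conc * rep(resp, each = S) * run_eff * f[, ti, drop = FALSE] *
      2^matrix(stats::rnorm(S * n_met, 0, sheet$noise), S, n_met)
    a_is <- rep(is_amount, each = S) * run_eff * f *
      2^matrix(stats::rnorm(S * n_is, 0, sheet$noise / 2), S, n_is)
    expected <- conc
    expected[!is_cal, ] <- NA_real_
    long <- function(A, analytes, role, conc_mat = NULL) {
      k <- length(analytes)
      data.frame(run_id = rep(sheet$run, k), sample_id = rep(sheet$sample, k),
                 analysis_id = rep(sheet$analysis, k),
                 condition = rep(sheet$condition, k),
                 clone_id = rep(sheet$clone, k),
                 replicate = rep(sheet$replicate, k),
                 analyte_id = rep(analytes, each = S),
                 analyte_role = role, area = as.vector(A),
                 expected_conc = if (is.null(conc_mat)) NA_real_
                                 else as.vector(conc_mat),
                 stringsAsFactors = FALSE)
    }
    pt <- peak_table(rbind(long(a_met, metabolites, "target", expected),
                           long(a_is, is_ids, "internal_standard")))
    designs <- lapply(stats::setNames(analyses, analyses), function(an) {
      s <- sheet[sheet$analysis == an, , drop = FALSE]
      experiment_design(an, model,
                        data.frame(sample_id = s$sample, condition = s$condition,
                                   clone = s$clone, replicate = s$replicate,
                                   stringsAsFactors = FALSE),
                        target_replicates = n_replicates)
    })
    panel <- data.frame(analyte_id = is_ids,
                        structure_match_target = NA_character_,
                        stringsAsFactors = FALSE)
    for (m in intersect(structure_matched, metabolites)) {
      panel$structure_match_target[panel$analyte_id == true_is[[m]]] <- m
    }
    list(peaks = pt, panel = panel, designs = designs,
         truth = .new_truth(seed, true_is_map = true_is,
                            planted_effects = eff,
                            null_metabolites = metabolites[colSums(abs(eff)) == 0]))
  })
}

#' Generate a log2-fold-change cohort with planted cluster structure
#'
#' Item profiles are cluster centroids (pairwise separated by `separation`
#' in Euclidean norm) on top of a shared, non-constant baseline profile,
#' plus Gaussian noise. Each item receives categorical functional properties
#' (family, fold, substrate class) agreeing with its true cluster with
#' probability `property_fidelity`. Adjusted p values and negative-binomial
#' replicate read counts are attached so the uniqueness filter is testable.
#'
#' @param seed integer seed.
#' @param n_items number of items (analyses/SLCs).
#' @param n_features number of profile features.
#' @param k_true number of planted clusters (<= n_items / 3).
#' @param separation Euclidean distance between cluster centroids.
#' @param noise_sd SD of the additive Gaussian profile noise.
#' @param property_fidelity probability that an item's property labels agree
#'   with its true cluster.
#' @param count_mean negative-binomial mean for replicate read counts.
#' @param count_size negative-binomial size (dispersion) parameter.
#' @return List with `diff` (stacked `diff_table` with count columns),
#'   `profiles` (item x feature matrix), `annotations` (long data frame
#'   `slc`, `class`, `property`) and `truth` (`synth_truth` with
#'   `true_labels`).
#' @export
gen_lfc_cohort <- function(seed, n_items = 40L, n_features = 60L, k_true = 4L,
                           separation = 10, noise_sd = 0.5,
                           property_fidelity = 1.0, count_mean = 200,
                           count_size = 5) {
  if (n_items < 3L || n_features < 2L || k_true < 1L) stop("degenerate sizes")
  if (k_true > n_items / 3) stop("k_true must be <= n_items / 3")
  if (k_true > n_features) stop("k_true must be <= n_features")
  with_seed(seed, {
    items <- sprintf("SLC%03d", seq_len(n_items))
    feats <- sprintf("G%04d", seq_len(n_features))
    labels <- stats::setNames(rep_len(seq_len(k_true), n_items), items)
    base <- sin(seq_len(n_features)) * 2          # shared non-constant baseline
    centroids <- matrix(0, k_true, n_features)
    for (k in seq_len(k_true)) centroids[k, k] <- separation / sqrt(2)
    prof <- matrix(stats::rnorm(n_items * n_features, 0, noise_sd),
                   n_items, n_features, dimnames = list(items, feats))
    prof <- prof + matrix(base, n_items, n_features, byrow = TRUE) +
      centroids[labels, , drop = FALSE]
    classes <- c("family", "fold", "substrate_class")
    ann <- do.call(rbind, lapply(classes, function(cl) {
      val <- vapply(labels, function(k) {
        if (stats::runif(1) < property_fidelity) k
        else sample(seq_len(k_true), 1L)
      }, numeric(1))
      data.frame(slc = items, class = cl,
                 property = sprintf("%s_%d", cl, val),
                 stringsAsFactors = FALSE)
    }))
    rownames(ann) <- NULL
    diff <- do.call(rbind, lapply(items, function(it) {
      padj <- stats::runif(n_features)
      big <- abs(prof[it, ] - base) > 1          # planted signal is significant
      padj[big] <- stats::runif(sum(big), 0, 0.01)
      data.frame(analysis = it, feature = feats, lfc = prof[it, ],
                 p = padj, padj = padj, significant = padj < 0.05,
                 count_uninduced_1 = stats::rnbinom(n_features, mu = count_mean,
                                                    size = count_size),
                 count_uninduced_2 = stats::rnbinom(n_features, mu = count_mean,
                                                    size = count_size),
                 count_induced_1 = stats::rnbinom(n_features, mu = count_mean,
                                                  size = count_size),
                 count_induced_2 = stats::rnbinom(n_features, mu = count_mean,
                                                  size = count_size),
                 stringsAsFactors = FALSE)
    }))
    rownames(diff) <- NULL
    class(diff) <- c("diff_table", "data.frame")
    list(diff = diff, profiles = prof, annotations = ann,
         truth = .new_truth(seed, true_labels = labels,
                            centroids = centroids))
  })
}

#' Generate a toy SLC-metabolite pair scenario with known categories
#'
#' Constructs, by explicit placement, an ontology, a reaction network, an
#' SLC substrate-annotation table and a cohort of significant differential
#' pairs whose category (annotated substrate, metabolic conversion, novel
#' non-orphan, novel orphan) is known by construction. Substrate pairs get
#' larger planted absolute log2 fold changes than conversion pairs.
#'
#' @param seed integer seed.
#' @param n_slcs number of SLCs (>= 4; one in three is orphan).
#' @return List with `graph`, `net`, `annotations` (data frame `slc`,
#'   `substrates` list column), `diff` (significant pair rows), and `truth`
#'   (`synth_truth` with `true_pair_categories`, a data frame `slc`,
#'   `metabolite`, `category`).
#' @export
gen_pair_scenario <- function(seed, n_slcs = 6L) {
  if (n_slcs < 4L) stop("need at least 4 SLCs")
  with_seed(seed, {
    slcs <- sprintf("SLC_%02d", seq_len(n_slcs))
    orphan <- seq_along(slcs) %% 3L == 0L
    # per non-orphan SLC: a substrate, its conversion product, an unrelated
    # metabolite; orphans get one metabolite hit
    subst <- sprintf("SUB%02d", seq_len(n_slcs))
    prod <- sprintf("PRD%02d", seq_len(n_slcs))
    unrel <- sprintf("UNR%02d", seq_len(n_slcs))
    terms <- c("chemical_entity", subst, prod, unrel)
    edges <- data.frame(source = c(subst, prod, unrel), relation = "is_a",
                        target = "chemical_entity", stringsAsFactors = FALSE)
    g <- ontology_graph(terms, edges)
    reactions <- stats::setNames(lapply(seq_len(n_slcs), function(i) {
      list(educts = subst[[i]], products = prod[[i]], proteins = character(),
           pathways = "P1")
    }), sprintf("RX%02d", seq_len(n_slcs)))
    pw <- data.frame(id = c("P_root", "P1", "P2"), stringsAsFactors = FALSE)
    pw$parents <- list(character(), "P_root", "P_root")
    net <- pathway_network("P_root", pw, reactions)
    ann <- data.frame(slc = slcs, stringsAsFactors = FALSE)
    ann$substrates <- lapply(seq_along(slcs), function(i) {
      if (orphan[[i]]) character() else subst[[i]]
    })
    rows <- list(); cats <- list()
    hit <- function(slc, met, category, lfc) {
      rows[[length(rows) + 1L]] <<- data.frame(
        analysis = slc, feature = met, lfc = lfc,
        p = 0.001, padj = 0.01, significant = TRUE, stringsAsFactors = FALSE)
      cats[[length(cats) + 1L]] <<- data.frame(
        slc = slc, metabolite = met, category = category,
        stringsAsFactors = FALSE)
    }
    for (i in seq_along(slcs)) {
      if (orphan[[i]]) {
        hit(slcs[[i]], unrel[[i]], "novel_orphan",
            stats::rnorm(1, 0, 0.8))
      } else {
        hit(slcs[[i]], subst[[i]], "annotated_substrate",
            sample(c(-1, 1), 1) * stats::runif(1, 2, 4))
        hit(slcs[[i]], prod[[i]], "metabolic_conversion",
            sample(c(-1, 1), 1) * stats::runif(1, 0.3, 1))
        hit(slcs[[i]], unrel[[i]], "novel_non_orphan",
            stats::rnorm(1, 0, 0.8))
      }
      # one insignificant pair per SLC: must receive no category
      rows[[length(rows) + 1L]] <- data.frame(
        analysis = slcs[[i]], feature = prod[[(i %% n_slcs) + 1L]],
        lfc = stats::rnorm(1, 0, 0.1), p = 0.8, padj = 0.9,
        significant = FALSE, stringsAsFactors = FALSE)
    }
    diff <- do.call(rbind, rows)
    class(diff) <- c("diff_table", "data.frame")
    list(graph = g, net = net, annotations = ann, diff = diff,
         truth = .new_truth(seed, true_pair_categories = do.call(rbind, cats)))
  })
}
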
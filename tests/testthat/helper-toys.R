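# Small hand-built fixtures shared across tests.

# taurine is_a amino_sulfonic_acid is_a chemical_entity; citrate/citric_acid
# conjugate pair; glucose a sibling leaf
toy_ontology <- function() {
  ontology_graph(
    terms = c("chemical_entity", "amino_sulfonic_acid", "taurine", "glucose",
              "citrate", "citric_acid"),
    edges = data.frame(
      source = c("amino_sulfonic_acid", "taurine", "glucose", "citrate",
                 "citric_acid"),
      relation = c("is_a", "is_a", "is_a", "is_conjugate_base_of", "is_a"),
      target = c("chemical_entity", "amino_sulfonic_acid", "chemical_entity",
                 "citric_acid", "chemical_entity"),
      stringsAsFactors = FALSE)
  )
}

# arginine -> ornithine conversion, an ATP-on-both-sides reaction, and a
# water-involving reaction, under a two-level pathway tree
toy_network <- function() {
  pw <- data.frame(id = c("P_root", "P_urea", "P_energy"),
                   stringsAsFactors = FALSE)
  pw$parents <- list(character(), "P_root", "P_root")
  pathway_network(
    "P_root", pw,
    list(R_arg = list(educts = "arginine", products = "ornithine",
                      proteins = "ARG1", pathways = "P_urea"),
         R_atp = list(educts = c("ATP", "glucose"),
                      products = c("ATP", "g6p"),
                      proteins = "HK1", pathways = "P_energy"),
         R_wat = list(educts = c("water", "x_ester"),
                      products = c("x_acid"),
                      proteins = character(), pathways = "P_energy")))
}

toy_conversion_ontology <- function() {
  terms <- c("chemical_entity", "arginine", "ornithine", "ATP", "glucose",
             "g6p", "water", "x_ester", "x_acid", "taurine")
  ontology_graph(
    terms,
    data.frame(source = setdiff(terms, "chemical_entity"),
               relation = "is_a", target = "chemical_entity",
               stringsAsFactors = FALSE))
}

# independent all-pairs matcher used as oracle: reachability by boolean
# matrix closure (distinct from the package's BFS)
brute_force_matches <- function(g) {
  n <- length(g$terms)
  idx <- setNames(seq_len(n), g$terms)
  up <- matrix(FALSE, n, n); eq <- matrix(FALSE, n, n)
  for (i in seq_len(nrow(g$edges))) {
    s <- idx[[g$edges$source[[i]]]]; t <- idx[[g$edges$target[[i]]]]
    if (g$edges$relation[[i]] %in% c("is_a", "has_role")) up[s, t] <- TRUE
    else { eq[s, t] <- TRUE; eq[t, s] <- TRUE }
  }
  closure <- function(adj) {
    reach <- adj | diag(TRUE, n)
    repeat {
      nxt <- reach | ((reach %*% reach) > 0)
      if (identical(nxt, reach)) return(reach)
      reach <- nxt
    }
  }
  upc <- closure(up | eq)
  m <- closure(eq) | upc | t(upc)
  dimnames(m) <- list(g$terms, g$terms)
  m
}

# normalized matrix built directly from a value matrix (bypassing peaks)
make_nm <- function(values, samples, stage = "batch_corrected") {
  structure(list(values = values, samples = samples, stage = stage),
            class = "normalized_matrix")
}
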
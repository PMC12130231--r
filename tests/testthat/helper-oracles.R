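# independent brute-force evaluation of the information quantities from the
# contingency counts, by explicit double loops
brute_coherence <- function(l1, l2) {
  common <- intersect(names(l1), names(l2))
  a <- l1[common]; b <- l2[common]
  n <- length(common)
  cl1 <- unique(a); cl2 <- unique(b)
  H1 <- 0; H2 <- 0; H12 <- 0; MI <- 0; VI <- 0
  for (i in cl1) {
    pi_ <- sum(a == i) / n
    H1 <- H1 - pi_ * log(pi_)
  }
  for (j in cl2) {
    pj <- sum(b == j) / n
    H2 <- H2 - pj * log(pj)
  }
  for (i in cl1) {
    for (j in cl2) {
      pij <- sum(a == i & b == j) / n
      if (pij == 0) next
      pi_ <- sum(a == i) / n; pj <- sum(b == j) / n
      H12 <- H12 - pij * log(pij)
      MI <- MI + pij * log(pij / (pi_ * pj))
      VI <- VI + pij * log(pi_ * pj / pij^2)
    }
  }
  list(H1 = H1, H2 = H2, H12 = H12, MI = MI, VI = VI,
       NVI = if (H12 > 0) VI / H12 else 0)
}

rand_labels <- function(n, k, items = sprintf("i%02d", seq_len(n))) {
  setNames(sample.int(k, n, replace = TRUE), items)
}
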
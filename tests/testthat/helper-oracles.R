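# Independent oracles and small fixture builders. Everything here is
# deliberately naive (enumeration, closed forms) and shares no code with the
# implementation paths it checks.

# Exhaustive SSM oracle: enumerate every subset of the PreSSM nodes of a
# pair and keep those that (1) span both genes, (2) are pairwise within
# extended distance d, and (3) cannot be extended by any outside node while
# preserving (2). Returns a sorted list of sorted key vectors.
oracle_ssms <- function(g1, g2, l, d) {
  nodes <- extract_nodes(g1, g2, l)
  n <- nrow(nodes)
  if (n == 0L) return(list())
  stopifnot(n <= 16L)  # 2^n enumeration
  ext <- lapply(nodes$key, build_extended)
  D <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- extended_distance(ext[[i]], ext[[j]])
  out <- list()
  for (mask in seq_len(2^n - 1L)) {
    S <- which(bitwAnd(mask, 2L^(seq_len(n) - 1L)) > 0L)
    sub <- D[S, S, drop = FALSE]
    if (any(sub > d)) next                                  # property 2
    outside <- setdiff(seq_len(n), S)
    addable <- vapply(outside, function(v) all(D[v, S] <= d), logical(1))
    if (any(addable)) next                                  # property 3
    if (!any(nodes$in_g1[S]) || !any(nodes$in_g2[S])) next  # property 1
    out[[length(out) + 1L]] <- nodes$key[S]
  }
  out[order(vapply(out, paste, character(1), collapse = " "))]
}

# canonical comparable form of enumerate_ssms() output
ssm_keysets <- function(ssms) {
  out <- lapply(ssms, function(s) sort(s$nodes))
  out[order(vapply(out, paste, character(1), collapse = " "))]
}

# random small instance: two genes over a reduced alphabet (high collision
# rate exercises node merging and palindromic collapse); at l = 6 the node
# count is bounded by the window count (<= 8 here)
random_small_pair <- function(alphabet = c("A", "T")) {
  rand_motif <- function() paste(sample(alphabet, sample(6:7, 1L),
                                        replace = TRUE), collapse = "")
  list(g1 = gene_set("g1", replicate(sample(1:2, 1L), rand_motif())),
       g2 = gene_set("g2", replicate(sample(1:2, 1L), rand_motif())))
}

# random realistic gene set (full alphabet)
random_gene_set <- function(id, n_motifs = 5L, len_range = 8:16) {
  gene_set(id, replicate(n_motifs,
    paste(sample(c("A", "C", "G", "T"), sample(len_range, 1L),
                 replace = TRUE), collapse = "")))
}

# brute-force hypergeometric upper tail P(X >= k) from point masses
hyper_tail_oracle <- function(k, K, N, m) {
  xs <- k:min(K, m)
  sum(choose(K, xs) * choose(N - K, m - xs)) / choose(N, m)
}

# brute-force two-sided Fisher p: enumerate all 2x2 tables with the observed
# margins, sum the probabilities of tables no more probable than observed
fisher_oracle <- function(a, b, c, d) {
  row1 <- a + b; row2 <- c + d; col1 <- a + c; n <- a + b + c + d
  prob <- function(x) choose(col1, x) * choose(n - col1, row1 - x) /
    choose(n, row1)
  xs <- max(0L, row1 - (n - col1)):min(row1, col1)
  ps <- vapply(xs, prob, numeric(1))
  sum(ps[ps <= prob(a) * (1 + 1e-7)])
}

# tiny deterministic database used across IO tests
tiny_db <- function() {
  motif_db(c("g1", "g1", "g2"), c("m1", "m2", "m1"),
           c("ACGTACGTA", "ACGTACGTAC", "TTTTTTTTTT"))
}
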
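test_that("type validation enforces the length and distance bounds", {
  expect_silent(ssm_type(6, 2))
  expect_silent(ssm_type(14, 4))
  expect_error(ssm_type(5, 0))
  expect_error(ssm_type(15, 0))
  expect_error(ssm_type(6, 3))   # floor(6/3) = 2
  expect_error(ssm_type(14, 5))  # floor(14/3) = 4
})

test_that("the type grid enumerates exactly the valid (l, d) combinations", {
  grid <- ssm_type_grid()
  full <- expand.grid(l = 6:14, d = 0:5)
  full <- full[full$d <= pmin(5, full$l %/% 3), ]
  full <- full[order(full$l, full$d), ]
  expect_equal(nrow(grid), nrow(full))
  expect_equal(unname(as.matrix(grid)), unname(as.matrix(full)))
})

test_that("potential counts reproduce the worked window arithmetic", {
  g1 <- gene_set("g1", c(strrep("A", 9), strrep("C", 10)))
  g2 <- gene_set("g2", strrep("G", 10))
  g3 <- gene_set("g3", c(strrep("T", 8), strrep("A", 9)))
  expect_equal(potential_ssm_count(g1, g2, 8), 15)  # (2 + 3) x 3
  expect_equal(potential_ssm_count(g2, g3, 8), 9)   # 3 x (1 + 2)
  expect_equal(potential_ssm_count(gene_set("x", strrep("A", 5)), g2, 8), 0)
})

test_that("potential counts are bilinear and symmetric, without window dedup", {
  g1 <- gene_set("g1", c("ACGTACGTA", "ACGTACGTA"))  # identical motifs count twice
  g2 <- gene_set("g2", "TTTTAAAACC")
  expect_equal(potential_ssm_count(g1, g2, 8),
               2 * potential_ssm_count(gene_set("g1", "ACGTACGTA"), g2, 8))
  set.seed(103)
  for (i in 1:20) {
    a <- random_gene_set("a", 3); b <- random_gene_set("b", 4)
    l <- sample(6:10, 1)
    expect_equal(potential_ssm_count(a, b, l), potential_ssm_count(b, a, l))
    doubled <- gene_set("a", rep(a$sequences, 2))
    expect_equal(potential_ssm_count(doubled, b, l),
                 2 * potential_ssm_count(a, b, l))
  }
})

test_that("windows with matching extended sequences merge into one node", {
  # complementary homopolymers share one extended class
  nodes <- extract_nodes(gene_set("g1", strrep("A", 8)),
                         gene_set("g2", strrep("T", 8)), 8)
  expect_equal(nrow(nodes), 1L)
  expect_true(nodes$in_g1 && nodes$in_g2)
  expect_equal(nodes$count, 2L)

  nodes2 <- extract_nodes(gene_set("g1", "ACGTACGTA"), gene_set("g2"), 8)
  expect_identical(nodes2$key, c("ACGTACGT", "ATGCATGC"))
  expect_true(all(nodes2$in_g1) && !any(nodes2$in_g2))

  empty <- extract_nodes(gene_set("g1"), gene_set("g2"), 8)
  expect_equal(nrow(empty), 0L)
})

test_that("enumeration matches the hand-built clique cases", {
  t80 <- ssm_type(8, 0); t81 <- ssm_type(8, 1)
  # a single shared node is a maximal 1-clique spanning both genes
  expect_length(enumerate_ssms(strrep("A", 8), strrep("A", 8), t80), 1L)
  # extended distance 8: no edge, no shared node
  expect_length(enumerate_ssms(strrep("A", 8), strrep("C", 8), t80), 0L)
  # the {A7C, A6C2} clique is discarded: both nodes from gene 2 only
  ssms <- enumerate_ssms(strrep("A", 8),
                         c("AAAAAAAC", "AAAAAACC"), t81)
  expect_length(ssms, 1L)
  expect_identical(ssms[[1]]$nodes, c("AAAAAAAA", "AAAAAAAC"))
})

test_that("SSMC packages the counts with a degenerate marker", {
  res <- ssm_count_result(strrep("A", 8), c("AAAAAAAC", "AAAAAACC"),
                          ssm_type(8, 1))
  expect_equal(res$ssm_count, 1L)
  expect_equal(res$potential_count, 2)
  expect_equal(res$ssmc, 0.5)
  expect_equal(ssm_count_result(strrep("A", 8), strrep("A", 8),
                                ssm_type(8, 0))$ssmc, 1)
  degen <- ssm_count_result(strrep("A", 5), strrep("A", 10), ssm_type(8, 0))
  expect_equal(degen$potential_count, 0)
  expect_true(is.na(degen$ssmc))
})

test_that("enumeration equals the exhaustive subset oracle on random instances", {
  set.seed(104)
  n_nonempty <- 0L
  for (i in 1:60) {
    inst <- random_small_pair()
    d <- sample(0:2, 1)
    got <- ssm_keysets(enumerate_ssms(inst$g1, inst$g2, ssm_type(6, d)))
    want <- oracle_ssms(inst$g1, inst$g2, 6, d)
    expect_identical(got, want)
    n_nonempty <- n_nonempty + (length(want) > 0L)
  }
  expect_gt(n_nonempty, 10L)  # the instances genuinely exercise the path
})

test_that("returned SSMs are sound cliques and maximal", {
  set.seed(105)
  for (i in 1:20) {
    g1 <- random_gene_set("g1", 3, 8:12)
    g2 <- random_gene_set("g2", 3, 8:12)
    type <- ssm_type(8, 2)
    nodes <- extract_nodes(g1, g2, type$l)
    ssms <- enumerate_ssms(g1, g2, type)
    for (s in ssms) {
      ext <- lapply(s$nodes, build_extended)
      if (length(ext) > 1L)
        for (a in seq_along(ext)) for (b in seq_along(ext))
          expect_lte(extended_distance(ext[[a]], ext[[b]]), type$d)
      outside <- setdiff(nodes$key, s$nodes)
      for (v in outside)
        expect_true(any(vapply(ext, function(e)
          extended_distance(e, build_extended(v)) > type$d, logical(1))))
      expect_true(any(nodes$in_g1[nodes$key %in% s$nodes]))
      expect_true(any(nodes$in_g2[nodes$key %in% s$nodes]))
    }
  }
})

test_that("results are invariant under strand/orientation relabeling", {
  set.seed(106)
  transforms <- list(identity, dna_complement, dna_reverse, dna_revcomp)
  for (i in 1:25) {
    g1 <- random_gene_set("g1", 4); g2 <- random_gene_set("g2", 4)
    tg1 <- gene_set("g1", vapply(g1$sequences, function(s)
      transforms[[sample(4, 1)]](s), character(1)))
    tg2 <- gene_set("g2", vapply(g2$sequences, function(s)
      transforms[[sample(4, 1)]](s), character(1)))
    for (td in list(c(6, 2), c(8, 1), c(10, 3))) {
      type <- ssm_type(td[1], td[2])
      a <- ssm_count_result(g1, g2, type)
      b <- ssm_count_result(tg1, tg2, type)
      expect_equal(b$ssm_count, a$ssm_count)
      expect_equal(b$potential_count, a$potential_count)
    }
  }
})

test_that("results are symmetric in the gene pair", {
  set.seed(107)
  for (i in 1:10) {
    g1 <- random_gene_set("g1", 4); g2 <- random_gene_set("g2", 4)
    type <- ssm_type(7, 2)
    a <- ssm_count_result(g1, g2, type)
    b <- ssm_count_result(g2, g1, type)
    expect_equal(a$ssm_count, b$ssm_count)
    expect_equal(a$potential_count, b$potential_count)
    expect_identical(ssm_keysets(enumerate_ssms(g1, g2, type)),
                     ssm_keysets(enumerate_ssms(g2, g1, type)))
  }
})

test_that("SSM existence is monotone in d (edges only get added)", {
  set.seed(108)
  for (i in 1:30) {
    g1 <- random_gene_set("g1", 3, 8:12)
    g2 <- random_gene_set("g2", 3, 8:12)
    counts <- vapply(0:3, function(d)
      length(enumerate_ssms(g1, g2, ssm_type(9, d))), integer(1))
    for (d in 1:3)
      if (counts[d] >= 1L) expect_gte(counts[d + 1L], 1L)
  }
})

test_that("clique enumeration agrees with an independent graph library", {
  skip_if_not_installed("igraph")
  set.seed(109)
  for (i in 1:20) {
    g1 <- random_gene_set("g1", 4, 8:14)
    g2 <- random_gene_set("g2", 4, 8:14)
    type <- ssm_type(8, 2)
    nodes <- extract_nodes(g1, g2, type$l)
    n <- nrow(nodes)
    D <- ext_dist_matrix(nodes$key)
    adj <- D <= type$d & upper.tri(D)
    gr <- igraph::graph_from_adjacency_matrix(adj | t(adj), mode = "undirected")
    cl <- igraph::max_cliques(gr)
    spanning <- Filter(function(v) any(nodes$in_g1[as.integer(v)]) &&
                         any(nodes$in_g2[as.integer(v)]), cl)
    want <- lapply(spanning, function(v) sort(nodes$key[as.integer(v)]))
    want <- want[order(vapply(want, paste, character(1), collapse = " "))]
    expect_identical(ssm_keysets(enumerate_ssms(g1, g2, type)), want)
  }
})

test_that("pair tables cover the grid and bulk scans match single pairs", {
  db <- motif_db(c("a", "a", "b", "c"), c("m1", "m2", "m1", "m1"),
                 c("ACGTACGTACGTACG", "TTAACCGGTTAACC",
                   "ACGTACGTACGTACG", "GGGTTTCCCAAAGG"))
  tab <- pair_ssm_table(db, "a", "b")
  expect_equal(nrow(tab), nrow(ssm_type_grid()))
  for (k in c(1L, 10L, nrow(tab))) {
    single <- ssm_count_result(gene_motifs(db, "a"), gene_motifs(db, "b"),
                               ssm_type(tab$l[k], tab$d[k]))
    expect_equal(tab$ssm_count[k], single$ssm_count)
    expect_equal(tab$potential_count[k], single$potential_count)
  }
  bulk <- scan_pairs(db, rbind(c("a", "b"), c("a", "c")))
  expect_equal(bulk[bulk$gene2 == "b", names(tab)[-(1:2)]],
               tab[, -(1:2)], ignore_attr = TRUE)
  expect_error(pair_ssm_table(db, "a", "zzz"), "unknown gene")
})
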
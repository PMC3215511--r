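test_that("configs validate their parameters and demand a seed", {
  expect_error(synthetic_config(n_genes = 10), "seed")
  expect_error(synthetic_config(n_genes = 0, seed = 1))
  expect_error(synthetic_config(
    n_genes = 5, planted_modules = list(list(motif = "ACGN")), seed = 1),
    "ACGT")
  expect_error(synthetic_config(
    n_genes = 5, length_bounds = c(6, 12),
    planted_modules = list(list(motif = strrep("A", 20))), seed = 1),
    "length_bounds")
  expect_error(synthetic_config(
    n_genes = 5, planted_modules = list(list(motif = "ACGTACGTAC",
                                             mutations = 11)), seed = 1),
    "mutation")
})

test_that("generation is exactly reproducible from the seed", {
  cfg <- synthetic_config(n_genes = 25, planted_modules = list(
    list(genes = 3, motif = "ACGTTAGCAC", mutations = 1)), seed = 77)
  a <- generate_db(cfg); b <- generate_db(cfg)
  expect_identical(a$db, b$db)
  expect_identical(a$truth, b$truth)
  c <- generate_db(synthetic_config(n_genes = 25, seed = 78))
  expect_false(identical(a$db, c$db))
})

test_that("emitted databases validate strictly and respect length bounds", {
  sim <- generate_db(synthetic_config(n_genes = 40, length_bounds = c(6, 22),
                                      gc_content = 0.6, seed = 21))
  tbl_seqs <- unlist(lapply(db_genes(sim$db), function(g)
    gene_motifs(sim$db, g)$sequences))
  # re-validating under strict policy must succeed
  expect_silent(motif_db(rep("g", length(tbl_seqs)),
                         sprintf("m%04d", seq_along(tbl_seqs)), tbl_seqs))
  lens <- nchar(tbl_seqs)
  expect_gt(length(lens), 100L)
  expect_true(all(lens >= 6 & lens <= 22))
})

test_that("summary statistics recover the configured moments", {
  sim <- generate_db(synthetic_config(n_genes = 2000, seed = 22))
  s <- db_summary(sim$db)
  se_count <- 8.9 / sqrt(2000)
  expect_lt(abs(s$motifs_per_gene_mean - 12.7), 3 * se_count)
  se_len <- 4.1 / sqrt(s$n_motifs)
  expect_lt(abs(s$motif_length_mean - 11.7), 3 * se_len)
  expect_lt(abs(s$motifs_per_gene_sd - 8.9), 0.6)
  expect_lt(abs(s$motif_length_sd - 4.1), 0.15)
})

test_that("an unmutated planted 10-mer links every module pair at (10,0)", {
  sim <- generate_db(synthetic_config(
    n_genes = 30, planted_modules = list(list(genes = 5,
                                              motif = "ACGTTAGCAC")),
    seed = 23))
  mod <- sim$truth$modules[[1]]$genes
  expect_length(mod, 5L)
  pairs <- t(utils::combn(mod, 2))
  for (p in seq_len(nrow(pairs))) {
    n <- length(enumerate_ssms(gene_motifs(sim$db, pairs[p, 1]),
                               gene_motifs(sim$db, pairs[p, 2]),
                               ssm_type(10, 0)))
    expect_gte(n, 1L)
  }
})

test_that("planted copies carry exactly the configured mutation count", {
  sim <- generate_db(synthetic_config(
    n_genes = 10, planted_modules = list(list(genes = c("g03", "g08"),
                                              motif = "ACGTACGTACGT",
                                              copies = 2, mutations = 2)),
    seed = 24))
  inst <- sim$truth$instances
  expect_equal(nrow(inst), 4L)
  muts <- vapply(inst$sequence, function(s)
    sum(charToRaw(s) != charToRaw("ACGTACGTACGT")), integer(1))
  expect_true(all(muts == 2L))
  # and the mutated copies really are in the database
  expect_true(all(inst$sequence %in% unlist(
    lapply(c("g03", "g08"), function(g) gene_motifs(sim$db, g)$sequences))))
})

test_that("annotations mirror planted modules over the full universe", {
  sim <- generate_db(synthetic_config(
    n_genes = 50, planted_modules = list(list(genes = 5,
                                              motif = "ACGTTAGCAC")),
    seed = 25))
  ann0 <- generate_annotations(sim$truth, n_background_categories = 0,
                               seed = 26)
  expect_identical(names(ann0$categories), "module01")
  expect_identical(ann0$categories$module01, sim$truth$modules[[1]]$genes)
  expect_identical(ann0$universe, sim$truth$genes)
  ann <- generate_annotations(sim$truth, n_background_categories = 10,
                              category_size_range = c(5, 15), seed = 26)
  expect_length(ann$categories, 11L)
  sizes <- lengths(ann$categories[startsWith(names(ann$categories), "bg")])
  expect_true(all(sizes >= 5 & sizes <= 15))
  # no planted modules, no background: empty table over the universe
  sim0 <- generate_db(synthetic_config(n_genes = 10, seed = 27))
  ann_empty <- generate_annotations(sim0$truth, 0, seed = 28)
  expect_length(ann_empty$categories, 0L)
  expect_identical(ann_empty$universe, sim0$truth$genes)
})

test_that("co-expression tables are symmetric with module pairs exact at noise 0", {
  sim <- generate_db(synthetic_config(
    n_genes = 20, planted_modules = list(list(genes = c("g03", "g09", "g15"),
                                              motif = "ACGTTAGCAC")),
    seed = 29))
  coex <- generate_coexpression(sim$truth, noise_rate = 0, seed = 30)
  expect_equal(nrow(coex), 6L)  # 3 unordered pairs, both orientations
  expect_identical(coexpressed_with(coex, "g03"), c("g09", "g15"))
  # symmetry: (x, y) present iff (y, x) present
  flipped <- paste(coex$coexpressed_gene, coex$query_gene)
  expect_setequal(paste(coex$query_gene, coex$coexpressed_gene), flipped)
  # uniform noise on an empty truth approximates the configured rate
  sim0 <- generate_db(synthetic_config(n_genes = 60, seed = 31))
  noisy <- generate_coexpression(sim0$truth, noise_rate = 0.2, seed = 32)
  n_pairs_all <- choose(60, 2)
  rate <- (nrow(noisy) / 2) / n_pairs_all
  expect_lt(abs(rate - 0.2), 3 * sqrt(0.2 * 0.8 / n_pairs_all))
})

test_that("recovery of a planted module degrades as mutations accumulate", {
  grid <- data.frame(l = c(8L, 8L, 10L, 10L), d = c(0L, 2L, 0L, 3L))
  recovered <- sapply(0:3, function(m) {
    vapply(1:6, function(s) {
      sim <- generate_db(synthetic_config(
        n_genes = 50, planted_modules = list(
          list(genes = 4, motif = "ACGTTAGCAC", mutations = m)),
        seed = 500 + 10 * s + m))
      mod <- sim$truth$modules[[1]]$genes
      nulls <- build_nulls(sim$db, grid, n_pairs = 150, seed = 600 + s)
      cex <- build_cexlist(mod[1], sim$db, nulls, t = 0.05)
      sum(mod[-1] %in% cex$gene_id)
    }, numeric(1))
  })
  means <- colMeans(recovered)
  expect_true(all(diff(means) <= 0))
  expect_gt(means[1], means[4])
})
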
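#' Empirical null distribution of SSMC from random gene pairs
#'
#' Whether a pair's corrected shared-motif count (SSMC) is exceptional is
#' judged against the SSMC distribution over random pairs of genes from the
#' same database. `sample_null()` draws `n_pairs` unordered pairs of
#' distinct genes (uniformly, with replacement across pairs), computes each
#' pair's SSMC for one `(l, d)` type, and keeps the sorted sample. Pairs
#' with no length-`l` window on either side are degenerate and contribute
#' SSMC = 0: absence of motif material is absence of evidence, and dropping
#' such pairs would bias the null toward motif-rich genes.
#'
#' For a whole type grid use [build_nulls()], which draws one shared pair
#' list and reuses each pair's window tables across all types.
#'
#' @param db a `motif_db` with at least two genes.
#' @param type an [ssm_type()].
#' @param n_pairs number of random pairs.
#' @param seed integer seed; the sample is fully reproducible from
#'   `(db, type, n_pairs, seed)`.
#' @return An object of class `ssm_null`: list with `l`, `d`, `sample`
#'   (ascending SSMC values) and `n`.
#' @export
sample_null <- function(db, type, n_pairs, seed) {
  stopifnot(inherits(type, "ssm_type"))
  nulls <- build_nulls(db, data.frame(l = type$l, d = type$d), n_pairs, seed)
  nulls$types[[1L]]
}

type_key <- function(l, d) sprintf("l%d_d%d", l, d)

#' Build null distributions for every type of a grid
#'
#' Draws a single seeded list of `n_pairs` random distinct-gene pairs and
#' computes each pair's SSMC for every `(l, d)` type in `grid`, sharing the
#' per-gene window tables across types. Reference analyses of this kind use
#' on the order of 50,000 pairs on a genome-scale database; scale `n_pairs`
#' to your database size (the p-value floor is `1/(n_pairs + 1)`).
#'
#' @param db a `motif_db` with at least two genes.
#' @param grid data frame of valid types (default [ssm_type_grid()]).
#' @param n_pairs number of random pairs.
#' @param seed integer seed.
#' @return An object of class `ssm_nulls`: list with `types` (named list of
#'   `ssm_null`, keyed `"l<l>_d<d>"`), `grid`, `n_pairs`, `seed`, `db_hash`.
#' @export
build_nulls <- function(db, grid = ssm_type_grid(), n_pairs, seed) {
  stopifnot(inherits(db, "motif_db"), n_pairs >= 1L)
  grid <- as_type_grid(grid)
  genes <- db_genes(db)
  if (length(genes) < 2L)
    stop("null sampling needs a database with at least 2 genes",
         call. = FALSE)
  pairs <- with_seed(seed, {
    i <- sample.int(length(genes), n_pairs, replace = TRUE)
    j <- sample.int(length(genes) - 1L, n_pairs, replace = TRUE)
    j <- ifelse(j >= i, j + 1L, j)  # uniform over distinct partners
    cbind(i, j)
  })
  cache <- new_window_cache(db)
  mat <- matrix(0, nrow = n_pairs, ncol = nrow(grid))
  for (p in seq_len(n_pairs)) {
    res <- pair_counts(cache, genes[pairs[p, 1L]], genes[pairs[p, 2L]], grid)
    mat[p, ] <- ifelse(is.na(res$ssmc), 0, res$ssmc)
  }
  types <- lapply(seq_len(nrow(grid)), function(k) {
    structure(list(l = grid$l[k], d = grid$d[k],
                   sample = sort(mat[, k]), n = n_pairs),
              class = "ssm_null")
  })
  names(types) <- type_key(grid$l, grid$d)
  structure(list(types = types, grid = grid, n_pairs = as.integer(n_pairs),
                 seed = as.integer(seed), db_hash = db_hash(db)),
            class = "ssm_nulls")
}

#' @export
print.ssm_nulls <- function(x, ...) {
  cat("ssm_nulls:", length(x$types), "type(s),", x$n_pairs,
      "random pairs, seed", x$seed, "\n")
  invisible(x)
}

#' Empirical right-tail p-value against a null sample
#'
#' The probability of finding an SSMC equal to or greater than `observed`
#' under the empirical null, estimated with add-one smoothing as
#' `(r + 1) / (n + 1)` where `r` counts null values `>= observed`. The
#' smoothing keeps the estimate strictly positive (a finite sample cannot
#' certify p = 0); the attainable range is `[1/(n+1), 1]`, and ties count
#' toward the tail.
#'
#' @param null an `ssm_null`.
#' @param observed SSMC value(s).
#' @return Numeric vector of p-values in `[1/(n+1), 1]`.
#' @export
empirical_p <- function(null, observed) {
  stopifnot(inherits(null, "ssm_null"))
  s <- null$sample
  vapply(observed, function(x) (sum(s >= x) + 1) / (null$n + 1), numeric(1))
}

#' Score a gene pair across a type grid
#'
#' Computes SSMC and its empirical p-value for every type in the grid and
#' combines them into the cp-value: the minimum p-value over all types, i.e.
#' the most exceptional shared-motif signal regardless of motif length or
#' allowed degeneracy. Degenerate types (zero potential shared motifs)
#' receive p = 1 — no material, no evidence. No multiplicity adjustment is
#' applied across types: the cp-value is a raw minimum, and is interpreted
#' relative to its threshold rather than as a calibrated probability.
#'
#' @param db a `motif_db`.
#' @param gene1,gene2 gene ids in `db`.
#' @param nulls an `ssm_nulls` covering every grid type.
#' @param grid type grid (default: the grid of `nulls`).
#' @return An object of class `pair_score`: list with `gene_pair`, `table`
#'   (per-type `l`, `d`, `ssmc`, `p_value`), `cp_value`, `best_type`.
#' @export
score_pair <- function(db, gene1, gene2, nulls, grid = NULL) {
  stopifnot(inherits(db, "motif_db"), inherits(nulls, "ssm_nulls"))
  grid <- as_type_grid(grid %||% nulls$grid)
  missing <- setdiff(type_key(grid$l, grid$d), names(nulls$types))
  if (length(missing))
    stop("no null distribution for type(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  cache <- new_window_cache(db)
  score_pair_cached(cache, gene1, gene2, nulls, grid)
}

score_pair_cached <- function(cache, gene1, gene2, nulls, grid) {
  res <- pair_counts(cache, gene1, gene2, grid)
  p <- vapply(seq_len(nrow(res)), function(k) {
    if (is.na(res$ssmc[k])) return(1)
    empirical_p(nulls$types[[type_key(res$l[k], res$d[k])]], res$ssmc[k])
  }, numeric(1))
  res$p_value <- p
  best <- which.min(p)  # first minimum in (l, d) order breaks ties
  structure(list(gene_pair = c(gene1, gene2), table = res,
                 cp_value = p[best],
                 best_type = c(l = res$l[best], d = res$d[best])),
            class = "pair_score")
}

#' @export
print.pair_score <- function(x, ...) {
  cat(sprintf("pair (%s, %s): cp-value %.4g at (%d,%d)SSM\n",
              x$gene_pair[1], x$gene_pair[2], x$cp_value,
              x$best_type[["l"]], x$best_type[["d"]]))
  invisible(x)
}

#' CEXlist: genes sharing a combined-exceptional number of motifs
#'
#' Scores a query gene against every other gene in the database and retains
#' those whose cp-value falls strictly below the threshold `t`. The result
#' is the list of candidate co-regulated genes for the query ("Combined
#' EXceptional" shared-motif counts). Members are sorted by ascending
#' cp-value, ties broken by gene id; the query itself is never a member.
#'
#' @param query gene id present in `db`.
#' @param db a `motif_db`.
#' @param nulls an `ssm_nulls`.
#' @param t cp-value threshold in `(0, 1]`.
#' @param grid type grid (default: the grid of `nulls`).
#' @param candidates optional subset of genes to score against (default: all
#'   other genes in `db`).
#' @return An object of class `cexlist`: data frame with columns `gene_id`,
#'   `cp_value`, `l`, `d` (the best type), plus attributes `query` and `t`.
#' @export
build_cexlist <- function(query, db, nulls, t, grid = NULL,
                          candidates = NULL) {
  stopifnot(inherits(db, "motif_db"), inherits(nulls, "ssm_nulls"),
            length(t) == 1L, t > 0, t <= 1)
  if (!query %in% db_genes(db))
    stop("query gene not in database: ", query, call. = FALSE)
  grid <- as_type_grid(grid %||% nulls$grid)
  candidates <- candidates %||% setdiff(db_genes(db), query)
  stopifnot(all(candidates %in% db_genes(db)))
  candidates <- setdiff(sort(candidates), query)
  cache <- new_window_cache(db)
  scores <- lapply(candidates, function(g)
    score_pair_cached(cache, query, g, nulls, grid))
  cp <- vapply(scores, `[[`, numeric(1), "cp_value")
  bl <- vapply(scores, function(s) s$best_type[["l"]], numeric(1))
  bd <- vapply(scores, function(s) s$best_type[["d"]], numeric(1))
  keep <- cp < t
  ord <- order(cp[keep], candidates[keep], method = "radix")
  out <- data.frame(gene_id = candidates[keep][ord],
                    cp_value = cp[keep][ord],
                    l = as.integer(bl[keep][ord]),
                    d = as.integer(bd[keep][ord]),
                    stringsAsFactors = FALSE)
  attr(out, "query") <- query
  attr(out, "t") <- t
  class(out) <- c("cexlist", "data.frame")
  out
}

#' @export
print.cexlist <- function(x, ...) {
  cat(sprintf("CEXlist(%s, t = %g): %d gene(s)\n", attr(x, "query"),
              attr(x, "t"), nrow(x)))
  if (nrow(x)) print.data.frame(head(x, 10L))
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}

#' Export a CEXlist as TSV
#'
#' Columns: `rank`, `gene_id`, `cp_value`, `l`, `d`. A `#`-prefixed header
#' line records the query and threshold.
#'
#' @param cex a `cexlist`.
#' @param path destination file.
#' @export
write_cexlist_tsv <- function(cex, path) {
  stopifnot(inherits(cex, "cexlist"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# CEXlist query=%s t=%g", attr(cex, "query"),
                     attr(cex, "t")), con)
  writeLines("rank\tgene_id\tcp_value\tl\td", con)
  if (nrow(cex))
    writeLines(sprintf("%d\t%s\t%.10g\t%d\t%d", seq_len(nrow(cex)),
                       cex$gene_id, cex$cp_value, cex$l, cex$d), con)
  invisible(path)
}

# ---- null cache ------------------------------------------------------------

#' Persist null distributions to a cache directory
#'
#' One TSV of sorted SSMC values per type plus a JSON sidecar recording the
#' database hash, pair count, seed and grid; [load_nulls()] refuses a cache
#' whose metadata does not match the database/parameters it is asked for.
#'
#' @param nulls an `ssm_nulls`.
#' @param dir cache directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_nulls <- function(nulls, dir) {
  stopifnot(inherits(nulls, "ssm_nulls"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (key in names(nulls$types)) {
    nl <- nulls$types[[key]]
    writeLines(c("ssmc", sprintf("%.17g", nl$sample)),
               file.path(dir, paste0("null_", key, ".tsv")))
  }
  meta <- list(db_hash = nulls$db_hash, n_pairs = nulls$n_pairs,
               seed = nulls$seed, grid = nulls$grid)
  jsonlite::write_json(meta, file.path(dir, "null_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load cached null distributions
#'
#' @param dir cache directory written by [save_nulls()].
#' @param db optional `motif_db`; if given, the cache must have been built
#'   from the same database content.
#' @return An `ssm_nulls`.
#' @export
load_nulls <- function(dir, db = NULL) {
  meta_path <- file.path(dir, "null_meta.json")
  if (!file.exists(meta_path))
    stop("no null cache at ", dir, " (missing null_meta.json); ",
         "build one with build_nulls() + save_nulls()", call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!is.null(db) && !identical(unname(meta$db_hash), unname(db_hash(db))))
    stop("null cache at ", dir, " was built from a different database",
         call. = FALSE)
  grid <- as_type_grid(as.data.frame(meta$grid))
  types <- lapply(seq_len(nrow(grid)), function(k) {
    f <- file.path(dir, paste0("null_", type_key(grid$l[k], grid$d[k]), ".tsv"))
    if (!file.exists(f)) stop("null cache incomplete: missing ", f,
                              call. = FALSE)
    vals <- as.numeric(readLines(f)[-1L])
    structure(list(l = grid$l[k], d = grid$d[k], sample = sort(vals),
                   n = length(vals)), class = "ssm_null")
  })
  names(types) <- type_key(grid$l, grid$d)
  structure(list(types = types, grid = grid,
                 n_pairs = as.integer(meta$n_pairs),
                 seed = as.integer(meta$seed), db_hash = meta$db_hash),
            class = "ssm_nulls")
}
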
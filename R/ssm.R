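#' SSM type: window length and maximum Hamming distance
#'
#' A shared-motif search is parameterised by the subsequence length `l` and
#' the maximum extended-Hamming distance `d` allowed between members of one
#' motif set. Valid types keep `l` in `[6, 14]` (the size range of classical
#' regulatory motifs) and `d` in `[0, 5]` with `d <= floor(l/3)`, so that
#' similarity never degenerates into chance alignment.
#'
#' @param l window length.
#' @param d maximum extended Hamming distance.
#' @return A list of class `ssm_type` with fields `l` and `d`.
#' @export
ssm_type <- function(l, d) {
  l <- as.integer(l); d <- as.integer(d)
  if (is.na(l) || l < 6L || l > 14L)
    stop("l must be in [6, 14]", call. = FALSE)
  if (is.na(d) || d < 0L || d > 5L || d > l %/% 3L)
    stop("d must be in [0, min(5, floor(l/3))]", call. = FALSE)
  structure(list(l = l, d = d), class = "ssm_type")
}

#' @export
print.ssm_type <- function(x, ...) {
  cat(sprintf("(%d,%d)SSM type\n", x$l, x$d)); invisible(x)
}

#' The full grid of SSM types
#'
#' All `(l, d)` with `6 <= l <= 14` and `0 <= d <= min(5, floor(l/3))`,
#' ordered by `(l, d)` — 36 types in total.
#'
#' @return A data frame with integer columns `l` and `d`.
#' @export
ssm_type_grid <- function() {
  rows <- do.call(rbind, lapply(6:14, function(l)
    data.frame(l = l, d = 0:min(5L, l %/% 3L))))
  rows$l <- as.integer(rows$l); rows$d <- as.integer(rows$d)
  rows
}

as_type_grid <- function(grid) {
  if (inherits(grid, "ssm_type")) grid <- data.frame(l = grid$l, d = grid$d)
  stopifnot(is.data.frame(grid), all(c("l", "d") %in% names(grid)))
  invisible(mapply(ssm_type, grid$l, grid$d))  # validate every row
  grid[order(grid$l, grid$d), c("l", "d"), drop = FALSE]
}

#' Number of potential shared motifs of a gene pair
#'
#' The product, over the two genes, of their total numbers of length-`l`
#' windows across all atomic motifs. Windows are counted positionally,
#' without deduplicating identical sequences: two motifs of lengths 9 and 10
#' against one of length 10 give `(2 + 3) x 3 = 15` potential length-8 shared
#' motifs. This is the denominator that corrects raw shared-motif counts for
#' differences in motif content (see [ssm_count_result()]).
#'
#' Note the deliberate asymmetry with [extract_nodes()]: graph nodes merge
#' windows with identical extended sequences, but the potential count does
#' not — it measures material, not diversity.
#'
#' @param g1,g2 `gene_set` objects (or character vectors of motif sequences).
#' @param l window length.
#' @return A non-negative integer (stored as double to avoid overflow on
#'   large databases).
#' @export
potential_ssm_count <- function(g1, g2, l) {
  g1 <- as_gene_set(g1, "g1"); g2 <- as_gene_set(g2, "g2")
  stopifnot(l >= 1L)
  as.numeric(sum(window_count(nchar(g1$sequences), l))) *
    sum(window_count(nchar(g2$sequences), l))
}

# all length-l windows of a set of motifs; windows never span motif
# boundaries
motif_windows <- function(sequences, l) {
  lens <- nchar(sequences)
  keep <- lens >= l
  if (!any(keep)) return(character())
  unlist(lapply(sequences[keep], function(s) {
    n <- nchar(s)
    substring(s, 1:(n - l + 1L), l:n)
  }), use.names = FALSE)
}

# per-gene node table: canonical keys of the gene's windows, with
# occurrence counts and the total positional window count
gene_window_table <- function(sequences, l) {
  w <- motif_windows(sequences, l)
  if (length(w) == 0L)
    return(list(keys = character(), counts = integer(), total = 0L))
  keys <- canonical_key(w)
  tab <- table(keys)
  list(keys = names(tab), counts = as.integer(tab), total = length(w))
}

#' PreSSM nodes of a gene pair
#'
#' Slides a window of length `l` over every atomic motif of both genes and
#' merges all windows whose extended sequences coincide into a single node
#' (a "PreSSM"), tagged with the genes it was drawn from and the number of
#' generating windows. These nodes are the vertices of the similarity graph
#' from which shared motifs are enumerated.
#'
#' @param g1,g2 `gene_set` objects (or character vectors of motif sequences).
#' @param l window length.
#' @return A data frame of class `pressm_nodes`, sorted by canonical `key`,
#'   with columns `key`, `count`, `in_g1`, `in_g2`; gene ids and `l` are
#'   attached as attributes.
#' @export
extract_nodes <- function(g1, g2, l) {
  g1 <- as_gene_set(g1, "g1"); g2 <- as_gene_set(g2, "g2")
  stopifnot(l >= 1L)
  w1 <- gene_window_table(g1$sequences, l)
  w2 <- gene_window_table(g2$sequences, l)
  keys <- sort(unique(c(w1$keys, w2$keys)))
  i1 <- match(keys, w1$keys); i2 <- match(keys, w2$keys)
  c1 <- ifelse(is.na(i1), 0L, w1$counts[i1])
  c2 <- ifelse(is.na(i2), 0L, w2$counts[i2])
  out <- data.frame(key = keys, count = c1 + c2,
                    in_g1 = c1 > 0L, in_g2 = c2 > 0L,
                    stringsAsFactors = FALSE)
  attr(out, "gene_ids") <- c(g1$gene_id, g2$gene_id)
  attr(out, "l") <- as.integer(l)
  class(out) <- c("pressm_nodes", "data.frame")
  out
}

#' Enumerate the shared motifs of a gene pair
#'
#' Builds the graph whose vertices are the PreSSM nodes of the pair, with an
#' edge wherever the extended Hamming distance is at most `d`, and returns
#' the maximal cliques that contain material from both genes. Each such
#' clique is one simple shared motif (SSM): a maximal set of mutually
#' similar, strand/orientation-degenerate subsequences present in both
#' genes' conserved promoter motifs. An isolated node occurring in both
#' genes is itself a valid (singleton) shared motif — the only possibility
#' at `d = 0`, where distinct keys are never adjacent.
#'
#' @param g1,g2 `gene_set` objects (or character vectors of motif sequences).
#' @param type an [ssm_type()].
#' @return A list of class `ssm_list`; each element has fields `nodes`
#'   (sorted canonical keys), `l`, `d`, `gene_pair`. Ordered
#'   lexicographically by key sequence, so output is deterministic.
#' @examples
#' enumerate_ssms("AAAAAAAA", c("AAAAAAAC", "AAAAAACC"), ssm_type(8, 1))
#' @export
enumerate_ssms <- function(g1, g2, type) {
  g1 <- as_gene_set(g1, "g1"); g2 <- as_gene_set(g2, "g2")
  stopifnot(inherits(type, "ssm_type"))
  nodes <- extract_nodes(g1, g2, type$l)
  cl <- ssm_cliques_cpp(nodes$key, nodes$in_g1, nodes$in_g2, type$d)
  ssms <- lapply(cl, function(idx) {
    list(nodes = nodes$key[idx], l = type$l, d = type$d,
         gene_pair = c(g1$gene_id, g2$gene_id))
  })
  key_str <- vapply(ssms, function(s) paste(s$nodes, collapse = " "),
                    character(1))
  ssms <- ssms[order(key_str, method = "radix")]
  structure(ssms, class = "ssm_list")
}

#' @export
print.ssm_list <- function(x, ...) {
  cat(length(x), "SSM(s)\n")
  for (s in head(x, 10L))
    cat("  {", paste(s$nodes, collapse = ", "), "}\n", sep = "")
  if (length(x) > 10L) cat("  ...\n")
  invisible(x)
}

#' Shared-motif count and corrected count (SSMC) for a gene pair
#'
#' Packages the number of shared motifs and the number of potential shared
#' motifs into the corrected count `ssmc = ssm_count / potential_count`.
#' Raw counts scale with how much motif material the two genes carry; the
#' ratio removes that dependence so pairs of motif-rich and motif-poor genes
#' become comparable. When a gene has no window of length `l` the potential
#' count is 0 and `ssmc` is `NA` (degenerate, never a division by zero).
#'
#' @param g1,g2 `gene_set` objects (or character vectors of motif sequences).
#' @param type an [ssm_type()].
#' @return A list of class `ssm_count` with fields `gene_pair`, `l`, `d`,
#'   `ssm_count`, `potential_count`, `ssmc`.
#' @export
ssm_count_result <- function(g1, g2, type) {
  g1 <- as_gene_set(g1, "g1"); g2 <- as_gene_set(g2, "g2")
  stopifnot(inherits(type, "ssm_type"))
  pot <- potential_ssm_count(g1, g2, type$l)
  n <- length(enumerate_ssms(g1, g2, type))
  structure(list(gene_pair = c(g1$gene_id, g2$gene_id),
                 l = type$l, d = type$d,
                 ssm_count = n, potential_count = pot,
                 ssmc = if (pot > 0) n / pot else NA_real_),
            class = "ssm_count")
}

#' @export
print.ssm_count <- function(x, ...) {
  cat(sprintf("(%d,%d)SSM for (%s, %s): %d SSM / %g potential -> SSMC %s\n",
              x$l, x$d, x$gene_pair[1], x$gene_pair[2], x$ssm_count,
              x$potential_count,
              if (is.na(x$ssmc)) "NA (degenerate)" else format(x$ssmc)))
  invisible(x)
}

# ---- bulk path -------------------------------------------------------------

# Environment caching per-(gene, l) window tables and per-gene sequence
# lists for one database; used by null sampling and whole-database scans.
new_window_cache <- function(db) {
  stopifnot(inherits(db, "motif_db"))
  e <- new.env(parent = emptyenv())
  e$seqs <- split(db$tbl$sequence, db$tbl$gene_id)
  e$tabs <- new.env(parent = emptyenv())
  e
}

cached_window_table <- function(cache, gene_id, l) {
  key <- paste0(gene_id, "\r", l)
  tab <- cache$tabs[[key]]
  if (is.null(tab)) {
    seqs <- cache$seqs[[gene_id]] %||% character()
    tab <- gene_window_table(seqs, l)
    cache$tabs[[key]] <- tab
  }
  tab
}

# SSM/potential/SSMC for one gene pair over a whole (l, d) grid, reusing the
# per-l distance matrix across the d values of that l
pair_counts <- function(cache, ga, gb, grid) {
  ssm <- integer(nrow(grid))
  pot <- numeric(nrow(grid))
  for (l in unique(grid$l)) {
    rows <- which(grid$l == l)
    wa <- cached_window_table(cache, ga, l)
    wb <- cached_window_table(cache, gb, l)
    pot[rows] <- as.numeric(wa$total) * wb$total
    if (wa$total == 0L || wb$total == 0L) next
    keys <- sort(unique(c(wa$keys, wb$keys)))
    in_a <- keys %in% wa$keys
    in_b <- keys %in% wb$keys
    ssm[rows] <- ssm_counts_multi_cpp(keys, in_a, in_b, grid$d[rows])
  }
  data.frame(l = grid$l, d = grid$d, ssm_count = ssm, potential_count = pot,
             ssmc = ifelse(pot > 0, ssm / pot, NA_real_))
}

#' Shared-motif counts for many gene pairs
#'
#' Bulk variant of [pair_ssm_table()]: computes `ssm_count`,
#' `potential_count` and `ssmc` for each supplied pair and each type of the
#' grid, sharing per-gene window tables across pairs. This is the routine
#' behind raw-count versus potential-count diagnostics (raw shared-motif
#' counts track motif content; the SSMC ratio removes most of that
#' dependence).
#'
#' @param db a `motif_db`.
#' @param pairs two-column matrix or data frame of gene ids.
#' @param grid a data frame of valid types (default [ssm_type_grid()]).
#' @return A data frame with one row per pair and type.
#' @export
scan_pairs <- function(db, pairs, grid = ssm_type_grid()) {
  stopifnot(inherits(db, "motif_db"))
  pairs <- as.matrix(pairs)
  stopifnot(ncol(pairs) == 2L)
  grid <- as_type_grid(grid)
  if (!all(pairs %in% db_genes(db)))
    stop("unknown gene id(s) in `pairs`", call. = FALSE)
  cache <- new_window_cache(db)
  out <- lapply(seq_len(nrow(pairs)), function(p)
    cbind(gene1 = pairs[p, 1L], gene2 = pairs[p, 2L],
          pair_counts(cache, pairs[p, 1L], pairs[p, 2L], grid),
          stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Shared-motif counts for a gene pair over a type grid
#'
#' Computes `ssm_count`, `potential_count` and `ssmc` for one pair of genes
#' from a database, for every `(l, d)` type in `grid`.
#'
#' @param db a `motif_db`.
#' @param gene1,gene2 gene ids in `db`.
#' @param grid a data frame of valid types (default [ssm_type_grid()]).
#' @return A data frame with one row per type.
#' @export
pair_ssm_table <- function(db, gene1, gene2, grid = ssm_type_grid()) {
  stopifnot(inherits(db, "motif_db"))
  grid <- as_type_grid(grid)
  for (g in c(gene1, gene2))
    if (!g %in% db$genes) stop("unknown gene id: ", g, call. = FALSE)
  cache <- new_window_cache(db)
  out <- pair_counts(cache, gene1, gene2, grid)
  cbind(gene1 = gene1, gene2 = gene2, out, stringsAsFactors = FALSE)
}
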
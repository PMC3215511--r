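#' Gene-category annotation table
#'
#' Maps category identifiers (GO-term-like or pathway-like labels) to gene
#' sets over a fixed gene universe. No ontology structure is modelled: each
#' category is a flat set, tested independently.
#'
#' @param categories named list; each element a character vector of gene ids.
#' @param universe character vector of all gene ids under consideration;
#'   every annotated gene must belong to it.
#' @return An object of class `annotation_table`.
#' @export
annotation_table <- function(categories, universe) {
  universe <- sort(unique(as.character(universe)))
  if (length(universe) == 0L) stop("empty gene universe", call. = FALSE)
  stopifnot(is.list(categories))
  if (length(categories) && is.null(names(categories)))
    stop("`categories` must be a named list", call. = FALSE)
  if (length(categories) == 0L)
    categories <- stats::setNames(list(), character())
  categories <- lapply(categories, function(g) sort(unique(as.character(g))))
  stray <- setdiff(unlist(categories, use.names = FALSE), universe)
  if (length(stray))
    stop("annotated gene(s) outside the universe: ",
         paste(head(stray, 5L), collapse = ", "), call. = FALSE)
  structure(list(categories = categories[order(names(categories))],
                 universe = universe),
            class = "annotation_table")
}

#' Read / write the two-column annotation TSV
#'
#' Dialect: `category_id<TAB>gene_id`, one pair per row, with a header line;
#' `#` comment lines are ignored. The universe defaults to the annotated
#' genes but is usually the full database gene set, passed explicitly.
#'
#' @param path file path.
#' @param universe optional gene universe (default: all genes in the file).
#' @return An `annotation_table`.
#' @export
read_annotation_tsv <- function(path, universe = NULL) {
  df <- read_two_col(path, c("category_id", "gene_id"))
  cats <- split(df$gene_id, df$category_id)
  annotation_table(cats, universe %||% unique(df$gene_id))
}

#' @rdname read_annotation_tsv
#' @param annot an `annotation_table` to write.
#' @export
write_annotation_tsv <- function(annot, path) {
  stopifnot(inherits(annot, "annotation_table"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("category_id\tgene_id", con)
  for (nm in names(annot$categories))
    if (length(annot$categories[[nm]]))
      writeLines(paste(nm, annot$categories[[nm]], sep = "\t"), con)
  invisible(path)
}

read_two_col <- function(path, expected_header) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0L)
    return(stats::setNames(data.frame(a = character(), b = character(),
                                      stringsAsFactors = FALSE),
                           expected_header))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (!identical(parts[[1L]], expected_header))
    stop("expected header '", paste(expected_header, collapse = "\\t"),
         "' in ", path, call. = FALSE)
  if (any(lengths(parts[-1L]) != 2L))
    stop("malformed two-column TSV: ", path, call. = FALSE)
  m <- do.call(rbind, parts[-1L])
  stats::setNames(data.frame(m[, 1L], m[, 2L], stringsAsFactors = FALSE),
                  expected_header)
}

#' Hypergeometric over-representation of categories in a gene list
#'
#' For each category with at least one gene in the list, tests whether the
#' overlap `k` between the list (size `m`) and the category (size `K`) is
#' larger than expected by chance when drawing `m` genes from a universe of
#' size `N`: the upper-tail hypergeometric probability `P(X >= k)`. Plain
#' per-category tests, no ontology decorrelation, and no multiplicity
#' correction — categories at `p <= alpha` are flagged as over-represented
#' and feed the [c_score()].
#'
#' @param gene_list character vector of gene ids; genes outside the
#'   annotation universe are dropped with a warning.
#' @param annot an `annotation_table`.
#' @param alpha over-representation flag threshold (default 0.05).
#' @return A data frame (class `enrichment_result`) sorted by ascending
#'   p-value: `category_id`, `k`, `m`, `K`, `N`, `p_value`,
#'   `over_represented`.
#' @export
hypergeom_enrich <- function(gene_list, annot, alpha = 0.05) {
  stopifnot(inherits(annot, "annotation_table"))
  gene_list <- unique(as.character(gene_list))
  outside <- setdiff(gene_list, annot$universe)
  if (length(outside)) {
    warning(length(outside), " gene(s) outside the annotation universe ",
            "dropped from the list", call. = FALSE)
    gene_list <- setdiff(gene_list, outside)
  }
  N <- length(annot$universe)
  m <- length(gene_list)
  rows <- lapply(names(annot$categories), function(cat) {
    genes <- annot$categories[[cat]]
    k <- length(intersect(gene_list, genes))
    if (k == 0L) return(NULL)
    K <- length(genes)
    p <- phyper(k - 1L, K, N - K, m, lower.tail = FALSE)
    data.frame(category_id = cat, k = k, m = m, K = K, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(category_id = character(), k = integer(),
                      m = integer(), K = integer(), N = integer(),
                      p_value = numeric(), stringsAsFactors = FALSE)
  out$over_represented <- out$p_value <= alpha
  out <- out[order(out$p_value, out$category_id, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Combined over-representation score of a gene list
#'
#' `c_score = sum_i log(1/p_i - 19)` (natural logarithm) over the
#' over-represented categories of a list. The constant 19 anchors the score
#' at zero for a category sitting exactly at the p = 0.05 flag threshold
#' (`log(1/0.05 - 19) = log 1 = 0`), so the score grows both with the number
#' of over-represented categories and with the strength of each. The
#' argument of the logarithm turns negative past p = 1/19, so only p-values
#' at or below 0.05 are admissible; passing anything larger is an error, not
#' a silent drop — filter with the `over_represented` flag of
#' [hypergeom_enrich()] first.
#'
#' @param p_values numeric vector of category p-values in `(0, 0.05]`; an
#'   empty vector scores 0.
#' @return The summed score (additive over concatenated lists).
#' @examples
#' c_score(0.05)  # exactly 0
#' c_score(0.01)  # log(81)
#' @export
c_score <- function(p_values) {
  if (length(p_values) == 0L) return(0)
  if (any(!is.finite(p_values)) || any(p_values <= 0) ||
      any(p_values > 0.05))
    stop("c_score is defined for p-values in (0, 0.05] only", call. = FALSE)
  sum(log(1 / p_values - 19))
}

#' Null distribution of c-scores for random gene lists
#'
#' Draws `n_lists` random gene lists of a fixed size (without replacement
#' within a list), runs [hypergeom_enrich()] on each, scores the
#' over-represented categories with [c_score()], and records the sample with
#' its mean and standard deviation. These nulls standardise observed
#' c-scores into z-scores; they are approximately normal, and their mean
#' grows with list size (more genes, more categories crossing the flag
#' threshold). Reference usage: 200 lists per size, sizes 100–3000.
#'
#' @param genes character vector to sample lists from (usually the full
#'   database gene set).
#' @param annot an `annotation_table`.
#' @param list_size size of each random list; at most `length(genes)`.
#' @param n_lists number of lists (>= 2, default 200).
#' @param seed integer seed.
#' @param alpha over-representation threshold passed to enrichment.
#' @return An object of class `cscore_null`: list with `list_size`,
#'   `sample`, `mu`, `sigma`, `n_lists`.
#' @export
build_cscore_null <- function(genes, annot, list_size, n_lists = 200L, seed,
                              alpha = 0.05) {
  genes <- unique(as.character(genes))
  stopifnot(inherits(annot, "annotation_table"), n_lists >= 2L)
  if (list_size > length(genes))
    stop("list_size exceeds the number of available genes", call. = FALSE)
  scores <- with_seed(seed, vapply(seq_len(n_lists), function(i) {
    lst <- sample(genes, list_size)
    enr <- suppressWarnings(hypergeom_enrich(lst, annot, alpha = alpha))
    c_score(enr$p_value[enr$over_represented])
  }, numeric(1)))
  structure(list(list_size = as.integer(list_size), sample = scores,
                 mu = mean(scores), sigma = sd(scores),
                 n_lists = as.integer(n_lists)),
            class = "cscore_null")
}

#' Standardised c-score
#'
#' `z = (c - mu) / sigma` against a [build_cscore_null()] distribution of
#' matching list size. Positive values indicate more clustering of the list
#' into biological categories than random lists of the same size.
#'
#' @param c observed c-score.
#' @param null a `cscore_null` with `sigma > 0`.
#' @return The z-score.
#' @export
z_score <- function(c, null) {
  stopifnot(inherits(null, "cscore_null"))
  if (!is.finite(null$sigma) || null$sigma <= 0)
    stop("degenerate c-score null (sigma = 0); the annotation yields no ",
         "variation across random lists", call. = FALSE)
  (c - null$mu) / null$sigma
}

#' Co-expression density of a gene list
#'
#' The fraction of a list `S` (typically CEXlist members) that also appears
#' in an externally derived co-expression set `G` for the same query gene:
#' `|G intersect S| / |S|`.
#'
#' @param G character vector of co-expressed genes.
#' @param S character vector of list members (or a `cexlist`).
#' @return A value in `[0, 1]`, or `NA` for an empty `S` (undefined, not 0).
#' @export
coexpression_density <- function(G, S) {
  if (inherits(S, "cexlist")) S <- S$gene_id
  S <- unique(as.character(S)); G <- unique(as.character(G))
  if (length(S) == 0L) return(NA_real_)
  length(intersect(G, S)) / length(S)
}

#' Fisher test of co-expression enrichment in versus out of a gene list
#'
#' Cross-tabulates the universe by membership of the list `S` and of the
#' co-expression set `G` and applies a two-sided Fisher exact test. The
#' enrichment ratio compares the co-expressed fraction inside the list with
#' the fraction outside: `(|G∩S|/|S|) / (|G\\S|/|U\\S|)`; it is reported as 0
#' when the list contains no co-expressed gene, and can fall below 1 (a
#' depletion), which is why the test is two-sided.
#'
#' @param G character vector of co-expressed genes (subset of `universe`).
#' @param S character vector of list members (or a `cexlist`), subset of
#'   `universe`, non-empty and not the whole universe.
#' @param universe character vector of all genes.
#' @return List with `enrichment_ratio`, `p_value`, and the 2x2 `table`.
#' @export
fisher_in_out <- function(G, S, universe) {
  if (inherits(S, "cexlist")) S <- S$gene_id
  S <- unique(as.character(S)); G <- unique(as.character(G))
  universe <- unique(as.character(universe))
  if (!all(S %in% universe) || !all(G %in% universe))
    stop("S and G must be subsets of the universe", call. = FALSE)
  if (length(S) < 1L || length(universe) - length(S) < 1L)
    stop("need at least one gene inside and one outside S", call. = FALSE)
  in_S <- universe %in% S
  in_G <- universe %in% G
  tab <- table(factor(in_S, levels = c(TRUE, FALSE)),
               factor(in_G, levels = c(TRUE, FALSE)),
               dnn = c("in_list", "co_expressed"))
  a <- tab[1L, 1L]                       # co-expressed, in list
  c_out <- tab[2L, 1L]                   # co-expressed, out of list
  ratio <- if (a == 0L) 0
           else if (c_out == 0L) Inf
           else (a / length(S)) / (c_out / (length(universe) - length(S)))
  p <- fisher.test(tab)$p.value
  list(enrichment_ratio = ratio, p_value = p, table = tab)
}

#' Read / write the two-column co-expression TSV
#'
#' Dialect: `query_gene<TAB>coexpressed_gene`, one pair per row, header
#' line, `#` comments ignored. The relation is symmetric: a pair is stored
#' in both orientations.
#'
#' @param path file path.
#' @return A data frame with columns `query_gene`, `coexpressed_gene`
#'   containing both orientations of every pair.
#' @export
read_coexpression_tsv <- function(path) {
  df <- read_two_col(path, c("query_gene", "coexpressed_gene"))
  sym <- unique(rbind(df,
                      stats::setNames(df[, 2:1],
                                      c("query_gene", "coexpressed_gene"))))
  sym <- sym[order(sym$query_gene, sym$coexpressed_gene, method = "radix"), ]
  rownames(sym) <- NULL
  sym
}

#' @rdname read_coexpression_tsv
#' @param coex data frame with columns `query_gene`, `coexpressed_gene`.
#' @export
write_coexpression_tsv <- function(coex, path) {
  stopifnot(all(c("query_gene", "coexpressed_gene") %in% names(coex)))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("query_gene\tcoexpressed_gene", con)
  if (nrow(coex))
    writeLines(paste(coex$query_gene, coex$coexpressed_gene, sep = "\t"),
               con)
  invisible(path)
}

#' Genes co-expressed with a query gene
#' @param coex co-expression data frame (see [read_coexpression_tsv()]).
#' @param gene query gene id.
#' @return Character vector of partners (possibly empty).
#' @export
coexpressed_with <- function(coex, gene) {
  sort(unique(coex$coexpressed_gene[coex$query_gene == gene]))
}
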
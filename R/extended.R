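#' DNA strand/orientation transforms
#'
#' Base-wise complement, reversal, and reverse complement of ACGT strings.
#' Vectorised.
#'
#' @param x character vector of ACGT sequences.
#' @return character vector of transformed sequences.
#' @export
dna_complement <- function(x) chartr("ACGT", "TGCA", x)

#' @rdname dna_complement
#' @export
dna_reverse <- function(x) stringi::stri_reverse(x)

#' @rdname dna_complement
#' @export
dna_revcomp <- function(x) stringi::stri_reverse(chartr("ACGT", "TGCA", x))

# canonical key of each window: lexicographically smallest of the four
# transforms; vectorised over windows
canonical_key <- function(x) {
  pmin(x, dna_complement(x), dna_reverse(x), dna_revcomp(x))
}

#' Build the extended sequence of a DNA word
#'
#' A word `w` is identified with its equivalence class
#' `{w, complement(w), reverse(w), revcomp(w)}`, so that a shared motif is
#' recognised regardless of strand or reading orientation. The class has 2
#' or 4 distinct members: the complement differs from `w` at every position,
#' so the class never collapses to one member, and palindromic structure
#' (under reversal or reverse complement) collapses four to two. Its
#' canonical key is the lexicographically smallest member.
#'
#' @param w a single ACGT string.
#' @return An object of class `extended_seq` with fields `members` (sorted,
#'   deduplicated), `canonical`, and `width`.
#' @examples
#' build_extended("AACG")$members  # 4 distinct members
#' build_extended("ACGT")$members  # collapses to 2
#' @export
build_extended <- function(w) {
  if (length(w) != 1L || is.na(w) || !grepl("^[ACGT]+$", w))
    stop("`w` must be a single non-empty ACGT string", call. = FALSE)
  members <- sort(unique(c(w, dna_complement(w), dna_reverse(w),
                           dna_revcomp(w))))
  structure(list(members = members, canonical = members[[1L]],
                 width = nchar(w)),
            class = "extended_seq")
}

#' @export
print.extended_seq <- function(x, ...) {
  cat("extended_seq {", paste(x$members, collapse = ", "), "} width ",
      x$width, "\n", sep = "")
  invisible(x)
}

# Hamming distance between two equal-length strings
hamming <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  if (length(ra) != length(rb))
    stop("Hamming distance undefined for unequal lengths", call. = FALSE)
  sum(ra != rb)
}

#' Distance between two extended sequences
#'
#' The minimum Hamming distance over all cross pairs of members. Because the
#' four transforms form a group under which Hamming distance is invariant,
#' the minimum over the (up to) 16 member pairs equals the minimum over the
#' four transforms of one class against a fixed representative of the other;
#' the distance is 0 exactly when the classes intersect (i.e. are equal).
#'
#' @param W1,W2 `extended_seq` objects of equal width (or ACGT strings, which
#'   are extended first).
#' @return A non-negative integer.
#' @examples
#' extended_distance("AAAA", "TTTT")  # 0: TTTT is the complement of AAAA
#' @export
extended_distance <- function(W1, W2) {
  if (is.character(W1)) W1 <- build_extended(W1)
  if (is.character(W2)) W2 <- build_extended(W2)
  stopifnot(inherits(W1, "extended_seq"), inherits(W2, "extended_seq"))
  if (W1$width != W2$width)
    stop("extended sequences must have equal width", call. = FALSE)
  min(vapply(W1$members, hamming, integer(1), b = W2$canonical))
}

#' Pairwise extended-distance matrix
#'
#' Extended Hamming distances between every pair of equal-length DNA words
#' (each word standing for its extended class). The matrix underlying the
#' similarity graph whose maximal cliques are the shared motifs.
#'
#' @param keys character vector of equal-length ACGT words.
#' @return A symmetric integer matrix with zero diagonal.
#' @export
ext_dist_matrix <- function(keys) {
  keys <- as.character(keys)
  if (length(keys) && (any(!grepl("^[ACGT]+$", keys)) ||
                       length(unique(nchar(keys))) > 1L))
    stop("`keys` must be equal-length ACGT words", call. = FALSE)
  ext_dist_matrix_cpp(keys)
}

#' Number of length-l windows of a motif
#'
#' A motif of length `m` contains `max(0, m - l + 1)` overlapping windows of
#' length `l` (e.g. a 9-mer has two 8-mers and a 10-mer has three).
#'
#' @param motif_length integer vector of motif lengths.
#' @param l window length, >= 1.
#' @return Integer vector of window counts.
#' @export
window_count <- function(motif_length, l) {
  stopifnot(l >= 1L, all(motif_length >= 0L))
  pmax(0L, as.integer(motif_length) - as.integer(l) + 1L)
}
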
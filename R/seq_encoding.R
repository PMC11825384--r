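#' @keywords internal
DNA_BASES <- c("A", "C", "G", "T")

#' Functional-group categories on a base-pair edge
#'
#' The four chemical group types a Watson-Crick base pair can present to a
#' protein in the major or minor groove: hydrogen-bond acceptor, hydrogen-bond
#' donor, nonpolar hydrogen, and methyl group.
#'
#' @export
FUNCTIONAL_GROUPS <- c("ACCEPTOR", "DONOR", "NONPOLAR_H", "METHYL")

# Groove-edge chemistry of the two Watson-Crick pairs, read 5'->3' along the
# reference strand across the pair. A:T seen from the A side: major-groove
# edge N7(A) acceptor, N6(A) donor, O4(T) acceptor, C5-methyl(T); minor-groove
# edge N3(A) acceptor, C2-H(A) nonpolar, O2(T) acceptor. G:C from the G side:
# major N7(G) acceptor, O6(G) acceptor, N4(C) donor, C5-H(C) nonpolar; minor
# N3(G) acceptor, N2(G) donor, O2(C) acceptor. Reading the same pair from the
# complementary strand reverses the spatial order of the groups, which fixes
# T and C.
.MAJOR_GROUPS <- list(
  A = c("ACCEPTOR", "DONOR", "ACCEPTOR", "METHYL"),
  G = c("ACCEPTOR", "ACCEPTOR", "DONOR", "NONPOLAR_H")
)
.MAJOR_GROUPS$T <- rev(.MAJOR_GROUPS$A)
.MAJOR_GROUPS$C <- rev(.MAJOR_GROUPS$G)

.MINOR_GROUPS <- list(
  A = c("ACCEPTOR", "NONPOLAR_H", "ACCEPTOR"),
  G = c("ACCEPTOR", "DONOR", "ACCEPTOR")
)
.MINOR_GROUPS$T <- rev(.MINOR_GROUPS$A)
.MINOR_GROUPS$C <- rev(.MINOR_GROUPS$G)

.group_onehot <- function(groups) {
  as.vector(vapply(groups, function(g) as.integer(FUNCTIONAL_GROUPS == g),
                   integer(4L)))
}

#' Validate and normalise a DNA sequence
#'
#' Uppercases the input and checks that every symbol is one of A, C, G, T.
#' IUPAC ambiguity codes (including N) are rejected: the physicochemical
#' encoding and the k-mer predictor are defined only for the four canonical
#' bases.
#'
#' @param x a single character string.
#' @param what label used in error messages.
#' @return the validated, uppercased sequence string.
#' @export
#' @examples
#' as_dna("acgt")
as_dna <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single character string", call. = FALSE)
  s <- toupper(x)
  if (nchar(s) < 1L)
    stop(what, " must have length >= 1", call. = FALSE)
  bad <- setdiff(unique(strsplit(s, "", fixed = TRUE)[[1]]), DNA_BASES)
  if (length(bad))
    stop("invalid alphabet: ", what, " contains symbol(s) ",
         paste(sQuote(bad), collapse = ", "),
         "; only A, C, G, T are allowed", call. = FALSE)
  s
}

.seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

#' Reverse complement of a DNA sequence
#'
#' @param s a DNA sequence string (validated via [as_dna()]).
#' @return the reverse-complement sequence string.
#' @export
#' @examples
#' reverse_complement("AAAC")  # "GTTT"
reverse_complement <- function(s) {
  s <- as_dna(s)
  paste(rev(.seq_chars(chartr("ACGT", "TGCA", s))), collapse = "")
}

#' Physicochemical functional-group encoding of a base pair
#'
#' Encodes one base pair by the ordered functional groups it presents on its
#' major-groove edge (4 groups) and minor-groove edge (3 groups), each group
#' as a length-4 one-hot vector over [FUNCTIONAL_GROUPS]. The concatenated
#' major vector has 16 slots and the minor vector 12, for 28 binary slots in
#' total with exactly 7 set.
#'
#' The minor-groove group lists of A and T coincide, as do those of G and C:
#' the minor-groove edge cannot resolve the orientation of a base pair.
#'
#' @param base one of `"A"`, `"C"`, `"G"`, `"T"`.
#' @return a list with components `major_groups`, `minor_groups` (character
#'   vectors of group names), `major_vector` (16 binary slots),
#'   `minor_vector` (12 slots) and `vector` (their 28-slot concatenation).
#' @export
#' @examples
#' enc <- encode_base_pair("A")
#' enc$major_groups
#' sum(enc$vector)  # 7 groups set
encode_base_pair <- function(base) {
  if (!is.character(base) || length(base) != 1L)
    stop("base must be a single character", call. = FALSE)
  base <- toupper(base)
  if (!base %in% DNA_BASES)
    stop("invalid alphabet: unknown base ", sQuote(base), call. = FALSE)
  maj <- .MAJOR_GROUPS[[base]]
  mino <- .MINOR_GROUPS[[base]]
  major_vector <- .group_onehot(maj)
  minor_vector <- .group_onehot(mino)
  list(base = base,
       major_groups = maj,
       minor_groups = mino,
       major_vector = major_vector,
       minor_vector = minor_vector,
       vector = c(major_vector, minor_vector))
}

# 28-slot encodings stacked as a 4 x 28 matrix, and the induced 4 x 4 L1
# substitution-cost matrix, both computed once at load.
.ENCODING_MATRIX <- local({
  m <- t(vapply(DNA_BASES, function(b) encode_base_pair(b)$vector,
                integer(28L)))
  rownames(m) <- DNA_BASES
  m
})

.PHYSCHEM_COST <- local({
  cost <- matrix(0L, 4L, 4L, dimnames = list(DNA_BASES, DNA_BASES))
  for (a in DNA_BASES) for (b in DNA_BASES)
    cost[a, b] <- sum(abs(.ENCODING_MATRIX[a, ] - .ENCODING_MATRIX[b, ]))
  cost
})

.check_equal_length <- function(s1, s2) {
  if (nchar(s1) != nchar(s2))
    stop("shape mismatch: sequences have different lengths (",
         nchar(s1), " vs ", nchar(s2), ")", call. = FALSE)
}

#' Base-readout distance under the physicochemical encoding
#'
#' Sums, over all positions, the L1 difference between the 28-slot
#' functional-group vectors of the two base pairs. Unlike the one-hot
#' distance, the cost of a substitution depends on how much edge chemistry
#' the two pairs share: A<->C and G<->T cost 6, all other substitutions 8.
#'
#' @param s1,s2 equal-length DNA sequence strings.
#' @return a nonnegative number; 0 iff the sequences are identical.
#' @seealso [onehot_distance()], [levenshtein_distance()]
#' @export
#' @examples
#' physchem_distance("A", "C")  # 6
#' physchem_distance("A", "G")  # 8
physchem_distance <- function(s1, s2) {
  s1 <- as_dna(s1); s2 <- as_dna(s2)
  .check_equal_length(s1, s2)
  c1 <- .seq_chars(s1); c2 <- .seq_chars(s2)
  sum(.PHYSCHEM_COST[cbind(c1, c2)])
}

#' Base-readout distance under one-hot encoding
#'
#' L1 distance between position-wise length-4 base one-hots; equal to twice
#' the Hamming distance.
#'
#' @inheritParams physchem_distance
#' @return a nonnegative even integer.
#' @export
onehot_distance <- function(s1, s2) {
  s1 <- as_dna(s1); s2 <- as_dna(s2)
  .check_equal_length(s1, s2)
  2L * sum(.seq_chars(s1) != .seq_chars(s2))
}

#' Levenshtein edit distance between two DNA sequences
#'
#' Unit-cost insertion/deletion/substitution edit distance. Lengths may
#' differ; this is the one base metric defined for unequal lengths.
#'
#' @param s1,s2 DNA sequence strings.
#' @return a nonnegative integer.
#' @export
#' @examples
#' levenshtein_distance("ACGT", "AGT")  # 1
levenshtein_distance <- function(s1, s2) {
  s1 <- as_dna(s1); s2 <- as_dna(s2)
  as.integer(adist(s1, s2))
}
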
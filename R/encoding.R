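# Nucleotide state-set encoding.
#
# Reference profiles and reads are handled as bit-vector state sets: each of
# the four DNA bases owns one bit, so an IUPAC ambiguity code is the bitwise
# union of its constituent bases.  Bit order is fixed as A=1, C=2, G=4, T=8
# and is relied on by the 5-bit packing layer.

#' Bit values of the four DNA bases
#'
#' Fixed bit assignment used throughout the package: A=1, C=2, G=4, T=8.
#' An IUPAC ambiguity code is encoded as the bitwise OR of its bases;
#' `N` is the full set 15.
#'
#' @format Named integer vector of length 4.
#' @export
DNA_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L)

# IUPAC DNA codes as base sets (gap handled separately by callers).
# Note: some literature examples use M loosely; this table is the IUPAC
# standard (M = A or C, K = G or T).
.iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.iupac_codes <- vapply(.iupac_sets, function(b) sum(DNA_BITS[b]), integer(1))

# code -> IUPAC character, index = code 1..15
.code_to_char <- local({
  out <- character(15)
  for (nm in names(.iupac_codes)) {
    if (nm == "U") next
    out[.iupac_codes[[nm]]] <- nm
  }
  out
})

#' Encode one nucleotide character as a 4-bit state set
#'
#' @param c A single character: an IUPAC DNA code (case-insensitive), `N`,
#'   or `-` when `allow_gap = TRUE`.
#' @param allow_gap Should `-` be accepted?  Queries must not contain gaps;
#'   reference alignments map `-` to the full state set 15, with gap
#'   presence recorded separately (see [encode_sequence()]).
#' @return Integer state code in 1..15 (`-` maps to 15 when allowed).
#' @examples
#' encode_nucleotide("A")  # 1
#' encode_nucleotide("K")  # 12 (G or T)
#' encode_nucleotide("N")  # 15
#' @export
encode_nucleotide <- function(c, allow_gap = FALSE) {
  enc <- encode_sequence(c, allow_gap = allow_gap)
  enc$states[1L]
}

#' Encode a nucleotide string as state codes plus a gap track
#'
#' @param x A single character string over IUPAC DNA codes (plus `-` if
#'   `allow_gap`).  Lowercase is folded to uppercase.
#' @param allow_gap Accept `-`?  When accepted, a gap position gets state
#'   code 15 and `gap = TRUE` at that position.
#' @param what Label used in error messages (e.g. a sequence name).
#' @return List with integer vector `states` (codes 1..15) and logical
#'   vector `gap`, both of length `nchar(x)`.
#' @export
encode_sequence <- function(x, allow_gap = FALSE, what = "sequence") {
  stopifnot(is.character(x), length(x) == 1L)
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  codes <- .iupac_codes[chars]
  gap <- chars == "-"
  if (allow_gap) codes[gap] <- 15L
  bad <- which(is.na(codes))
  if (length(bad)) {
    stop(sprintf("invalid character '%s' at position %d in %s",
                 chars[bad[1]], bad[1], what), call. = FALSE)
  }
  list(states = unname(codes), gap = unname(gap))
}

#' Decode a 4-bit state code to its IUPAC character
#'
#' Inverse of [encode_nucleotide()] for the 15 non-empty state sets.
#'
#' @param code Integer vector of codes in 1..15.
#' @return Character vector of IUPAC codes.
#' @export
decode_state <- function(code) {
  stopifnot(all(code >= 1L & code <= 15L))
  .code_to_char[code]
}

#' Scoring parameters of the site-calibrated alignment recurrence
#'
#' The recurrence scores a read (query) against a per-edge ancestral state
#' profile.  At a site whose CGAP flag is set, the gap open/extend pair is
#' replaced by `gap_open_extend_cgap` and `cgap_penalty` is added to the
#' diagonal move; this calibrates the scoring to the indel structure of the
#' reference.  Defaults are the published constants: mismatch 3, CGAP
#' penalty 3, (gap open+extend, extend) = (4, 1) at ordinary sites and
#' (0, 0) at CGAP sites, insertion cost 3.  Lower scores are better.
#'
#' @param mismatch Cost of a diagonal move whose state sets do not
#'   intersect.
#' @param cgap_penalty Cost added to every diagonal move at a CGAP site.
#' @param gap_open_extend Integer pair `(GPOE, GPE)`: cost of the first
#'   reference-gap step in a run, and of each further step, at an ordinary
#'   site.
#' @param gap_open_extend_cgap Same pair used at CGAP sites.
#' @param insertion_cost Cost of consuming one query character without
#'   advancing in the reference (linear, non-affine).
#' @return Object of class `papara_params`.
#' @export
scoring_params <- function(mismatch = 3L, cgap_penalty = 3L,
                           gap_open_extend = c(4L, 1L),
                           gap_open_extend_cgap = c(0L, 0L),
                           insertion_cost = 3L) {
  p <- list(mismatch = as.integer(mismatch),
            cgap_penalty = as.integer(cgap_penalty),
            gap_open_extend = as.integer(gap_open_extend),
            gap_open_extend_cgap = as.integer(gap_open_extend_cgap),
            insertion_cost = as.integer(insertion_cost))
  if (length(p$gap_open_extend) != 2L || length(p$gap_open_extend_cgap) != 2L)
    stop("gap penalties must be integer pairs (open+extend, extend)")
  if (any(unlist(p) < 0L)) stop("all penalties must be non-negative")
  structure(p, class = "papara_params")
}

#' Construct a parsimony state vector by hand
#'
#' Mostly useful for tests and examples; pipelines obtain state vectors
#' from [all_edge_state_vectors()].
#'
#' @param states Integer vector of state codes in 1..15.
#' @param cgap Logical vector of per-site CGAP flags (default all FALSE).
#' @param edge_id Integer edge identifier (optional).
#' @return Object of class `papara_profile` with fields `edge_id`,
#'   `states`, `cgap`.
#' @export
parsimony_state_vector <- function(states, cgap = NULL, edge_id = NA_integer_) {
  states <- as.integer(states)
  if (length(states) < 1L) stop("empty state vector")
  if (any(states < 1L | states > 15L)) stop("state codes must be in 1..15")
  if (is.null(cgap)) cgap <- rep(FALSE, length(states))
  cgap <- as.logical(cgap)
  if (length(cgap) != length(states)) stop("cgap length must equal states length")
  structure(list(edge_id = as.integer(edge_id), states = states, cgap = cgap),
            class = "papara_profile")
}

#' State vector from a plain DNA string
#'
#' Convenience wrapper: encodes a gap-free IUPAC string as a
#' `papara_profile` with all CGAP flags clear.
#'
#' @param x Character string.
#' @param cgap Optional logical CGAP track.
#' @return A `papara_profile`.
#' @export
state_vector_from_seq <- function(x, cgap = NULL) {
  enc <- encode_sequence(x, allow_gap = FALSE)
  parsimony_state_vector(enc$states, cgap = cgap)
}
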
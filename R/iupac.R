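## IUPAC nucleotide semantics.
##
## Each of the 15 ambiguity codes denotes a nonempty subset of {A,C,G,T},
## encoded here as a 4-bit mask (A=1, C=2, G=4, T=8). All degenerate
## primer/site matching in the package reduces to bit tests on these masks.

IUPAC_CODES <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  M = 3L, R = 5L, W = 9L, S = 6L, Y = 10L, K = 12L,
  V = 7L, H = 11L, D = 13L, B = 14L, N = 15L
)

# ASCII-indexed lookup, 0 for any non-IUPAC byte
.IUPAC_BITS <- local({
  v <- integer(127)
  v[utf8ToInt(paste(names(IUPAC_CODES), collapse = ""))] <- unname(IUPAC_CODES)
  v
})

#' Convert an IUPAC string to per-position base-set bitmasks
#' @return integer vector, one 4-bit mask per residue
#' @noRd
iupacBits <- function(x) {
  ints <- utf8ToInt(x)
  if (any(ints > 127L)) return(rep(0L, length(ints)))  # force validation failure
  .IUPAC_BITS[ints]
}

#' Normalize residues to canonical IUPAC form
#'
#' Case-folds to upper case and converts RNA `U` to `T`. Does not validate;
#' see [assertIupac()].
#' @param x character vector of sequences.
#' @return character vector, same length.
#' @keywords internal
normalizeResidues <- function(x) {
  chartr("U", "T", toupper(x))
}

#' Validate an IUPAC sequence, reporting the first offending position
#' @noRd
assertIupac <- function(x, id = "sequence") {
  bits <- iupacBits(x)
  bad <- which(bits == 0L)
  if (length(bad)) {
    rflpStop(
      "AlphabetError",
      sprintf("non-IUPAC character '%s' in record \"%s\" at position %d",
              substr(x, bad[1L], bad[1L]), id, bad[1L]),
      record = id, position = bad[1L]
    )
  }
  invisible(bits)
}

#' Match degenerate IUPAC symbols
#'
#' Compares IUPAC nucleotide symbols under the two matching semantics used
#' throughout the package. In \code{strict} mode a template symbol matches a
#' pattern symbol only when the template's base set is a subset of the
#' pattern's, i.e. every base the template could represent is accepted by the
#' pattern -- the match is guaranteed whatever the true underlying base. In
#' \code{permissive} mode the two base sets merely have to intersect.
#'
#' Strict matching is the default for primer binding and restriction-site
#' recognition because it makes in-silico digests reproducible: an ambiguous
#' template base must guarantee the site before a cut is called.
#'
#' @param pattern,template character vectors of single IUPAC symbols, or two
#'   equal-length IUPAC strings compared position by position.
#' @param mode `"strict"` (subset) or `"permissive"` (intersection).
#' @return logical vector of per-position match results.
#' @examples
#' iupacMatch("R", "A")                      # TRUE: {A} within {A,G}
#' iupacMatch("R", "N")                      # FALSE: N not guaranteed
#' iupacMatch("R", "N", mode = "permissive") # TRUE: sets intersect
#' @export
iupacMatch <- function(pattern, template, mode = c("strict", "permissive")) {
  mode <- match.arg(mode)
  if (length(pattern) == 1L && length(template) == 1L &&
      nchar(pattern) == nchar(template) && nchar(pattern) > 1L) {
    p <- assertIupac(pattern, "pattern")
    t <- assertIupac(template, "template")
  } else {
    if (length(pattern) != length(template))
      pattern <- rep_len(pattern, length(template))
    p <- vapply(pattern, function(s) assertIupac(s, "pattern")[1L], integer(1L))
    t <- vapply(template, function(s) assertIupac(s, "template")[1L], integer(1L))
  }
  if (mode == "strict") bitwAnd(t, bitwNot(p) %% 16L) == 0L
  else bitwAnd(t, p) != 0L
}

#' Reverse complement of an IUPAC sequence
#'
#' Ambiguity codes are complemented by complementing their base sets
#' (R to Y, S to S, W to W, K to M, B to V, D to H, N to N), so
#' \code{revComp} is an involution on valid IUPAC text.
#'
#' @param x character vector of IUPAC DNA sequences (case-insensitive;
#'   `U` is normalized to `T`).
#' @return character vector of reverse complements, upper case.
#' @examples
#' revComp("ACGT")  # "ACGT"
#' revComp("RGA")   # "TCY"
#' @export
revComp <- function(x) {
  x <- normalizeResidues(x)
  vapply(x, function(s) {
    assertIupac(s, "sequence")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1L), USE.NAMES = FALSE)
}

#' Count mismatches of a degenerate pattern at every offset of a template
#'
#' Workhorse for primer and site scanning. Both arguments are bitmask
#' vectors from [iupacBits()].
#'
#' @param tb template bitmasks; @param pb pattern bitmasks.
#' @param mode strict (subset) or permissive (intersection) per-position test.
#' @return integer vector of mismatch counts, one per 1-based start offset
#'   (length `length(tb) - length(pb) + 1`), or `integer(0)` if the pattern
#'   is longer than the template.
#' @noRd
mismatchProfile <- function(tb, pb, mode = "strict") {
  n <- length(tb); k <- length(pb)
  if (k > n) return(integer(0))
  mm <- integer(n - k + 1L)
  for (j in seq_len(k)) {
    seg <- tb[j:(n - k + j)]
    bad <- if (mode == "strict") bitwAnd(seg, bitwNot(pb[j]) %% 16L) != 0L
           else bitwAnd(seg, pb[j]) == 0L
    mm <- mm + as.integer(bad)
  }
  mm
}
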
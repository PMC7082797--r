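#' Map restriction cut positions on a linear sequence
#'
#' Finds every occurrence of an enzyme's recognition site on the top strand
#' and of its reverse complement (relevant for non-palindromic sites) and
#' returns the resulting cut coordinates under the blunt single-cut model: a
#' top-strand occurrence starting at 0-based `i` cuts at `i + cutOffset`; a
#' bottom-strand occurrence cuts at `i + length(site) - cutOffset`.
#' Overlapping occurrences all count; duplicate cut coordinates (e.g. from
#' palindromic sites found on both strands) are collapsed.
#'
#' In `strict` mode an ambiguous template base must guarantee the site
#' (base set contained in the site symbol's set) for a cut to be called, so
#' digests are reproducible; `permissive` mode calls a cut whenever the
#' base sets intersect and is meant for exploratory screening.
#'
#' @param seq IUPAC text of a linear molecule (or `DNAString`).
#' @param enzyme a [RestrictionEnzyme-class].
#' @param mode `"strict"` or `"permissive"`.
#' @return sorted integer vector of 0-based cut coordinates.
#' @examples
#' draI <- restrictionEnzyme("DraI", "TTTAAA", 3)
#' findSites(paste0(strrep("G", 8), "TTTAAA", strrep("C", 8)), draI)  # 11
#' @export
findSites <- function(seq, enzyme, mode = c("strict", "permissive")) {
  mode <- match.arg(mode)
  stopifnot(is(enzyme, "RestrictionEnzyme"))
  if (is(seq, "DNAString")) seq <- as.character(seq)
  s <- normalizeResidues(seq)
  assertIupac(s, "sequence")
  site <- enzyme@site
  m <- nchar(site)
  off <- enzyme@cutOffset
  tb <- iupacBits(s)
  cuts <- integer()
  topHits <- which(mismatchProfile(tb, iupacBits(site), mode) == 0L) - 1L
  cuts <- c(cuts, topHits + off)
  rcSite <- revComp(site)
  if (!identical(rcSite, site)) {
    botHits <- which(mismatchProfile(tb, iupacBits(rcSite), mode) == 0L) - 1L
    cuts <- c(cuts, botHits + m - off)
  }
  # cuts at the very ends of the molecule produce no new fragment boundary
  cuts <- cuts[cuts > 0L & cuts < nchar(s)]
  sort(unique(cuts))
}

#' Digest a linear molecule into a fragment-length multiset
#'
#' Applies [findSites()] and converts the cut coordinates into fragment
#' lengths (consecutive differences of `0`, the cuts, and the molecule
#' length). Fragment lengths always sum to the molecule length. PCR
#' products are linear, so only linear digestion is modeled.
#'
#' @param x the molecule: an [Amplicon-class], IUPAC string, `DNAString`,
#'   or a single-record slice of a `DNAStringSet`.
#' @param enzyme a [RestrictionEnzyme-class].
#' @param mode site-matching mode, see [findSites()].
#' @param id identifier recorded in the result (defaults to the input's
#'   own id when it has one).
#' @return a [DigestResult-class]; fragments are sorted descending.
#' @examples
#' draI <- restrictionEnzyme("DraI", "TTTAAA", 3)
#' fragments(digestLinear(paste0(strrep("G", 8), "TTTAAA", strrep("C", 8)),
#'                        draI))  # 11, 11
#' @export
digestLinear <- function(x, enzyme, mode = c("strict", "permissive"),
                         id = NULL) {
  mode <- match.arg(mode)
  if (is(x, "Amplicon")) {
    if (is.null(id)) id <- x@sourceId
    x <- x@residues
  } else if (is(x, "DNAStringSet")) {
    if (length(x) != 1L) rflpStop("BadArgument", "supply a single sequence")
    if (is.null(id)) id <- names(x)[1L]
    x <- as.character(x)[1L]
  } else if (is(x, "DNAString")) {
    x <- as.character(x)
  }
  if (is.null(id)) id <- "seq"
  s <- normalizeResidues(x)
  if (!nzchar(s)) rflpStop("EmptyInput", "cannot digest an empty sequence")
  cuts <- findSites(s, enzyme, mode)
  frags <- diff(c(0L, cuts, nchar(s)))
  new("DigestResult", ampliconId = as.character(id), enzyme = enzyme@name,
      fragments = sort(as.integer(frags), decreasing = TRUE),
      cutPositions = as.integer(cuts))
}

#' Load a restriction-enzyme table
#'
#' Reads a tab-separated enzyme table (`name<TAB>site<TAB>cut_offset`) into
#' [RestrictionEnzyme-class] objects. With no argument, loads the bundled
#' library: DraI and AluI (the two assay enzymes) plus a subset of common
#' commercially available enzymes used by [screenEnzymes()] as the default
#' candidate pool.
#'
#' @param file optional path to a user enzyme table.
#' @return named list of [RestrictionEnzyme-class] objects.
#' @examples
#' enz <- loadEnzymes()
#' enz$DraI
#' @export
loadEnzymes <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "enzymes.tsv", package = "rflpkit",
                        mustWork = TRUE)
  tab <- utils::read.table(file, sep = "\t", header = TRUE,
                           colClasses = c("character", "character", "integer"),
                           quote = "", comment.char = "#")
  out <- lapply(seq_len(nrow(tab)), function(i)
    restrictionEnzyme(tab$name[i], tab$site[i], tab$cut_offset[i]))
  names(out) <- tab$name
  out
}
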
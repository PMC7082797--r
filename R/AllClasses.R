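#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<-
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' Primer class
#'
#' A degenerate oligonucleotide written 5' to 3'. Assay primers are expected
#' to be at least 10 nt; shorter probe sequences can still be scanned with
#' [findPrimerMatches()] by passing plain character strings.
#'
#' @slot name primer name.
#' @slot residues IUPAC residues, 5' to 3'.
#' @exportClass Primer
setClass("Primer", representation(name = "character", residues = "character"))

setValidity("Primer", function(object) {
  if (length(object@residues) != 1L || !nzchar(object@residues))
    return("residues must be a single nonempty string")
  bits <- iupacBits(object@residues)
  if (any(bits == 0L)) return("residues contain non-IUPAC characters")
  if (nchar(object@residues) < 10L)
    return("assay primers must be at least 10 nt")
  TRUE
})

#' Construct a Primer
#' @param name primer name.
#' @param residues IUPAC residues, 5' to 3' (case-insensitive, U normalized).
#' @return a [Primer-class] object.
#' @examples
#' primer("16S-Forward", "TTAAATTGCTGTRGTATT")
#' @export
primer <- function(name, residues) {
  new("Primer", name = as.character(name),
      residues = normalizeResidues(residues))
}

#' PrimerPair class
#'
#' @slot forward,reverse [Primer-class] objects (both written 5' to 3').
#' @slot expectedLength expected amplicon length in bp, or `NA` if unknown.
#' @exportClass PrimerPair
setClass("PrimerPair", representation(
  forward = "Primer", reverse = "Primer", expectedLength = "integer"
))

setValidity("PrimerPair", function(object) {
  el <- object@expectedLength
  if (length(el) != 1L) return("expectedLength must be length 1")
  if (!is.na(el) &&
      el <= nchar(object@forward@residues) + nchar(object@reverse@residues))
    return("expectedLength must exceed the combined primer lengths")
  TRUE
})

#' Construct a PrimerPair
#' @param forward,reverse [Primer-class] objects or IUPAC strings.
#' @param expectedLength expected amplicon length (bp), optional.
#' @export
primerPair <- function(forward, reverse, expectedLength = NA_integer_) {
  if (is.character(forward)) forward <- primer("forward", forward)
  if (is.character(reverse)) reverse <- primer("reverse", reverse)
  new("PrimerPair", forward = forward, reverse = reverse,
      expectedLength = as.integer(expectedLength))
}

#' Amplicon class
#'
#' A PCR product extracted in silico from a template. Coordinates are
#' 0-based half-open on the plus strand of the template; for origin-spanning
#' products on circular templates `end` exceeds the template length and is
#' interpreted modulo the length.
#'
#' @slot sourceId template identifier.
#' @slot start,end 0-based half-open plus-strand coordinates.
#' @slot residues amplicon residues (including both primer-binding regions
#'   unless primers were trimmed).
#' @slot species,region optional labels propagated from the template.
#' @exportClass Amplicon
setClass("Amplicon", representation(
  sourceId = "character", start = "integer", end = "integer",
  residues = "character", species = "character", region = "character"
))

setValidity("Amplicon", function(object) {
  if (nchar(object@residues) != object@end - object@start)
    return("residue length must equal end - start")
  TRUE
})

#' RestrictionEnzyme class
#'
#' Blunt/palindromic model of a type II restriction enzyme: a recognition
#' site and a single top-strand cut offset. Overhang geometry is ignored
#' because only fragment lengths are observable on agarose gels.
#'
#' @slot name enzyme name, e.g. `"DraI"`.
#' @slot site IUPAC recognition site, e.g. `"TTTAAA"`.
#' @slot cutOffset cut position counted from the site's 5' end on the top
#'   strand (`DraI` TTT^AAA has offset 3; `AluI` AG^CT has offset 2).
#' @exportClass RestrictionEnzyme
setClass("RestrictionEnzyme", representation(
  name = "character", site = "character", cutOffset = "integer"
))

setValidity("RestrictionEnzyme", function(object) {
  if (!nzchar(object@site) || any(iupacBits(object@site) == 0L))
    return("site must be nonempty IUPAC text")
  if (object@cutOffset < 0L || object@cutOffset > nchar(object@site))
    return("cutOffset must lie within the recognition site")
  TRUE
})

#' Construct a RestrictionEnzyme
#' @param name enzyme name.
#' @param site IUPAC recognition site.
#' @param cutOffset top-strand cut offset from the site's 5' end.
#' @examples
#' restrictionEnzyme("DraI", "TTTAAA", 3)
#' @export
restrictionEnzyme <- function(name, site, cutOffset) {
  new("RestrictionEnzyme", name = as.character(name),
      site = normalizeResidues(site), cutOffset = as.integer(cutOffset))
}

#' DigestResult class
#'
#' Outcome of digesting one linear amplicon with one enzyme.
#'
#' @slot ampliconId identifier of the digested molecule.
#' @slot enzyme enzyme name.
#' @slot fragments fragment lengths in bp, sorted descending.
#' @slot cutPositions 0-based cut coordinates, sorted ascending.
#' @exportClass DigestResult
setClass("DigestResult", representation(
  ampliconId = "character", enzyme = "character",
  fragments = "integer", cutPositions = "integer"
))

setValidity("DigestResult", function(object) {
  if (length(object@fragments) != length(object@cutPositions) + 1L)
    return("fragment count must be cut count + 1")
  if (is.unsorted(rev(object@fragments)))
    return("fragments must be sorted descending")
  TRUE
})

#' GelModel class
#'
#' Resolution model of an agarose gel. Fragments shorter than `minVisible`
#' are not scored; fragments closer than `coMigrationTol` co-migrate and are
#' read as a single band. Defaults emulate a 4% agarose gel run for small
#' fragment separation.
#'
#' @slot minVisible smallest visible fragment (bp).
#' @slot coMigrationTol co-migration tolerance (bp).
#' @slot percentAgarose gel concentration, metadata only.
#' @exportClass GelModel
setClass("GelModel", representation(
  minVisible = "integer", coMigrationTol = "integer", percentAgarose = "numeric"
))

setValidity("GelModel", function(object) {
  if (object@minVisible < 1L) return("minVisible must be >= 1")
  if (object@coMigrationTol < 0L) return("coMigrationTol must be >= 0")
  TRUE
})

#' Construct a GelModel
#' @param minVisible smallest visible fragment in bp.
#' @param coMigrationTol bands differing by at most this many bp co-migrate.
#' @param percentAgarose gel concentration (metadata).
#' @export
gelModel <- function(minVisible = 40L, coMigrationTol = 5L, percentAgarose = 4) {
  new("GelModel", minVisible = as.integer(minVisible),
      coMigrationTol = as.integer(coMigrationTol),
      percentAgarose = as.numeric(percentAgarose))
}

#' RflpPattern class
#'
#' A gel-visible band pattern: the unit that is compared, grouped into
#' per-species catalogs and classified by dichotomous keys.
#'
#' @slot bands visible band sizes in bp, sorted descending.
#' @slot sourceIds identifiers of the member sequences.
#' @slot species species label (`NA` if unknown).
#' @slot enzyme,region digestion enzyme and marker region the pattern came
#'   from; used to refuse comparisons across assays.
#' @exportClass RflpPattern
setClass("RflpPattern", representation(
  bands = "integer", sourceIds = "character",
  species = "character", enzyme = "character", region = "character"
))

setValidity("RflpPattern", function(object) {
  if (is.unsorted(rev(object@bands))) return("bands must be sorted descending")
  if (length(object@bands) && any(object@bands < 1L))
    return("bands must be positive")
  TRUE
})

#' Construct an RflpPattern
#' @param bands band sizes in bp (sorted internally).
#' @param species,enzyme,region optional labels.
#' @param sourceIds identifiers of member sequences.
#' @export
rflpPattern <- function(bands, species = NA_character_, enzyme = NA_character_,
                        region = NA_character_, sourceIds = character()) {
  new("RflpPattern", bands = sort(as.integer(bands), decreasing = TRUE),
      sourceIds = as.character(sourceIds), species = as.character(species),
      enzyme = as.character(enzyme), region = as.character(region))
}

#' PatternCatalog class
#'
#' Distinct band patterns per species under a fixed gel model, built by
#' leader clustering in input order (tolerance-based band equality is not
#' transitive, so the catalog depends on input order; file order is used and
#' recorded, making results reproducible).
#'
#' @slot patterns list of [RflpPattern-class], grouped by species in first
#'   appearance order.
#' @slot gel the [GelModel-class] the patterns were read under.
#' @slot enzyme,region assay labels.
#' @exportClass PatternCatalog
setClass("PatternCatalog", representation(
  patterns = "list", gel = "GelModel", enzyme = "character", region = "character"
))

setValidity("PatternCatalog", function(object) {
  if (!all(vapply(object@patterns, is, logical(1L), "RflpPattern")))
    return("patterns must all be RflpPattern objects")
  TRUE
})

#' KeyFeature class
#'
#' One testable statement about a band pattern, the building block of key
#' couplet leads. Kinds:
#' \describe{
#'   \item{band_count_gt / band_count_le / band_count_eq}{number of visible
#'     bands compared with `threshold`.}
#'   \item{nth_band_gt / nth_band_lt / nth_band_le}{size of the band at
#'     `rank` (1 = largest) compared with `threshold` bp.}
#'   \item{nth_band_near}{band at `rank` within `tol` bp of `threshold`
#'     ("middle band approximately 175 bp").}
#'   \item{has_band_near / no_band_near}{presence/absence of any band within
#'     `tol` bp of `threshold`.}
#' }
#' A pattern lacking a band at `rank` fails `nth_band_gt`, `nth_band_lt`
#' and `nth_band_near`; the complementary `nth_band_le` holds vacuously, so
#' the two leads of a generated couplet stay exhaustive.
#'
#' @slot kind one of the kinds above.
#' @slot rank band rank (1 = largest); 0 for count and any-band kinds.
#' @slot threshold count or bp threshold.
#' @slot tol tolerance in bp for the `near` kinds.
#' @exportClass KeyFeature
setClass("KeyFeature", representation(
  kind = "character", rank = "integer", threshold = "integer", tol = "integer"
))

.KEY_FEATURE_KINDS <- c(
  "band_count_gt", "band_count_le", "band_count_eq",
  "nth_band_gt", "nth_band_lt", "nth_band_le",
  "nth_band_near", "has_band_near", "no_band_near"
)

setValidity("KeyFeature", function(object) {
  if (!object@kind %in% .KEY_FEATURE_KINDS) return("unknown feature kind")
  if (object@threshold <= 0L) return("threshold must be positive")
  if (object@rank < 0L) return("rank must be >= 0")
  TRUE
})

keyFeature <- function(kind, threshold, rank = 0L, tol = 0L) {
  new("KeyFeature", kind = kind, rank = as.integer(rank),
      threshold = as.integer(threshold), tol = as.integer(tol))
}

#' KeyCouplet class
#'
#' A numbered pair of mutually exclusive leads. Each lead is a
#' [KeyFeature-class] plus a consequent: either another couplet number or a
#' species name.
#'
#' @slot number couplet number (1-based).
#' @slot backRef number of the couplet this one is reached from (`NA` for
#'   the first couplet); printed as \code{2(1)}.
#' @slot featureA,featureB the two leads' features.
#' @slot consequentA,consequentB species name, or a couplet number encoded
#'   as its decimal string.
#' @slot toCoupletA,toCoupletB `TRUE` when the consequent is a couplet
#'   reference.
#' @exportClass KeyCouplet
setClass("KeyCouplet", representation(
  number = "integer", backRef = "integer",
  featureA = "KeyFeature", featureB = "KeyFeature",
  consequentA = "character", consequentB = "character",
  toCoupletA = "logical", toCoupletB = "logical"
))

#' DichotomousKey class
#'
#' An ordered set of couplets classifying a band pattern to a species or to
#' "undetermined". Built by [buildKey()], parsed by [parseKey()], applied
#' with [applyKey()].
#'
#' @slot couplets list of [KeyCouplet-class], numbered 1..n.
#' @slot enzyme,region assay the key is valid for.
#' @slot gel gel model (its `coMigrationTol` interprets "approximately").
#' @exportClass DichotomousKey
setClass("DichotomousKey", representation(
  couplets = "list", enzyme = "character", region = "character", gel = "GelModel"
))

setValidity("DichotomousKey", function(object) {
  if (!length(object@couplets)) return("a key needs at least one couplet")
  nums <- vapply(object@couplets, function(co) co@number, integer(1L))
  if (!identical(nums, seq_along(object@couplets)))
    return("couplets must be numbered 1..n in order")
  # every couplet reference must exist and every path must terminate
  n <- length(nums)
  targets <- lapply(object@couplets, function(co) {
    refs <- integer()
    if (co@toCoupletA) refs <- c(refs, as.integer(co@consequentA))
    if (co@toCoupletB) refs <- c(refs, as.integer(co@consequentB))
    refs
  })
  if (any(unlist(targets) > n | unlist(targets) < 1L))
    return("couplet reference out of range")
  state <- integer(n)  # 0 unvisited, 1 on stack, 2 done
  visit <- function(i) {
    if (state[i] == 1L) return(FALSE)
    if (state[i] == 2L) return(TRUE)
    state[i] <<- 1L
    for (j in targets[[i]]) if (!visit(j)) return(FALSE)
    state[i] <<- 2L
    TRUE
  }
  if (!visit(1L)) return("key contains a cycle")
  TRUE
})

#' SyntheticConfig class
#'
#' Ground-truth recipe for the amplicon simulator: per-species fragment
#' patterns to plant, how many sequences to emit, and how much intra-species
#' variation to inject.
#'
#' @slot plantedPatterns named list (one element per species) of lists of
#'   integer fragment-length vectors, each summing to `ampliconLength`.
#' @slot seqsPerSpecies sequences emitted per species (distributed
#'   round-robin over that species' planted patterns).
#' @slot ampliconLength amplicon length in bp.
#' @slot substitutionRate per-site substitution probability outside
#'   protected windows (primer-binding regions and planted sites).
#' @slot maxMutations if non-`NA`, overrides `substitutionRate`: each
#'   sequence receives k substitutions, k drawn uniformly from 0..maxMutations.
#' @slot indelRate per-site indel probability outside protected windows.
#' @slot sharedBackground if `TRUE`, all species share one random background
#'   and differ only at their planted recognition sites.
#' @slot seed RNG seed making the dataset reproducible.
#' @exportClass SyntheticConfig
setClass("SyntheticConfig", representation(
  plantedPatterns = "list", seqsPerSpecies = "integer",
  ampliconLength = "integer", substitutionRate = "numeric",
  maxMutations = "integer", indelRate = "numeric",
  sharedBackground = "logical", seed = "integer"
))

setValidity("SyntheticConfig", function(object) {
  if (!length(object@plantedPatterns))
    return("at least one species is required")
  if (is.null(names(object@plantedPatterns)) ||
      any(!nzchar(names(object@plantedPatterns))))
    return("plantedPatterns must be a named list (names = species)")
  for (sp in names(object@plantedPatterns)) {
    pats <- object@plantedPatterns[[sp]]
    if (!length(pats)) return(sprintf("species '%s' has no planted pattern", sp))
    for (fr in pats) {
      if (any(fr < 1L)) return("planted fragments must be >= 1 bp")
      if (sum(fr) != object@ampliconLength)
        return(sprintf("planted fragments for '%s' must sum to ampliconLength", sp))
    }
  }
  if (object@substitutionRate < 0 || object@substitutionRate >= 1)
    return("substitutionRate must be in [0, 1)")
  if (object@indelRate < 0 || object@indelRate >= 1)
    return("indelRate must be in [0, 1)")
  if (object@seqsPerSpecies < 1L) return("seqsPerSpecies must be >= 1")
  TRUE
})
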
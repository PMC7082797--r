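#' Accessors
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x an rflpkit object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("bands", function(x) standardGeneric("bands"))

#' @rdname accessors
#' @export
setMethod("bands", "RflpPattern", function(x) x@bands)

#' @rdname accessors
#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))

#' @rdname accessors
#' @export
setMethod("fragments", "DigestResult", function(x) x@fragments)

#' @rdname accessors
#' @export
setGeneric("cutPositions", function(x) standardGeneric("cutPositions"))

#' @rdname accessors
#' @export
setMethod("cutPositions", "DigestResult", function(x) x@cutPositions)

#' @rdname accessors
#' @export
setGeneric("speciesLabel", function(x) standardGeneric("speciesLabel"))

#' @rdname accessors
#' @export
setMethod("speciesLabel", "RflpPattern", function(x) x@species)

#' @rdname accessors
#' @export
setMethod("speciesLabel", "Amplicon", function(x) x@species)

#' @rdname accessors
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))

#' @rdname accessors
#' @export
setMethod("residues", "Amplicon", function(x) x@residues)

#' @rdname accessors
#' @export
setMethod("residues", "Primer", function(x) x@residues)

#' @rdname accessors
#' @export
setGeneric("patterns", function(x) standardGeneric("patterns"))

#' @rdname accessors
#' @export
setMethod("patterns", "PatternCatalog", function(x) x@patterns)

#' @rdname accessors
#' @export
setGeneric("couplets", function(x) standardGeneric("couplets"))

#' @rdname accessors
#' @export
setMethod("couplets", "DichotomousKey", function(x) x@couplets)

#' Pattern counts per species
#'
#' Number of distinct cataloged band patterns for each species, the quantity
#' tabulated when summarizing intra-species RFLP variation.
#'
#' @param x a [PatternCatalog-class].
#' @return named integer vector, one entry per species in first-appearance
#'   order.
#' @export
setGeneric("patternCounts", function(x) standardGeneric("patternCounts"))

#' @rdname patternCounts
#' @export
setMethod("patternCounts", "PatternCatalog", function(x) {
  sp <- vapply(x@patterns, function(p) p@species, character(1L))
  cnt <- table(factor(sp, levels = unique(sp)))
  stats::setNames(as.integer(cnt), names(cnt))
})

## show methods ---------------------------------------------------------

setMethod("show", "Primer", function(object) {
  cat(sprintf("Primer %s: 5'-%s-3' (%d nt)\n",
              object@name, object@residues, nchar(object@residues)))
})

setMethod("show", "PrimerPair", function(object) {
  cat(sprintf("PrimerPair %s / %s (expected product: %s bp)\n",
              object@forward@name, object@reverse@name,
              ifelse(is.na(object@expectedLength), "?", object@expectedLength)))
})

setMethod("show", "Amplicon", function(object) {
  cat(sprintf("Amplicon from %s [%d, %d) %d bp%s\n",
              object@sourceId, object@start, object@end,
              nchar(object@residues),
              ifelse(is.na(object@species), "",
                     paste0(" species=", object@species))))
})

setMethod("show", "RestrictionEnzyme", function(object) {
  cat(sprintf("RestrictionEnzyme %s: 5'-%s^%s-3'\n", object@name,
              substr(object@site, 1L, object@cutOffset),
              substr(object@site, object@cutOffset + 1L, nchar(object@site))))
})

setMethod("show", "DigestResult", function(object) {
  cat(sprintf("DigestResult %s x %s: fragments [%s]\n",
              object@ampliconId, object@enzyme,
              paste(object@fragments, collapse = ", ")))
})

setMethod("show", "GelModel", function(object) {
  cat(sprintf("GelModel: %g%% agarose, min visible %d bp, co-migration tol %d bp\n",
              object@percentAgarose, object@minVisible, object@coMigrationTol))
})

setMethod("show", "RflpPattern", function(object) {
  cat(sprintf("RflpPattern%s [%s] (%s, %s; n=%d)\n",
              ifelse(is.na(object@species), "", paste0(" ", object@species)),
              paste(object@bands, collapse = ", "),
              object@enzyme, object@region, length(object@sourceIds)))
})

setMethod("show", "PatternCatalog", function(object) {
  cnt <- patternCounts(object)
  cat(sprintf("PatternCatalog (%s, %s): %d patterns across %d species\n",
              object@enzyme, object@region, length(object@patterns),
              length(cnt)))
  for (sp in names(cnt)) cat(sprintf("  %s: %d pattern(s)\n", sp, cnt[[sp]]))
})

setMethod("show", "DichotomousKey", function(object) {
  cat(sprintf("DichotomousKey (%s digestion of %s, tol %d bp): %d couplets\n",
              object@enzyme, object@region, object@gel@coMigrationTol,
              length(object@couplets)))
  cat(formatKey(object, style = "pretty"), sep = "\n")
})

setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf(
    "SyntheticConfig: %d species x %d seqs, %d bp amplicons, seed %d\n",
    length(object@plantedPatterns), object@seqsPerSpecies,
    object@ampliconLength, object@seed))
})
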
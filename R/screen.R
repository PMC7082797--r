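#' Rank restriction enzymes by species-discriminating power
#'
#' Formalizes the assay-design step of screening commercially available
#' enzymes for candidates: for each enzyme the labeled amplicons are
#' digested and cataloged with [groupPatterns()], and a species pair counts
#' as \emph{separated} when no cataloged pattern of one species equals any
#' pattern of the other under the gel model. The score is the fraction of
#' species pairs separated. Enzymes producing several patterns within one
#' species are penalized as a secondary criterion only -- intra-species
#' pattern multiplicity is tolerable in an assay, just undesirable.
#'
#' Ranking order: score descending, then intra-species splits ascending,
#' then fewest total cuts (cheaper, simpler gels), then name. With a
#' `target` species the result also reports whether the enzyme separates
#' the target from every other species, the usual design goal when one
#' invasive species must be told apart from natives.
#'
#' @param seqs labeled amplicons as accepted by [groupPatterns()].
#' @param library list of [RestrictionEnzyme-class] (e.g. [loadEnzymes()]).
#' @param gel a [GelModel-class].
#' @param target optional species name of primary interest.
#' @param mode site-matching mode passed to the digester.
#' @return data.frame sorted by rank with columns `enzyme`, `score`,
#'   `pairs_separated`, `pairs_total`, `intra_species_splits`, `total_cuts`,
#'   `discriminates_target`.
#' @export
screenEnzymes <- function(seqs, library = loadEnzymes(), gel = gelModel(),
                          target = NULL, mode = "strict") {
  if (!length(library)) rflpStop("EmptyLibrary", "no enzymes to screen")
  if (!all(vapply(library, is, logical(1L), "RestrictionEnzyme")))
    rflpStop("BadArgument", "library must contain RestrictionEnzyme objects")
  probe <- groupPatterns(seqs, library[[1L]], gel, mode = mode)
  speciesAll <- unique(vapply(probe@patterns, function(p) p@species,
                              character(1L)))
  if (length(speciesAll) < 2L)
    rflpStop("BadArgument", "screening needs at least two species")
  if (!is.null(target) && !target %in% speciesAll)
    rflpStop("BadArgument", sprintf("target species '%s' not in data", target))
  pairsIdx <- utils::combn(speciesAll, 2L)
  nPairs <- ncol(pairsIdx)
  lab <- .extractLabeled(seqs)
  rows <- lapply(library, function(enz) {
    cat_ <- groupPatterns(seqs, enz, gel, mode = mode)
    patsBySp <- split(cat_@patterns,
                      vapply(cat_@patterns, function(p) p@species,
                             character(1L)))
    separated <- logical(nPairs)
    for (q in seq_len(nPairs)) {
      a <- patsBySp[[pairsIdx[1L, q]]]
      b <- patsBySp[[pairsIdx[2L, q]]]
      shared <- FALSE
      for (pa in a) for (pb in b)
        if (patternsEqual(pa, pb, gel)) { shared <- TRUE; break }
      separated[q] <- !shared
    }
    counts <- patternCounts(cat_)
    totalCuts <- sum(vapply(lab$texts, function(s)
      length(findSites(s, enz, mode)), integer(1L)))
    discr <- if (is.null(target)) NA else {
      all(separated[pairsIdx[1L, ] == target | pairsIdx[2L, ] == target])
    }
    data.frame(enzyme = enz@name,
               score = sum(separated) / nPairs,
               pairs_separated = sum(separated),
               pairs_total = nPairs,
               intra_species_splits = sum(counts > 1L),
               total_cuts = totalCuts,
               discriminates_target = discr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$intra_species_splits, out$total_cuts,
                   out$enzyme), , drop = FALSE]
  rownames(out) <- NULL
  out
}
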
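#' Convert a digest to the band pattern visible on a gel
#'
#' Applies the gel resolution model to a fragment multiset: fragments
#' shorter than `minVisible` are dropped, and fragments linked by pairwise
#' differences of at most `coMigrationTol` (single-linkage chaining) merge
#' into one band whose size is the rounded mean of the merged fragments --
#' on the gel they are a single indistinguishable band.
#'
#' @param result a [DigestResult-class], or a bare integer vector of
#'   fragment lengths.
#' @param gel a [GelModel-class].
#' @param species,region labels stored on the pattern ([DigestResult-class]
#'   inputs carry their enzyme name along).
#' @return an [RflpPattern-class] with bands sorted descending.
#' @examples
#' toVisibleBands(c(100, 100, 38), gelModel())  # single band at 100
#' bands(toVisibleBands(c(160, 158, 60), gelModel(coMigrationTol = 5)))
#' @export
toVisibleBands <- function(result, gel = gelModel(),
                           species = NA_character_, region = NA_character_) {
  stopifnot(is(gel, "GelModel"))
  if (is(result, "DigestResult")) {
    frags <- result@fragments
    enzyme <- result@enzyme
    ids <- result@ampliconId
  } else {
    frags <- as.integer(result)
    enzyme <- NA_character_
    ids <- character()
  }
  vis <- sort(frags[frags >= gel@minVisible])
  if (!length(vis))
    rflpStop("EmptyPattern",
             sprintf("no fragment reaches the %d bp visibility limit",
                     gel@minVisible))
  grp <- cumsum(c(1L, as.integer(diff(vis) > gel@coMigrationTol)))
  bandSizes <- as.integer(round(tapply(vis, grp, mean)))
  rflpPattern(bandSizes, species = species, enzyme = enzyme,
              region = region, sourceIds = ids)
}

#' Compare two band patterns under a gel model
#'
#' Two patterns are read as the same on a gel when they have the same
#' number of bands and each positionally matched pair (largest with
#' largest, and so on) differs by at most the gel's co-migration tolerance.
#' This relation is reflexive and symmetric but deliberately not
#' transitive (tolerances chain), which is why cataloging uses
#' order-stable leader clustering rather than exact partitioning.
#'
#' @param a,b [RflpPattern-class] objects produced under the same enzyme
#'   and marker region (a mismatch there raises `IncomparablePatterns`).
#' @param gel a [GelModel-class] supplying the tolerance.
#' @return `TRUE` or `FALSE`.
#' @examples
#' g <- gelModel()
#' patternsEqual(rflpPattern(c(200, 150, 88)), rflpPattern(c(203, 149, 86)), g)
#' @export
patternsEqual <- function(a, b, gel = gelModel()) {
  stopifnot(is(a, "RflpPattern"), is(b, "RflpPattern"), is(gel, "GelModel"))
  if (!is.na(a@enzyme) && !is.na(b@enzyme) && a@enzyme != b@enzyme)
    rflpStop("IncomparablePatterns",
             sprintf("patterns from different enzymes (%s vs %s)",
                     a@enzyme, b@enzyme))
  if (!is.na(a@region) && !is.na(b@region) && a@region != b@region)
    rflpStop("IncomparablePatterns",
             sprintf("patterns from different regions (%s vs %s)",
                     a@region, b@region))
  if (length(a@bands) != length(b@bands)) return(FALSE)
  all(abs(a@bands - b@bands) <= gel@coMigrationTol)
}

#' Catalog the distinct band patterns of each species
#'
#' Digests every labeled amplicon, converts fragments to visible bands and
#' groups them per species by leader clustering in input order: each
#' pattern joins the first cataloged pattern of its species it equals under
#' [patternsEqual()], otherwise it founds a new cataloged pattern (with
#' itself as representative). The per-species number of cataloged patterns
#' is the intra-species RFLP variability tabulated for an assay.
#'
#' @param seqs amplicons as a `DNAStringSet` with a `species` metadata
#'   column (see [amplifySet()] or [parseFasta()]), or a list of
#'   [Amplicon-class] objects carrying species labels.
#' @param enzyme a [RestrictionEnzyme-class].
#' @param gel a [GelModel-class].
#' @param mode site-matching mode passed to [digestLinear()].
#' @param region marker-region label recorded in the catalog (defaults to
#'   the first non-missing region among the inputs).
#' @return a [PatternCatalog-class].
#' @export
groupPatterns <- function(seqs, enzyme, gel = gelModel(),
                          mode = "strict", region = NULL) {
  stopifnot(is(enzyme, "RestrictionEnzyme"), is(gel, "GelModel"))
  lab <- .extractLabeled(seqs)
  ids <- lab$ids; species <- lab$species; texts <- lab$texts
  if (is.null(region)) {
    known <- lab$regions[!is.na(lab$regions)]
    region <- if (length(known)) known[1L] else NA_character_
  }
  catalog <- list()
  for (i in seq_along(texts)) {
    dg <- digestLinear(texts[i], enzyme, mode = mode, id = ids[i])
    pat <- toVisibleBands(dg, gel, species = species[i], region = region)
    placed <- FALSE
    for (k in seq_along(catalog)) {
      if (catalog[[k]]@species == species[i] &&
          patternsEqual(catalog[[k]], pat, gel)) {
        catalog[[k]]@sourceIds <- c(catalog[[k]]@sourceIds, ids[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) catalog[[length(catalog) + 1L]] <- pat
  }
  # order patterns by species first appearance, preserving founding order
  spOrder <- unique(species)
  ord <- order(match(vapply(catalog, function(p) p@species, character(1L)),
                     spOrder))
  new("PatternCatalog", patterns = catalog[ord], gel = gel,
      enzyme = enzyme@name, region = as.character(region))
}

# Normalize the two accepted labeled-amplicon representations (list of
# Amplicon objects, or DNAStringSet with species mcols) to parallel vectors.
.extractLabeled <- function(seqs) {
  if (is.list(seqs)) {
    ids <- vapply(seqs, function(a) a@sourceId, character(1L))
    species <- vapply(seqs, function(a) a@species, character(1L))
    regions <- vapply(seqs, function(a) a@region, character(1L))
    texts <- vapply(seqs, function(a) a@residues, character(1L))
  } else {
    mc <- S4Vectors::mcols(seqs)
    if (is.null(mc) || !"species" %in% colnames(mc))
      rflpStop("MissingSpecies", "sequences must carry a species label")
    ids <- names(seqs)
    species <- mc$species
    regions <- if ("region" %in% colnames(mc)) mc$region
               else rep(NA_character_, length(seqs))
    texts <- as.character(seqs)
  }
  if (!length(texts)) rflpStop("EmptyInput", "no sequences to catalog")
  if (any(is.na(species)))
    rflpStop("MissingSpecies",
             sprintf("record \"%s\" has no species label",
                     ids[which(is.na(species))[1L]]))
  list(ids = ids, species = species, regions = regions, texts = texts)
}

#' Build a catalog directly from known band patterns
#'
#' For workflows that start from observed gel readings rather than
#' sequences: wraps a list of [RflpPattern-class] (or a named list of band
#' vectors) into a [PatternCatalog-class] suitable for [buildKey()].
#'
#' @param patterns list of [RflpPattern-class], or a named list of integer
#'   band vectors (names = species; a species may be repeated for multiple
#'   patterns).
#' @param gel,enzyme,region catalog attributes.
#' @return a [PatternCatalog-class].
#' @export
patternCatalog <- function(patterns, gel = gelModel(),
                           enzyme = NA_character_, region = NA_character_) {
  if (length(patterns) && !is(patterns[[1L]], "RflpPattern")) {
    if (is.null(names(patterns)))
      rflpStop("MissingSpecies", "band vectors must be named by species")
    patterns <- lapply(seq_along(patterns), function(i)
      rflpPattern(patterns[[i]], species = names(patterns)[i],
                  enzyme = enzyme, region = region))
  }
  for (p in patterns) {
    if (!is.na(enzyme) && !is.na(p@enzyme) && p@enzyme != enzyme)
      rflpStop("IncomparablePatterns", "pattern enzyme differs from catalog")
  }
  new("PatternCatalog", patterns = patterns, gel = gel,
      enzyme = as.character(enzyme), region = as.character(region))
}

#' Export a catalog as a data frame
#'
#' One row per cataloged pattern: species, pattern index within species,
#' comma-joined descending bands, member count and representative (first
#' member) id. `write.table(as(x, "data.frame"), ...)` gives the on-disk
#' catalog format.
#'
#' @param x a [PatternCatalog-class].
#' @param ... ignored.
#' @return data.frame with columns `species`, `pattern_index`, `bands`,
#'   `n_members`, `representative_id`.
#' @export
as.data.frame.PatternCatalog <- function(x, ...) {
  sp <- vapply(x@patterns, function(p) p@species, character(1L))
  idx <- stats::ave(seq_along(sp), sp, FUN = seq_along)
  data.frame(
    species = sp,
    pattern_index = as.integer(idx),
    bands = vapply(x@patterns, function(p)
      paste(p@bands, collapse = ","), character(1L)),
    n_members = vapply(x@patterns, function(p)
      max(1L, length(p@sourceIds)), integer(1L)),
    representative_id = vapply(x@patterns, function(p)
      if (length(p@sourceIds)) p@sourceIds[1L] else NA_character_,
      character(1L)),
    stringsAsFactors = FALSE
  )
}

#' Render band patterns as a virtual gel
#'
#' Draws one lane per pattern plus a ladder lane, with band vertical
#' position proportional to `a - b * log10(bp)` (the classical
#' log-migration model), scaled to the canvas. Bands are placed by size
#' only, so lanes with the same bands render identically whatever the
#' input order of their band vectors. Output is deterministic for fixed
#' input: a monospace text gel for the console and an SVG 1.1 document for
#' reports.
#'
#' @param patterns list of [RflpPattern-class] (or integer band vectors).
#' @param ladder ladder band sizes in bp.
#' @param labels lane labels; defaults to pattern species or `L1`, `L2`...
#' @param rows text-rendering height in character rows.
#' @return list with elements `text` (character vector of lines) and `svg`
#'   (single SVG string), invisibly; the text gel is printed unless
#'   `quiet = TRUE`.
#' @param quiet suppress printing of the text gel.
#' @export
renderGel <- function(patterns, ladder = c(500L, 400L, 300L, 200L, 100L, 50L),
                      labels = NULL, rows = 24L, quiet = FALSE) {
  if (is(patterns, "RflpPattern")) patterns <- list(patterns)
  bandsList <- lapply(patterns, function(p)
    if (is(p, "RflpPattern")) p@bands else sort(as.integer(p),
                                                decreasing = TRUE))
  if (!length(bandsList)) rflpStop("EmptyInput", "no patterns to render")
  if (any(vapply(bandsList, function(b) any(b < 1L), logical(1L))))
    rflpStop("BadArgument", "bands must be >= 1 bp")
  if (is.null(labels)) {
    labels <- vapply(seq_along(patterns), function(i) {
      p <- patterns[[i]]
      if (is(p, "RflpPattern") && !is.na(p@species)) p@species
      else paste0("L", i)
    }, character(1L))
  }
  allBp <- c(ladder, unlist(bandsList))
  lo <- max(1L, min(allBp)); hi <- max(allBp)
  # migration position in [0, 1]: 0 = well (largest), 1 = front (smallest)
  mig <- function(bp) {
    if (hi == lo) return(rep(0.5, length(bp)))
    (log10(hi) - log10(bp)) / (log10(hi) - log10(lo))
  }
  lanes <- c(list(ladder), bandsList)
  laneNames <- c("ladder", labels)

  ## text rendering
  laneW <- max(6L, nchar(laneNames) + 1L)
  canvas <- matrix(" ", nrow = rows, ncol = length(lanes))
  for (j in seq_along(lanes)) {
    r <- 1L + as.integer(round(mig(lanes[[j]]) * (rows - 1L)))
    canvas[r, j] <- "="
  }
  pad <- function(s) formatC(s, width = laneW, flag = "-")
  textOut <- c(
    paste(vapply(laneNames, pad, character(1L)), collapse = ""),
    vapply(seq_len(rows), function(r)
      paste(vapply(canvas[r, ], function(ch)
        formatC(strrep(ch, ifelse(ch == "=", 4L, 1L)), width = laneW,
                flag = "-"), character(1L)), collapse = ""),
      character(1L))
  )

  ## SVG rendering
  laneWpx <- 60; topPad <- 30; h <- 400; w <- laneWpx * length(lanes) + 20
  svg <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%d" height="%d">',
            w, h + topPad + 20),
    sprintf('<rect x="0" y="0" width="%d" height="%d" fill="#202020"/>',
            w, h + topPad + 20)
  )
  for (j in seq_along(lanes)) {
    x <- 10 + (j - 1L) * laneWpx
    svg <- c(svg, sprintf(
      '<text x="%d" y="20" fill="#eeeeee" font-size="11" font-family="monospace">%s</text>',
      x, laneNames[j]))
    for (bp in lanes[[j]]) {
      y <- topPad + mig(bp) * (h - 10)
      fill <- if (j == 1L) "#aaaaaa" else "#f5f5f5"
      svg <- c(svg, sprintf(
        '<rect x="%d" y="%.1f" width="%d" height="3" fill="%s"/>',
        x, y, laneWpx - 16L, fill))
      if (j == 1L)
        svg <- c(svg, sprintf(
          '<text x="%d" y="%.1f" fill="#aaaaaa" font-size="9" font-family="monospace">%d</text>',
          x + laneWpx - 14L, y + 3, bp))
    }
  }
  svg <- c(svg, "</svg>")
  out <- list(text = textOut, svg = paste(svg, collapse = "\n"))
  if (!quiet) cat(textOut, sep = "\n")
  invisible(out)
}

#' Write a virtual gel to an SVG file
#'
#' @param patterns,ladder,labels as in [renderGel()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeGelSVG <- function(patterns, file,
                        ladder = c(500L, 400L, 300L, 200L, 100L, 50L),
                        labels = NULL) {
  g <- renderGel(patterns, ladder = ladder, labels = labels, quiet = TRUE)
  writeLines(g$svg, file)
  invisible(file)
}
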
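#' Locate degenerate primer binding sites on a template
#'
#' Scans the plus strand of a template for positions where a primer binds
#' with at most `maxMismatch` mismatches under strict IUPAC matching (a
#' template symbol matches only when its base set is contained in the
#' primer symbol's set, so a reported hit binds whatever the true base is).
#' For `strand = "minus"` the primer's reverse complement is matched
#' against the plus strand, i.e. hits are sites the primer would bind on
#' the bottom strand. On circular templates, matches spanning the origin
#' are reported with `start < length(template)` and `end` possibly beyond
#' it.
#'
#' PCR extension fails quickly when the primer's 3' end is unpaired, so a
#' 3'-anchor can require the terminal `anchor3` primer positions to match
#' exactly regardless of `maxMismatch`.
#'
#' @param template a template sequence: IUPAC string, `DNAString`, or a
#'   single-record slice of a [parseFasta()] result (topology is then taken
#'   from its metadata).
#' @param primer a [Primer-class] or IUPAC string (5' to 3').
#' @param strand `"plus"` or `"minus"`.
#' @param maxMismatch maximum tolerated mismatches.
#' @param anchor3 number of 3'-terminal primer positions that must match
#'   exactly (0 disables anchoring).
#' @param circular treat the template as circular.
#' @return data.frame with 0-based half-open `start`, `end` and
#'   `mismatches`, sorted by `start`.
#' @examples
#' findPrimerMatches(paste0("AAAA", "TTTGGG", "AAAA"), "TTTGGG")
#' @export
findPrimerMatches <- function(template, primer, strand = c("plus", "minus"),
                              maxMismatch = 0L, anchor3 = 0L,
                              circular = FALSE) {
  strand <- match.arg(strand)
  tpl <- .templateInfo(template, circular)
  p <- if (is(primer, "Primer")) primer@residues else normalizeResidues(primer)
  assertIupac(p, "primer")
  if (nchar(p) > nchar(tpl$seq))
    rflpStop("NoMatchPossible",
             sprintf("primer (%d nt) longer than template (%d nt)",
                     nchar(p), nchar(tpl$seq)))
  pm <- if (strand == "plus") p else revComp(p)
  hits <- .scanPrimer(tpl$scanSeq, pm, maxMismatch, anchor3,
                      anchorAtEnd = (strand == "plus"))
  if (tpl$circular) hits <- hits[hits$start < tpl$len, , drop = FALSE]
  hits[order(hits$start), , drop = FALSE]
}

# Resolve the template argument into residues + topology; circular
# templates are scanned on seq + head(seq, needed overlap).
.templateInfo <- function(template, circular = FALSE, overlap = NULL) {
  topo <- NULL
  if (is(template, "DNAStringSet") || is(template, "BStringSet")) {
    if (length(template) != 1L)
      rflpStop("BadTemplate", "supply a single template sequence")
    mc <- S4Vectors::mcols(template)
    if (!is.null(mc) && "topology" %in% colnames(mc)) topo <- mc$topology[1L]
    template <- as.character(template)[1L]
  } else if (is(template, "DNAString")) {
    template <- as.character(template)
  }
  s <- unname(normalizeResidues(template))
  assertIupac(s, "template")
  circ <- isTRUE(circular) || identical(topo, "circular")
  len <- nchar(s)
  ov <- if (is.null(overlap)) len else min(overlap, len)
  list(seq = s, len = len, circular = circ,
       scanSeq = if (circ) paste0(s, substr(s, 1L, ov)) else s)
}

# Core scan: mismatch profile + optional exact 3' anchor.
# anchorAtEnd: primer 3' end maps to the window's right edge (plus-strand
# primer); FALSE for a reverse-complemented minus-strand primer, whose 3'
# end maps to the window's left edge.
.scanPrimer <- function(seqText, primerText, maxMismatch, anchor3,
                        anchorAtEnd = TRUE) {
  tb <- iupacBits(seqText)
  pb <- iupacBits(primerText)
  mm <- mismatchProfile(tb, pb)
  if (!length(mm))
    return(data.frame(start = integer(), end = integer(),
                      mismatches = integer()))
  keep <- mm <= maxMismatch
  if (anchor3 > 0L) {
    k <- length(pb)
    a <- min(anchor3, k)
    idx <- if (anchorAtEnd) (k - a + 1L):k else 1L:a
    anchorOk <- rep(TRUE, length(mm))
    for (j in idx) {
      seg <- tb[j:(length(tb) - k + j)]
      anchorOk <- anchorOk & (bitwAnd(seg, bitwNot(pb[j]) %% 16L) == 0L)
    }
    keep <- keep & anchorOk
  }
  st <- which(keep) - 1L
  data.frame(start = st, end = st + nchar(primerText),
             mismatches = mm[keep])
}

#' Extract the amplicons a primer pair would produce
#'
#' Pairs every plus-strand forward-primer hit with every minus-strand
#' reverse-primer hit downstream of it and returns the spanned products,
#' mirroring exhaustive in-silico PCR. Both template orientations are
#' considered (the forward primer may bind either strand), so a template
#' and its reverse complement yield products of identical lengths; all
#' coordinates and residues are reported on the plus strand. The amplicon runs from the first
#' base of the forward match to the last base of the reverse match, so both
#' primer-binding regions are included (PCR products are digested
#' untrimmed); set `trimPrimers = TRUE` to remove them, e.g. when deposited
#' amplicon sequences lack primer regions. An empty result is not an error:
#' some species simply fail to amplify with a given primer set.
#'
#' Defaults allow 2 whole-primer mismatches but require the 3 terminal 3'
#' positions of each primer to match exactly, reflecting the sensitivity of
#' polymerase extension to 3' mispairing. Circular templates yield
#' origin-spanning products whose `end` exceeds the template length
#' (coordinates modulo length).
#'
#' @param template as in [findPrimerMatches()].
#' @param pair a [PrimerPair-class].
#' @param maxMismatch per-primer mismatch allowance.
#' @param maxProduct longest product reported (bp); suppresses spurious
#'   distant pairings.
#' @param anchor3 exact-match 3' anchor length per primer.
#' @param circular treat the template as circular.
#' @param trimPrimers remove the primer-binding regions from the reported
#'   residues (coordinates still span the full product).
#' @param id,species,region labels for the resulting amplicons; default to
#'   the template's own labels when it comes from [parseFasta()].
#' @return list of [Amplicon-class], sorted by start then length.
#' @examples
#' pp <- primerPair("GGTCAACAAATC", "GGGTTTGGGTTT")
#' tpl <- paste0(strrep("A", 30), "GGTCAACAAATC", strrep("C", 60),
#'               revComp("GGGTTTGGGTTT"), strrep("A", 30))
#' length(amplify(tpl, pp)[[1]]@residues)
#' @export
amplify <- function(template, pair, maxMismatch = 2L, maxProduct = 2000L,
                    anchor3 = 3L, circular = FALSE, trimPrimers = FALSE,
                    id = NULL, species = NA_character_,
                    region = NA_character_) {
  stopifnot(is(pair, "PrimerPair"))
  if (maxProduct <= 0L) rflpStop("BadArgument", "maxProduct must be > 0")
  if (is(template, "DNAStringSet") && length(template) == 1L) {
    mc <- S4Vectors::mcols(template)
    if (is.null(id)) id <- names(template)[1L]
    if (!is.null(mc)) {
      if (is.na(species) && "species" %in% colnames(mc))
        species <- mc$species[1L]
      if (is.na(region) && "region" %in% colnames(mc)) region <- mc$region[1L]
    }
  }
  if (is.null(id)) id <- "template"
  tpl <- .templateInfo(template, circular, overlap = maxProduct)
  fLen <- nchar(pair@forward@residues)
  rLen <- nchar(pair@reverse@residues)

  # spans (0-based start, length) of products with the forward primer on the
  # given strand's 5' side; `seqText` is the strand being read
  spansOn <- function(seqText) {
    fwd <- try(findPrimerMatches(seqText, pair@forward, "plus",
                                 maxMismatch, anchor3, tpl$circular),
               silent = TRUE)
    rv <- try(findPrimerMatches(seqText, pair@reverse, "minus",
                                maxMismatch, anchor3, tpl$circular),
              silent = TRUE)
    if (inherits(fwd, "try-error") || inherits(rv, "try-error"))
      return(data.frame(start = integer(), len = integer()))
    spans <- data.frame(start = integer(), len = integer())
    for (i in seq_len(nrow(fwd))) {
      for (j in seq_len(nrow(rv))) {
        fs <- fwd$start[i]; rs <- rv$start[j]; re <- rv$end[j]
        if (tpl$circular && !(fs < rs)) {
          # origin-spanning: reverse site wrapped around before the forward
          len <- (re - fs) %% tpl$len
        } else {
          if (!(fs < rs)) next
          len <- re - fs
          if (!tpl$circular && re > tpl$len) next
        }
        if (len > maxProduct || len <= fLen + rLen) next
        spans[nrow(spans) + 1L, ] <- c(fs, len)
      }
    }
    spans
  }

  # orientation 1: forward primer binds the plus strand
  spans <- spansOn(tpl$seq)
  spans$fwdAtStart <- rep(TRUE, nrow(spans))
  # orientation 2: forward primer binds the minus strand; pairing is found
  # on the reverse complement and mapped back to plus coordinates
  sp2 <- spansOn(revComp(tpl$seq))
  if (nrow(sp2)) {
    sp2$start <- (tpl$len - (sp2$start + sp2$len)) %% tpl$len
    sp2$fwdAtStart <- FALSE
    spans <- rbind(spans, sp2)
  }
  if (!nrow(spans)) return(list())
  spans <- spans[!duplicated(spans[, c("start", "len")]), , drop = FALSE]
  spans <- spans[order(spans$start, spans$len), , drop = FALSE]
  lapply(seq_len(nrow(spans)), function(i)
    .mkAmplicon(tpl, id, spans$start[i], spans$start[i] + spans$len[i],
                fLen, rLen, trimPrimers, species, region,
                fwdAtStart = spans$fwdAtStart[i]))
}

.mkAmplicon <- function(tpl, id, start, end, fLen, rLen, trimPrimers,
                        species, region, fwdAtStart = TRUE) {
  res <- substr(tpl$scanSeq, start + 1L, end)  # end may exceed len (circular)
  st <- start; en <- end
  if (trimPrimers) {
    # with the forward primer on the minus strand the reverse primer's
    # binding region sits at the plus-strand 5' end
    headLen <- if (fwdAtStart) fLen else rLen
    tailLen <- if (fwdAtStart) rLen else fLen
    res <- substr(res, headLen + 1L, nchar(res) - tailLen)
    st <- start + headLen; en <- end - tailLen
  }
  new("Amplicon", sourceId = id, start = as.integer(st), end = as.integer(en),
      residues = res, species = as.character(species),
      region = as.character(region))
}

#' Amplify every record of a sequence set
#'
#' Convenience wrapper running [amplify()] over each record of a
#' [parseFasta()] result and returning the products as a labeled
#' `DNAStringSet` ready for digestion and pattern grouping. Records that
#' fail to amplify are dropped (with a message), as in the wet protocol
#' where not every species amplifies with every primer set.
#'
#' @param seqs a `DNAStringSet` with [parseFasta()] metadata.
#' @param pair a [PrimerPair-class].
#' @param ... passed to [amplify()].
#' @param quiet suppress the per-record failure message.
#' @return `DNAStringSet` of amplicon sequences; `mcols()` has `species`,
#'   `region`, `sourceId`, `start`, `end`. Ids are the source ids, with
#'   `.2`, `.3`, ... suffixes when one template yields several products.
#' @export
amplifySet <- function(seqs, pair, ..., quiet = FALSE) {
  allAmp <- list()
  for (i in seq_along(seqs)) {
    amps <- amplify(seqs[i], pair, ...)
    if (!length(amps)) {
      if (!quiet)
        message("no amplification for record ", names(seqs)[i])
      next
    }
    for (k in seq_along(amps)) {
      a <- amps[[k]]
      nm <- if (k == 1L) a@sourceId else paste0(a@sourceId, ".", k)
      allAmp[[nm]] <- a
    }
  }
  if (!length(allAmp)) {
    out <- Biostrings::DNAStringSet()
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
      species = character(), region = character(), sourceId = character(),
      start = integer(), end = integer())
    return(out)
  }
  out <- Biostrings::DNAStringSet(
    vapply(allAmp, function(a) a@residues, character(1L)))
  names(out) <- names(allAmp)
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    species  = vapply(allAmp, function(a) a@species, character(1L)),
    region   = vapply(allAmp, function(a) a@region, character(1L)),
    sourceId = vapply(allAmp, function(a) a@sourceId, character(1L)),
    start    = vapply(allAmp, function(a) a@start, integer(1L)),
    end      = vapply(allAmp, function(a) a@end, integer(1L)))
  out
}

#' Bundled primer pairs
#'
#' The four mitochondrial marker primer pairs shipped with the package,
#' read from `inst/extdata/primers.tsv`:
#' \describe{
#'   \item{16S}{16S-Forward / 16S-Reverse, 438 bp product, digested with
#'     DraI in the 16S assay.}
#'   \item{COI-short}{COI-F / COI-R, 691 bp.}
#'   \item{COI-LCO}{LCO1490 / HCO2198, 710 bp, amplifying the same region
#'     as COI-short with a 10 bp overhang on either side.}
#'   \item{COI-long}{Cox1-F / cox1-R, 849 bp.}
#' }
#'
#' @param file optional path to a user primer table with columns
#'   `pair`, `role` (forward/reverse), `name`, `residues`,
#'   `expected_length`.
#' @return named list of [PrimerPair-class] objects.
#' @examples
#' names(defaultPrimerPairs())
#' @export
defaultPrimerPairs <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "primers.tsv", package = "rflpkit",
                        mustWork = TRUE)
  tab <- utils::read.table(file, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "")
  out <- list()
  for (pr in unique(tab$pair)) {
    sub <- tab[tab$pair == pr, , drop = FALSE]
    f <- sub[sub$role == "forward", , drop = FALSE]
    r <- sub[sub$role == "reverse", , drop = FALSE]
    if (nrow(f) != 1L || nrow(r) != 1L)
      rflpStop("BadPrimerTable",
               sprintf("pair '%s' needs one forward and one reverse primer", pr))
    out[[pr]] <- primerPair(primer(f$name, f$residues),
                            primer(r$name, r$residues),
                            as.integer(f$expected_length))
  }
  out
}
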
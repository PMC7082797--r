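## Dichotomous keys over band patterns.
##
## A key is an ordered list of numbered couplets; each couplet offers two
## mutually exclusive statements (leads) about the visible band pattern and
## each lead either names a species or forwards to another couplet. Keys
## built by buildKey() have complementary leads; parsed keys (like the
## built-in North-American 16S key) may leave gaps between their leads, in
## which case classification stops with "undetermined".

## ---- feature evaluation ----------------------------------------------

# Returns list(value = TRUE/FALSE, ambiguous = TRUE/FALSE). `ambiguous`
# flags a band lying within tol of a strict size threshold: on a real gel
# such a call is within reading error and is surfaced as a warning.
evalFeature <- function(f, bandsDesc, tol) {
  k <- f@kind
  if (k == "band_count_gt")
    return(list(value = length(bandsDesc) > f@threshold, ambiguous = FALSE))
  if (k == "band_count_le")
    return(list(value = length(bandsDesc) <= f@threshold, ambiguous = FALSE))
  if (k == "band_count_eq")
    return(list(value = length(bandsDesc) == f@threshold, ambiguous = FALSE))
  if (k %in% c("has_band_near", "no_band_near")) {
    useTol <- if (f@tol > 0L) f@tol else tol
    hit <- any(abs(bandsDesc - f@threshold) <= useTol)
    return(list(value = if (k == "has_band_near") hit else !hit,
                ambiguous = FALSE))
  }
  v <- if (f@rank >= 1L && f@rank <= length(bandsDesc)) bandsDesc[f@rank]
       else NA_integer_
  if (is.na(v)) {
    # a missing rank cannot exceed, fall below or sit near a size, but the
    # complementary "at most" statement holds vacuously -- this keeps the
    # two leads of a generated couplet exhaustive
    return(list(value = k == "nth_band_le", ambiguous = FALSE))
  }
  if (k == "nth_band_near") {
    useTol <- if (f@tol > 0L) f@tol else tol
    return(list(value = abs(v - f@threshold) <= useTol, ambiguous = FALSE))
  }
  value <- switch(k,
    nth_band_gt = v > f@threshold,
    nth_band_lt = v < f@threshold,
    nth_band_le = v <= f@threshold)
  list(value = value, ambiguous = abs(v - f@threshold) <= tol)
}

# Logical complement of a feature, used for generated couplets.
complementFeature <- function(f) {
  flip <- c(band_count_gt = "band_count_le", band_count_le = "band_count_gt",
            nth_band_gt = "nth_band_le", nth_band_le = "nth_band_gt",
            has_band_near = "no_band_near", no_band_near = "has_band_near")
  if (!f@kind %in% names(flip))
    rflpStop("BadFeature", sprintf("cannot complement feature kind %s", f@kind))
  keyFeature(flip[[f@kind]], f@threshold, f@rank, f@tol)
}

## ---- feature (de)serialization ---------------------------------------

formatFeature <- function(f) {
  switch(f@kind,
    band_count_gt = sprintf("count>%d", f@threshold),
    band_count_le = sprintf("count<=%d", f@threshold),
    band_count_eq = sprintf("count==%d", f@threshold),
    nth_band_gt   = sprintf("band%d>%d", f@rank, f@threshold),
    nth_band_lt   = sprintf("band%d<%d", f@rank, f@threshold),
    nth_band_le   = sprintf("band%d<=%d", f@rank, f@threshold),
    nth_band_near = sprintf("band%d~%d", f@rank, f@threshold),
    has_band_near = sprintf("any~%d", f@threshold),
    no_band_near  = sprintf("!any~%d", f@threshold))
}

parseFeature <- function(s, line) {
  s <- trimws(s)
  m <- regexec("^count(>|<=|==)([0-9]+)$", s)[[1L]]
  if (m[1L] != -1L) {
    g <- regmatches(s, list(m))[[1L]]
    kind <- switch(g[2L], ">" = "band_count_gt", "<=" = "band_count_le",
                   "==" = "band_count_eq")
    return(keyFeature(kind, as.integer(g[3L])))
  }
  m <- regexec("^band([0-9]+)(>|<=|<|~)([0-9]+)$", s)[[1L]]
  if (m[1L] != -1L) {
    g <- regmatches(s, list(m))[[1L]]
    kind <- switch(g[3L], ">" = "nth_band_gt", "<" = "nth_band_lt",
                   "<=" = "nth_band_le", "~" = "nth_band_near")
    return(keyFeature(kind, as.integer(g[4L]), rank = as.integer(g[2L])))
  }
  m <- regexec("^(!?)any~([0-9]+)$", s)[[1L]]
  if (m[1L] != -1L) {
    g <- regmatches(s, list(m))[[1L]]
    kind <- if (g[2L] == "!") "no_band_near" else "has_band_near"
    return(keyFeature(kind, as.integer(g[3L])))
  }
  rflpStop("KeyParseError",
           sprintf("line %d: cannot parse feature \"%s\"", line, s),
           line = line)
}

# Human phrasing used by the pretty printer.
describeFeature <- function(f) {
  rankWord <- function(r) {
    if (r == 1L) "Largest band" else if (r == 2L) "Middle band"
    else sprintf("Band %d (from largest)", r)
  }
  switch(f@kind,
    band_count_gt = sprintf("More than %d band%s present", f@threshold,
                            if (f@threshold == 1L) "" else "s"),
    band_count_le = sprintf("At most %d band%s present", f@threshold,
                            if (f@threshold == 1L) "" else "s"),
    band_count_eq = if (f@threshold == 2L) "Only two bands present"
                    else sprintf("Exactly %d bands present", f@threshold),
    nth_band_gt   = sprintf("%s > %d bp", rankWord(f@rank), f@threshold),
    nth_band_lt   = sprintf("%s < %d bp", rankWord(f@rank), f@threshold),
    nth_band_le   = sprintf("%s <= %d bp", rankWord(f@rank), f@threshold),
    nth_band_near = sprintf("%s approximately %d bp", rankWord(f@rank),
                            f@threshold),
    has_band_near = sprintf("A band near %d bp present", f@threshold),
    no_band_near  = sprintf("No band near %d bp", f@threshold))
}

## ---- key construction ------------------------------------------------

#' Build a dichotomous key from a pattern catalog
#'
#' Constructs an identification key by greedy recursive splitting of the
#' cataloged patterns. At each node the candidate features are (i)
#' band-count thresholds at every observed band count, (ii) nth-band size
#' thresholds at midpoints between adjacent observed sizes whose gap
#' exceeds twice the co-migration tolerance (so each branch keeps a
#' full-tolerance safety margin), and (iii) presence of a band near each
#' observed band size. The feature maximizing the minimum branch size is
#' chosen (ties: band-count features first, then smaller band rank, then
#' larger threshold margin); recursion continues until every node holds a
#' single pattern. Couplets are numbered breadth-first and carry
#' back-references to the couplet they are reached from.
#'
#' Construction refuses catalogs in which two species share a band pattern
#' (error `IndistinguishableSpecies`, naming the pair) -- no fragment-size
#' key can separate them, the situation seen with H. longicornis and
#' H. asiatica 16S/DraI patterns.
#'
#' @param catalog a [PatternCatalog-class] with at least two distinct
#'   patterns.
#' @param gel gel model; defaults to the catalog's own.
#' @return a [DichotomousKey-class].
#' @seealso [applyKey()], [formatKey()], [parseKey()]
#' @export
buildKey <- function(catalog, gel = NULL) {
  stopifnot(is(catalog, "PatternCatalog"))
  if (is.null(gel)) gel <- catalog@gel
  pats <- catalog@patterns
  if (length(pats) < 2L)
    rflpStop("KeyConstructionFailure", "need at least two distinct patterns")
  tol <- gel@coMigrationTol
  # cross-species indistinguishability check
  for (i in seq_along(pats)) {
    for (j in seq_len(i - 1L)) {
      if (pats[[i]]@species != pats[[j]]@species &&
          patternsEqual(pats[[i]], pats[[j]], gel))
        rflpStop("IndistinguishableSpecies",
                 sprintf("species share one band pattern: %s / %s",
                         pats[[j]]@species, pats[[i]]@species),
                 pair = c(pats[[j]]@species, pats[[i]]@species))
    }
  }

  bandsOf <- lapply(pats, function(p) p@bands)
  speciesOf <- vapply(pats, function(p) p@species, character(1L))

  evalOn <- function(f, idx)
    vapply(idx, function(i) evalFeature(f, bandsOf[[i]], tol)$value,
           logical(1L))

  candidates <- function(idx) {
    feats <- list(); margins <- numeric()
    counts <- vapply(idx, function(i) length(bandsOf[[i]]), integer(1L))
    for (cc in sort(unique(counts))) {
      feats[[length(feats) + 1L]] <- keyFeature("band_count_gt", cc)
      margins <- c(margins, Inf)
    }
    maxRank <- max(counts)
    for (r in seq_len(maxRank)) {
      vals <- sort(unique(unlist(lapply(idx, function(i) {
        b <- bandsOf[[i]]
        if (r <= length(b)) b[r] else NULL
      }))))
      if (length(vals) >= 2L) {
        for (q in seq_len(length(vals) - 1L)) {
          gap <- vals[q + 1L] - vals[q]
          if (gap > 2L * tol) {
            thr <- as.integer(floor((vals[q] + vals[q + 1L]) / 2))
            feats[[length(feats) + 1L]] <-
              keyFeature("nth_band_gt", thr, rank = r)
            margins <- c(margins, min(thr - vals[q], vals[q + 1L] - thr))
          }
        }
      }
    }
    for (x in sort(unique(unlist(bandsOf[idx])))) {
      feats[[length(feats) + 1L]] <- keyFeature("has_band_near", x, tol = tol)
      margins <- c(margins, 0)
    }
    list(feats = feats, margins = margins)
  }

  pickFeature <- function(idx) {
    cand <- candidates(idx)
    best <- NULL; bestKeyVec <- NULL; bestSplit <- NULL
    kindPri <- c(band_count_gt = 1, nth_band_gt = 2, has_band_near = 3)
    for (q in seq_along(cand$feats)) {
      f <- cand$feats[[q]]
      onA <- evalOn(f, idx)
      nA <- sum(onA); nB <- length(idx) - nA
      if (nA == 0L || nB == 0L) next
      # larger min branch, count-kind first, smaller rank, larger margin,
      # smaller threshold as the final deterministic tie-break
      keyVec <- c(-min(nA, nB), kindPri[[f@kind]], f@rank,
                  -cand$margins[q], f@threshold)
      if (is.null(best) || .lexLess(keyVec, bestKeyVec)) {
        best <- f; bestKeyVec <- keyVec; bestSplit <- onA
      }
    }
    if (is.null(best))
      rflpStop("KeyConstructionFailure",
               "feature pool exhausted before all patterns were separated")
    list(feature = best, onA = bestSplit)
  }

  ## breadth-first construction: couplets are numbered in the order nodes
  ## are dequeued, matching the numbering style of printed keys
  coupletsOut <- list()
  nodes <- list()
  pending <- list(list(idx = seq_along(pats), backRef = NA_integer_))
  assignedNumber <- 0L
  while (length(pending)) {
    node <- pending[[1L]]; pending <- pending[-1L]
    assignedNumber <- assignedNumber + 1L
    node$number <- assignedNumber
    pick <- pickFeature(node$idx)
    node$feature <- pick$feature
    node$idxA <- node$idx[pick$onA]
    node$idxB <- node$idx[!pick$onA]
    for (childIdx in list(node$idxA, node$idxB)) {
      if (length(childIdx) > 1L)
        pending[[length(pending) + 1L]] <-
          list(idx = childIdx, backRef = node$number)
    }
    nodes[[node$number]] <- node
  }
  # child couplet numbers follow from BFS order; map each internal node's
  # pattern set to its number
  idxKey <- function(idx) paste(sort(idx), collapse = ",")
  numberByIdx <- new.env(parent = emptyenv())
  for (n in nodes) assign(idxKey(n$idx), n$number, envir = numberByIdx)
  for (n in nodes) {
    mkLead <- function(childIdx) {
      if (length(childIdx) == 1L) {
        list(consequent = speciesOf[childIdx], toCouplet = FALSE)
      } else {
        list(consequent = as.character(get(idxKey(childIdx),
                                           envir = numberByIdx)),
             toCouplet = TRUE)
      }
    }
    leadA <- mkLead(n$idxA); leadB <- mkLead(n$idxB)
    coupletsOut[[n$number]] <- new("KeyCouplet",
      number = n$number, backRef = n$backRef,
      featureA = n$feature, featureB = complementFeature(n$feature),
      consequentA = leadA$consequent, consequentB = leadB$consequent,
      toCoupletA = leadA$toCouplet, toCoupletB = leadB$toCouplet)
  }
  new("DichotomousKey", couplets = coupletsOut, enzyme = catalog@enzyme,
      region = catalog@region, gel = gel)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.lexLess <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

## ---- key application -------------------------------------------------

#' Classify a band pattern with a dichotomous key
#'
#' Walks the key from couplet 1, at each couplet taking the first lead
#' whose statement holds for the visible bands. "Approximately X bp"
#' statements use the key's gel co-migration tolerance. If neither lead
#' holds (possible in printed keys whose leads do not cover all cases) the
#' walk stops and the pattern is `"undetermined"`. Any band lying within
#' tolerance of a strict size threshold adds an ambiguity warning to the
#' trace: on a real gel that comparison is within reading error.
#'
#' @param key a [DichotomousKey-class].
#' @param bandsOrPattern integer vector of band sizes (any order) or an
#'   [RflpPattern-class].
#' @param applyGel also apply the key's gel visibility filter to the input
#'   bands before classification (drop sub-`minVisible` bands, merge
#'   co-migrating ones). Defaults to `TRUE` for raw band vectors.
#' @return list of class `keyClassification`:
#'   `species` (name or `"undetermined"`), `trace` (couplet numbers
#'   visited), `leads` (`"a"`/`"b"` taken at each), `stalledAt` (couplet
#'   number if undetermined, else `NA`), `warnings` (ambiguity messages).
#' @examples
#' k <- naKey16S()
#' applyKey(k, c(430, 120))$species   # H. leporispalustris
#' applyKey(k, c(160, 150, 128))$trace
#' @export
applyKey <- function(key, bandsOrPattern, applyGel = TRUE) {
  stopifnot(is(key, "DichotomousKey"))
  if (is(bandsOrPattern, "RflpPattern")) {
    bands <- bandsOrPattern@bands
    applyGel <- FALSE  # patterns are already gel-filtered
  } else {
    bands <- as.integer(bandsOrPattern)
  }
  if (!length(bands) || any(bands < 1L))
    rflpStop("BadArgument", "bands must be positive sizes in bp")
  if (applyGel)
    bands <- toVisibleBands(bands, key@gel)@bands
  bands <- sort(bands, decreasing = TRUE)
  tol <- key@gel@coMigrationTol
  trace <- integer(); leads <- character(); warningsOut <- character()
  cur <- 1L
  repeat {
    co <- key@couplets[[cur]]
    trace <- c(trace, cur)
    ra <- evalFeature(co@featureA, bands, tol)
    rb <- evalFeature(co@featureB, bands, tol)
    if (ra$ambiguous || rb$ambiguous)
      warningsOut <- c(warningsOut, sprintf(
        "couplet %d: a band lies within %d bp of a size threshold", cur, tol))
    if (ra$value) { pickTo <- co@consequentA; toC <- co@toCoupletA; leads <- c(leads, "a") }
    else if (rb$value) { pickTo <- co@consequentB; toC <- co@toCoupletB; leads <- c(leads, "b") }
    else {
      return(structure(list(species = "undetermined", trace = trace,
                            leads = leads, stalledAt = cur,
                            warnings = warningsOut, bands = bands),
                       class = "keyClassification"))
    }
    if (!toC) {
      return(structure(list(species = pickTo, trace = trace, leads = leads,
                            stalledAt = NA_integer_, warnings = warningsOut,
                            bands = bands),
                       class = "keyClassification"))
    }
    cur <- as.integer(pickTo)
  }
}

#' @export
print.keyClassification <- function(x, ...) {
  cat(sprintf("bands [%s] -> %s (trace %s)\n",
              paste(x$bands, collapse = ", "), x$species,
              paste(x$trace, collapse = " -> ")))
  if (!is.na(x$stalledAt))
    cat(sprintf("  no lead satisfied at couplet %d\n", x$stalledAt))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

## ---- key serialization -----------------------------------------------

#' Serialize a key
#'
#' `style = "machine"` emits the canonical on-disk form, one couplet per
#' line -- \code{num(back) feature -> consequent | feature -> consequent} --
#' preceded by a header line carrying the assay attributes. This form
#' round-trips exactly through [parseKey()]. `style = "pretty"` emits the
#' traditional printed layout with dot leaders and back-references.
#'
#' @param key a [DichotomousKey-class].
#' @param style `"machine"` or `"pretty"`.
#' @return character vector of lines.
#' @export
formatKey <- function(key, style = c("machine", "pretty")) {
  style <- match.arg(style)
  stopifnot(is(key, "DichotomousKey"))
  if (style == "machine") {
    header <- sprintf("# key enzyme=%s region=%s tol=%d min_visible=%d",
                      key@enzyme, key@region, key@gel@coMigrationTol,
                      key@gel@minVisible)
    lines <- vapply(key@couplets, function(co) {
      sprintf("%d(%s) %s -> %s | %s -> %s",
              co@number,
              ifelse(is.na(co@backRef), "-", as.character(co@backRef)),
              formatFeature(co@featureA), co@consequentA,
              formatFeature(co@featureB), co@consequentB)
    }, character(1L))
    c(header, lines)
  } else {
    unlist(lapply(key@couplets, function(co) {
      label <- if (is.na(co@backRef)) sprintf("%d", co@number)
               else sprintf("%d(%d)", co@number, co@backRef)
      leadLine <- function(f, cons, toC) {
        target <- if (toC) cons else paste0("*", cons, "*")
        desc <- describeFeature(f)
        dots <- strrep(".", max(3L, 60L - nchar(desc)))
        sprintf("%s %s%s %s", label, desc, dots, target)
      }
      a <- leadLine(co@featureA, co@consequentA, co@toCoupletA)
      b <- sub(sprintf("^%s ", gsub("([()])", "\\\\\\1", label)),
               strrep(" ", nchar(label) + 1L),
               leadLine(co@featureB, co@consequentB, co@toCoupletB))
      c(a, b)
    }))
  }
}

#' Parse a key from its canonical text form
#'
#' Inverse of [formatKey()] (machine style). Malformed lines raise
#' `KeyParseError` with the offending line number; structural problems
#' (dangling couplet references, cycles) are caught by the key's validity
#' checks.
#'
#' @param x path to a key file, or the key text as a character vector when
#'   `text = TRUE`.
#' @param text treat `x` as literal text.
#' @return a [DichotomousKey-class].
#' @export
parseKey <- function(x, text = FALSE) {
  lines <- if (text) unlist(strsplit(x, "\n", fixed = TRUE)) else {
    if (!file.exists(x))
      rflpStop("MissingFile", sprintf("key file not found: %s", x))
    readLines(x)
  }
  enzyme <- NA_character_; region <- NA_character_
  tol <- 5L; minVis <- 40L
  couplets <- list()
  sawAny <- FALSE
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (!nzchar(line)) next
    if (startsWith(line, "#")) {
      grab <- function(k, cast = identity) {
        m <- regmatches(line, regexec(sprintf("%s=([^ ]+)", k), line))[[1L]]
        if (length(m) == 2L) cast(m[2L]) else NULL
      }
      enzyme <- grab("enzyme") %||% enzyme
      region <- grab("region") %||% region
      tol <- grab("tol", as.integer) %||% tol
      minVis <- grab("min_visible", as.integer) %||% minVis
      next
    }
    m <- regexec("^([0-9]+)\\((-|[0-9]+)\\)\\s+(.*)$", line)[[1L]]
    if (m[1L] == -1L)
      rflpStop("KeyParseError",
               sprintf("line %d: expected 'num(back) ...'", ln), line = ln)
    g <- regmatches(line, list(m))[[1L]]
    number <- as.integer(g[2L])
    backRef <- if (g[3L] == "-") NA_integer_ else as.integer(g[3L])
    halves <- strsplit(g[4L], " | ", fixed = TRUE)[[1L]]
    if (length(halves) != 2L)
      rflpStop("KeyParseError",
               sprintf("line %d: couplet needs exactly two leads", ln),
               line = ln)
    parseLead <- function(h) {
      parts <- strsplit(h, " -> ", fixed = TRUE)[[1L]]
      if (length(parts) != 2L)
        rflpStop("KeyParseError",
                 sprintf("line %d: lead needs 'feature -> consequent'", ln),
                 line = ln)
      cons <- trimws(parts[2L])
      list(feature = parseFeature(parts[1L], ln), consequent = cons,
           toCouplet = grepl("^[0-9]+$", cons))
    }
    la <- parseLead(halves[1L]); lb <- parseLead(halves[2L])
    couplets[[length(couplets) + 1L]] <- new("KeyCouplet",
      number = number, backRef = backRef,
      featureA = la$feature, featureB = lb$feature,
      consequentA = la$consequent, consequentB = lb$consequent,
      toCoupletA = la$toCouplet, toCoupletB = lb$toCouplet)
    sawAny <- TRUE
  }
  if (!sawAny)
    rflpStop("KeyParseError", "no couplets found", line = 0L)
  ord <- order(vapply(couplets, function(co) co@number, integer(1L)))
  new("DichotomousKey", couplets = couplets[ord],
      enzyme = enzyme, region = region,
      gel = gelModel(minVisible = minVis, coMigrationTol = tol))
}

#' The built-in key to North American Haemaphysalis ticks
#'
#' The published five-couplet key classifying DraI digests of the 438 bp
#' 16S rRNA amplicon to the four Haemaphysalis species found in North
#' America (H. longicornis, H. leporispalustris, H. juxtakochi,
#' H. chordeilis). Usable directly on observed band sizes without any
#' sequence data. Note the printed key's couplet 3 leaves two-band
#' patterns whose largest band falls between 300 and 400 bp uncovered;
#' such patterns classify as `"undetermined"` rather than being forced to
#' a species.
#'
#' @return a [DichotomousKey-class].
#' @examples
#' applyKey(naKey16S(), c(430, 120))$species
#' @export
naKey16S <- function() {
  parseKey(system.file("extdata", "na16s_key.txt", package = "rflpkit",
                       mustWork = TRUE))
}
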
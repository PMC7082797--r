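#' Configure a synthetic amplicon dataset
#'
#' Builds the ground-truth recipe consumed by [simulateAmplicons()].
#' Defaults mirror the geometry of the 16S assay (438 bp amplicons digested
#' with DraI), so simulated gels resemble the real ones.
#'
#' @param plantedPatterns named list: one element per species, each a list
#'   of integer fragment-length vectors (one per planted pattern), every
#'   vector summing to `ampliconLength`.
#' @param seqsPerSpecies sequences generated per species, distributed
#'   round-robin over that species' planted patterns.
#' @param ampliconLength amplicon length in bp.
#' @param substitutionRate per-site substitution probability outside
#'   protected windows.
#' @param maxMutations if set, overrides `substitutionRate`: each sequence
#'   gets k substitutions with k drawn uniformly from 0..`maxMutations`.
#' @param indelRate per-site indel probability outside protected windows.
#' @param sharedBackground generate one common random background for all
#'   species, so species differ only at their planted recognition sites
#'   (the right fixture for enzyme screening).
#' @param seed RNG seed; the dataset is byte-identical across runs with the
#'   same seed.
#' @return a [SyntheticConfig-class].
#' @examples
#' syntheticConfig(list("sp A" = list(c(200, 150, 88)),
#'                      "sp B" = list(438)), seqsPerSpecies = 5, seed = 42)
#' @export
syntheticConfig <- function(plantedPatterns, seqsPerSpecies = 10L,
                            ampliconLength = 438L, substitutionRate = 0,
                            maxMutations = NA_integer_, indelRate = 0,
                            sharedBackground = FALSE, seed = 1L) {
  if (!length(plantedPatterns))
    rflpStop("InfeasibleConfig", "at least one species is required")
  plantedPatterns <- lapply(plantedPatterns, function(pp) {
    if (is.numeric(pp)) pp <- list(pp)
    lapply(pp, as.integer)
  })
  new("SyntheticConfig", plantedPatterns = plantedPatterns,
      seqsPerSpecies = as.integer(seqsPerSpecies),
      ampliconLength = as.integer(ampliconLength),
      substitutionRate = as.numeric(substitutionRate),
      maxMutations = as.integer(maxMutations),
      indelRate = as.numeric(indelRate),
      sharedBackground = isTRUE(sharedBackground),
      seed = as.integer(seed))
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
withSeed <- function(seed, code) {
  hadSeed <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (hadSeed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

.randBases <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

# Concrete realization of an IUPAC string: each symbol replaced by a random
# member of its base set (a concrete base always strict-matches the symbol).
.concretize <- function(iupac) {
  bits <- iupacBits(iupac)
  vapply(bits, function(b) {
    opts <- c("A", "C", "G", "T")[bitwAnd(b, c(1L, 2L, 4L, 8L)) != 0L]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1L))
}

#' Generate a species-labeled synthetic amplicon set with known truth
#'
#' For each planted pattern of each species a master amplicon is built: the
#' forward primer's concrete sequence at the 5' end, the reverse
#' complement of the reverse primer at the 3' end, a concrete instance of
#' the enzyme's recognition site at every planted cut position, and random
#' background elsewhere. Rejection sampling removes chance occurrences of
#' the recognition site outside the planted windows, so the planted
#' fragment multiset is exact ground truth: with no mutation every
#' generated sequence digests to exactly its planted fragments. Per-
#' sequence substitutions/indels are then applied outside the protected
#' windows (primer-binding regions and planted sites); mutations can create
#' new sites -- that is intended intra-species noise, and the truth table
#' keeps the intended fragments.
#'
#' @param config a [SyntheticConfig-class].
#' @param enzyme the planted [RestrictionEnzyme-class]; default DraI.
#' @param pair the flanking [PrimerPair-class]; default the 16S pair.
#' @return list with `sequences` (labeled `DNAStringSet` ready for
#'   [amplifySet()]/[groupPatterns()]), `truth` (data.frame `id`,
#'   `species`, `pattern_index`, `intended_fragments`), and `masters`
#'   (named character vector of master amplicons).
#' @examples
#' cfg <- syntheticConfig(list(A = list(c(200, 150, 88)), B = list(438)),
#'                        seqsPerSpecies = 3, seed = 7)
#' sim <- simulateAmplicons(cfg)
#' fragments(digestLinear(sim$sequences[1], loadEnzymes()$DraI))
#' @export
simulateAmplicons <- function(config,
                              enzyme = loadEnzymes()$DraI,
                              pair = defaultPrimerPairs()[["16S"]]) {
  stopifnot(is(config, "SyntheticConfig"), is(enzyme, "RestrictionEnzyme"),
            is(pair, "PrimerPair"))
  L <- config@ampliconLength
  m <- nchar(enzyme@site)
  off <- enzyme@cutOffset
  fLen <- nchar(pair@forward@residues)
  rLen <- nchar(pair@reverse@residues)
  if (L < fLen + rLen + m)
    rflpStop("InfeasibleConfig",
             "amplicon shorter than primers plus one recognition site")

  # site windows implied by a fragment vector; errors on infeasible geometry
  windowsFor <- function(frags) {
    cuts <- cumsum(frags)
    cuts <- cuts[-length(cuts)]
    if (!length(cuts)) return(integer(0))
    starts <- cuts - off                      # 0-based window starts
    if (any(starts < fLen) || any(starts + m > L - rLen))
      rflpStop("InfeasibleConfig",
               "planted site would fall inside a primer-binding region")
    if (any(diff(starts) < m))
      rflpStop("InfeasibleConfig",
               "planted sites overlap; fragments too short for the site")
    starts
  }
  speciesNames <- names(config@plantedPatterns)
  winBySpPat <- lapply(config@plantedPatterns, function(pp)
    lapply(pp, windowsFor))

  withSeed(config@seed, {
    fwdConc <- .concretize(pair@forward@residues)
    revConc <- .concretize(revComp(pair@reverse@residues))
    siteInstanceAt <- function(starts)
      lapply(starts, function(s) .concretize(enzyme@site))

    primerIdx <- c(seq_len(fLen), (L - rLen + 1L):L)
    buildMaster <- function(background, starts, siteInst) {
      v <- background
      v[seq_len(fLen)] <- fwdConc
      v[(L - rLen + 1L):L] <- revConc
      for (k in seq_along(starts))
        v[(starts[k] + 1L):(starts[k] + m)] <- siteInst[[k]]
      v
    }
    # remove recognition-site occurrences whose cut is not planted by
    # re-randomizing nearby unprotected positions
    scrub <- function(v, plantedCuts, protected) {
      for (iter in seq_len(200L)) {
        cuts <- findSites(paste(v, collapse = ""), enzyme)
        extra <- setdiff(cuts, plantedCuts)
        if (!length(extra)) {
          if (!setequal(intersect(cuts, plantedCuts), plantedCuts))
            rflpStop("InfeasibleConfig",
                     "planted site destroyed by overlapping constraints")
          return(v)
        }
        for (cp in extra) {
          win <- max(1L, cp - m + 1L):min(L, cp + m)
          tgt <- setdiff(win, protected)
          if (!length(tgt))
            rflpStop("InfeasibleConfig",
                     "chance recognition site inside protected windows")
          v[tgt] <- .randBases(length(tgt))
        }
      }
      rflpStop("InfeasibleConfig",
               "could not purge chance recognition sites")
    }

    masters <- list()       # [[species]][[patternIndex]] = char vector
    if (config@sharedBackground) {
      allWins <- unlist(lapply(winBySpPat, function(ws)
        unlist(lapply(ws, function(st)
          if (length(st)) unlist(lapply(st, function(s) (s + 1L):(s + m)))
          else integer()))))
      protectedAll <- sort(unique(c(primerIdx, allWins)))
      background <- .randBases(L)
      for (iter in seq_len(200L)) {
        ok <- TRUE
        for (sp in speciesNames) {
          for (pi in seq_along(winBySpPat[[sp]])) {
            starts <- winBySpPat[[sp]][[pi]]
            inst <- lapply(starts, function(s) .concretize(enzyme@site))
            mv <- buildMaster(background, starts, inst)
            plantedCuts <- starts + off
            cuts <- findSites(paste(mv, collapse = ""), enzyme)
            extra <- setdiff(cuts, plantedCuts)
            if (length(extra)) {
              ok <- FALSE
              for (cp in extra) {
                win <- max(1L, cp - m + 1L):min(L, cp + m)
                tgt <- setdiff(win, protectedAll)
                if (!length(tgt))
                  rflpStop("InfeasibleConfig",
                           "chance recognition site inside protected windows")
                background[tgt] <- .randBases(length(tgt))
              }
            } else {
              masters[[sp]][[pi]] <- mv
            }
          }
        }
        if (ok) break
        if (iter == 200L)
          rflpStop("InfeasibleConfig",
                   "could not purge chance recognition sites")
        masters <- list()
      }
    } else {
      for (sp in speciesNames) {
        masters[[sp]] <- list()
        for (pi in seq_along(winBySpPat[[sp]])) {
          starts <- winBySpPat[[sp]][[pi]]
          inst <- siteInstanceAt(starts)
          protected <- sort(unique(c(primerIdx,
            if (length(starts)) unlist(lapply(starts, function(s)
              (s + 1L):(s + m))) else integer())))
          v <- buildMaster(.randBases(L), starts, inst)
          masters[[sp]][[pi]] <- scrub(v, starts + off, protected)
        }
      }
    }

    mutate <- function(v, protected) {
      free <- setdiff(seq_along(v), protected)
      if (length(free)) {
        if (!is.na(config@maxMutations)) {
          k <- sample(0:config@maxMutations, 1L)
          if (k > 0L) {
            pos <- sample(free, min(k, length(free)))
            for (p in pos)
              v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1L)
          }
        } else if (config@substitutionRate > 0) {
          hit <- free[stats::runif(length(free)) < config@substitutionRate]
          for (p in hit)
            v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1L)
        }
        if (config@indelRate > 0) {
          dels <- free[stats::runif(length(free)) < config@indelRate / 2]
          ins <- free[stats::runif(length(free)) < config@indelRate / 2]
          if (length(dels) || length(ins)) {
            keep <- setdiff(seq_along(v), dels)
            out <- character(0)
            for (p in keep) {
              out <- c(out, v[p])
              if (p %in% ins) out <- c(out, .randBases(1L))
            }
            v <- out
          }
        }
      }
      v
    }

    ids <- character(); spLab <- character(); patIdx <- integer()
    seqsOut <- character(); intended <- character()
    for (sp in speciesNames) {
      nPat <- length(winBySpPat[[sp]])
      for (k in seq_len(config@seqsPerSpecies)) {
        pi <- ((k - 1L) %% nPat) + 1L
        starts <- winBySpPat[[sp]][[pi]]
        protected <- sort(unique(c(primerIdx,
          if (length(starts)) unlist(lapply(starts, function(s)
            (s + 1L):(s + m))) else integer())))
        v <- mutate(masters[[sp]][[pi]], protected)
        id <- sprintf("%s_%02d", gsub("[^A-Za-z0-9]+", "_", sp), k)
        ids <- c(ids, id)
        spLab <- c(spLab, sp)
        patIdx <- c(patIdx, pi)
        seqsOut <- c(seqsOut, paste(v, collapse = ""))
        intended <- c(intended, paste(
          sort(config@plantedPatterns[[sp]][[pi]], decreasing = TRUE),
          collapse = ","))
      }
    }
    seqs <- Biostrings::DNAStringSet(seqsOut)
    names(seqs) <- ids
    S4Vectors::mcols(seqs) <- S4Vectors::DataFrame(
      species = spLab, region = rep("synthetic", length(ids)),
      topology = rep("linear", length(ids)))
    list(
      sequences = seqs,
      truth = data.frame(id = ids, species = spLab, pattern_index = patIdx,
                         intended_fragments = intended,
                         stringsAsFactors = FALSE),
      masters = vapply(unlist(masters, recursive = FALSE),
                       paste, character(1L), collapse = "")
    )
  })
}
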
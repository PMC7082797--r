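# Independent oracles and fixture generators. Everything here is written
# from first principles (regex scans, set tables) so it never shares code
# with the implementation under test.

# base sets of the 15 IUPAC codes, written out independently
ORACLE_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# reverse complement by letter table (independent of the package's)
oracleRevComp <- function(s) {
  comp <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                 "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", s)
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

# IUPAC site -> regex character classes
siteRegex <- function(site) {
  paste(vapply(strsplit(site, "")[[1]], function(ch)
    paste0("[", paste(ORACLE_SETS[[ch]], collapse = ""), "]"),
    character(1)), collapse = "")
}

# all 0-based start positions of (possibly overlapping) site occurrences
regexStarts <- function(seqText, site) {
  hits <- gregexpr(sprintf("(?=%s)", siteRegex(site)), seqText,
                   perl = TRUE)[[1]]
  if (hits[1] == -1) integer(0) else as.integer(hits) - 1L
}

# naive re-scan digestion oracle: both strands, blunt single-cut model
oracleFragments <- function(seqText, site, cutOffset) {
  n <- nchar(seqText)
  m <- nchar(site)
  cuts <- regexStarts(seqText, site) + cutOffset
  rc <- oracleRevComp(site)
  if (rc != site) cuts <- c(cuts, regexStarts(seqText, rc) + m - cutOffset)
  cuts <- sort(unique(cuts[cuts > 0 & cuts < n]))
  sort(diff(c(0L, cuts, n)), decreasing = TRUE)
}

# per-offset strict mismatch counts for a primer, by direct set comparison
oracleMismatch <- function(seqText, primerText) {
  tpl <- strsplit(seqText, "")[[1]]
  prm <- strsplit(primerText, "")[[1]]
  n <- length(tpl); k <- length(prm)
  if (k > n) return(integer(0))
  vapply(0:(n - k), function(s) {
    sum(vapply(seq_len(k), function(j) {
      !all(ORACLE_SETS[[tpl[s + j]]] %in% ORACLE_SETS[[prm[j]]])
    }, logical(1)))
  }, integer(1))
}

randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

randomIupac <- function(n) paste(sample(names(ORACLE_SETS), n,
                                        replace = TRUE), collapse = "")

randomEnzyme <- function(i) {
  len <- sample(c(4L, 6L), 1)
  restrictionEnzyme(paste0("Rnd", i), randomDna(len), sample(0:len, 1))
}

# visible-band computation written out independently of the gel module
oracleVisible <- function(frags, minVisible = 40, tol = 5) {
  v <- sort(frags[frags >= minVisible])
  if (!length(v)) return(integer(0))
  out <- integer(0); cur <- v[1]
  members <- v[1]
  for (x in v[-1]) {
    if (x - members[length(members)] <= tol) {
      members <- c(members, x)
    } else {
      out <- c(out, as.integer(round(mean(members))))
      members <- x
    }
  }
  out <- c(out, as.integer(round(mean(members))))
  sort(out, decreasing = TRUE)
}

# --- fixture generators -------------------------------------------------

# fragment vectors whose DraI-site geometry is always feasible in a 438 bp
# amplicon flanked by the 16S primers: cuts live on a coarse grid, keeping
# every fragment visible and every inter-pattern gap resolvable
gridFragments <- function(nCuts) {
  if (nCuts == 0) return(438L)
  cuts <- sort(sample(seq(60L, 380L, by = 40L), nCuts))
  as.integer(diff(c(0L, cuts, 438L)))
}

gelDistinct <- function(a, b, minVisible = 40, tol = 5) {
  va <- oracleVisible(a, minVisible, tol); vb <- oracleVisible(b, minVisible, tol)
  length(va) != length(vb) || any(abs(va - vb) > tol)
}

# a planted-pattern list for the simulator: per species 1..maxPat patterns,
# pairwise gel-distinct within each species
randomPlanted <- function(nSpecies, maxPat = 2) {
  out <- list()
  for (i in seq_len(nSpecies)) {
    nPat <- sample(seq_len(maxPat), 1)
    pats <- list()
    guard <- 0
    while (length(pats) < nPat) {
      cand <- gridFragments(sample(0:3, 1))
      if (all(vapply(pats, function(p) gelDistinct(p, cand), logical(1))))
        pats[[length(pats) + 1]] <- cand
      guard <- guard + 1
      if (guard > 200) break
    }
    out[[paste0("species_", i)]] <- pats
  }
  out
}

# random band patterns on a 30 bp grid: any two distinct patterns are
# separable under tol 5 (every rank gap is at least 30 > 2 * tol)
randomGridCatalog <- function(nSpecies, tol = 5) {
  seen <- character(0)
  pats <- list()
  for (i in seq_len(nSpecies)) {
    repeat {
      k <- sample(1:4, 1)
      b <- sort(sample(seq(50L, 430L, by = 30L), k), decreasing = TRUE)
      key <- paste(b, collapse = ",")
      if (!key %in% seen) { seen <- c(seen, key); break }
    }
    pats[[i]] <- rflpPattern(b, species = paste0("sp_", i),
                             enzyme = "DraI", region = "16S")
  }
  patternCatalog(pats, gel = gelModel(coMigrationTol = tol),
                 enzyme = "DraI", region = "16S")
}
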
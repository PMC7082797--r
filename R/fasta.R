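#' Read IUPAC DNA sequences from FASTA
#'
#' Reads a multi-record FASTA file (wrapped or unwrapped lines) into a
#' [Biostrings::DNAStringSet] whose metadata columns carry per-record
#' labels. Headers follow the dialect
#' \preformatted{>id [species=H. longicornis] [region=16S] [topology=circular]}
#' where every bracketed tag is optional; unrecognized bracketed tags are
#' ignored. Residues are case-folded to upper case and RNA `U` is converted
#' to `T`; gap characters are rejected (the toolkit digests unaligned
#' amplicons).
#'
#' Alternatively a two-column tab-separated sidecar (`id<TAB>species`) can
#' supply species labels for plain headers; see `speciesMap`.
#'
#' @param file path to a FASTA file, or a character vector of FASTA text
#'   when `text = TRUE`.
#' @param text logical; treat `file` as literal FASTA text.
#' @param speciesMap optional path to a tab-separated `id<TAB>species` file
#'   applied after parsing.
#' @return a `DNAStringSet`; `names()` hold ids, `mcols()` has columns
#'   `species`, `region`, `topology`.
#' @examples
#' fa <- parseFasta(c(">a [species=H. longicornis] [region=16S]", "TTTAAA"),
#'                  text = TRUE)
#' S4Vectors::mcols(fa)$species
#' @export
parseFasta <- function(file, text = FALSE, speciesMap = NULL) {
  if (text) {
    tf <- tempfile(fileext = ".fa")
    on.exit(unlink(tf), add = TRUE)
    writeLines(file, tf)
    file <- tf
  }
  if (!file.exists(file))
    rflpStop("MissingFile", sprintf("file not found: %s", file))
  raw <- Biostrings::readBStringSet(file)
  if (length(raw) == 0L)
    rflpStop("EmptyInput", sprintf("no FASTA records in %s", file))
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  if (any(!nzchar(ids)))
    rflpStop("EmptyInput", "FASTA record with empty id")
  if (anyDuplicated(ids))
    rflpStop("DuplicateId",
             sprintf("duplicate id \"%s\"", ids[duplicated(ids)][1L]))
  tag <- function(h, key) {
    m <- regmatches(h, regexec(sprintf("\\[%s=([^]]*)\\]", key), h))[[1L]]
    if (length(m) == 2L) m[2L] else NA_character_
  }
  species  <- vapply(headers, tag, character(1L), key = "species",
                     USE.NAMES = FALSE)
  region   <- vapply(headers, tag, character(1L), key = "region",
                     USE.NAMES = FALSE)
  topology <- vapply(headers, tag, character(1L), key = "topology",
                     USE.NAMES = FALSE)
  topology[is.na(topology)] <- "linear"
  if (!all(topology %in% c("linear", "circular")))
    rflpStop("BadTopology", "topology must be 'linear' or 'circular'")
  res <- normalizeResidues(as.character(raw))
  for (i in seq_along(res)) {
    if (!nzchar(res[i]))
      rflpStop("EmptyInput", sprintf("record \"%s\" has no residues", ids[i]))
    assertIupac(res[i], ids[i])
  }
  out <- Biostrings::DNAStringSet(res)
  names(out) <- ids
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    species = species, region = region, topology = topology
  )
  if (!is.null(speciesMap)) out <- applySpeciesMap(out, speciesMap)
  out
}

#' Apply a sidecar id-to-species map
#'
#' @param seqs a `DNAStringSet` from [parseFasta()].
#' @param file tab-separated file with columns `id` and `species` (no
#'   header).
#' @return `seqs` with the `species` metadata column filled in.
#' @export
applySpeciesMap <- function(seqs, file) {
  map <- utils::read.table(file, sep = "\t", header = FALSE,
                           col.names = c("id", "species"),
                           colClasses = "character", quote = "")
  idx <- match(names(seqs), map$id)
  hit <- !is.na(idx)
  S4Vectors::mcols(seqs)$species[hit] <- map$species[idx[hit]]
  seqs
}

#' Write sequences to FASTA with bracketed label tags
#'
#' Inverse of [parseFasta()]: species/region tags and non-default topology
#' are re-emitted as bracketed header tags so a parse/write cycle preserves
#' records exactly.
#'
#' @param seqs a `DNAStringSet` with the metadata columns used by
#'   [parseFasta()] (missing columns are treated as unlabeled).
#' @param file output path.
#' @param width residues per line.
#' @return `file`, invisibly.
#' @export
writeFasta <- function(seqs, file, width = 70L) {
  mc <- S4Vectors::mcols(seqs)
  getcol <- function(nm) {
    if (!is.null(mc) && nm %in% colnames(mc)) mc[[nm]]
    else rep(NA_character_, length(seqs))
  }
  species <- getcol("species"); region <- getcol("region")
  topology <- getcol("topology")
  headers <- vapply(seq_along(seqs), function(i) {
    h <- names(seqs)[i]
    if (!is.na(species[i])) h <- paste0(h, " [species=", species[i], "]")
    if (!is.na(region[i]))  h <- paste0(h, " [region=", region[i], "]")
    if (!is.na(topology[i]) && topology[i] != "linear")
      h <- paste0(h, " [topology=", topology[i], "]")
    h
  }, character(1L))
  con <- file(file, "w")
  on.exit(close(con))
  seqc <- as.character(seqs)
  for (i in seq_along(seqc)) {
    writeLines(paste0(">", headers[i]), con)
    s <- seqc[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(file)
}
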
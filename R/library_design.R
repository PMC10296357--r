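# Library design: turn coding sequences into the tiled 51-nt / 17-aa
# peptide library with vector-complementary flanks for synthesis.

GENETIC_CODE_STD <- Biostrings::GENETIC_CODE

translateCDS <- function(cds) {
  as.character(Biostrings::translate(Biostrings::DNAStringSet(cds),
                                     no.init.codon = TRUE))
}

#' Strip a terminal stop codon from a CDS
#'
#' Peptide tiles are expressed as N-terminal fusions to a reporter, so the
#' terminal stop codon of each coding sequence is removed before tiling.
#' Sequences not ending in TAA/TAG/TGA are returned unchanged.
#'
#' @param cds Character vector of ACGT coding sequences, lengths multiples
#'   of 3.
#' @return Character vector with terminal stop codons removed.
#' @examples
#' stripTerminalStop("ATGAAATAA")  # "ATGAAA"
#' @export
stripTerminalStop <- function(cds) {
  if (any(nchar(cds) %% 3L != 0L))
    stop("CDS length must be a multiple of 3")
  last <- substr(cds, nchar(cds) - 2L, nchar(cds))
  ifelse(last %in% STOP_CODONS, substr(cds, 1L, nchar(cds) - 3L), cds)
}

validateCDS <- function(cds, id = "cds") {
  if (!grepl("^[ACGT]+$", cds))
    stop("CDS for '", id, "' contains non-ACGT characters")
  if (nchar(cds) %% 3L != 0L)
    stop("CDS for '", id, "' is not a multiple of 3 after stop removal")
  aa <- translateCDS(cds)
  if (grepl("\\*", aa))
    stop("CDS for '", id, "' contains an internal stop codon")
  if (grepl("[^ACDEFGHIKLMNPQRSTVWY]", aa))
    stop("protein '", id, "' contains non-standard residues (e.g. U/X); ",
         "only the 20 standard amino acids are supported")
  aa
}

#' Tile one coding sequence into 51-nt library fragments
#'
#' Fragments start every `stepNT` nucleotides (default 15 nt = 5 codons)
#' so that consecutive tiles overlap by `tileNT - stepNT` = 36 nt
#' (12 residues). By default the tail of a CDS whose length minus 51 is
#' not a multiple of 15 is not covered; with `anchorFinal = TRUE` one
#' extra tile anchored at the 3' end is emitted and flagged.
#'
#' @param cds A single ACGT coding sequence (terminal stop allowed; it is
#'   stripped before tiling).
#' @param proteinId Identifier used in tile names.
#' @param tileNT Tile length in nucleotides (default 51).
#' @param stepNT Step between tile starts (default 15).
#' @param anchorFinal Emit a 3'-anchored remainder tile when the regular
#'   grid does not reach the end of the CDS.
#' @return A [TileSet].
#' @examples
#' ts <- tileCDS(strrep("ATGAAATTTGGGCCCTAG", 5), "toy")
#' length(ts)
#' @export
tileCDS <- function(cds, proteinId = "protein", tileNT = 51L, stepNT = 15L,
                    anchorFinal = FALSE) {
  stopifnot(length(cds) == 1L, tileNT %% 3L == 0L, stepNT %% 3L == 0L)
  cds <- stripTerminalStop(toupper(cds))
  validateCDS(cds, proteinId)
  L <- nchar(cds)
  if (L < tileNT)
    stop("protein too short: CDS of '", proteinId, "' has ", L,
         " nt after stop removal; need at least ", tileNT)
  starts <- seq.int(0L, L - tileNT, by = stepNT)
  anchored <- rep(FALSE, length(starts))
  if (anchorFinal && (L - tileNT) %% stepNT != 0L) {
    starts <- c(starts, L - tileNT)
    anchored <- c(anchored, TRUE)
  }
  dna <- substring(cds, starts + 1L, starts + tileNT)
  tl <- DataFrame(
    peptide_id = sprintf("%s_t%03d", proteinId, seq_along(starts) - 1L),
    protein_id = proteinId,
    tile_index = seq_along(starts) - 1L,
    nt_start = as.integer(starts),
    aa_start = as.integer(starts %/% 3L),
    dna = dna,
    peptide = translateCDS(dna),
    anchored_final = anchored)
  new("TileSet", tiles = tl)
}

#' Tile a set of coding sequences
#'
#' @param cdsSet Named character vector (or `DNAStringSet`) of coding
#'   sequences; names become protein ids.
#' @inheritParams tileCDS
#' @param skipShort Skip (with a warning) proteins shorter than one tile
#'   instead of failing.
#' @return A [TileSet] covering all proteins.
#' @export
tileLibrary <- function(cdsSet, tileNT = 51L, stepNT = 15L,
                        anchorFinal = FALSE, skipShort = FALSE) {
  if (methods::is(cdsSet, "DNAStringSet")) cdsSet <- as.character(cdsSet)
  if (is.null(names(cdsSet)) || anyDuplicated(names(cdsSet)))
    stop("cdsSet must have unique names (protein ids)")
  parts <- lapply(names(cdsSet), function(id) {
    res <- tryCatch(tileCDS(cdsSet[[id]], id, tileNT, stepNT, anchorFinal),
                    error = function(e) e)
    if (inherits(res, "error")) {
      if (skipShort && grepl("protein too short", conditionMessage(res))) {
        warning(conditionMessage(res), call. = FALSE)
        return(NULL)
      }
      stop(res)
    }
    res@tiles
  })
  new("TileSet", tiles = do.call(rbind, parts[!vapply(parts, is.null,
                                                      logical(1))]))
}

#' Add synthesis flanks to library tiles
#'
#' Each 51-nt insert is flanked 5' and 3' by primer-binding regions
#' complementary to the expression vector, yielding the full-length
#' synthesized oligo. Stripping the flanks recovers the insert exactly.
#'
#' @param tiles A [TileSet].
#' @param flank5,flank3 Non-empty ACGT flank sequences; defaults are the
#'   vector-side primer anchors.
#' @return Named character vector of oligo sequences
#'   (`flank5 || dna || flank3`), names = `peptide_id`.
#' @export
addFlanks <- function(tiles, flank5 = DEFAULT_FLANK5,
                      flank3 = DEFAULT_FLANK3) {
  stopifnot(is(tiles, "TileSet"))
  if (length(tiles) == 0L) stop("empty TileSet")
  for (fl in c(flank5, flank3))
    if (!nzchar(fl) || !grepl("^[ACGT]+$", fl))
      stop("flanks must be non-empty ACGT sequences")
  setNames(paste0(flank5, tiles@tiles$dna, flank3), tiles@tiles$peptide_id)
}

#' Recover tile inserts from oligos by stripping known flanks
#'
#' @param oligos Character vector of oligo sequences.
#' @inheritParams addFlanks
#' @return Character vector of inserts.
#' @export
stripFlanks <- function(oligos, flank5 = DEFAULT_FLANK5,
                        flank3 = DEFAULT_FLANK3) {
  if (!all(startsWith(oligos, flank5) & endsWith(oligos, flank3)))
    stop("some oligos do not carry the expected flanks")
  substring(oligos, nchar(flank5) + 1L, nchar(oligos) - nchar(flank3))
}

#' Read coding sequences from a FASTA file
#'
#' @param path FASTA file of CDS records.
#' @return Named character vector of sequences.
#' @export
readCDSFasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  as.character(x)
}

#' Write the oligo pool and tile manifest
#'
#' Writes `<prefix>_oligos.fasta` (flanked oligos) and `<prefix>_tiles.tsv`
#' (the tile manifest read back by [readTileManifest()]).
#'
#' @param tiles A [TileSet].
#' @param prefix Output path prefix.
#' @inheritParams addFlanks
#' @return Invisibly, the two file paths.
#' @export
writeLibrary <- function(tiles, prefix, flank5 = DEFAULT_FLANK5,
                         flank3 = DEFAULT_FLANK3) {
  oligos <- addFlanks(tiles, flank5, flank3)
  fa <- paste0(prefix, "_oligos.fasta")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(oligos), fa)
  tsv <- paste0(prefix, "_tiles.tsv")
  writeTileManifest(tiles, tsv)
  invisible(c(oligos = fa, tiles = tsv))
}

#' @rdname writeLibrary
#' @param path Manifest TSV path.
#' @export
writeTileManifest <- function(tiles, path) {
  write.table(as.data.frame(tiles@tiles), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeLibrary
#' @export
readTileManifest <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c(peptide_id = "character",
                                  protein_id = "character",
                                  dna = "character",
                                  peptide = "character"))
  new("TileSet", tiles = as(df, "DataFrame"))
}
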
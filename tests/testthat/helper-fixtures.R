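# Shared fixture builders: random coding sequences, toy libraries and
# small simulated screens. Everything is generated in code at test time.

CODONS_BY_AA <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), gc)[degronScan::AA_ALPHABET20]
})

# random in-frame CDS of nAA residues (no stop codons)
randomCDS <- function(nAA) {
  aa <- sample(degronScan::AA_ALPHABET20, nAA, replace = TRUE)
  paste(vapply(aa, function(r) sample(CODONS_BY_AA[[r]], 1L),
               character(1)), collapse = "")
}

randomDNA <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# library of nTiles distinct random 51-mers wrapped as a TileSet
randomTileSet <- function(nTiles, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dna <- unique(replicate(nTiles * 2L, randomDNA(51L)))[seq_len(nTiles)]
  tilesFromDNA(dna)
}

# wrap arbitrary 51-mers (possibly duplicated) into a valid TileSet
tilesFromDNA <- function(dna, protein_id = sprintf("p%04d", seq_along(dna))) {
  n <- length(dna)
  new("TileSet", tiles = S4Vectors::DataFrame(
    peptide_id = sprintf("%s_t000", protein_id),
    protein_id = protein_id,
    tile_index = rep(0L, n),
    nt_start = rep(0L, n),
    aa_start = rep(0L, n),
    dna = dna,
    peptide = vapply(dna, function(s) as.character(
      Biostrings::translate(Biostrings::DNAString(s))), character(1),
      USE.NAMES = FALSE),
    anchored_final = rep(FALSE, n)))
}

# substitute one base at position pos
mutateAt <- function(seq, pos, to = NULL) {
  old <- substr(seq, pos, pos)
  if (is.null(to)) to <- setdiff(c("A", "C", "G", "T"), old)[1]
  substr(seq, pos, pos) <- to
  seq
}

# small complete simulated screen used by several module tests
smallScreen <- function(nProteins = 6L, readsPerBin = 3e4, seed = 42L,
                        ...) {
  cfg <- simConfig(nProteins = nProteins, readsPerBin = readsPerBin,
                   seed = seed, ...)
  cds <- generateProteome(cfg)
  tiles <- tileLibrary(cds, skipShort = TRUE)
  sim <- simulateBins(tiles, cfg)
  list(cfg = cfg, cds = cds, tiles = tiles, counts = sim$counts,
       truth = sim$truth)
}

# ScreenCounts built directly from a raw count matrix
countsFromMatrix <- function(raw) {
  tiles <- randomTileSet(nrow(raw), seed = 99L)
  rownames(raw) <- tileTable(tiles)$peptide_id
  colnames(raw) <- paste0("gate", 1:4)
  degronScan:::newScreenCounts(raw, tileTable(tiles))
}
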
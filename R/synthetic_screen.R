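# Synthetic-screen simulator: proteins, latent degron strengths from a
# known weight vector, multinomial FACS-bin read counts, and raw reads.
# Everything downstream of sequencing is testable against the ground truth
# this module records.

#' Ground-truth amino-acid weights used by the default simulation
#'
#' Hydrophobic residues (L, I, V, F, W, Y, M, C) destabilize (positive
#' weight), charged residues (D, E, K, R) stabilize (negative weight),
#' mirroring the hydrophobicity preference of quality-control degrons.
#' Magnitudes are per-residue log-odds contributions.
#' @return Named numeric vector over the 20 amino acids.
#' @export
defaultTrueWeights <- function() {
  w <- setNames(numeric(20), AA_ALPHABET20)
  w[c("L", "I", "F", "W", "V", "M", "Y", "C")] <-
    c(0.50, 0.45, 0.45, 0.40, 0.35, 0.30, 0.30, 0.25)
  w[c("D", "E", "K", "R")] <- c(-0.50, -0.45, -0.30, -0.25)
  w[c("N", "Q", "S", "T", "P", "A")] <-
    c(-0.10, -0.10, -0.05, -0.05, -0.20, 0.10)
  w
}

#' Configuration of a synthetic screen
#'
#' @param nProteins Number of random proteins.
#' @param proteinLengthRange Integer `c(min, max)` protein length in
#'   residues.
#' @param trueWeights Named numeric over the 20 amino acids: ground-truth
#'   per-residue degron log-odds.
#' @param trueIntercept Ground-truth intercept of the degron logit.
#' @param cellsPerPeptide Expected number of sorted cells carrying each
#'   library member.
#' @param readsPerBin Sequencing reads drawn per FACS gate.
#' @param readErrorRate Per-base substitution probability in emitted
#'   reads.
#' @param sigma Gaussian jitter (PSI units) of a cell's latent score
#'   around its peptide's true PSI before gating.
#' @param binBoundaries Three increasing thresholds cutting the latent
#'   score into gates 1..4.
#' @param flank5,flank3 Read prefix/suffix emulating vector-side
#'   amplicon sequence.
#' @param seed Integer seed fixing all simulator randomness.
#' @return A list of class `SimConfig`.
#' @export
simConfig <- function(nProteins = 20L,
                      proteinLengthRange = c(100L, 300L),
                      trueWeights = defaultTrueWeights(),
                      trueIntercept = -1.5,
                      cellsPerPeptide = 200L,
                      readsPerBin = 1e5,
                      readErrorRate = 0.001,
                      sigma = 0.5,
                      binBoundaries = c(1.75, 2.5, 3.25),
                      flank5 = DEFAULT_FLANK5,
                      flank3 = DEFAULT_FLANK3,
                      seed = 1L) {
  stopifnot(length(proteinLengthRange) == 2L,
            proteinLengthRange[1] <= proteinLengthRange[2],
            proteinLengthRange[1] >= 17L)
  if (!identical(sort(names(trueWeights)), AA_ALPHABET20))
    stop("trueWeights must be named by the 20 standard amino acids")
  if (length(binBoundaries) != 3L || any(diff(binBoundaries) <= 0))
    stop("binBoundaries must be 3 strictly increasing thresholds")
  if (readErrorRate < 0 || readErrorRate >= 1)
    stop("readErrorRate must be in [0, 1)")
  if (cellsPerPeptide <= 0 || readsPerBin <= 0)
    stop("cellsPerPeptide and readsPerBin must be positive")
  structure(list(nProteins = as.integer(nProteins),
                 proteinLengthRange = as.integer(proteinLengthRange),
                 trueWeights = trueWeights[AA_ALPHABET20],
                 trueIntercept = trueIntercept,
                 cellsPerPeptide = as.integer(cellsPerPeptide),
                 readsPerBin = readsPerBin,
                 readErrorRate = readErrorRate,
                 sigma = sigma,
                 binBoundaries = binBoundaries,
                 flank5 = flank5, flank3 = flank3,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

# Codons per amino acid (standard code, stops excluded)
codonsByAA <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), gc)[AA_ALPHABET20]
}

#' Generate a random proteome with matching coding sequences
#'
#' Amino acids are drawn uniformly; each CDS codon is drawn uniformly
#' among the synonymous codons of its residue. Fully reproducible from
#' `cfg$seed`.
#'
#' @param cfg A [simConfig()].
#' @return Named character vector of CDS (no stop codons); the attribute
#'   `"aa"` carries the protein sequences.
#' @export
generateProteome <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  codons <- codonsByAA()
  lens <- sample(seq.int(cfg$proteinLengthRange[1],
                         cfg$proteinLengthRange[2]),
                 cfg$nProteins, replace = TRUE)
  aa <- vapply(lens, function(L)
    paste(sample(AA_ALPHABET20, L, replace = TRUE), collapse = ""),
    character(1))
  cds <- vapply(aa, function(s) {
    res <- strsplit(s, "")[[1]]
    paste(vapply(res, function(r) {
      cc <- codons[[r]]
      cc[sample.int(length(cc), 1L)]
    }, character(1)), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  names(cds) <- sprintf("sim%04d", seq_along(cds))
  attr(cds, "aa") <- setNames(aa, names(cds))
  cds
}

#' True degron probability of peptides under a ground-truth model
#'
#' `plogis(intercept + sum over residues of w[aa])` for each peptide.
#' @param peptides Character vector of peptide sequences.
#' @param weights Named per-residue weights.
#' @param intercept Intercept.
#' @return Numeric vector of probabilities.
#' @export
trueDegronProbability <- function(peptides, weights, intercept) {
  counts <- peptideCompositionMatrix(peptides)
  as.numeric(stats::plogis(intercept + counts %*% weights[AA_ALPHABET20]))
}

#' Simulate four-gate FACS sorting and sequencing counts
#'
#' Each peptide's true degron probability `p` maps to a latent stability
#' index `PSI_true = 4 - 3 p`. Every sorted cell carrying the peptide
#' draws a Gaussian jitter (`cfg$sigma`) around `PSI_true` and falls into
#' one of four gates cut at `cfg$binBoundaries`. Per gate, sequencing
#' reads are a multinomial draw over peptides proportional to that gate's
#' cell counts, totalling `cfg$readsPerBin` reads.
#'
#' @param tiles A [TileSet].
#' @param cfg A [simConfig()].
#' @return A list with `counts` (a [ScreenCounts-class]) and `truth`
#'   (DataFrame: `peptide_id`, `p_true`, `psi_true`).
#' @export
simulateBins <- function(tiles, cfg) {
  stopifnot(is(tiles, "TileSet"), inherits(cfg, "SimConfig"))
  if (length(tiles) == 0L) stop("tiles must be non-empty")
  set.seed(cfg$seed + 1L)
  tl <- tileTable(tiles)
  p <- trueDegronProbability(tl$peptide, cfg$trueWeights, cfg$trueIntercept)
  psiTrue <- 4 - 3 * p
  # gate probabilities per peptide: N(psi_true, sigma) cut at boundaries
  b <- cfg$binBoundaries
  cum <- vapply(b, function(th) pnorm(th, mean = psiTrue, sd = cfg$sigma),
                numeric(length(psiTrue)))
  if (length(psiTrue) == 1L) cum <- matrix(cum, nrow = 1L)
  gateP <- cbind(cum[, 1], cum[, 2] - cum[, 1], cum[, 3] - cum[, 2],
                 1 - cum[, 3])
  nPep <- nrow(tl)
  cells <- matrix(0L, nPep, 4L)
  for (i in seq_len(nPep))
    cells[i, ] <- as.integer(rmultinom(1L, cfg$cellsPerPeptide, gateP[i, ]))
  raw <- matrix(0L, nPep, 4L,
                dimnames = list(tl$peptide_id, paste0("gate", 1:4)))
  for (g in 1:4) {
    tot <- sum(cells[, g])
    if (tot > 0)
      raw[, g] <- as.integer(rmultinom(1L, cfg$readsPerBin, cells[, g]))
  }
  counts <- newScreenCounts(raw, tl)
  truth <- DataFrame(peptide_id = tl$peptide_id, p_true = p,
                     psi_true = psiTrue)
  list(counts = counts, truth = truth)
}

newScreenCounts <- function(raw, tileDF) {
  se <- SummarizedExperiment(
    assays = list(raw = raw),
    rowData = tileDF[match(rownames(raw), tileDF$peptide_id), , drop = FALSE],
    colData = DataFrame(gate = 1:4, row.names = paste0("gate", 1:4)))
  new("ScreenCounts", se)
}

#' Emit raw reads from simulated bin counts
#'
#' Each read is `flank5 || tile dna || flank3` with independent per-base
#' substitution errors at `cfg$readErrorRate`. The multiset size per gate
#' equals the gate's raw counts.
#'
#' @param counts A [ScreenCounts-class] from [simulateBins()].
#' @param tiles The [TileSet] the counts refer to.
#' @param cfg A [simConfig()].
#' @param shuffle Randomize read order within each gate (counting must be
#'   order-invariant; kept optional for reproducible toy examples).
#' @return List of 4 character vectors of reads, one per gate.
#' @export
emitReads <- function(counts, tiles, cfg, shuffle = TRUE) {
  stopifnot(is(counts, "ScreenCounts"), is(tiles, "TileSet"))
  set.seed(cfg$seed + 2L)
  dna <- tileDNA(tiles)[rownames(counts)]
  raw <- assay(counts, "raw")
  lapply(1:4, function(g) {
    reads <- rep(paste0(cfg$flank5, dna, cfg$flank3), raw[, g])
    if (length(reads) && shuffle) reads <- sample(reads)
    mutateReads(reads, cfg$readErrorRate)
  })
}

# Vectorized per-base substitution noise: draw the number of errors per
# read from Binomial(len, rate), then mutate only the affected reads.
mutateReads <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0L) return(reads)
  len <- nchar(reads)
  nerr <- rbinom(length(reads), len, rate)
  hit <- which(nerr > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    pos <- sample.int(len[i], nerr[i])
    for (p in pos) {
      old <- substr(reads[i], p, p)
      substr(reads[i], p, p) <- sample(setdiff(bases, old), 1L)
    }
  }
  reads
}

#' Write a simulated screen to disk
#'
#' Writes the library FASTA + manifest, ground truth TSV, raw count TSV
#' and per-bin FASTQ files (constant quality scores).
#'
#' @param sim Result of [simulateBins()].
#' @param tiles The simulated [TileSet].
#' @param cfg The [simConfig()] used.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of paths written.
#' @export
writeScreenData <- function(sim, tiles, cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- writeLibrary(tiles, file.path(dir, "library"),
                        cfg$flank5, cfg$flank3)
  truthPath <- file.path(dir, "ground_truth.tsv")
  write.table(as.data.frame(sim$truth), truthPath, sep = "\t",
              quote = FALSE, row.names = FALSE)
  countsPath <- file.path(dir, "raw_counts.tsv")
  writeCountTable(sim$counts, countsPath)
  reads <- emitReads(sim$counts, tiles, cfg)
  fq <- vapply(1:4, function(g) {
    p <- file.path(dir, sprintf("bin%d.fastq", g))
    writeFastq(reads[[g]], p, prefix = sprintf("bin%d_read", g))
    p
  }, character(1))
  invisible(c(paths, truth = truthPath, counts = countsPath,
              setNames(fq, paste0("bin", 1:4))))
}

writeFastq <- function(reads, path, prefix = "read") {
  if (length(reads) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- sprintf("%s%07d", prefix, seq_along(reads))
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(
                                strrep("I", nchar(reads))))
  invisible(path)
}
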
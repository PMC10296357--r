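# Protein Stability Index: frequency-weighted mean FACS-gate number per
# peptide, projected onto protein residues and smoothed with a running
# median.

#' Protein Stability Index of one frequency vector
#'
#' `PSI = sum(g * f_g) / sum(f_g)` over gates g = 1..4, where `f_g` is
#' the (normalized) read frequency of the peptide at gate g. The result
#' lies in [1, 4]; low PSI means destabilizing (degron-like).
#'
#' @param f Numeric vector of 4 non-negative per-gate frequencies, or a
#'   matrix with 4 columns (one row per peptide).
#' @return PSI value(s).
#' @examples
#' computePSI(c(1, 1, 1, 1))  # 2.5
#' computePSI(c(3, 1, 0, 0))  # 1.25
#' @export
computePSI <- function(f) {
  if (is.matrix(f)) {
    stopifnot(ncol(f) == 4L)
    if (any(f < 0)) stop("frequencies must be non-negative")
    tot <- rowSums(f)
    if (any(tot == 0)) stop("PSI undefined for all-zero frequency rows")
    return(as.numeric(f %*% (1:4)) / unname(tot))
  }
  stopifnot(length(f) == 4L)
  if (any(f < 0)) stop("frequencies must be non-negative")
  if (sum(f) == 0) stop("PSI undefined for all-zero frequencies")
  sum((1:4) * f) / sum(f)
}

#' Per-peptide PSI table from a normalized count table
#'
#' One row per peptide with at least one raw read; peptides absent from
#' all gates are omitted (their number is reported as an attribute).
#' Frequencies are the per-gate normalized values (each non-empty gate
#' scaled to 1e6 total reads), so PSI weighs gates equally regardless of
#' per-gate sequencing depth; `total_reads` is the raw total used by the
#' downstream read-count filter.
#'
#' @param counts A [ScreenCounts-class]; [normalizeBins()] is applied if
#'   assay `"normalized"` is missing.
#' @return [S4Vectors::DataFrame] with `peptide_id`, `protein_id`,
#'   `psi`, `total_reads`, `f1..f4`.
#' @export
psiTable <- function(counts) {
  stopifnot(is(counts, "ScreenCounts"))
  if (!"normalized" %in% assayNames(counts))
    counts <- normalizeBins(counts)
  raw <- assay(counts, "raw")
  norm <- assay(counts, "normalized")
  keep <- rowSums(raw) > 0
  norm <- norm[keep, , drop = FALSE]
  out <- DataFrame(
    peptide_id = rownames(norm),
    protein_id = rowData(counts)$protein_id[keep],
    psi = computePSI(norm),
    total_reads = as.integer(rowSums(raw)[keep]),
    f1 = norm[, 1], f2 = norm[, 2], f3 = norm[, 3], f4 = norm[, 4])
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Running median with missing-value support
#'
#' `out[i]` is the median of the defined values among positions
#' `i - (w-1)/2 .. i + (w-1)/2`, the window truncated at the sequence
#' ends. Positions that are `NA` on input stay `NA` on output; `NA`
#' neighbors are skipped, not propagated.
#'
#' @param x Numeric vector, `NA` for missing.
#' @param window Odd window width (default 5, i.e. plus/minus two).
#' @return Numeric vector, same length as `x`.
#' @export
runningMedian <- function(x, window = 5L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be a positive odd integer")
  n <- length(x)
  if (n == 0L) return(x)
  h <- (window - 1L) %/% 2L
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(x[i])) next
    win <- x[max(1L, i - h):min(n, i + h)]
    out[i] <- median(win, na.rm = TRUE)
  }
  out
}

#' Project peptide PSI values onto protein residues
#'
#' Two tracks: `central` places each tile's PSI at the tile's central
#' residue (position 9 of the 17-mer); `coverage-mean` (default) gives
#' each residue the mean PSI over all scored tiles containing it.
#' Uncovered residues are `NA`. The raw track is smoothed with
#' [runningMedian()].
#'
#' @param psis PSI table from [psiTable()].
#' @param tiles The [TileSet] providing tile coordinates.
#' @param track `"coverage-mean"` or `"central"`.
#' @param window Running-median window (odd; default 5).
#' @param proteinLengths Optional named vector of protein lengths in
#'   residues; defaults to the extent covered by the tiling (last tile's
#'   `aa_start` + 17).
#' @return [S4Vectors::DataFrame] with `protein_id`, `position`
#'   (1-based), `raw`, `smoothed`, `coverage` (scored tiles per residue).
#' @export
residueProfiles <- function(psis, tiles, track = c("coverage-mean", "central"),
                            window = 5L, proteinLengths = NULL) {
  track <- match.arg(track)
  stopifnot(is(tiles, "TileSet"))
  tl <- tileTable(tiles)
  m <- match(psis$peptide_id, tl$peptide_id)
  if (anyNA(m))
    stop("peptides without tile coordinates: ",
         paste(head(psis$peptide_id[is.na(m)]), collapse = ", "))
  dat <- data.frame(protein_id = tl$protein_id[m],
                    aa_start = tl$aa_start[m], psi = psis$psi)
  parts <- lapply(split(dat, dat$protein_id), function(d) {
    pid <- d$protein_id[1]
    L <- if (!is.null(proteinLengths)) proteinLengths[[pid]]
         else max(d$aa_start) + 17L
    raw <- rep(NA_real_, L)
    cov <- integer(L)
    if (track == "central") {
      pos <- d$aa_start + 9L          # 1-based central residue
      agg <- tapply(d$psi, pos, mean)
      raw[as.integer(names(agg))] <- as.numeric(agg)
      cnt <- tapply(d$psi, pos, length)
      cov[as.integer(names(cnt))] <- as.integer(cnt)
    } else {
      sums <- numeric(L)
      for (k in seq_len(nrow(d))) {
        span <- (d$aa_start[k] + 1L):min(d$aa_start[k] + 17L, L)
        sums[span] <- sums[span] + d$psi[k]
        cov[span] <- cov[span] + 1L
      }
      raw[cov > 0] <- sums[cov > 0] / cov[cov > 0]
    }
    DataFrame(protein_id = pid, position = seq_len(L), raw = raw,
              smoothed = runningMedian(raw, window), coverage = cov)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Write per-peptide PSI and per-residue tracks as TSV
#'
#' @param psis PSI table from [psiTable()].
#' @param path Output TSV path.
#' @return Invisibly `path`.
#' @export
writePsiTable <- function(psis, path) {
  write.table(as.data.frame(psis), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writePsiTable
#' @param profiles Residue profiles from [residueProfiles()].
#' @export
writeResidueProfiles <- function(profiles, path) {
  write.table(as.data.frame(profiles), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
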
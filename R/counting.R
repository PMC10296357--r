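# Read trimming, single-mismatch matching against the tile library, and
# per-bin counting with 1e6-reads/bin normalization.
#
# The 1-mismatch lookup uses the pigeonhole principle: a 51-mer within
# Hamming distance 1 of a library member matches at least one of the
# member's two halves exactly, so two half-sequence hash maps replace the
# enumeration of all 153 point mutants per query. A brute-force full
# Hamming scan (bruteForceMatch) is kept as the independent test oracle.

#' Trim a read down to its 51-nt candidate insert
#'
#' Two modes. `fixedLength`: drop a constant-length prefix and keep the
#' next `insertLength` bases. `anchor`: locate the first exact occurrence
#' of the configured vector flank and keep the `insertLength` bases that
#' follow it. Reads where the insert cannot be recovered (anchor absent,
#' read too short) yield `NA` and are later counted as unmatched, not
#' errors.
#'
#' @param reads Character vector of read sequences.
#' @param anchor Anchor sequence for anchor mode (default: the 5' vector
#'   flank).
#' @param fixedLength If non-`NULL`, use fixed-length mode with this
#'   prefix length instead of anchor mode.
#' @param insertLength Insert length to recover (default 51).
#' @return Character vector of inserts, `NA` where trimming failed.
#' @export
trimPrefix <- function(reads, anchor = DEFAULT_FLANK5, fixedLength = NULL,
                       insertLength = 51L) {
  if (!is.null(fixedLength)) {
    out <- substring(reads, fixedLength + 1L, fixedLength + insertLength)
  } else {
    at <- regexpr(anchor, reads, fixed = TRUE)
    start <- ifelse(at > 0L, at + nchar(anchor), NA_integer_)
    out <- substring(reads, start, start + insertLength - 1L)
  }
  out[is.na(out) | nchar(out) < insertLength] <- NA_character_
  out
}

#' Build a single-mismatch match index over a tile library
#'
#' Identical DNA inserts from different tiles are collapsed into one
#' index entry carrying all member `peptide_id`s; matched counts are
#' later replicated into each member's row, flagged `shared`.
#'
#' @param tiles A [TileSet].
#' @return A `MatchIndex` list (opaque; pass to [matchReads()] /
#'   [countBins()]).
#' @export
buildMatchIndex <- function(tiles) {
  stopifnot(is(tiles, "TileSet"))
  tl <- tileTable(tiles)
  if (any(!grepl("^[ACGT]+$", tl$dna)))
    stop("library contains non-ACGT characters")
  L <- unique(nchar(tl$dna))
  if (length(L) != 1L) stop("all library inserts must share one length")
  dnaU <- unique(tl$dna)
  groupOf <- match(tl$dna, dnaU)
  members <- split(tl$peptide_id, groupOf)   # group id -> peptide_ids
  half <- L %/% 2L
  h1 <- substring(dnaU, 1L, half)
  h2 <- substring(dnaU, half + 1L, L)
  exact <- new.env(hash = TRUE, parent = emptyenv())
  half1 <- new.env(hash = TRUE, parent = emptyenv())
  half2 <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(dnaU)) {
    assign(dnaU[i], i, envir = exact)
    half1[[h1[i]]] <- c(half1[[h1[i]]], i)
    half2[[h2[i]]] <- c(half2[[h2[i]]], i)
  }
  idx <- list(dna = dnaU, members = members, exact = exact,
              half1 = half1, half2 = half2, half = half, len = L,
              tiles = tl)
  idx$hasNeighbor <- vapply(seq_along(dnaU), function(i) {
    cand <- setdiff(candidateGroups(idx, dnaU[i], h1[i], h2[i]), i)
    any(hammingTo(dnaU[cand], dnaU[i]) <= 1L)
  }, logical(1))
  class(idx) <- "MatchIndex"
  idx
}

hammingTo <- function(seqs, query) {
  if (length(seqs) == 0L) return(integer(0))
  q <- utf8ToInt(query)
  vapply(seqs, function(s) sum(utf8ToInt(s) != q), integer(1),
         USE.NAMES = FALSE)
}

candidateGroups <- function(idx, query, q1 = NULL, q2 = NULL) {
  if (is.null(q1)) q1 <- substring(query, 1L, idx$half)
  if (is.null(q2)) q2 <- substring(query, idx$half + 1L, idx$len)
  unique(c(idx$half1[[q1]], idx$half2[[q2]]))
}

# Core per-query lookup: returns list(status, group, mismatches).
lookupOne <- function(idx, query, policy) {
  if (is.na(query) || nchar(query) != idx$len ||
      grepl("[^ACGT]", query))
    return(list(status = "unmatched", group = NA_integer_,
                mismatches = NA_integer_))
  g0 <- idx$exact[[query]]
  if (!is.null(g0)) {
    # exact hit; ambiguous only if another member sits within distance 1
    # and the policy does not prefer the closer match
    if (idx$hasNeighbor[g0] && policy == "drop")
      return(list(status = "ambiguous", group = NA_integer_,
                  mismatches = NA_integer_))
    return(list(status = "unique", group = g0, mismatches = 0L))
  }
  cand <- candidateGroups(idx, query)
  d <- hammingTo(idx$dna[cand], query)
  hit <- cand[d <= 1L]
  if (length(hit) == 0L)
    return(list(status = "unmatched", group = NA_integer_,
                mismatches = NA_integer_))
  if (length(hit) == 1L)
    return(list(status = "unique", group = hit,
                mismatches = min(d[d <= 1L])))
  list(status = "ambiguous", group = NA_integer_,
       mismatches = NA_integer_)
}

#' Match reads (or trimmed inserts) against the library
#'
#' @param queries Character vector of candidate 51-nt inserts (`NA`
#'   allowed; counts as unmatched).
#' @param index A `MatchIndex` from [buildMatchIndex()].
#' @param policy `"drop"` (default): any query with two or more library
#'   members within Hamming distance 1 is ambiguous and discarded.
#'   `"keep-best"`: an exact (0-mismatch) hit beats distance-1 neighbors.
#' @return `data.frame` with `status` (`unique`/`ambiguous`/`unmatched`),
#'   `group` (index entry), `peptide_id` (first member id, `NA` unless
#'   unique) and `mismatches` (0 or 1, `NA` unless unique).
#' @export
matchReads <- function(queries, index, policy = c("drop", "keep-best")) {
  policy <- match.arg(policy)
  n <- length(queries)
  status <- character(n); group <- integer(n); mm <- integer(n)
  # vectorized fast path: exact hits with no distance-1 neighbor
  exactHit <- match(queries, index$dna)
  fast <- !is.na(exactHit) & !index$hasNeighbor[pmax(exactHit, 1L)]
  status[fast] <- "unique"; group[fast] <- exactHit[fast]; mm[fast] <- 0L
  for (i in which(!fast)) {
    r <- lookupOne(index, queries[i], policy)
    status[i] <- r$status
    group[i] <- r$group
    mm[i] <- r$mismatches
  }
  data.frame(
    status = status,
    group = group,
    peptide_id = vapply(group, function(g)
      if (is.na(g)) NA_character_ else index$members[[g]][1L], character(1)),
    mismatches = mm)
}

#' Brute-force Hamming matcher (test oracle)
#'
#' Scans the whole library per query; same status/assignment policy as
#' [matchReads()]. Quadratic; for verification only.
#' @inheritParams matchReads
#' @return As [matchReads()].
#' @export
bruteForceMatch <- function(queries, index, policy = c("drop", "keep-best")) {
  policy <- match.arg(policy)
  res <- lapply(queries, function(q) {
    if (is.na(q) || nchar(q) != index$len || grepl("[^ACGT]", q))
      return(list("unmatched", NA_integer_, NA_integer_))
    d <- hammingTo(index$dna, q)
    hit <- which(d <= 1L)
    if (length(hit) == 0L) return(list("unmatched", NA_integer_, NA_integer_))
    if (length(hit) == 1L) return(list("unique", hit, d[hit]))
    if (policy == "keep-best" && sum(d == min(d[hit])) == 1L && min(d) == 0L)
      return(list("unique", which.min(d), 0L))
    list("ambiguous", NA_integer_, NA_integer_)
  })
  group <- vapply(res, function(r) r[[2]], integer(1))
  data.frame(
    status = vapply(res, function(r) r[[1]], character(1)),
    group = group,
    peptide_id = vapply(group, function(g)
      if (is.na(g)) NA_character_ else index$members[[g]][1L], character(1)),
    mismatches = vapply(res, function(r) r[[3]], integer(1)))
}

#' Count uniquely matched reads per peptide and FACS gate
#'
#' Trims each gate's reads, matches them with at most one mismatch, and
#' tabulates unique matches. Counts of a collapsed duplicate-DNA group
#' are replicated into each member tile's row (`rowData(x)$shared`
#' flags these rows). Match statistics per gate (unique / ambiguous /
#' unmatched fractions) are stored in `metadata(x)$match_stats`.
#'
#' @param readsByGate List of 4 character vectors of reads (gates 1..4);
#'   empty gates allowed (all-zero column, with a warning).
#' @param index `MatchIndex` from [buildMatchIndex()].
#' @param trim `NULL` to match reads as-is (already trimmed), or a list
#'   passed to [trimPrefix()]: `list(anchor=)` or `list(fixedLength=)`.
#' @param policy Ambiguity policy, see [matchReads()].
#' @return A [ScreenCounts-class] with assay `"raw"`.
#' @export
countBins <- function(readsByGate, index, trim = list(),
                      policy = c("drop", "keep-best")) {
  policy <- match.arg(policy)
  stopifnot(length(readsByGate) == 4L)
  tl <- index$tiles
  groupOf <- match(tl$dna, index$dna)
  raw <- matrix(0L, nrow(tl), 4L,
                dimnames = list(tl$peptide_id, paste0("gate", 1:4)))
  stats <- matrix(0, 4L, 3L,
                  dimnames = list(paste0("gate", 1:4),
                                  c("unique", "ambiguous", "unmatched")))
  for (g in 1:4) {
    reads <- readsByGate[[g]]
    if (length(reads) == 0L) {
      warning("gate ", g, " has no reads; column left at zero")
      next
    }
    inserts <- if (is.null(trim)) reads
               else do.call(trimPrefix, c(list(reads), trim))
    # collapse duplicate inserts: match each distinct string once
    isna <- is.na(inserts)
    tab <- table(inserts[!isna])
    qs <- names(tab)
    multK <- as.integer(tab)
    m <- matchReads(qs, index, policy)
    uniq <- m$status == "unique"
    if (any(uniq)) {
      byGroup <- tapply(multK[uniq], m$group[uniq], sum)
      gidx <- as.integer(names(byGroup))
      for (k in seq_along(gidx))
        raw[groupOf == gidx[k], g] <- as.integer(byGroup[k])
    }
    stats[g, "unique"] <- sum(multK[uniq])
    stats[g, "ambiguous"] <- sum(multK[m$status == "ambiguous"])
    stats[g, "unmatched"] <- sum(multK[m$status == "unmatched"]) + sum(isna)
  }
  shared <- vapply(index$members[groupOf], length, integer(1)) > 1L
  tl$shared <- shared
  out <- newScreenCounts(raw, tl)
  metadata(out)$match_stats <- stats
  metadata(out)$policy <- policy
  out
}

#' Normalize each gate to one million reads
#'
#' Adds assay `"normalized"` with `raw * 1e6 / colSums(raw)` per gate.
#' Gates with zero total stay zero and are recorded in
#' `metadata(x)$empty_gates`.
#'
#' @param counts A [ScreenCounts-class].
#' @return The [ScreenCounts-class] with assay `"normalized"`.
#' @export
normalizeBins <- function(counts) {
  stopifnot(is(counts, "ScreenCounts"))
  raw <- assay(counts, "raw")
  totals <- colSums(raw)
  if (all(totals == 0)) stop("all four gates are empty; nothing to normalize")
  norm <- sweep(raw, 2L, pmax(totals, 1), "/") * 1e6
  norm[, totals == 0] <- 0
  assay(counts, "normalized", withDimnames = FALSE) <- norm
  metadata(counts)$empty_gates <- which(totals == 0)
  if (any(totals == 0))
    warning("empty gate(s): ", paste(which(totals == 0), collapse = ", "))
  counts
}

#' Read one bin's reads from FASTQ or a plain sequence list
#'
#' @param path File path; `.fastq`/`.fq` (optionally `.gz`) parsed as
#'   FASTQ (qualities ignored), anything else as one sequence per line.
#' @return Character vector of reads.
#' @export
readBinReads <- function(path) {
  if (grepl("\\.(fastq|fq)(\\.gz)?$", path)) {
    if (file.size(path) == 0L) return(character(0))
    as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
  } else {
    x <- readLines(path)
    x[nzchar(x)]
  }
}

#' Write / read a peptide-by-gate count table as TSV
#'
#' Columns: `peptide_id`, `protein_id`, raw counts `gate1..gate4`, and,
#' when present, `norm1..norm4`.
#' @param counts A [ScreenCounts-class].
#' @param path TSV path.
#' @return Invisibly `path`; `readCountTable()` returns a
#'   [ScreenCounts-class].
#' @export
writeCountTable <- function(counts, path) {
  raw <- assay(counts, "raw")
  df <- data.frame(peptide_id = rownames(raw),
                   protein_id = rowData(counts)$protein_id,
                   raw, check.names = FALSE)
  if ("normalized" %in% assayNames(counts)) {
    norm <- assay(counts, "normalized")
    colnames(norm) <- paste0("norm", 1:4)
    df <- cbind(df, norm)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCountTable
#' @export
readCountTable <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c(peptide_id = "character",
                                  protein_id = "character"))
  raw <- as.matrix(df[, paste0("gate", 1:4)])
  rownames(raw) <- df$peptide_id
  out <- newScreenCounts(raw, DataFrame(peptide_id = df$peptide_id,
                                        protein_id = df$protein_id))
  if (all(paste0("norm", 1:4) %in% colnames(df))) {
    norm <- as.matrix(df[, paste0("norm", 1:4)])
    dimnames(norm) <- dimnames(raw)
    assay(out, "normalized", withDimnames = FALSE) <- norm
  }
  out
}
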
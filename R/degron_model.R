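# Composition-based ridge logistic degron predictor: PSI-derived binary
# labels -> 20 residue weights + intercept -> per-residue degron
# probability tracks and degron region calls.

#' Encode 17-mer peptides as amino-acid composition vectors
#'
#' Order-free composition features: residue counts (default) or
#' frequencies (counts / 17). Any permutation of a peptide encodes
#' identically.
#'
#' @param peptides Character vector of 17-residue peptides (standard
#'   alphabet).
#' @param mode `"counts"` or `"freqs"`.
#' @return Numeric matrix, one row per peptide, 20 alphabetical residue
#'   columns.
#' @export
encodePeptides <- function(peptides, mode = c("counts", "freqs")) {
  mode <- match.arg(mode)
  if (any(nchar(peptides) != 17L))
    stop("peptides must be exactly 17 residues")
  m <- peptideCompositionMatrix(peptides)
  if (mode == "freqs") m <- m / 17
  m
}

# Residue-count matrix over the 20-letter alphabet (any peptide length);
# rejects non-standard residues.
peptideCompositionMatrix <- function(peptides) {
  bad <- grepl(paste0("[^", paste(AA_ALPHABET20, collapse = ""), "]"),
               peptides)
  if (any(bad))
    stop("non-standard residues in peptide(s): ",
         paste(head(peptides[bad], 3), collapse = ", "))
  m <- Biostrings::letterFrequency(
    Biostrings::AAStringSet(peptides), AA_ALPHABET20)
  colnames(m) <- AA_ALPHABET20
  m
}

#' Build the training set from PSI-labeled peptides
#'
#' Peptides with fewer than `minReads` raw reads summed over the four
#' gates are filtered out. Remaining peptides with PSI below `lo` are
#' labeled unstable (1, degron); PSI above `hi` stable (0); mid-range
#' PSI values (including the two boundary values exactly) are omitted to
#' reduce label noise.
#'
#' @param psis PSI table from [psiTable()].
#' @param peptides Named character vector mapping `peptide_id` to its
#'   17-mer (e.g. `tilePeptides(tiles)`).
#' @param minReads Minimum combined raw reads (default 50).
#' @param lo,hi PSI label thresholds (defaults 2.2 / 2.8).
#' @return `data.frame` with `peptide_id`, `peptide`, `label`, `psi`,
#'   `total_reads`; attributes `n_low_reads`, `n_midrange`,
#'   `n_boundary` record the filtered counts.
#' @export
buildTrainingSet <- function(psis, peptides, minReads = 50L,
                             lo = 2.2, hi = 2.8) {
  stopifnot(lo < hi)
  pep <- peptides[psis$peptide_id]
  if (anyNA(pep))
    stop("missing peptide sequences for some PSI records")
  enough <- psis$total_reads >= minReads
  psi <- psis$psi
  label <- ifelse(psi < lo, 1L, ifelse(psi > hi, 0L, NA_integer_))
  keep <- enough & !is.na(label)
  out <- data.frame(peptide_id = psis$peptide_id[keep],
                    peptide = unname(pep[keep]),
                    label = label[keep],
                    psi = psi[keep],
                    total_reads = psis$total_reads[keep])
  if (sum(out$label == 1L) == 0L || sum(out$label == 0L) == 0L)
    stop("training set degenerate after filtering: ",
         sum(out$label == 1L), " unstable / ", sum(out$label == 0L),
         " stable peptides")
  attr(out, "n_low_reads") <- sum(!enough)
  attr(out, "n_midrange") <- sum(enough & is.na(label))
  attr(out, "n_boundary") <- sum(enough & (psi == lo | psi == hi))
  out
}

#' Train the ridge logistic degron model
#'
#' Minimizes mean logistic loss plus `lambda/2 * ||w||^2` (intercept
#' unpenalized) by full Newton iteration — deterministic and independent
#' of training-row order. The ridge term keeps weights finite even on
#' separable data.
#'
#' @param trainingSet From [buildTrainingSet()] (or any data.frame with
#'   `peptide` and `label` columns).
#' @param lambda Ridge strength (default 0.001).
#' @param featureMode `"counts"` (default) or `"freqs"`.
#' @param tol Convergence threshold on the max-norm of the penalized
#'   gradient.
#' @param maxIter Newton iteration cap.
#' @return A [DegronModel-class].
#' @export
trainDegronModel <- function(trainingSet, lambda = 0.001,
                             featureMode = c("counts", "freqs"),
                             tol = 1e-10, maxIter = 100L) {
  featureMode <- match.arg(featureMode)
  X <- encodePeptides(trainingSet$peptide, featureMode)
  y <- as.numeric(trainingSet$label)
  stopifnot(all(y %in% c(0, 1)))
  if (!any(y == 1) || !any(y == 0))
    stop("both classes must be present")
  fit <- ridgeLogisticNewton(X, y, lambda, tol, maxIter)
  if (!fit$converged)
    stop("Newton optimizer did not converge in ", maxIter,
         " iterations; final gradient norm ", fit$grad_norm)
  new("DegronModel",
      weights = setNames(fit$w, AA_ALPHABET20),
      intercept = fit$b, lambda = lambda, featureMode = featureMode,
      fit = list(iterations = fit$iterations, grad_norm = fit$grad_norm,
                 converged = fit$converged,
                 n_pos = sum(y == 1), n_neg = sum(y == 0)))
}

# Newton solver for: mean_i log(1 + exp(-s_i * eta_i)) + lambda/2 ||w||^2
# with eta = b + X w, s = 2y - 1. Penalty excludes the intercept.
ridgeLogisticNewton <- function(X, y, lambda, tol = 1e-10, maxIter = 100L) {
  n <- nrow(X); p <- ncol(X)
  Z <- cbind(1, X)
  beta <- numeric(p + 1L)
  pen <- c(0, rep(lambda, p))
  for (it in seq_len(maxIter)) {
    eta <- as.numeric(Z %*% beta)
    mu <- stats::plogis(eta)
    grad <- as.numeric(crossprod(Z, mu - y)) / n + pen * beta
    gnorm <- max(abs(grad))
    if (gnorm <= tol)
      return(list(b = unname(beta[1]), w = unname(beta[-1]),
                  iterations = it - 1L, grad_norm = gnorm,
                  converged = TRUE))
    wts <- mu * (1 - mu)
    H <- crossprod(Z, Z * wts) / n + diag(pen)
    step <- solve(H, grad)
    # halving line search guards rare overshoot on near-separable data
    obj0 <- mean(log1p(exp(-(2 * y - 1) * eta))) +
      lambda / 2 * sum(beta[-1]^2)
    alpha <- 1
    repeat {
      cand <- beta - alpha * step
      etaC <- as.numeric(Z %*% cand)
      objC <- mean(log1p(exp(-(2 * y - 1) * etaC))) +
        lambda / 2 * sum(cand[-1]^2)
      if (objC <= obj0 || alpha < 1e-8) break
      alpha <- alpha / 2
    }
    beta <- beta - alpha * step
  }
  eta <- as.numeric(Z %*% beta)
  mu <- stats::plogis(eta)
  grad <- as.numeric(crossprod(Z, mu - y)) / n + pen * beta
  list(b = unname(beta[1]), w = unname(beta[-1]), iterations = maxIter,
       grad_norm = max(abs(grad)), converged = max(abs(grad)) <= tol)
}

# Penalized objective, exposed for finite-difference checks in tests.
ridgeLogisticLoss <- function(beta, X, y, lambda) {
  eta <- as.numeric(cbind(1, X) %*% beta)
  mean(log1p(exp(-(2 * y - 1) * eta))) + lambda / 2 * sum(beta[-1]^2)
}

#' Degron probability of 17-mer peptides
#'
#' `plogis(intercept + w . encode(peptide))`; strictly inside (0, 1).
#'
#' @param object A [DegronModel-class].
#' @param peptides Character vector of 17-mers.
#' @param ... Unused.
#' @return Numeric vector of probabilities.
#' @export
setMethod("predict", "DegronModel", function(object, peptides, ...) {
  X <- encodePeptides(peptides, object@featureMode)
  as.numeric(stats::plogis(object@intercept + X %*% object@weights))
})

#' Scan a protein for per-residue degron probability
#'
#' Residue i (1-based) receives the model probability of the 17-mer
#' centered on it, defined for i in 9 .. L-8; the terminal eight
#' residues per end carry no prediction. Optionally a cubic smoothing
#' spline over the defined positions is added as a `smoothed` column.
#'
#' @param model A [DegronModel-class].
#' @param aaSeq Protein sequence (single string, length >= 17).
#' @param proteinId Identifier for the output table.
#' @param spline Add a smoothing-spline track (default `FALSE`; the
#'   discrete track is canonical).
#' @return [S4Vectors::DataFrame] with `protein_id`, `position`,
#'   `probability` (`NA` at undefined ends) and optionally `smoothed`.
#' @export
scanProtein <- function(model, aaSeq, proteinId = "protein",
                        spline = FALSE) {
  stopifnot(is(model, "DegronModel"), length(aaSeq) == 1L)
  L <- nchar(aaSeq)
  if (L < 17L) stop("protein shorter than one 17-mer window")
  starts <- 1:(L - 16L)
  windows <- substring(aaSeq, starts, starts + 16L)
  prob <- rep(NA_real_, L)
  prob[starts + 8L] <- predict(model, windows)
  out <- DataFrame(protein_id = proteinId, position = seq_len(L),
                   probability = prob)
  if (spline) {
    def <- which(!is.na(prob))
    sm <- rep(NA_real_, L)
    if (length(def) >= 4L) {
      fitted <- stats::smooth.spline(def, prob[def])
      sm[def] <- stats::predict(fitted, def)$y
    } else sm[def] <- prob[def]
    out$smoothed <- sm
  }
  out
}

#' Call degron regions from a probability profile
#'
#' Maximal runs of consecutive defined residues with probability strictly
#' above `cutoff`; runs shorter than `minLength` are dropped.
#'
#' @param profile Output of [scanProtein()] (one protein).
#' @param cutoff Probability cutoff (default 0.85).
#' @param minLength Minimum run length in residues (default 1).
#' @return `data.frame` with `protein_id`, `start`, `end` (1-based
#'   inclusive), `length`, `peak_probability`, `cutoff`.
#' @export
callDegrons <- function(profile, cutoff = 0.85, minLength = 1L) {
  p <- profile$probability
  above <- !is.na(p) & p > cutoff
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= minLength
  out <- data.frame(
    protein_id = rep(profile$protein_id[1], sum(keep)),
    start = profile$position[starts[keep]],
    end = profile$position[ends[keep]],
    length = r$lengths[keep],
    peak_probability = vapply(which(keep), function(k)
      max(p[starts[k]:ends[k]]), numeric(1)),
    cutoff = rep(cutoff, sum(keep)))
  rownames(out) <- NULL
  out
}

#' Scan a whole proteome and call degrons
#'
#' @param model A [DegronModel-class].
#' @param proteome Named character vector of protein sequences.
#' @param cutoff Degron probability cutoff (default 0.85).
#' @param minLength Minimum degron length.
#' @return List with `profiles` (rbind of [scanProtein()] tables) and
#'   `calls` (rbind of [callDegrons()] tables). Proteins shorter than 17
#'   residues are skipped with a warning.
#' @export
scanProteome <- function(model, proteome, cutoff = 0.85, minLength = 1L) {
  stopifnot(!is.null(names(proteome)))
  profs <- list(); calls <- list()
  for (id in names(proteome)) {
    if (nchar(proteome[[id]]) < 17L) {
      warning("skipping '", id, "': shorter than 17 residues")
      next
    }
    pr <- scanProtein(model, proteome[[id]], id)
    profs[[id]] <- pr
    calls[[id]] <- callDegrons(pr, cutoff, minLength)
  }
  list(profiles = do.call(rbind, unname(profs)),
       calls = do.call(rbind, unname(calls)))
}

#' Serialize / restore a degron model as JSON
#'
#' The JSON object carries per-residue weights, intercept, lambda,
#' feature mode and training metadata.
#'
#' @param model A [DegronModel-class].
#' @param path JSON file path.
#' @return Invisibly `path`; `readDegronModel()` returns the
#'   [DegronModel-class].
#' @export
writeDegronModel <- function(model, path) {
  jsonlite::write_json(
    list(weights = as.list(model@weights), intercept = model@intercept,
         lambda = model@lambda, feature_mode = model@featureMode,
         fit = model@fit),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeDegronModel
#' @export
readDegronModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("DegronModel",
      weights = setNames(as.numeric(x$weights[AA_ALPHABET20]),
                         AA_ALPHABET20),
      intercept = x$intercept, lambda = x$lambda,
      featureMode = x$feature_mode,
      fit = as.list(x$fit))
}

#' Write degron calls as a BED-like TSV
#'
#' On-disk coordinates are 0-based half-open (`start0`, `end`), the
#' in-memory tables stay 1-based inclusive.
#' @param calls From [callDegrons()] / [scanProteome()].
#' @param path TSV path.
#' @return Invisibly `path`.
#' @export
writeDegronCalls <- function(calls, path) {
  bed <- data.frame(protein_id = calls$protein_id,
                    start0 = calls$start - 1L, end = calls$end,
                    peak_probability = calls$peak_probability)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
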
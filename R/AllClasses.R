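#' TileSet: a tiled peptide library
#'
#' Container for the tiles of one or more proteins. Each tile is a 51-nt
#' fragment of a coding sequence translating to a 17-residue peptide;
#' consecutive tiles advance 15 nt (5 residues) and therefore overlap by
#' 36 nt (12 residues). An optional 3'-anchored remainder tile covers the
#' final residues when the CDS length minus 51 is not a multiple of 15.
#'
#' Columns of the underlying [S4Vectors::DataFrame]: `peptide_id`
#' (unique tile identifier `<protein>_t<index>`), `protein_id`,
#' `tile_index` (0-based), `nt_start` and `aa_start` (0-based offsets into
#' the CDS / protein), `dna` (51 nt), `peptide` (17 aa), and
#' `anchored_final` (logical).
#'
#' @slot tiles A [S4Vectors::DataFrame] with one row per tile.
#' @seealso [tileCDS()], [tileLibrary()], [addFlanks()]
#' @export
setClass("TileSet", slots = c(tiles = "DFrame"))

setValidity("TileSet", function(object) {
  tl <- object@tiles
  need <- c("peptide_id", "protein_id", "tile_index", "nt_start",
            "aa_start", "dna", "peptide", "anchored_final")
  if (!all(need %in% colnames(tl)))
    return(paste("missing tile columns:",
                 paste(setdiff(need, colnames(tl)), collapse = ", ")))
  if (nrow(tl) == 0L) return(TRUE)
  if (any(nchar(tl$dna) != 51L)) return("all tile dna must be 51 nt")
  if (any(nchar(tl$peptide) != 17L)) return("all tile peptides must be 17 aa")
  if (any(tl$nt_start %% 3L != 0L)) return("nt_start must be in frame")
  if (any(tl$aa_start * 3L != tl$nt_start))
    return("aa_start must equal nt_start/3")
  if (anyDuplicated(tl$peptide_id)) return("peptide_id must be unique")
  TRUE
})

#' ScreenCounts: peptide-by-gate read counts
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one row per library
#' peptide and four columns, one per FACS gate (gates ordered 1..4 from
#' low to high reporter ratio). Assay `"raw"` holds integer read counts;
#' after [normalizeBins()] assay `"normalized"` holds reads-per-million
#' style values in which each non-empty gate column sums to 1e6.
#'
#' @seealso [countBins()], [normalizeBins()], [psiTable()]
#' @export
setClass("ScreenCounts", contains = "SummarizedExperiment")

setValidity("ScreenCounts", function(object) {
  if (ncol(object) != 4L) return("ScreenCounts must have exactly 4 gates")
  if (!"raw" %in% assayNames(object)) return("assay 'raw' is required")
  raw <- assay(object, "raw")
  if (any(raw < 0)) return("raw counts must be non-negative")
  if (!"gate" %in% colnames(colData(object)))
    return("colData must carry a 'gate' column")
  if (!identical(as.integer(colData(object)$gate), 1:4))
    return("gates must be 1,2,3,4 in order")
  TRUE
})

#' DegronModel: composition-based ridge logistic degron predictor
#'
#' Logistic regression on amino-acid composition of 17-mers with an L2
#' (ridge) penalty on the 20 residue weights (intercept unpenalized).
#' `predict()` maps a peptide to a degron probability
#' `plogis(intercept + sum(w[aa] * count[aa]))`.
#'
#' @slot weights Named numeric of length 20 (alphabetical residue order).
#' @slot intercept Numeric scalar.
#' @slot lambda Ridge penalty strength on the mean-loss scale.
#' @slot featureMode `"counts"` (residue counts, default) or `"freqs"`
#'   (counts/17).
#' @slot fit List of optimizer diagnostics (iterations, gradient norm,
#'   convergence flag) and training-set summary.
#' @seealso [trainDegronModel()], [scanProtein()], [callDegrons()]
#' @export
setClass("DegronModel",
         slots = c(weights = "numeric", intercept = "numeric",
                   lambda = "numeric", featureMode = "character",
                   fit = "list"))

setValidity("DegronModel", function(object) {
  if (!identical(names(object@weights), AA_ALPHABET20))
    return("weights must be named by the 20 amino acids in alphabetical order")
  if (length(object@intercept) != 1L || !is.finite(object@intercept))
    return("intercept must be a finite scalar")
  if (length(object@lambda) != 1L || object@lambda < 0)
    return("lambda must be a non-negative scalar")
  if (!object@featureMode %in% c("counts", "freqs"))
    return("featureMode must be 'counts' or 'freqs'")
  if (any(!is.finite(object@weights))) return("weights must be finite")
  TRUE
})

#' @describeIn TileSet number of tiles
#' @param x,object A `TileSet`.
#' @export
setMethod("length", "TileSet", function(x) nrow(x@tiles))

#' @describeIn TileSet the tile table as a [S4Vectors::DataFrame]
#' @export
setGeneric("tileTable", function(x) standardGeneric("tileTable"))

#' @rdname TileSet
#' @export
setMethod("tileTable", "TileSet", function(x) x@tiles)

#' @describeIn TileSet tile peptides as a named character vector
#' @export
setGeneric("tilePeptides", function(x) standardGeneric("tilePeptides"))

#' @rdname TileSet
#' @export
setMethod("tilePeptides", "TileSet", function(x)
  setNames(x@tiles$peptide, x@tiles$peptide_id))

#' @describeIn TileSet tile DNA inserts as a named character vector
#' @export
setGeneric("tileDNA", function(x) standardGeneric("tileDNA"))

#' @rdname TileSet
#' @export
setMethod("tileDNA", "TileSet", function(x)
  setNames(x@tiles$dna, x@tiles$peptide_id))

setMethod("show", "TileSet", function(object) {
  tl <- object@tiles
  cat("TileSet with", nrow(tl), "tiles over",
      length(unique(tl$protein_id)), "protein(s)\n")
  if (nrow(tl) > 0) {
    cat("  tile length 51 nt / 17 aa, step 15 nt;",
        sum(tl$anchored_final), "3'-anchored remainder tile(s)\n")
    show(head(as.data.frame(tl), 4))
  }
})

#' @describeIn DegronModel residue weights of the fitted model
#' @export
setMethod("weights", "DegronModel", function(object, ...) object@weights)

#' @describeIn DegronModel intercept of the fitted model
#' @export
setGeneric("intercept", function(object) standardGeneric("intercept"))

#' @rdname DegronModel
#' @export
setMethod("intercept", "DegronModel", function(object) object@intercept)

setMethod("show", "DegronModel", function(object) {
  cat("DegronModel (ridge logistic regression on amino-acid composition)\n")
  cat("  lambda:", object@lambda, " features:", object@featureMode, "\n")
  cat("  intercept:", format(object@intercept, digits = 4), "\n")
  w <- sort(object@weights, decreasing = TRUE)
  cat("  top destabilizing:",
      paste(sprintf("%s=%.3f", names(w)[1:3], w[1:3]), collapse = " "), "\n")
  cat("  top stabilizing:  ",
      paste(sprintf("%s=%.3f", rev(names(w))[1:3], rev(w)[1:3]),
            collapse = " "), "\n")
  if (length(object@fit))
    cat("  trained on", object@fit$n_pos, "degron /", object@fit$n_neg,
        "stable peptides; grad norm",
        format(object@fit$grad_norm, digits = 3), "\n")
})
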
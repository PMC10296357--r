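# Degron characterization: Kyte-Doolittle hydropathy vs degron
# probability, torsion-rule secondary structure, and Shrake-Rupley
# accessible surface area with a Mann-Whitney degron-vs-proteome
# comparison.

#' Mean Kyte-Doolittle hydropathy of peptides
#'
#' Per-residue hydropathy values are summed and divided by peptide
#' length.
#' @param peptides Character vector of peptide sequences (standard
#'   alphabet).
#' @return Numeric vector of mean hydropathy scores.
#' @examples
#' kdScore(strrep("I", 17))  # 4.5
#' @export
kdScore <- function(peptides) {
  counts <- peptideCompositionMatrix(peptides)
  as.numeric(counts %*% KYTE_DOOLITTLE[AA_ALPHABET20]) / nchar(peptides)
}

#' Peptide hydropathy versus predicted degron probability
#'
#' @param peptides Character vector of 17-mers.
#' @param model A [DegronModel-class].
#' @return `data.frame` with `peptide`, `kd`, `probability`; attribute
#'   `"spearman"` holds the rank correlation (`NA`, flagged by attribute
#'   `"degenerate"`, when probabilities are constant).
#' @export
hydropathyVsProbability <- function(peptides, model) {
  if (length(peptides) < 3L)
    stop("need at least 3 peptides for a correlation")
  out <- data.frame(peptide = peptides, kd = kdScore(peptides),
                    probability = predict(model, peptides))
  degenerate <- stats::sd(out$probability) == 0
  attr(out, "spearman") <- if (degenerate) NA_real_ else
    cor(out$kd, out$probability, method = "spearman")
  attr(out, "degenerate") <- degenerate
  out
}

## ---- atom sets and backbone geometry ----

#' Construct an atom table
#'
#' The light-weight atom container used by the structural routines: one
#' row per atom with Cartesian coordinates (Angstrom), element, PDB-style
#' atom name, residue number/letter and chain.
#'
#' @param x,y,z Coordinates (Angstrom).
#' @param element Element symbols (C, N, O, S, ...).
#' @param atom Atom names (`"N"`, `"CA"`, `"C"`, ...).
#' @param resno Residue numbers.
#' @param resid One-letter residue codes.
#' @param chain Chain identifiers.
#' @return `data.frame` of class `AtomSet`.
#' @export
atomSet <- function(x, y, z, element, atom = element,
                    resno = seq_along(x), resid = "A", chain = "A") {
  stopifnot(all(is.finite(c(x, y, z))))
  out <- data.frame(x = x, y = y, z = z, element = element, atom = atom,
                    resno = resno, resid = resid, chain = chain)
  class(out) <- c("AtomSet", "data.frame")
  out
}

#' Read an atom table from a PDB or mmCIF file
#'
#' Thin wrapper over `bio3d::read.pdb()` / `bio3d::read.cif()` keeping
#' protein heavy atoms of the first model.
#' @param path Structure file (`.pdb` or `.cif`).
#' @return An [atomSet()] table.
#' @export
readStructure <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("reading structure files requires the 'bio3d' package")
  pdb <- if (grepl("\\.cif$", path)) bio3d::read.cif(path)
         else bio3d::read.pdb(path)
  a <- pdb$atom[pdb$atom$type == "ATOM", ]
  aa1 <- toupper(a$resid)
  map <- setNames(AA_ALPHABET20,
                  c("ALA", "CYS", "ASP", "GLU", "PHE", "GLY", "HIS",
                    "ILE", "LYS", "LEU", "MET", "ASN", "PRO", "GLN",
                    "ARG", "SER", "THR", "VAL", "TRP", "TYR"))
  atomSet(a$x, a$y, a$z,
          element = ifelse(is.na(a$elesy) | a$elesy == "",
                           substr(gsub("[0-9]", "", a$elety), 1, 1),
                           a$elesy),
          atom = a$elety, resno = a$resno,
          resid = unname(map[aa1]) |> (\(v) ifelse(is.na(v), "X", v))(),
          chain = ifelse(is.na(a$chain), "A", a$chain))
}

# dihedral angle (degrees, in (-180, 180]) of points p1-p2-p3-p4
dihedralAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# place atom D given A, B, C with |CD| = bond, angle(BCD) = theta (deg)
# and dihedral(A,B,C,D) = chi (deg) -- standard internal-coordinate step
placeAtom <- function(a, b, c, bond, theta, chi) {
  th <- theta * pi / 180; ch <- chi * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- bond * c(-cos(th), sin(th) * cos(ch), -sin(th) * sin(ch))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Build an ideal peptide backbone from torsion angles
#'
#' Generates N, CA, C atoms per residue with standard bond geometry
#' (N-CA 1.458 A, CA-C 1.525 A, C-N 1.329 A; omega fixed at 180 deg) and
#' the requested phi/psi angles. Used to construct reference helices and
#' strands for testing and as a general fixture generator.
#'
#' @param phi,psi Torsion angles in degrees; scalars are recycled to
#'   `n` residues.
#' @param n Number of residues.
#' @param sequence Optional residue letters (default all "A").
#' @return An [atomSet()] backbone table (3 atoms per residue).
#' @export
buildBackbone <- function(phi = -57, psi = -47, n = 20L, sequence = NULL) {
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  if (is.null(sequence)) sequence <- rep("A", n)
  coords <- matrix(0, 3L * n, 3L)
  # residue 1: N at origin, CA on x-axis, C in the xy-plane
  coords[1, ] <- c(0, 0, 0)
  coords[2, ] <- c(1.458, 0, 0)
  ang <- 111.2 * pi / 180
  coords[3, ] <- coords[2, ] + 1.525 * c(-cos(ang), sin(ang), 0)
  for (i in 2:n) {
    Nprev <- coords[3 * (i - 2) + 1, ]
    CAprev <- coords[3 * (i - 2) + 2, ]
    Cprev <- coords[3 * (i - 2) + 3, ]
    Ni <- placeAtom(Nprev, CAprev, Cprev, 1.329, 116.2, psi[i - 1])
    CAi <- placeAtom(CAprev, Cprev, Ni, 1.458, 121.7, 180)
    Ci <- placeAtom(Cprev, Ni, CAi, 1.525, 111.2, phi[i])
    coords[3 * (i - 1) + 1:3, ] <- rbind(Ni, CAi, Ci)
  }
  atomSet(coords[, 1], coords[, 2], coords[, 3],
          element = rep(c("N", "C", "C"), n),
          atom = rep(c("N", "CA", "C"), n),
          resno = rep(seq_len(n), each = 3L),
          resid = rep(sequence, each = 3L))
}

#' Backbone torsion angles of an atom table
#'
#' @param atoms An [atomSet()] with N/CA/C atoms per residue (one chain).
#' @return `data.frame` with `resno`, `phi`, `psi` in degrees (`NA` at
#'   chain termini or where backbone atoms are missing).
#' @export
torsionAngles <- function(atoms) {
  resnos <- sort(unique(atoms$resno))
  getAtom <- function(rn, nm) {
    i <- which(atoms$resno == rn & atoms$atom == nm)
    if (length(i) != 1L) return(NULL)
    as.numeric(atoms[i, c("x", "y", "z")])
  }
  n <- length(resnos)
  phi <- psi <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    N <- getAtom(resnos[k], "N"); CA <- getAtom(resnos[k], "CA")
    C <- getAtom(resnos[k], "C")
    if (is.null(N) || is.null(CA) || is.null(C)) next
    if (k > 1L) {
      Cp <- getAtom(resnos[k - 1L], "C")
      if (!is.null(Cp)) phi[k] <- dihedralAngle(Cp, N, CA, C)
    }
    if (k < n) {
      Nn <- getAtom(resnos[k + 1L], "N")
      if (!is.null(Nn)) psi[k] <- dihedralAngle(N, CA, C, Nn)
    }
  }
  data.frame(resno = resnos, phi = phi, psi = psi)
}

#' Assign secondary-structure classes from backbone geometry
#'
#' Torsion-rule classifier over `{helix, sheet, turn, bend, other}`:
#' helix for phi in (-100, -30) and psi in (-80, -5) in runs of at least
#' 4 residues; sheet for phi in (-180, -40) and psi in (90, 180] or
#' below -170 in runs of at least 3; remaining residues where the chain
#' direction (CA(i-2)->CA(i) vs CA(i)->CA(i+2)) turns by at least 70
#' degrees are `turn` when the five-residue span is compact (CA(i-2) to
#' CA(i+2) under 7 A) and `bend` otherwise; everything else, including
#' termini without torsions, is `other`. This is a geometric stand-in
#' for hydrogen-bond-based assignments (DSSP); externally computed
#' annotations can be supplied instead wherever a `StructureAnnotation`
#' is accepted.
#'
#' @param atoms An [atomSet()] backbone (one chain).
#' @return Character vector of classes, one per residue (by `resno`
#'   order).
#' @export
assignSecondaryStructure <- function(atoms) {
  tor <- torsionAngles(atoms)
  n <- nrow(tor)
  helixOK <- !is.na(tor$phi) & !is.na(tor$psi) &
    tor$phi > -100 & tor$phi < -30 & tor$psi > -80 & tor$psi < -5
  sheetOK <- !is.na(tor$phi) & !is.na(tor$psi) &
    tor$phi > -180 & tor$phi < -40 &
    ((tor$psi > 90 & tor$psi <= 180) | tor$psi < -170)
  cls <- rep("other", n)
  cls[runFilter(sheetOK, 3L)] <- "sheet"
  cls[runFilter(helixOK, 4L)] <- "helix"   # helix rule wins on overlap
  # curvature of the CA trace for unassigned residues
  ca <- atoms[atoms$atom == "CA", ]
  ca <- ca[order(ca$resno), ]
  if (nrow(ca) == n && n >= 5L) {
    for (i in 3:(n - 2L)) {
      if (cls[i] != "other") next
      v1 <- as.numeric(ca[i, c("x", "y", "z")] - ca[i - 2L, c("x", "y", "z")])
      v2 <- as.numeric(ca[i + 2L, c("x", "y", "z")] - ca[i, c("x", "y", "z")])
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      if (ang >= 70) {
        span <- sqrt(sum((ca[i + 2L, c("x", "y", "z")] -
                            ca[i - 2L, c("x", "y", "z")])^2))
        cls[i] <- if (span < 7) "turn" else "bend"
      }
    }
  }
  cls
}

# indices belonging to TRUE-runs of at least minRun
runFilter <- function(flag, minRun) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= minRun
  unlist(lapply(which(keep), function(k) starts[k]:ends[k]),
         use.names = FALSE)
}

## ---- accessible surface area ----

# fixed golden-spiral lattice on the unit sphere; orientation is tied to
# the molecule frame after centering, so results are deterministic (and
# rotationally invariant only up to the documented lattice tolerance)
goldenSpiralPoints <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley accessible surface area
#'
#' For each atom, test points on a sphere of radius `r + probe` are
#' checked against all neighbor spheres; the unoccluded fraction times
#' the sphere area is the atom's ASA. Residue ASA is the sum over the
#' residue's atoms.
#'
#' @param atoms An [atomSet()] table.
#' @param probe Probe radius in Angstrom (default 1.4, water).
#' @param nPoints Test points per atom (default 960).
#' @param radii Named van der Waals radii per element; defaults to the
#'   built-in table (C 1.70, N 1.55, O 1.52, S 1.80 A).
#' @return List with `atom_asa` (per atom, A^2) and `residue_asa`
#'   (named by `resno`).
#' @export
shrakeRupleyASA <- function(atoms, probe = 1.4, nPoints = 960L,
                            radii = VDW_RADII) {
  stopifnot(nrow(atoms) >= 1L)
  r <- radii[atoms$element]
  if (anyNA(r))
    stop("no van der Waals radius for element(s): ",
         paste(unique(atoms$element[is.na(r)]), collapse = ", "))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  xyz <- sweep(xyz, 2L, colMeans(xyz))   # molecule frame: centered
  sph <- goldenSpiralPoints(nPoints)
  n <- nrow(xyz)
  rExp <- r + probe
  asa <- numeric(n)
  for (i in seq_len(n)) {
    pts <- sweep(sph * rExp[i], 2L, xyz[i, ], "+")
    d2 <- rowSums(sweep(xyz, 2L, xyz[i, ])^2)
    nb <- which(d2 > 0 & d2 < (rExp + rExp[i])^2)
    if (length(setdiff(which(d2 == 0), i)) > 0L)
      warning("overlapping identical atoms at row ", i,
              "; computed as-is")
    free <- rep(TRUE, nPoints)
    for (j in nb) {
      dd <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      free <- free & dd >= rExp[j]^2
      if (!any(free)) break
    }
    asa[i] <- mean(free) * 4 * pi * rExp[i]^2
  }
  residue <- tapply(asa, atoms$resno, sum)
  list(atom_asa = asa,
       residue_asa = setNames(as.numeric(residue), names(residue)))
}

#' Relative solvent exposure per residue
#'
#' Absolute residue ASA divided by a per-residue maximum-ASA reference
#' (default [MAX_ASA_TIEN2013]), clipped to [0, 1].
#'
#' @param asa Named numeric residue ASA (A^2).
#' @param residues One-letter residue codes aligned with `asa`.
#' @param maxASA Reference table (named by residue letter).
#' @return Numeric vector in [0, 1].
#' @export
relativeASA <- function(asa, residues, maxASA = MAX_ASA_TIEN2013) {
  mx <- maxASA[residues]
  if (anyNA(mx))
    stop("unknown residue(s): ",
         paste(unique(residues[is.na(mx)]), collapse = ", "))
  pmin(1, pmax(0, as.numeric(asa) / as.numeric(mx)))
}

#' Annotate a structure: secondary structure + ASA per residue
#'
#' @param atoms An [atomSet()] table of one protein chain.
#' @param proteinId Identifier for the output.
#' @inheritParams shrakeRupleyASA
#' @return [S4Vectors::DataFrame] `StructureAnnotation`: `protein_id`,
#'   `position` (1-based, renumbered along the chain), `ss`, `asa`,
#'   `relative_asa`, `source = "computed"`.
#' @export
annotateStructure <- function(atoms, proteinId = "protein", probe = 1.4,
                              nPoints = 960L) {
  ss <- assignSecondaryStructure(atoms)
  sr <- shrakeRupleyASA(atoms, probe, nPoints)
  resnos <- sort(unique(atoms$resno))
  resLetters <- vapply(resnos, function(rn)
    atoms$resid[atoms$resno == rn][1L], character(1))
  asa <- as.numeric(sr$residue_asa[as.character(resnos)])
  rel <- if (all(resLetters %in% names(MAX_ASA_TIEN2013)))
    relativeASA(asa, resLetters) else rep(NA_real_, length(asa))
  DataFrame(protein_id = proteinId, position = seq_along(resnos),
            ss = ss, asa = asa, relative_asa = rel, source = "computed")
}

#' Read an external per-residue structure annotation TSV
#'
#' Expected columns: `protein_id`, `position`, `ss`, `asa` (and
#' optionally `relative_asa`). Lets users supply DSSP-derived classes in
#' place of the built-in geometric classifier.
#' @param path TSV path.
#' @return A `StructureAnnotation` [S4Vectors::DataFrame].
#' @export
readAnnotationTSV <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c(protein_id = "character",
                                  ss = "character"))
  if (!all(c("protein_id", "position", "ss", "asa") %in% colnames(df)))
    stop("annotation must have protein_id, position, ss, asa columns")
  if (is.null(df$relative_asa)) df$relative_asa <- NA_real_
  out <- as(df, "DataFrame")
  out$source <- "external_annotation"
  out
}

#' Secondary-structure and ASA composition of predicted degrons
#'
#' Joins a degron probability scan with a per-residue structure
#' annotation; residues with probability above `cutoff` form the degron
#' population. Reports secondary-structure class proportions for degron
#' residues versus all residues, and a two-sided Mann-Whitney U test
#' comparing degron-residue ASA against all residues (normal
#' approximation with tie correction; exact for small samples).
#'
#' @param profiles Scan table ([scanProtein()] / [scanProteome()]).
#' @param annotation `StructureAnnotation` covering the same proteins
#'   and positions.
#' @param cutoff Degron probability cutoff (default 0.85).
#' @return List: `proportions` (`data.frame` class x degron/all),
#'   `n_degron`, `n_all`, `U`, `p_value`.
#' @export
degronStructureReport <- function(profiles, annotation, cutoff = 0.85) {
  key <- function(d) paste(d$protein_id, d$position)
  m <- match(key(profiles), key(annotation))
  if (anyNA(m)) {
    missing <- unique(profiles$protein_id[is.na(m)])
    stop("annotation does not cover protein(s): ",
         paste(head(missing, 3), collapse = ", "))
  }
  ann <- annotation[m, ]
  classes <- c("helix", "sheet", "turn", "bend", "other")
  degron <- !is.na(profiles$probability) & profiles$probability > cutoff
  propOf <- function(idx) {
    tab <- table(factor(ann$ss[idx], levels = classes))
    as.numeric(tab) / max(1L, sum(tab))
  }
  proportions <- data.frame(class = classes,
                            degron = propOf(degron),
                            all = propOf(rep(TRUE, nrow(ann))))
  xs <- ann$asa[degron]; ys <- ann$asa
  if (length(xs) >= 1L) {
    wt <- suppressWarnings(wilcox.test(
      xs, ys, alternative = "two.sided",
      exact = min(length(xs), length(ys)) <= 20L, correct = TRUE))
    U <- unname(wt$statistic); pv <- wt$p.value
  } else {
    U <- NA_real_; pv <- NA_real_
  }
  list(proportions = proportions, n_degron = sum(degron),
       n_all = nrow(ann), U = U, p_value = pv)
}
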
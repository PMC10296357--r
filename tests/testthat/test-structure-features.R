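# Hydropathy, backbone geometry, secondary-structure rules,
# Shrake-Rupley ASA and the degron structure report.

test_that("Kyte-Doolittle peptide scores are length-normalized means", {
  expect_equal(kdScore(strrep("I", 17)), 4.5)
  expect_equal(kdScore(strrep("R", 17)), -4.5)
  for (n in c(5, 17, 60)) expect_equal(kdScore(strrep("I", n)), 4.5)
  expect_equal(kdScore("IR"), 0)
  expect_equal(kdScore(c("LLLL", "DDDD")), c(3.8, -3.5))
  expect_error(kdScore("AXA"), "non-standard")
})

test_that("hydropathy-probability table pairs every peptide and flags degeneracy", {
  set.seed(601)
  peps <- replicate(30, paste(sample(AA_ALPHABET20, 17, replace = TRUE),
                              collapse = ""))
  w <- defaultTrueWeights()
  model <- new("DegronModel", weights = w[AA_ALPHABET20],
               intercept = -1.5, lambda = 0.001,
               featureMode = "counts", fit = list())
  tab <- hydropathyVsProbability(peps, model)
  expect_identical(nrow(tab), 30L)
  expect_true(is.finite(attr(tab, "spearman")))
  zero <- new("DegronModel", weights = setNames(numeric(20), AA_ALPHABET20),
              intercept = 0, lambda = 0, featureMode = "counts",
              fit = list())
  ztab <- hydropathyVsProbability(peps, zero)
  expect_true(attr(ztab, "degenerate"))
  expect_true(is.na(attr(ztab, "spearman")))
  expect_error(hydropathyVsProbability(peps[1:2], model), "at least 3")
})

test_that("backbone builder reproduces the requested torsion angles", {
  bb <- buildBackbone(phi = -57, psi = -47, n = 12L)
  tor <- torsionAngles(bb)
  expect_equal(tor$phi[2:12], rep(-57, 11), tolerance = 1e-6)
  expect_equal(tor$psi[1:11], rep(-47, 11), tolerance = 1e-6)
  mix <- buildBackbone(phi = c(0, -60, -120, 80), psi = c(30, -40, 130, 0),
                       n = 4L)
  tmix <- torsionAngles(mix)
  expect_equal(tmix$phi[2:4], c(-60, -120, 80), tolerance = 1e-6)
  expect_equal(tmix$psi[1:3], c(30, -40, 130), tolerance = 1e-6)
})

test_that("ideal helices and strands classify as helix and sheet in their interiors", {
  helix <- buildBackbone(phi = -57, psi = -47, n = 20L)
  clsH <- assignSecondaryStructure(helix)
  expect_true(all(clsH[2:19] == "helix"))
  strand <- buildBackbone(phi = -120, psi = 130, n = 15L)
  clsS <- assignSecondaryStructure(strand)
  expect_true(all(clsS[2:14] == "sheet"))
  # termini lack torsions; two residues give no torsions at all
  tiny <- buildBackbone(n = 2L)
  expect_identical(assignSecondaryStructure(tiny), c("other", "other"))
})

test_that("a hairpin reversal is picked up by the curvature rules", {
  # extended arms joined by a type-I beta-turn reversal
  phi <- c(rep(-120, 6), -60, -90, rep(-120, 6))
  psi <- c(rep(130, 6), -30, 0, rep(130, 6))
  bb <- buildBackbone(phi = phi, psi = psi, n = 14L)
  cls <- assignSecondaryStructure(bb)
  expect_true(any(cls[7:8] %in% c("turn", "bend")))
})

test_that("single-atom Shrake-Rupley ASA matches the closed-form sphere area", {
  for (el in c("C", "N", "O", "S")) {
    a <- atomSet(0, 0, 0, el)
    got <- shrakeRupleyASA(a, nPoints = 960L)$atom_asa
    want <- 4 * pi * (degronScan:::VDW_RADII[[el]] + 1.4)^2
    expect_lt(abs(got - want) / want, 0.01)
  }
  expect_error(shrakeRupleyASA(atomSet(0, 0, 0, "Zz")), "radius")
})

test_that("far-apart atoms are additive and buried atoms lose their surface", {
  rC <- degronScan:::VDW_RADII[["C"]]
  iso <- shrakeRupleyASA(atomSet(0, 0, 0, "C"))$atom_asa
  two <- shrakeRupleyASA(atomSet(c(0, 20), c(0, 0), c(0, 0),
                                 c("C", "C"), resno = c(1L, 2L)))
  expect_equal(sum(two$atom_asa), 2 * iso, tolerance = 1e-9)
  expect_equal(unname(two$residue_asa), two$atom_asa)
  # atom enclosed by a dense shell of neighbors has ~zero ASA
  sph <- degronScan:::goldenSpiralPoints(60L) * 2.4
  shell <- atomSet(c(0, sph[, 1]), c(0, sph[, 2]), c(0, sph[, 3]),
                   rep("C", 61L))
  buried <- shrakeRupleyASA(shell)$atom_asa[1]
  expect_lt(buried, 0.5)
})

test_that("ASA error shrinks with the sphere-point count and survives translation", {
  want <- 4 * pi * (degronScan:::VDW_RADII[["C"]] + 1.4)^2
  errs <- vapply(c(96L, 240L, 960L), function(n) {
    # a second atom creates partial occlusion so lattice resolution matters
    res <- shrakeRupleyASA(atomSet(c(0, 3.2), 0, 0, c("C", "C")),
                           nPoints = n)
    abs(sum(res$atom_asa) - shrakeRupleyASA(
      atomSet(c(0, 3.2), 0, 0, c("C", "C")), nPoints = 3840L)$atom_asa |>
        sum())
  }, numeric(1))
  expect_true(all(diff(errs) <= 0))
  set.seed(602)
  bb <- buildBackbone(n = 6L)
  a1 <- shrakeRupleyASA(bb)$residue_asa
  shifted <- bb; shifted$x <- bb$x + 13.7; shifted$y <- bb$y - 4.2
  a2 <- shrakeRupleyASA(shifted)$residue_asa
  expect_equal(a1, a2, tolerance = 1e-6)
})

test_that("relative ASA normalizes by the reference maxima and clips to [0,1]", {
  expect_equal(relativeASA(c(r1 = 64.5), "A"), 0.5)
  expect_equal(relativeASA(c(r1 = 200), "A"), 1)     # ratio 1.55 clipped
  expect_equal(relativeASA(c(r1 = 0), "G"), 0)
  expect_error(relativeASA(c(r1 = 10), "X"), "unknown residue")
  # center residue of an extended tripeptide is nearly fully exposed
  bb <- buildBackbone(phi = -120, psi = 130, n = 3L, sequence = rep("G", 3))
  asa <- shrakeRupleyASA(bb)$residue_asa
  rel <- relativeASA(asa["2"], "G")
  expect_gt(rel, 0.6)
})

test_that("degron structure report compares classes and ASA against the proteome", {
  set.seed(603)
  n <- 40L
  ann <- S4Vectors::DataFrame(
    protein_id = "p1", position = 1:n,
    ss = c(rep("helix", 15), rep("other", 25)),
    asa = c(runif(15, 5, 40), runif(25, 60, 120)),
    relative_asa = NA_real_, source = "computed")
  prob <- rep(0.1, n); prob[3:12] <- 0.95   # degrons only inside helices
  prof <- S4Vectors::DataFrame(protein_id = "p1", position = 1:n,
                               probability = prob)
  rep1 <- degronStructureReport(prof, ann, cutoff = 0.85)
  expect_equal(rep1$proportions$degron[rep1$proportions$class == "helix"], 1)
  expect_equal(sum(rep1$proportions$degron), 1)
  expect_equal(sum(rep1$proportions$all), 1)
  expect_identical(rep1$n_degron, 10L)
  # Mann-Whitney U equals the brute-force pairwise count
  xs <- ann$asa[prob > 0.85]; ys <- ann$asa
  bruteU <- sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  expect_equal(unname(rep1$U), bruteU)
  expect_lt(rep1$p_value, 0.01)   # degrons drawn from the buried range
  # degenerate self-vs-self comparison: identical proportions, p near 1
  prof2 <- prof; prof2$probability <- rep(0.95, n)
  rep2 <- degronStructureReport(prof2, ann, cutoff = 0.85)
  expect_equal(rep2$proportions$degron, rep2$proportions$all)
  expect_gt(rep2$p_value, 0.9)
  expect_error(degronStructureReport(
    S4Vectors::DataFrame(protein_id = "p2", position = 1:3,
                         probability = 0.5), ann),
    "does not cover")
})

test_that("external annotations load and join with scan profiles", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "ann.tsv")
  df <- data.frame(protein_id = "p1", position = 1:20,
                   ss = rep(c("helix", "sheet"), 10),
                   asa = seq(10, 200, length.out = 20))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- readAnnotationTSV(path)
  expect_identical(unique(ann$source), "external_annotation")
  prof <- S4Vectors::DataFrame(protein_id = "p1", position = 1:20,
                               probability = c(rep(0.9, 5), rep(0.1, 15)))
  rep3 <- degronStructureReport(prof, ann)
  expect_identical(rep3$n_degron, 5L)
})
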
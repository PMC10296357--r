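# Training-set assembly, ridge logistic optimization, prediction,
# proteome scanning and degron calling.

randomPeptide <- function(n = 17L)
  paste(sample(AA_ALPHABET20, n, replace = TRUE), collapse = "")

toyPsiTable <- function(psi, reads = 200L) {
  S4Vectors::DataFrame(
    peptide_id = sprintf("pep%03d", seq_along(psi)),
    psi = psi, total_reads = rep_len(reads, length(psi)))
}

test_that("training-set assembly enforces read and PSI label rules", {
  set.seed(501)
  psi <- c(1.9, 3.1, 2.5, 2.2, 2.8, 1.0, 3.9, 2.1999, 2.8001)
  reads <- c(200L, 200L, 200L, 200L, 200L, 49L, 50L, 200L, 200L)
  tab <- toyPsiTable(psi, reads)
  peps <- setNames(replicate(length(psi), randomPeptide()),
                   tab$peptide_id)
  ts <- buildTrainingSet(tab, peps)
  # <50 reads excluded even though psi 1.0 would label unstable
  expect_false("pep006" %in% ts$peptide_id)
  # mid-range and exact boundary values excluded
  expect_false(any(c("pep003", "pep004", "pep005") %in% ts$peptide_id))
  expect_identical(attr(ts, "n_low_reads"), 1L)
  expect_identical(attr(ts, "n_boundary"), 2L)
  got <- setNames(ts$label, ts$peptide_id)
  expect_identical(got[c("pep001", "pep002", "pep007", "pep008",
                         "pep009")],
                   c(pep001 = 1L, pep002 = 0L, pep007 = 0L,
                     pep008 = 1L, pep009 = 0L))
  expect_error(buildTrainingSet(toyPsiTable(c(1.0, 1.5)),
                                setNames(replicate(2, randomPeptide()),
                                         c("pep001", "pep002"))),
               "degenerate")
})

test_that("composition encoding is permutation-invariant and conserving", {
  p <- "ACDEFGHIKLMNPQRST"
  X <- encodePeptides(p)
  expect_identical(colnames(X), AA_ALPHABET20)
  expect_equal(unname(rowSums(X)), 17)
  expect_equal(unname(rowSums(encodePeptides(p, "freqs"))), 1)
  homo <- encodePeptides(strrep("A", 17))
  expect_equal(unname(homo[1, ]), c(17, rep(0, 19)))
  set.seed(502)
  shuf <- paste(sample(strsplit(p, "")[[1]]), collapse = "")
  expect_equal(encodePeptides(shuf), X)
  expect_error(encodePeptides("SHORT"), "17 residues")
  expect_error(encodePeptides(strrep("X", 17)), "non-standard")
})

test_that("the optimizer reaches a stationary point of the penalized loss", {
  set.seed(503)
  peps <- replicate(300, randomPeptide())
  labels <- rbinom(300, 1, plogis(kdScore(peps)))
  ts <- data.frame(peptide = peps, label = labels)
  model <- trainDegronModel(ts, lambda = 0.001)
  beta <- c(intercept(model), weights(model))
  X <- encodePeptides(peps)
  # independent finite-difference gradient of the objective
  fd <- vapply(seq_along(beta), function(j) {
    h <- 1e-6
    bp <- beta; bp[j] <- bp[j] + h
    bm <- beta; bm[j] <- bm[j] - h
    (degronScan:::ridgeLogisticLoss(bp, X, labels, 0.001) -
       degronScan:::ridgeLogisticLoss(bm, X, labels, 0.001)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(fd)), 1e-5)
})

test_that("training is order-invariant and matches an independent ridge fit", {
  skip_if_not_installed("glmnet")
  set.seed(504)
  peps <- replicate(400, randomPeptide())
  labels <- as.integer(kdScore(peps) + rnorm(400, 0, 1) > 0)
  ts <- data.frame(peptide = peps, label = labels)
  model <- trainDegronModel(ts, lambda = 0.05)
  shuffled <- ts[sample(nrow(ts)), ]
  model2 <- trainDegronModel(shuffled, lambda = 0.05)
  expect_true(all(abs(weights(model) - weights(model2)) <= 1e-8))
  # glmnet with alpha=0 minimizes the same mean-loss + lambda/2 ||w||^2
  X <- encodePeptides(peps)
  g <- glmnet::glmnet(X, labels, family = "binomial", alpha = 0,
                      lambda = 0.05, standardize = FALSE,
                      thresh = 1e-14)
  expect_equal(unname(weights(model)), as.numeric(g$beta),
               tolerance = 5e-3)
  expect_equal(intercept(model), as.numeric(g$a0), tolerance = 5e-3)
})

test_that("ridge keeps separable fits finite and heavy penalties shrink to the prior", {
  ts <- data.frame(peptide = c(rep(strrep("L", 17), 6),
                               rep(strrep("D", 17), 4)),
                   label = c(rep(1L, 6), rep(0L, 4)))
  model <- trainDegronModel(ts, lambda = 0.001)
  expect_true(all(is.finite(weights(model))))
  expect_gt(weights(model)[["L"]], 0)
  expect_lt(weights(model)[["D"]], 0)
  big <- trainDegronModel(ts, lambda = 1e6)
  expect_true(all(abs(weights(big)) < 1e-3))
  expect_equal(plogis(intercept(big)), 0.6, tolerance = 0.01)
})

test_that("prediction is the logistic of the composition score", {
  w <- setNames(numeric(20), AA_ALPHABET20)
  w["L"] <- 0.3; w["D"] <- -0.2
  model <- new("DegronModel", weights = w, intercept = -1,
               lambda = 0.001, featureMode = "counts", fit = list())
  expect_equal(predict(model, strrep("L", 17)),
               plogis(-1 + 17 * 0.3), tolerance = 1e-12)
  expect_equal(predict(model, paste0(strrep("L", 8), strrep("D", 9))),
               plogis(-1 + 8 * 0.3 - 9 * 0.2), tolerance = 1e-12)
  zero <- new("DegronModel", weights = setNames(numeric(20), AA_ALPHABET20),
              intercept = 0, lambda = 0, featureMode = "counts",
              fit = list())
  expect_equal(predict(zero, randomPeptide()), 0.5)
  # substituting in a higher-weight residue strictly raises probability
  base <- paste0("G", strrep("A", 16))
  up <- paste0("L", strrep("A", 16))
  expect_gt(predict(model, up), predict(model, base))
})

test_that("proteome scans define exactly L-16 interior positions", {
  set.seed(505)
  w <- defaultTrueWeights()
  model <- new("DegronModel", weights = w[AA_ALPHABET20], intercept = -1.5,
               lambda = 0.001, featureMode = "counts", fit = list())
  p17 <- randomPeptide(17)
  prof <- scanProtein(model, p17)
  expect_identical(which(!is.na(prof$probability)), 9L)
  p100 <- randomPeptide(100)
  prof100 <- scanProtein(model, p100)
  expect_identical(sum(!is.na(prof100$probability)), 84L)
  expect_true(all(is.na(prof100$probability[c(1:8, 93:100)])))
  homo <- scanProtein(model, strrep("L", 40))
  vals <- homo$probability[!is.na(homo$probability)]
  expect_equal(vals, rep(vals[1], length(vals)))
  expect_error(scanProtein(model, "SHORTPEP"), "17")
})

test_that("degron calls equal a brute-force threshold-run scan", {
  bruteCalls <- function(p, cutoff) {
    above <- !is.na(p) & p > cutoff
    calls <- list()
    i <- 1L
    while (i <= length(p)) {
      if (above[i]) {
        j <- i
        while (j < length(p) && above[j + 1L]) j <- j + 1L
        calls[[length(calls) + 1L]] <- c(i, j)
        i <- j + 1L
      } else i <- i + 1L
    }
    calls
  }
  set.seed(506)
  for (rep in 1:200) {
    p <- runif(sample(17:80, 1))
    p[c(1:8, (length(p) - 7):length(p))] <- NA
    prof <- S4Vectors::DataFrame(protein_id = "x",
                                 position = seq_along(p),
                                 probability = p)
    cutoff <- runif(1, 0.2, 0.9)
    got <- callDegrons(prof, cutoff)
    want <- bruteCalls(p, cutoff)
    expect_identical(nrow(got), length(want))
    if (length(want)) {
      expect_identical(got$start, vapply(want, `[`, numeric(1), 1) |>
                         as.integer())
      expect_identical(got$end, vapply(want, `[`, numeric(1), 2) |>
                         as.integer())
      expect_equal(got$peak_probability, vapply(want, function(se)
        max(p[se[1]:se[2]]), numeric(1)))
    }
  }
  # explicit toys: no calls below cutoff; two separated runs give two calls
  flat <- S4Vectors::DataFrame(protein_id = "x", position = 1:50,
                               probability = rep(0.2, 50))
  expect_identical(nrow(callDegrons(flat, 0.85)), 0L)
  p2 <- rep(0.1, 80); p2[20:35] <- 0.95; p2[60:70] <- 0.9
  two <- callDegrons(S4Vectors::DataFrame(protein_id = "x",
                                          position = 1:80,
                                          probability = p2), 0.85)
  expect_identical(two$start, c(20L, 60L))
  expect_identical(two$end, c(35L, 70L))
  # minimum length filter drops short runs
  expect_identical(nrow(callDegrons(S4Vectors::DataFrame(
    protein_id = "x", position = 1:80, probability = p2),
    0.85, minLength = 12L)), 1L)
})

test_that("models round-trip through JSON and composition symmetry holds end to end", {
  set.seed(507)
  peps <- replicate(200, randomPeptide())
  ts <- data.frame(peptide = peps,
                   label = as.integer(kdScore(peps) > 0))
  model <- trainDegronModel(ts)
  path <- withr::local_tempfile(fileext = ".json")
  writeDegronModel(model, path)
  back <- readDegronModel(path)
  expect_equal(weights(back), weights(model))
  expect_equal(intercept(back), intercept(model))
  expect_identical(back@featureMode, model@featureMode)
  pep <- randomPeptide()
  shuf <- paste(sample(strsplit(pep, "")[[1]]), collapse = "")
  expect_equal(predict(model, pep), predict(model, shuf))
})
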
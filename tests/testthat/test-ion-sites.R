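test_that("an isolated ion has an empty coordination shell", {
  lone <- AtomicStructure(data.frame(
    name = "NA", element = "NA", resname = "NA", chain = "I",
    resseq = 900L, x = 0, y = 0, z = 0, hetero = TRUE))
  sh <- findCoordination(lone, list(chain = "I", resseq = 900,
                                    name = "NA"))
  expect_equal(sh@coordinationNumber, 0L)
  expect_true(is.na(sh@meanDistance))
})

test_that("a synthetic octahedral shell measures CN 6, 2.40 A, 90 deg", {
  s <- makeIonSite("NA", cn = 6, meanDist = 2.40)
  sh <- findCoordination(s, list(chain = "I", resseq = 900, name = "NA"))
  expect_equal(sh@coordinationNumber, 6L)
  expect_equal(sh@meanDistance, 2.40, tolerance = 1e-9)
  expect_equal(sh@minAngle, 90, tolerance = 1e-6)
})

test_that("carbons are never ligands and cutoff bounds are enforced", {
  s <- makeIonSite("NA", cn = 4, meanDist = 2.4)
  a <- atoms(s)
  a <- rbind(a, data.frame(serial = max(a$serial) + 1L, name = "CB",
                           element = "C", altloc = "", resname = "ALA",
                           chain = "Q", resseq = 1L, inscode = "",
                           x = 2.2, y = 0.4, z = 0.4, occupancy = 1,
                           bfactor = 0, hetero = FALSE))
  s2 <- AtomicStructure(a)
  sh <- findCoordination(s2, list(chain = "I", resseq = 900, name = "NA"))
  expect_equal(sh@coordinationNumber, 4L)
  expect_false(any(sh@ligands$element == "C"))
  expect_error(findCoordination(s2, c(0, 0, 0), cutoff = 4),
               "cutoff")
  expect_error(findCoordination(s2, list(chain = "Z", resseq = 1,
                                         name = "NA")), "not found")
})

test_that("ligand classes split carbonyl, side-chain and water oxygens", {
  s <- makeIonSite("NA", cn = 5, meanDist = 2.4, nWaters = 2)
  sh <- findCoordination(s, list(chain = "I", resseq = 900, name = "NA"))
  tab <- table(sh@ligands$class)
  expect_equal(unname(tab[["backbone carbonyl O"]]), 3L)
  expect_equal(unname(tab[["water O"]]), 2L)
})

test_that("decision table calls the printed alkali signatures", {
  mkShell <- function(cn, mean, classes = "backbone carbonyl O") {
    lig <- data.frame(name = "O", resname = "GLY", chain = "L",
                      resseq = seq_len(cn), element = "O",
                      class = classes, distance = rep(mean, cn))
    new("CoordinationShell", center = c(0, 0, 0), ligands = lig,
        coordinationNumber = as.integer(cn), meanDistance = mean,
        minAngle = 90, cutoff = 3.5)
  }
  # CN 5 at 2.40 A all-oxygen: the Na+ signature
  expect_equal(classifySite(mkShell(5, 2.40))$identity, "Na+")
  # CN 6 at 2.85 A all-oxygen: K+
  expect_equal(classifySite(mkShell(6, 2.85))$identity, "K+")
  # bare position
  empty <- new("CoordinationShell", center = c(0, 0, 0),
               ligands = mkShell(1, 2.4)@ligands[0, ],
               coordinationNumber = 0L, meanDistance = NA_real_,
               minAngle = NA_real_, cutoff = 3.0)
  expect_true(classifySite(empty)$identity %in% c("water", "ambiguous"))
  expect_false(classifySite(empty)$identity %in% c("Na+", "K+"))
  # a nitrogen-rich shell at Na distances is not an alkali call
  ligN <- mkShell(5, 2.40)
  ligN@ligands$element <- "N"; ligN@ligands$class <- "N"
  expect_false(classifySite(ligN)$identity == "Na+")
})

test_that("the decision table is exhaustive and unique on a CN x distance grid", {
  for (cn in 0:9) for (md in seq(2.0, 3.4, by = 0.1)) {
    lig <- if (cn > 0)
      data.frame(name = "O", resname = "GLY", chain = "L",
                 resseq = seq_len(cn), element = "O",
                 class = "backbone carbonyl O", distance = rep(md, cn))
    else
      data.frame(name = character(), resname = character(),
                 chain = character(), resseq = integer(),
                 element = character(), class = character(),
                 distance = numeric())
    sh <- new("CoordinationShell", center = c(0, 0, 0), ligands = lig,
              coordinationNumber = cn,
              meanDistance = if (cn > 0) md else NA_real_,
              minAngle = NA_real_, cutoff = 3.5)
    call <- classifySite(sh)
    expect_length(call$identity, 1L)
    expect_true(call$identity %in% c("Na+", "K+", "water", "ambiguous"))
    expect_true(call$score >= 0 && call$score <= 1)
    if (call$identity %in% c("Na+", "K+")) expect_equal(call$score, 1)
  }
})

test_that("site calls are invariant under rigid transforms", {
  set.seed(5)
  s <- makeIonSite("NA", cn = 5, meanDist = 2.4, nWaters = 2)
  base <- classifySite(findCoordination(
    s, list(chain = "I", resseq = 900, name = "NA")))
  for (k in 1:5) {
    sT <- transformStructure(s, randomRotation(), stats::rnorm(3, 0, 30))
    callT <- classifySite(findCoordination(
      sT, list(chain = "I", resseq = 900, name = "NA")))
    expect_equal(callT$identity, base$identity)
    expect_equal(callT$score, base$score)
  }
})

test_that("deleting a ligand never increases the coordination number", {
  s <- makeIonSite("NA", cn = 6, meanDist = 2.4)
  full <- findCoordination(s, list(chain = "I", resseq = 900,
                                   name = "NA"))@coordinationNumber
  a <- atoms(s)
  for (drop in which(a$name == "O")) {
    s2 <- AtomicStructure(a[-drop, ])
    cn2 <- findCoordination(s2, list(chain = "I", resseq = 900,
                                     name = "NA"))@coordinationNumber
    expect_lte(cn2, full)
  }
})

test_that("a planted Na-like shell outranks bulk waters in a scan", {
  set.seed(17)
  site <- makeIonSite("NA", cn = 5, meanDist = 2.4, nWaters = 2)
  # 20 bulk-like waters far apart (no tight shells)
  n <- 20L
  pos <- matrix(stats::runif(3 * n, 12, 60), ncol = 3)
  bulk <- AtomicStructure(data.frame(
    name = "O", element = "O", resname = "HOH",
    chain = "W", resseq = 200L + seq_len(n),
    x = pos[, 1], y = pos[, 2], z = pos[, 3], hetero = TRUE))
  s <- AtomicStructure(rbind(atoms(site), atoms(bulk)))
  tab <- scanCandidateIons(s)
  expect_equal(tab$resname[1], "NA")
  expect_equal(tab$identity[1], "Na+")
  expect_equal(tab$cn[1], 5L)
  expect_equal(tab$nCarbonylO[1], 3L)
  expect_equal(tab$nWaterO[1], 2L)
})

test_that("a structure without solvent yields an empty scan", {
  expect_message(tab <- scanCandidateIons(makeIdealHelix(10)),
                 "no solvent")
  expect_equal(nrow(tab), 0L)
})
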
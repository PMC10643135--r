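test_that("superposing a structure on itself gives identity and zero rmsd", {
  s <- makeIdealHelix(20)
  fit <- superpose(s, s, selectionSpec("A"))
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)
  expect_equal(fit$translation, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
})

test_that("a constructed rotation + translation is inverted exactly", {
  s <- makeIdealHelix(20)
  R <- rotationMatrix(c(0, 0, 1), 30)
  mov <- transformStructure(s, R, c(1, 2, 3))
  fit <- superpose(s, mov, selectionSpec("A"))
  expect_lt(fit$rmsd, 1e-6)
  expect_equal(fit$rotation %*% R, diag(3), tolerance = 1e-9)
  # cross-check the recovered rmsd against an independent superposition
  ref_xyz <- as.numeric(t(coords(s)))
  mov_xyz <- as.numeric(t(coords(mov)))
  b3d <- suppressWarnings(bio3d::fit.xyz(ref_xyz, mov_xyz))
  expect_equal(sqrt(mean((b3d - ref_xyz)^2) * 3), fit$rmsd,
               tolerance = 1e-6)
})

test_that("reflected coordinates never yield an improper rotation", {
  s <- makeIdealHelix(15)
  a <- atoms(s)
  a$x <- -a$x                     # mirror
  mirrored <- AtomicStructure(a)
  fit <- superpose(s, mirrored, selectionSpec("A"))
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_gt(fit$rmsd, 0.5)
})

test_that("superposition rmsd is invariant under rigid pre-transforms", {
  set.seed(3)
  s <- makeIdealHelix(18)
  mov <- transformStructure(s, rotationMatrix(c(1, 1, 0), 40), c(5, 0, -2))
  base <- superpose(s, mov, selectionSpec("A"))$rmsd
  for (k in 1:5) {
    pre <- transformStructure(mov, randomRotation(), stats::rnorm(3, 0, 10))
    expect_equal(superpose(s, pre, selectionSpec("A"))$rmsd, base,
                 tolerance = 1e-7)
  }
})

test_that("degenerate cores are rejected", {
  s <- makeIdealHelix(10)
  expect_error(superpose(s, s, selectionSpec("A", resseq = 1:2)),
               "fewer than 3")
  line <- AtomicStructure(data.frame(
    name = "CA", element = "C", resname = "GLY", chain = "A",
    resseq = 1:5, x = seq(0, 8, by = 2), y = 0, z = 0, hetero = FALSE))
  expect_error(superpose(line, line, selectionSpec("A")), "collinear")
})

test_that("identical states give zero domain motion", {
  hp <- makeHingePair(26)
  dm <- domainMotion(hp$ref, hp$ref, selectionSpec("A"),
                     selectionSpec("B"))
  expect_equal(dm@rotationAngle, 0, tolerance = 1e-4)
  expect_equal(dm@maxDisplacement, 0, tolerance = 1e-9)
})

test_that("a constructed 26-degree hinge is recovered within 0.1 degree", {
  hp <- makeHingePair(26)
  dm <- domainMotion(hp$ref, hp$mov, selectionSpec("A"),
                     selectionSpec("B"))
  expect_equal(dm@rotationAngle, 26, tolerance = 0.1)
  expect_lt(dm@rmsdDomain, 1e-6)
  expect_equal(abs(sum(dm@rotationAxis * hp$axis)), 1, tolerance = 1e-6)
})

test_that("hinge recovery holds over 100 seeded random axis/angle draws", {
  set.seed(2024)
  for (k in 1:100) {
    ang <- stats::runif(1, 2, 170)
    axis <- stats::rnorm(3)
    hp <- makeHingePair(ang, axis = axis,
                        scramble = list(rotation = randomRotation(),
                                        translation = stats::rnorm(3, 0, 15)))
    dm <- domainMotion(hp$ref, hp$mov, selectionSpec("A"),
                       selectionSpec("B"))
    expect_equal(dm@rotationAngle, ang, tolerance = 0.1)
    expect_true(dm@rotationAngle >= 0 && dm@rotationAngle <= 180)
  }
})

test_that("core and domain selections must be disjoint", {
  hp <- makeHingePair(10)
  expect_error(domainMotion(hp$ref, hp$mov, selectionSpec("A"),
                            selectionSpec("A")), "disjoint")
})

test_that("helix tilt recovers a constructed tilt and is symmetric", {
  core <- makeIdealHelix(12, origin = c(30, 0, 0), chain = "A")
  hx <- makeIdealHelix(15, chain = "H", startRes = 50L)
  ref <- AtomicStructure(rbind(atoms(core), atoms(hx)))
  R <- rotationMatrix(c(1, 0, 0), 25)
  hxT <- transformStructure(hx, R, c(0, 0, 0))
  mov <- AtomicStructure(rbind(atoms(core), atoms(hxT)))
  t1 <- helixTilt(ref, mov, selectionSpec("A"), selectionSpec("H"))
  expect_equal(t1$tilt, 25, tolerance = 0.5)
  t2 <- helixTilt(mov, ref, selectionSpec("A"), selectionSpec("H"))
  expect_equal(t2$tilt, t1$tilt, tolerance = 1e-6)
})

test_that("a shared rigid motion leaves the tilt at zero", {
  core <- makeIdealHelix(12, origin = c(30, 0, 0), chain = "A")
  hx <- makeIdealHelix(15, chain = "H", startRes = 50L)
  ref <- AtomicStructure(rbind(atoms(core), atoms(hx)))
  mov <- transformStructure(ref, rotationMatrix(c(2, 1, 1), 55),
                            c(-3, 8, 1))
  t0 <- helixTilt(ref, mov, selectionSpec("A"), selectionSpec("H"))
  expect_equal(t0$tilt, 0, tolerance = 1e-6)
  expect_equal(t0$shift, 0, tolerance = 1e-6)
})

test_that("the helix axis of an ideal helix matches its construction axis", {
  ax <- c(1, 2, 2) / 3
  h <- makeIdealHelix(20, axis = ax)
  fit <- helixAxis(coords(h))
  expect_gt(abs(sum(fit$direction * ax)), cos(1 * pi / 180))
  # finite non-integer turn count leaves a small end effect in the fit
  expect_lt(fit$fitRmsd, 0.2)
  # rise between consecutive Calpha along the axis
  rise <- diff(coords(h) %*% ax)
  expect_equal(as.numeric(rise), rep(1.5, 19), tolerance = 1e-9)
})

test_that("non-helical selections are flagged by the axis fit", {
  set.seed(9)
  blob <- AtomicStructure(data.frame(
    name = "CA", element = "C", resname = "GLY", chain = "Z",
    resseq = 1:12, x = stats::rnorm(12, 0, 4), y = stats::rnorm(12, 0, 4),
    z = seq(0, 22, by = 2), hetero = FALSE))
  expect_warning(helixTilt(blob, blob, selectionSpec("Z", 1:12),
                           selectionSpec("Z")), "helical|rmsd")
})

test_that("crosslink compatibility against the DSS span", {
  h <- makeIdealHelix(30)
  # consecutive residues sit ~3.8 A apart
  pairs <- data.frame(chain1 = "A", res1 = c(1L, 1L, 5L),
                      chain2 = "A", res2 = c(2L, 30L, 99L))
  out <- crosslinkCheck(h, pairs, maxAllowed = 30)
  expect_true(out$compatible[1])
  expect_true(out$resolved[1] && out$resolved[2])
  expect_false(out$resolved[3])          # residue 99 absent, kept as a row
  expect_equal(nrow(out), 3L)
  d12 <- sqrt(sum((coords(h)[1, ] - coords(h)[2, ])^2))
  expect_equal(out$caDistance[1], d12)
  # a pair beyond the span is incompatible
  far <- AtomicStructure(data.frame(
    name = "CA", element = "C", resname = "LYS", chain = "A",
    resseq = c(1L, 2L), x = c(0, 35), y = 0, z = c(0, 0.5),
    hetero = FALSE))
  out2 <- crosslinkCheck(far, data.frame(chain1 = "A", res1 = 1L,
                                         chain2 = "A", res2 = 2L))
  expect_false(out2$compatible[1])
  # empty request -> empty report
  empty <- crosslinkCheck(h, data.frame(chain1 = character(),
                                        res1 = integer(),
                                        chain2 = character(),
                                        res2 = integer()))
  expect_equal(nrow(empty), 0L)
})
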
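# Synthetic structures and spectra with exactly known ground truth. These
# are minimal geometric scaffolds, not physically realistic decoys: each
# generator guarantees one measurable property (a gap, an angle, a radius
# profile, a coordination shell) so the corresponding analysis stage can be
# validated without any external model.

# rotation taking unit vector `from` onto unit vector `to`
.rotationBetween <- function(from, to) {
  from <- from / sqrt(sum(from^2)); to <- to / sqrt(sum(to^2))
  v <- c(from[2] * to[3] - from[3] * to[2],
         from[3] * to[1] - from[1] * to[3],
         from[1] * to[2] - from[2] * to[1])
  c2 <- sum(from * to)
  s <- sqrt(sum(v^2))
  if (s < 1e-12) {
    if (c2 > 0) return(diag(3))
    # antiparallel: rotate 180 deg about any perpendicular
    p <- if (abs(from[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- p - sum(p * from) * from
    v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + K + K %*% K * ((1 - c2) / s^2)
}

#' Rotation matrix from axis and angle
#'
#' @param axis rotation axis (any length).
#' @param angleDeg angle in degrees.
#' @return 3 x 3 proper rotation matrix (Rodrigues form).
#' @export
rotationMatrix <- function(axis, angleDeg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angleDeg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

#' Ideal alpha-helix Calpha trace
#'
#' Canonical helix geometry: 100 degrees turn per residue, 1.5 Angstrom
#' rise, 2.3 Angstrom radius, aligned to a given axis.
#'
#' @param nRes number of residues (>= 7).
#' @param axis helix axis direction (default +z).
#' @param origin position of the helix start (Angstrom).
#' @param chain chain id.
#' @param startRes first residue number.
#' @return An [AtomicStructure-class] of ALA Calpha atoms.
#' @export
makeIdealHelix <- function(nRes, axis = c(0, 0, 1), origin = c(0, 0, 0),
                           chain = "A", startRes = 1L) {
  if (nRes < 7L) stop("a helix fixture needs >= 7 residues")
  i <- seq_len(nRes) - 1L
  local <- cbind(2.3 * cos(i * 100 * pi / 180),
                 2.3 * sin(i * 100 * pi / 180),
                 1.5 * i)
  R <- .rotationBetween(c(0, 0, 1), axis)
  xyz <- sweep(local %*% t(R), 2, origin, "+")
  AtomicStructure(data.frame(
    name = "CA", element = "C", resname = "ALA", chain = chain,
    resseq = startRes + i, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    hetero = FALSE), id = "ideal_helix")
}

#' Planar [2Fe-2S] rhomb fragment
#'
#' Fe2S2 rhomb with Fe-Fe 2.70 Angstrom and all four Fe-S bonds 2.28
#' Angstrom, the geometry template of a typical plant-type ferredoxin
#' cluster.
#'
#' @param center rhomb centre (Angstrom).
#' @param orientation 3 x 3 rotation applied to the local frame (Fe-Fe
#'   along x, S-S along y).
#' @param chain,resseq residue addressing of the FES group.
#' @return An [AtomicStructure-class] fragment (residue code FES).
#' @export
makeFesCluster <- function(center = c(0, 0, 0), orientation = diag(3),
                           chain = "X", resseq = 901L) {
  feFe <- 2.70; feS <- 2.28
  yS <- sqrt(feS^2 - (feFe / 2)^2)
  local <- rbind(c(-feFe / 2, 0, 0), c(feFe / 2, 0, 0),
                 c(0, yS, 0), c(0, -yS, 0))
  xyz <- sweep(local %*% t(orientation), 2, center, "+")
  AtomicStructure(data.frame(
    name = c("FE1", "FE2", "S1", "S2"),
    element = c("FE", "FE", "S", "S"),
    resname = "FES", chain = chain, resseq = as.integer(resseq),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], hetero = TRUE),
    id = "fes_cluster")
}

# planar 16-heavy-atom flavin-like ring system (three linearly fused
# hexagons sharing edges, bond 1.4 A, plus two exocyclic O). The extreme-x
# atoms sit at y = +/-0.7, z = 0, which makes inter-ring gaps exactly
# controllable (closest pairs share y).
.flavinRingCoords <- function() {
  centers <- c(0, 2.4249, 4.8497)   # 1.4 * sqrt(3) apart: fused hexagons
  verts <- NULL
  for (cx in centers) {
    ang <- (seq(30, 330, by = 60)) * pi / 180
    verts <- rbind(verts, cbind(cx + 1.4 * cos(ang), 1.4 * sin(ang)))
  }
  # dedupe the shared edge vertices
  key <- paste(round(verts[, 1], 3), round(verts[, 2], 3))
  verts <- verts[!duplicated(key), , drop = FALSE]
  verts <- verts[order(verts[, 1], verts[, 2]), , drop = FALSE]   # 14 atoms
  ringNames <- c("N1", "C2", "N3", "C4", "C4A", "N5", "C5A", "C6",
                 "C7", "C8", "C9", "C9A", "N10", "C10")
  # exocyclic O2/O4 off the first ring, purely in +/-y so the extreme-x
  # atoms are unchanged
  o2at <- verts[1, ] + c(0, -1.23)
  o4at <- verts[2, ] + c(0, 1.23)
  coords <- rbind(verts, o2at, o4at)
  data.frame(name = c(ringNames, "O2", "O4"),
             element = c(substr(ringNames, 1, 1), "O", "O"),
             x = coords[, 1], y = coords[, 2], z = 0,
             stringsAsFactors = FALSE)
}

#' Pair of flavin-like ring systems at a controlled edge gap
#'
#' Two coplanar isoalloxazine-like ring systems whose closest heavy-atom
#' pair is separated by exactly \code{gap} Angstrom.
#'
#' @param gap closest ring-ring heavy-atom distance (Angstrom, > 1).
#' @param resnames residue codes of the two rings (default both FMN).
#' @return An [AtomicStructure-class] with two hetero groups.
#' @export
makeFlavinPair <- function(gap, resnames = c("FMN", "FMN")) {
  if (gap <= 1) stop("gap must exceed 1 Angstrom")
  ring <- .flavinRingCoords()
  r1 <- ring
  r1$resname <- resnames[1]; r1$chain <- "B"; r1$resseq <- 801L
  r2 <- ring
  shift <- max(r1$x) - min(ring$x) + gap
  r2$x <- r2$x + shift
  r2$resname <- resnames[2]; r2$chain <- "C"; r2$resseq <- 802L
  both <- rbind(r1, r2)
  both$hetero <- TRUE
  AtomicStructure(both, id = "flavin_pair")
}

# symmetric unit direction sets for coordination numbers 1..8
.cnDirections <- function(cn) {
  s3 <- 1 / sqrt(3)
  sets <- list(
    rbind(c(1, 0, 0)),
    rbind(c(1, 0, 0), c(-1, 0, 0)),
    rbind(c(1, 0, 0), c(-0.5, sqrt(3) / 2, 0), c(-0.5, -sqrt(3) / 2, 0)),
    rbind(c(s3, s3, s3), c(s3, -s3, -s3), c(-s3, s3, -s3),
          c(-s3, -s3, s3)),
    rbind(c(1, 0, 0), c(-0.5, sqrt(3) / 2, 0), c(-0.5, -sqrt(3) / 2, 0),
          c(0, 0, 1), c(0, 0, -1)),
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
          c(0, 0, 1), c(0, 0, -1)),
    rbind(cbind(cos(2 * pi * (0:4) / 5), sin(2 * pi * (0:4) / 5), 0),
          c(0, 0, 1), c(0, 0, -1)),
    {
      a <- 2 * pi * (0:3) / 4
      rbind(cbind(cos(a), sin(a), 1 / sqrt(2)),
            cbind(cos(a + pi / 4), sin(a + pi / 4), -1 / sqrt(2))) /
        sqrt(1.5)
    })
  if (cn < 1 || cn > length(sets))
    stop("coordination numbers 1..8 are supported")
  m <- sets[[cn]]
  m / sqrt(rowSums(m^2))
}

#' Ion site with a controlled first coordination shell
#'
#' Places a monatomic ion at the centre with \code{cn} oxygen ligands at
#' exactly \code{meanDist} Angstrom in a symmetric arrangement.
#' \code{nWaters} of the ligands are water oxygens; the remainder are
#' backbone carbonyl oxygens (GLY residues). Infeasible shells (ligand
#' clashes closer than 2.2 Angstrom) are rejected.
#'
#' @param identity ion residue code, \code{"NA"} or \code{"K"}.
#' @param cn coordination number 1..8.
#' @param meanDist centre-ligand distance (Angstrom).
#' @param nWaters how many ligands are waters (default 0).
#' @param center ion position.
#' @param chain chain id of the ion (ligands go to chain L / W).
#' @return An [AtomicStructure-class].
#' @export
makeIonSite <- function(identity = c("NA", "K"), cn = 5, meanDist = 2.4,
                        nWaters = 0L, center = c(0, 0, 0), chain = "I") {
  identity <- match.arg(identity)
  dirs <- .cnDirections(cn)
  pos <- sweep(dirs * meanDist, 2, center, "+")
  if (cn >= 2) {
    dd <- as.matrix(stats::dist(pos))
    if (min(dd[upper.tri(dd)]) < 2.2)
      stop("infeasible shell: ligand-ligand clash at CN ", cn,
           " and distance ", meanDist)
  }
  if (nWaters > cn) stop("nWaters exceeds the coordination number")
  isWater <- seq_len(cn) > (cn - nWaters)
  ion <- data.frame(name = identity, element = identity,
                    resname = identity, chain = chain, resseq = 900L,
                    x = center[1], y = center[2], z = center[3],
                    hetero = TRUE)
  lig <- data.frame(name = "O", element = "O",
                    resname = ifelse(isWater, "HOH", "GLY"),
                    chain = ifelse(isWater, "W", "L"),
                    resseq = 100L + seq_len(cn),
                    x = pos[, 1], y = pos[, 2], z = pos[, 3],
                    hetero = isWater)
  AtomicStructure(rbind(ion, lig), id = "ion_site")
}

#' Atom-lined channel with a known radius profile
#'
#' Stacks rings of carbon atoms around the z axis. At the station of ring
#' k the true probe radius is \code{radii[k]}: the atoms sit at ring radius
#' \code{radii[k] + r_vdw(C)} so the analytic probe radius equals the
#' requested value.
#'
#' @param radii vector of true probe radii per ring (Angstrom).
#' @param step ring spacing along z (default 2 Angstrom).
#' @param ringAtoms atoms per ring (default 12).
#' @param zStart z of the first ring.
#' @return An [AtomicStructure-class]; ring k is residue \code{k} of chain
#'   P (residue code RNG).
#' @export
makeChannel <- function(radii, step = 2, ringAtoms = 12L, zStart = -2) {
  vdwC <- vdwTable()[["C"]]
  rows <- list()
  for (k in seq_along(radii)) {
    ang <- 2 * pi * (seq_len(ringAtoms) - 1L) / ringAtoms
    rr <- radii[k] + vdwC
    rows[[k]] <- data.frame(
      name = sprintf("C%02d", seq_len(ringAtoms)), element = "C",
      resname = "RNG", chain = "P", resseq = k,
      x = rr * cos(ang), y = rr * sin(ang),
      z = zStart + (k - 1) * step, hetero = FALSE)
  }
  AtomicStructure(do.call(rbind, rows), id = "channel")
}

#' Two-state pair with a known hinge rotation
#'
#' Builds a static core helix (chain A) plus a mobile domain helix
#' (chain B), then creates a second state in which the domain is rotated
#' by \code{angle} degrees about \code{axis} through a hinge point at the
#' domain's base, and the whole moving structure is additionally subjected
#' to a global rigid scramble (so that core superposition is actually
#' exercised).
#'
#' @param angle hinge rotation in degrees.
#' @param axis hinge axis direction.
#' @param nCore,nDomain residues in core and domain helices.
#' @param scramble optional list \code{list(rotation =, translation =)}
#'   applied to the whole moving state; defaults to a fixed non-trivial
#'   transform.
#' @return list \code{ref}, \code{mov} of [AtomicStructure-class], plus
#'   \code{hinge}, \code{axis}.
#' @export
makeHingePair <- function(angle, axis = c(0, 1, 0), nCore = 30L,
                          nDomain = 20L,
                          scramble = list(
                            rotation = rotationMatrix(c(1, 2, 3), 17),
                            translation = c(4, -2, 7))) {
  core <- makeIdealHelix(nCore, axis = c(0, 0, 1), origin = c(0, 0, 0),
                         chain = "A", startRes = 1L)
  hinge <- c(8, 0, 1.5 * nCore + 4)
  domain <- makeIdealHelix(nDomain, axis = c(1, 0, 0), origin = hinge,
                           chain = "B", startRes = 101L)
  ref <- AtomicStructure(rbind(atoms(core), atoms(domain)),
                         id = "hinge_ref")
  R <- rotationMatrix(axis, angle)
  domMoved <- transformStructure(domain, R,
                                 as.numeric(hinge - R %*% hinge))
  mov <- AtomicStructure(rbind(atoms(core), atoms(domMoved)),
                         id = "hinge_mov")
  mov <- transformStructure(mov, scramble$rotation, scramble$translation)
  list(ref = ref, mov = mov, hinge = hinge, axis = axis / sqrt(sum(axis^2)))
}

#' Simulated spectrum with seeded Gaussian noise
#'
#' @param model a [mossbauerDoublet()] or a list of [eprComponent()]s.
#' @param axis velocity (mm/s) or field (mT) grid.
#' @param noiseSigma Gaussian noise s.d. (>= 0), in ordinate units.
#' @param seed integer seed; the global RNG state is left untouched.
#' @param frequencyGHz required for EPR models.
#' @return A [Spectrum1D-class] with \code{noiseSigma} and \code{seed} in
#'   its metadata.
#' @export
makeNoisySpectrum <- function(model, axis, noiseSigma = 0, seed = 1L,
                              frequencyGHz = NULL) {
  if (noiseSigma < 0) stop("noiseSigma must be >= 0")
  base <- if (is(model, "MossbauerDoublet")) {
    simulateMossbauer(model, axis)
  } else {
    if (is.null(frequencyGHz))
      stop("frequencyGHz is required for EPR models")
    simulateEprPowder(model, frequencyGHz, axis)
  }
  noise <- if (noiseSigma > 0) {
    oldSeed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(oldSeed)) assign(".Random.seed", oldSeed,
                                    envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    stats::rnorm(length(axis), 0, noiseSigma)
  } else rep(0, length(axis))
  meta <- base@metadata
  meta$noiseSigma <- noiseSigma
  meta$seed <- seed
  spectrum1D(axis, base@ordinate + noise,
             axisUnit = meta$axisUnit, metadata = meta)
}
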
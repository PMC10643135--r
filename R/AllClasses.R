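#' @import methods
NULL

.ATOM_COLS <- c("serial", "name", "element", "altloc", "resname", "chain",
                "resseq", "inscode", "x", "y", "z", "occupancy", "bfactor",
                "hetero")

#' Atomic model container
#'
#' An \code{AtomicStructure} holds the atoms of one model of a macromolecular
#' structure as a flat table, preserving author chain identifiers and residue
#' numbering. All coordinates are in Angstrom. Hydrogens are dropped on input;
#' alternate locations are collapsed to a single conformer.
#'
#' @slot id single string identifying the structure (defaults to the file stem).
#' @slot atoms data.frame with one row per atom and columns
#'   \code{serial, name, element, altloc, resname, chain, resseq, inscode,
#'   x, y, z, occupancy, bfactor, hetero}.
#' @slot sourceFormat \code{"pdb"}, \code{"mmcif"} or \code{"memory"} for
#'   structures built programmatically.
#'
#' @seealso [readStructure()], [writeStructure()], [atoms()], [coords()]
#' @export
setClass("AtomicStructure",
         representation(id = "character",
                        atoms = "data.frame",
                        sourceFormat = "character"))

setValidity("AtomicStructure", function(object) {
  a <- object@atoms
  msg <- character()
  missing_cols <- setdiff(.ATOM_COLS, names(a))
  if (length(missing_cols))
    msg <- c(msg, paste("missing atom columns:",
                        paste(missing_cols, collapse = ", ")))
  if (length(msg)) return(msg)
  if (nrow(a)) {
    if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
      msg <- c(msg, "non-finite atom coordinates")
    occ <- a$occupancy
    if (any(!is.na(occ) & (occ < 0 | occ > 1)))
      msg <- c(msg, "occupancy outside [0, 1]")
    key <- paste(a$chain, a$resseq, a$inscode, a$name, a$altloc)
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate (chain, resseq, inscode, name, altloc) atom key")
  }
  if (length(object@id) != 1L) msg <- c(msg, "id must be a single string")
  if (length(msg)) msg else TRUE
})

#' Recognised redox cofactor
#'
#' A hetero group matched against the cofactor registry, carrying the subset
#' of its heavy atoms that form the redox-active "edge" used for
#' edge-to-edge distance measurements (conjugated ring system of flavins and
#' quinones, the Fe2S2 rhomb of iron-sulfur clusters, the bare ion for
#' monatomic ions).
#'
#' @slot kind registry kind, e.g. \code{"FMN"}, \code{"FES"}, \code{"ion"}.
#' @slot label unique label, by default \code{"<resname>_<chain><resseq>"}.
#' @slot chain,resseq author chain id and residue number of the group.
#' @slot atoms all heavy atoms of the group (data.frame, atom columns).
#' @slot edgeAtoms the redox-active subset of \code{atoms}.
#'
#' @seealso [extractCofactors()], [edgeToEdgeDistance()]
#' @export
setClass("Cofactor",
         representation(kind = "character", label = "character",
                        chain = "character", resseq = "integer",
                        atoms = "data.frame", edgeAtoms = "data.frame"))

setValidity("Cofactor", function(object) {
  msg <- character()
  if (nrow(object@edgeAtoms) == 0L)
    msg <- c(msg, "edgeAtoms is empty")
  if (!all(object@edgeAtoms$name %in% object@atoms$name))
    msg <- c(msg, "edgeAtoms not a subset of atoms")
  if (any(object@edgeAtoms$element %in% c("H", "D")))
    msg <- c(msg, "hydrogens are not allowed in edgeAtoms")
  if (length(msg)) msg else TRUE
})

#' Rigid-body domain motion between two states
#'
#' Result of [domainMotion()]: after superposing the two states on a static
#' core, the moving domain's own best-fit rigid transform is decomposed into
#' a rotation angle/axis and a screw translation along the axis. The largest
#' per-atom displacement of the domain (after core superposition, before any
#' domain fit) quantifies the reach of the motion.
#'
#' @slot rotationAngle degrees in [0, 180].
#' @slot rotationAxis unit 3-vector.
#' @slot screwTranslation Angstrom translated along the rotation axis.
#' @slot maxDisplacement largest per-atom displacement (Angstrom).
#' @slot centroidShift displacement of the domain centroid (Angstrom).
#' @slot rmsdDomain residual RMSD of the domain after fitting its own
#'   rigid transform (Angstrom); near zero for a truly rigid domain.
#' @slot nPairs number of paired atoms used.
#' @export
setClass("DomainTransform",
         representation(rotationAngle = "numeric", rotationAxis = "numeric",
                        screwTranslation = "numeric",
                        maxDisplacement = "numeric",
                        centroidShift = "numeric",
                        rmsdDomain = "numeric", nPairs = "integer"))

setValidity("DomainTransform", function(object) {
  msg <- character()
  if (object@rotationAngle < -1e-9 || object@rotationAngle > 180 + 1e-9)
    msg <- c(msg, "rotationAngle outside [0, 180]")
  if (abs(sqrt(sum(object@rotationAxis^2)) - 1) > 1e-6)
    msg <- c(msg, "rotationAxis is not unit length")
  if (object@maxDisplacement < 0) msg <- c(msg, "negative maxDisplacement")
  if (length(msg)) msg else TRUE
})

#' First coordination shell of a candidate ion position
#'
#' All non-hydrogen, non-carbon atoms within the cutoff of a centre,
#' classified by ligand chemistry. Basis of the Na+/K+/water site call.
#'
#' @slot center 3-vector (Angstrom).
#' @slot ligands data.frame: \code{name, resname, chain, resseq, element,
#'   class, distance} with class one of backbone carbonyl O / side-chain O /
#'   water O / N / S / other.
#' @slot coordinationNumber number of ligands.
#' @slot meanDistance mean centre-ligand distance (Angstrom).
#' @slot minAngle smallest ligand-centre-ligand angle (degrees; \code{NA}
#'   for fewer than two ligands).
#' @slot cutoff shell cutoff used (Angstrom).
#' @seealso [findCoordination()], [classifySite()]
#' @export
setClass("CoordinationShell",
         representation(center = "numeric", ligands = "data.frame",
                        coordinationNumber = "integer",
                        meanDistance = "numeric", minAngle = "numeric",
                        cutoff = "numeric"))

setValidity("CoordinationShell", function(object) {
  msg <- character()
  if (object@coordinationNumber != nrow(object@ligands))
    msg <- c(msg, "coordinationNumber disagrees with ligand table")
  if (nrow(object@ligands)) {
    if (any(object@ligands$distance > object@cutoff + 1e-9))
      msg <- c(msg, "ligand beyond cutoff")
    if (!is.na(object@meanDistance) &&
        (object@meanDistance < min(object@ligands$distance) - 1e-9 ||
         object@meanDistance > max(object@ligands$distance) + 1e-9))
      msg <- c(msg, "meanDistance outside ligand distance range")
  }
  if (length(msg)) msg else TRUE
})

#' Channel radius profile
#'
#' Probe-sphere radius along a user-defined pathway line, one point per
#' station. The radius at a station is the largest sphere centred in the
#' plane normal to the pathway that does not overlap any atom's van der
#' Waals sphere.
#'
#' @slot points data.frame: \code{station, x, y, z, radius} plus the three
#'   nearest atoms (\code{nearest1..3}, formatted \code{"RES chain:resseq
#'   name (gap)"}).
#' @slot seed integer seed that made the stochastic optimisation
#'   reproducible.
#' @slot parameters list: step, bulk radius cap, restart count, van der
#'   Waals table.
#' @seealso [poreProfile()], [constrictionReport()]
#' @export
setClass("PoreProfile",
         representation(points = "data.frame", seed = "integer",
                        parameters = "list"))

setValidity("PoreProfile", function(object) {
  p <- object@points
  msg <- character()
  if (nrow(p) > 1 && any(diff(p$station) <= 0))
    msg <- c(msg, "stations not strictly increasing")
  if (nrow(p) && any(p$radius < 0)) msg <- c(msg, "negative radius")
  if (length(msg)) msg else TRUE
})

#' One-dimensional spectrum
#'
#' A sampled 1-D lineshape: velocity axis (mm/s) for Moessbauer spectra or
#' magnetic field axis (mT) for EPR spectra.
#'
#' @slot axis strictly increasing abscissa values.
#' @slot ordinate signal values, same length as \code{axis}.
#' @slot metadata list: \code{axisUnit}, and where relevant
#'   \code{frequencyGHz}, \code{noiseSigma}, \code{seed}.
#' @export
setClass("Spectrum1D",
         representation(axis = "numeric", ordinate = "numeric",
                        metadata = "list"))

setValidity("Spectrum1D", function(object) {
  msg <- character()
  if (length(object@axis) != length(object@ordinate))
    msg <- c(msg, "axis and ordinate lengths differ")
  if (length(object@axis) > 1 && any(diff(object@axis) <= 0))
    msg <- c(msg, "axis not strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Moessbauer quadrupole doublet model
#'
#' Zero-field doublet of two Lorentzian lines centred at
#' \code{isomerShift +/- quadrupoleSplitting/2}, with total area
#' \code{amplitude} split between the lines by \code{asymmetry}
#' (ratio of low- to high-velocity line area).
#'
#' @slot isomerShift delta, mm/s.
#' @slot quadrupoleSplitting Delta-E_Q >= 0, mm/s.
#' @slot linewidth Lorentzian FWHM Gamma > 0, mm/s (default 0.24, a typical
#'   minimum experimental linewidth).
#' @slot amplitude total absorption area (arbitrary units).
#' @slot asymmetry area ratio of the two lines (1 = symmetric doublet).
#' @seealso [simulateMossbauer()], [fitMossbauer()]
#' @export
setClass("MossbauerDoublet",
         representation(isomerShift = "numeric",
                        quadrupoleSplitting = "numeric",
                        linewidth = "numeric", amplitude = "numeric",
                        asymmetry = "numeric"))

setValidity("MossbauerDoublet", function(object) {
  msg <- character()
  if (object@linewidth <= 0) msg <- c(msg, "linewidth must be > 0")
  if (object@quadrupoleSplitting < 0)
    msg <- c(msg, "quadrupoleSplitting must be >= 0")
  if (object@asymmetry <= 0) msg <- c(msg, "asymmetry must be > 0")
  if (length(msg)) msg else TRUE
})

#' CW EPR spectral component
#'
#' One component of a powder EPR simulation: either an axial species with
#' effective g values \code{gPar}/\code{gPerp} or an isotropic species with
#' \code{gIso}. Linewidth is the Gaussian FWHM in gauss; \code{weight} is the
#' component's fraction of the total absorption double integral.
#'
#' @slot kind \code{"axial"} or \code{"isotropic"}.
#' @slot gPar,gPerp,gIso dimensionless g values (only the relevant ones set).
#' @slot linewidth Gaussian FWHM, gauss.
#' @slot weight fraction in [0, 1].
#' @seealso [simulateEprPowder()], [fitEprWeights()]
#' @export
setClass("EprComponent",
         representation(kind = "character", gPar = "numeric",
                        gPerp = "numeric", gIso = "numeric",
                        linewidth = "numeric", weight = "numeric"))

setValidity("EprComponent", function(object) {
  msg <- character()
  if (!object@kind %in% c("axial", "isotropic"))
    msg <- c(msg, "kind must be 'axial' or 'isotropic'")
  gs <- if (object@kind == "axial") c(object@gPar, object@gPerp) else
    object@gIso
  if (any(!is.finite(gs)) || any(gs <= 1.5) || any(gs >= 2.5))
    msg <- c(msg, "g values must lie in (1.5, 2.5)")
  if (object@linewidth <= 0) msg <- c(msg, "linewidth must be > 0")
  if (object@weight < 0 || object@weight > 1)
    msg <- c(msg, "weight must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Cofactor chain distance/rate report
#'
#' All-pairs edge-to-edge distances along an ordered cofactor chain, with
#' empirical tunneling rates and a fast/obstructed classification against a
#' distance threshold.
#'
#' @slot order cofactor labels in chain order.
#' @slot pairs data.frame: \code{a, b, consecutive, distance, atomA, atomB,
#'   log10Rate, rate, class}.
#' @slot fastThreshold Angstrom threshold separating fast from obstructed
#'   pairs.
#' @seealso [buildChainReport()]
#' @export
setClass("ChainReport",
         representation(order = "character", pairs = "data.frame",
                        fastThreshold = "numeric"))
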
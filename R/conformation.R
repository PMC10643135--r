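#' Atom selection by chain, residue range and atom name
#'
#' @param chain chain identifier.
#' @param resseq integer vector of residue numbers (any order, ranges
#'   welcome, e.g. \code{5:40}); \code{NULL} selects the whole chain.
#' @param atomNames atom-name filter, default \code{"CA"}.
#' @return a \code{SelectionSpec} list.
#' @export
selectionSpec <- function(chain, resseq = NULL, atomNames = "CA") {
  structure(list(chain = chain, resseq = resseq, atomNames = atomNames),
            class = "SelectionSpec")
}

.resolveSelection <- function(s, spec) {
  a <- atoms(s)
  keep <- a$chain %in% spec$chain
  if (!is.null(spec$resseq)) keep <- keep & a$resseq %in% spec$resseq
  if (!is.null(spec$atomNames)) keep <- keep & a$name %in% spec$atomNames
  a <- a[keep, , drop = FALSE]
  a[order(a$chain, a$resseq, a$inscode, a$name), , drop = FALSE]
}

# Pair atoms of two structures by (chain, resseq, inscode, name).
.pairedCoords <- function(ref, mov, spec) {
  ra <- .resolveSelection(ref, spec)
  ma <- .resolveSelection(mov, spec)
  rkey <- paste(ra$chain, ra$resseq, ra$inscode, ra$name)
  mkey <- paste(ma$chain, ma$resseq, ma$inscode, ma$name)
  common <- intersect(rkey, mkey)
  if (length(common) < length(rkey) || length(common) < length(mkey)) {
    unmatched <- union(setdiff(rkey, mkey), setdiff(mkey, rkey))
    warning("unmatched atoms dropped from pairing: ",
            paste(utils::head(unmatched, 5), collapse = "; "),
            if (length(unmatched) > 5) " ..." else "", call. = FALSE)
  }
  list(ref = as.matrix(ra[match(common, rkey), c("x", "y", "z")]),
       mov = as.matrix(ma[match(common, mkey), c("x", "y", "z")]),
       keys = common)
}

# Kabsch: least-squares proper rotation R and translation t such that
# R %*% mov_i + t ~ ref_i. det(R) = +1 always (no improper solutions).
.kabsch <- function(refm, movm) {
  stopifnot(nrow(refm) == nrow(movm), nrow(refm) >= 3L)
  cr <- colMeans(refm); cm <- colMeans(movm)
  P <- sweep(movm, 2, cm); Q <- sweep(refm, 2, cr)
  H <- t(P) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- as.numeric(cr - R %*% cm)
  fitted <- sweep(movm %*% t(R), 2, t, "+")
  rmsd <- sqrt(mean(rowSums((fitted - refm)^2)))
  list(rotation = R, translation = t, rmsd = rmsd)
}

.checkNonCollinear <- function(m) {
  if (nrow(m) < 3L) stop("fewer than 3 paired atoms")
  sv <- svd(sweep(m, 2, colMeans(m)))$d
  if (sv[2] < 1e-6 * max(sv[1], 1))
    stop("paired atoms are collinear; superposition is underdetermined")
}

#' Least-squares superposition of two states
#'
#' Pairs atoms of a core selection by (chain, residue, atom name) and finds
#' the proper rotation + translation that best superposes the moving
#' structure onto the reference (Kabsch algorithm; the determinant of the
#' rotation is constrained to +1, so mirror solutions are never returned).
#'
#' @param ref,mov two [AtomicStructure-class] states of the same molecule.
#' @param core a [selectionSpec()] resolving to >= 3 non-collinear paired
#'   atoms.
#' @return list: \code{rotation} (3x3), \code{translation} (3-vector),
#'   \code{rmsd} (Angstrom over the core pairs), \code{nPairs}.
#' @export
superpose <- function(ref, mov, core) {
  pc <- .pairedCoords(ref, mov, core)
  .checkNonCollinear(pc$ref)
  .checkNonCollinear(pc$mov)
  fit <- .kabsch(pc$ref, pc$mov)
  fit$nPairs <- nrow(pc$ref)
  fit
}

# angle (deg, [0,180]) and unit axis of a rotation matrix
.rotAngleAxis <- function(R) {
  cosA <- (sum(diag(R)) - 1) / 2
  cosA <- min(1, max(-1, cosA))
  angle <- acos(cosA) * 180 / pi
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  nv <- sqrt(sum(v^2))
  if (nv > 1e-8) {
    axis <- v / nv
  } else if (angle < 90) {       # angle ~ 0: axis arbitrary
    axis <- c(0, 0, 1)
  } else {                       # angle ~ 180: axis from symmetric part
    ev <- eigen((R + diag(3)) / 2, symmetric = TRUE)
    axis <- ev$vectors[, which.max(ev$values)]
    axis <- axis / sqrt(sum(axis^2))
  }
  list(angle = angle, axis = axis)
}

#' Rigid-body motion of a domain between two states
#'
#' Superposes the two states on a static core, then fits the best rigid
#' transform of the (core-aligned) moving domain relative to the reference
#' domain and decomposes it into rotation angle/axis and screw translation.
#' The maximum displacement is the largest per-atom shift of the domain
#' after core superposition -- the reach of the motion at the domain's
#' distal tip.
#'
#' @param ref,mov the two states.
#' @param core [selectionSpec()] for the static core (e.g. the
#'   transmembrane subunits).
#' @param domain [selectionSpec()] for the moving domain; must be disjoint
#'   from the core.
#' @return A [DomainTransform-class].
#' @examples
#' hp <- makeHingePair(26)
#' dm <- domainMotion(hp$ref, hp$mov,
#'                    core = selectionSpec("A"), domain = selectionSpec("B"))
#' dm@rotationAngle
#' @export
domainMotion <- function(ref, mov, core, domain) {
  if (identical(core$chain, domain$chain) &&
      (is.null(core$resseq) || is.null(domain$resseq) ||
       length(intersect(core$resseq, domain$resseq))))
    stop("core and domain selections must be disjoint")
  fit <- superpose(ref, mov, core)
  movAligned <- transformStructure(mov, fit$rotation, fit$translation)
  pc <- .pairedCoords(ref, movAligned, domain)
  .checkNonCollinear(pc$ref)
  # transform carrying the reference domain onto the aligned moving domain
  dfit <- .kabsch(pc$mov, pc$ref)
  aa <- .rotAngleAxis(dfit$rotation)
  disp <- sqrt(rowSums((pc$mov - pc$ref)^2))
  centShift <- sqrt(sum((colMeans(pc$mov) - colMeans(pc$ref))^2))
  new("DomainTransform",
      rotationAngle = aa$angle, rotationAxis = aa$axis,
      screwTranslation = sum(aa$axis * dfit$translation),
      maxDisplacement = max(disp), centroidShift = centShift,
      rmsdDomain = dfit$rmsd, nPairs = nrow(pc$ref))
}

setMethod("show", "DomainTransform", function(object) {
  cat(sprintf(paste0("DomainTransform: rotation %.1f deg about (%.2f %.2f ",
                     "%.2f), screw %.1f A\n"),
              object@rotationAngle, object@rotationAxis[1],
              object@rotationAxis[2], object@rotationAxis[3],
              object@screwTranslation))
  cat(sprintf("  max displacement %.1f A, centroid shift %.1f A, domain rmsd %.2f A (%d atoms)\n",
              object@maxDisplacement, object@centroidShift,
              object@rmsdDomain, object@nPairs))
})

#' Principal axis of a helical Calpha trace
#'
#' First principal component of the Calpha coordinates, with the direction
#' disambiguated to point from N to C terminus. The fit RMSD is the root
#' mean square perpendicular distance of the atoms from the axis line; for
#' an ideal alpha-helix it equals the helix radius spread (~0), and values
#' above ~1 Angstrom indicate a non-helical selection.
#'
#' @param m n x 3 matrix of Calpha coordinates in N-to-C order (n >= 7).
#' @return list: \code{centroid}, \code{direction} (unit), \code{fitRmsd}.
#' @export
helixAxis <- function(m) {
  if (nrow(m) < 7L) stop("helix axis fit needs >= 7 Calpha atoms")
  cen <- colMeans(m)
  sv <- svd(sweep(m, 2, cen))
  dir <- sv$v[, 1]
  if (sum(dir * (m[nrow(m), ] - m[1, ])) < 0) dir <- -dir
  # perpendicular residuals to the axis line
  rel <- sweep(m, 2, cen)
  par <- rel %*% dir
  perp2 <- rowSums(rel^2) - as.numeric(par)^2
  radial <- sqrt(pmax(perp2, 0))
  # spread about the mean helix radius, not the raw radial distance
  fitRmsd <- sqrt(mean((radial - mean(radial))^2))
  list(centroid = cen, direction = as.numeric(dir), fitRmsd = fitRmsd)
}

#' Tilt of a helix between two states
#'
#' After superposing the two states on a core, fits the principal axis of
#' the helix Calpha trace in each state (N-to-C oriented) and returns the
#' angle between the two axes, together with the helix centroid shift.
#'
#' @param ref,mov the two states.
#' @param core [selectionSpec()] for the static core.
#' @param helix [selectionSpec()] covering >= 7 consecutive residues of the
#'   helix (Calpha atoms).
#' @return list: \code{tilt} (degrees), \code{shift} (Angstrom, centroid
#'   displacement), \code{refAxis}, \code{movAxis} (see [helixAxis()]).
#' @export
helixTilt <- function(ref, mov, core, helix) {
  fit <- superpose(ref, mov, core)
  movAligned <- transformStructure(mov, fit$rotation, fit$translation)
  pc <- .pairedCoords(ref, movAligned, helix)
  if (nrow(pc$ref) < 7L) stop("helix selection resolves to < 7 paired Calpha")
  axR <- helixAxis(pc$ref)
  axM <- helixAxis(pc$mov)
  if (axR$fitRmsd > 1.0 || axM$fitRmsd > 1.0)
    warning("helix axis fit rmsd > 1.0 Angstrom: selection may not be helical",
            call. = FALSE)
  cosA <- min(1, max(-1, sum(axR$direction * axM$direction)))
  list(tilt = acos(cosA) * 180 / pi,
       shift = sqrt(sum((axM$centroid - axR$centroid)^2)),
       refAxis = axR, movAxis = axM)
}

#' Crosslink distance-restraint compatibility
#'
#' Checks Calpha-Calpha distances of crosslinked residue pairs against the
#' maximum span of the crosslinker (default 30 Angstrom, appropriate for
#' lysine-lysine DSS including side-chain flexibility). Unresolvable
#' residues are flagged, not dropped.
#'
#' @param s an [AtomicStructure-class].
#' @param pairs data.frame with columns \code{chain1, res1, chain2, res2}.
#' @param maxAllowed Angstrom (default 30).
#' @return data.frame: the input pairs plus \code{caDistance},
#'   \code{maxAllowed}, \code{compatible}, \code{resolved}.
#' @export
crosslinkCheck <- function(s, pairs, maxAllowed = 30) {
  if (!nrow(pairs))
    return(cbind(pairs, data.frame(caDistance = numeric(),
                                   maxAllowed = numeric(),
                                   compatible = logical(),
                                   resolved = logical())))
  a <- atoms(s)
  ca <- a[a$name == "CA", , drop = FALSE]
  lookup <- function(chain, res) {
    hit <- which(ca$chain == chain & ca$resseq == res)
    if (length(hit)) as.numeric(ca[hit[1], c("x", "y", "z")]) else NULL
  }
  out <- pairs
  out$caDistance <- NA_real_
  out$maxAllowed <- maxAllowed
  out$compatible <- NA
  out$resolved <- FALSE
  for (i in seq_len(nrow(pairs))) {
    p1 <- lookup(pairs$chain1[i], pairs$res1[i])
    p2 <- lookup(pairs$chain2[i], pairs$res2[i])
    if (is.null(p1) || is.null(p2)) next
    d <- sqrt(sum((p1 - p2)^2))
    out$caDistance[i] <- d
    out$compatible[i] <- d <= maxAllowed
    out$resolved[i] <- TRUE
  }
  out
}
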
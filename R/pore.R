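#' Van der Waals radius table
#'
#' Bondi-style radii used by the pore profiler; unknown elements fall back
#' to the carbon radius.
#'
#' @param overrides optional named numeric vector of replacements
#'   (element = radius in Angstrom).
#' @return named numeric vector.
#' @export
vdwTable <- function(overrides = NULL) {
  tab <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
           FE = 1.40, "NA" = 2.27, K = 2.75, MG = 1.73, CA = 2.31,
           ZN = 1.39, CL = 1.75)
  if (!is.null(overrides)) tab[names(overrides)] <- overrides
  tab
}

.vdwRadii <- function(elements, tab) {
  r <- unname(tab[elements])
  r[is.na(r)] <- tab[["C"]]
  r
}

# orthonormal basis (u, v) of the plane normal to w
.planeBasis <- function(w) {
  w <- w / sqrt(sum(w^2))
  a <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * w) * w
  u <- u / sqrt(sum(u^2))
  v <- c(w[2] * u[3] - w[3] * u[2],
         w[3] * u[1] - w[1] * u[3],
         w[1] * u[2] - w[2] * u[1])
  list(w = w, u = u, v = v)
}

#' Channel radius profile along a pathway
#'
#' Marches along the line \code{start + t * direction} in steps of
#' \code{step} and, at each station, finds the largest probe sphere centred
#' in the plane normal to the pathway that does not overlap any atom's van
#' der Waals sphere. The in-plane centre is optimised by seeded random
#' restarts (each station is also seeded from the previous optimum, which
#' keeps the centerline continuous) followed by Nelder-Mead refinement.
#' The march stops on each side when the radius exceeds \code{bulkCap}
#' (the probe has reached bulk) or no atoms remain near the plane.
#'
#' The profile is deterministic for a given seed.
#'
#' @param s an [AtomicStructure-class].
#' @param start 3-vector on the pathway (Angstrom).
#' @param direction pathway direction (need not be unit length).
#' @param step station spacing in (0.1, 1.0] Angstrom (default 0.25).
#' @param seed integer seed for the restart sampler.
#' @param bulkCap radius (Angstrom) above which the probe is considered in
#'   bulk solvent (default 10).
#' @param nRestarts random restarts per station (default 16).
#' @param maxHalfLength maximum march distance each way (default 50).
#' @param vdw radius table from [vdwTable()].
#' @param searchRadius in-plane search disc radius (default 5).
#' @return A [PoreProfile-class].
#' @examples
#' ch <- makeChannel(c(5, 3, 5))
#' pp <- poreProfile(ch, start = c(0, 0, 0), direction = c(0, 0, 1),
#'                   seed = 1)
#' min(profilePoints(pp)$radius)  # ~ 3 - 1.7 = 1.3
#' @export
poreProfile <- function(s, start, direction, step = 0.25, seed = 1L,
                        bulkCap = 10, nRestarts = 16L, maxHalfLength = 50,
                        vdw = vdwTable(), searchRadius = 5) {
  if (!(step > 0.1 && step <= 1.0))
    stop("step must lie in (0.1, 1.0] Angstrom")
  if (sqrt(sum(direction^2)) < 1e-12) stop("direction must be non-zero")
  basis <- .planeBasis(direction)
  xyz <- coords(s)
  if (!nrow(xyz)) stop("no channel environment: structure has no atoms")
  radii <- .vdwRadii(atoms(s)$element, vdw)
  reach <- bulkCap + max(radii) + searchRadius
  clearance <- function(center) {
    d2 <- (xyz[, 1] - center[1])^2 + (xyz[, 2] - center[2])^2 +
      (xyz[, 3] - center[3])^2
    min(sqrt(d2) - radii)
  }
  # stochastic restarts + local refinement, all RNG local to the call
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed,
                                  envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  optimStation <- function(p0, prevUV) {
    planePoint <- function(uv) p0 + uv[1] * basis$u + uv[2] * basis$v
    # clearance capped just above bulk and the centre confined to the
    # search disc, so the probe cannot drift out of the channel sideways
    obj <- function(uv) {
      pen <- max(0, sqrt(sum(uv^2)) - searchRadius)
      -(min(clearance(planePoint(uv)), bulkCap + 0.5)) + 100 * pen^2
    }
    starts <- rbind(c(0, 0), prevUV,
                    matrix(stats::runif(2L * nRestarts, -searchRadius,
                                        searchRadius), ncol = 2L))
    best <- NULL
    for (k in seq_len(nrow(starts))) {
      o <- stats::optim(starts[k, ], obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-10, maxit = 400))
      if (is.null(best) || o$value < best$value) best <- o
    }
    list(uv = best$par, center = planePoint(best$par),
         radius = max(0, min(clearance(planePoint(best$par)),
                             bulkCap + 0.5)))
  }
  march <- function(sgn) {
    pts <- list(); prevUV <- c(0, 0); t <- if (sgn > 0) step else -step
    repeat {
      p0 <- start + t * basis$w
      dAx <- sqrt(colSums((t(xyz) - p0)^2))
      if (min(dAx) > reach) break
      opt <- optimStation(p0, prevUV)
      pts[[length(pts) + 1L]] <- c(t, opt$center, opt$radius)
      if (opt$radius > bulkCap || abs(t) >= maxHalfLength) break
      prevUV <- opt$uv
      t <- t + sgn * step
    }
    pts
  }
  p0 <- start
  if (min(sqrt(colSums((t(xyz) - p0)^2))) > reach)
    stop("no channel environment: no atoms near the pathway start")
  opt0 <- optimStation(p0, c(0, 0))
  if (opt0$radius == 0)
    warning("pathway start lies inside an atom; radius clamped at 0",
            call. = FALSE)
  rows <- c(rev(march(-1)), list(c(0, opt0$center, opt0$radius)),
            march(+1))
  m <- do.call(rbind, rows)
  pts <- data.frame(station = m[, 1], x = m[, 2], y = m[, 3], z = m[, 4],
                    radius = m[, 5])
  # three nearest atoms (by gap to the vdW surface) at each station
  a <- atoms(s)
  near <- t(vapply(seq_len(nrow(pts)), function(i) {
    cen <- as.numeric(pts[i, c("x", "y", "z")])
    gap <- sqrt((a$x - cen[1])^2 + (a$y - cen[2])^2 +
                  (a$z - cen[3])^2) - radii
    ord <- order(gap)[seq_len(min(3L, nrow(a)))]
    out <- sprintf("%s %s:%d %s (%.2f)", a$resname[ord], a$chain[ord],
                   a$resseq[ord], a$name[ord], gap[ord])
    length(out) <- 3L
    out
  }, character(3)))
  pts$nearest1 <- near[, 1]; pts$nearest2 <- near[, 2]
  pts$nearest3 <- near[, 3]
  new("PoreProfile", points = pts, seed = as.integer(seed),
      parameters = list(step = step, bulkCap = bulkCap,
                        nRestarts = nRestarts, vdw = vdw,
                        start = start, direction = basis$w))
}

#' @describeIn poreProfile station table of a profile.
#' @param profile a [PoreProfile-class].
#' @export
profilePoints <- function(profile) profile@points

setMethod("show", "PoreProfile", function(object) {
  p <- object@points
  i <- which.min(p$radius)
  cat(sprintf("PoreProfile: %d stations over [%.1f, %.1f] A (step %.2f, seed %d)\n",
              nrow(p), min(p$station), max(p$station),
              object@parameters$step, object@seed))
  cat(sprintf("  constriction: radius %.2f A at station %.2f (%s)\n",
              p$radius[i], p$station[i], p$nearest1[i]))
})

#' Constriction of a pore profile
#'
#' Returns the station of globally minimal radius and the residues owning
#' the five atoms nearest (by van der Waals gap) to the constriction
#' centre.
#'
#' @param profile a [PoreProfile-class].
#' @param s the [AtomicStructure-class] the profile was computed on.
#' @return list: \code{point} (one-row data.frame) and \code{residues}
#'   (data.frame \code{resname, chain, resseq, gap}).
#' @export
constrictionReport <- function(profile, s) {
  p <- profilePoints(profile)
  if (!nrow(p)) stop("empty profile")
  i <- which.min(p$radius)
  cen <- as.numeric(p[i, c("x", "y", "z")])
  a <- atoms(s)
  gap <- sqrt((a$x - cen[1])^2 + (a$y - cen[2])^2 + (a$z - cen[3])^2) -
    .vdwRadii(a$element, profile@parameters$vdw)
  ord <- order(gap)[seq_len(min(5L, nrow(a)))]
  res <- data.frame(resname = a$resname[ord], chain = a$chain[ord],
                    resseq = a$resseq[ord], gap = gap[ord],
                    stringsAsFactors = FALSE)
  res <- res[!duplicated(res[, c("resname", "chain", "resseq")]), ,
             drop = FALSE]
  list(point = p[i, , drop = FALSE], residues = res)
}
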
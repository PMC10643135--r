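#' Edge-to-edge distance between two cofactors
#'
#' Minimum Euclidean distance between any heavy atom of the first cofactor's
#' edge set and any heavy atom of the second's -- the distance that governs
#' electron tunneling between the centres.
#'
#' @param a,b [Cofactor-class] objects with non-empty edge sets.
#' @return list with elements \code{a}, \code{b} (labels), \code{distance}
#'   (Angstrom) and \code{atomA}, \code{atomB} (names of the achieving
#'   atoms, qualified by residue).
#' @examples
#' cf <- extractCofactors(makeFlavinPair(5.7))
#' edgeToEdgeDistance(cf[[1]], cf[[2]])$distance
#' @export
edgeToEdgeDistance <- function(a, b) {
  for (cf in list(a, b)) {
    if (nrow(cf@edgeAtoms) == 0L)
      stop("cofactor '", cf@label, "' has an empty edge set")
  }
  pa <- as.matrix(a@edgeAtoms[, c("x", "y", "z")])
  pb <- as.matrix(b@edgeAtoms[, c("x", "y", "z")])
  # squared cross-distance matrix
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
  d2[d2 < 0] <- 0
  ij <- arrayInd(which.min(d2), dim(d2))
  atomTag <- function(cf, i) paste0(cf@edgeAtoms$resname[i], "_",
                                    cf@edgeAtoms$chain[i],
                                    cf@edgeAtoms$resseq[i], ":",
                                    cf@edgeAtoms$name[i])
  list(a = a@label, b = b@label,
       distance = sqrt(d2[ij[1], ij[2]]),
       atomA = atomTag(a, ij[1]), atomB = atomTag(b, ij[2]))
}

#' Parameters of the empirical electron-tunneling ruler
#'
#' The exergonic Moser-Dutton parameterisation
#' \deqn{\log_{10} k = A - B\,R - C\,(\Delta G + \lambda)^2/\lambda}
#' with defaults \eqn{A = 15} (log10 s^-1), \eqn{B = 0.6} (log10 per
#' Angstrom) and \eqn{C = 3.1} (eV^-1). With \code{activationless = TRUE}
#' (or \eqn{\Delta G = -\lambda}) the Franck-Condon term vanishes and the
#' rate depends on distance alone. Endergonic steps are handled by supplying
#' \code{deltaG > 0} in the same expression.
#'
#' @param intercept log10 rate at zero distance (default 15).
#' @param slope distance decay, log10 per Angstrom (default 0.6, > 0).
#' @param fcCoeff Franck-Condon coefficient, 1/eV (default 3.1).
#' @param deltaG driving force in eV (negative = exergonic); required unless
#'   \code{activationless}.
#' @param lambda reorganisation energy in eV (> 0); required unless
#'   \code{activationless}.
#' @param activationless if TRUE, forces \eqn{\Delta G = -\lambda}.
#' @return validated parameter list of class \code{"RulerParams"}.
#' @export
rulerParams <- function(intercept = 15, slope = 0.6, fcCoeff = 3.1,
                        deltaG = NULL, lambda = NULL,
                        activationless = is.null(deltaG) && is.null(lambda)) {
  if (slope <= 0) stop("slope must be > 0")
  if (!activationless) {
    if (is.null(deltaG) || is.null(lambda))
      stop("deltaG and lambda are required unless activationless = TRUE")
    if (lambda <= 0) stop("lambda must be > 0")
  }
  structure(list(intercept = intercept, slope = slope, fcCoeff = fcCoeff,
                 deltaG = deltaG, lambda = lambda,
                 activationless = activationless),
            class = "RulerParams")
}

#' Electron-tunneling rate at a given edge-to-edge distance
#'
#' Evaluates the empirical ruler (see [rulerParams()]). Distances below van
#' der Waals contact (3.6 Angstrom) are clamped to contact with a warning.
#'
#' @param distance edge-to-edge distance R, Angstrom.
#' @param params a [rulerParams()] object.
#' @return rate in s^-1 (vectorised over \code{distance}).
#' @examples
#' etRate(14, rulerParams())         # ~10^6.6 s^-1
#' log10(etRate(3.6, rulerParams())) # 12.84 at contact
#' @export
etRate <- function(distance, params = rulerParams()) {
  stopifnot(inherits(params, "RulerParams"))
  if (any(distance < 3.6)) {
    warning("distance below 3.6 Angstrom contact; clamped", call. = FALSE)
    distance <- pmax(distance, 3.6)
  }
  fc <- if (params$activationless) 0 else
    params$fcCoeff * (params$deltaG + params$lambda)^2 / params$lambda
  10^(params$intercept - params$slope * distance - fc)
}

#' Ratio of tunneling rates at two distances
#'
#' With the Franck-Condon term shared between the two steps it cancels, and
#' the ratio is purely distance-determined:
#' \eqn{k_1/k_2 = 10^{B |R_2 - R_1|}}.
#'
#' @param r1,r2 edge-to-edge distances, Angstrom.
#' @param params a [rulerParams()] object (only the slope enters).
#' @return dimensionless rate ratio (>= 1).
#' @examples
#' rateRatio(7.2, 27.3)  # ~1.1e12
#' @export
rateRatio <- function(r1, r2, params = rulerParams()) {
  stopifnot(inherits(params, "RulerParams"))
  10^(params$slope * abs(r2 - r1))
}

#' Distance at which the ruler yields a given rate
#'
#' Inverts the activationless ruler \eqn{\log_{10} k = A - B R} for R.
#'
#' @param log10Rate target rate as log10(s^-1).
#' @param params a [rulerParams()] object.
#' @return distance in Angstrom.
#' @examples
#' rulerDistance(6.5)  # ~14 Angstrom for mid-band fast transfer
#' @export
rulerDistance <- function(log10Rate, params = rulerParams()) {
  stopifnot(inherits(params, "RulerParams"))
  fc <- if (params$activationless) 0 else
    params$fcCoeff * (params$deltaG + params$lambda)^2 / params$lambda
  (params$intercept - fc - log10Rate) / params$slope
}

#' All-pairs distance and rate report along a cofactor chain
#'
#' Computes edge-to-edge distances between every pair of cofactors in a
#' stated chain order, converts them to tunneling rates, and classifies each
#' pair as \code{"fast"} (distance <= threshold) or \code{"obstructed"}.
#'
#' @param cofactors list of [Cofactor-class] objects (e.g. from
#'   [extractCofactors()]).
#' @param order character vector of cofactor labels defining the chain
#'   order; each must resolve to exactly one instance. Unqualified residue
#'   codes (e.g. \code{"FMN"}) are accepted when unambiguous.
#' @param params a [rulerParams()] object.
#' @param fastThreshold Angstrom; default 14, the distance at which
#'   activationless rates fall to the 10^6-10^7 s^-1 band typical of
#'   productive electron transfer.
#' @return A [ChainReport-class].
#' @export
buildChainReport <- function(cofactors, order = NULL,
                             params = rulerParams(), fastThreshold = 14) {
  labels <- vapply(cofactors, function(cf) cf@label, character(1))
  if (is.null(order)) order <- labels
  idx <- vapply(order, function(lab) {
    hit <- which(labels == lab)
    if (!length(hit)) {
      kinds <- vapply(cofactors, function(cf) cf@kind, character(1))
      codes <- sub("_.*$", "", labels)
      hit <- which(codes == lab | kinds == lab)
    }
    if (length(hit) == 0L)
      stop("label '", lab, "' matches no cofactor")
    if (length(hit) > 1L)
      stop("label '", lab, "' is ambiguous (matches ",
           paste(labels[hit], collapse = ", "),
           "); qualify it with chain/residue")
    hit
  }, integer(1))
  n <- length(idx)
  if (n < 2L)
    return(new("ChainReport", order = unname(labels[idx]),
               pairs = data.frame(), fastThreshold = fastThreshold))
  rows <- list()
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    dp <- edgeToEdgeDistance(cofactors[[idx[i]]], cofactors[[idx[j]]])
    k <- suppressWarnings(etRate(dp$distance, params))
    rows[[length(rows) + 1L]] <- data.frame(
      a = dp$a, b = dp$b, consecutive = (j == i + 1L),
      distance = dp$distance, atomA = dp$atomA, atomB = dp$atomB,
      log10Rate = log10(k), rate = k,
      class = if (dp$distance <= fastThreshold) "fast" else "obstructed",
      stringsAsFactors = FALSE)
  }
  new("ChainReport", order = unname(labels[idx]),
      pairs = do.call(rbind, rows), fastThreshold = fastThreshold)
}

#' @describeIn buildChainReport pairs table of a report.
#' @param report a [ChainReport-class].
#' @export
chainPairs <- function(report) report@pairs

setMethod("show", "ChainReport", function(object) {
  cat("ChainReport:", paste(object@order, collapse = " -> "), "\n")
  p <- object@pairs
  if (nrow(p)) {
    p$distance <- round(p$distance, 1)     # report to 0.1 Angstrom
    p$rate <- signif(p$rate, 2)            # rates to 2 s.f.
    print(p[, c("a", "b", "consecutive", "distance", "rate", "class")],
          row.names = FALSE)
  }
  cat("fast threshold:", object@fastThreshold, "Angstrom\n")
})
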
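#' @describeIn MossbauerDoublet-class constructor.
#' @param isomerShift,quadrupoleSplitting,linewidth,amplitude,asymmetry see
#'   slots.
#' @export
mossbauerDoublet <- function(isomerShift, quadrupoleSplitting,
                             linewidth = 0.24, amplitude = 1,
                             asymmetry = 1) {
  new("MossbauerDoublet", isomerShift = isomerShift,
      quadrupoleSplitting = quadrupoleSplitting, linewidth = linewidth,
      amplitude = amplitude, asymmetry = asymmetry)
}

setMethod("show", "MossbauerDoublet", function(object) {
  cat(sprintf("MossbauerDoublet: delta %.3f mm/s, dEQ %.3f mm/s, Gamma %.3f mm/s, area %.3g, asymmetry %.2f\n",
              object@isomerShift, object@quadrupoleSplitting,
              object@linewidth, object@amplitude, object@asymmetry))
})

#' Construct a Spectrum1D
#'
#' @param axis strictly increasing abscissa.
#' @param ordinate signal values.
#' @param axisUnit e.g. \code{"mm/s"} or \code{"mT"}.
#' @param metadata further metadata entries.
#' @return A [Spectrum1D-class].
#' @export
spectrum1D <- function(axis, ordinate, axisUnit = "",
                       metadata = list()) {
  metadata$axisUnit <- axisUnit
  new("Spectrum1D", axis = axis, ordinate = ordinate, metadata = metadata)
}

setMethod("show", "Spectrum1D", function(object) {
  cat(sprintf("Spectrum1D: %d points, axis [%.3g, %.3g] %s\n",
              length(object@axis), min(object@axis), max(object@axis),
              object@metadata$axisUnit))
})

# area-A Lorentzian with FWHM G centred at c, evaluated at v
.lorentzian <- function(v, c, A, G) {
  (2 * A / (pi * G)) / (1 + (2 * (v - c) / G)^2)
}

.doubletOrdinate <- function(v, delta, dEQ, G, A, asym) {
  a1 <- A * asym / (1 + asym)
  a2 <- A / (1 + asym)
  -(.lorentzian(v, delta - dEQ / 2, a1, G) +
      .lorentzian(v, delta + dEQ / 2, a2, G))
}

#' Simulate a zero-field Moessbauer doublet
#'
#' Transmission-style absorption: two Lorentzian dips of FWHM Gamma centred
#' at \code{delta +/- dEQ/2}, total area \code{amplitude} split between the
#' lines by \code{asymmetry}.
#'
#' @param d a [mossbauerDoublet()] model.
#' @param velocity strictly increasing velocity grid, mm/s.
#' @return A [Spectrum1D-class]; the ordinate is negative-going, with
#'   minima at the two line centres.
#' @examples
#' sp <- simulateMossbauer(mossbauerDoublet(0.3, 0.51),
#'                         seq(-2, 2, by = 0.005))
#' sp@axis[order(sp@ordinate)[1:2]]  # ~0.045 and ~0.555 mm/s
#' @export
simulateMossbauer <- function(d, velocity) {
  lo <- d@isomerShift - d@quadrupoleSplitting / 2
  hi <- d@isomerShift + d@quadrupoleSplitting / 2
  if (min(velocity) > lo || max(velocity) < hi)
    warning("velocity grid does not cover both line centres", call. = FALSE)
  spectrum1D(velocity,
             .doubletOrdinate(velocity, d@isomerShift,
                              d@quadrupoleSplitting, d@linewidth,
                              d@amplitude, d@asymmetry),
             axisUnit = "mm/s")
}

#' Least-squares fit of a Moessbauer doublet
#'
#' Fits isomer shift, quadrupole splitting, linewidth and amplitude (the
#' asymmetry is taken from \code{init} and fitted too) by
#' Levenberg-Marquardt least squares. Non-convergence is reported in the
#' result, not raised.
#'
#' @param spec a [Spectrum1D-class] containing a resolvable doublet.
#' @param init a [mossbauerDoublet()] with starting values.
#' @return list: \code{doublet} (fitted [MossbauerDoublet-class]),
#'   \code{se} (named standard errors), \code{converged},
#'   \code{residualNorm}.
#' @export
fitMossbauer <- function(spec, init) {
  df <- data.frame(v = spec@axis, y = spec@ordinate)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ .doubletOrdinate(v, delta, dEQ, G, A, asym),
      data = df,
      start = list(delta = init@isomerShift,
                   dEQ = init@quadrupoleSplitting,
                   G = init@linewidth, A = init@amplitude,
                   asym = init@asymmetry),
      lower = c(delta = -Inf, dEQ = 0, G = 1e-4, A = 1e-12, asym = 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(doublet = init, se = NULL, converged = FALSE,
                residualNorm = sqrt(sum((df$y - .doubletOrdinate(
                  df$v, init@isomerShift, init@quadrupoleSplitting,
                  init@linewidth, init@amplitude, init@asymmetry))^2))))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  list(doublet = mossbauerDoublet(cf[["delta"]], cf[["dEQ"]], cf[["G"]],
                                  cf[["A"]], cf[["asym"]]),
       se = se, converged = TRUE,
       residualNorm = sqrt(sum(stats::resid(fit)^2)))
}

#' @describeIn EprComponent-class constructor.
#' @param kind,gPar,gPerp,gIso,linewidth,weight see slots.
#' @export
eprComponent <- function(kind = c("axial", "isotropic"), gPar = NA_real_,
                         gPerp = NA_real_, gIso = NA_real_,
                         linewidth = 20, weight = 1) {
  kind <- match.arg(kind)
  new("EprComponent", kind = kind, gPar = gPar, gPerp = gPerp, gIso = gIso,
      linewidth = linewidth, weight = weight)
}

setMethod("show", "EprComponent", function(object) {
  if (object@kind == "axial")
    cat(sprintf("EprComponent axial: g|| %.3f, gT %.3f, linewidth %.0f G, weight %.3f\n",
                object@gPar, object@gPerp, object@linewidth, object@weight))
  else
    cat(sprintf("EprComponent isotropic: g %.3f, linewidth %.0f G, weight %.3f\n",
                object@gIso, object@linewidth, object@weight))
})

# resonance field in mT: h*nu = g muB B  =>  B[mT] = 71.4477 nu[GHz] / g
.resField <- function(g, freqGHz) 71.4477 * freqGHz / g

.trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) +
                                          utils::tail(y, -1)) / 2)

# powder absorption lineshape of one component, unit double integral
.componentAbsorption <- function(comp, freqGHz, field, nTheta = 1800L) {
  sigma <- (comp@linewidth / 10) / (2 * sqrt(2 * log(2)))  # G -> mT, FWHM
  if (comp@kind == "isotropic") {
    B0 <- .resField(comp@gIso, freqGHz)
    if (B0 < min(field) || B0 > max(field))
      warning("resonance field ", round(B0, 1),
              " mT outside the field grid", call. = FALSE)
    y <- stats::dnorm(field, B0, sigma)
  } else {
    theta <- (seq_len(nTheta) - 0.5) * (pi / 2) / nTheta
    g <- sqrt(comp@gPar^2 * cos(theta)^2 + comp@gPerp^2 * sin(theta)^2)
    B <- .resField(g, freqGHz)
    if (min(B) < min(field) || max(B) > max(field))
      warning("part of the powder pattern lies outside the field grid",
              call. = FALSE)
    w <- sin(theta)
    y <- rep(0, length(field))
    for (j in seq_along(theta))
      y <- y + w[j] * stats::dnorm(field, B[j], sigma)
  }
  y / .trapz(field, y)
}

#' Simulate a CW powder EPR derivative spectrum
#'
#' For each orientation on a sin-weighted polar grid the resonance field is
#' taken from the axial effective g value
#' \eqn{g(\theta)^2 = g_\parallel^2\cos^2\theta + g_\perp^2\sin^2\theta},
#' broadened by a Gaussian of the component's linewidth; component
#' absorptions are normalised to unit double integral, combined by weight,
#' and differentiated to give the field-modulated first-derivative
#' spectrum.
#'
#' @param components list of [eprComponent()] objects whose weights sum
#'   to 1.
#' @param frequencyGHz microwave frequency (X-band is near 9.4 GHz; always
#'   stated explicitly).
#' @param field strictly increasing field grid, mT.
#' @param nTheta orientation grid size (default 1800).
#' @return A [Spectrum1D-class] (first derivative, arbitrary units).
#' @examples
#' sp <- simulateEprPowder(list(eprComponent("isotropic", gIso = 2.0023,
#'                                           linewidth = 20)),
#'                         9.4, seq(320, 350, by = 0.02))
#' @export
simulateEprPowder <- function(components, frequencyGHz, field,
                              nTheta = 1800L) {
  w <- vapply(components, function(cc) cc@weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-6)
    stop("component weights must sum to 1 (got ", signif(sum(w), 4), ")")
  absorb <- rep(0, length(field))
  for (cc in components)
    absorb <- absorb + cc@weight *
      .componentAbsorption(cc, frequencyGHz, field, nTheta)
  deriv <- .gradient(absorb, field)
  spectrum1D(field, deriv, axisUnit = "mT",
             metadata = list(frequencyGHz = frequencyGHz,
                             kind = "derivative"))
}

# central-difference gradient, one-sided at the ends
.gradient <- function(y, x) {
  n <- length(y)
  g <- numeric(n)
  g[1] <- (y[2] - y[1]) / (x[2] - x[1])
  g[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  g[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
  g
}

#' Fit component weights of a multi-component EPR spectrum
#'
#' With g values and linewidths held fixed, fits the non-negative
#' component weights (plus a global scale) to an observed derivative
#' spectrum by least squares and normalises them to sum to 1.
#'
#' @param spec observed derivative [Spectrum1D-class].
#' @param components list of [eprComponent()] objects (weights ignored).
#' @param frequencyGHz microwave frequency, GHz.
#' @param nTheta orientation grid size.
#' @return named numeric vector of weights summing to 1.
#' @export
fitEprWeights <- function(spec, components, frequencyGHz, nTheta = 1800L) {
  basis <- vapply(components, function(cc) {
    .gradient(.componentAbsorption(cc, frequencyGHz, spec@axis, nTheta),
              spec@axis)
  }, numeric(length(spec@axis)))
  if (length(components) > 1L) {
    cm <- stats::cor(basis)
    if (any(cm[upper.tri(cm)] > 1 - 1e-8))
      stop("degenerate design: two components have identical lineshapes")
  }
  # non-negative least squares on the raw coefficients
  obj <- function(logc) {
    co <- exp(logc)
    sum((spec@ordinate - basis %*% co)^2)
  }
  ls <- stats::coef(stats::lm(spec@ordinate ~ basis - 1))
  start <- log(pmax(ls, 1e-8))
  co <- exp(stats::optim(start, obj, method = "BFGS",
                         control = list(maxit = 500, reltol = 1e-14))$par)
  w <- co / sum(co)
  names(w) <- vapply(components, function(cc)
    if (cc@kind == "axial") sprintf("axial_g%.3f", cc@gPar)
    else sprintf("iso_g%.3f", cc@gIso), character(1))
  w
}

#' Write / read a spectrum as two-column text
#'
#' Plain-text exchange format: a small \code{#}-prefixed header carrying
#' the axis unit and metadata, then two whitespace-separated columns.
#'
#' @param spec a [Spectrum1D-class].
#' @param path file path.
#' @return \code{writeSpectrum}: \code{path}, invisibly;
#'   \code{readSpectrum}: a [Spectrum1D-class].
#' @export
writeSpectrum <- function(spec, path) {
  hdr <- c(paste0("# axisUnit: ", spec@metadata$axisUnit),
           if (!is.null(spec@metadata$frequencyGHz))
             paste0("# frequencyGHz: ", spec@metadata$frequencyGHz))
  writeLines(c(hdr, paste(format(spec@axis, digits = 10),
                          format(spec@ordinate, digits = 10))), path)
  invisible(path)
}

#' @rdname writeSpectrum
#' @export
readSpectrum <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  dat <- utils::read.table(text = grep("^#", lines, value = TRUE,
                                       invert = TRUE))
  meta <- list()
  unit <- sub("^# axisUnit: ", "", grep("^# axisUnit:", hdr, value = TRUE))
  fq <- sub("^# frequencyGHz: ", "",
            grep("^# frequencyGHz:", hdr, value = TRUE))
  if (length(fq)) meta$frequencyGHz <- as.numeric(fq)
  spectrum1D(dat[[1]], dat[[2]],
             axisUnit = if (length(unit)) unit else "", metadata = meta)
}
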
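#' Classification bands for ion-site calls
#'
#' Alkali-coordination windows used by [classifySite()]. Defaults: Na-O
#' 2.2-2.6 Angstrom at coordination number 4-6 with >= 80% oxygen ligands;
#' K-O 2.6-3.1 Angstrom at coordination number 5-8; hydrogen-bond band
#' 2.6-3.2 Angstrom for water at coordination number <= 4.
#'
#' @param naCN,naDist,naFracO Na+ bands.
#' @param kCN,kDist K+ bands.
#' @param hbDist,waterMaxCN water (hydrogen-bond) bands.
#' @return list of class \code{"IonRules"}.
#' @export
ionRules <- function(naCN = c(4, 6), naDist = c(2.2, 2.6), naFracO = 0.8,
                     kCN = c(5, 8), kDist = c(2.6, 3.1),
                     hbDist = c(2.6, 3.2), waterMaxCN = 4) {
  structure(list(naCN = naCN, naDist = naDist, naFracO = naFracO,
                 kCN = kCN, kDist = kDist, hbDist = hbDist,
                 waterMaxCN = waterMaxCN), class = "IonRules")
}

.ligandClass <- function(name, resname, element) {
  water <- resname %in% c("HOH", "WAT", "DOD")
  ifelse(water & element == "O", "water O",
  ifelse(element == "O" & name == "O" & !water, "backbone carbonyl O",
  ifelse(element == "O", "side-chain O",
  ifelse(element == "N", "N",
  ifelse(element == "S", "S", "other")))))
}

#' First coordination shell around a candidate ion position
#'
#' Collects all non-hydrogen, non-carbon atoms within the cutoff of a
#' centre and classifies them by ligand chemistry (backbone carbonyl O,
#' side-chain O, water O, N, S, other). Carbon is never counted as a
#' ligand. When the centre is an atom of the structure, atoms of its own
#' residue are excluded from the shell.
#'
#' @param s an [AtomicStructure-class].
#' @param center either a numeric 3-vector, or a list
#'   \code{list(chain =, resseq =, name =)} naming an atom of \code{s}.
#' @param cutoff shell radius in (2.0, 3.5] Angstrom (default 3.0).
#' @return A [CoordinationShell-class].
#' @examples
#' site <- makeIonSite("NA", cn = 5, meanDist = 2.4)
#' sh <- findCoordination(site, list(chain = "I", resseq = 900, name = "NA"))
#' sh@coordinationNumber
#' @export
findCoordination <- function(s, center, cutoff = 3.0) {
  if (!(cutoff > 2.0 && cutoff <= 3.5))
    stop("cutoff must lie in (2.0, 3.5] Angstrom")
  a <- atoms(s)
  excl <- rep(FALSE, nrow(a))
  if (is.list(center)) {
    hit <- which(a$chain == center$chain & a$resseq == center$resseq &
                   a$name == center$name)
    if (!length(hit))
      stop("center atom not found: ", center$chain, " ", center$resseq,
           " ", center$name)
    cen <- as.numeric(a[hit[1], c("x", "y", "z")])
    excl <- a$chain == a$chain[hit[1]] & a$resseq == a$resseq[hit[1]] &
      a$inscode == a$inscode[hit[1]]
  } else {
    cen <- as.numeric(center)
    stopifnot(length(cen) == 3L)
  }
  cand <- !excl & !a$element %in% c("H", "D", "C")
  d <- sqrt((a$x - cen[1])^2 + (a$y - cen[2])^2 + (a$z - cen[3])^2)
  keep <- which(cand & d <= cutoff)
  lig <- a[keep, c("name", "resname", "chain", "resseq", "element"),
           drop = FALSE]
  lig$class <- .ligandClass(lig$name, lig$resname, lig$element)
  lig$distance <- d[keep]
  lig <- lig[order(lig$distance), , drop = FALSE]
  rownames(lig) <- NULL
  minAngle <- NA_real_
  if (nrow(lig) >= 2L) {
    v <- sweep(as.matrix(a[keep, c("x", "y", "z")]), 2, cen)
    v <- v[order(d[keep]), , drop = FALSE]
    v <- v / sqrt(rowSums(v^2))
    cosang <- tcrossprod(v)
    minAngle <- acos(min(1, max(-1,
      max(cosang[upper.tri(cosang)])))) * 180 / pi
  }
  new("CoordinationShell", center = cen, ligands = lig,
      coordinationNumber = nrow(lig),
      meanDistance = if (nrow(lig)) mean(lig$distance) else NA_real_,
      minAngle = minAngle, cutoff = cutoff)
}

setMethod("show", "CoordinationShell", function(object) {
  cat(sprintf("CoordinationShell: CN %d, mean distance %.2f A, min angle %.0f deg (cutoff %.1f A)\n",
              object@coordinationNumber,
              object@meanDistance, object@minAngle, object@cutoff))
  if (nrow(object@ligands)) {
    tab <- table(object@ligands$class)
    cat("  ligands:", paste(names(tab), tab, sep = " x", collapse = ", "),
        "\n")
  }
})

#' Classify a coordination shell as Na+, K+, water or ambiguous
#'
#' Decision table over coordination number, mean ligand distance and ligand
#' chemistry, evaluated in the order Na+ then K+ then water (first full
#' match wins, which makes the call unique even where distance bands share
#' a boundary):
#' \itemize{
#'   \item Na+: CN within the Na band, mean distance within the Na-O band,
#'     and >= 80\% oxygen ligands.
#'   \item K+: CN within the K band and mean distance within the K-O band.
#'   \item water: CN <= 2, or mean distance in the hydrogen-bond band with
#'     CN <= 4.
#'   \item otherwise ambiguous.
#' }
#' The score is the ion-likeness of the shell: the best fraction of Na+ or
#' K+ criteria met. A full ion call therefore always has score 1.
#'
#' @param shell a [CoordinationShell-class].
#' @param rules an [ionRules()] object.
#' @return list of class \code{"SiteCall"}: \code{identity} (\code{"Na+"},
#'   \code{"K+"}, \code{"water"} or \code{"ambiguous"}), \code{score} in
#'   [0, 1], and \code{rationale}, a named logical vector of per-criterion
#'   outcomes.
#' @export
classifySite <- function(shell, rules = ionRules()) {
  cn <- shell@coordinationNumber
  md <- shell@meanDistance
  fracO <- if (cn > 0)
    mean(shell@ligands$element == "O") else 0
  inband <- function(x, b) !is.na(x) && x >= b[1] && x <= b[2]
  crit <- c(
    na_cn = cn >= rules$naCN[1] && cn <= rules$naCN[2],
    na_dist = inband(md, rules$naDist),
    na_fracO = fracO >= rules$naFracO,
    k_cn = cn >= rules$kCN[1] && cn <= rules$kCN[2],
    k_dist = inband(md, rules$kDist),
    water_lowCN = cn <= 2,
    water_hb = inband(md, rules$hbDist) && cn <= rules$waterMaxCN)
  fNa <- mean(crit[c("na_cn", "na_dist", "na_fracO")])
  fK <- mean(crit[c("k_cn", "k_dist")])
  identity <- if (fNa == 1) "Na+"
    else if (fK == 1) "K+"
    else if (crit[["water_lowCN"]] || crit[["water_hb"]]) "water"
    else "ambiguous"
  structure(list(identity = identity, score = max(fNa, fK),
                 rationale = crit,
                 coordinationNumber = cn, meanDistance = md,
                 fractionO = fracO),
            class = "SiteCall")
}

#' Screen all solvent and ion positions of a structure
#'
#' Evaluates the coordination shell of every modeled water oxygen and every
#' monatomic ion, classifies each, and returns the table ordered ion calls
#' first, then by ion-likeness score (descending), then by coordination
#' number.
#'
#' @param s an [AtomicStructure-class].
#' @param solventCodes residue codes treated as water.
#' @param ionCodes residue codes treated as monatomic ions.
#' @param cutoff shell cutoff, Angstrom.
#' @param rules an [ionRules()] object.
#' @return data.frame: \code{chain, resseq, resname, x, y, z, cn,
#'   meanDistance, nCarbonylO, nWaterO, identity, score}.
#' @export
scanCandidateIons <- function(s, solventCodes = c("HOH", "WAT", "DOD"),
                              ionCodes = c("NA", "K", "MG", "CA", "RB",
                                           "CS", "ZN"),
                              cutoff = 3.0, rules = ionRules()) {
  a <- atoms(s)
  cand <- which((a$resname %in% solventCodes & a$element == "O") |
                  (a$resname %in% ionCodes &
                     a$name %in% ionCodes))
  if (!length(cand)) {
    message("no solvent or monatomic ions in structure")
    return(data.frame())
  }
  rows <- lapply(cand, function(i) {
    shell <- findCoordination(
      s, list(chain = a$chain[i], resseq = a$resseq[i], name = a$name[i]),
      cutoff = cutoff)
    call <- classifySite(shell, rules)
    data.frame(chain = a$chain[i], resseq = a$resseq[i],
               resname = a$resname[i],
               x = a$x[i], y = a$y[i], z = a$z[i],
               cn = shell@coordinationNumber,
               meanDistance = shell@meanDistance,
               nCarbonylO = sum(shell@ligands$class ==
                                  "backbone carbonyl O"),
               nWaterO = sum(shell@ligands$class == "water O"),
               identity = call$identity, score = call$score,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  isIon <- out$identity %in% c("Na+", "K+")
  out <- out[order(-isIon, -out$score, -out$cn), , drop = FALSE]
  rownames(out) <- NULL
  out
}
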
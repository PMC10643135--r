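# Edge-atom conventions: the tunneling "edge" of a cofactor is its conjugated
# heavy-atom system, not the full ligand. Ribityl/adenosine tails, isoprenoid
# tails and coordinating cysteine Sg are excluded.

.FLAVIN_EDGE <- c("N1", "C2", "O2", "N3", "C4", "O4",
                  "C4A", "C4X", "N5", "C5A", "C5X",
                  "C6", "C7", "C8", "C9", "C9A", "N10", "C10")
.FLAVIN_CANONICAL <- 16L  # 14 ring atoms + O2 + O4 (name variants collapse)

#' Default cofactor registry
#'
#' Maps each cofactor kind to the hetero residue codes that represent it and
#' to the atom names of its redox-active edge. Flavins use the isoalloxazine
#' ring heavy atoms plus the exocyclic O2/O4 (both \code{C4A/C5A/C10} and
#' \code{C4X/C5X} naming variants are accepted); [2Fe-2S] clusters use the
#' Fe2S2 rhomb only; quinones the head-group ring with carbonyl and methoxy
#' oxygens; NAD(H) the nicotinamide ring; monatomic ions the ion itself.
#'
#' @param overrides optional named list replacing or adding entries; each
#'   entry is \code{list(codes = <residue codes>, edge = <atom names>)}.
#' @return named list of registry entries.
#' @export
cofactorRegistry <- function(overrides = NULL) {
  reg <- list(
    FAD = list(codes = "FAD", edge = .FLAVIN_EDGE),
    FMN = list(codes = "FMN", edge = .FLAVIN_EDGE),
    RBF = list(codes = "RBF", edge = .FLAVIN_EDGE),
    FES = list(codes = c("FES", "FS2"), edge = c("FE1", "FE2", "S1", "S2")),
    UQ1 = list(codes = "UQ1",
               edge = c("C1", "C2", "C3", "C4", "C5", "C6",
                        "O1", "O2", "O3", "O4", "O5", "O6")),
    UQ2 = list(codes = c("UQ2", "UQ"),
               edge = c("C1", "C2", "C3", "C4", "C5", "C6",
                        "O1", "O2", "O3", "O4", "O5", "O6")),
    HQNO = list(codes = "HQO",
                edge = c("N1", "C2", "C3", "C4", "O4", "C4A",
                         "C5", "C6", "C7", "C8", "C8A", "O1")),
    NAD = list(codes = c("NAD", "NAI"),
               edge = c("N1N", "C2N", "C3N", "C4N", "C5N", "C6N",
                        "C7N", "O7N", "N7N")),
    ion = list(codes = c("NA", "K", "MG", "CA", "ZN", "RB", "CS"),
               edge = c("NA", "K", "MG", "CA", "ZN", "RB", "CS"))
  )
  if (!is.null(overrides)) {
    for (k in names(overrides)) reg[[k]] <- overrides[[k]]
  }
  reg
}

#' Extract recognised cofactors from a structure
#'
#' Scans the hetero residues of a structure against a registry and returns
#' one [Cofactor-class] per match, with its edge atoms resolved by name.
#' An instance is kept when at least half of the registry's edge atoms are
#' present; fewer triggers a warning and the residue is dropped. Waters are
#' never cofactors. Output is ordered by (chain, resseq) and therefore
#' invariant under atom-order permutation of the input.
#'
#' @param s an [AtomicStructure-class].
#' @param registry a registry from [cofactorRegistry()].
#' @param minEdgeFraction minimum fraction of edge atoms that must resolve
#'   (default 0.5).
#' @return list of [Cofactor-class] objects.
#' @examples
#' s <- makeFlavinPair(5.7)
#' length(extractCofactors(s))
#' @export
extractCofactors <- function(s, registry = cofactorRegistry(),
                             minEdgeFraction = 0.5) {
  for (k in names(registry)) {
    if (!length(registry[[k]]$edge))
      stop("registry kind '", k, "' has no edge atom names")
  }
  a <- atoms(s)
  a <- a[!a$resname %in% c("HOH", "WAT", "DOD") &
           !a$element %in% c("H", "D"), , drop = FALSE]
  if (!nrow(a)) return(list())
  code2kind <- list()
  for (k in names(registry))
    for (code in registry[[k]]$codes) code2kind[[code]] <- k
  a <- a[a$resname %in% names(code2kind), , drop = FALSE]
  if (!nrow(a)) return(list())
  res <- unique(a[, c("chain", "resseq", "inscode", "resname")])
  res <- res[order(res$chain, res$resseq, res$inscode), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(res))) {
    ri <- res[i, ]
    kind <- code2kind[[ri$resname]]
    edge_names <- registry[[kind]]$edge
    ra <- a[a$chain == ri$chain & a$resseq == ri$resseq &
              a$inscode == ri$inscode & a$resname == ri$resname, ,
            drop = FALSE]
    ra <- ra[order(ra$serial), , drop = FALSE]
    ea <- ra[ra$name %in% edge_names, , drop = FALSE]
    denom <- if (kind %in% c("FAD", "FMN", "RBF")) .FLAVIN_CANONICAL else
      if (kind == "ion") 1L else length(edge_names)
    if (nrow(ea) < minEdgeFraction * denom) {
      warning("cofactor ", ri$resname, " ", ri$chain, ri$resseq,
              " dropped: only ", nrow(ea), "/", denom,
              " edge atoms present", call. = FALSE)
      next
    }
    missing_edge <- setdiff(edge_names, ra$name)
    label <- paste0(ri$resname, "_", ri$chain, ri$resseq)
    cof <- new("Cofactor", kind = kind, label = label,
               chain = ri$chain, resseq = as.integer(ri$resseq),
               atoms = ra, edgeAtoms = ea)
    attr(cof, "missingEdgeAtoms") <- missing_edge
    out[[label]] <- cof
  }
  out
}
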
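#' Construct an AtomicStructure from an atom table
#'
#' Low-level constructor. Most users will call [readStructure()] or one of
#' the fixture generators instead. Missing optional columns are filled with
#' defaults (serial = row number, occupancy 1, bfactor 0, altloc/inscode "",
#' hetero FALSE). Elements are inferred from atom names when absent.
#'
#' @param atoms data.frame with at least \code{name, resname, chain, resseq,
#'   x, y, z}.
#' @param id structure identifier.
#' @param sourceFormat provenance tag.
#' @return An [AtomicStructure-class].
#' @export
AtomicStructure <- function(atoms, id = "structure", sourceFormat = "memory") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  n <- nrow(atoms)
  if (is.null(atoms$serial) || anyDuplicated(atoms$serial))
    atoms$serial <- seq_len(max(n, 0L))
  if (is.null(atoms$element)) atoms$element <- guessElement(atoms$name)
  if (is.null(atoms$altloc)) atoms$altloc <- rep("", n)
  if (is.null(atoms$inscode)) atoms$inscode <- rep("", n)
  if (is.null(atoms$occupancy)) atoms$occupancy <- rep(1, n)
  if (is.null(atoms$bfactor)) atoms$bfactor <- rep(0, n)
  if (is.null(atoms$hetero)) atoms$hetero <- rep(FALSE, n)
  atoms$resseq <- as.integer(atoms$resseq)
  atoms$serial <- as.integer(atoms$serial)
  atoms <- atoms[, .ATOM_COLS, drop = FALSE]
  rownames(atoms) <- NULL
  new("AtomicStructure", id = id, atoms = atoms, sourceFormat = sourceFormat)
}

#' Infer element symbols from PDB atom names
#'
#' Standard PDB convention: two-letter elements (FE, NA, CL, ...) are
#' recognised first, otherwise the first alphabetic character of the name is
#' the element.
#'
#' @param name character vector of atom names.
#' @return character vector of element symbols.
#' @export
guessElement <- function(name) {
  two <- c("FE", "NA", "MG", "CL", "ZN", "MN", "CU", "BR", "CA", "RB", "CS")
  nm <- toupper(gsub("[^A-Za-z].*$", "", gsub("^[0-9']+", "", name)))
  out <- substr(nm, 1L, 1L)
  hit <- substr(nm, 1L, 2L) %in% two & nchar(nm) >= 2L &
    !grepl("^C[ABGDEZH]", nm) & !grepl("^N[ABGDEZH]", nm)
  out[hit] <- substr(nm[hit], 1L, 2L)
  # monatomic ion residues are unambiguous
  out[nm %in% two] <- nm[nm %in% two]
  out
}

#' Read an atomic model from PDB or mmCIF
#'
#' Parses the first model of a coordinate file, preserving author chain ids
#' and residue numbering. Alternate locations are collapsed (conformer "A" /
#' first listed is retained), hydrogens are dropped, waters are retained.
#'
#' @param path path to a \code{.pdb} or \code{.cif} file.
#' @param format \code{"auto"} (by extension), \code{"pdb"} or
#'   \code{"mmcif"}.
#' @return An [AtomicStructure-class].
#' @examples
#' h <- makeIdealHelix(12)
#' f <- tempfile(fileext = ".pdb")
#' writeStructure(h, f)
#' s <- readStructure(f)
#' nAtoms(s)
#' @export
readStructure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "mmcif") {
      bio3d::read.cif(path, verbose = FALSE)
    } else {
      bio3d::read.pdb(path, multi = FALSE, rm.alt = TRUE, verbose = FALSE)
    },
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  a <- parsed$atom
  el <- toupper(trimws(a$elesy))
  el[is.na(el) | el == ""] <- guessElement(a$elety[is.na(el) | el == ""])
  atoms <- data.frame(
    serial = as.integer(a$eleno),
    name = trimws(a$elety),
    element = el,
    altloc = ifelse(is.na(a$alt), "", a$alt),
    resname = trimws(a$resid),
    chain = ifelse(is.na(a$chain), "", a$chain),
    resseq = as.integer(a$resno),
    inscode = ifelse(is.na(a$insert), "", a$insert),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, pmin(pmax(a$o, 0), 1)),
    bfactor = ifelse(is.na(a$b), 0, a$b),
    hetero = a$type == "HETATM",
    stringsAsFactors = FALSE)
  if (!nrow(atoms))
    stop("failed to parse ", format, " file '", path,
         "': no atom records found", call. = FALSE)
  atoms <- atoms[!atoms$element %in% c("H", "D"), , drop = FALSE]
  # collapse any alternates the parser kept: highest occupancy wins
  key <- paste(atoms$chain, atoms$resseq, atoms$inscode, atoms$name)
  if (anyDuplicated(key)) {
    ord <- order(key, -atoms$occupancy)
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resseq,
                                     atoms$inscode, atoms$name)), ,
                   drop = FALSE]
    atoms <- atoms[order(atoms$serial), , drop = FALSE]
  }
  atoms$altloc <- rep("", nrow(atoms))
  id <- sub("\\.(pdb|cif)(\\.gz)?$", "", basename(path), ignore.case = TRUE)
  AtomicStructure(atoms, id = id, sourceFormat = format)
}

#' Write an atomic model as a PDB file
#'
#' @param s an [AtomicStructure-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeStructure <- function(s, path) {
  a <- atoms(s)
  bio3d::write.pdb(file = path,
                   type = ifelse(a$hetero, "HETATM", "ATOM"),
                   eleno = a$serial, elety = a$name, resid = a$resname,
                   chain = a$chain, resno = a$resseq, insert = a$inscode,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   o = a$occupancy, b = a$bfactor, elesy = a$element)
  invisible(path)
}

#' @describeIn AtomicStructure-class atom table accessor.
#' @param s,object an \code{AtomicStructure}.
#' @export
atoms <- function(s) s@atoms

#' @describeIn AtomicStructure-class number of atoms.
#' @export
nAtoms <- function(s) nrow(s@atoms)

#' @describeIn AtomicStructure-class structure identifier.
#' @export
structureId <- function(s) s@id

#' @describeIn AtomicStructure-class coordinates as an n x 3 matrix.
#' @export
coords <- function(s) {
  m <- as.matrix(s@atoms[, c("x", "y", "z")])
  rownames(m) <- NULL
  m
}

#' Apply a rigid transform to a structure
#'
#' Maps every atom position \code{p} to \code{R p + t}.
#'
#' @param s an [AtomicStructure-class].
#' @param rotation 3 x 3 proper rotation matrix.
#' @param translation 3-vector (Angstrom).
#' @return the transformed [AtomicStructure-class].
#' @export
transformStructure <- function(s, rotation = diag(3),
                               translation = c(0, 0, 0)) {
  xyz <- coords(s) %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  a <- s@atoms
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  initialize(s, atoms = a)
}

#' Hetero-group inventory of a structure
#'
#' Counts hetero residues by residue code (waters excluded), mirroring the
#' ligand inventory of a deposited model's validation table.
#'
#' @param s an [AtomicStructure-class].
#' @return named integer vector of residue-code counts.
#' @export
heteroInventory <- function(s) {
  a <- atoms(s)
  a <- a[a$hetero & !a$resname %in% c("HOH", "WAT", "DOD"), , drop = FALSE]
  if (!nrow(a)) return(integer())
  res <- unique(a[, c("chain", "resseq", "inscode", "resname")])
  table(res$resname) |> c()
}

setMethod("show", "AtomicStructure", function(object) {
  a <- object@atoms
  cat("AtomicStructure '", object@id, "' (", object@sourceFormat, ")\n",
      sep = "")
  cat("  ", nrow(a), " atoms, ", length(unique(a$chain)), " chain(s): ",
      paste(sort(unique(a$chain)), collapse = " "), "\n", sep = "")
  inv <- heteroInventory(object)
  if (length(inv))
    cat("  hetero groups:",
        paste(names(inv), inv, sep = " x", collapse = ", "), "\n")
})

setMethod("show", "Cofactor", function(object) {
  cat("Cofactor ", object@label, " [", object@kind, "] chain ",
      object@chain, " resseq ", object@resseq, ": ", nrow(object@atoms),
      " atoms, ", nrow(object@edgeAtoms), " edge atoms\n", sep = "")
})
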
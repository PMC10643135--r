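# Independent oracles used across the suite.

# exhaustive double-loop minimum pairwise distance (checks the vectorised
# edge-to-edge implementation)
bruteMinDistance <- function(ma, mb) {
  best <- Inf
  for (i in seq_len(nrow(ma))) for (j in seq_len(nrow(mb))) {
    d <- sqrt(sum((ma[i, ] - mb[j, ])^2))
    if (d < best) best <- d
  }
  best
}

# a single hand-written ATOM record (fixed-column PDB)
minimalPdbFile <- function() {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1      11.104   6.134  -6.504  1.00 10.00           C",
    "END"), f)
  f
}

# local path where deposited coordinate files would be staged; the files
# are not shipped with the package
depositedPath <- function(code) {
  file.path(system.file("extdata", package = "redoxmap"), "deposited",
            paste0(code, ".pdb"))
}

randomRotation <- function() {
  axis <- stats::rnorm(3)
  rotationMatrix(axis, stats::runif(1, 0, 180))
}
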
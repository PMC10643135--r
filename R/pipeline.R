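#' Validate an analysis configuration
#'
#' A configuration is a named list (or a YAML/JSON file) selecting stages
#' and their inputs:
#' \preformatted{
#' structure:  path               # required
#' structure2: path               # required for motion/tilt stages
#' seed:       integer            # default 1
#' stages:     [distances, ions, pore, motion, crosslinks]
#' chain:      {order: [labels], fastThreshold: 14}
#' ruler:      {intercept: 15, slope: 0.6, fcCoeff: 3.1,
#'              deltaG: ..., lambda: ...}
#' selections: {core: {chain: A, from: 1, to: 30, atom: CA},
#'              domain: {...}, helices: [{...}, ...]}
#' pore:       {start: [x, y, z], direction: [x, y, z], step: 0.25}
#' crosslinks: {path: pairs.csv, maxAllowed: 30}
#' outputDir:  path
#' }
#' Referenced files must exist at validation time.
#'
#' @param config named list or path to a YAML/JSON file.
#' @return the normalised configuration list, invisibly on success;
#'   validation problems raise an error naming the offending field.
#' @export
validateConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a file path")
  if (is.null(config$structure))
    stop("config field 'structure' is required")
  if (!file.exists(config$structure))
    stop("config field 'structure': file not found: ", config$structure)
  config$seed <- as.integer(config$seed %||% 1L)
  config$stages <- config$stages %||% "distances"
  bad <- setdiff(config$stages,
                 c("distances", "ions", "pore", "motion", "crosslinks"))
  if (length(bad))
    stop("config field 'stages': unknown stage(s) ",
         paste(bad, collapse = ", "))
  if (any(config$stages %in% "motion")) {
    if (is.null(config$structure2))
      stop("config field 'structure2' is required for the motion stage")
    if (!file.exists(config$structure2))
      stop("config field 'structure2': file not found: ",
           config$structure2)
    for (f in c("core", "domain"))
      if (is.null(config$selections[[f]]))
        stop("config field 'selections.", f,
             "' is required for the motion stage")
  }
  if (any(config$stages %in% "pore")) {
    for (f in c("start", "direction"))
      if (is.null(config$pore[[f]]) || length(config$pore[[f]]) != 3L)
        stop("config field 'pore.", f, "' must be a 3-vector")
  }
  if (any(config$stages %in% "crosslinks")) {
    if (is.null(config$crosslinks$path) ||
        !file.exists(config$crosslinks$path))
      stop("config field 'crosslinks.path': file not found")
  }
  invisible(config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.selFromConfig <- function(x) {
  resseq <- if (!is.null(x$from)) seq(x$from, x$to) else x$resseq
  selectionSpec(x$chain, resseq, x$atom %||% "CA")
}

#' Run the full structural analysis and write a report bundle
#'
#' Executes the requested stages on one or two structure files and writes
#' \code{report.json} plus per-stage TSV tables into the output directory.
#' Every numeric output carries its unit in the report; the seed, package
#' version and a hash of the configuration are recorded. For fixed inputs,
#' configuration and seed the JSON report is byte-identical across runs
#' (no timestamps are embedded).
#'
#' A failing stage is recorded under \code{errors} in the report and does
#' not prevent the other stages from running.
#'
#' @param config configuration list or file path (see [validateConfig()]).
#' @param outputDir overrides \code{config$outputDir}; \code{NULL} writes
#'   no files and only returns the report.
#' @return the report, a named list, invisibly.
#' @export
runReport <- function(config, outputDir = config$outputDir %||% NULL) {
  cfg <- validateConfig(config)
  s <- readStructure(cfg$structure)
  report <- list(
    tool = "redoxmap",
    version = as.character(utils::packageVersion("redoxmap")),
    seed = cfg$seed,
    configHash = .configHash(cfg),
    units = list(distance = "Angstrom", rate = "s^-1", angle = "degrees",
                 velocity = "mm/s", field = "mT", linewidth = "G"),
    structure = structureId(s))
  errors <- list()
  tsv <- list()

  if ("distances" %in% cfg$stages) {
    res <- tryCatch({
      cofs <- extractCofactors(s)
      rp <- do.call(rulerParams, as.list(cfg$ruler %||% list()))
      cr <- buildChainReport(cofs, order = cfg$chain$order,
                             params = rp,
                             fastThreshold =
                               cfg$chain$fastThreshold %||% 14)
      tsv$distances <- chainPairs(cr)
      list(order = cr@order,
           fastThreshold = cr@fastThreshold,
           pairs = chainPairs(cr))
    }, error = function(e) {
      errors$distances <<- conditionMessage(e); NULL
    })
    if (!is.null(res)) report$distances <- res
  }
  if ("ions" %in% cfg$stages) {
    res <- tryCatch({
      tab <- scanCandidateIons(s)
      tsv$ions <- tab
      tab
    }, error = function(e) { errors$ions <<- conditionMessage(e); NULL })
    if (!is.null(res)) report$ions <- res
  }
  if ("pore" %in% cfg$stages) {
    res <- tryCatch({
      pp <- poreProfile(s, start = as.numeric(cfg$pore$start),
                        direction = as.numeric(cfg$pore$direction),
                        step = cfg$pore$step %||% 0.25, seed = cfg$seed)
      con <- constrictionReport(pp, s)
      tsv$pore <- profilePoints(pp)
      list(constrictionRadius = con$point$radius,
           constrictionStation = con$point$station,
           residues = con$residues, points = profilePoints(pp))
    }, error = function(e) { errors$pore <<- conditionMessage(e); NULL })
    if (!is.null(res)) report$pore <- res
  }
  if ("motion" %in% cfg$stages) {
    res <- tryCatch({
      s2 <- readStructure(cfg$structure2)
      core <- .selFromConfig(cfg$selections$core)
      domain <- .selFromConfig(cfg$selections$domain)
      dm <- domainMotion(s, s2, core, domain)
      out <- list(rotationAngle = dm@rotationAngle,
                  rotationAxis = dm@rotationAxis,
                  screwTranslation = dm@screwTranslation,
                  maxDisplacement = dm@maxDisplacement,
                  centroidShift = dm@centroidShift,
                  rmsdDomain = dm@rmsdDomain)
      if (!is.null(cfg$selections$helices)) {
        out$helixTilts <- lapply(cfg$selections$helices, function(h) {
          ht <- helixTilt(s, s2, core, .selFromConfig(h))
          list(chain = h$chain, tilt = ht$tilt, shift = ht$shift)
        })
      }
      out
    }, error = function(e) { errors$motion <<- conditionMessage(e); NULL })
    if (!is.null(res)) report$motion <- res
  }
  if ("crosslinks" %in% cfg$stages) {
    res <- tryCatch({
      pairs <- utils::read.csv(cfg$crosslinks$path,
                               stringsAsFactors = FALSE)
      tab <- crosslinkCheck(s, pairs,
                            maxAllowed = cfg$crosslinks$maxAllowed %||% 30)
      tsv$crosslinks <- tab
      tab
    }, error = function(e) {
      errors$crosslinks <<- conditionMessage(e); NULL
    })
    if (!is.null(res)) report$crosslinks <- res
  }
  report$errors <- errors
  report$completed <- length(errors) == 0L

  if (!is.null(outputDir)) {
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report,
                         file.path(outputDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (nm in names(tsv))
      utils::write.table(tsv[[nm]],
                         file.path(outputDir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(report)
}

# stable hash of the configuration (md5 of its canonical JSON)
.configHash <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}
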
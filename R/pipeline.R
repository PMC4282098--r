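#' @include io.R simulation.R evaluation.R
NULL

## "lattice:RxC" or a file path (+ n for edge lists)
.resolveGraph <- function(spec, n = NULL) {
  if (is(spec, "AreaGraph")) return(spec)
  m <- regmatches(spec, regexec("^lattice:([0-9]+)x([0-9]+)$", spec))[[1L]]
  if (length(m) == 3L)
    return(latticeGraph(as.integer(m[2L]), as.integer(m[3L])))
  readEdgeList(spec, n)
}

.stage <- function(name, verbose, expr) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(force(expr), error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  if (verbose)
    message(sprintf("[%s] done in %.1fs", name,
                    proc.time()[["elapsed"]] - t0))
  out
}

#' Run the end-to-end modelling workflow
#'
#' Orchestrates (optionally) simulate, then elicit, fit and evaluate, from a
#' configuration list or a YAML file with the same structure. Recognized
#' fields: \code{seed}; \code{outDir}; \code{model} (lcar/bym/iar);
#' \code{graph} (\code{"lattice:RxC"} or an edge-list file); \code{nAreas}
#' (for edge-list files); \code{data}/\code{prior} (CSV paths);
#' \code{pathFile} (pre-elicited removal order); \code{epsilon};
#' \code{simulate} (list of \code{\link{scenario}} arguments; replaces
#' \code{data}/\code{prior}); \code{mcmc} (list of \code{\link{mcmcConfig}}
#' arguments). Outputs (samples, summary JSON, and for a simulated run the
#' data CSVs) are written under \code{outDir}; every output records the seed
#' and a config hash, and a rerun with the same config is identical.
#'
#' @param config list or path to a YAML file.
#' @param verbose print stage timings (default TRUE).
#' @return invisibly, the summary list.
#' @export
runPipeline <- function(config, verbose = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  seed <- as.integer(config$seed %||% 1L)
  outDir <- config$outDir %||% "localcar-run"
  model <- config$model %||% "lcar"
  eps <- as.numeric(config$epsilon %||% 1e-4)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cfgHash <- .hashConfig(config)

  graph <- .stage("graph", verbose,
                  .resolveGraph(config$graph %||% "lattice:12x12",
                                config$nAreas))

  if (!is.null(config$simulate)) {
    sim <- .stage("simulate", verbose, {
      set.seed(seed)
      scn <- do.call(scenario, config$simulate)
      m <- regmatches(config$graph %||% "lattice:12x12",
                      regexec("^lattice:([0-9]+)x([0-9]+)$",
                              config$graph %||% "lattice:12x12"))[[1L]]
      coords <- if (length(m) == 3L)
        latticeCoords(as.integer(m[2L]), as.integer(m[3L]))
      else as.matrix(utils::read.csv(config$coords))
      genDataset(scn, graph, coords)
    })
    data <- sim@study
    prior <- sim@prior
    utils::write.csv(data.frame(area_id = seq_len(nAreas(data)),
                                observed = data@Y, expected = data@E,
                                data@X[, -1L, drop = FALSE]),
                     file.path(outDir, "study.csv"), row.names = FALSE)
    truthDf <- data.frame(area_id = seq_len(nAreas(data)),
                          phiTrue = sim@truth$phiTrue,
                          template = sim@truth$template)
    utils::write.csv(truthDf, file.path(outDir, "truth.csv"),
                     row.names = FALSE)
  } else {
    data <- .stage("read-data", verbose, readArealCSV(config$data))
    prior <- if (!is.null(config$prior))
      .stage("read-prior", verbose, readPriorCSV(config$prior, data@X))
  }

  path <- NULL
  if (model == "lcar") {
    if (!is.null(config$pathFile)) {
      if (!file.exists(config$pathFile))
        stop("model 'lcar' needs the elicited path: file '",
             config$pathFile, "' not found", call. = FALSE)
      path <- .stage("read-path", verbose, readPath(config$pathFile, graph))
    } else if (!is.null(prior)) {
      path <- .stage("elicit", verbose,
                     elicitPath(graph, prior, precisionSpec(epsilon = eps)))
      writePath(path, file.path(outDir, "path.txt"))
    } else {
      stop("model 'lcar' needs either 'prior' data to elicit a path or a ",
           "'pathFile'", call. = FALSE)
    }
  }

  mc <- do.call(mcmcConfig, c(config$mcmc, list(seed = seed)))
  fit <- .stage("fit", verbose, switch(
    model,
    lcar = lcarFit(data, path, precisionSpec(epsilon = eps), mc),
    bym = bymFit(data, graph, mc),
    iar = iarFit(data, graph, mc),
    stop("unknown model '", model, "'", call. = FALSE)))
  writeSamples(fit, file.path(outDir, "samples"))

  summary <- .stage("evaluate", verbose, {
    rs <- riskSummaries(fit, data)
    resid <- sir(data) - rs$fitted$median
    d <- dic(fit, data)
    out <- list(
      seed = seed, configHash = cfgHash, model = model,
      beta = lapply(seq_len(ncol(fit@beta)), function(i) list(
        name = colnames(fit@beta)[i],
        median = stats::median(fit@beta[, i]),
        lower = stats::quantile(fit@beta[, i], 0.025, names = FALSE),
        upper = stats::quantile(fit@beta[, i], 0.975, names = FALSE))),
      dic = d$dic, pD = d$pD,
      moran = moranPermutation(resid, graph,
                               nPerm = config$nPerm %||% 1000L),
      acceptance = fit@acceptance)
    if (model == "lcar") {
      ep <- edgePosteriorSummary(fit)
      out$edgesRemoved <- list(mode = ep$mode, lower = ep$lower,
                               upper = ep$upper)
    }
    out
  })
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
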
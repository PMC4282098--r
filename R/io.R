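#' @include inference.R
NULL

#' Read study-period areal count data from CSV
#'
#' Requires columns \code{area_id}, \code{observed}, \code{expected}; every
#' other column is taken as a covariate. Rows are sorted by \code{area_id}
#' and an intercept column is prepended, so a shuffled file yields the same
#' object.
#'
#' @param path CSV file with a header.
#' @return a \code{\linkS4class{CountData}}.
#' @export
readArealCSV <- function(path) {
  df <- utils::read.csv(path)
  need <- c("area_id", "observed", "expected")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(df$observed != round(df$observed)))
    stop("'observed' must be integer counts (row ",
         which(df$observed != round(df$observed))[1L], ")", call. = FALSE)
  bad <- which(!(df$expected > 0))
  if (length(bad))
    stop("'expected' must be positive (row ", bad[1L], ")", call. = FALSE)
  df <- df[order(df$area_id), , drop = FALSE]
  rownames(df) <- NULL
  covars <- setdiff(names(df), need)
  X <- if (length(covars)) as.matrix(df[, covars, drop = FALSE]) else NULL
  countData(df$observed, df$expected, X)
}

#' Read historical count data from CSV
#'
#' Long format with columns \code{area_id}, \code{year}, \code{observed},
#' \code{expected}; every (year, area) combination must be present. The
#' covariate design is shared with the study period and passed separately.
#'
#' @param path CSV file with a header.
#' @param X design matrix of the study period (e.g.
#'   \code{countData@X}); intercept-only when NULL.
#' @return a \code{\linkS4class{PriorCounts}}.
#' @export
readPriorCSV <- function(path, X = NULL) {
  df <- utils::read.csv(path)
  need <- c("area_id", "year", "observed", "expected")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  years <- sort(unique(df$year))
  areas <- sort(unique(df$area_id))
  if (nrow(df) != length(years) * length(areas))
    stop("prior CSV must contain every (year, area) combination",
         call. = FALSE)
  df <- df[order(df$year, df$area_id), , drop = FALSE]
  Yh <- matrix(df$observed, nrow = length(years), byrow = TRUE)
  Eh <- matrix(df$expected, nrow = length(years), byrow = TRUE)
  if (is.null(X)) X <- matrix(1, length(areas), 1L)
  priorCounts(Yh, Eh, as.matrix(X))
}

#' Serialize a candidate path to text files
#'
#' Writes the removal order as one edge per line (two 1-based area indices)
#' and the cached log-determinants to a \code{<file>.logdets} sidecar whose
#' first line records epsilon, so elicitation and fitting can run as
#' separate steps.
#'
#' @param path a \code{\linkS4class{CandidatePath}}.
#' @param file output file for the removal order.
#' @return invisibly, the sidecar file name.
#' @export
writePath <- function(path, file) {
  stopifnot(is(path, "CandidatePath"))
  e <- path@graph@edges[path@removalOrder, , drop = FALSE]
  writeLines(paste(e[, 1L], e[, 2L]), file)
  sidecar <- paste0(file, ".logdets")
  writeLines(c(sprintf("# epsilon %.17g", path@epsilon),
               sprintf("%.17g", path@logdets)), sidecar)
  invisible(sidecar)
}

#' Read a candidate path written by \code{\link{writePath}}
#'
#' @param file removal-order file (the \code{.logdets} sidecar must sit next
#'   to it).
#' @param graph the \code{\linkS4class{AreaGraph}} the path belongs to.
#' @return a \code{\linkS4class{CandidatePath}} (elicitation log-likelihoods
#'   are not serialized and come back as NA).
#' @export
readPath <- function(file, graph) {
  pairs <- utils::read.table(file, header = FALSE)
  key <- paste(graph@edges[, 1L], graph@edges[, 2L])
  ord <- match(paste(pmin(pairs[, 1L], pairs[, 2L]),
                     pmax(pairs[, 1L], pairs[, 2L])), key)
  if (anyNA(ord))
    stop("path file contains a pair that is not an edge of the graph",
         call. = FALSE)
  sidecar <- readLines(paste0(file, ".logdets"))
  eps <- as.numeric(sub("# epsilon ", "", sidecar[1L], fixed = TRUE))
  ld <- as.numeric(sidecar[-1L])
  new("CandidatePath", graph = graph, removalOrder = as.integer(ord),
      logdets = ld, epsilon = eps,
      loglik = rep(NA_real_, length(ld)))
}

## short deterministic hash of an R object (config fingerprinting)
.hashConfig <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L)[-(1:14)])
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write posterior samples to per-chain CSV files
#'
#' One CSV per chain with named columns plus a \code{manifest.json}
#' recording the model, dimensions, seed, config hash and acceptance rates.
#' Values round-trip bit-exactly through \code{\link{readSamples}}.
#'
#' @param samples a \code{\linkS4class{PosteriorSamples}} with at least one
#'   draw.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest as a list.
#' @export
writeSamples <- function(samples, dir) {
  stopifnot(is(samples, "PosteriorSamples"))
  if (nrow(samples@beta) == 0L)
    stop("no draws to write", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- samples@config
  for (ch in unique(samples@chain)) {
    sel <- samples@chain == ch
    df <- data.frame(samples@beta[sel, , drop = FALSE], check.names = FALSE)
    names(df) <- paste0("beta.", seq_len(ncol(samples@beta)))
    phi <- samples@phi[sel, , drop = FALSE]
    colnames(phi) <- paste0("phi.", seq_len(ncol(phi)))
    df <- cbind(df, phi)
    if (length(samples@phiStar)) df$phiStar <- samples@phiStar[sel]
    df$tau2 <- samples@tau2[sel]
    if (length(samples@pathIndex)) df$pathIndex <- samples@pathIndex[sel]
    if (ncol(samples@theta)) {
      th <- samples@theta[sel, , drop = FALSE]
      colnames(th) <- paste0("theta.", seq_len(ncol(th)))
      df <- cbind(df, th)
    }
    if (length(samples@sigma2)) df$sigma2 <- samples@sigma2[sel]
    utils::write.csv(df, file.path(dir, sprintf("chain%d.csv", ch)),
                     row.names = FALSE)
  }
  manifest <- list(
    model = samples@model,
    nChains = length(unique(samples@chain)),
    nSample = cfg@nSample, nBurn = cfg@nBurn, seed = cfg@seed,
    nAreas = ncol(samples@phi), nCoef = ncol(samples@beta),
    configHash = .hashConfig(cfg),
    acceptance = samples@acceptance,
    betaNames = colnames(samples@beta))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read posterior samples written by \code{\link{writeSamples}}
#'
#' @param dir directory containing \code{chain*.csv} and
#'   \code{manifest.json}.
#' @return a \code{\linkS4class{PosteriorSamples}}.
#' @export
readSamples <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^chain[0-9]+\\.csv$",
                           full.names = TRUE))
  chains <- lapply(files, utils::read.csv)
  pick <- function(df, prefix) {
    cols <- grep(paste0("^", prefix, "\\."), names(df))
    as.matrix(df[, cols, drop = FALSE])
  }
  get1 <- function(df, col) if (col %in% names(df)) df[[col]] else NULL
  parts <- lapply(chains, function(df) list(
    beta = pick(df, "beta"), phi = pick(df, "phi"),
    phiStar = get1(df, "phiStar"), tau2 = df$tau2,
    pathIndex = get1(df, "pathIndex"),
    theta = if (length(grep("^theta\\.", names(df)))) pick(df, "theta"),
    sigma2 = get1(df, "sigma2")))
  cfg <- mcmcConfig(nSample = man$nSample, nBurn = man$nBurn,
                    nChains = man$nChains, seed = man$seed)
  out <- .bindChains(parts, man$model, cfg,
                     hasTheta = !is.null(parts[[1L]]$theta))
  colnames(out@beta) <- man$betaNames
  out
}
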
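#' Read a binary response matrix from CSV
#'
#' Strict parser for the package's response format: a header row of item
#' identifiers followed by one row per examinee with 0/1 cells.  Any other
#' token is an error naming the offending row and column.
#'
#' @param path CSV file path.
#' @return integer N x J matrix with item names as column names.
#' @export
readResponses <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        strip.white = TRUE)
  if (nrow(df) < 1 || ncol(df) < 1) stop("empty response file: ", path)
  M <- as.matrix(df)
  bad <- which(matrix(!(M %in% c("0", "1")), nrow(M)), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("invalid response token '%s' at row %d, column '%s'",
                 M[bad[1, 1], bad[1, 2]], bad[1, 1], colnames(M)[bad[1, 2]]))
  U <- matrix(as.integer(M), nrow(M), ncol(M), dimnames = dimnames(M))
  rownames(U) <- NULL
  U
}

#' Write a binary response matrix to CSV
#'
#' @param U integer 0/1 matrix; columns are given `item1..itemJ` names when
#'   unnamed.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeResponses <- function(U, path) {
  U <- validateResponses(U)
  if (is.null(colnames(U))) colnames(U) <- paste0("item", seq_len(ncol(U)))
  utils::write.csv(as.data.frame(U), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a fitted model to JSON
#'
#' Writes every slot of a [SAEMFit-class] to JSON at full precision, so
#' that [readFit()] reconstructs the object losslessly.
#'
#' @param fit a [SAEMFit-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFit <- function(fit, path) {
  stopifnot(is(fit, "SAEMFit"))
  ctl <- fit@control
  ctl$seed <- if (is.null(ctl$seed)) NA else ctl$seed
  obj <- list(
    items = as.list(fit@items),
    eta = fit@eta,
    mass = fit@mass,
    grid = list(lo = fit@grid@lo, hi = fit@grid@hi, step = fit@grid@step),
    mode = fit@mode, knots = fit@knots, degree = fit@degree,
    converged = fit@converged, iterations = fit@iterations,
    logLik = fit@logLik, nParams = fit@nParams,
    criteria = as.list(fit@criteria),
    trajectory = fit@trajectory,
    control = ctl)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Reconstruct a fitted model from JSON
#'
#' @param path a file written by [writeFit()].
#' @return a [SAEMFit-class].
#' @export
readFit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ctl <- obj$control
  if (!is.null(ctl$seed) && is.na(ctl$seed)) ctl$seed <- NULL
  new("SAEMFit",
      items = data.frame(a = obj$items$a, b = obj$items$b, c = obj$items$c),
      eta = as.numeric(obj$eta %||% numeric(0)),
      mass = as.numeric(obj$mass),
      grid = buildGrid(obj$grid$lo, obj$grid$hi, obj$grid$step),
      mode = obj$mode,
      knots = if (is.null(obj$knots) || is.na(obj$knots)) NA_integer_ else as.integer(obj$knots),
      degree = if (is.null(obj$degree) || is.na(obj$degree)) NA_integer_ else as.integer(obj$degree),
      converged = obj$converged, iterations = as.integer(obj$iterations),
      logLik = obj$logLik, nParams = as.integer(obj$nParams),
      criteria = c(aic = obj$criteria$aic, bic = obj$criteria$bic,
                   hqic = obj$criteria$hqic),
      trajectory = as.numeric(obj$trajectory),
      control = ctl)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
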
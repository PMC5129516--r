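## Small shared utilities: seed substreams, parameter serialization,
## lifeline CSV round-trip.

#' Derive a named substream seed
#'
#' All randomness in the package flows from one top-level seed;
#' independent stages (simulation, turbulence noise, stitching) use
#' substreams derived deterministically from the top seed and the
#' stream name, so stages can be re-run or reordered without
#' perturbing each other.
#'
#' @param seed top-level integer seed
#' @param stream stream name, e.g. "simulate", "noise", "stitch"
#' @return an integer seed
#' @export
deriveSeed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

## serialize parameters for provenance metadata
paramsAsList <- function(params) {
  s <- slotNames(params)
  stats::setNames(lapply(s, function(x) slot(params, x)), s)
}

#' Write lifelines to long-format CSV
#'
#' The on-disk interchange contract: columns \code{particle_id},
#' \code{t}, \code{qs_frac} (and \code{Cs} when present), one row per
#' particle-timepoint. Values are written in full double precision
#' (17 significant digits), so a read-back reproduces the object
#' exactly.
#'
#' @param lifelines a \linkS4class{LifelineSet}
#' @param path output file path
#' @return invisibly, \code{path}
#' @seealso [readLifelineCSV()]
#' @export
writeLifelineCSV <- function(lifelines, path) {
  stopifnot(is(lifelines, "LifelineSet"))
  q <- qsFrac(lifelines)
  t <- lifelineTimes(lifelines)
  df <- data.frame(
    particle_id = rep(particleIds(lifelines), times = ncol(q)),
    t = rep(t, each = nrow(q)),
    qs_frac = as.vector(q))
  if ("Cs" %in% assayNames(lifelines))
    df$Cs <- as.vector(assay(lifelines, "Cs"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = ","), con)
  fmt <- function(x) formatC(x, digits = 17, format = "g")
  body <- do.call(paste, c(lapply(df, fmt), sep = ","))
  writeLines(body, con)
  invisible(path)
}

#' Read lifelines from long-format CSV
#'
#' @param path CSV file written by [writeLifelineCSV()] (or any file
#'   honouring the same column contract)
#' @return a \linkS4class{LifelineSet}
#' @export
readLifelineCSV <- function(path) {
  if (!file.exists(path)) stop("lifeline file not found: ", path)
  df <- utils::read.csv(path)
  need <- c("particle_id", "t", "qs_frac")
  if (!all(need %in% colnames(df)))
    stop("lifeline CSV must have columns: ", paste(need, collapse = ", "))
  ids <- unique(df$particle_id)
  t <- sort(unique(df$t))
  o <- order(match(df$particle_id, ids), df$t)
  df <- df[o, ]
  q <- matrix(df$qs_frac, nrow = length(ids), ncol = length(t), byrow = TRUE)
  Cs <- if ("Cs" %in% colnames(df))
    matrix(df$Cs, nrow = length(ids), ncol = length(t), byrow = TRUE)
  LifelineSet(q, t, Cs = Cs, particle_id = ids,
              metadata = list(provenance = paste0("read[", basename(path), "]"),
                              value_type = "qs_frac"))
}
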
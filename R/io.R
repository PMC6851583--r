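## Plain-text interchange: tidy CSV abundance tables, per-sample
## flow-event CSVs with a key,value metadata header, and MPN well tables.

#' Read and write abundance tables
#'
#' Tidy CSV with columns \code{treatment}, \code{light}, \code{replicate},
#' \code{time_h}, \code{target} (\code{host}/\code{virus}),
#' \code{value_per_ml} and optionally \code{latent_per_ml} (noiseless
#' values, written by the simulator).
#'
#' @param df abundance data.frame (as in [abundance()]).
#' @param path CSV file path.
#' @return \code{readAbundance} returns the data.frame;
#'   \code{writeAbundance} returns \code{path} invisibly.
#' @export
writeAbundance <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeAbundance
#' @export
readAbundance <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("treatment", "light", "replicate", "time_h", "target",
            "value_per_ml")
  if (!all(need %in% names(df)))
    stop("abundance file must have columns: ", paste(need, collapse = ", "))
  df
}

#' Read and write MPN well tables
#'
#' CSV with columns \code{dilution}, \code{positive}, \code{total},
#' \code{volume_ml}.
#'
#' @param assay a [DilutionAssay-class].
#' @param path CSV file path.
#' @return \code{readMPNWells} returns a [DilutionAssay-class];
#'   \code{writeMPNWells} returns \code{path} invisibly.
#' @export
writeMPNWells <- function(assay, path) {
  utils::write.csv(
    data.frame(dilution = assay@dilution, positive = assay@positive,
               total = assay@total, volume_ml = assay@volume),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeMPNWells
#' @export
readMPNWells <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("dilution", "positive", "total", "volume_ml")
  if (!all(need %in% names(df)))
    stop("MPN wells file must have columns: ", paste(need, collapse = ", "))
  DilutionAssay(df$dilution, df$positive, df$total, df$volume_ml)
}

#' Read and write flow-event tables
#'
#' One CSV per sample: metadata as leading \code{# key,value} comment
#' lines (sample_id, treatment, light, replicate, time_h) followed by a
#' single \code{fluorescence} column, one event per row.
#'
#' @param sample a [FlowSample-class].
#' @param path CSV file path (for a single sample) or directory (for
#'   \code{readFlowEventsDir}).
#' @return \code{readFlowEvents} returns a [FlowSample-class];
#'   \code{readFlowEventsDir} a named list of them; writers return the
#'   path invisibly.
#' @export
writeFlowEvents <- function(sample, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(sample_id = sample@sampleId, treatment = sample@treatment,
            light = sample@light, replicate = sample@replicate,
            time_h = sample@timeH)
  writeLines(paste0("# ", names(meta), ",", as.character(meta)), con)
  writeLines("fluorescence", con)
  writeLines(format(sample@fluorescence, digits = 10, trim = TRUE,
                    scientific = FALSE), con)
  invisible(path)
}

#' @rdname writeFlowEvents
#' @export
readFlowEvents <- function(path) {
  lines <- readLines(path)
  metaL <- grep("^# ", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^# ", "", metaL), ",", fixed = TRUE))
  meta <- stats::setNames(kv[, 2], kv[, 1])
  body <- lines[!startsWith(lines, "#")]
  fl <- as.numeric(body[-1])
  FlowSample(fl,
             sampleId = unname(meta["sample_id"]),
             treatment = unname(meta["treatment"]),
             light = unname(meta["light"]),
             replicate = as.numeric(meta["replicate"]),
             timeH = as.numeric(meta["time_h"]))
}

#' @rdname writeFlowEvents
#' @export
readFlowEventsDir <- function(path) {
  files <- sort(list.files(path, pattern = "\\.csv$", full.names = TRUE))
  out <- lapply(files, readFlowEvents)
  names(out) <- vapply(out, function(s) s@sampleId, character(1))
  out
}
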
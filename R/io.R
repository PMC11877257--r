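#' Read a voltage sweep from CSV + JSON sidecar
#'
#' The sweep file is a two-column CSV (\code{time_ms,voltage_mV}) with the
#' stimulation protocol in a JSON sidecar named \code{<path>.json} (fields
#' \code{amplitude_pA}, \code{onset_ms}, \code{duration_ms},
#' \code{sampling_khz}, \code{cell_id}, optional \code{holding_pA}).
#'
#' @param path Path to the sweep CSV.
#' @param sidecar Path to the protocol JSON; default \code{paste0(path, ".json")}.
#' @return A \code{\link{voltage_sweep}}.
#' @seealso \code{\link{write_sweep}}
#' @export
read_sweep <- function(path, sidecar = paste0(path, ".json")) {
  if (!file.exists(path)) stop("sweep file not found: ", path)
  if (!file.exists(sidecar)) stop("protocol sidecar not found: ", sidecar)
  df <- utils::read.csv(path)
  if (!all(c("time_ms", "voltage_mV") %in% names(df)))
    stop("sweep CSV must have columns time_ms,voltage_mV: ", path)
  bad <- which(!is.finite(df$time_ms) | !is.finite(df$voltage_mV))
  if (length(bad))
    stop("non-numeric value in sweep file ", path, " at data line ", bad[1L])
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  need <- c("amplitude_pA", "onset_ms", "duration_ms", "sampling_khz")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("sidecar missing field(s): ", paste(miss, collapse = ", "))
  voltage_sweep(
    time_ms = df$time_ms, voltage_mV = df$voltage_mV,
    sampling_khz = meta$sampling_khz,
    protocol = step_protocol(meta$amplitude_pA, meta$onset_ms,
                             meta$duration_ms,
                             if (is.null(meta$holding_pA)) 0 else meta$holding_pA),
    cell_id = if (is.null(meta$cell_id)) "cell" else meta$cell_id)
}

#' Write a voltage sweep to CSV + JSON sidecar
#'
#' @param sweep A \code{\link{voltage_sweep}}.
#' @param path Output CSV path; the protocol goes to \code{paste0(path, ".json")}.
#' @return \code{path}, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  stopifnot(inherits(sweep, "voltage_sweep"))
  df <- data.frame(time_ms = sweep$time_ms, voltage_mV = sweep$voltage_mV)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(amplitude_pA = sweep$protocol$amplitude_pA,
               onset_ms = sweep$protocol$onset_ms,
               duration_ms = sweep$protocol$duration_ms,
               holding_pA = sweep$protocol$holding_pA,
               sampling_khz = sweep$sampling_khz,
               cell_id = sweep$cell_id)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a cells-by-features table from CSV
#'
#' The CSV must contain the 12 canonical feature columns (any order; see
#' \code{\link{canonical_features}}), an optional \code{cell_id} column and
#' optional \code{morphology} / \code{firing_pattern} label columns with
#' values drawn from the fixed vocabularies.
#'
#' @param path CSV path.
#' @return A \code{\link{feature_table}} with features in canonical order.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  feature_table(
    values = df[, intersect(names(df), canonical_features()), drop = FALSE],
    cell_ids = if ("cell_id" %in% names(df)) df$cell_id else NULL,
    morphology = if ("morphology" %in% names(df)) {
      m <- as.character(df$morphology); m[m == ""] <- NA; m
    } else NULL,
    firing_pattern = if ("firing_pattern" %in% names(df)) {
      p <- as.character(df$firing_pattern); p[p == ""] <- NA; p
    } else NULL)
}

#' Write a feature table to CSV
#'
#' @param table A \code{\link{feature_table}}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write subset-screen results to CSV
#'
#' One row per feature subset with columns
#' \code{mask,chi2,df,p_value,significant}; rows are sorted by the mask read
#' as a binary integer, ascending, regardless of input order.
#'
#' @param results Data frame of screen results (e.g. the \code{results}
#'   element of \code{\link{subset_screen}} output).
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_screen_results <- function(results, path) {
  if (inherits(results, "l1_screen")) results <- results$results
  need <- c("mask", "chi2", "df", "p_value", "significant")
  miss <- setdiff(need, names(results))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(results) == 0L) stop("results must be non-empty")
  if (anyDuplicated(results$mask))
    stop("duplicate masks in results")
  ord <- order(vapply(results$mask, function(m) strtoi(m, base = 2L), 0))
  utils::write.csv(results[ord, need], path, row.names = FALSE)
  invisible(path)
}

#' Read subset-screen results from CSV
#'
#' @param path CSV path written by \code{\link{write_screen_results}}.
#' @return Data frame with columns \code{mask,chi2,df,p_value,significant}.
#' @export
read_screen_results <- function(path) {
  df <- utils::read.csv(path, colClasses = c(mask = "character"))
  df$significant <- as.logical(df$significant)
  df
}
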
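#' Canonical intrinsic-property names
#'
#' The twelve intrinsic electrophysiological properties used throughout the
#' package, in canonical order: resting membrane potential, spike threshold,
#' spike peak amplitude, spike half-width, first spike latency, maximum spike
#' rise slope, AHP amplitude, AHP duration, input resistance, membrane time
#' constant, cell capacitance, depolarizing hump. Subset masks (e.g.
#' \code{"111100101111"}) index bits in this order, so that mask decodes to
#' {resting Vm, threshold, peak amplitude, half-width, AHP amplitude, input
#' resistance, time constant, capacitance, hump}.
#'
#' @return Character vector of length 12.
#' @export
canonical_features <- function() {
  c("resting_vm_mV", "threshold_mV", "peak_amplitude_mV", "half_width_ms",
    "first_spike_latency_ms", "max_rise_slope_mV_per_ms", "ahp_amplitude_mV",
    "ahp_duration_ms", "input_resistance_Mohm", "time_constant_ms",
    "capacitance_pF", "depolarizing_hump_mV")
}

.morph_levels <- c("NGC", "eNGC", "SBC-like")
.pattern_levels <- c("LS", "NLS", "BS")

#' Cells-by-features table of intrinsic properties
#'
#' A matrix of the 12 intrinsic properties (columns, canonical order) for a
#' set of cells, with optional per-cell morphology labels (\code{NGC},
#' \code{eNGC}, \code{SBC-like}) and firing-pattern labels (\code{LS},
#' \code{NLS}, \code{BS}).
#'
#' @param values Numeric matrix or data.frame, cells x features. Column names
#'   must be the canonical feature names (any order; reordered on input).
#' @param cell_ids Character vector of cell identifiers (default rownames or
#'   \code{cell_1 ...}).
#' @param morphology Optional per-cell morphology label.
#' @param firing_pattern Optional per-cell firing-pattern label.
#'
#' @return Object of class \code{"feature_table"}: a list with elements
#'   \code{values} (numeric matrix), \code{cell_ids}, \code{morphology},
#'   \code{firing_pattern}.
#' @export
feature_table <- function(values, cell_ids = NULL, morphology = NULL,
                          firing_pattern = NULL) {
  values <- as.matrix(values)
  canon <- canonical_features()
  if (is.null(colnames(values)) && ncol(values) == 12L)
    colnames(values) <- canon
  missing_cols <- setdiff(canon, colnames(values))
  if (length(missing_cols))
    stop("missing feature column(s): ", paste(missing_cols, collapse = ", "))
  values <- values[, canon, drop = FALSE]
  storage.mode(values) <- "double"
  n <- nrow(values)
  if (is.null(cell_ids))
    cell_ids <- if (!is.null(rownames(values))) rownames(values)
                else paste0("cell_", seq_len(n))
  if (length(cell_ids) != n) stop("cell_ids length mismatch")
  chk_label <- function(lab, levels, what) {
    if (is.null(lab)) return(NULL)
    lab <- as.character(lab)
    if (length(lab) != n) stop(what, " length mismatch")
    bad <- setdiff(stats::na.omit(unique(lab)), levels)
    if (length(bad))
      stop("unknown ", what, " value(s): ", paste(bad, collapse = ", "),
           " (allowed: ", paste(levels, collapse = ", "), ")")
    lab
  }
  structure(
    list(values = values,
         cell_ids = as.character(cell_ids),
         morphology = chk_label(morphology, .morph_levels, "morphology"),
         firing_pattern = chk_label(firing_pattern, .pattern_levels,
                                    "firing_pattern")),
    class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("Feature table: %d cells x %d intrinsic properties\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$morphology))
    cat("  morphology labels:",
        paste(names(table(x$morphology)), table(x$morphology),
              sep = "=", collapse = ", "), "\n")
  if (!is.null(x$firing_pattern))
    cat("  firing patterns:  ",
        paste(names(table(x$firing_pattern)), table(x$firing_pattern),
              sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.feature_table <- function(x, ...) {
  df <- data.frame(cell_id = x$cell_ids, x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(x$morphology)) df$morphology <- x$morphology
  if (!is.null(x$firing_pattern)) df$firing_pattern <- x$firing_pattern
  df
}

#' @export
dim.feature_table <- function(x) dim(x$values)

# convert mask (12-char binary string or logical/integer vector) to logical
.parse_mask <- function(mask, k = 12L) {
  if (is.character(mask)) {
    stopifnot(length(mask) == 1L)
    bits <- strsplit(mask, "")[[1L]]
    if (!all(bits %in% c("0", "1")))
      stop("mask string must contain only 0/1")
    m <- bits == "1"
  } else if (is.logical(mask)) {
    m <- mask
  } else {
    m <- as.integer(mask) != 0L
  }
  if (length(m) != k) stop("mask must have length ", k)
  if (!any(m)) stop("mask must select at least one feature")
  m
}

.mask_string <- function(m) paste(as.integer(m), collapse = "")
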
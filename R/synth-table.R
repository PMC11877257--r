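# Synthetic cells-by-features tables with known subtype structure.

#' Specification of a synthetic labelled feature table
#'
#' Per-subtype multivariate-normal feature distributions. The default preset
#' reproduces the reported per-subtype means of the 12 intrinsic properties
#' for mouse mPFC L1 interneurons (see \code{\link{l1in_reference}}), with
#' SDs reconstructed from the reported SEMs as \code{SEM * sqrt(n)}.
#'
#' @param n_per_subtype Named integer vector of cells per subtype.
#' @param feature_means Subtypes x 12 matrix of feature means (canonical
#'   column order).
#' @param feature_sds Subtypes x 12 matrix of positive feature SDs.
#' @param correlation Common within-subtype feature correlation (default 0).
#' @param seed Optional seed.
#' @return Object of class \code{"synthetic_dataset_spec"}.
#' @export
synthetic_dataset_spec <- function(n_per_subtype, feature_means, feature_sds,
                                   correlation = 0, seed = NULL) {
  feature_means <- as.matrix(feature_means)
  feature_sds <- as.matrix(feature_sds)
  s <- length(n_per_subtype)
  if (is.null(names(n_per_subtype)))
    stop("n_per_subtype must be named by subtype")
  if (any(n_per_subtype < 1)) stop("counts must be >= 1")
  if (!all(dim(feature_means) == c(s, 12L)) ||
      !all(dim(feature_sds) == c(s, 12L)))
    stop("feature_means and feature_sds must be subtypes x 12")
  if (any(feature_sds <= 0)) stop("feature_sds must be positive")
  if (abs(correlation) >= 1) stop("correlation must be in (-1, 1)")
  structure(list(n_per_subtype = n_per_subtype,
                 feature_means = feature_means, feature_sds = feature_sds,
                 correlation = correlation, seed = seed),
            class = "synthetic_dataset_spec")
}

#' Preset spec reproducing the reported mPFC L1IN subtype distributions
#'
#' Means and SEM-derived SDs of the 12 intrinsic properties for NGC (n=11),
#' eNGC (n=12) and SBC-like (n=10) cells, from the bundled reference
#' summaries.
#'
#' @param n_per_subtype Cells per subtype; defaults to the reported counts.
#' @param correlation Within-subtype feature correlation.
#' @param seed Optional seed.
#' @return A \code{\link{synthetic_dataset_spec}}.
#' @export
table_preset_spec <- function(n_per_subtype = NULL, correlation = 0,
                              seed = NULL) {
  ref <- l1in_reference()$intrinsic_by_subtype
  n_ref <- ref$n
  if (is.null(n_per_subtype)) n_per_subtype <- n_ref
  sds <- ref$sem * sqrt(matrix(n_ref, nrow = 3, ncol = 12))
  synthetic_dataset_spec(n_per_subtype, ref$mean, sds,
                         correlation = correlation, seed = seed)
}

#' Spec with planted cluster structure
#'
#' Three subtypes separated by \code{separation} pooled SDs on each of
#' \code{n_informative} features (unit SD, means 0, separation,
#' 2*separation); the remaining features are standard-normal noise identical
#' across subtypes. Used to validate that the clustering screen recovers
#' known structure.
#'
#' @param separation Between-adjacent-subtype mean separation in pooled SDs.
#' @param n_informative Number of informative features (placed first in
#'   canonical order).
#' @param n_per_subtype Cells per subtype; defaults to the reported
#'   morphologically registered counts (11, 12, 10).
#' @param seed Optional seed.
#' @return A \code{\link{synthetic_dataset_spec}} with attribute
#'   \code{"informative"} marking the informative feature indices.
#' @export
planted_cluster_spec <- function(separation = 3, n_informative = 4,
                                 n_per_subtype = c(NGC = 11, eNGC = 12,
                                                   "SBC-like" = 10),
                                 seed = NULL) {
  means <- matrix(0, 3, 12)
  means[, seq_len(n_informative)] <-
    matrix(separation * (0:2), 3, n_informative)
  spec <- synthetic_dataset_spec(n_per_subtype, means,
                                 matrix(1, 3, 12), seed = seed)
  attr(spec, "informative") <- seq_len(n_informative)
  spec
}

#' Sample a labelled feature table from a spec
#'
#' Draws per-subtype multivariate-normal feature vectors and attaches the
#' subtype as the morphology label. Deterministic under the spec's seed.
#'
#' @param spec A \code{\link{synthetic_dataset_spec}}.
#' @return A \code{\link{feature_table}} with morphology labels.
#' @export
sample_feature_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_dataset_spec"))
  k <- 12L
  rho <- spec$correlation
  Sigma <- matrix(rho, k, k); diag(Sigma) <- 1
  L <- tryCatch(chol(Sigma),
                error = function(e) stop("correlation matrix is not positive definite"))
  .with_seed(spec$seed, {
    rows <- lapply(seq_along(spec$n_per_subtype), function(s) {
      n <- spec$n_per_subtype[s]
      Z <- matrix(stats::rnorm(n * k), n, k) %*% L
      sweep(Z, 2L, spec$feature_sds[s, ], "*") +
        matrix(spec$feature_means[s, ], n, k, byrow = TRUE)
    })
    values <- do.call(rbind, rows)
    colnames(values) <- canonical_features()
    feature_table(values,
                  morphology = rep(names(spec$n_per_subtype),
                                   spec$n_per_subtype))
  })
}
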
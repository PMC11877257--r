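# Ward hierarchical clustering of intrinsic properties, the exhaustive
# feature-subset screen against morphology labels, weighted subset
# selection, and permutation validation.

#' Configuration for the clustering screen
#'
#' @param n_clusters Number of clusters to cut the Ward tree into.
#' @param alpha Significance level for the cluster-morphology association.
#' @param standardize Z-score each masked feature before clustering. On by
#'   default: the 12 properties mix units (mV, ms, MOhm, pF) and raw
#'   Euclidean distances would be dominated by input resistance.
#' @param seed Seed for permutation procedures.
#' @param n_shuffles Number of shuffles for permutation validation.
#' @param target_subset_size Size of the feature subset selected by
#'   \code{\link{weight_and_select}}.
#' @return Object of class \code{"screen_config"}.
#' @export
screen_config <- function(n_clusters = 3, alpha = 0.05, standardize = TRUE,
                          seed = NULL, n_shuffles = 1000,
                          target_subset_size = 9) {
  if (n_clusters < 2) stop("n_clusters must be >= 2")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (n_shuffles < 1) stop("n_shuffles must be >= 1")
  structure(list(n_clusters = n_clusters, alpha = alpha,
                 standardize = standardize, seed = seed,
                 n_shuffles = n_shuffles,
                 target_subset_size = target_subset_size),
            class = "screen_config")
}

.table_values <- function(table) {
  if (inherits(table, "feature_table")) table$values else as.matrix(table)
}

# z-score columns; constant columns are an error (zero distance information)
.standardize <- function(x) {
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant feature after masking: ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  scale(x)
}

# canonical group labels: 1..k by descending size; ties broken by ascending
# group mean of the first masked feature
.canonical_groups <- function(raw, first_feature) {
  sizes <- tabulate(raw)
  means <- vapply(seq_along(sizes),
                  function(g) mean(first_feature[raw == g]), 0)
  ord <- order(-sizes, means)
  relabel <- integer(length(sizes))
  relabel[ord] <- seq_along(sizes)
  relabel[raw]
}

#' Ward clustering on a feature subset
#'
#' Z-scores the masked features (unless \code{standardize} is off), builds
#' Ward linkage (\code{ward.D2}) on Euclidean distances and cuts the tree
#' into exactly \code{n_clusters} groups. Groups are labelled 1..k by
#' descending size (ties by ascending mean of the first masked feature), so
#' labels are reproducible and invariant to cell order.
#'
#' @param table A \code{\link{feature_table}} or numeric matrix.
#' @param mask Feature subset: a binary string (e.g. \code{"111100101111"}),
#'   or logical/integer vector over the table's columns. Default: all.
#' @param config A \code{\link{screen_config}}.
#' @return Integer vector of per-cell group assignments in 1..k.
#' @export
ward_cluster <- function(table, mask = NULL, config = screen_config()) {
  x <- .table_values(table)
  if (!is.null(mask)) x <- x[, .parse_mask(mask, ncol(x)), drop = FALSE]
  if (nrow(x) < config$n_clusters)
    stop("need at least n_clusters cells")
  if (anyNA(x)) stop("masked features contain missing values")
  if (config$standardize) x <- .standardize(x)
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  raw <- stats::cutree(hc, k = config$n_clusters)
  .canonical_groups(raw, x[, 1L])
}

# Pearson chi-squared on a contingency table built from observed levels only
.pearson_chi2 <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
  E <- outer(rs, cs) / N
  chi2 <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
       min_expected = min(E))
}

#' Chi-squared association between cluster assignment and labels
#'
#' Pearson chi-squared test (no continuity correction) on the groups x
#' labels contingency table of the labelled cells; unlabelled cells
#' (\code{NA}) are ignored. A warning is logged when the minimum expected
#' count is below 5, matching the small labelled samples this screen is
#' typically run on.
#'
#' @param assignment Per-cell group assignment.
#' @param labels Per-cell category labels (NA = unlabelled).
#' @param warn_expected Warn when min expected count < 5.
#' @return List: \code{chi2}, \code{df}, \code{p_value}, \code{table}.
#' @export
association_test <- function(assignment, labels, warn_expected = FALSE) {
  keep <- !is.na(labels)
  tab <- table(group = assignment[keep], label = as.character(labels[keep]))
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("degenerate contingency table: need >= 2 groups and >= 2 label categories")
  res <- .pearson_chi2(tab)
  if (warn_expected && res$min_expected < 5)
    warning("minimum expected count ", signif(res$min_expected, 3), " < 5")
  list(chi2 = res$chi2, df = res$df, p_value = res$p_value, table = tab)
}

# precompute per-feature squared Euclidean distance vectors (dist layout)
.feature_sqdists <- function(x) {
  lapply(seq_len(ncol(x)), function(j) unclass(stats::dist(x[, j]))^2)
}

.dist_from_sq <- function(sq, n) {
  structure(sqrt(sq), Size = n, Diag = FALSE, Upper = FALSE,
            method = "euclidean", class = "dist")
}

# screen core shared by subset_screen and the shuffled variant
.screen_masks <- function(x, labels, config, masks = NULL) {
  n <- nrow(x); k <- ncol(x)
  if (config$standardize) x <- .standardize(x)
  sq <- .feature_sqdists(x)
  if (is.null(masks)) masks <- seq_len(2^k - 1L)
  out <- data.frame(mask = character(length(masks)), size = 0L,
                    chi2 = NA_real_, df = NA_integer_, p_value = NA_real_,
                    significant = FALSE, note = "",
                    stringsAsFactors = FALSE)
  bit_mat <- vapply(seq_len(k), function(b) bitwAnd(masks, bitwShiftL(1L, k - b)) > 0L,
                    logical(length(masks)))
  if (length(masks) == 1L) bit_mat <- matrix(bit_mat, nrow = 1L)
  for (i in seq_along(masks)) {
    sel <- which(bit_mat[i, ])
    out$mask[i] <- paste(as.integer(bit_mat[i, ]), collapse = "")
    out$size[i] <- length(sel)
    res <- tryCatch({
      s <- sq[[sel[1L]]]
      if (length(sel) > 1L) for (j in sel[-1L]) s <- s + sq[[j]]
      hc <- stats::hclust(.dist_from_sq(s, n), method = "ward.D2")
      grp <- .canonical_groups(stats::cutree(hc, k = config$n_clusters),
                               x[, sel[1L]])
      association_test(grp, labels)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$note[i] <- conditionMessage(res)
    } else {
      out$chi2[i] <- res$chi2
      out$df[i] <- res$df
      out$p_value[i] <- res$p_value
      out$significant[i] <- res$p_value < config$alpha
    }
  }
  out
}

#' Exhaustive feature-subset clustering screen
#'
#' For every non-empty subset of the table's features (2^k - 1 subsets, 4095
#' for the canonical 12), clusters the cells with Ward's method on that
#' subset and tests the association between the resulting groups and the
#' morphology labels with a Pearson chi-squared test. Per-subset errors
#' (e.g. degenerate tables) are recorded in the output row, not raised.
#'
#' @param table A \code{\link{feature_table}} or numeric matrix.
#' @param labels Per-cell labels; defaults to the table's morphology labels.
#' @param config A \code{\link{screen_config}}.
#' @return Object of class \code{"l1_screen"}: list with \code{results} (one
#'   row per subset, in ascending mask-as-binary-integer order), the
#'   \code{config}, and the data used.
#' @examples
#' tab <- sample_feature_table(planted_cluster_spec(seed = 1))
#' scr <- subset_screen(tab)
#' summary(scr)
#' @export
subset_screen <- function(table, labels = NULL, config = screen_config()) {
  x <- .table_values(table)
  if (is.null(labels) && inherits(table, "feature_table"))
    labels <- table$morphology
  if (is.null(labels)) stop("labels are required")
  k <- ncol(x)
  if (k > 20L) stop("refusing to enumerate 2^k - 1 subsets for k > 20")
  results <- .screen_masks(x, labels, config)
  structure(list(results = results, config = config, values = x,
                 labels = labels),
            class = "l1_screen")
}

#' @export
print.l1_screen <- function(x, ...) {
  cat(sprintf("Feature-subset Ward-clustering screen: %d subsets of %d features\n",
              nrow(x$results), ncol(x$values)))
  cat(sprintf("  %d cells (%d labelled); %d clusters; alpha = %g\n",
              nrow(x$values), sum(!is.na(x$labels)),
              x$config$n_clusters, x$config$alpha))
  cat(sprintf("  significant subsets: %d (%.1f%%)\n",
              sum(x$results$significant),
              100 * mean(x$results$significant)))
  invisible(x)
}

#' @export
summary.l1_screen <- function(object, ...) {
  sel <- weight_and_select(object)
  out <- list(n_subsets = nrow(object$results),
              n_significant = sum(object$results$significant),
              selection = sel)
  class(out) <- "summary.l1_screen"
  out
}

#' @export
print.summary.l1_screen <- function(x, ...) {
  cat(sprintf("Subsets screened: %d; significant: %d\n",
              x$n_subsets, x$n_significant))
  s <- x$selection
  cat(sprintf("Selected subset #%s (%d features):\n  %s\n", s$mask,
              sum(.parse_mask(s$mask, nchar(s$mask))),
              paste(s$features, collapse = ", ")))
  cat(sprintf("Covers %d of %d significant subsets (%.1f%%)\n",
              s$coverage_count, x$n_significant,
              100 * s$coverage_fraction))
  cat(sprintf("Association on selected subset: chi2 = %.4g, p = %.4g%s\n",
              s$selected_chi2, s$selected_p,
              if (isTRUE(s$significance_lost_with_next))
                "; adding the next-ranked feature loses significance" else ""))
  invisible(x)
}

#' @export
plot.l1_screen <- function(x, ...) {
  w <- feature_weights(x)
  graphics::barplot(w, las = 2, cex.names = 0.7,
                    ylab = "significant subsets containing feature",
                    main = "Feature weights in significant subsets", ...)
  invisible(x)
}

#' Feature weights from a screen
#'
#' Weight of a feature = number of significant subsets containing it.
#'
#' @param screen An \code{\link{subset_screen}} result.
#' @return Named integer vector over the table's features.
#' @export
feature_weights <- function(screen) {
  stopifnot(inherits(screen, "l1_screen"))
  res <- screen$results[screen$results$significant, , drop = FALSE]
  k <- ncol(screen$values)
  w <- integer(k)
  names(w) <- colnames(screen$values)
  for (m in res$mask) w <- w + (strsplit(m, "")[[1L]] == "1")
  w
}

#' Select the top-weighted feature subset from a screen
#'
#' Ranks features by their weight (frequency among significant subsets, ties
#' broken by canonical order), selects the top \code{target_subset_size},
#' and reports how many significant subsets the selection fully covers. Also
#' tests whether the selected subset's own cluster-morphology association is
#' significant and whether significance is lost when the next-ranked feature
#' is added.
#'
#' @param screen An \code{\link{subset_screen}} result.
#' @param config Config; defaults to the screen's own.
#' @return List: \code{mask}, \code{features}, \code{weights},
#'   \code{coverage_count}, \code{coverage_fraction}, \code{selected_chi2},
#'   \code{selected_p}, \code{extended_p},
#'   \code{significance_lost_with_next}.
#' @export
weight_and_select <- function(screen, config = screen$config) {
  stopifnot(inherits(screen, "l1_screen"))
  res <- screen$results[screen$results$significant, , drop = FALSE]
  if (nrow(res) == 0L) stop("no significant subsets to select from")
  w <- feature_weights(screen)
  k <- length(w)
  size <- min(config$target_subset_size, k)
  rank_order <- order(-w, seq_len(k))
  top <- sort(rank_order[seq_len(size)])
  sel_mask <- replace(logical(k), top, TRUE)
  sig_bits <- lapply(strsplit(res$mask, ""), function(b) b == "1")
  covered <- vapply(sig_bits, function(b) all(!b | sel_mask), logical(1))
  assoc <- function(m) {
    grp <- ward_cluster(screen$values, m, config)
    association_test(grp, screen$labels)
  }
  sel_res <- tryCatch(assoc(sel_mask), error = function(e) NULL)
  ext_res <- NULL
  if (size < k) {
    ext_mask <- replace(sel_mask, rank_order[size + 1L], TRUE)
    ext_res <- tryCatch(assoc(ext_mask), error = function(e) NULL)
  }
  sel_p <- if (is.null(sel_res)) NA_real_ else sel_res$p_value
  ext_p <- if (is.null(ext_res)) NA_real_ else ext_res$p_value
  list(mask = .mask_string(sel_mask),
       features = names(w)[top],
       weights = w,
       coverage_count = sum(covered),
       coverage_fraction = sum(covered) / nrow(res),
       selected_chi2 = if (is.null(sel_res)) NA_real_ else sel_res$chi2,
       selected_p = sel_p,
       extended_p = ext_p,
       significance_lost_with_next =
         !is.na(sel_p) && sel_p < config$alpha &&
         !is.na(ext_p) && ext_p >= config$alpha)
}

#' Permutation validation of the clustering screen
#'
#' Two variants. \code{"screen"}: shuffle every feature column independently
#' across cells once per shuffle, rerun the full subset screen on the
#' shuffled data, and report the number of significant subsets attained (and
#' the minimum p-value). \code{"selected"}: for each of \code{n_shuffles}
#' shuffles, cluster the shuffled data on one fixed mask and record the
#' association p-value; reports the fraction significant, which should match
#' alpha on null data.
#'
#' @param table A \code{\link{feature_table}} or matrix.
#' @param labels Per-cell labels; default the table's morphology.
#' @param config A \code{\link{screen_config}} (its \code{seed} and
#'   \code{n_shuffles} drive the procedure).
#' @param variant \code{"selected"} (default) or \code{"screen"}.
#' @param mask Mask for the \code{"selected"} variant (default all features).
#' @return For \code{"selected"}: list with \code{fraction_significant},
#'   \code{p_values}, \code{n_shuffles}. For \code{"screen"}: list with
#'   \code{n_significant}, \code{min_p}, \code{results} per shuffle.
#' @export
permutation_validation <- function(table, labels = NULL,
                                   config = screen_config(),
                                   variant = c("selected", "screen"),
                                   mask = NULL) {
  variant <- match.arg(variant)
  x <- .table_values(table)
  if (is.null(labels) && inherits(table, "feature_table"))
    labels <- table$morphology
  if (is.null(labels)) stop("labels are required")
  n <- nrow(x)
  shuffle_cols <- function(x)
    apply(x, 2L, function(col) col[sample.int(n)])
  if (variant == "selected") {
    m <- if (is.null(mask)) rep(TRUE, ncol(x)) else .parse_mask(mask, ncol(x))
    .with_seed(config$seed, {
      p <- vapply(seq_len(config$n_shuffles), function(s) {
        xs <- shuffle_cols(x)
        colnames(xs) <- colnames(x)
        grp <- tryCatch(ward_cluster(xs, m, config), error = function(e) NULL)
        if (is.null(grp)) return(NA_real_)
        tryCatch(association_test(grp, labels)$p_value,
                 error = function(e) NA_real_)
      }, 0)
      frac <- mean(p < config$alpha, na.rm = TRUE)
      list(fraction_significant = if (is.nan(frac)) 0 else frac,
           p_values = p, n_shuffles = config$n_shuffles)
    })
  } else {
    .with_seed(config$seed, {
      xs <- shuffle_cols(x)
      colnames(xs) <- colnames(x)
      res <- .screen_masks(xs, labels, config)
      list(n_significant = sum(res$significant, na.rm = TRUE),
           min_p = min(res$p_value, na.rm = TRUE),
           results = res)
    })
  }
}
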
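#' Bundled reference summaries for mouse mPFC Layer 1 interneurons
#'
#' Published summary statistics from a whole-cell characterization of mouse
#' medial-prefrontal-cortex Layer 1 interneurons, bundled so the package's
#' worked examples and the reproduction script can run without any external
#' data. Counts are exact; continuous variables are mean/SEM/n summaries.
#'
#' @return A list:
#' \describe{
#'   \item{firing_by_morphology}{3 x 2 counts, morphology (NGC, eNGC,
#'     SBC-like) by firing pattern (LS, NLS), for the 33 morphologically
#'     registered cells.}
#'   \item{group_by_morphology}{3 x 3 counts, electrophysiological cluster
#'     (Groups 1-3 from the nine-feature Ward clustering) by morphology.}
#'   \item{morphology_counts}{Counts of the 39 reconstructed cells per
#'     morphological type.}
#'   \item{axonal_extent}{Per-morphology mean/SEM/n of tangential extent,
#'     vertical extent and soma depth (um).}
#'   \item{intrinsic_by_subtype}{mean and sem: 3 x 12 matrices (subtypes x
#'     canonical features); n: per-subtype cell counts.}
#'   \item{eipsc_amplitude, eipsc_latency}{Per-target-group mean/SEM/n of
#'     light-evoked IPSC amplitude (pA) and latency (ms).}
#'   \item{pharmacology}{Paired mean/SEM/n for the bicuculline block and the
#'     TTX / TTX+4-AP controls.}
#'   \item{connectivity}{Pair counts: electrically coupled and chemically
#'     connected fractions, group-pair proportions, and the reported
#'     coupling-strength and latency summaries.}
#' }
#' @examples
#' ref <- l1in_reference()
#' chi2_independence(ref$firing_by_morphology)
#' @export
l1in_reference <- function() {
  canon <- canonical_features()
  subtypes <- c("NGC", "eNGC", "SBC-like")
  mean_mat <- matrix(c(
    # resting, threshold, peak amp, half-width, latency, slope,
    # AHP amp, AHP dur, Rin, tau, Cap, hump  (one row per subtype)
    -72.6, -32.4, 48.2, 1.2, 1037.4, 125.1, 1.7, 462.1, 372.1, 13.4, 31.0, 0.9,
    -71.4, -34.7, 53.1, 1.2,  734.4, 135.5, 2.4, 527.1, 299.5, 11.7, 26.7, 0.7,
    -68.2, -36.4, 53.2, 1.2,  559.2, 150.1, 2.0, 557.7, 539.2, 18.5, 28.7, 1.3),
    nrow = 3, byrow = TRUE, dimnames = list(subtypes, canon))
  sem_mat <- matrix(c(
    2.1, 1.5, 3.1, 0.1, 166.6, 12.4, 0.3, 101.5,  33.5, 2.1, 3.2, 0.4,
    2.1, 1.1, 2.6, 0.1, 154.5, 12.1, 0.3, 130.1,  23.0, 1.4, 1.3, 0.3,
    1.3, 2.4, 5.2, 0.1, 161.1, 20.0, 0.5, 118.1, 100.3, 3.0, 1.8, 0.5),
    nrow = 3, byrow = TRUE, dimnames = list(subtypes, canon))
  list(
    firing_by_morphology = matrix(
      c(10, 1, 9, 3, 4, 6), nrow = 3, byrow = TRUE,
      dimnames = list(subtypes, c("LS", "NLS"))),
    group_by_morphology = matrix(
      c(1, 0, 4, 7, 4, 3, 3, 8, 3), nrow = 3, byrow = TRUE,
      dimnames = list(paste("Group", 1:3), subtypes)),
    morphology_counts = c(NGC = 16L, eNGC = 11L, "SBC-like" = 12L),
    axonal_extent = list(
      tangential_um = list(mean = c(137.2, 328.4, 202.3),
                           sem = c(10.6, 19.8, 31.5), n = c(16, 11, 12)),
      vertical_um = list(mean = c(118.2, 118.0, 256.9),
                         sem = c(8.2, 7.5, 18.9), n = c(16, 11, 12)),
      soma_depth_um = list(mean = c(89.5, 80.7, 95.1),
                           sem = c(6.4, 6.4, 12.3), n = c(16, 11, 12))),
    intrinsic_by_subtype = list(
      mean = mean_mat, sem = sem_mat,
      n = c(NGC = 11L, eNGC = 12L, "SBC-like" = 10L)),
    eipsc_amplitude = list(
      group = c("L2/3PyN", "L2/3IN", "L5/6PyN", "L5/6IN"),
      mean = c(371.9, 233.5, 551.5, 57.0),
      sem = c(72.3, 60.3, 124.1, 13.2),
      n = c(14, 18, 12, 6)),
    eipsc_latency = list(
      group = c("L2/3PyN", "L2/3IN", "L5/6PyN", "L5/6IN"),
      mean = c(4.0, 4.0, 3.6, 5.1),
      sem = c(0.5, 0.2, 0.3, 0.3),
      n = c(12, 17, 12, 6)),
    pharmacology = list(
      bmi = list(before = c(mean = 150.5, sem = 29.3),
                 after = c(mean = 7.5, sem = 0.7), n = 10),
      ttx = list(before = c(mean = 344.3, sem = 46.9),
                 ttx = c(mean = 23.3, sem = 1.6),
                 ttx_4ap = c(mean = 360.9, sem = 52.2), n = 5)),
    connectivity = list(
      electrical_pairs = c(connected = 6L, tested = 41L),
      chemical_pairs = c(connected = 7L, tested = 26L,
                         bidirectional = 2L, unidirectional = 5L),
      group2_group3_chemical = c(connected = 5L, tested = 7L),
      group3_intra_chemical = c(connected = 2L, tested = 3L),
      group2_intra_electrical = c(connected = 3L, tested = 6L),
      coupling_strength = c(mean = 0.05, sem = 0.01),
      latency_ms = list(
        chemical = c(mean = 2.6, sem = 0.2, n = 7),
        electrical = c(mean = 0.8, sem = 0.2, n = 6))))
}
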
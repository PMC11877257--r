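test_that("ward clustering recovers planted blobs and canonicalizes labels", {
  tab <- sample_feature_table(planted_cluster_spec(separation = 6, n_informative = 12, seed = 2))
  grp <- ward_cluster(tab, config = screen_config())
  truth <- as.integer(factor(tab$morphology,
                             levels = c("NGC", "eNGC", "SBC-like")))
  # perfect recovery up to relabelling
  expect_equal(length(unique(paste(grp, truth))), 3L)
  # permutation equivariance: shuffling cells permutes assignments identically
  set.seed(9); perm <- sample(nrow(tab$values))
  grp_perm <- ward_cluster(tab$values[perm, ], config = screen_config())
  expect_identical(grp_perm, grp[perm])
  # affine rescaling of a feature is absorbed by standardization
  v2 <- tab$values; v2[, 3] <- v2[, 3] * 1000 + 5
  expect_identical(ward_cluster(v2, config = screen_config()), grp)
})

test_that("ward clustering degenerate cases", {
  x <- matrix(rnorm(20), 5, 4)
  expect_equal(sort(ward_cluster(x, config = screen_config(n_clusters = 5))),
               1:5)                           # singletons
  x2 <- rbind(x, x[1, ])                      # duplicate rows share a group
  g <- ward_cluster(x2, config = screen_config(n_clusters = 3))
  expect_equal(g[1], g[6])
  xc <- x; xc[, 2] <- 7
  expect_error(ward_cluster(xc, config = screen_config()), "constant")
})

test_that("association test matches reported statistics and is label-invariant", {
  grp <- rep(1:3, c(5, 14, 14))
  lab <- c("SBC-like", "NGC", rep("SBC-like", 3),                  # group 1
           rep("NGC", 7), rep("eNGC", 4), rep("SBC-like", 3),      # group 2
           rep("NGC", 3), rep("eNGC", 8), rep("SBC-like", 3))      # group 3
  res <- association_test(grp, lab)
  expect_equal(res$chi2, 10.55, tolerance = 1e-3)
  expect_equal(res$df, 4L)
  # invariant to relabelling the groups
  res2 <- association_test(c(3, 1, 2)[grp], lab)
  expect_equal(res2$chi2, res$chi2)
  expect_error(association_test(rep(1, 10), lab[1:10]), "degenerate")
  expect_error(association_test(grp, rep("NGC", length(grp))), "degenerate")
})

test_that("subset screen enumerates 2^k - 1 sorted subsets", {
  tab <- toy_table(n_per = 8)
  for (k in c(1L, 3L, 5L)) {
    scr <- subset_screen(tab$values[, seq_len(k), drop = FALSE],
                         labels = tab$morphology,
                         config = screen_config(n_clusters = 2))
    expect_equal(nrow(scr$results), 2^k - 1L)
    ints <- strtoi(scr$results$mask, base = 2L)
    expect_identical(ints, seq_len(2^k - 1L))    # ascending mask order
    expect_equal(unique(nchar(scr$results$mask)), k)
  }
})

test_that("null labels give roughly alpha significant subsets on disjoint blocks", {
  set.seed(21)
  vals <- matrix(rnorm(60 * 12), 60, 12,
                 dimnames = list(NULL, canonical_features()))
  labs <- sample(rep(c("NGC", "eNGC", "SBC-like"), each = 20))
  # disjoint 3-feature blocks -> 4 independent 7-subset screens
  sig <- unlist(lapply(0:3, function(b) {
    scr <- subset_screen(vals[, b * 3 + 1:3], labels = labs,
                         config = screen_config())
    scr$results$significant
  }))
  expect_lt(mean(sig), 0.2)   # compatible with the 5% nominal level
})

test_that("weight_and_select applies the frequency weighting and coverage rule", {
  # hand-built screen: 3 features, significant masks {100, 110}
  res <- data.frame(mask = c("001", "010", "011", "100", "101", "110", "111"),
                    size = c(1L, 1L, 2L, 1L, 2L, 2L, 3L),
                    chi2 = 1, df = 1L,
                    p_value = c(.5, .5, .5, .01, .5, .04, .5),
                    significant = c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE,
                                    FALSE),
                    note = "")
  tab <- toy_table(n_per = 8)
  scr <- structure(list(results = res,
                        config = screen_config(target_subset_size = 1,
                                               n_clusters = 2),
                        values = tab$values[, 1:3], labels = tab$morphology),
                   class = "l1_screen")
  sel <- weight_and_select(scr)
  expect_equal(unname(sel$weights), c(2L, 1L, 0L))
  expect_identical(sel$mask, "100")
  expect_equal(sel$coverage_count, 1L)       # "100" covers itself, not "110"
  expect_equal(sel$coverage_fraction, 0.5)
  # single significant mask: selection of that size equals it, coverage 1
  res2 <- res; res2$significant <- res2$mask == "110"
  scr2 <- scr; scr2$results <- res2
  scr2$config <- screen_config(target_subset_size = 2, n_clusters = 2)
  sel2 <- weight_and_select(scr2)
  expect_identical(sel2$mask, "110")
  expect_equal(sel2$coverage_count, 1L)
  # all masks significant: top-k subset covers 2^k - 1 of them
  res3 <- res; res3$significant <- TRUE
  scr3 <- scr; scr3$results <- res3
  scr3$config <- screen_config(target_subset_size = 2, n_clusters = 2)
  expect_equal(weight_and_select(scr3)$coverage_count, 2^2 - 1L)
  res4 <- res; res4$significant <- FALSE
  scr4 <- scr; scr4$results <- res4
  expect_error(weight_and_select(scr4), "no significant")
})

test_that("screen on planted structure selects the informative features", {
  tab <- sample_feature_table(planted_cluster_spec(seed = 7))
  scr <- subset_screen(tab)
  expect_equal(nrow(scr$results), 4095L)
  sel <- weight_and_select(scr)
  informative <- seq_len(4)
  picked <- which(strsplit(sel$mask, "")[[1]] == "1")
  expect_gte(length(intersect(picked, informative)), 3L)
  expect_lt(sel$selected_p, 0.05)
})

test_that("permutation validation is seeded and degenerate-safe", {
  tab <- toy_table(n_per = 6)
  cfg <- screen_config(seed = 3, n_shuffles = 25, n_clusters = 2)
  a <- permutation_validation(tab, config = cfg, mask = "110000000000")
  b <- permutation_validation(tab, config = cfg, mask = "110000000000")
  expect_identical(a$p_values, b$p_values)
  expect_equal(length(a$p_values), 25L)
  # constant labels can never be significant
  const <- feature_table(tab$values, morphology = rep("NGC", nrow(tab$values)))
  pc <- permutation_validation(const, config = cfg, mask = "110000000000")
  expect_equal(pc$fraction_significant, 0)
  # screen variant returns a full 2^k - 1 result set
  sc <- permutation_validation(tab$values[, 1:4], labels = tab$morphology,
                               config = screen_config(seed = 5, n_clusters = 2),
                               variant = "screen")
  expect_equal(nrow(sc$results), 15L)
})

test_that("screen object methods print and summarise", {
  tab <- sample_feature_table(planted_cluster_spec(seed = 3))
  scr <- subset_screen(tab)
  expect_output(print(scr), "4095 subsets")
  expect_output(print(summary(scr)), "Selected subset")
  w <- feature_weights(scr)
  expect_identical(names(w), canonical_features())
})
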
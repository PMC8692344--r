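small_cohort_data <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- cohort_spec(insomnia_profiles(60), n_per_profile = 2,
                          night_duration = 60, seed = 31)
      coh <- simulate_cohort(spec)
      cache <<- somnotype:::process_cohort(coh, pipeline_config())
    }
    cache
  }
})

test_that("feature matrix has the 33 documented variables and no gaps", {
  d <- small_cohort_data()
  fm <- build_feature_matrix(d$metrics, d$power)
  expect_equal(dim(fm), c(6, 33))
  expect_identical(colnames(fm), feature_names())
  expect_false(anyNA(fm))
  # identical inputs give identical rows
  m2 <- d$metrics[c(1, 1)]; p2 <- d$power[c(1, 1)]
  names(m2) <- names(p2) <- c("a", "b")
  fm2 <- build_feature_matrix(m2, p2, impute = FALSE)
  expect_equal(unname(fm2["a", ]), unname(fm2["b", ]))
})

test_that("z-scoring normalizes columns, is idempotent, rejects constants", {
  X <- random_features(40, 33, seed = 2)
  z <- zscore_features(X)
  expect_lt(max(abs(colMeans(z))), 1e-9)
  expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-9)
  expect_lt(max(abs(zscore_features(z) - z)), 1e-9)
  Xc <- X; Xc[, 3] <- 5
  expect_error(zscore_features(Xc), colnames(X)[3])
})

test_that("PCA satisfies the trace identity and recovers low-rank structure", {
  z <- zscore_features(random_features(40, 33, seed = 3))
  proj <- run_pca(z, n_components = 10)
  expect_equal(sum(proj$eigenvalues), 33, tolerance = 1e-9)
  expect_true(all(diff(proj$explained_variance) <= 1e-12))
  expect_lt(max(abs(colMeans(proj$scores))), 1e-9)
  expect_error(run_pca(z, n_components = 34), "n_components")
  # rank-2 fixture
  set.seed(4)
  B <- matrix(rnorm(40 * 2), 40, 2) %*% matrix(rnorm(2 * 33), 2, 33)
  rownames(B) <- sprintf("s%02d", 1:40)
  zB <- zscore_features(B + matrix(rnorm(40 * 33, sd = 1e-6), 40, 33))
  pB <- run_pca(zB, 5)
  expect_gte(sum(pB$explained_variance[1:2]), 0.999)
})

test_that("Ward clustering matches the exhaustive-search oracle (n <= 8)", {
  set.seed(11)
  for (r in 1:50) {
    n <- sample(4:8, 1)
    X <- matrix(rnorm(n * 3), n, 3, dimnames = list(paste0("s", 1:n), NULL))
    hc <- ward_cluster(X)
    bf <- bf_ward(X)
    expect_equal(sort(hc$height), sort(bf$heights), tolerance = 1e-8)
    for (s in seq_len(n - 1)) {
      hp <- unname(split(seq_len(n), cutree(hc, k = n - s)))
      expect_identical(canonical_partition(hp),
                       canonical_partition(bf$partitions[[s]]))
    }
  }
})

test_that("Ward dendrograms have n-1 monotone merges and separate far clouds", {
  X <- rbind(matrix(rnorm(20 * 2), 20, 2), matrix(rnorm(20 * 2, mean = 10), 20, 2))
  rownames(X) <- paste0("s", 1:40)
  hc <- ward_cluster(X)
  expect_length(hc$height, 39)
  expect_true(all(diff(hc$height) >= -1e-9))
  expect_gte(max(hc$height), 10 * sort(hc$height, decreasing = TRUE)[2])
})

test_that("permutation selection finds planted clusters and respects contracts", {
  set.seed(21)
  X <- rbind(matrix(rnorm(20 * 33), 20, 33),
             matrix(rnorm(20 * 33), 20, 33) + rep(c(rep(6, 5), rep(0, 28)), each = 20),
             matrix(rnorm(20 * 33), 20, 33) + rep(c(rep(0, 28), rep(6, 5)), each = 20))
  rownames(X) <- sprintf("s%02d", 1:60)
  colnames(X) <- paste0("f", 1:33)
  proj3 <- run_pca(zscore_features(X), 10)
  sel <- permutation_select_k(proj3, n_permutations = 100, seed = 5)
  expect_equal(sel$k_opt, 3L)
  expect_true(all(sel$pvalues > 0 & sel$pvalues <= 1))
  expect_true(all(sel$pvalues_adjusted >= sel$pvalues - 1e-12))
  expect_error(permutation_select_k(X, n_permutations = 50), "100")
  expect_error(permutation_select_k(X[1:8, ], n_permutations = 100, k_max = 10),
               "k_max")
  # determinism
  sel2 <- permutation_select_k(proj3, n_permutations = 100, seed = 5)
  expect_identical(sel$pvalues, sel2$pvalues)
})

test_that("subject input order does not change the discovered partition", {
  set.seed(22)
  X <- rbind(matrix(rnorm(15 * 5), 15, 5), matrix(rnorm(15 * 5, 8), 15, 5))
  rownames(X) <- sprintf("s%02d", 1:30)
  perm <- sample(30)
  a1 <- assign_subtypes(ward_cluster(X), 2)
  a2 <- assign_subtypes(ward_cluster(X[perm, ]), 2)
  expect_equal(ari(a1[rownames(X)], a2[rownames(X)]), 1)
})

test_that("subtype assignment produces stable size-ordered labels", {
  set.seed(23)
  X <- rbind(matrix(rnorm(12 * 3), 12, 3), matrix(rnorm(5 * 3, 9), 5, 3))
  rownames(X) <- sprintf("s%02d", 1:17)
  hc <- ward_cluster(X)
  expect_equal(unname(assign_subtypes(hc, 1)), rep(1L, 17))
  expect_equal(sort(unname(assign_subtypes(hc, 17))), 1:17)
  a <- assign_subtypes(hc, 2)
  expect_equal(unname(table(a)), c(12L, 5L), ignore_attr = TRUE)
  expect_true(all(a[1:12] == 1L))               # larger cluster gets label 1
})

test_that("subtype characterization reports means, SEMs and paired deltas", {
  X <- random_features(6, 4, seed = 9)
  colnames(X) <- c("tst", "se", "waso", "sol")
  asg <- setNames(c(1L, 1L, 1L, 2L, 2L, 3L), rownames(X))
  reports <- data.frame(subject = rownames(X), subj_tst = c(300, 310, 280, 400, 390, 350),
                        sq = c(6, 5, 7, 4, 5, 5), objective_tst = rep(350, 6))
  night2 <- data.frame(subject = rownames(X), d_se = c(1, 2, 3, -1, 0, 5))
  rep_ <- characterize_subtypes(asg, X, reports, night2)
  s <- rep_$summary
  expect_equal(s$mean[s$subtype == 1 & s$variable == "tst"],
               mean(X[1:3, "tst"]))
  expect_equal(s$sem[s$subtype == 1 & s$variable == "tst"],
               sd(X[1:3, "tst"]) / sqrt(3))
  expect_true(is.na(s$sem[s$subtype == 3 & s$variable == "tst"]))  # singleton
  expect_equal(s$mean[s$subtype == 1 & s$variable == "ssm"],
               mean((350 - c(300, 310, 280)) / 350))
  d <- rep_$night2_deltas
  expect_equal(d$mean[d$subtype == 1 & d$variable == "d_se"], 2)
})
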
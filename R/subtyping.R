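# Subtype discovery: 33-variable feature matrix -> z-scores -> PCA ->
# Ward (Euclidean) agglomerative clustering -> permutation test for the
# number of clusters -> stable subtype assignment and descriptive report.

#' Names of the default 33 clustering variables
#'
#' Nine macrostructure variables (TIB, TST, SE, SOL, WASO, REM latency and
#' three arousal indices), eight stage variables (minutes and percent of
#' TST for N1/N2/N3/REM), twelve absolute delta-power variables
#' (global/left/right x N2/N3/NREM/REM) and four asymmetry indices
#' (wake, NREM, REM, all-night).
#'
#' @return Character vector of length 33 (fixed column order).
#' @export
feature_names <- function() {
  c("tib", "tst", "se", "sol", "waso", "rem_latency",
    "arousal_index_total", "arousal_index_nrem", "arousal_index_rem",
    "n1_min", "n2_min", "n3_min", "rem_min",
    "n1_pct", "n2_pct", "n3_pct", "rem_pct",
    paste0("delta_", rep(c("global", "left", "right"), each = 4), "_",
           rep(c("n2", "n3", "nrem", "rem"), 3)),
    "iai_w", "iai_nrem", "iai_rem", "iai_all")
}

power_cell <- function(power, stage, scope, band = "delta") {
  v <- power$power[power$stage == stage & power$scope == scope &
                     power$band == band]
  if (length(v) == 0) NA_real_ else v[1]
}

# 33-entry feature vector for one subject.
subject_features <- function(metrics, power) {
  iai <- iai_table(power, c("W", "NREM", "R", "ALL"))
  stage_map <- c(n2 = "N2", n3 = "N3", nrem = "NREM", rem = "R")
  delta <- unlist(lapply(c("global", "left", "right"), function(sc)
    vapply(stage_map, function(st) power_cell(power, st, sc), 0)))
  v <- c(metrics$tib, metrics$tst, metrics$se, metrics$sol, metrics$waso,
         metrics$rem_latency, metrics$arousal_index_total,
         metrics$arousal_index_nrem, metrics$arousal_index_rem,
         metrics$n1_min, metrics$n2_min, metrics$n3_min, metrics$rem_min,
         metrics$n1_pct, metrics$n2_pct, metrics$n3_pct, metrics$rem_pct,
         delta,
         iai$iai[iai$stage == "W"], iai$iai[iai$stage == "NREM"],
         iai$iai[iai$stage == "R"], iai$iai[iai$stage == "ALL"])
  stats::setNames(as.numeric(v), feature_names())
}

#' Build the subjects x 33 clustering feature matrix
#'
#' Combines per-subject macroarchitecture metrics and stage band-power
#' tables into the default 33-variable matrix. Subjects missing more than
#' 25% of features are excluded (with a message); remaining missing cells
#' (e.g. REM-dependent variables on a night without REM) are imputed with
#' the cohort median of the feature when `impute = TRUE`.
#'
#' @param metrics Named list (by subject id) of one-row metric frames from
#'   [compute_sleep_metrics()].
#' @param power Named list (same ids) of `stage_band_power` tables.
#' @param impute Impute remaining missing cells with cohort medians
#'   (default `TRUE`).
#' @return Numeric matrix of class `feature_matrix`, subjects x 33, with
#'   subject ids as row names and attribute `imputed` counting filled cells.
#' @export
build_feature_matrix <- function(metrics, power, impute = TRUE) {
  ids <- names(metrics)
  stopifnot(!is.null(ids), setequal(ids, names(power)))
  m <- t(vapply(ids, function(id) subject_features(metrics[[id]], power[[id]]),
                numeric(33)))
  rownames(m) <- ids
  frac_na <- rowMeans(is.na(m))
  drop <- frac_na > 0.25
  if (any(drop)) {
    message("excluding ", sum(drop), " subject(s) missing >25% of features: ",
            paste(ids[drop], collapse = ", "))
    m <- m[!drop, , drop = FALSE]
  }
  n_imp <- 0L
  if (impute && anyNA(m)) {
    for (j in seq_len(ncol(m))) {
      nas <- is.na(m[, j])
      if (any(nas)) {
        m[nas, j] <- stats::median(m[, j], na.rm = TRUE)
        n_imp <- n_imp + sum(nas)
      }
    }
  }
  structure(m, class = c("feature_matrix", class(m)), imputed = n_imp,
            zscored = FALSE)
}

#' Column-wise z-scoring of a feature matrix
#'
#' `(x - mean) / sd` per column (sd with `n - 1` denominator), so every
#' column of the result has mean 0 and unit variance. Idempotent up to
#' numerical noise.
#'
#' @param fm Numeric matrix (subjects x features).
#' @return Matrix of the same shape with attribute `zscored = TRUE`.
#' @export
zscore_features <- function(fm) {
  if (nrow(fm) < 2) stop("z-scoring needs at least 2 subjects", call. = FALSE)
  sds <- apply(fm, 2, stats::sd)
  zero <- which(sds == 0 | !is.finite(sds))
  if (length(zero)) {
    stop("zero-variance feature(s): ", paste(colnames(fm)[zero], collapse = ", "),
         call. = FALSE)
  }
  z <- scale(fm)
  out <- z[, , drop = FALSE]
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  structure(out, class = c("feature_matrix", "matrix", "array"), zscored = TRUE)
}

#' Principal component analysis of the z-scored feature matrix
#'
#' Eigendecomposition of the feature covariance ([stats::prcomp()]); the
#' retained component scores are the coordinates used for clustering.
#'
#' @param fm Z-scored feature matrix from [zscore_features()].
#' @param n_components Number of retained components (default 10).
#' @return Object of class `pc_projection`: list with `scores`
#'   (subjects x components), `eigenvalues` (all), `explained_variance`
#'   (all, proportions, non-increasing), `rotation`, `n_components`.
#' @export
run_pca <- function(fm, n_components = 10) {
  if (!isTRUE(attr(fm, "zscored"))) {
    warning("feature matrix does not appear to be z-scored")
  }
  p_max <- min(nrow(fm) - 1L, ncol(fm))
  if (n_components > p_max) {
    stop("n_components (", n_components, ") exceeds min(subjects - 1, features) = ",
         p_max, call. = FALSE)
  }
  pc <- stats::prcomp(fm, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  structure(
    list(scores = pc$x[, seq_len(n_components), drop = FALSE],
         eigenvalues = ev, explained_variance = ev / sum(ev),
         rotation = pc$rotation, n_components = n_components),
    class = "pc_projection"
  )
}

#' @export
print.pc_projection <- function(x, ...) {
  cum <- sum(x$explained_variance[seq_len(x$n_components)])
  cat(sprintf("<pc_projection> %d subjects, %d components (%.1f%% of variance)\n",
              nrow(x$scores), x$n_components, 100 * cum))
  invisible(x)
}

scores_of <- function(x) {
  if (inherits(x, "pc_projection")) x$scores else as.matrix(x)
}

#' Ward agglomerative clustering
#'
#' Hierarchical agglomeration on Euclidean distances with Ward's minimum
#' variance criterion: each merge is the pair of clusters whose fusion
#' minimally increases the total within-cluster sum of squares
#' ([stats::hclust()] method `"ward.D2"`; heights are reported on the
#' distance scale, `sqrt(2 * delta SS)`, and are monotone non-decreasing).
#'
#' @param proj A `pc_projection` from [run_pca()], or a numeric matrix of
#'   coordinates (subjects x dimensions).
#' @return An object of class `c("ward_dendrogram", "hclust")`.
#' @export
ward_cluster <- function(proj) {
  X <- scores_of(proj)
  if (nrow(X) < 2) stop("clustering needs at least 2 subjects", call. = FALSE)
  hc <- stats::hclust(stats::dist(X), method = "ward.D2")
  hc$labels <- rownames(X)
  class(hc) <- c("ward_dendrogram", "hclust")
  hc
}

# Separation statistic of cutting level k: the dendrogram height of the
# merge that fuses k clusters into k - 1 (equivalently, the height at which
# the tree last shows k clusters). heights must be the full sorted merge
# heights of n - 1 merges.
cut_level_statistic <- function(heights, k) {
  n <- length(heights) + 1L
  sort(heights)[n - k + 1L]
}

#' Permutation test for the number of clusters
#'
#' Each replicate independently permutes every component column across
#' subjects (destroying joint structure while preserving marginals) and
#' re-runs Ward clustering. For each cutting level `k = 2..k_max` the
#' observed separation statistic -- the dendrogram height of the merge that
#' reduces `k` clusters to `k - 1` -- is compared one-sidedly to its
#' permutation distribution, with add-one smoothing:
#' `p_k = (1 + #\{replicates >= observed\}) / (1 + n_permutations)`.
#'
#' Because `k_max - 1` cutting levels are examined, selection uses
#' family-wise calibrated (Westfall-Young max-T) p-values: each level's
#' statistic is standardized by its permutation mean and SD, and the
#' adjusted `p_k` compares the observed standardized statistic to the
#' permutation distribution of the maximum standardized statistic across
#' levels. Under structureless data the probability that any level reaches
#' `p < alpha` is then close to `alpha` itself. The optimal number of
#' clusters is the first cutting level (ascending `k` from 2) whose
#' adjusted probability is below `alpha`; if no level qualifies,
#' `k_opt = 1`.
#'
#' @param proj A `pc_projection` (or score matrix).
#' @param n_permutations Number of permutation replicates (>= 100;
#'   default 500).
#' @param alpha Significance level (default 0.05).
#' @param k_max Deepest cutting level examined (default 10; must be < n).
#' @param seed Integer seed for the permutations.
#' @return Object of class `cluster_selection`: list with `k_opt`,
#'   `pvalues` (raw per-level, named, k = 2..k_max), `pvalues_adjusted`
#'   (family-wise, used for selection), `statistics` (observed heights),
#'   `n_permutations`, `alpha`, `dendrogram` (the observed tree).
#' @export
permutation_select_k <- function(proj, n_permutations = 500, alpha = 0.05,
                                 k_max = 10, seed = 1) {
  X <- scores_of(proj)
  n <- nrow(X)
  if (k_max >= n) stop("k_max must be smaller than the number of subjects",
                       call. = FALSE)
  if (n_permutations < 100) stop("n_permutations must be >= 100", call. = FALSE)
  hc <- ward_cluster(X)
  ks <- 2:k_max
  obs <- vapply(ks, function(k) cut_level_statistic(hc$height, k), 0)
  set.seed(seed)
  perm <- matrix(0, n_permutations, length(ks))
  for (b in seq_len(n_permutations)) {
    Xp <- apply(X, 2, sample)
    hp <- stats::hclust(stats::dist(Xp), method = "ward.D2")
    perm[b, ] <- vapply(ks, function(k) cut_level_statistic(hp$height, k), 0)
  }
  pvals <- vapply(seq_along(ks), function(j) {
    (1 + sum(perm[, j] >= obs[j])) / (1 + n_permutations)
  }, 0)
  mu <- colMeans(perm)
  sdv <- apply(perm, 2, stats::sd)
  sdv[sdv == 0] <- 1
  z_obs <- (obs - mu) / sdv
  max_z <- apply(sweep(sweep(perm, 2, mu), 2, sdv, "/"), 1, max)
  padj <- vapply(z_obs, function(z) (1 + sum(max_z >= z)) / (1 + n_permutations), 0)
  names(pvals) <- names(padj) <- ks
  sig <- padj < alpha
  k_opt <- if (any(sig)) ks[which(sig)[1]] else 1L
  structure(
    list(k_opt = as.integer(k_opt), pvalues = pvals, pvalues_adjusted = padj,
         statistics = stats::setNames(obs, ks),
         n_permutations = n_permutations, alpha = alpha, dendrogram = hc),
    class = "cluster_selection"
  )
}

#' @export
print.cluster_selection <- function(x, ...) {
  cat(sprintf("<cluster_selection> k_opt = %d (alpha = %g, %d permutations)\n",
              x$k_opt, x$alpha, x$n_permutations))
  print(round(rbind(raw = x$pvalues, adjusted = x$pvalues_adjusted), 4))
  invisible(x)
}

#' Cut the dendrogram into subtypes with stable labels
#'
#' Cuts the Ward tree at `k` clusters and relabels them 1..k by descending
#' cluster size, ties broken by the lowest contained subject index, so
#' labels do not depend on merge order.
#'
#' @param dendrogram A `ward_dendrogram` from [ward_cluster()].
#' @param k Number of clusters (1 <= k <= n).
#' @return Integer vector of cluster labels named by subject id.
#' @export
assign_subtypes <- function(dendrogram, k) {
  n <- length(dendrogram$height) + 1L
  if (k < 1 || k > n) stop("k must be in 1..n", call. = FALSE)
  raw <- stats::cutree(dendrogram, k = k)
  sizes <- table(raw)
  first_idx <- vapply(names(sizes), function(l) min(which(raw == as.integer(l))), 0)
  ord <- order(-as.integer(sizes), first_idx)
  relabel <- stats::setNames(seq_along(ord), names(sizes)[ord])
  out <- as.integer(relabel[as.character(raw)])
  names(out) <- names(raw)
  out
}

sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

#' Descriptive characterization of subtypes
#'
#' Per-subtype mean and standard error of every feature, plus subjective
#' sleep quality and the sleep-state misperception index when reports are
#' supplied, and paired night-1 vs night-2 deltas when a restricted-night
#' table is supplied. Purely descriptive; no inferential statistics.
#'
#' @param assignments Named integer vector from [assign_subtypes()].
#' @param features Feature matrix (raw scale) with matching row names.
#' @param reports Optional data.frame with columns `subject`, `subj_tst`,
#'   `sq`, and `objective_tst`.
#' @param night2 Optional data.frame of paired night-2 minus night-1
#'   differences, columns `subject` plus any numeric delta columns.
#' @return Object of class `subtype_report`: list of data.frames `summary`
#'   (subtype x feature: n, mean, sem) and optionally `night2_deltas`.
#' @export
characterize_subtypes <- function(assignments, features, reports = NULL,
                                  night2 = NULL) {
  ids <- names(assignments)
  features <- features[ids, , drop = FALSE]
  vars <- as.data.frame(unclass(features))
  if (!is.null(reports)) {
    r <- reports[match(ids, reports$subject), ]
    vars$sq <- r$sq
    vars$ssm <- (r$objective_tst - r$subj_tst) / r$objective_tst
  }
  per_cluster <- function(df, cl) {
    do.call(rbind, lapply(sort(unique(cl)), function(g) {
      sub <- df[cl == g, , drop = FALSE]
      do.call(rbind, lapply(names(sub), function(v) {
        data.frame(subtype = g, variable = v, n = sum(!is.na(sub[[v]])),
                   mean = mean(sub[[v]], na.rm = TRUE), sem = sem(sub[[v]]))
      }))
    }))
  }
  out <- list(summary = per_cluster(vars, assignments))
  if (!is.null(night2)) {
    d <- night2[match(ids, night2$subject), setdiff(names(night2), "subject"),
                drop = FALSE]
    out$night2_deltas <- per_cluster(d, assignments)
  }
  structure(out, class = "subtype_report")
}

#' @export
print.subtype_report <- function(x, ...) {
  s <- x$summary
  for (g in unique(s$subtype)) {
    n <- s$n[s$subtype == g][1]
    cat(sprintf("Subtype %d (n = %d)\n", g, n))
    key <- s[s$subtype == g & s$variable %in%
               c("tst", "se", "waso", "delta_global_nrem", "ssm", "sq"), ]
    for (i in seq_len(nrow(key))) {
      cat(sprintf("  %-18s %8.3f +/- %s\n", key$variable[i], key$mean[i],
                  ifelse(is.na(key$sem[i]), "NA", sprintf("%.3f", key$sem[i]))))
    }
  }
  if (!is.null(x$night2_deltas)) cat("(night-2 minus night-1 deltas available)\n")
  invisible(x)
}
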
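# Comparative analyses over the survey's method combinations: significance
# scans of mean graph properties between conditions, subject-rank
# dendrograms, pairwise SVM classification and the surprise-vs-SVM relation.

#' Two-sample mean-difference test with variance pre-test
#'
#' A two-sided F-test at `alpha` decides between Student's (equal
#' variances) and Welch's (unequal) two-sided t-test; the direction is the
#' sign of mean(x) - mean(y). Two degenerate equal samples give p = 1.
#'
#' @param x,y numeric samples with >= 2 values each.
#' @param alpha level of the variance pre-test.
#' @return list with `p_value`, `direction` ("<" when mean(x) < mean(y)),
#'   and `test_used` ("student" or "welch").
#' @export
mean_difference_test <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  direction <- if (mean(x) < mean(y)) "<" else ">"
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    p <- if (mean(x) == mean(y)) 1 else 0
    return(list(p_value = p, direction = direction, test_used = "student"))
  }
  equal_var <- if (stats::var(x) == 0 || stats::var(y) == 0) FALSE else {
    stats::var.test(x, y)$p.value >= alpha
  }
  tt <- stats::t.test(x, y, var.equal = equal_var)
  list(p_value = tt$p.value, direction = direction,
       test_used = if (equal_var) "student" else "welch")
}

#' Fraction of significant between-condition differences across variants
#'
#' For each clustering family x edge family x property x condition pair x
#' direction, the fraction of method variants (parameter settings x
#' thresholds x subgraphs) whose between-condition mean test is significant
#' (p < `alpha`) in that direction. Variants absent from the table (e.g.,
#' skipped because their graphs disconnected) are simply not counted.
#'
#' @param tbl data.frame with columns `subject_id`, `condition`,
#'   `clustering_family`, `edge_family`, `variant`, `property`, `value`.
#' @param pairs list of 2-vectors of condition labels to compare.
#' @param alpha significance level.
#' @return data.frame with one row per family pair / property / condition
#'   pair / direction: columns `n_variants`, `n_significant`, `fraction`.
#' @export
significance_scan <- function(tbl,
                              pairs = list(c("C", "MCI"), c("C", "AD"),
                                           c("MCI", "AD")),
                              alpha = 0.05) {
  needed <- c("subject_id", "condition", "clustering_family", "edge_family",
              "variant", "property", "value")
  stopifnot(all(needed %in% names(tbl)))
  out <- list()
  groups <- unique(tbl[, c("clustering_family", "edge_family", "property")])
  for (gi in seq_len(nrow(groups))) {
    g <- groups[gi, ]
    sub <- tbl[tbl$clustering_family == g$clustering_family &
                 tbl$edge_family == g$edge_family &
                 tbl$property == g$property, ]
    variants <- unique(sub$variant)
    for (pair in pairs) {
      res <- lapply(variants, function(v) {
        vs <- sub[sub$variant == v, ]
        x <- vs$value[vs$condition == pair[1L]]
        y <- vs$value[vs$condition == pair[2L]]
        if (length(x) < 2L || length(y) < 2L) return(NULL)
        mean_difference_test(x, y)
      })
      res <- res[!vapply(res, is.null, logical(1))]
      if (length(res) == 0L) next
      for (dir in c("<", ">")) {
        hits <- vapply(res, function(r) {
          r$p_value < alpha && r$direction == dir
        }, logical(1))
        out[[length(out) + 1L]] <- data.frame(
          clustering_family = g$clustering_family,
          edge_family = g$edge_family, property = g$property,
          pair = paste(pair, collapse = "-"), direction = dir,
          n_variants = length(res), n_significant = sum(hits),
          fraction = mean(hits))
      }
    }
  }
  do.call(rbind, out)
}

#' Subject-rank profiles per method combination
#'
#' Subjects are ranked by ascending per-subject mean of a graph property
#' (ties broken by subject id); one rank vector per method combination.
#' Combinations missing any subject are dropped with a message.
#'
#' @param tbl data.frame with columns `subject_id`, `variant`, `value`
#'   (one row per subject x combination).
#' @return matrix of ranks, one row per combination (rownames = variants),
#'   columns ordered by subject id.
#' @export
rank_profiles <- function(tbl) {
  stopifnot(all(c("subject_id", "variant", "value") %in% names(tbl)))
  subjects <- sort(unique(tbl$subject_id))
  variants <- unique(tbl$variant)
  rows <- list()
  for (v in variants) {
    sub <- tbl[tbl$variant == v, ]
    if (!setequal(sub$subject_id, subjects) ||
        nrow(sub) != length(subjects)) {
      message("rank_profiles: dropping incomplete combination ", v)
      next
    }
    sub <- sub[match(subjects, sub$subject_id), ]
    rows[[v]] <- rank(sub$value, ties.method = "first")
  }
  if (length(rows) == 0L) stop("no complete combination to rank")
  profiles <- do.call(rbind, rows)
  colnames(profiles) <- subjects
  profiles
}

#' Agglomerative linkage over rank-profile distances
#'
#' Euclidean distances between rank vectors, clustered by average linkage
#' (UPGMA).
#'
#' @param profiles rank matrix from [rank_profiles()].
#' @return an `hclust` tree (heights = linkage distances).
#' @export
rank_distance_linkage <- function(profiles) {
  stopifnot(is.matrix(profiles), nrow(profiles) >= 2L)
  stats::hclust(stats::dist(profiles, method = "euclidean"),
                method = "average")
}

#' Newick string of a linkage tree
#'
#' @param hc an `hclust` object.
#' @return single Newick string.
#' @export
linkage_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}

svm_loo_accuracy <- function(x, y) {
  n <- nrow(x)
  pred <- vapply(seq_len(n), function(i) {
    fit <- e1071::svm(x[-i, , drop = FALSE], y[-i], kernel = "radial",
                      scale = FALSE)
    as.character(stats::predict(fit, x[i, , drop = FALSE]))
  }, character(1))
  mean(pred == as.character(y))
}

#' Pairwise SVM classification with leave-one-out evaluation
#'
#' Radial-basis support vector classification with default parameters on
#' two conditions' feature vectors, scored by leave-one-out accuracy.
#' Features are chosen by greedy forward selection maximizing the LOO
#' accuracy (ties keep the smaller feature set, so redundant duplicate
#' columns change nothing).
#'
#' @param features matrix (subjects x d).
#' @param labels condition label per row (2 distinct values, >= 2 each).
#' @param max_features cap on the number of selected features.
#' @return list with `accuracy`, `selected` (feature column indices), and
#'   `accuracy_all` (accuracy with every feature, for reference).
#' @export
svm_pairwise_loo <- function(features, labels,
                             max_features = ncol(features)) {
  labels <- factor(labels)
  stopifnot(nlevels(labels) == 2L, all(table(labels) >= 2L),
            nrow(features) == length(labels))
  selected <- integer(0)
  best_acc <- 0
  repeat {
    remaining <- setdiff(seq_len(ncol(features)), selected)
    if (length(remaining) == 0L || length(selected) >= max_features) break
    accs <- vapply(remaining, function(j) {
      svm_loo_accuracy(features[, c(selected, j), drop = FALSE], labels)
    }, numeric(1))
    if (max(accs) <= best_acc) break   # strict improvement required
    j <- remaining[which.max(accs)]
    selected <- c(selected, j)
    best_acc <- max(accs)
  }
  list(accuracy = best_acc, selected = selected,
       accuracy_all = svm_loo_accuracy(features, labels))
}

#' Correlation between negative surprise and SVM accuracy
#'
#' Pearson correlation and least-squares line over method combinations,
#' excluding the families in `exclude` (reported separately).
#'
#' @param surprise per-combination mean negative surprise.
#' @param accuracy per-combination SVM accuracy.
#' @param family edge family per combination.
#' @param exclude families left out of the fit.
#' @return list with `r`, `slope`, `intercept`, `included` (logical mask).
#' @export
surprise_vs_svm <- function(surprise, accuracy, family,
                            exclude = "TE") {
  stopifnot(length(surprise) == length(accuracy),
            length(family) == length(surprise))
  inc <- !(family %in% exclude)
  if (sum(inc) < 3L) stop("need at least 3 included combinations")
  if (stats::sd(surprise[inc]) == 0 || stats::sd(accuracy[inc]) == 0) {
    stop("zero-variance input: correlation undefined")
  }
  fit <- stats::lm(accuracy[inc] ~ surprise[inc])
  list(r = stats::cor(surprise[inc], accuracy[inc]),
       slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       included = inc)
}
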
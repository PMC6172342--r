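# Functional-connectivity edge estimation: linear correlation, piecewise
# linear (h2) nonlinear correlation, binned mutual information, and binned
# transfer entropy, each with optional sliding windows and delay scans.

#' Edge-estimator specification
#'
#' One of the 16 named estimator variants of the survey: four families
#' (corr, H2, MIT, TE), directed or undirected, full-length window (130) or
#' sliding 50-point windows with 20% (10-point) overlap.
#'
#' @param family one of "corr", "H2", "MIT", "TE".
#' @param directed logical; directed estimators scan delays up to
#'   `max_delay` and keep the largest value.
#' @param window_length window size in time points.
#' @param window_overlap_fraction fractional overlap of consecutive windows.
#' @param max_delay maximum delay (time steps) scanned by directed variants.
#' @param n_bins histogram/bin count (10 for H2, 5 for MIT, 3 for the
#'   coarse-grained TE histogram).
#' @param te_past_samples length of the past blocks used by TE (5 samples =
#'   15 s at TR 3 s).
#' @param name variant name (e.g. "BcorrU1").
#' @return object of class `edge_method_spec`.
#' @export
edge_method_spec <- function(family = c("corr", "H2", "MIT", "TE"),
                             directed = FALSE,
                             window_length = 130L,
                             window_overlap_fraction = 0,
                             max_delay = 5L,
                             n_bins = switch(match.arg(family),
                                             H2 = 10L, MIT = 5L, 3L),
                             te_past_samples = 5L,
                             name = NULL) {
  family <- match.arg(family)
  spec <- structure(list(family = family, directed = directed,
                         window_length = as.integer(window_length),
                         window_overlap_fraction = window_overlap_fraction,
                         max_delay = as.integer(max_delay),
                         n_bins = as.integer(n_bins),
                         te_past_samples = as.integer(te_past_samples),
                         name = name %||% family),
                    class = "edge_method_spec")
  spec
}

#' The 16 edge-estimator presets of the survey
#'
#' @return named list of [edge_method_spec()] objects (BcorrU1 .. BTED2):
#'   each family in undirected/directed form, with full-length (1) and
#'   sliding-window (2) variants.
#' @export
edge_presets <- function() {
  out <- list()
  for (family in c("corr", "H2", "MIT", "TE")) {
    for (directed in c(FALSE, TRUE)) {
      for (win in 1:2) {
        nm <- paste0("B", if (family == "corr") "corr" else family,
                     if (directed) "D" else "U", win)
        out[[nm]] <- edge_method_spec(
          family = family, directed = directed,
          window_length = if (win == 1L) 130L else 50L,
          window_overlap_fraction = if (win == 1L) 0 else 0.2,
          name = nm)
      }
    }
  }
  out
}

#' Sliding-window index ranges
#'
#' Half-open windows of `window_length` points starting at multiples of
#' step = window_length * (1 - overlap_fraction); the last window ends at or
#' before `n_timepoints`. Returned 1-based inclusive.
#'
#' @param n_timepoints series length.
#' @param window_length window size (at most `n_timepoints`).
#' @param overlap_fraction fractional overlap in [0, 1).
#' @return integer matrix with columns `start`, `end` (1-based, inclusive).
#' @export
sliding_windows <- function(n_timepoints, window_length, overlap_fraction) {
  stopifnot(window_length <= n_timepoints, window_length >= 1L)
  step <- as.integer(round(window_length * (1 - overlap_fraction)))
  if (step <= 0L) stop("window step must be positive")
  starts <- seq.int(0L, as.integer(n_timepoints) - as.integer(window_length),
                    by = step)
  cbind(start = as.integer(starts + 1L),
        end = as.integer(starts + window_length))
}

check_pair <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("series must have equal length >= 3")
  }
  if (stats::var(x) <= 0 || stats::var(y) <= 0) {
    stop("degenerate (constant) series")
  }
}

# apply a lag-0 bivariate statistic over source-lagged alignments
# stat(x_t, y_{t+tau}), tau = 0..max_delay, and keep the maximum
max_over_delays <- function(x, y, max_delay, stat) {
  n <- length(x)
  vals <- vapply(0:max_delay, function(tau) {
    stat(x[seq_len(n - tau)], y[seq_len(n - tau) + tau])
  }, numeric(1))
  max(vals)
}

#' Linear correlation edge weight
#'
#' Absolute Pearson correlation; the directed variant scans source lags
#' 0..`max_delay` (x leading y) and keeps the largest value, so directed
#' weights dominate the undirected (lag-0) ones.
#'
#' @param x,y numeric series of equal length >= 3, non-constant.
#' @param directed scan delays?
#' @param max_delay maximum lag scanned when directed.
#' @return weight in [0, 1].
#' @export
edge_corr <- function(x, y, directed = FALSE, max_delay = 5L) {
  check_pair(x, y)
  if (!directed) return(abs(stats::cor(x, y)))
  max_over_delays(x, y, max_delay, function(a, b) abs(stats::cor(a, b)))
}

# piecewise-linear h2: regression curve of y on x through the per-bin mean
# points of n_bins equal-count bins of x, end segments extended linearly
h2_one_direction <- function(x, y, n_bins) {
  n <- length(x)
  nb <- min(n_bins, n %/% 2L)
  if (nb < n_bins) {
    message("h2: bins with < 2 points merged (", nb, " bins used)")
  }
  if (nb < 2L) return(0)
  ord <- order(x)
  bin <- ceiling(seq_along(ord) / (n / nb))
  bin <- pmin(bin, nb)
  cx <- vapply(split(x[ord], bin), mean, numeric(1))
  cy <- vapply(split(y[ord], bin), mean, numeric(1))
  keep <- !duplicated(cx)
  cx <- cx[keep]; cy <- cy[keep]
  if (length(cx) < 2L) return(0)
  k <- length(cx)
  seg <- findInterval(x, cx, all.inside = TRUE)  # extends end segments
  slope <- (cy[seg + 1L] - cy[seg]) / (cx[seg + 1L] - cx[seg])
  pred <- cy[seg] + slope * (x - cx[seg])
  vy <- mean((y - mean(y))^2)
  h2 <- 1 - mean((y - pred)^2) / vy
  min(max(h2, 0), 1)
}

#' Nonlinear (h2) correlation edge weight
#'
#' Variance fraction of one series explained by a piecewise-linear
#' regression on the other over `n_bins` equal-count bins. Undirected: the
#' larger of the two directions at lag 0; directed: maximum over source
#' lags, regressing y on the lagged x.
#'
#' @inheritParams edge_corr
#' @param n_bins number of equal-count bins of the predictor.
#' @return weight in [0, 1].
#' @export
edge_h2 <- function(x, y, directed = FALSE, max_delay = 5L, n_bins = 10L) {
  check_pair(x, y)
  if (!directed) {
    return(max(h2_one_direction(x, y, n_bins),
               h2_one_direction(y, x, n_bins)))
  }
  max_over_delays(x, y, max_delay,
                  function(a, b) h2_one_direction(a, b, n_bins))
}

discretize <- function(x, n_bins) {
  rng <- range(x)
  if (diff(rng) <= 0) stop("degenerate (constant) series")
  br <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
}

entropy_nat <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

mi_normalized <- function(xb, yb) {
  jt <- table(xb, yb)
  hx <- entropy_nat(rowSums(jt))
  hy <- entropy_nat(colSums(jt))
  if (hx <= 0 || hy <= 0) return(0)
  mi <- hx + hy - entropy_nat(jt)
  max(min(mi / sqrt(hx * hy), 1), 0)
}

#' Mutual-information edge weight
#'
#' Mutual information from an `n_bins` x `n_bins` joint histogram (bin
#' edges at each series' min/max, right-closed last bin), normalized as
#' I / sqrt(H(X) H(Y)) so identical series give 1. Directed: maximum over
#' source lags; undirected: lag 0.
#'
#' @inheritParams edge_corr
#' @param n_bins histogram bins per axis.
#' @return weight in [0, 1].
#' @export
edge_mit <- function(x, y, directed = FALSE, max_delay = 5L, n_bins = 5L) {
  check_pair(x, y)
  stat <- function(a, b) mi_normalized(discretize(a, n_bins),
                                       discretize(b, n_bins))
  if (!directed) return(stat(x, y))
  max_over_delays(x, y, max_delay, stat)
}

# rolling mean over blocks of `width` trailing samples ending at each index
trailing_block_mean <- function(x, width) {
  cs <- cumsum(c(0, x))
  n <- length(x)
  idx <- width:n
  (cs[idx + 1L] - cs[idx + 1L - width]) / width
}

te_one_direction <- function(x, y, past, lag, n_bins) {
  n <- length(y)
  first_t <- past + lag + 1L
  if (first_t > n - 1L) stop("series too short for TE past/lag structure")
  ts_idx <- first_t:n
  yt <- y[ts_idx]
  ypm <- trailing_block_mean(y, past)            # ends at past..n
  yp <- ypm[ts_idx - past]                       # block ending at t-1
  xpm <- trailing_block_mean(x, past)
  xp <- xpm[ts_idx - past - lag]                 # source block lagged
  ytb <- discretize(yt, n_bins)
  ypb <- discretize(yp, n_bins)
  xpb <- discretize(xp, n_bins)
  h_ypl <- entropy_nat(table(ypb))
  h_y_yp <- entropy_nat(table(ytb, ypb)) - h_ypl        # H(Y | YP)
  h_xp_yp <- entropy_nat(table(xpb, ypb))
  h_all <- entropy_nat(table(ytb, xpb, ypb))
  te <- h_y_yp - (h_all - h_xp_yp)                      # I(Y; XP | YP)
  if (h_y_yp <= 0) return(0)
  max(min(te / h_y_yp, 1), 0)
}

#' Transfer-entropy edge weight
#'
#' Binned transfer entropy TE(x -> y) = I(y_t ; x_past | y_past) with
#' `past_samples`-long past blocks, normalized by H(y_t | y_past) to [0, 1].
#' To keep the histogram estimable at rfMRI series lengths, each past block
#' is coarse-grained to its mean before binning. Directed: maximum over
#' lags of the source past block; undirected: mean of the two directions.
#'
#' @inheritParams edge_corr
#' @param past_samples length of the past blocks.
#' @param n_bins bins per (coarse-grained) variable.
#' @return weight in [0, 1].
#' @export
edge_te <- function(x, y, directed = FALSE, max_delay = 5L,
                    past_samples = 5L, n_bins = 3L) {
  check_pair(x, y)
  if (length(x) <= past_samples + max_delay + 1L) {
    stop("series too short for the requested past/delay structure")
  }
  if (!directed) {
    return(mean(c(te_one_direction(x, y, past_samples, 0L, n_bins),
                  te_one_direction(y, x, past_samples, 0L, n_bins))))
  }
  max(vapply(0:max_delay, function(lag) {
    te_one_direction(x, y, past_samples, lag, n_bins)
  }, numeric(1)))
}

edge_weight <- function(x, y, spec) {
  switch(spec$family,
         corr = edge_corr(x, y, spec$directed, spec$max_delay),
         H2 = edge_h2(x, y, spec$directed, spec$max_delay, spec$n_bins),
         MIT = edge_mit(x, y, spec$directed, spec$max_delay, spec$n_bins),
         TE = edge_te(x, y, spec$directed, spec$max_delay,
                      spec$te_past_samples, spec$n_bins))
}

#' Weighted connectivity graph container
#'
#' @param weights non-negative clusters x clusters matrix, zero diagonal;
#'   symmetric when undirected.
#' @param directed logical.
#' @param node_ids aligned cluster ids.
#' @param method an [edge_method_spec()] or tag describing the estimator.
#' @return object of class `connectivity_graph`.
#' @export
connectivity_graph <- function(weights, directed, node_ids = seq_len(nrow(weights)),
                               method = NULL) {
  stopifnot(is.matrix(weights), nrow(weights) == ncol(weights),
            all(is.finite(weights)), all(weights >= 0),
            all(diag(weights) == 0))
  if (!directed) stopifnot(isTRUE(all.equal(weights, t(weights))))
  structure(list(weights = weights, directed = directed,
                 node_ids = node_ids, method = method),
            class = "connectivity_graph")
}

#' Build the connectivity graph of a parcellated subject
#'
#' Applies the family estimator of `spec` to every cluster pair within each
#' sliding window and averages the per-window weights. Absolute values,
#' zero diagonal; symmetry holds for undirected specs. Clusters whose mean
#' series is constant in some window get all incident weights set to 0 with
#' a warning, rather than failing the subject.
#'
#' @param ts a `cluster_ts` from [extract_mean_timeseries()].
#' @param spec an [edge_method_spec()].
#' @return a `connectivity_graph`.
#' @export
build_graph <- function(ts, spec) {
  stopifnot(inherits(ts, "cluster_ts"), inherits(spec, "edge_method_spec"))
  x <- ts$series
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 clusters to build a graph")
  win <- sliding_windows(ncol(x), min(spec$window_length, ncol(x)),
                         spec$window_overlap_fraction)
  degenerate <- rep(FALSE, n)
  for (w in seq_len(nrow(win))) {
    seg <- x[, win[w, 1L]:win[w, 2L], drop = FALSE]
    degenerate <- degenerate | apply(seg, 1L, stats::var) <= 0
  }
  if (any(degenerate)) {
    warning(sum(degenerate),
            " cluster series constant within a window; their edges set to 0")
  }
  W <- matrix(0, n, n)
  live <- which(!degenerate)
  pairs <- if (spec$directed) {
    subset(expand.grid(i = live, j = live), i != j)
  } else {
    if (length(live) >= 2L) {
      cm <- utils::combn(live, 2L)
      data.frame(i = cm[1L, ], j = cm[2L, ])
    } else data.frame(i = integer(0), j = integer(0))
  }
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$i[r]; j <- pairs$j[r]
    vals <- vapply(seq_len(nrow(win)), function(w) {
      rng <- win[w, 1L]:win[w, 2L]
      edge_weight(x[i, rng], x[j, rng], spec)
    }, numeric(1))
    W[i, j] <- mean(vals)
    if (!spec$directed) W[j, i] <- W[i, j]
  }
  connectivity_graph(W, spec$directed, ts$cluster_ids, spec)
}
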
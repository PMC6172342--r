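# Partially exchangeable model by sufficiency: the empirical mean and
# covariance of previous subjects' graph feature vectors are sufficient for
# predicting a new subject of the same condition, giving a multivariate-t
# posterior predictive. Condition probabilities follow by Bayes' theorem and
# are scored by negative surprise (log probability of the true condition).

#' Model hyperparameters
#'
#' Defaults follow the survey's common choice for all graph constructions:
#' kappa0 = 1, delta0 = 0.5 in every coordinate, Delta0 = 2.5 I — an initial
#' predictive centered on positive values of order unity. nu0 is not pinned
#' down by that choice; the default d + 2 is the smallest integer making the
#' predictive covariance finite, and is exposed here for users to vary.
#'
#' @param d feature dimension.
#' @param kappa0 positive pseudo-count on the mean.
#' @param nu0 degrees of freedom, > d - 1.
#' @param delta0 prior mean vector (length d).
#' @param Delta0 prior scatter matrix (d x d, symmetric positive definite).
#' @return object of class `hyperparams`.
#' @export
hyperparams <- function(d, kappa0 = 1, nu0 = d + 2,
                        delta0 = rep(0.5, d), Delta0 = 2.5 * diag(d)) {
  stopifnot(d >= 1, kappa0 > 0, nu0 > d - 1, length(delta0) == d,
            is.matrix(Delta0), all(dim(Delta0) == d),
            isTRUE(all.equal(Delta0, t(Delta0))))
  structure(list(d = as.integer(d), kappa0 = kappa0, nu0 = nu0,
                 delta0 = delta0, Delta0 = Delta0),
            class = "hyperparams")
}

#' Posterior update from a batch of feature vectors
#'
#' One-shot conjugate update: kappa = kappa0 + n, nu = nu0 + n,
#' delta = (kappa0 delta0 + n fbar) / (kappa0 + n),
#' Delta = Delta0 + n Cov(f) + kappa0 n / (kappa0 + n)
#' (fbar - delta0)(fbar - delta0)', where fbar and Cov(f) are the empirical
#' mean and covariance (divisor n) of the batch. n = 0 returns the
#' hyperparameters unchanged.
#'
#' @param features matrix (subjects x d) or list of d-vectors.
#' @param hyper a [hyperparams()].
#' @return object of class `posterior_params` with fields kappa, nu, delta,
#'   Delta, n, d.
#' @export
posterior_update <- function(features, hyper) {
  stopifnot(inherits(hyper, "hyperparams"))
  if (is.list(features)) features <- do.call(rbind, features)
  if (is.null(features)) features <- matrix(numeric(0), 0L, hyper$d)
  if (is.vector(features)) features <- matrix(features, ncol = hyper$d)
  if (ncol(features) != hyper$d) {
    stop("feature dimension does not match the hyperparameters")
  }
  n <- nrow(features)
  if (n == 0L) {
    post <- list(kappa = hyper$kappa0, nu = hyper$nu0, delta = hyper$delta0,
                 Delta = hyper$Delta0, n = 0L, d = hyper$d)
    return(structure(post, class = "posterior_params"))
  }
  fbar <- colMeans(features)
  centered <- sweep(features, 2L, fbar)
  cov_n <- crossprod(centered) / n
  kappa <- hyper$kappa0 + n
  nu <- hyper$nu0 + n
  delta <- (hyper$kappa0 * hyper$delta0 + n * fbar) / (hyper$kappa0 + n)
  dd <- fbar - hyper$delta0
  Delta <- hyper$Delta0 + n * cov_n +
    hyper$kappa0 * n / (hyper$kappa0 + n) * tcrossprod(dd)
  structure(list(kappa = kappa, nu = nu, delta = delta, Delta = Delta,
                 n = n, d = hyper$d),
            class = "posterior_params")
}

# log density of the multivariate t with df degrees of freedom, location mu
# and scale matrix S (via Cholesky; errors if S is not positive definite)
dmvt_log <- function(x, df, mu, S) {
  d <- length(mu)
  R <- tryCatch(chol(S), error = function(e) {
    stop("scale matrix is not positive definite")
  })
  z <- backsolve(R, x - mu, transpose = TRUE)
  quad <- sum(z^2)
  lgamma((df + d) / 2) - lgamma(df / 2) - (d / 2) * log(df * pi) -
    sum(log(diag(R))) - (df + d) / 2 * log1p(quad / df)
}

#' Posterior predictive log likelihood of a new feature vector
#'
#' The multivariate t with nu - d + 1 degrees of freedom, location delta
#' and scale ((kappa + 1) / (kappa (nu - d + 1))) Delta.
#'
#' @param f0 d-vector of graph features.
#' @param post a `posterior_params`.
#' @return log density (natural log).
#' @export
log_likelihood <- function(f0, post) {
  stopifnot(inherits(post, "posterior_params"), length(f0) == post$d)
  df <- post$nu - post$d + 1
  if (df <= 0) stop("nu - d + 1 must be positive")
  S <- (post$kappa + 1) / (post$kappa * df) * post$Delta
  dmvt_log(f0, df, post$delta, S)
}

#' Condition probabilities for a new subject
#'
#' probs proportional to exp(log likelihood) x prior, normalized via
#' log-sum-exp.
#'
#' @param f0 d-vector of graph features.
#' @param posts named list of `posterior_params`, one per condition.
#' @param prior named prior over the same conditions (sums to 1); uniform
#'   by default.
#' @return list with `probs` and `prior` (both named).
#' @export
condition_probabilities <- function(f0, posts,
                                    prior = stats::setNames(
                                      rep(1 / length(posts), length(posts)),
                                      names(posts))) {
  stopifnot(length(posts) >= 2L, !is.null(names(posts)),
            setequal(names(prior), names(posts)),
            isTRUE(all.equal(sum(prior), 1)))
  prior <- prior[names(posts)]
  ll <- vapply(posts, function(p) log_likelihood(f0, p), numeric(1))
  lp <- ll + log(prior)
  if (all(!is.finite(lp))) stop("all condition likelihoods vanish")
  m <- max(lp)
  probs <- exp(lp - m) / sum(exp(lp - m))
  list(probs = probs, prior = prior)
}

#' Negative surprise of the true condition
#'
#' Natural log of the probability assigned to the condition that actually
#' holds: 0 for a sure event, -Inf for an impossible one.
#'
#' @param probs output of [condition_probabilities()] (or a named
#'   probability vector).
#' @param true_condition condition label.
#' @return log probability.
#' @export
negative_surprise <- function(probs, true_condition) {
  p <- if (is.list(probs)) probs$probs else probs
  if (!true_condition %in% names(p)) {
    stop("true condition absent from the probability vector")
  }
  log(p[[true_condition]])
}

#' Leave-one-out negative-surprise evaluation
#'
#' Holds out each subject in turn, updates every condition's posterior on
#' the remaining subjects, and scores the held-out subject's probability
#' of its true condition by negative surprise.
#'
#' @param features named list (one entry per condition) of feature matrices
#'   (subjects x d), each with >= 2 rows.
#' @param hyper a [hyperparams()].
#' @param prior prior over conditions (uniform by default).
#' @return list with `per_subject` (data.frame: condition, index,
#'   surprise, prob_true) and `mean_surprise`.
#' @export
loo_evaluate <- function(features, hyper,
                         prior = stats::setNames(
                           rep(1 / length(features), length(features)),
                           names(features))) {
  stopifnot(length(features) >= 2L, !is.null(names(features)))
  ns <- vapply(features, nrow, integer(1))
  if (any(ns < 2L)) {
    stop("every condition needs at least 2 subjects for leave-one-out")
  }
  full_posts <- lapply(features, posterior_update, hyper = hyper)
  rows <- list()
  for (cond in names(features)) {
    f <- features[[cond]]
    for (i in seq_len(nrow(f))) {
      posts <- full_posts
      posts[[cond]] <- posterior_update(f[-i, , drop = FALSE], hyper)
      cp <- condition_probabilities(f[i, ], posts, prior)
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, index = i,
        prob_true = unname(cp$probs[[cond]]),
        surprise = unname(negative_surprise(cp, cond)))
    }
  }
  per_subject <- do.call(rbind, rows)
  list(per_subject = per_subject,
       mean_surprise = mean(per_subject$surprise))
}
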
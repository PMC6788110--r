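#' Permute a node-weight assignment
#'
#' Reassigns the observed pool of weights to the node labels. Mode
#' `"shuffle"` draws a uniformly random permutation of the observed weight
#' multiset (without replacement; the pool is preserved exactly), mode
#' `"resample"` draws i.i.d. with replacement from the pool. The label set
#' is unchanged. Uses the current R random stream; call [set.seed()] (or
#' use [null_distribution()]) for reproducibility.
#'
#' @param weights named numeric vector.
#' @param mode `"shuffle"` or `"resample"`.
#' @return named numeric vector over the same labels.
#' @export
permute_weights <- function(weights, mode = c("shuffle", "resample")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(weights), length(weights) >= 1)
  vals <- as.numeric(weights)
  n <- length(vals)
  out <- switch(mode,
    shuffle = vals[sample.int(n)],
    resample = vals[sample.int(n, n, replace = TRUE)]
  )
  setNames(out, names(weights))
}

#' Permutation null distribution of CMPA scores
#'
#' Generates the null distribution of the CMPA score under random
#' reassignment of the observed weight pool to the network's nodes: each
#' node is assigned a random expression value from the pool of real values,
#' and the mechanism is rescored. By default all node weights enter the
#' pool, including the zero placeholders of unmeasured nodes, since they are
#' part of the realized weight vector; `measured_only = TRUE` restricts the
#' permutation to nodes recorded as measured by [attach_weights()].
#'
#' @param net a `causal_network` (extracted, central set).
#' @param weights named numeric vector over the network nodes.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed; the distribution is bitwise reproducible.
#' @param mode `"shuffle"` (without replacement, default) or `"resample"`.
#' @param propagate logical, as in [cmpa_score()]; use the same setting as
#'   the observed score.
#' @param measured_only logical, permute only measured node weights.
#' @param break_cycles logical, see [schedule_hubs()]; a hub cycle surfaces
#'   once, before any permutation.
#' @return object of class `"cmpa_null"`: list with `scores` (length
#'   `n_perm`), `n_perm`, `seed`, `mode`.
#' @export
null_distribution <- function(net, weights, n_perm = 10000L, seed = 0L,
                              mode = c("shuffle", "resample"),
                              propagate = TRUE, measured_only = FALSE,
                              break_cycles = FALSE) {
  mode <- match.arg(mode)
  n_perm <- as.integer(n_perm)
  if (is.na(n_perm) || n_perm < 2L) stop("n_perm must be >= 2", call. = FALSE)
  stopifnot(inherits(net, "causal_network"))
  labels <- net$nodes$label
  if (!all(labels %in% names(weights))) {
    stop("weights missing for node(s): ",
         paste(setdiff(labels, names(weights)), collapse = ", "),
         call. = FALSE)
  }
  w <- as.numeric(weights[labels])
  plan <- .score_plan(net, weights = setNames(w, labels),
                      break_cycles = break_cycles)
  perm_idx <- seq_along(labels)
  if (measured_only) {
    unmeasured <- attr(weights, "unmeasured")
    if (!is.null(unmeasured)) perm_idx <- which(!labels %in% unmeasured)
  }
  pool <- w[perm_idx]
  m <- length(pool)
  scores <- numeric(n_perm)
  set.seed(as.integer(seed))
  for (i in seq_len(n_perm)) {
    wi <- w
    wi[perm_idx] <- if (mode == "shuffle") {
      pool[sample.int(m)]
    } else {
      pool[sample.int(m, m, replace = TRUE)]
    }
    scores[i] <- .eval_plan(plan, wi, propagate = propagate)$score
  }
  structure(
    list(scores = scores, n_perm = n_perm, seed = as.integer(seed),
         mode = mode),
    class = "cmpa_null"
  )
}

#' @export
print.cmpa_null <- function(x, ...) {
  cat(sprintf("CMPA permutation null: %d scores (mode %s, seed %d)\n",
              x$n_perm, x$mode, x$seed))
  cat(sprintf("  mean %.6g, sd %.6g\n", mean(x$scores), sd(x$scores)))
  invisible(x)
}

#' One-sample Student's t-test of the permutation null against the observed score
#'
#' Tests the null hypothesis that the mean of the permutation CMPA scores
#' equals the observed CMPA score: `t = (null_mean - observed) / (sd /
#' sqrt(n))` with `n - 1` degrees of freedom and a two-sided p-value. The
#' null hypothesis is rejected below the 0.05 threshold, indicating that
#' the observed score is specific to the mechanism rather than an artifact
#' of the weight pool.
#'
#' @param null a `"cmpa_null"` object (or numeric vector of null scores).
#' @param observed the observed CMPA score.
#' @return list of class `"cmpa_ttest"`: `t_statistic`, `df`, `p_value`,
#'   `null_mean`, `null_sd`, `observed`, `reject` (at alpha = 0.05).
#' @examples
#' one_sample_t_test(c(1, 2, 3), observed = 0)
#' @export
one_sample_t_test <- function(null, observed) {
  scores <- if (inherits(null, "cmpa_null")) null$scores else as.numeric(null)
  n <- length(scores)
  if (n < 2) stop("need at least 2 null scores", call. = FALSE)
  stopifnot(is.numeric(observed), length(observed) == 1, is.finite(observed))
  m <- mean(scores)
  s <- sd(scores)
  if (s == 0) {
    stop("null distribution has zero variance; the t-test is degenerate. ",
         "Use empirical_p() instead.", call. = FALSE)
  }
  t_stat <- (m - observed) / (s / sqrt(n))
  p <- 2 * pt(-abs(t_stat), df = n - 1)
  structure(
    list(t_statistic = t_stat, df = n - 1L, p_value = p, null_mean = m,
         null_sd = s, observed = observed, reject = p < 0.05),
    class = "cmpa_ttest"
  )
}

#' @export
print.cmpa_ttest <- function(x, ...) {
  cat(sprintf("One-sample t-test: t = %.4g, df = %d, p = %.4g\n",
              x$t_statistic, x$df, x$p_value))
  cat(sprintf("  null mean %.6g vs observed %.6g; %s H0 at 0.05\n",
              x$null_mean, x$observed,
              if (x$reject) "reject" else "do not reject"))
  invisible(x)
}

#' Empirical (add-one) permutation p-value
#'
#' The two-sided permutation p-value
#' `(1 + #\{|s_i| >= |observed|\}) / (n_perm + 1)`: the rank of the observed
#' score's magnitude within the null. A distribution-free companion to
#' [one_sample_t_test()] that remains valid when the null is degenerate or
#' far from Gaussian.
#'
#' @param null a `"cmpa_null"` object (or numeric vector of null scores).
#' @param observed the observed CMPA score.
#' @return p-value in (0, 1].
#' @export
empirical_p <- function(null, observed) {
  scores <- if (inherits(null, "cmpa_null")) null$scores else as.numeric(null)
  stopifnot(length(scores) >= 1, is.numeric(observed), length(observed) == 1)
  (1 + sum(abs(scores) >= abs(observed))) / (length(scores) + 1)
}

#' Score a mechanism and assess its specificity by permutation
#'
#' Convenience wrapper: computes the observed CMPA score, the permutation
#' null distribution, the one-sample Student's t-test and the empirical
#' p-value in one call. When the null distribution is degenerate (zero
#' variance) the t-test fields are `NA` with a warning and the empirical
#' p-value remains valid.
#'
#' @inheritParams null_distribution
#' @return object of class `"cmpa_test"`: list with `fit` (the `"cmpa"`
#'   object), `null`, `t_test` (a `"cmpa_ttest"` or `NULL`), `empirical_p`,
#'   `reject` (t-test rejection at 0.05, or `NA` when degenerate).
#' @export
cmpa_test <- function(net, weights, n_perm = 10000L, seed = 0L,
                      mode = c("shuffle", "resample"), propagate = TRUE,
                      measured_only = FALSE, break_cycles = FALSE) {
  mode <- match.arg(mode)
  fit <- cmpa_score(net, weights, propagate = propagate,
                    break_cycles = break_cycles)
  null <- null_distribution(net, weights, n_perm = n_perm, seed = seed,
                            mode = mode, propagate = propagate,
                            measured_only = measured_only,
                            break_cycles = break_cycles)
  tt <- tryCatch(one_sample_t_test(null, fit$score), error = function(e) {
    warning("degenerate null distribution: ", conditionMessage(e),
            call. = FALSE)
    NULL
  })
  structure(
    list(fit = fit, null = null, t_test = tt,
         empirical_p = empirical_p(null, fit$score),
         reject = if (is.null(tt)) NA else tt$reject),
    class = "cmpa_test"
  )
}

#' @export
print.cmpa_test <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$t_test)) print(x$t_test) else
    cat("t-test: degenerate null (zero variance)\n")
  cat(sprintf("empirical p: %.4g\n", x$empirical_p))
  invisible(x)
}

#' Histogram of the permutation null with the observed score
#'
#' @param x a `"cmpa_test"` object.
#' @param ... passed to [graphics::hist()].
#' @return `x`, invisibly.
#' @export
plot.cmpa_test <- function(x, ...) {
  graphics::hist(x$null$scores, breaks = "FD",
                 main = "Permutation null of the CMPA score",
                 xlab = "CMPA score", ...)
  graphics::abline(v = x$fit$score, col = "red", lwd = 2)
  invisible(x)
}
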
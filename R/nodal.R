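#' Hypergeometric distribution of the observed positive-node count
#'
#' If a patient truly harbors `p_true` positive nodes among a nodal
#' population of `m_total`, and pathology examines `n_examined` nodes drawn
#' without replacement, the observed number of positive nodes `k` is
#' hypergeometric. Probabilities are computed in log space (log-binomial
#' coefficients) so large nodal populations do not overflow.
#'
#' @param p_true true number of positive nodes, `0 <= p_true <= m_total`.
#' @param m_total nodal population size.
#' @param n_examined number of examined nodes, `1 <= n_examined <= m_total`.
#' @return named numeric vector of `Pr(k observed)` for
#'   `k = 0 ... min(p_true, n_examined)`; sums to 1 within 1e-12.
#' @examples
#' detection_pmf(p_true = 2, m_total = 10, n_examined = 5)["0"]  # 2/9
#' @export
detection_pmf <- function(p_true, m_total, n_examined) {
  stopifnot(length(p_true) == 1, length(m_total) == 1, length(n_examined) == 1)
  if (m_total < 1 || m_total != floor(m_total)) {
    stop("m_total must be a positive integer", call. = FALSE)
  }
  if (p_true < 0 || p_true > m_total || p_true != floor(p_true)) {
    stop("p_true must be an integer in [0, m_total]", call. = FALSE)
  }
  if (n_examined < 1 || n_examined > m_total || n_examined != floor(n_examined)) {
    stop("n_examined must be an integer in [1, m_total]", call. = FALSE)
  }
  k <- 0:min(p_true, n_examined)
  lp <- lchoose(p_true, k) + lchoose(m_total - p_true, n_examined - k) -
    lchoose(m_total, n_examined)
  pmf <- exp(lp)
  pmf[!is.finite(pmf)] <- 0  # infeasible k (n - k > M - p) has -Inf log-prob
  names(pmf) <- k
  pmf
}

#' Construct a prior over the true positive-node count
#'
#' @param mass named numeric vector; names are true positive-node counts,
#'   values their probabilities (normalized here).
#' @param source label recording where the prior came from.
#' @return a `node_prior`: list with integer `support`, probability `mass`
#'   and `source`.
#' @export
node_prior <- function(mass, source = "custom") {
  p <- suppressWarnings(as.integer(names(mass)))
  if (anyNA(p) || any(p < 0)) {
    stop("prior support must be named by non-negative integers", call. = FALSE)
  }
  m <- as.numeric(mass)
  if (any(m < 0) || sum(m) <= 0) {
    stop("prior masses must be non-negative with positive total", call. = FALSE)
  }
  ord <- order(p)
  structure(list(support = p[ord], mass = m[ord] / sum(m), source = source),
            class = "node_prior")
}

#' @export
print.node_prior <- function(x, ...) {
  cat(sprintf("Prior over true positive-node count (%s): support 0..%d, P(p=0)=%.3f, E[p]=%.2f\n",
              x$source, max(x$support), sum(x$mass[x$support == 0]),
              sum(x$support * x$mass)))
  invisible(x)
}

#' Estimate the positive-node prior from thoroughly examined patients
#'
#' The empirical distribution of the observed positive-node count among
#' patients whose ELN count is at least `min_eln` is taken as the
#' distribution of the true count: with near-complete nodal sampling the
#' observed count approaches the truth. The default threshold is the
#' cohort's 90th ELN percentile.
#'
#' @param cohort an `eln_cohort`.
#' @param min_eln minimum ELN count to qualify as near-complete sampling.
#' @param min_patients minimum number of qualifying patients (default 50).
#' @return a `node_prior` with source `"empirical"`.
#' @export
estimate_prior <- function(cohort, min_eln = NULL, min_patients = 50) {
  cohort <- as_cohort(cohort)
  if (is.null(min_eln)) {
    min_eln <- as.numeric(quantile(cohort$eln_count, 0.9, type = 1))
  }
  qual <- cohort$positive_count[cohort$eln_count >= min_eln]
  if (length(qual) < min_patients) {
    stop(sprintf(
      "only %d patients have eln_count >= %s; at least %d required to estimate the prior",
      length(qual), format(min_eln), min_patients), call. = FALSE)
  }
  tab <- table(factor(qual, levels = 0:max(qual)))
  prior <- node_prior(setNames(as.numeric(tab), names(tab)),
                      source = "empirical")
  attr(prior, "min_eln") <- min_eln
  attr(prior, "n_used") <- length(qual)
  prior
}

#' Posterior probability of occult (undetected) positive nodes
#'
#' Bayes' theorem over the hypergeometric sampling model: given a prior on
#' the true positive-node count and an observation of `k_observed` positive
#' nodes among `n_examined` examined (out of a nodal population `m_total`),
#' returns the posterior probability that the true count exceeds the
#' observed one — for a declared node-negative patient (`k_observed = 0`),
#' the probability of at least one undetected positive node.
#'
#' @param prior a [node_prior].
#' @param m_total nodal population size; must be at least the prior's
#'   largest support point.
#' @param n_examined examined node count.
#' @param k_observed observed positive-node count.
#' @return probability in `[0, 1]`.
#' @examples
#' pr <- node_prior(c(`0` = 0.5, `2` = 0.5))
#' occult_probability(pr, m_total = 10, n_examined = 5, k_observed = 0)  # 2/11
#' @export
occult_probability <- function(prior, m_total, n_examined, k_observed = 0) {
  stopifnot(inherits(prior, "node_prior"))
  if (max(prior$support) > m_total) {
    stop("prior support exceeds m_total", call. = FALSE)
  }
  if (k_observed < 0 || k_observed > n_examined || n_examined > m_total) {
    stop("need 0 <= k_observed <= n_examined <= m_total", call. = FALSE)
  }
  lik <- vapply(prior$support, function(p) {
    if (k_observed > min(p, n_examined)) return(0)
    pmf <- detection_pmf(p, m_total, n_examined)
    unname(pmf[as.character(k_observed)])
  }, numeric(1))
  joint <- prior$mass * lik
  denom <- sum(joint)
  if (denom <= 0) {
    stop(sprintf(
      "observation (k=%d in n=%d) has zero probability under the prior",
      k_observed, n_examined), call. = FALSE)
  }
  sum(joint[prior$support > k_observed]) / denom
}

#' Tabulate occult-disease probability against the examined-node count
#'
#' For each examined count `n` in `n_range`, the posterior probability of
#' harboring more positive nodes than observed, for observed counts
#' `k = 0, ..., k_max`. The `k = 0` column is the headline quantity: the
#' chance that a declared node-negative patient is truly node-positive. It
#' is non-increasing in `n` and exactly 0 at `n = m_total` (full sampling
#' leaves nothing undetected).
#'
#' @param prior a [node_prior].
#' @param m_total nodal population size.
#' @param n_range integer vector of examined counts (default `1:m_total`).
#' @param k_max largest observed count to tabulate (default 0).
#' @return an `occult_table` data frame with column `n` and one
#'   `p_occult_given_k<k>` column per observed count; entries are `NA` where
#'   `k > n` or the observation has zero prior probability.
#' @export
occult_table <- function(prior, m_total, n_range = seq_len(m_total), k_max = 0) {
  stopifnot(inherits(prior, "node_prior"))
  out <- data.frame(n = as.integer(n_range))
  for (k in 0:k_max) {
    out[[sprintf("p_occult_given_k%d", k)]] <- vapply(n_range, function(n) {
      if (k > n) return(NA_real_)
      tryCatch(occult_probability(prior, m_total, n, k),
               error = function(e) NA_real_)
    }, numeric(1))
  }
  structure(out, class = c("occult_table", "data.frame"),
            m_total = m_total, prior_source = prior$source)
}
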
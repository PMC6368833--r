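# Internal helpers shared across modules: seed substreams, interval
# arithmetic, and the ModelSummary contract used by every fitting function.

#' Derive a reproducible substream seed from a master seed and labels
#'
#' All stochastic stages draw their seeds through this function so that
#' results are invariant to the order in which sites (or model terms) are
#' processed: the substream seed depends only on the master seed and the
#' labels, never on iteration order.
#'
#' @param master integer master seed.
#' @param ... character or numeric labels identifying the substream
#'   (e.g. site id, direction, indicator dimension).
#' @return An integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @export
substream_seed <- function(master, ...) {
  labels <- paste(vapply(list(...), as.character, character(1)),
                  collapse = "\r")
  codes <- utf8ToInt(labels)
  h <- as.double(master) %% 2147483647
  # 31-bit multiplicative string hash; kept in double precision, which is
  # exact below 2^53 so the modular arithmetic never loses bits
  for (k in codes) {
    h <- (h * 31 + k) %% 2147483647
  }
  as.integer(h)
}

#' Run an expression under a local RNG seed
#'
#' Restores the caller's RNG state afterwards, so calling package functions
#' does not disturb a user's random-number stream.
#' @noRd
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# 5% and 95% normal quantile multiplier for 90% intervals
Z90 <- stats::qnorm(0.95)

#' Build a ModelSummary tibble from estimates and standard errors
#'
#' The package-wide fit contract: one row per term with the point estimate,
#' the 5% and 95% quantiles of its (approximate) sampling distribution, and
#' the probability that the quantity is positive. With the
#' normal-approximation backend the quantiles are `estimate +/- 1.645 * SE`
#' and `prob_positive = pnorm(estimate / SE)`.
#'
#' @param term character vector of term names.
#' @param estimate,se numeric vectors of point estimates and standard errors.
#' @param backend character tag recording which estimation backend produced
#'   the summary.
#' @param df degrees of freedom for the reference distribution: `Inf`
#'   (default) gives normal quantiles; finite values give t-based
#'   intervals, appropriate when the effective sample size is a modest
#'   number of clusters.
#' @return A tibble of class `mt_model_summary` with columns `term`,
#'   `estimate`, `q05`, `q95`, `prob_positive` and a `backend` attribute.
#' @export
model_summary <- function(term, estimate, se, backend = "ml_normal_approx",
                          df = Inf) {
  estimate <- as.numeric(estimate)
  se <- as.numeric(se)
  # degenerate (zero-SE) fits arise on noise-free data; the sign is then
  # known with certainty
  prob <- ifelse(se > 0, stats::pt(estimate / se, df),
                 ifelse(estimate > 0, 1, ifelse(estimate < 0, 0, 0.5)))
  q <- stats::qt(0.95, df)
  out <- tibble::tibble(
    term = as.character(term),
    estimate = estimate,
    q05 = estimate - q * se,
    q95 = estimate + q * se,
    prob_positive = prob
  )
  attr(out, "backend") <- backend
  class(out) <- c("mt_model_summary", class(out))
  out
}

#' @noRd
summary_row <- function(fit_summary, term) {
  i <- match(term, fit_summary$term)
  if (is.na(i)) stop("term not found in model summary: ", term)
  fit_summary[i, ]
}

#' Fixed-effect estimates, standard errors and covariance of a glmmTMB fit
#' @noRd
fixef_stats <- function(fit) {
  est <- glmmTMB::fixef(fit)$cond
  V <- stats::vcov(fit)$cond
  list(estimate = est, se = sqrt(diag(V)), vcov = V)
}

#' z-standardize a vector, guarding against zero variance
#' @noRd
zscore <- function(x, name = deparse(substitute(x))) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("cannot standardize '", name, "': zero or undefined variance")
  }
  (x - mean(x)) / s
}
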
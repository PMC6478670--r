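#' Pre-/post-test probability updating
#'
#' The value of a detection step lies in how far it moves a pre-test
#' probability of the outcome to a post-test probability.  The two are
#' linked on the odds scale: post-test odds = pre-test odds x likelihood
#' ratio.  `update_risk()` applies a likelihood ratio, `derive_lr()`
#' recovers the likelihood ratio implied by an observed pre/post pair
#' (its exact inverse), and `chain_tests()` applies a sequence of
#' likelihood ratios for sequential testing, which under conditional
#' independence equals a single update with their product.
#'
#' @param pretest_prob pre-test probability, strictly inside (0, 1).
#' @param likelihood_ratio positive likelihood ratio.
#' @param horizon optional label for the time horizon (e.g. `"3-year"`).
#' @return An object of class `risk_estimate`: list with `pretest_prob`,
#'   `likelihood_ratio`, `posttest_prob`, `fold_change` (post/pre on the
#'   probability scale) and `horizon`.
#' @examples
#' update_risk(0.15, 1.99)              # ~0.26
#' derive_lr(0.15, 0.26)                # ~1.99
#' chain_tests(0.0043, c(34.9, 1.99))
#' @export
update_risk <- function(pretest_prob, likelihood_ratio, horizon = NULL) {
  check_prob(pretest_prob, "pretest_prob")
  if (!is.finite(likelihood_ratio) || likelihood_ratio <= 0)
    stop("likelihood ratio must be positive and finite", call. = FALSE)
  odds <- pretest_prob / (1 - pretest_prob)
  post_odds <- odds * likelihood_ratio
  post <- post_odds / (1 + post_odds)
  structure(list(pretest_prob = pretest_prob,
                 likelihood_ratio = likelihood_ratio,
                 posttest_prob = post,
                 fold_change = post / pretest_prob,
                 horizon = horizon),
            class = "risk_estimate")
}

#' @rdname update_risk
#' @param posttest_prob post-test probability, strictly inside (0, 1).
#' @export
derive_lr <- function(pretest_prob, posttest_prob) {
  check_prob(pretest_prob, "pretest_prob")
  check_prob(posttest_prob, "posttest_prob")
  (posttest_prob / (1 - posttest_prob)) / (pretest_prob / (1 - pretest_prob))
}

#' @rdname update_risk
#' @param lrs numeric vector of positive likelihood ratios, applied in
#'   order (may be empty).
#' @export
chain_tests <- function(pretest_prob, lrs, horizon = NULL) {
  check_prob(pretest_prob, "pretest_prob")
  if (length(lrs) == 0)
    return(update_risk(pretest_prob, 1, horizon = horizon))
  if (any(!is.finite(lrs)) || any(lrs <= 0))
    stop("all likelihood ratios must be positive and finite", call. = FALSE)
  p <- pretest_prob
  for (lr in lrs) p <- update_risk(p, lr)$posttest_prob
  structure(list(pretest_prob = pretest_prob,
                 likelihood_ratio = prod(lrs),
                 posttest_prob = p,
                 fold_change = p / pretest_prob,
                 horizon = horizon),
            class = "risk_estimate")
}

#' Fold change between two probabilities
#'
#' Ratio on the probability (risk) scale, `prob_a / prob_b` — the scale on
#' which risk-enrichment multiples like "35-fold" are quoted, as opposed
#' to the odds scale on which likelihood ratios live.
#'
#' @param prob_a,prob_b probabilities in (0, 1).
#' @return `prob_a / prob_b`.
#' @examples
#' fold_change(0.15, 0.0043)   # ~34.9
#' @export
fold_change <- function(prob_a, prob_b) {
  check_prob(prob_a, "prob_a")
  check_prob(prob_b, "prob_b")
  prob_a / prob_b
}

#' Combine a baseline risk with an equivalent relative risk
#'
#' Approximate bridge from a score's equivalent relative risk to an
#' absolute outcome probability.  `scale = "risk"` multiplies the baseline
#' probability by the relative risk and caps at 1; `scale = "odds"` treats
#' the relative risk as an odds multiplier (exact when the relative risk
#' is an odds ratio).  Neither is a validated absolute-risk model; both
#' are provided for exploratory use.
#'
#' @param baseline_risk baseline outcome probability in (0, 1).
#' @param rr positive relative risk, e.g. from [pps_to_rr()].
#' @param scale `"risk"` or `"odds"`.
#' @return Combined probability in (0, 1].
#' @export
absolute_risk <- function(baseline_risk, rr, scale = c("risk", "odds")) {
  scale <- match.arg(scale)
  check_prob(baseline_risk, "baseline_risk")
  if (!is.finite(rr) || rr <= 0)
    stop("relative risk must be positive and finite", call. = FALSE)
  if (scale == "risk") min(1, baseline_risk * rr)
  else update_risk(baseline_risk, rr)$posttest_prob
}

check_prob <- function(p, what) {
  if (length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1)
    stop(what, " must be a single probability strictly inside (0, 1)",
         call. = FALSE)
  invisible(p)
}

#' @export
print.risk_estimate <- function(x, digits = 4, ...) {
  cat("Risk update",
      if (!is.null(x$horizon)) paste0(" (", x$horizon, " horizon)"),
      "\n", sep = "")
  cat(sprintf("  pre-test probability:  %s\n",
              signif(x$pretest_prob, digits)))
  cat(sprintf("  likelihood ratio:      %s\n",
              signif(x$likelihood_ratio, digits)))
  cat(sprintf("  post-test probability: %s\n",
              signif(x$posttest_prob, digits)))
  cat(sprintf("  fold change (risk scale): %s\n",
              signif(x$fold_change, digits)))
  invisible(x)
}
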
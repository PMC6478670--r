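#' Score distribution in a hypothetical general population
#'
#' Computes the probability mass function of the total score when factor
#' levels are drawn independently with their configured prevalences.
#' `method = "enumeration"` convolves the per-factor score distributions
#' sequentially and is exact; `method = "monte_carlo"` draws `n`
#' synthetic individuals (the permutation-style emulation) and tabulates
#' their scores, reproducibly for a fixed `seed`.
#'
#' Independence across factors is assumed; the composite factors already
#' encode the within-group dependencies (generation by origin, ethnicity
#' by ethnic density) as joint levels.
#'
#' @param object a [pps()] object.
#' @param method `"enumeration"` (exact convolution) or `"monte_carlo"`.
#' @param n number of simulated individuals (Monte Carlo only).
#' @param seed integer seed (Monte Carlo only); the caller's RNG state is
#'   left untouched.
#' @return An object of class `pps_distribution`: list with `pmf`
#'   (data.frame `score`, `probability`, ascending, on the rounding grid),
#'   `method`, `n`, `seed`, `support` (attainable min/max totals), `scale`,
#'   `grid`.
#' @examples
#' fit <- pps()
#' d <- pps_distribution(fit)
#' summary(d)
#' @export
pps_distribution <- function(object, method = c("enumeration", "monte_carlo"),
                             n = NULL, seed = NULL) {
  stopifnot(inherits(object, "pps"))
  method <- match.arg(method)
  s <- object$scores
  if (anyNA(s$prevalence))
    stop("every scored level needs a prevalence", call. = FALSE)
  rng <- score_range(object)
  if (method == "enumeration") {
    pmf <- enumerate_pmf(s, grid = object$grid)
    out <- list(pmf = pmf, method = method, n = NULL, seed = NULL)
  } else {
    if (is.null(n) || n < 1)
      stop("monte_carlo requires n >= 1", call. = FALSE)
    n <- as.integer(n)
    totals <- simulate(object, nsim = n, seed = seed)
    tab <- table(totals)
    pmf <- data.frame(score = as.numeric(names(tab)),
                      probability = as.numeric(tab) / n)
    pmf <- pmf[order(pmf$score), , drop = FALSE]
    rownames(pmf) <- NULL
    out <- list(pmf = pmf, method = method, n = n, seed = seed)
  }
  out$support <- rng
  out$scale <- object$scale
  out$grid <- object$grid
  class(out) <- "pps_distribution"
  out
}

# exact convolution of per-factor pmfs on integer grid units
enumerate_pmf <- function(scores, grid) {
  units <- round(scores$final_score / grid)
  if (max(abs(units * grid - scores$final_score)) > 1e-9)
    stop("final scores are not on the rounding grid", call. = FALSE)
  pmf <- c(`0` = 1)
  for (f in unique(scores$factor)) {
    i <- scores$factor == f
    u <- units[i]; p <- scores$prevalence[i]
    keys <- rep(as.numeric(names(pmf)), each = sum(i)) + u
    vals <- rep(unname(pmf), each = sum(i)) * p
    pmf <- tapply(vals, keys, sum)
  }
  d <- data.frame(score = as.numeric(names(pmf)) * grid,
                  probability = as.numeric(pmf))
  d <- d[d$probability > 0, , drop = FALSE]
  d <- d[order(d$score), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Simulate total scores for synthetic individuals
#'
#' Draws `nsim` individuals, each factor level independently from its
#' configured prevalence, and returns their total final scores.  Backs the
#' Monte-Carlo path of [pps_distribution()].
#'
#' @param object a [pps()] object.
#' @param nsim number of individuals.
#' @param seed optional integer seed; the caller's RNG state is restored
#'   on exit.
#' @param ... unused.
#' @return Numeric vector of `nsim` total scores.
#' @export
simulate.pps <- function(object, nsim = 1, seed = NULL, ...) {
  stopifnot(nsim >= 1)
  nsim <- as.integer(nsim)
  s <- object$scores
  with_preserved_rng(seed, {
    totals <- numeric(nsim)
    for (f in unique(s$factor)) {
      i <- which(s$factor == f)
      draw <- sample.int(length(i), nsim, replace = TRUE,
                         prob = s$prevalence[i])
      totals <- totals + s$final_score[i][draw]
    }
    totals
  })
}

# run expr under an optional seed, restoring the global RNG state
with_preserved_rng <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' Summarise a score distribution
#'
#' Reports the fractions of the population in the bins used to read the
#' score histogram: negative scores (equivalent RR below 1), scores in
#' [0, 5] (RR roughly 1 to 3), scores above 5 (RR above 3) and scores
#' above 15 (RR above 30).  The relative-risk thresholds are mapped to the
#' score axis through `rr_to_pps()` (10 log10 3 = 4.77, 10 log10 30 =
#' 14.77) and aligned to the enclosing half-integer grid points, 5 and 15.
#'
#' @param object a `pps_distribution`.
#' @param ... unused.
#' @return Object of class `pps_distribution_summary`: list with
#'   `frac_negative`, `frac_zero_to_five`, `frac_rr_gt_3`,
#'   `frac_rr_gt_30`, `min_score`, `max_score`, `method`, `n`, `seed`.
#' @export
summary.pps_distribution <- function(object, ...) {
  s <- object$pmf$score; p <- object$pmf$probability
  structure(list(frac_negative = sum(p[s < 0]),
                 frac_zero_to_five = sum(p[s >= 0 & s <= 5]),
                 frac_rr_gt_3 = sum(p[s > 5]),
                 frac_rr_gt_30 = sum(p[s > 15]),
                 min_score = min(s), max_score = max(s),
                 method = object$method, n = object$n, seed = object$seed),
            class = "pps_distribution_summary")
}

#' @export
print.pps_distribution_summary <- function(x, ...) {
  cat("Score distribution summary (", x$method,
      if (!is.null(x$n)) paste0(", n = ", x$n, ", seed = ",
                                x$seed %||% "none"), ")\n", sep = "")
  cat(sprintf("  negative score (RR < 1):   %5.1f%%\n", 100 * x$frac_negative))
  cat(sprintf("  score in [0, 5] (RR 1-3):  %5.1f%%\n", 100 * x$frac_zero_to_five))
  cat(sprintf("  score > 5  (RR > 3):       %5.1f%%\n", 100 * x$frac_rr_gt_3))
  cat(sprintf("  score > 15 (RR > 30):      %5.1f%%\n", 100 * x$frac_rr_gt_30))
  cat(sprintf("  observed support: %.1f to %.1f\n", x$min_score, x$max_score))
  invisible(x)
}

#' @export
print.pps_distribution <- function(x, ...) {
  cat("Total-score distribution (", x$method, ")\n", sep = "")
  cat("  support points:", nrow(x$pmf),
      sprintf(" in [%.1f, %.1f]\n", min(x$pmf$score), max(x$pmf$score)))
  print(summary(x))
  invisible(x)
}

#' Export a score histogram
#'
#' Writes a tab-separated file with columns `score`, `probability`,
#' `equivalent_rr` (the relative risk `10^(score/scale)` matching each
#' grid point).
#'
#' @param dist a `pps_distribution`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_histogram <- function(dist, path) {
  stopifnot(inherits(dist, "pps_distribution"))
  d <- dist$pmf
  d$equivalent_rr <- 10^(d$score / dist$scale)
  ok <- tryCatch({
    utils::write.table(d, path, sep = "\t", row.names = FALSE,
                       quote = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) stop("cannot write histogram to '", path, "': ",
                              conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Plot a score distribution
#'
#' Histogram of the score probability mass with the equivalent
#' relative-risk curve overlaid on a secondary axis.
#'
#' @param x a `pps_distribution`.
#' @param ... passed to [graphics::barplot()].
#' @return `x`, invisibly.
#' @export
plot.pps_distribution <- function(x, ...) {
  d <- x$pmf
  mids <- graphics::barplot(d$probability, names.arg = d$score,
                            xlab = "Total score", ylab = "Proportion",
                            border = NA, ...)
  rr <- 10^(d$score / x$scale)
  graphics::lines(mids, rr / max(rr) * max(d$probability),
                  lty = 3, lwd = 2, col = "blue")
  graphics::axis(4, at = pretty(c(0, max(d$probability))),
                 labels = signif(pretty(c(0, max(d$probability))) /
                                   max(d$probability) * max(rr), 2))
  graphics::mtext("Equivalent relative risk", side = 4, line = 2)
  invisible(x)
}

#' Plot the per-level scores of a fitted scoring system
#' @param x a [pps()] object.
#' @param ... passed to [graphics::barplot()].
#' @return `x`, invisibly.
#' @export
plot.pps <- function(x, ...) {
  s <- x$scores
  op <- graphics::par(mar = c(4, 14, 1, 1))
  on.exit(graphics::par(op))
  graphics::barplot(rev(s$final_score),
                    names.arg = rev(paste(s$factor, s$level, sep = ": ")),
                    horiz = TRUE, las = 1, xlab = "Final score",
                    cex.names = 0.6, ...)
  invisible(x)
}
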
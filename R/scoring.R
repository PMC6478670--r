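#' Scoring primitives
#'
#' The scoring construction turns a relative risk into points in three
#' steps: the raw score is the base-10 logarithm of the relative risk; the
#' population mean of the raw score (prevalence-weighted over the factor's
#' levels) is subtracted so that the factor averages to zero in the
#' population; the centered score is multiplied by a scale (default 10)
#' and rounded to a grid (default half integers).
#'
#' `round_to_half()` rounds to the nearest multiple of `grid`; exact
#' midpoints round away from zero, so e.g. 0.25 becomes 0.5 and -1.25
#' becomes -1.5 on the default grid.
#'
#' @param relative_risk positive relative risk (or odds ratio used in that
#'   role); vectorised.
#' @return `raw_score()` returns log10 of the relative risk.
#' @examples
#' raw_score(2.2)                               # 0.342
#' population_mean_raw(c(0.342, 0), c(0.736, 0.264))
#' round_to_half(0.9)                           # 1
#' @export
raw_score <- function(relative_risk) {
  if (any(!is.finite(relative_risk)) || any(relative_risk <= 0))
    stop("relative risk must be a positive finite number", call. = FALSE)
  log10(relative_risk)
}

#' @rdname raw_score
#' @param raw numeric vector of per-level raw scores.
#' @param prevalence numeric vector of per-level prevalences, summing to 1.
#' @export
population_mean_raw <- function(raw, prevalence) {
  if (length(raw) != length(prevalence))
    stop("raw scores and prevalences must have equal length", call. = FALSE)
  if (abs(sum(prevalence) - 1) > 1e-6)
    stop("prevalences must sum to 1 (got ", format(sum(prevalence)), ")",
         call. = FALSE)
  sum(prevalence * raw)
}

#' @rdname raw_score
#' @param x numeric vector to round.
#' @param grid spacing of the rounding grid (default 0.5).
#' @export
round_to_half <- function(x, grid = 0.5) {
  stopifnot(is.numeric(x), grid > 0)
  if (any(!is.finite(x))) stop("cannot round non-finite values", call. = FALSE)
  y <- abs(x) / grid
  f <- floor(y)
  frac <- y - f
  # half-away-from-zero; tolerate float error at the midpoint
  up <- frac > 0.5 | abs(frac - 0.5) < 1e-9
  sign(x) * (f + as.numeric(up)) * grid
}

#' Build a polyrisk scoring system
#'
#' `pps()` is the model-fitting entry point of the package: it takes a
#' risk-factor configuration (relative risks and population prevalences)
#' and constructs the additive scoring system.  For every level the raw
#' score is `log10(relative_risk)`; the centered score subtracts the
#' factor's prevalence-weighted mean raw score (so each factor, and hence
#' the total, has population mean zero before rounding); the final score
#' is the centered score times `scale`, rounded to the `grid`.  A total
#' score S corresponds to an equivalent relative risk of
#' `10^(S / scale)` relative to the population average.
#'
#' @param factors a [factor_table()]; defaults to the shipped prototype
#'   configuration [pps_factors()].
#' @param scale multiplier applied to centered scores (default 10).
#' @param grid rounding grid for final scores (default 0.5).
#' @return An object of class `pps` with components `scores` (data.frame
#'   of factor, level, relative_risk, prevalence, raw_score,
#'   centered_score, final_score), `factors`, `scale`, `grid`, `call`.
#'   Methods: [print.pps()], [summary.pps()], [coef.pps()],
#'   [predict.pps()], [simulate.pps()], [plot.pps()].
#' @examples
#' fit <- pps()
#' coef(fit)["Urbanicity:Yes"]
#' summary(fit)
#' @export
pps <- function(factors = pps_factors(), scale = 10, grid = 0.5) {
  stopifnot(inherits(factors, "factor_table"), scale > 0, grid > 0)
  validate_factor_table(factors)
  d <- factors$data
  d$raw_score <- raw_score(d$relative_risk)
  d$centered_score <- NA_real_
  for (f in unique(d$factor)) {
    i <- d$factor == f
    m <- population_mean_raw(d$raw_score[i], d$prevalence[i])
    d$centered_score[i] <- d$raw_score[i] - m
  }
  d$final_score <- round_to_half(scale * d$centered_score, grid = grid)
  structure(list(scores = d[, c("factor", "level", "relative_risk",
                                "prevalence", "raw_score",
                                "centered_score", "final_score")],
                 factors = factors, scale = scale, grid = grid,
                 call = match.call()),
            class = "pps")
}

#' @export
print.pps <- function(x, digits = 3, ...) {
  cat("Polyrisk scoring system (log10 relative risk, prevalence-centered,",
      "\n  scale", x$scale, ", grid", x$grid, ")\n\n")
  s <- x$scores
  for (f in unique(s$factor)) {
    rows <- s[s$factor == f, ]
    cat(f, "\n")
    for (i in seq_len(nrow(rows)))
      cat(sprintf("  %-45s %6s\n", rows$level[i],
                  format(rows$final_score[i], nsmall = 1)))
  }
  rng <- score_range(x)
  cat(sprintf("\nTotal score range: %.1f to %.1f\n", rng[1], rng[2]))
  invisible(x)
}

#' Extract the final scores of a fitted scoring system
#' @param object a [pps()] object.
#' @param ... unused.
#' @return Named numeric vector of final scores, names `"Factor:Level"`.
#' @export
coef.pps <- function(object, ...) {
  s <- object$scores
  stats::setNames(s$final_score, paste0(s$factor, ":", s$level))
}

# sum of per-factor minima and maxima of final scores
score_range <- function(object) {
  s <- object$scores
  mins <- tapply(s$final_score, s$factor, min)
  maxs <- tapply(s$final_score, s$factor, max)
  c(min = sum(mins), max = sum(maxs))
}

#' Summarise a polyrisk scoring system
#'
#' Reports per-factor score ranges, the attainable total-score range, and
#' the residual per-factor rounding bias (the prevalence-weighted mean of
#' the final scores, which the centering construction keeps within one
#' half of the rounding grid of zero).
#'
#' @param object a [pps()] object.
#' @param ... unused.
#' @return An object of class `summary.pps`, printed with its own method.
#' @export
summary.pps <- function(object, ...) {
  s <- object$scores
  per_factor <- do.call(rbind, lapply(unique(s$factor), function(f) {
    rows <- s[s$factor == f, ]
    data.frame(factor = f, n_levels = nrow(rows),
               min_score = min(rows$final_score),
               max_score = max(rows$final_score),
               rounding_bias = sum(rows$prevalence * rows$final_score),
               stringsAsFactors = FALSE)
  }))
  structure(list(per_factor = per_factor, range = score_range(object),
                 scale = object$scale, grid = object$grid),
            class = "summary.pps")
}

#' @export
print.summary.pps <- function(x, digits = 3, ...) {
  cat("Polyrisk scoring system:", nrow(x$per_factor), "factors\n\n")
  pf <- x$per_factor
  pf$rounding_bias <- round(pf$rounding_bias, digits)
  print(pf, row.names = FALSE)
  cat(sprintf("\nTotal score range: %.1f to %.1f (equivalent RR %.3g to %.3g)\n",
              x$range[1], x$range[2],
              10^(x$range[1] / x$scale), 10^(x$range[2] / x$scale)))
  invisible(x)
}

#' Invert published scores back to the implied relative risk
#'
#' Given the published final scores of the exposed and baseline levels of
#' a two-level factor, recover the relative risk implied by the
#' construction, `10^((s_present - s_absent)/scale)`, and the interval of
#' exposure prevalences consistent with both rounded scores under the
#' half-grid rounding slack.  Useful for validating a published table when
#' the underlying prevalence file is not available.
#'
#' @param score_present final score of the exposed level.
#' @param score_absent final score of the baseline level; must be smaller.
#' @param scale,grid construction parameters (defaults 10 and 0.5).
#' @return List with `implied_rr` and `prevalence_interval` (length-2
#'   numeric; the open set of prevalences reproducing both scores,
#'   intersected over the two rounding constraints).
#' @examples
#' invert_published_scores(1, -2.5)   # urbanicity: RR ~2.24, p near 0.736
#' @export
invert_published_scores <- function(score_present, score_absent,
                                    scale = 10, grid = 0.5) {
  if (!is.finite(score_present) || !is.finite(score_absent))
    stop("scores must be finite", call. = FALSE)
  if (score_present <= score_absent)
    stop("score_present must exceed score_absent (degenerate factor)",
         call. = FALSE)
  half <- grid / 2
  # s_present - s_absent = scale * log10(RR) up to two roundings of +-half
  log_rr <- (score_present - score_absent) / scale
  implied_rr <- 10^log_rr
  # s_absent = -scale * p * log10(RR) +- half  =>  p interval
  lo <- (-score_absent - half) / (scale * log_rr)
  hi <- (-score_absent + half) / (scale * log_rr)
  list(implied_rr = implied_rr,
       prevalence_interval = c(max(0, lo), min(1, hi)))
}

#' Write a fitted scoring system to disk
#'
#' @param object a [pps()] object.
#' @param path output file.
#' @param format `"csv"` (columns factor,level,raw_score,centered_score,
#'   final_score), `"json"`, or `"table2"` — a pretty-printed layout with
#'   one row per level and the final score in the last column.
#' @return `path`, invisibly.
#' @export
write_scoring_table <- function(object, path,
                                format = c("csv", "json", "table2")) {
  stopifnot(inherits(object, "pps"))
  format <- match.arg(format)
  s <- object$scores
  if (format == "csv") {
    utils::write.csv(s[, c("factor", "level", "raw_score",
                           "centered_score", "final_score")],
                     path, row.names = FALSE, fileEncoding = "UTF-8")
  } else if (format == "json") {
    jsonlite::write_json(
      list(scale = object$scale, grid = object$grid,
           scores = s[, c("factor", "level", "raw_score",
                          "centered_score", "final_score")]),
      path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  } else {
    lines <- c("Factor\tLevel\tPPS")
    for (f in unique(s$factor)) {
      rows <- s[s$factor == f, ]
      for (i in seq_len(nrow(rows)))
        lines <- c(lines, paste(if (i == 1L) f else "", rows$level[i],
                                format(rows$final_score[i], nsmall = 1),
                                sep = "\t"))
    }
    writeLines(lines, path, useBytes = TRUE)
  }
  invisible(path)
}
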
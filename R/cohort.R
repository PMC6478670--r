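#' Generate a synthetic cohort of factor profiles
#'
#' Draws `n` individuals with each factor level sampled independently from
#' its configured prevalence (or a per-factor override), then masks each
#' assignment missing independently with probability `missingness_rate`.
#' Stands in for self-administered or record-extracted factor data when
#' exercising the scoring pipeline end to end.
#'
#' @param factors a [factor_table()] (or a [pps()] object, whose
#'   configuration is used).
#' @param n number of individuals (>= 1).
#' @param seed optional integer seed; the caller's RNG state is restored.
#' @param missingness_rate probability in [0, 1) that any single
#'   assignment is masked missing.
#' @param overrides optional named list, factor name -> named numeric
#'   vector of level prevalences (summing to 1) replacing the configured
#'   ones for that factor.
#' @return data.frame with an `id` column and one character column per
#'   factor (`NA` = missing), ready for [predict.pps()].
#' @examples
#' cohort <- generate_cohort(pps_factors(), n = 5, seed = 1)
#' predict(pps(), cohort)
#' @export
generate_cohort <- function(factors, n, seed = NULL, missingness_rate = 0,
                            overrides = NULL) {
  if (inherits(factors, "pps")) factors <- factors$factors
  stopifnot(inherits(factors, "factor_table"))
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("n must be a single integer >= 1", call. = FALSE)
  n <- as.integer(n)
  if (!is.numeric(missingness_rate) || missingness_rate < 0 ||
      missingness_rate >= 1)
    stop("missingness_rate must lie in [0, 1)", call. = FALSE)
  d <- factors$data
  fnames <- unique(d$factor)
  if (!is.null(overrides)) {
    if (is.null(names(overrides)) || !all(names(overrides) %in% fnames))
      stop("overrides must be named after configured factors", call. = FALSE)
    for (f in names(overrides)) {
      ov <- overrides[[f]]
      levs <- d$level[d$factor == f]
      if (is.null(names(ov)) || !setequal(names(ov), levs))
        stop("override for factor '", f, "' must name every level",
             call. = FALSE)
      if (any(ov < 0) || abs(sum(ov) - 1) > 1e-6)
        stop("override prevalences for factor '", f, "' must be ",
             "non-negative and sum to 1", call. = FALSE)
    }
  }
  with_preserved_rng(seed, {
    cols <- lapply(fnames, function(f) {
      levs <- d$level[d$factor == f]
      prob <- if (!is.null(overrides[[f]])) unname(overrides[[f]][levs])
              else d$prevalence[d$factor == f]
      lv <- levs[sample.int(length(levs), n, replace = TRUE, prob = prob)]
      if (missingness_rate > 0)
        lv[stats::runif(n) < missingness_rate] <- NA_character_
      lv
    })
    names(cols) <- fnames
    cbind(data.frame(id = as.character(seq_len(n)),
                     stringsAsFactors = FALSE),
          as.data.frame(cols, check.names = FALSE,
                        stringsAsFactors = FALSE))
  })
}

#' Write profiles to disk
#'
#' Inverse of [read_profiles()]: CSV with one row per individual and one
#' column per factor (empty cell = missing), or JSON records.
#'
#' @param profiles data.frame as produced by [generate_cohort()].
#' @param path output file.
#' @param format `"csv"`, `"json"`, or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "csv")
    utils::write.csv(profiles, path, row.names = FALSE, na = "",
                     fileEncoding = "UTF-8")
  else
    jsonlite::write_json(profiles, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null")
  invisible(path)
}
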
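#' Convert between total scores and equivalent relative risks
#'
#' A total score S on a scoring system with scale 10 corresponds to a
#' relative risk of `10^(S/10)` against the population average, since the
#' score is an additive decomposition of log10 relative risk.  The two
#' functions are exact inverses.
#'
#' @param total_pps numeric total score(s).
#' @param scale construction scale (default 10).
#' @return `pps_to_rr()` the equivalent relative risk; `rr_to_pps()` the
#'   score equivalent of a relative risk, `scale * log10(rr)`.
#' @examples
#' pps_to_rr(5)      # ~3.16, the "RR = 3" bin edge
#' rr_to_pps(30)     # 14.77
#' @export
pps_to_rr <- function(total_pps, scale = 10) {
  stopifnot(is.numeric(total_pps), all(is.finite(total_pps)))
  10^(total_pps / scale)
}

#' @rdname pps_to_rr
#' @param rr positive relative risk(s).
#' @export
rr_to_pps <- function(rr, scale = 10) {
  if (any(!is.finite(rr)) || any(rr <= 0))
    stop("relative risk must be positive and finite", call. = FALSE)
  scale * log10(rr)
}

#' Score individual factor profiles
#'
#' Sums the final scores of each individual's assigned levels.  Profiles
#' may be incomplete; missing factors are handled by policy:
#' `"population_average"` (default) substitutes the factor's
#' prevalence-weighted mean final score — the zero-information value under
#' the centering construction, approximately 0; `"omit"` contributes 0 and
#' counts the factor in `n_missing`; `"error"` aborts.  Factors under
#' `"population_average"` are also counted in `n_missing`.
#'
#' @param object a [pps()] object.
#' @param newdata a data.frame with one column per factor (cells are level
#'   labels, `NA` or `""` = missing) and an optional `id` column, or a
#'   single named character vector / list for one individual.
#' @param missing missing-factor policy; see Details.
#' @param per_factor if `TRUE`, include one column per factor with the
#'   individual contribution.
#' @param ... unused.
#' @return data.frame with columns `id`, `total_pps`, `equivalent_rr`,
#'   `n_missing` (plus per-factor contributions if requested).
#' @examples
#' fit <- pps()
#' predict(fit, c(Urbanicity = "Yes", `Childhood trauma` = "Yes"))
#' @export
predict.pps <- function(object, newdata,
                        missing = c("population_average", "omit", "error"),
                        per_factor = FALSE, ...) {
  missing <- match.arg(missing)
  if (!is.data.frame(newdata)) {
    stopifnot(!is.null(names(newdata)))
    newdata <- as.data.frame(as.list(newdata), check.names = FALSE,
                             stringsAsFactors = FALSE)
  }
  s <- object$scores
  factors <- unique(s$factor)
  unknown <- setdiff(setdiff(names(newdata), "id"), factors)
  if (length(unknown))
    stop("unknown factor(s) in profiles: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  ids <- if (!is.null(newdata$id)) as.character(newdata$id)
         else as.character(seq_len(nrow(newdata)))

  # per-factor lookup of final scores and the population-average fill-in
  lookup <- lapply(factors, function(f) {
    rows <- s[s$factor == f, ]
    list(scores = stats::setNames(rows$final_score, rows$level),
         average = sum(rows$prevalence * rows$final_score))
  })
  names(lookup) <- factors

  n <- nrow(newdata)
  contrib <- matrix(0, n, length(factors),
                    dimnames = list(NULL, factors))
  n_missing <- integer(n)
  for (f in factors) {
    lv <- if (f %in% names(newdata)) as.character(newdata[[f]])
          else rep(NA_character_, n)
    lv[!is.na(lv) & lv == ""] <- NA_character_
    miss <- is.na(lv)
    bad <- !miss & !lv %in% names(lookup[[f]]$scores)
    if (any(bad))
      stop("unknown level '", lv[which(bad)[1]], "' for factor '", f,
           "' (individual ", ids[which(bad)[1]], ")", call. = FALSE)
    if (any(miss)) {
      if (missing == "error")
        stop("missing assignment for factor '", f, "' (individual ",
             ids[which(miss)[1]], ") under missing = \"error\"",
             call. = FALSE)
      n_missing[miss] <- n_missing[miss] + 1L
      contrib[miss, f] <- if (missing == "population_average")
        lookup[[f]]$average else 0
    }
    if (any(!miss))
      contrib[!miss, f] <- lookup[[f]]$scores[lv[!miss]]
  }
  total <- rowSums(contrib)
  out <- data.frame(id = ids, total_pps = total,
                    equivalent_rr = pps_to_rr(total, scale = object$scale),
                    n_missing = n_missing, stringsAsFactors = FALSE)
  if (per_factor)
    out <- cbind(out, as.data.frame(contrib, check.names = FALSE))
  out
}

#' Read individual profiles from disk
#'
#' CSV: one row per individual, one column per factor, cells are level
#' labels, empty cells are missing; an `id` column is optional.  JSON: an
#' array of records mapping factor name to level label.
#'
#' @param path file to read.
#' @param format `"csv"`, `"json"`, or `"auto"` (by extension).
#' @return data.frame suitable for [predict.pps()].
#' @export
read_profiles <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("profile file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "csv") {
    d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         encoding = "UTF-8", colClasses = "character")
  } else {
    recs <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (!length(recs)) stop("no profiles in ", path, call. = FALSE)
    cols <- unique(unlist(lapply(recs, names)))
    d <- as.data.frame(
      lapply(stats::setNames(cols, cols), function(cl)
        vapply(recs, function(r) as.character(r[[cl]] %||% NA_character_),
               character(1))),
      check.names = FALSE, stringsAsFactors = FALSE)
  }
  if (!nrow(d)) stop("no profiles in ", path, call. = FALSE)
  for (cl in setdiff(names(d), "id"))
    d[[cl]][!is.na(d[[cl]]) & d[[cl]] == ""] <- NA_character_
  d
}
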
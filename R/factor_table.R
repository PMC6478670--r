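#' Risk-factor configuration tables
#'
#' A factor table holds, for every risk (or protective) factor, its levels,
#' each level's relative risk and its population prevalence, together with
#' measurement metadata.  It is the single input from which a polyrisk
#' scoring system is built with [pps()].
#'
#' Each factor must have exactly one baseline (unexposed) level, its level
#' labels must be unique, and the prevalences across its levels must sum
#' to 1 (an individual holds exactly one level per factor).  Odds ratios
#' from the epidemiological literature are accepted in the relative-risk
#' role, as is conventional for rare outcomes.
#'
#' @param data data.frame with columns `factor`, `level`, `relative_risk`,
#'   `prevalence`, `baseline` (logical), and optionally `evidence_class`,
#'   `instrument`, `cutoff`.
#' @param provenance character string describing the source of the numbers.
#' @param components optional named list keyed `"<factor>::<level>"`, each
#'   element a named numeric vector of component relative risks for levels
#'   built by [build_composite_factor()].  A composite level's relative
#'   risk must equal the product of its component relative risks.
#' @return An object of class `factor_table`.
#' @seealso [read_factor_table()], [pps_factors()], [build_composite_factor()]
#' @examples
#' urb <- factor_table(data.frame(
#'   factor        = "Urbanicity",
#'   level         = c("Yes", "No"),
#'   relative_risk = c(2.2, 1),
#'   prevalence    = c(0.736, 0.264),
#'   baseline      = c(FALSE, TRUE)))
#' urb
#' @export
factor_table <- function(data, provenance = "user-supplied", components = list()) {
  stopifnot(is.data.frame(data))
  required <- c("factor", "level", "relative_risk", "prevalence", "baseline")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols))
    stop("factor table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  optional <- c("evidence_class", "instrument", "cutoff")
  for (col in optional)
    if (is.null(data[[col]])) data[[col]] <- NA_character_
  data <- data[, c(required, optional)]
  data$factor        <- as.character(data$factor)
  data$level         <- as.character(data$level)
  data$relative_risk <- as.numeric(data$relative_risk)
  data$prevalence    <- as.numeric(data$prevalence)
  data$baseline      <- as.logical(data$baseline)
  rownames(data) <- NULL
  x <- structure(list(data = data,
                      provenance = as.character(provenance)[1],
                      components = components),
                 class = "factor_table")
  validate_factor_table(x)
  x
}

# Enforces the configuration invariants; errors name the factor and rule.
validate_factor_table <- function(x, prev_tol = 1e-6) {
  d <- x$data
  if (anyNA(d$relative_risk) || any(d$relative_risk <= 0))
    stop("relative risks must be positive for all levels (factor '",
         d$factor[which(is.na(d$relative_risk) | d$relative_risk <= 0)[1]],
         "')", call. = FALSE)
  if (anyNA(d$prevalence) || any(d$prevalence < 0 | d$prevalence > 1))
    stop("prevalences must lie in [0, 1] (factor '",
         d$factor[which(is.na(d$prevalence) | d$prevalence < 0 | d$prevalence > 1)[1]],
         "')", call. = FALSE)
  if (anyDuplicated(unique(d$factor)))
    stop("factor names must be unique", call. = FALSE)
  for (f in unique(d$factor)) {
    rows <- d[d$factor == f, ]
    if (anyDuplicated(rows$level))
      stop("level labels must be unique within factor '", f, "'", call. = FALSE)
    if (abs(sum(rows$prevalence) - 1) > prev_tol)
      stop("prevalences for factor '", f, "' sum to ",
           format(sum(rows$prevalence)), ", not 1", call. = FALSE)
    if (sum(rows$baseline) != 1L)
      stop("factor '", f, "' must have exactly one baseline level",
           call. = FALSE)
  }
  for (key in names(x$components)) {
    parts <- strsplit(key, "::", fixed = TRUE)[[1]]
    row <- d[d$factor == parts[1] & d$level == parts[2], ]
    if (nrow(row) != 1L)
      stop("components entry '", key, "' does not match a configured level",
           call. = FALSE)
    if (abs(row$relative_risk - prod(x$components[[key]])) > 1e-9)
      stop("composite level '", key, "' relative risk does not equal the ",
           "product of its component relative risks", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.factor_table <- function(x, ...) {
  d <- x$data
  cat("Risk-factor table: ", length(unique(d$factor)), " factors, ",
      nrow(d), " levels\n", sep = "")
  cat("Provenance:", x$provenance, "\n\n")
  print(d[, c("factor", "level", "relative_risk", "prevalence", "baseline")],
        row.names = FALSE, ...)
  invisible(x)
}

#' Number of factors in a factor table
#' @param x a `factor_table`.
#' @return integer count of factors.
#' @export
n_factors <- function(x) {
  stopifnot(inherits(x, "factor_table"))
  length(unique(x$data$factor))
}

#' Read and write factor tables
#'
#' The CSV interchange format has one row per factor level with columns
#' `factor,level,relative_risk,prevalence,baseline,evidence_class,
#' instrument,cutoff` (header mandatory, UTF-8).  The JSON format nests
#' levels inside factors and additionally preserves composite-component
#' metadata; both round-trip losslessly through [write_factor_table()].
#'
#' @param path file to read or write.
#' @param format `"csv"`, `"json"`, or `"auto"` (by file extension).
#' @return `read_factor_table()` returns a validated [factor_table()];
#'   `write_factor_table()` returns `path` invisibly.
#' @export
read_factor_table <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("factor table file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "csv") {
    d <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE,
                                  encoding = "UTF-8"),
                  error = function(e) stop("cannot parse '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
    d$baseline <- parse_flag(d$baseline, path)
    return(factor_table(d, provenance = paste0("file:", basename(path))))
  }
  j <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                error = function(e) stop("cannot parse '", path, "': ",
                                         conditionMessage(e), call. = FALSE))
  if (is.null(j$factors))
    stop("JSON factor table must have a top-level 'factors' key (", path, ")",
         call. = FALSE)
  rows <- list(); components <- list()
  for (f in j$factors) {
    if (is.null(f$name) || is.null(f$levels))
      stop("each JSON factor needs 'name' and 'levels' keys (", path, ")",
           call. = FALSE)
    for (lv in f$levels) {
      rows[[length(rows) + 1L]] <- data.frame(
        factor         = f$name,
        level          = lv$label,
        relative_risk  = as.numeric(lv$relative_risk),
        prevalence     = as.numeric(lv$prevalence),
        baseline       = isTRUE(lv$baseline),
        evidence_class = lv$evidence_class %||% NA_character_,
        instrument     = f$instrument %||% NA_character_,
        cutoff         = f$cutoff %||% NA_character_,
        stringsAsFactors = FALSE)
      if (!is.null(lv$components))
        components[[paste0(f$name, "::", lv$label)]] <-
          unlist(lv$components)
    }
  }
  factor_table(do.call(rbind, rows),
               provenance = j$provenance %||% paste0("file:", basename(path)),
               components = components)
}

#' @rdname read_factor_table
#' @param x a `factor_table`.
#' @export
write_factor_table <- function(x, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(x, "factor_table"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "csv") {
    utils::write.csv(x$data, path, row.names = FALSE, fileEncoding = "UTF-8")
    return(invisible(path))
  }
  factors <- lapply(unique(x$data$factor), function(f) {
    rows <- x$data[x$data$factor == f, ]
    levels <- lapply(seq_len(nrow(rows)), function(i) {
      lv <- list(label = rows$level[i],
                 relative_risk = rows$relative_risk[i],
                 prevalence = rows$prevalence[i],
                 baseline = rows$baseline[i],
                 evidence_class = rows$evidence_class[i])
      key <- paste0(f, "::", rows$level[i])
      if (!is.null(x$components[[key]]))
        lv$components <- as.list(x$components[[key]])
      lv
    })
    list(name = f, instrument = rows$instrument[1], cutoff = rows$cutoff[1],
         levels = levels)
  })
  jsonlite::write_json(list(provenance = x$provenance, factors = factors),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

parse_flag <- function(v, path) {
  if (is.logical(v)) return(v)
  out <- tolower(trimws(as.character(v))) %in% c("true", "t", "1", "yes")
  bad <- !tolower(trimws(as.character(v))) %in%
    c("true", "t", "1", "yes", "false", "f", "0", "no")
  if (any(bad))
    stop("cannot parse baseline flag '", v[which(bad)[1]], "' in ", path,
         call. = FALSE)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Combine logically dependent factors into one composite factor
#'
#' Several epidemiological exposures are not independent dimensions: an
#' immigrant cannot be both first- and second-generation, and an ethnic
#' density stratum only applies to minority-ethnicity individuals.  This
#' builder crosses a set of component factors, drops inadmissible
#' combinations, optionally collapses combinations in which some components
#' are not applicable, and assigns each remaining level the product of its
#' component relative risks together with a supplied joint prevalence.
#' On the log scale the composite risk is therefore the sum of the
#' component log relative risks.
#'
#' @param name name of the resulting factor.
#' @param components named list; each element a data.frame with columns
#'   `label` and `relative_risk` giving the levels of one component.
#' @param joint data.frame with one column per component (matching
#'   `names(components)`) plus a `prevalence` column; one row per admissible
#'   combination.  An `NA` in a component column marks that component as
#'   not applicable for the row (its relative risk contributes 1); such
#'   rows must be declared through `collapse`.
#' @param exclude optional list of named character vectors; any full
#'   combination matching all entries of a vector is inadmissible.
#' @param collapse optional list of named character vectors; all
#'   combinations matching a vector are merged into a single level defined
#'   by the vector's components alone (e.g. a reference ethnicity that is
#'   not stratified by ethnic density).
#' @param baseline label (after collapsing) of the baseline level.
#' @param sep separator used to build combined level labels.
#' @return A one-factor [factor_table()] whose `components` metadata records
#'   the per-level component relative risks.
#' @examples
#' imm <- build_composite_factor(
#'   "Immigration",
#'   components = list(
#'     generation = data.frame(label = c("Not immigrant", "1st generation",
#'                                       "2nd generation"),
#'                             relative_risk = c(1, 1.78, 1.58)),
#'     origin     = data.frame(label = c("North Africa", "Other regions"),
#'                             relative_risk = c(1.26, 1))),
#'   joint = data.frame(
#'     generation = c("Not immigrant", "1st generation", "1st generation",
#'                    "2nd generation", "2nd generation"),
#'     origin     = c(NA, "North Africa", "Other regions",
#'                    "North Africa", "Other regions"),
#'     prevalence = c(0.8, 0.025, 0.075, 0.025, 0.075)),
#'   collapse = list(c(generation = "Not immigrant")),
#'   baseline = "Not immigrant")
#' @export
build_composite_factor <- function(name, components, joint,
                                   exclude = NULL, collapse = NULL,
                                   baseline, sep = ", ") {
  stopifnot(is.list(components), length(components) >= 1L,
            !is.null(names(components)), is.data.frame(joint))
  comp_names <- names(components)
  for (cn in comp_names) {
    comp <- components[[cn]]
    if (!all(c("label", "relative_risk") %in% names(comp)))
      stop("component '", cn, "' needs columns label and relative_risk",
           call. = FALSE)
  }
  all_labels <- unlist(lapply(components, function(c) c$label))
  if (anyDuplicated(all_labels))
    stop("component level labels overlap across components: ",
         paste(unique(all_labels[duplicated(all_labels)]), collapse = ", "),
         call. = FALSE)
  if (!all(comp_names %in% names(joint)))
    stop("joint prevalence table must have one column per component",
         call. = FALSE)
  if (is.null(joint$prevalence))
    stop("joint prevalence table needs a 'prevalence' column", call. = FALSE)

  # admissible set: full crossing, minus exclusions, with collapse patterns
  # replacing every combination they match by one collapsed row
  grid <- expand.grid(lapply(components, function(c) c$label),
                      stringsAsFactors = FALSE)
  names(grid) <- comp_names
  matches <- function(row, pattern)
    all(vapply(names(pattern),
               function(k) identical(unname(row[[k]]), unname(pattern[[k]])),
               logical(1)))
  if (length(exclude))
    grid <- grid[!vapply(seq_len(nrow(grid)), function(i)
      any(vapply(exclude, function(p) matches(grid[i, , drop = FALSE], p),
                 logical(1))), logical(1)), , drop = FALSE]
  admissible <- grid
  if (length(collapse)) {
    keep <- rep(TRUE, nrow(admissible))
    collapsed_rows <- list()
    for (p in collapse) {
      hit <- vapply(seq_len(nrow(admissible)), function(i)
        matches(admissible[i, , drop = FALSE], p), logical(1))
      if (!any(hit)) next
      keep <- keep & !hit
      row <- as.list(rep(NA_character_, length(comp_names)))
      names(row) <- comp_names
      row[names(p)] <- unname(p)
      collapsed_rows[[length(collapsed_rows) + 1L]] <-
        as.data.frame(row, stringsAsFactors = FALSE)
    }
    admissible <- rbind(admissible[keep, , drop = FALSE],
                        do.call(rbind, collapsed_rows))
  }
  key_of <- function(d) apply(d[, comp_names, drop = FALSE], 1L, function(r)
    paste(ifelse(is.na(r), "<NA>", r), collapse = "\r"))
  adm_keys <- key_of(admissible)
  joint_keys <- key_of(joint)
  if (anyDuplicated(joint_keys))
    stop("duplicate combination in joint prevalences for '", name, "'",
         call. = FALSE)
  extra <- setdiff(joint_keys, adm_keys)
  if (length(extra))
    stop("joint prevalence supplied for inadmissible combination in '",
         name, "': ", gsub("\r", " x ", extra[1]), call. = FALSE)
  miss <- setdiff(adm_keys, joint_keys)
  if (length(miss))
    stop("joint prevalence missing for admissible combination in '",
         name, "': ", gsub("\r", " x ", miss[1]), call. = FALSE)
  joint <- joint[match(adm_keys, joint_keys), , drop = FALSE]

  rr_lookup <- function(cn, label) {
    if (is.na(label)) return(1)
    comp <- components[[cn]]
    comp$relative_risk[match(label, comp$label)]
  }
  labels <- character(nrow(joint)); rrs <- numeric(nrow(joint))
  comp_meta <- list()
  for (i in seq_len(nrow(joint))) {
    labs <- unlist(joint[i, comp_names, drop = FALSE])
    present <- !is.na(labs)
    labels[i] <- paste(labs[present], collapse = sep)
    parts <- vapply(comp_names[present], function(cn) rr_lookup(cn, joint[[cn]][i]),
                    numeric(1))
    names(parts) <- labs[present]
    rrs[i] <- prod(parts)
    comp_meta[[paste0(name, "::", labels[i])]] <- parts
  }
  d <- data.frame(factor = name, level = labels, relative_risk = rrs,
                  prevalence = joint$prevalence,
                  baseline = labels == baseline,
                  stringsAsFactors = FALSE)
  if (sum(d$baseline) != 1L)
    stop("baseline label '", baseline, "' does not match exactly one ",
         "composite level of '", name, "'", call. = FALSE)
  factor_table(d, provenance = paste0("composite:", name),
               components = comp_meta)
}

#' Check whether an individual profile can be scored against a table
#'
#' Diagnostic helper: returns a character vector of problems (unknown
#' factors, unknown level labels).  An empty result means every assignment
#' in the profile is scoreable.  Missing factors are not problems; the
#' scorer handles them according to its missing-data policy.
#'
#' @param table a [factor_table()] or [pps()] object.
#' @param profile named list or named character vector mapping factor name
#'   to level label (NAs ignored).
#' @return character vector of problem descriptions (possibly empty).
#' @export
validate_profile_support <- function(table, profile) {
  d <- if (inherits(table, "pps")) table$factors$data else table$data
  stopifnot(!is.null(names(profile)))
  problems <- character(0)
  for (f in names(profile)) {
    lev <- profile[[f]]
    if (is.na(lev)) next
    if (!f %in% d$factor) {
      problems <- c(problems, paste0("unknown factor: ", f))
      next
    }
    if (!lev %in% d$level[d$factor == f])
      problems <- c(problems,
                    paste0("unknown level '", lev, "' for factor '", f, "'"))
  }
  problems
}
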
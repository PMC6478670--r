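test_that("factor table validation rejects malformed configurations", {
  base <- data.frame(factor = "F", level = c("a", "b"),
                     relative_risk = c(2, 1), prevalence = c(0.3, 0.7),
                     baseline = c(FALSE, TRUE))
  expect_s3_class(factor_table(base), "factor_table")

  bad <- base; bad$prevalence <- c(0.3, 0.6)
  expect_error(factor_table(bad), "sum to 0\\.9")
  expect_error(factor_table(bad), "'F'")

  bad <- base; bad$level <- c("a", "a")
  expect_error(factor_table(bad), "unique within factor")

  bad <- base; bad$baseline <- c(FALSE, FALSE)
  expect_error(factor_table(bad), "exactly one baseline")

  bad <- base; bad$relative_risk <- c(-2, 1)
  expect_error(factor_table(bad), "positive")

  bad <- base; bad$prevalence <- c(1.3, -0.3)
  expect_error(factor_table(bad), "\\[0, 1\\]")

  expect_error(factor_table(base[, -3]), "missing required column")
})

test_that("CSV and JSON factor tables round-trip losslessly", {
  tab <- pps_factors()
  for (fmt in c("csv", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_factor_table(tab, path)
    back <- read_factor_table(path)
    expect_equal(back$data$factor, tab$data$factor)
    expect_equal(back$data$level, tab$data$level)
    expect_equal(back$data$relative_risk, tab$data$relative_risk)
    expect_equal(back$data$prevalence, tab$data$prevalence)
    expect_equal(back$data$baseline, tab$data$baseline)
  }
  # JSON additionally preserves composite-component metadata
  path <- withr::local_tempfile(fileext = ".json")
  write_factor_table(tab, path)
  back <- read_factor_table(path)
  expect_setequal(names(back$components), names(tab$components))
})

test_that("single-factor file loads as a one-factor two-level table", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("factor,level,relative_risk,prevalence,baseline",
               "Urbanicity,Yes,2.2,0.736,FALSE",
               "Urbanicity,No,1,0.264,TRUE"), path)
  tab <- read_factor_table(path)
  expect_equal(n_factors(tab), 1L)
  expect_equal(nrow(tab$data), 2L)
  expect_equal(tab$data$relative_risk[tab$data$level == "Yes"], 2.2)
})

test_that("loading a file with bad prevalences names the violated rule", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("factor,level,relative_risk,prevalence,baseline",
               "Urbanicity,Yes,2.2,0.7,FALSE",
               "Urbanicity,No,1,0.2,TRUE"), path)
  expect_error(read_factor_table(path), "Urbanicity.*sum")
  expect_error(read_factor_table("no/such/file.csv"), "not found")
})

test_that("shipped default configuration has the published row structure", {
  tab <- pps_factors()
  expect_equal(n_factors(tab), 8L)
  counts <- table(tab$data$factor)
  expect_equal(sort(as.integer(counts)), sort(c(2L, 7L, 5L, 2L, 2L, 2L, 2L, 2L)))
  expect_equal(unname(counts[["Ethnicity"]]), 7L)
  expect_equal(unname(counts[["Immigration"]]), 5L)
  # per-factor prevalences sum to 1
  sums <- tapply(tab$data$prevalence, tab$data$factor, sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  # shipped extdata copy matches the in-code constructor
  shipped <- read_factor_table(
    system.file("extdata", "pps_factors.csv", package = "polyrisk"))
  expect_equal(shipped$data$relative_risk, tab$data$relative_risk)
  expect_equal(shipped$data$prevalence, tab$data$prevalence)
})

test_that("composite factors multiply component risks and keep mass 1", {
  tab <- pps_factors()
  d <- tab$data
  for (key in names(tab$components)) {
    parts <- strsplit(key, "::", fixed = TRUE)[[1]]
    rr <- d$relative_risk[d$factor == parts[1] & d$level == parts[2]]
    # log-additivity of the composite
    expect_equal(log10(rr), sum(log10(tab$components[[key]])),
                 tolerance = 1e-12)
  }
  expect_equal(sum(d$prevalence[d$factor == "Ethnicity"]), 1, tolerance = 1e-12)
  expect_equal(sum(d$prevalence[d$factor == "Immigration"]), 1,
               tolerance = 1e-12)
})

test_that("composite builder handles collapse, exclusion and errors", {
  comp <- list(
    gen = data.frame(label = c("none", "first", "second"),
                     relative_risk = c(1, 1.8, 1.6)),
    origin = data.frame(label = c("NA region", "other"),
                        relative_risk = c(1.3, 1)))
  joint <- data.frame(
    gen = c("none", "first", "first", "second", "second"),
    origin = c(NA, "NA region", "other", "NA region", "other"),
    prevalence = c(0.8, 0.02, 0.08, 0.02, 0.08))
  f <- build_composite_factor("Migration", comp, joint,
                              collapse = list(c(gen = "none")),
                              baseline = "none")
  expect_equal(nrow(f$data), 5L)
  expect_equal(f$data$relative_risk[f$data$level == "first, NA region"],
               1.8 * 1.3, tolerance = 1e-12)
  expect_equal(sum(f$data$prevalence), 1)

  # missing admissible combination
  expect_error(
    build_composite_factor("Migration", comp, joint[-2, ],
                           collapse = list(c(gen = "none")),
                           baseline = "none"),
    "missing for admissible combination")
  # prevalence supplied for an excluded combination
  joint2 <- joint; joint2$gen[1] <- "none"; joint2$origin[1] <- "other"
  expect_error(
    build_composite_factor("Migration", comp, joint2,
                           exclude = list(c(gen = "none", origin = "other"),
                                          c(gen = "none", origin = "NA region")),
                           baseline = "first, NA region"),
    "inadmissible combination")
  # overlapping component labels
  comp2 <- comp; comp2$origin$label <- c("none", "other2")
  expect_error(build_composite_factor("X", comp2, joint, baseline = "none"),
               "overlap")
})

test_that("single-component composite passes through unchanged", {
  comp <- list(only = data.frame(label = c("Yes", "No"),
                                 relative_risk = c(2.2, 1)))
  joint <- data.frame(only = c("Yes", "No"), prevalence = c(0.736, 0.264))
  f <- build_composite_factor("Urbanicity", comp, joint, baseline = "No")
  u <- urbanicity_table()
  expect_equal(f$data$relative_risk[match(u$data$level, f$data$level)],
               u$data$relative_risk)
  expect_equal(f$data$prevalence[match(u$data$level, f$data$level)],
               u$data$prevalence)
})

test_that("profile support diagnostics name unknown factors and levels", {
  tab <- pps_factors()
  expect_equal(validate_profile_support(tab, c("Childhood trauma" = "Yes")),
               character(0))
  expect_match(validate_profile_support(tab, c(Diet = "Vegan")),
               "unknown factor: Diet")
  expect_match(validate_profile_support(tab, c(Urbanicity = "Maybe")),
               "unknown level 'Maybe'")
  both <- validate_profile_support(
    tab, list(Diet = "Vegan", Urbanicity = "Maybe", "Premorbid IQ" = "<93.6"))
  expect_length(both, 2L)
})
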
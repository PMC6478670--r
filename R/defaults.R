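#' Default factor configuration for the Psychosis Polyrisk Score prototype
#'
#' Eight factor groups: childhood trauma, ethnicity (crossed with ethnic
#' density), immigration (generation crossed with region of origin),
#' premorbid IQ, non-right-handedness, impaired olfactory identification,
#' Clinical High Risk state for Psychosis (PQ-16), and urbanicity.
#' Relative risks come from umbrella-review evidence; protective odds
#' ratios (olfactory identification 0.19, premorbid IQ 0.47) are
#' re-oriented so the scored level is the risk-increasing direction
#' (RR = 1/OR for the impaired level).
#'
#' Only the urbanicity prevalence (73.6% urban) is an externally reported
#' population value.  The remaining prevalences, and the component relative
#' risks of the two composite factors, are approximate: they are
#' reverse-engineered from the published half-integer scores under the
#' centering construction (a baseline score of s at relative risk RR pins
#' the exposure prevalence to a narrow interval around
#' -s / (10 log10 RR)), with plausibility arguments breaking the remaining
#' slack.  The provenance string flags this.  Supplying measured
#' prevalences through [factor_table()] replaces them wholesale.
#'
#' @return A validated [factor_table()] with 8 factors and 24 levels.
#' @examples
#' tab <- pps_factors()
#' n_factors(tab)
#' @export
pps_factors <- function() {
  binary <- function(factor, yes, no, rr, p_yes, evidence_class,
                     instrument, cutoff) {
    factor_table(data.frame(
      factor = factor, level = c(yes, no),
      relative_risk = c(rr, 1), prevalence = c(p_yes, 1 - p_yes),
      baseline = c(FALSE, TRUE),
      evidence_class = evidence_class,
      instrument = instrument, cutoff = cutoff,
      stringsAsFactors = FALSE))
  }

  trauma <- binary("Childhood trauma", "Yes", "No",
                   rr = 2.87, p_yes = 0.109, evidence_class = "III",
                   instrument = "Childhood trauma questionnaire",
                   cutoff = "Moderate to severe")

  density <- data.frame(
    label = c("Low ethnic density area", "Medium ethnic density area",
              "High ethnic density area"),
    relative_risk = 10^c(0.25, 0.20, 0))
  ethnicity <- build_composite_factor(
    "Ethnicity",
    components = list(
      ethnicity = data.frame(
        label = c("White", "Black Caribbean", "Other non-white"),
        relative_risk = 10^c(0, 0.55, 0.30)),
      density = density),
    joint = data.frame(
      ethnicity = c("White",
                    rep(c("Black Caribbean", "Other non-white"), each = 3)),
      density   = c(NA, rep(density$label, 2)),
      prevalence = c(0.60,
                     0.40 * 0.20 * c(0.2, 0.5, 0.3),
                     0.40 * 0.80 * c(0.2, 0.5, 0.3))),
    collapse = list(c(ethnicity = "White")),
    baseline = "White")
  ethnicity$data$evidence_class <- "I"
  ethnicity$data$instrument <- "Self-defined"
  ethnicity$data$cutoff <- "Non-white ethnicity"

  immigration <- build_composite_factor(
    "Immigration",
    components = list(
      generation = data.frame(
        label = c("Not immigrant", "1st generation immigrant",
                  "2nd generation immigrant"),
        relative_risk = 10^c(0, 0.25, 0.20)),
      origin = data.frame(
        label = c("From North Africa", "From other regions"),
        relative_risk = 10^c(0.10, 0))),
    joint = data.frame(
      generation = c("Not immigrant",
                     rep(c("1st generation immigrant",
                           "2nd generation immigrant"), each = 2)),
      origin = c(NA, rep(c("From North Africa", "From other regions"), 2)),
      prevalence = c(0.80, 0.025, 0.075, 0.025, 0.075)),
    collapse = list(c(generation = "Not immigrant")),
    baseline = "Not immigrant")
  immigration$data$evidence_class <- "II"
  immigration$data$instrument <- "Self-defined"
  immigration$data$cutoff <- "First- or second-generation"

  iq <- binary("Premorbid IQ", "<93.6", ">93.6",
               rr = 1 / 0.47, p_yes = 0.335, evidence_class = "II",
               instrument = "National adult reading test", cutoff = "<93.6")

  handedness <- binary("Non-right handedness", "Yes", "No",
                       rr = 1.58, p_yes = 0.10, evidence_class = "III",
                       instrument = "Self-defined",
                       cutoff = "Non-right handedness")

  olfaction <- binary("Olfactory identification impairment", "Yes", "No",
                      rr = 1 / 0.19, p_yes = 0.22, evidence_class = "II",
                      instrument = "University of Pennsylvania smell identification test",
                      cutoff = "Mild microsmia")

  chrp <- binary("Clinical high risk state for psychosis", ">9", "<9",
                 rr = 9.32, p_yes = 0.14, evidence_class = "I",
                 instrument = "Prodromal questionnaire (16-item version)",
                 cutoff = ">9")

  urbanicity <- binary("Urbanicity", "Yes", "No",
                       rr = 2.2, p_yes = 0.736, evidence_class = "I",
                       instrument = "Population density of local authority",
                       cutoff = "Urban center of at least 50,000 inhabitants")

  pieces <- list(trauma, ethnicity, immigration, iq, handedness,
                 olfaction, chrp, urbanicity)
  factor_table(
    do.call(rbind, lapply(pieces, function(p) p$data)),
    provenance = paste(
      "PPS prototype defaults; urbanicity prevalence is a reported",
      "population value, remaining prevalences and composite component",
      "relative risks are approximate (reverse-engineered from the",
      "published half-integer scores)"),
    components = do.call(c, lapply(pieces, function(p) p$components)))
}
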
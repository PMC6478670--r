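# Small factor tables built in code for unit tests.

urbanicity_table <- function() {
  factor_table(data.frame(
    factor = "Urbanicity", level = c("Yes", "No"),
    relative_risk = c(2.2, 1), prevalence = c(0.736, 0.264),
    baseline = c(FALSE, TRUE)))
}

trauma_urbanicity_table <- function() {
  factor_table(data.frame(
    factor = rep(c("Urbanicity", "Childhood trauma"), each = 2),
    level = c("Yes", "No", "Yes", "No"),
    relative_risk = c(2.2, 1, 2.87, 1),
    prevalence = c(0.736, 0.264, 0.109, 0.891),
    baseline = c(FALSE, TRUE, FALSE, TRUE)))
}

flat_table <- function() {
  factor_table(data.frame(
    factor = rep("Anything", 3), level = c("a", "b", "c"),
    relative_risk = 1, prevalence = c(0.2, 0.3, 0.5),
    baseline = c(TRUE, FALSE, FALSE)))
}

# the Table-2 scoring system: factor -> level -> final score
published_scores <- function() {
  list(
    "Childhood trauma" = c(Yes = 4, No = -0.5),
    "Ethnicity" = c(
      "White" = -2,
      "Black Caribbean, Low ethnic density area" = 6,
      "Black Caribbean, Medium ethnic density area" = 5.5,
      "Black Caribbean, High ethnic density area" = 3.5,
      "Other non-white, Low ethnic density area" = 3.5,
      "Other non-white, Medium ethnic density area" = 3,
      "Other non-white, High ethnic density area" = 1),
    "Immigration" = c(
      "Not immigrant" = -0.5,
      "1st generation immigrant, From North Africa" = 3,
      "1st generation immigrant, From other regions" = 2,
      "2nd generation immigrant, From North Africa" = 2.5,
      "2nd generation immigrant, From other regions" = 1.5),
    "Premorbid IQ" = c("<93.6" = 2, ">93.6" = -1),
    "Non-right handedness" = c(Yes = 2, No = 0),
    "Olfactory identification impairment" = c(Yes = 5.5, No = -1.5),
    "Clinical high risk state for psychosis" = c(">9" = 8.5, "<9" = -1.5),
    "Urbanicity" = c(Yes = 1, No = -2.5))
}

# profile hitting the named element of each factor's published scores
profile_at <- function(pick = c("max", "min")) {
  pick <- match.arg(pick)
  pub <- published_scores()
  out <- vapply(pub, function(sc)
    names(sc)[if (pick == "max") which.max(sc) else which.min(sc)],
    character(1))
  stats::setNames(out, names(pub))
}
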
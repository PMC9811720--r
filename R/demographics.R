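#' @name demographics
#' @title Age and gender extraction for patient-case retrieval
#' @description Patient cases and MEDLINE abstracts carry demographic
#'   evidence as free text ("a 38-year-old male presented with ...") or as
#'   MeSH check-tags ("Middle Aged", "Female"). These helpers extract an age
#'   in years and a gender, and map the age onto the standard demographic
#'   categories used for retrieval.
NULL

AGE_CATEGORIES <- c("Fetus", "Newborn", "Infant", "Preschool", "Child",
                    "Adolescent", "Young", "Middle age", "Aged", "Aged 80",
                    "Adult", "Unknown")

# lower bounds of the half-open age intervals, in years
AGE_BREAKS <- c(Newborn = 0, Infant = 1 / 12, Preschool = 2, Child = 6,
                Adolescent = 13, Young = 19, `Middle age` = 35, Aged = 60,
                `Aged 80` = 80)

#' Extract an age (in years) from free text
#'
#' Matches the first age expression of the forms "N-year(s)-old",
#' "N year(s) old", and the month/week variants ("18-month-old",
#' "3 weeks old"); months and weeks are converted to fractional years.
#'
#' @param text character scalar.
#' @return age in years (numeric) or `NA_real_` when no expression matches.
#' @export
#' @examples
#' extract_age("38-year-old male")     # 38
#' extract_age("a 18-month-old infant")  # 1.5
extract_age <- function(text) {
  if (is.na(text) || !nzchar(text)) return(NA_real_)
  pat <- "(\\d+(?:\\.\\d+)?)[- ]?(year|month|week)s?[- ]?old"
  m <- regmatches(text, regexpr(pat, text, ignore.case = TRUE, perl = TRUE))
  if (length(m) == 0L) return(NA_real_)
  parts <- regmatches(m, regexec(pat, m, ignore.case = TRUE, perl = TRUE))[[1]]
  value <- as.numeric(parts[2])
  unit <- tolower(parts[3])
  switch(unit, year = value, month = value / 12, week = value / 52.1775)
}

#' Classify an age in years into a demographic category
#'
#' The category intervals are half-open `[lower, upper)` so every
#' non-negative age falls in exactly one category: Newborn `[0, 1/12)`,
#' Infant `[1/12, 2)`, Preschool `[2, 6)`, Child `[6, 13)`, Adolescent
#' `[13, 19)`, Young `[19, 35)`, Middle age `[35, 60)`, Aged `[60, 80)`,
#' Aged 80 `[80, Inf)`. A shared endpoint belongs to the upper category
#' (age 60 is "Aged"). "Fetus" and "Adult" are textual categories (see
#' [parse_demographic()]) and are never produced from a numeric age.
#'
#' @param age_years non-negative numeric.
#' @return category string.
#' @export
classify_age <- function(age_years) {
  if (is.na(age_years)) return("Unknown")
  if (age_years < 0) stop("age must be non-negative")
  names(AGE_BREAKS)[findInterval(age_years, AGE_BREAKS)]
}

GENDER_LEXICON <- list(
  Female = c("female", "woman", "girl"),
  Male = c("male", "man", "boy"))

# Minimal stemming for the gender vocabulary: fold plurals (women -> woman,
# men -> man, trailing -s) onto the lexicon stems. Token-level matching, so
# "human" never matches "man".
stem_gender_token <- function(tok) {
  if (tok == "women") return("woman")
  if (tok == "men") return("man")
  sub("s$", "", tok)
}

#' Extract a gender mention from free text
#'
#' Stem-matches tokens against the gender vocabulary (female/woman/girl,
#' male/man/boy, plus plurals). When both genders are mentioned the gender of
#' the first occurrence wins.
#'
#' @param text character scalar.
#' @return `"Female"`, `"Male"`, or `"Unknown"`.
#' @export
extract_gender <- function(text) {
  toks <- tokenize(text)
  if (length(toks) == 0L) return("Unknown")
  stems <- vapply(toks, stem_gender_token, "")
  for (s in stems) {
    if (s %in% GENDER_LEXICON$Female) return("Female")
    if (s %in% GENDER_LEXICON$Male) return("Male")
  }
  "Unknown"
}

#' Parse a demographic phrase into an age category and gender
#'
#' Used both for topic demographics ("38-year-old male") and abstract text.
#' Numeric ages take precedence; the literal tokens "fetus" and "adult" map
#' to their categories only when no numeric age is present (a numeric age
#' always has a finer category than "Adult").
#'
#' @param text character scalar.
#' @return list with `age_years`, `age_category`, `gender`.
#' @export
parse_demographic <- function(text) {
  age <- extract_age(text)
  cat <- classify_age(age)
  if (is.na(age)) {
    toks <- tokenize(text)
    if ("fetus" %in% toks) cat <- "Fetus"
    else if ("adult" %in% toks || "adults" %in% toks) cat <- "Adult"
  }
  list(age_years = age, age_category = cat, gender = extract_gender(text))
}

#' Default MeSH check-tag to demographic category map
#'
#' Loads the mapping shipped with the package (MEDLINE check-tags such as
#' "Middle Aged", "Aged, 80 and over", "Female" mapped to age categories and
#' genders). Users can supply their own table of the same shape.
#'
#' @param path optional path to a JSON map
#'   `{"Heading": {"age_category": ..., "gender": ...}, ...}`.
#' @return named list of lists.
#' @export
default_mesh_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "mesh_demographics.json",
                        package = "pmretrieve")
  }
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

#' Demographic profile of a document
#'
#' Extracts age and gender from the abstract with regex/stem matching first;
#' any attribute still missing falls back to the document's MeSH headings via
#' `mesh_map`; anything still missing is Unknown. The `source` field records
#' where the profile's evidence came from.
#'
#' @param doc a [document()].
#' @param mesh_map a map as returned by [default_mesh_map()].
#' @return list with `age_years`, `age_category`, `gender`, `source`
#'   (one of `"abstract_regex"`, `"mesh_fallback"`, `"none"`).
#' @export
demographic_profile <- function(doc, mesh_map = default_mesh_map()) {
  prof <- parse_demographic(doc$abstract)
  source <- if (prof$age_category != "Unknown" || prof$gender != "Unknown") {
    "abstract_regex"
  } else {
    "none"
  }
  if (prof$age_category == "Unknown" || prof$gender == "Unknown") {
    hits <- mesh_map[names(mesh_map) %in% doc$mesh_headings]
    for (h in hits) {
      if (prof$age_category == "Unknown" && !is.null(h$age_category)) {
        prof$age_category <- h$age_category
        if (source == "none") source <- "mesh_fallback"
      }
      if (prof$gender == "Unknown" && !is.null(h$gender)) {
        prof$gender <- h$gender
        if (source == "none") source <- "mesh_fallback"
      }
    }
  }
  list(age_years = prof$age_years, age_category = prof$age_category,
       gender = prof$gender, source = source)
}
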
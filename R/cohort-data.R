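#' Analysis variables derived from a pregnancy notification form
#'
#' Returns the coding scheme applied to raw questionnaire responses before
#' any regression: one entry per analysis variable, with its category labels
#' ordered so that the reference category comes first. Maternal age is banded
#' into `<20`, `20-24`, `25-39` (reference) and `>=40`; gestational weeks at
#' registration become the binary `late_registration` item (12 weeks or later
#' counts as late); the six raw "feeling at pregnancy" responses are pooled
#' into `happy`, `unexpected_happy` and `unexpected_other`. All other items
#' pass through with their questionnaire categories.
#'
#' Two flavours of missingness are kept distinct throughout: `not_answered`
#' (the respondent left the item blank) and `not_investigated` (the
#' municipality never digitized the item, so it is structurally missing for
#' every record from that municipality).
#'
#' @return A named list; each element has `categories` (character, reference
#'   first) and `source` (the raw cohort column the variable is derived from).
#' @export
coded_variables <- function() {
  v <- function(source, categories) list(source = source, categories = categories)
  list(
    marital_status = v("marital_status",
      c("married", "unmarried", "not_answered", "not_investigated")),
    maternal_age = v("maternal_age_years",
      c("25-39", "<20", "20-24", ">=40")),
    late_registration = v("gestational_weeks_at_registration",
      c("no", "yes", "not_answered")),
    pregnancy_progress = v("pregnancy_progress",
      c("good", "not_good", "not_answered", "not_investigated")),
    birth_order = v("birth_order",
      c("subsequent", "first", "not_answered")),
    abortion_history = v("abortion_history",
      c("no", "yes", "not_answered")),
    infertility_treatment = v("infertility_treatment",
      c("no", "yes", "not_answered", "not_investigated")),
    feeling_at_pregnancy = v("feeling_at_pregnancy",
      c("happy", "unexpected_happy", "unexpected_other", "not_answered")),
    return_to_parents_home = v("return_to_parents_home",
      c("yes", "no", "not_answered", "not_investigated")),
    has_helper = v("has_helper",
      c("yes", "no", "not_answered")),
    worries_anxiety = v("worries_anxiety",
      c("no", "yes", "not_answered", "not_investigated")),
    smoking = v("smoking",
      c("no", "stopped_after_confirmation", "yes", "not_answered")),
    passive_smoking = v("passive_smoking",
      c("no", "yes", "not_answered", "not_investigated")),
    alcohol = v("alcohol",
      c("no", "yes", "not_answered")),
    disease_history = v("disease_history",
      c("no", "yes", "not_answered", "not_investigated")),
    mental_illness_history = v("mental_illness_history",
      c("no", "yes", "not_answered", "not_investigated")),
    depressive_symptoms = v("depressive_symptoms",
      c("no", "yes", "not_answered"))
  )
}

# raw enum labels accepted for each pass-through questionnaire item
raw_enum_levels <- function() {
  list(
    marital_status = c("married", "unmarried", "not_answered", "not_investigated"),
    pregnancy_progress = c("good", "not_good", "not_answered", "not_investigated"),
    birth_order = c("first", "subsequent", "not_answered"),
    abortion_history = c("yes", "no", "not_answered"),
    infertility_treatment = c("yes", "no", "not_answered", "not_investigated"),
    feeling_at_pregnancy = c("happy", "unexpected_happy", "unexpected_puzzled",
                             "dont_know_what_to_do", "no_feeling", "other",
                             "not_answered"),
    return_to_parents_home = c("yes", "no", "not_answered", "not_investigated"),
    has_helper = c("yes", "no", "not_answered"),
    worries_anxiety = c("yes", "no", "not_answered", "not_investigated"),
    smoking = c("no", "stopped_after_confirmation", "yes", "not_answered"),
    passive_smoking = c("yes", "no", "not_answered", "not_investigated"),
    alcohol = c("yes", "no", "not_answered"),
    disease_history = c("yes", "no", "not_answered", "not_investigated"),
    mental_illness_history = c("yes", "no", "not_answered", "not_investigated"),
    depressive_symptoms = c("yes", "no", "not_answered")
  )
}

feeling_pool <- c("unexpected_puzzled", "dont_know_what_to_do", "no_feeling", "other")

#' Recode a cohort of raw pregnancy notification records
#'
#' Applies the coding scheme of [coded_variables()] to a cohort of raw
#' records: bands maternal age, derives the late-registration indicator from
#' gestational weeks (>= 12 weeks is late), pools the "unexpected" feelings,
#' and passes the remaining items through. Blank cells (`NA`) become
#' `not_answered`, except where `availability` flags the (municipality,
#' variable) pair as not digitized, in which case they become
#' `not_investigated`.
#'
#' Recoding is deterministic and idempotent at the category level: recoding a
#' cohort twice gives the same analysis categories.
#'
#' @param cohort A data frame with one row per mother-child pair. Required
#'   columns: `household_id`, `municipality_id`, `outcome_rccrc` (logical or
#'   0/1), `maternal_age_years`, `gestational_weeks_at_registration`, and the
#'   raw questionnaire items named in [coded_variables()].
#' @param availability Optional field-availability map: a named list from
#'   `municipality_id` to a character vector of analysis variable names that
#'   the municipality did not digitize (read one from disk with
#'   [read_availability()]).
#' @return A tibble with `household_id`, `municipality_id`, one factor column
#'   per analysis variable (levels ordered reference first) and a logical
#'   `outcome` column.
#' @export
recode_cohort <- function(cohort, availability = NULL) {
  cohort <- tibble::as_tibble(cohort)
  if (nrow(cohort) == 0) abort("cohort is empty")
  req <- c("household_id", "municipality_id", "outcome_rccrc",
           "maternal_age_years", "gestational_weeks_at_registration",
           names(raw_enum_levels()))
  missing_cols <- setdiff(req, names(cohort))
  if (length(missing_cols) > 0) {
    abort(paste0("cohort is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (anyNA(cohort$outcome_rccrc)) abort("outcome_rccrc must be present for every record")

  specs <- coded_variables()
  enums <- raw_enum_levels()
  masked <- function(varname) {
    # records whose municipality did not digitize this analysis variable
    if (is.null(availability)) return(rep(FALSE, nrow(cohort)))
    muni_masks <- purrr::map_lgl(as.character(cohort$municipality_id),
                                 function(m) varname %in% (availability[[m]] %||% character()))
    muni_masks
  }

  age <- cohort$maternal_age_years
  if (anyNA(age)) abort("maternal_age_years must be present for every record")
  if (any(age < 0 | age > 60)) abort("maternal_age_years outside [0, 60]")
  age_band <- dplyr::case_when(
    age < 20 ~ "<20",
    age < 25 ~ "20-24",
    age < 40 ~ "25-39",
    TRUE ~ ">=40"
  )

  weeks <- cohort$gestational_weeks_at_registration
  if (any(weeks[!is.na(weeks)] < 0)) abort("gestational weeks must be nonnegative")
  late <- dplyr::if_else(is.na(weeks), "not_answered",
                         dplyr::if_else(weeks >= 12, "yes", "no"))

  out <- tibble::tibble(
    household_id = cohort$household_id,
    municipality_id = cohort$municipality_id
  )
  out$maternal_age <- factor(age_band, levels = specs$maternal_age$categories)
  out$late_registration <- factor(late, levels = specs$late_registration$categories)

  for (item in names(enums)) {
    x <- as.character(cohort[[item]])
    ni <- masked(item)
    x[is.na(x) & ni] <- "not_investigated"
    x[is.na(x)] <- "not_answered"
    bad <- setdiff(unique(x), c(enums[[item]], "not_investigated"))
    if (length(bad) > 0) {
      abort(sprintf("unknown label(s) in %s: %s", item, paste(bad, collapse = ", ")))
    }
    if (item == "feeling_at_pregnancy") {
      x[x %in% feeling_pool] <- "unexpected_other"
    }
    varname <- names(specs)[purrr::map_chr(specs, "source") == item]
    out[[varname]] <- factor(x, levels = specs[[varname]]$categories)
  }

  out <- out[, c("household_id", "municipality_id", names(specs))]
  out$outcome <- as.logical(cohort$outcome_rccrc)
  out
}

#' Recode a single record
#'
#' Single-record convenience wrapper around [recode_cohort()].
#'
#' @param record A named list or one-row data frame of raw fields.
#' @return A named list mapping analysis variable name to category label.
#' @export
recode_record <- function(record) {
  df <- tibble::as_tibble(record)
  if (nrow(df) != 1) abort("record must be a single row")
  rec <- recode_cohort(df)
  vars <- names(coded_variables())
  purrr::map(rlang::set_names(vars), function(v) as.character(rec[[v]][1]))
}

#' Collapse small "not answered" groups into the reference category
#'
#' Record-level version of the merge rule of [merge_small_not_answered()]:
#' for each analysis variable whose `not_answered` group has fewer than
#' `threshold` records, those records are recoded into the reference
#' category and the merged level is relabelled `"<ref>/not_answered"`.
#' `not_investigated` groups are never collapsed. Tabulating a collapsed
#' cohort gives exactly the table produced by merging the tabulated
#' uncollapsed cohort.
#'
#' @param recoded A recoded cohort from [recode_cohort()].
#' @param threshold Minimum `not_answered` group size that is kept separate.
#' @return The cohort with collapsed factor levels.
#' @export
collapse_small_not_answered <- function(recoded, threshold = 5) {
  for (v in intersect(names(coded_variables()), names(recoded))) {
    x <- recoded[[v]]
    n_na <- sum(x == "not_answered", na.rm = TRUE)
    if (n_na > 0 && n_na < threshold) {
      ref <- levels(x)[1]
      merged <- paste0(ref, "/not_answered")
      lv <- levels(x)
      lv[lv == ref] <- merged
      lv[lv == "not_answered"] <- merged
      levels(x) <- lv
      recoded[[v]] <- x
    }
  }
  recoded
}

new_count_table <- function(variable, category, reference, n_total, n_events) {
  if (any(n_events > n_total)) abort("n_events exceeds n_total in a category")
  if (sum(reference) != 1) abort("count table must have exactly one reference row")
  tibble::new_tibble(
    tibble::tibble(variable = variable, category = category,
                   reference = reference, n_total = as.integer(n_total),
                   n_events = as.integer(n_events)),
    class = "count_table"
  )
}

#' Tabulate one analysis variable against the outcome
#'
#' Builds the per-category (total, events) table that is the sufficient
#' input for a crude exact logistic regression of the variable.
#'
#' @param records A recoded cohort ([recode_cohort()]), optionally collapsed
#'   with [collapse_small_not_answered()].
#' @param variable Analysis variable name.
#' @return A `count_table` tibble with columns `variable`, `category`,
#'   `reference`, `n_total`, `n_events`. Categories with no records are
#'   dropped; totals conserve record and event counts.
#' @export
build_count_table <- function(records, variable) {
  if (nrow(records) == 0) abort("empty cohort")
  if (!variable %in% names(records)) abort(sprintf("no variable '%s' in records", variable))
  x <- records[[variable]]
  lv <- levels(x)
  n_total <- tabulate(x, nbins = length(lv))
  n_events <- tabulate(x[records$outcome], nbins = length(lv))
  keep <- n_total > 0
  new_count_table(variable, lv[keep], seq_along(lv)[keep] == 1,
                  n_total[keep], n_events[keep])
}

#' Merge a small "not answered" row into the reference row
#'
#' Categories left blank by fewer than `threshold` respondents carry little
#' information of their own, and for those the `not_answered` row is pooled
#' with the reference row, which keeps the sparse regressions estimable.
#' The merged row is labelled `"<ref>/not_answered"`. Rows flagged
#' `not_investigated` (structurally missing) are never merged.
#'
#' @param table A `count_table`.
#' @param threshold Minimum `not_answered` row size that is kept separate.
#' @return The (possibly) merged `count_table`.
#' @export
merge_small_not_answered <- function(table, threshold = 5) {
  i_na <- which(table$category == "not_answered")
  if (length(i_na) == 0) return(table)
  if (table$n_total[i_na] == 0 || table$n_total[i_na] >= threshold) return(table)
  i_ref <- which(table$reference)
  table$n_total[i_ref] <- table$n_total[i_ref] + table$n_total[i_na]
  table$n_events[i_ref] <- table$n_events[i_ref] + table$n_events[i_na]
  table$category[i_ref] <- paste0(table$category[i_ref], "/not_answered")
  table[-i_na, ]
}

#' Load the packaged published-cohort count tables
#'
#' The package ships the per-category totals and event counts of the
#' published 893-mother cohort (11 events): one row per analysis category
#' with its number of mothers and number of children registered with the
#' RCCRC by age 3. Every crude exact logistic regression of the original
#' analysis is recomputable from these counts alone.
#'
#' @param path Optional path to an alternative fixture CSV.
#' @return A named list of `count_table` tibbles, one per analysis variable.
#'   Each table sums to the cohort totals; a corrupted fixture raises an
#'   integrity error.
#' @export
load_table1_fixture <- function(path = NULL) {
  path <- path %||% system.file("extdata", "table1_counts.csv",
                                package = "prenatalrisk", mustWork = TRUE)
  raw <- readr::read_csv(path, col_types = readr::cols(
    variable = readr::col_character(),
    category = readr::col_character(),
    reference = readr::col_logical(),
    n_total = readr::col_integer(),
    n_events = readr::col_integer()
  ))
  tables <- purrr::map(
    split(raw, factor(raw$variable, levels = unique(raw$variable))),
    function(d) new_count_table(d$variable, d$category, d$reference,
                                d$n_total, d$n_events)
  )
  n <- purrr::map_int(tables, ~ sum(.x$n_total))
  e <- purrr::map_int(tables, ~ sum(.x$n_events))
  if (any(n != 893L) || any(e != 11L)) {
    abort("fixture integrity error: a variable does not sum to (893 mothers, 11 events)")
  }
  tables
}

#' Read a cohort CSV
#'
#' Reads raw cohort records in the package's CSV dialect: one row per
#' mother-child pair, lowercase snake_case enum labels, blank cells meaning
#' "not answered" (or "not investigated" where the availability map says the
#' municipality skipped the item).
#'
#' @param path CSV file path.
#' @return A raw cohort tibble suitable for [recode_cohort()].
#' @export
read_cohort <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    household_id = readr::col_character(),
    municipality_id = readr::col_character(),
    maternal_age_years = readr::col_integer(),
    gestational_weeks_at_registration = readr::col_integer(),
    outcome_rccrc = readr::col_logical(),
    .default = readr::col_character()
  ))
}

#' Write a cohort CSV
#' @param cohort A raw cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, na = "")
  invisible(path)
}

#' Read a municipality field-availability map
#'
#' The map records, for each municipality, which questionnaire items it did
#' not digitize; responses to those items are structurally missing
#' ("not investigated") for all its records. Accepts YAML or JSON.
#'
#' @param path YAML or JSON file: a mapping from municipality id to a list of
#'   analysis variable names.
#' @return A named list of character vectors.
#' @export
read_availability <- function(path) {
  parsed <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  purrr::map(parsed, as.character)
}
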
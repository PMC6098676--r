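#' Stage-classification and registry conventions
#'
#' Conventions needed to turn dated life-history records into annual stage
#' counts. Only the female adulthood rule (calved, or reached seven years
#' without calving) affects PFC; the remaining settings exist so that full
#' calf/subadult/adult census tables can be emulated.
#'
#' @param calf_subadult_age Age (years) at which a calf becomes a subadult.
#' @param female_adult_age Age (years) conferring adulthood on a female that
#'   has not yet calved. A female that calves is adult from her first calving
#'   regardless of age.
#' @param male_adult_age Age (years) at which a male becomes adult.
#' @param import_age Named list of nominal ages (years) imputed to imported
#'   individuals whose birth dates are unknown, by entry stage. Midpoints of
#'   the stage intervals by default; the adult value is a working convention.
#'
#' @return A list of class `pfc_lh_config`.
#' @export
#' @examples
#' lh_config(calf_subadult_age = 3)
lh_config <- function(calf_subadult_age = 3.5,
                      female_adult_age = 7,
                      male_adult_age = 7,
                      import_age = list(calf = 1.75, subadult = 5.25, adult = 10)) {
  stopifnot(
    calf_subadult_age > 0,
    female_adult_age > calf_subadult_age,
    male_adult_age > calf_subadult_age,
    all(c("calf", "subadult", "adult") %in% names(import_age))
  )
  structure(
    list(
      calf_subadult_age = calf_subadult_age,
      female_adult_age = female_adult_age,
      male_adult_age = male_adult_age,
      import_age = import_age
    ),
    class = "pfc_lh_config"
  )
}

#' Assemble a life-history registry
#'
#' Builds the registry tibble used by every downstream function and checks
#' its internal consistency: event ordering, strictly increasing calving
#' dates, the 15-month gestation bound between successive calvings, and the
#' absence of calving records for males. Imported individuals with unknown
#' birth dates receive a nominal (imputed) birth date from their entry stage
#' so that later stage transitions are well defined.
#'
#' @param records A data frame with columns `individual_id`, `sex`
#'   (`"female"`/`"male"`), `birth_date` (`Date`, `NA` for imports of unknown
#'   age), `entry_date` (`Date`; birth or import), `entry_stage` (`"calf"`,
#'   `"subadult"`, `"adult"`, or `NA` for individuals born in the
#'   population), `exit_date` (`Date` or `NA`), `exit_cause` (`"death"`,
#'   `"export"`, `"censored"`, or `NA`), and `calving_dates` (a list column
#'   of `Date` vectors; empty for males).
#' @param config A [lh_config()] object.
#' @param gestation_months Lower bound (months) on the spacing of successive
#'   calvings, from the species' gestation length.
#'
#' @return A tibble of class `pfc_registry` with the input columns plus
#'   `age_basis_date` (the known or imputed birth date used for ageing) and
#'   `birth_imputed` (logical).
#' @export
life_history <- function(records, config = lh_config(), gestation_months = 15) {
  required <- c(
    "individual_id", "sex", "birth_date", "entry_date", "entry_stage",
    "exit_date", "exit_cause", "calving_dates"
  )
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop("registry is missing columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  out <- tibble::as_tibble(records)
  if (anyDuplicated(out$individual_id)) {
    stop("duplicated individual_id in registry", call. = FALSE)
  }
  if (!all(out$sex %in% c("female", "male"))) {
    stop("sex must be 'female' or 'male'", call. = FALSE)
  }
  ok_stage <- is.na(out$entry_stage) | out$entry_stage %in% c("calf", "subadult", "adult")
  if (!all(ok_stage)) stop("unknown entry_stage", call. = FALSE)
  ok_cause <- is.na(out$exit_cause) | out$exit_cause %in% c("death", "export", "censored")
  if (!all(ok_cause)) stop("unknown exit_cause", call. = FALSE)
  out$calving_dates <- purrr::map(out$calving_dates, function(d) {
    if (is.null(d) || all(is.na(d))) as.Date(character()) else as.Date(d)
  })

  imputed <- is.na(out$birth_date)
  if (any(imputed & is.na(out$entry_stage))) {
    stop("individuals with unknown birth_date need an entry_stage", call. = FALSE)
  }
  basis <- as.Date(ifelse(imputed,
    out$entry_date - round(365.25 *
      unlist(config$import_age[ifelse(is.na(out$entry_stage), "adult", out$entry_stage)])),
    out$birth_date
  ), origin = "1970-01-01")
  out$age_basis_date <- basis
  out$birth_imputed <- imputed

  # per-individual event ordering and gestation spacing; dates are whole
  # calendar days, so allow one day of slack for rounding of event times
  min_gap <- gestation_months * (365.25 / 12) - 1
  for (i in seq_len(nrow(out))) {
    cd <- out$calving_dates[[i]]
    if (out$sex[i] == "male" && length(cd)) {
      stop("male ", out$individual_id[i], " has calving dates", call. = FALSE)
    }
    if (!is.na(out$exit_date[i]) && out$entry_date[i] > out$exit_date[i]) {
      stop("entry after exit for ", out$individual_id[i], call. = FALSE)
    }
    if (length(cd)) {
      if (any(cd < out$entry_date[i])) {
        stop("calving before entry for ", out$individual_id[i], call. = FALSE)
      }
      if (!is.na(out$exit_date[i]) && any(cd > out$exit_date[i])) {
        stop("calving after exit for ", out$individual_id[i], call. = FALSE)
      }
      if (length(cd) > 1) {
        gaps <- as.numeric(diff(cd))
        if (any(gaps <= 0)) {
          stop("calving dates not strictly increasing for ", out$individual_id[i],
            call. = FALSE
          )
        }
        if (any(gaps < min_gap)) {
          stop(
            "calvings closer than the ", gestation_months,
            "-month gestation bound for ", out$individual_id[i],
            call. = FALSE
          )
        }
      }
    }
  }
  attr(out, "lh_config") <- config
  class(out) <- c("pfc_registry", class(out))
  out
}

registry_config <- function(registry) {
  cfg <- attr(registry, "lh_config")
  if (is.null(cfg)) lh_config() else cfg
}

age_years <- function(basis_date, date) as.numeric(date - basis_date) / 365.25

#' Stage of each individual on a date
#'
#' Classifies every individual alive (present) on `date` as calf, subadult
#' or adult. A female is adult if she has calved on or before `date` or has
#' reached `female_adult_age` (seven years by default) without calving;
#' males and pre-adult females are staged by age against the configured
#' boundaries.
#'
#' @param registry A [life_history()] registry.
#' @param date A `Date`.
#' @param strict If `TRUE` (default), raise an error when `date` falls
#'   outside some individual's lifespan instead of dropping the individual.
#'
#' @return A tibble with columns `individual_id`, `sex`, `stage`.
#' @export
#' @examples
#' reg <- life_history(tibble::tibble(
#'   individual_id = "f1", sex = "female",
#'   birth_date = as.Date("2000-01-01"), entry_date = as.Date("2000-01-01"),
#'   entry_stage = NA_character_, exit_date = as.Date(NA),
#'   exit_cause = NA_character_, calving_dates = list(as.Date(character()))
#' ))
#' classify_stage(reg, as.Date("2007-01-01"))
classify_stage <- function(registry, date, strict = TRUE) {
  date <- as.Date(date)
  cfg <- registry_config(registry)
  alive <- registry$entry_date <= date &
    (is.na(registry$exit_date) | registry$exit_date >= date)
  if (strict && !all(alive)) {
    stop(
      "date ", format(date), " outside lifespan of: ",
      paste(registry$individual_id[!alive], collapse = ", "),
      call. = FALSE
    )
  }
  sub <- registry[alive, , drop = FALSE]
  age <- age_years(sub$age_basis_date, date)
  has_calved <- purrr::map_lgl(sub$calving_dates, function(cd) any(cd <= date))
  adult_age <- ifelse(sub$sex == "female", cfg$female_adult_age, cfg$male_adult_age)
  stage <- dplyr::case_when(
    sub$sex == "female" & has_calved ~ "adult",
    age >= adult_age ~ "adult",
    age >= cfg$calf_subadult_age ~ "subadult",
    TRUE ~ "calf"
  )
  tibble::tibble(individual_id = sub$individual_id, sex = sub$sex, stage = stage)
}

# date on which a female first satisfies the adult rule (Inf-like NA if never)
female_adult_onset <- function(registry) {
  cfg <- registry_config(registry)
  by_age <- registry$age_basis_date + round(cfg$female_adult_age * 365.25)
  first_calf <- purrr::map_dbl(registry$calving_dates, function(cd) {
    if (length(cd)) as.numeric(min(cd)) else Inf
  })
  pmin(as.numeric(by_age), first_calf)
}

#' Annual proportion of females calving
#'
#' For each requested year, the denominator counts every female who was alive
#' as an adult during any part of the year — including females reaching
#' adulthood, dying, or being exported mid-year — and the numerator counts
#' calvings dated within the year. PFC is their ratio.
#'
#' @param registry A [life_history()] registry.
#' @param years Integer vector of calendar years.
#'
#' @return A tibble of class `pfc_series` with columns `year`, `births`,
#'   `adult_females`, `pfc`.
#' @export
compute_pfc <- function(registry, years) {
  years <- as.integer(years)
  fem <- registry[registry$sex == "female", , drop = FALSE]
  onset <- female_adult_onset(fem)
  all_calvings <- as.Date(unlist(fem$calving_dates), origin = "1970-01-01")
  rows <- purrr::map(years, function(y) {
    y_start <- as.Date(sprintf("%d-01-01", y))
    y_end <- as.Date(sprintf("%d-12-31", y))
    present <- fem$entry_date <= y_end &
      (is.na(fem$exit_date) | fem$exit_date >= y_start)
    # adult during part of the year: adult onset no later than the last day
    # the female is present in the year (adulthood is absorbing)
    last_present <- pmin(as.numeric(y_end), as.numeric(fem$exit_date), na.rm = TRUE)
    denom <- sum(present & onset <= last_present)
    births <- sum(all_calvings >= y_start & all_calvings <= y_end)
    if (denom < 1) {
      stop("PFC undefined in ", y, ": no adult female present", call. = FALSE)
    }
    tibble::tibble(year = y, births = births, adult_females = denom,
      pfc = births / denom)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("pfc_series", class(out))
  out
}

#' Recover integer birth counts from a rounded PFC
#'
#' Census tables often print PFC rounded to a few decimals alongside the
#' adult-female count. This recovers the integer numerator, erroring if no
#' integer is consistent with the printed value.
#'
#' @param pfc Proportion(s) in \[0, 1\].
#' @param n_adult_females Positive integer count(s).
#'
#' @return Integer vector of birth counts.
#' @export
#' @examples
#' births_from_census(0.8, 5)
births_from_census <- function(pfc, n_adult_females) {
  stopifnot(all(pfc >= 0 & pfc <= 1), all(n_adult_females >= 1))
  x <- round(pfc * n_adult_females)
  bad <- abs(pfc - x / n_adult_females) >= 0.5 / n_adult_females
  if (any(bad)) {
    stop(
      "rounded PFC inconsistent with an integer birth count at: ",
      paste(sprintf("(%.4f, %d)", pfc[bad], n_adult_females[bad]), collapse = " "),
      call. = FALSE
    )
  }
  as.integer(x)
}

#' Annual sex-by-stage census table
#'
#' Counts individuals by sex and stage at the end of each calendar year
#' (December 31), the composition a year-end census would record, together
#' with per-year import and export tallies per cell.
#'
#' @param registry A [life_history()] registry.
#' @param years Integer vector of calendar years.
#'
#' @return A tibble of class `pfc_census` with one row per year and columns
#'   `f_calf`, `f_subadult`, `f_adult`, `m_calf`, `m_subadult`, `m_adult`,
#'   matching `*_imports` and `*_exports` columns, and `total`.
#' @export
census_summary <- function(registry, years) {
  years <- as.integer(years)
  cells <- c(
    "f_calf", "f_subadult", "f_adult",
    "m_calf", "m_subadult", "m_adult"
  )
  rows <- purrr::map(years, function(y) {
    y_start <- as.Date(sprintf("%d-01-01", y))
    y_end <- as.Date(sprintf("%d-12-31", y))
    counts <- stats::setNames(rep(0L, 6), cells)
    if (nrow(registry)) {
      st <- classify_stage(registry, y_end, strict = FALSE)
      # drop individuals that exited before year end
      exited <- !is.na(registry$exit_date) & registry$exit_date < y_end
      st <- st[!st$individual_id %in% registry$individual_id[exited], , drop = FALSE]
      if (nrow(st)) {
        key <- paste0(substr(st$sex, 1, 1), "_", st$stage)
        tab <- table(factor(key, levels = cells))
        counts[] <- as.integer(tab)
      }
    }
    imp <- stats::setNames(rep(0L, 6), paste0(cells, "_imports"))
    exp_ <- stats::setNames(rep(0L, 6), paste0(cells, "_exports"))
    if (nrow(registry)) {
      imported <- registry$entry_date >= y_start & registry$entry_date <= y_end &
        !is.na(registry$entry_stage)
      if (any(imported)) {
        at_entry <- paste0(
          substr(registry$sex[imported], 1, 1), "_",
          registry$entry_stage[imported]
        )
        imp[] <- as.integer(table(factor(at_entry, levels = cells)))
      }
      exported <- which(!is.na(registry$exit_cause) & registry$exit_cause == "export" &
        registry$exit_date >= y_start & registry$exit_date <= y_end)
      for (i in exported) {
        st_exp <- classify_stage(registry[i, , drop = FALSE], registry$exit_date[i])
        key <- paste0(substr(st_exp$sex, 1, 1), "_", st_exp$stage, "_exports")
        exp_[key] <- exp_[key] + 1L
      }
    }
    tibble::tibble(year = y, !!!as.list(counts), !!!as.list(imp), !!!as.list(exp_))
  })
  out <- dplyr::bind_rows(rows)
  out$total <- rowSums(out[, cells])
  class(out) <- c("pfc_census", class(out))
  out
}

#' Reproductive-performance benchmark bands
#'
#' The field benchmark for black rhinoceros classifies the percentage of
#' cows with a calf of the year into four bands: below 29% very poor–poor,
#' 29–33% poor–moderate, 33–40% moderate–good, and above 40% good–excellent.
#' The bands partition \[0, 1\]; 0.40 itself falls in moderate–good, so that
#' "good–excellent" means strictly exceeding the 0.40 threshold.
#'
#' @return A tibble with columns `label`, `lower`, `upper` and the interval
#'   closure conventions.
#' @export
benchmark_bands <- function() {
  tibble::tibble(
    label = c("very poor-poor", "poor-mod", "mod-good", "good-excellent"),
    lower = c(0, 0.29, 0.33, 0.40),
    upper = c(0.29, 0.33, 0.40, 1),
    lower_closed = c(TRUE, TRUE, TRUE, FALSE),
    upper_closed = c(FALSE, FALSE, TRUE, TRUE)
  )
}

#' Classify PFC values against the benchmark bands
#'
#' @param pfc Proportion(s) in \[0, 1\].
#' @return A factor with the band labels of [benchmark_bands()].
#' @export
#' @examples
#' classify_benchmark(c(0.26, 0.45))
classify_benchmark <- function(pfc) {
  if (any(pfc < 0 | pfc > 1)) stop("pfc must lie in [0, 1]", call. = FALSE)
  bands <- benchmark_bands()
  lab <- cut(pfc,
    breaks = c(0, 0.29, 0.33, 0.40, 1),
    labels = bands$label, include.lowest = TRUE, right = TRUE
  )
  # cut() with right = TRUE closes intervals on the right: (0.29, 0.33] etc.
  # The band convention closes them on the left except at 0.40; fix the two
  # interior left endpoints.
  lab[pfc == 0.29] <- "poor-mod"
  lab[pfc == 0.33] <- "mod-good"
  factor(lab, levels = bands$label)
}
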
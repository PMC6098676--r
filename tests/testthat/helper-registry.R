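# registry construction helpers used across test files

new_record <- function(id, sex, birth = NA, entry = birth, entry_stage = NA,
                       exit = NA, exit_cause = NA, calvings = NULL) {
  tibble::tibble(
    individual_id = id,
    sex = sex,
    birth_date = as.Date(birth),
    entry_date = as.Date(entry),
    entry_stage = as.character(entry_stage),
    exit_date = as.Date(exit),
    exit_cause = as.character(exit_cause),
    calving_dates = list(if (is.null(calvings)) as.Date(character()) else as.Date(calvings))
  )
}

# a registry emulating the Table-1-style 1994 situation: 5 adult females
# all year, 4 births in 1994
registry_1994 <- function() {
  females <- purrr::map_dfr(1:5, function(i) {
    new_record(sprintf("f%d", i), "female",
      birth = sprintf("%d-03-01", 1980 + i),
      calvings = if (i <= 4) sprintf("1994-%02d-15", 2 * i) else NULL
    )
  })
  life_history(females)
}

# random valid registry for property tests: n founder females plus their
# calves, calving at valid gestation-respecting intervals
random_registry <- function(n_females = 6, years = 12, seed = 1) {
  set.seed(seed)
  recs <- purrr::map_dfr(seq_len(n_females), function(i) {
    birth <- as.Date("1990-01-01") + round(stats::runif(1, 0, 365 * 3))
    first <- birth + round(365.25 * stats::runif(1, 6.5, 8.5))
    calvings <- first
    repeat {
      gap <- 365.25 / 12 * (16 + stats::rgamma(1, 2, scale = 5))
      nxt <- calvings[length(calvings)] + round(gap)
      if (nxt > as.Date("1990-01-01") + 365.25 * years) break
      calvings <- c(calvings, nxt)
    }
    new_record(sprintf("f%02d", i), "female", birth = format(birth), calvings = format(calvings))
  })
  life_history(recs)
}
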
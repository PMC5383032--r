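# Shared fixture builders. All fixtures are constructed in code; file-based
# ones are written to tempfiles at test time.

# A small hand-written census cross-tab: 4 strata, one suppressed cell,
# one Unknown-ethnicity row.
tiny_census <- function() {
  tibble::tibble(
    age_band_low = c(40L, 40L, 40L, 41L),
    sex = c("female", "female", "female", "male"),
    ethnicity = c("Maori", "European", "Unknown", "European"),
    nzdep_quintile = c("3", "3", "3", "1"),
    never = c(12L, 30L, 6L, 20L),
    ex = c(5L, 10L, 0L, NA),
    current = c(3L, 10L, 4L, 7L)
  )
}

write_census_fixture <- function(strata = tiny_census(), sentinel = "..C") {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  write_census_crosstab(strata, path, sentinel = sentinel)
  path
}

# A valid complete population of n persons, deterministic given the seed.
make_pop <- function(n = 20L, seed = 42L) {
  withr::with_seed(seed, {
    cfg <- world_config(n_truth = n)
    make_ground_truth(cfg)
  })
}

# Admin-record fixture with known conditional disease frequencies.
make_admin <- function(n = 5000L, seed = 1L) {
  withr::with_seed(seed, derive_admin_records(
    make_ground_truth(world_config(n_truth = n))))
}
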
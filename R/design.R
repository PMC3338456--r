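#' Construct a meadow monitoring study design
#'
#' Describes the sampling frame of a multi-allotment meadow monitoring
#' study: grazing allotments, meadows nested within allotments, fixed-count
#' monitoring sites per meadow, survey years and within-year grazing
#' seasons. The default reproduces a 3-allotment, 24-meadow design with
#' five monitoring sites per meadow (120 sites) surveyed 2006--2008 over
#' early/mid/late grazing seasons.
#'
#' @param config Optional named list overriding any of `n_allotments`,
#'   `meadows_per_allotment` (integer vector, one entry per allotment),
#'   `sites_per_meadow`, `years`, `seasons`.
#' @return An object of class `study_design`: a list with the fields above
#'   plus derived totals `n_meadows` and `n_sites`.
#' @examples
#' d <- make_design()
#' d$n_sites   # 120
#' make_design(list(n_allotments = 2, meadows_per_allotment = c(2, 3),
#'                  sites_per_meadow = 4))$n_sites  # 20
#' @export
make_design <- function(config = list()) {
  defaults <- list(
    n_allotments = 3L,
    meadows_per_allotment = c(8L, 8L, 8L),
    sites_per_meadow = 5L,
    years = 2006:2008,
    seasons = c("early", "mid", "late")
  )
  assert_that(is.list(config), "config must be a list")
  unknown <- setdiff(names(config), names(defaults))
  assert_that(length(unknown) == 0L,
              paste0("unknown design key(s): ", paste(unknown, collapse = ", ")),
              class = "meadowsem_config_error")
  cfg <- modifyList(defaults, config)

  assert_that(is_count(cfg$n_allotments),
              "n_allotments must be a positive integer",
              class = "meadowsem_config_error")
  assert_that(all(vapply(cfg$meadows_per_allotment, is_count, logical(1))),
              "meadows_per_allotment must be positive integers",
              class = "meadowsem_config_error")
  assert_that(length(cfg$meadows_per_allotment) == cfg$n_allotments,
              "meadows_per_allotment must have one entry per allotment",
              class = "meadowsem_config_error")
  assert_that(is_count(cfg$sites_per_meadow),
              "sites_per_meadow must be a positive integer",
              class = "meadowsem_config_error")
  assert_that(length(cfg$years) >= 1,
              "at least one survey year required",
              class = "meadowsem_config_error")
  assert_that(length(cfg$seasons) == 3L,
              "exactly three ordered grazing seasons required",
              class = "meadowsem_config_error")

  cfg$n_allotments <- as.integer(cfg$n_allotments)
  cfg$meadows_per_allotment <- as.integer(cfg$meadows_per_allotment)
  cfg$sites_per_meadow <- as.integer(cfg$sites_per_meadow)
  cfg$n_meadows <- sum(cfg$meadows_per_allotment)
  cfg$n_sites <- cfg$n_meadows * cfg$sites_per_meadow
  structure(cfg, class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("Meadow monitoring design:\n")
  cat(sprintf("  %d allotments, %d meadows (%s per allotment), %d sites/meadow = %d sites\n",
              x$n_allotments, x$n_meadows,
              paste(x$meadows_per_allotment, collapse = "/"),
              x$sites_per_meadow, x$n_sites))
  cat(sprintf("  years: %s; seasons: %s\n",
              paste(x$years, collapse = ", "),
              paste(x$seasons, collapse = " < ")))
  invisible(x)
}
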
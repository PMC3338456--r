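#' Composite meadow-scale hydrologic rank
#'
#' Site-level wetness ranks are integers on a fixed 0 (driest) to 6
#' (continuously flooded) scale. The meadow-scale composite is the
#' arithmetic mean of its site ranks, rounded to the nearest integer. A
#' meadow with three rank-6 sites and two rank-0 sites has mean score 3.6
#' and composite rank 4.
#'
#' @param site_ranks Non-empty vector of integer site ranks in 0..6.
#' @param rounding `"half-up"` (default; 3.5 rounds to 4) or `"half-even"`
#'   (banker's rounding, as in base [round()]).
#' @return Object of class `composite_rank`: list with `mean_score`,
#'   `rank` and `n_sites`.
#' @examples
#' composite_meadow_rank(c(6, 6, 6, 0, 0))  # mean 3.6, rank 4
#' @export
composite_meadow_rank <- function(site_ranks, rounding = c("half-up", "half-even")) {
  rounding <- match.arg(rounding)
  assert_that(length(site_ranks) > 0, "site_ranks must be non-empty")
  assert_that(is.numeric(site_ranks) && !anyNA(site_ranks) &&
                all(site_ranks == round(site_ranks)) &&
                all(site_ranks >= 0 & site_ranks <= 6),
              "site ranks must be integers in 0..6")
  m <- mean(site_ranks)
  r <- if (rounding == "half-up") round_half_up(m) else round(m)
  structure(list(mean_score = m, rank = as.integer(r),
                 n_sites = length(site_ranks)),
            class = "composite_rank")
}

#' @export
print.composite_rank <- function(x, ...) {
  cat(sprintf("Composite hydrologic rank: %d (mean score %.3g over %d sites)\n",
              x$rank, x$mean_score, x$n_sites))
  invisible(x)
}

#' Compute composite ranks for every meadow in a site table
#'
#' @param sites Data frame with at least `meadow` and `site_rank` columns
#'   (one row per site or per site-season-year; ranks are constant within
#'   site, duplicates are collapsed by `site`).
#' @param rounding Passed to [composite_meadow_rank()].
#' @return Data frame with one row per meadow: `meadow`, `mean_score`,
#'   `composite_rank`, `n_sites`.
#' @export
composite_rank_table <- function(sites, rounding = "half-up") {
  assert_that(all(c("meadow", "site", "site_rank") %in% names(sites)),
              "sites table needs columns meadow, site, site_rank")
  one <- sites[!duplicated(sites[c("meadow", "site")]),
               c("meadow", "site", "site_rank")]
  out <- lapply(split(one$site_rank, one$meadow), function(r) {
    cr <- composite_meadow_rank(r, rounding = rounding)
    data.frame(mean_score = cr$mean_score, composite_rank = cr$rank,
               n_sites = cr$n_sites)
  })
  res <- do.call(rbind, out)
  res <- cbind(meadow = names(out), res)
  rownames(res) <- NULL
  res$meadow <- if (is.numeric(one$meadow)) as.numeric(res$meadow) else res$meadow
  res[order(res$meadow), , drop = FALSE]
}
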
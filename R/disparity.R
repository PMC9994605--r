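#' Disparity metrics between SPD and no-SPD smoking prevalence
#'
#' The relative metric is the smoking prevalence ratio (SPD prevalence
#' divided by no-SPD prevalence); the absolute metric is the difference in
#' prevalence, in percentage points. The relative difference is the excess
#' relative prevalence, `ratio - 1`. Both perspectives can move in opposite
#' directions: when both groups decline but the disadvantaged group declines
#' proportionally less, the absolute gap narrows while the ratio widens.
#'
#' @param spd_prev,nospd_prev Prevalence fractions in `[0, 1]`.
#' @param digits Optional rounding for display (`NULL` = full precision).
#' @return `prevalence_ratio()`: the ratio; `absolute_difference()`: the gap
#'   in percentage points; `relative_change()`: percent change from a base
#'   value.
#' @export
prevalence_ratio <- function(spd_prev, nospd_prev, digits = NULL) {
  if (any(nospd_prev <= 0))
    stop("prevalence ratio undefined: zero denominator", call. = FALSE)
  r <- spd_prev / nospd_prev
  if (!is.null(digits)) r <- round(r, digits)
  r
}

#' @rdname prevalence_ratio
#' @export
absolute_difference <- function(spd_prev, nospd_prev, digits = NULL) {
  d <- (spd_prev - nospd_prev) * 100
  if (!is.null(digits)) d <- round(d, digits)
  d
}

#' @rdname prevalence_ratio
#' @param prev_t,prev_base Prevalence at the reporting and base years.
#' @export
relative_change <- function(prev_t, prev_base, digits = 0) {
  if (any(prev_base <= 0))
    stop("relative change undefined: zero base prevalence", call. = FALSE)
  ch <- (prev_t - prev_base) / prev_base * 100
  if (!is.null(digits)) ch <- round(ch, digits)
  ch
}

#' Disparity report across milestone years
#'
#' Builds a summary-table-style report: per gender and milestone year, the
#' SPD and no-SPD prevalences, the absolute difference (percentage points),
#' the relative difference (ratio - 1), the prevalence ratio, and the
#' relative change of each group's prevalence from the first milestone year.
#' Display rounding follows the reporting conventions (prevalence and
#' absolute difference to 0.1 percent, ratio and relative difference to 1
#' decimal, change to whole percent); set `raw = TRUE` for full precision.
#'
#' @param spd_trajectory,nospd_trajectory [project()] results for the two
#'   strata.
#' @param years Milestone years (default 2023, 2040, 2060, 2080, 2100).
#' @param raw Skip display rounding.
#' @return Data frame classed `spd_disparity` with one row per gender-year.
#' @export
disparity_report <- function(spd_trajectory, nospd_trajectory,
                             years = c(2023, 2040, 2060, 2080, 2100),
                             raw = FALSE) {
  traj_years <- as.integer(names(spd_trajectory))
  rows <- lapply(GENDERS, function(g) {
    sp <- vapply(years, function(y)
      smoking_prevalence(spd_trajectory[[match(y, traj_years)]], g), numeric(1))
    np <- vapply(years, function(y)
      smoking_prevalence(nospd_trajectory[[match(y, traj_years)]], g),
      numeric(1))
    data.frame(
      gender = g, year = years,
      spd_prev = if (raw) sp else round(sp * 100, 1) / 100,
      nospd_prev = if (raw) np else round(np * 100, 1) / 100,
      absolute_difference = absolute_difference(sp, np,
                                                if (raw) NULL else 1),
      relative_difference = {
        rd <- prevalence_ratio(sp, np) - 1
        if (raw) rd else round(rd, 1)
      },
      prevalence_ratio = prevalence_ratio(sp, np, if (raw) NULL else 1),
      spd_change_from_base = relative_change(sp, sp[1],
                                             if (raw) NULL else 0),
      nospd_change_from_base = relative_change(np, np[1],
                                               if (raw) NULL else 0)
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("spd_disparity", class(out))
  out
}

#' Write a disparity report as CSV or Markdown
#'
#' The Markdown layout mirrors the summary table: one block per gender with
#' rows for SPD prevalence, non-SPD prevalence, absolute difference,
#' relative difference and prevalence ratio, columns by milestone year.
#'
#' @param report A [disparity_report()] data frame.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_disparity_csv <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_disparity_csv
#' @export
write_disparity_md <- function(report, path) {
  lines <- character(0)
  for (g in unique(report$gender)) {
    r <- report[report$gender == g, ]
    hdr <- paste0("| ", g, " | ", paste(r$year, collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", nrow(r) + 1L), collapse = "|"), "|")
    row <- function(label, vals)
      paste0("| ", label, " | ", paste(vals, collapse = " | "), " |")
    lines <- c(lines, hdr, sep,
      row("SPD smoking prevalence", sprintf("%.1f%%", r$spd_prev * 100)),
      row("Non-SPD smoking prevalence", sprintf("%.1f%%", r$nospd_prev * 100)),
      row("Absolute difference", sprintf("%.1f%%", r$absolute_difference)),
      row("Relative difference", sprintf("%.1f", r$relative_difference)),
      row("Prevalence ratio", sprintf("%.1f", r$prevalence_ratio)),
      "")
  }
  writeLines(lines, path)
  invisible(path)
}
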
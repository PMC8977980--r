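#' Build a cohort comparison table
#'
#' Machine-readable rendering of the three cohort tables: baseline
#' characteristics compared by gender (`table1`), mapping and driver metrics
#' compared by RAc presence or gender (`table2`), and the recurrence
#' analysis (`table3`, grouped by recurrence and including the RAc-location
#' contingency block). Continuous rows are summarized as mean (SD) and
#' compared with Welch's t-test; binary rows as n (%) with the chi-square
#' test (Fisher when a 2x2 expected cell is below 5). Patients inside the
#' blanking window are excluded from `table3`.
#'
#' @param cohort a `cohort_table`
#' @param which `"table1"`, `"table2"` or `"table3"`
#' @param group2 grouping for `table2`: `"has_rac"` (default) or `"gender"`
#' @param blanking_days blanking window for `table3` (default 90)
#' @return data.frame: `variable`, `overall`, one column per group, `test`,
#'   `p`; `table3` additionally carries the location block in
#'   `attr(, "rac_location")`
#' @export
build_table <- function(cohort, which = c("table1", "table2", "table3"),
                        group2 = c("has_rac", "gender"),
                        blanking_days = 90) {
  which <- match.arg(which)
  group2 <- match.arg(group2)
  rows <- switch(which,
    table1 = list(age = "cont", hypertension = "bin", diabetes = "bin",
                  heart_failure = "bin", chads_vasc = "cont", bsa_m2 = "cont"),
    table2 = list(la_volume_cm3 = "cont", la_area_cm2 = "cont",
                  mean_voltage_mv = "cont", lva50_pct = "cont",
                  lva35_pct = "cont", lva10_pct = "cont", burden = "cont",
                  has_rac = "bin"),
    table3 = list(la_volume_cm3 = "cont", la_area_cm2 = "cont",
                  mean_voltage_mv = "cont", lva50_pct = "cont",
                  burden = "cont", has_rac = "bin", n_rac_sites = "cont"))
  missing_cols <- setdiff(names(rows), names(cohort))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  grp_col <- switch(which, table1 = "gender", table2 = group2,
                    table3 = "recurrence")
  if (which == "table2" && group2 == "has_rac") rows$has_rac <- NULL
  if (which == "table3") {
    cohort <- cohort[cohort$follow_up_days > blanking_days, , drop = FALSE]
  }
  grp <- cohort[[grp_col]]
  if (is.logical(grp)) grp <- factor(grp, levels = c(FALSE, TRUE))
  grp <- droplevels(factor(grp))
  degenerate <- nlevels(grp) < 2L

  fmt_cont <- function(x) sprintf("%.1f (%.1f)", mean(x), stats::sd(x))
  fmt_bin <- function(x) sprintf("%d (%.1f)", sum(x), 100 * mean(x))
  out <- lapply(names(rows), function(v) {
    x <- cohort[[v]]
    type <- rows[[v]]
    groups <- split(x, grp)
    if (type == "cont") {
      cells <- c(fmt_cont(x), vapply(groups, fmt_cont, character(1)))
      test <- "welch-t"
      p <- if (degenerate) NA_real_ else
        welch_t_test(groups[[1L]], groups[[2L]])$p
    } else {
      cells <- c(fmt_bin(x), vapply(groups, fmt_bin, character(1)))
      tab <- table(grp, factor(x, levels = c(FALSE, TRUE)))
      res <- if (degenerate) NULL else tryCatch(contingency_test(tab),
                                                error = function(e) NULL)
      test <- if (is.null(res)) "chi-square" else res$method
      p <- if (is.null(res)) NA_real_ else res$p
    }
    stats::setNames(
      data.frame(variable = v, t(cells), test = test, p = p,
                 stringsAsFactors = FALSE),
      c("variable", "overall",
        paste0(grp_col, "=", levels(grp)), "test", "p"))
  })
  out <- do.call(rbind, out)
  if (degenerate) attr(out, "flag") <- "single-group cohort: comparisons undefined"
  if (which == "table3") {
    loc <- recurrence_by_rac_location(cohort, blanking_days = NULL)
    tab <- cbind(loc$recurrence, loc$n - loc$recurrence)
    attr(out, "rac_location") <- loc
    attr(out, "rac_location_p") <- tryCatch(
      suppressWarnings(chi_square_test(tab)$p),
      error = function(e) NA_real_)
  }
  out
}
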
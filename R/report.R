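#' Relative error in percent
#'
#' `(calculated - actual) / actual * 100`, the signed percentage error used
#' throughout the validation tables.
#'
#' @param actual ground-truth value(s), nonzero.
#' @param calculated estimated value(s).
#' @return signed percentage error(s).
#' @export
relative_error <- function(actual, calculated) {
  check_finite(actual, "actual"); check_finite(calculated, "calculated")
  if (any(actual == 0)) stop_bowl("actual value must be nonzero")
  (calculated - actual) / actual * 100
}

#' Build a per-bowl error report
#'
#' Takes rows of actual vs calculated values for any set of quantities
#' (diameter, depth, capacity, ...) and produces the validation-table
#' layout: per-row relative error rounded half-away-from-zero to one
#' decimal, plus max-|error| and median summaries.
#'
#' @param rows data frame with columns `bowl`, `quantity`, `actual`,
#'   `calculated`.
#' @return object of class `error_report`: the augmented `table` and a
#'   `summary` data frame per quantity.
#' @export
build_error_report <- function(rows) {
  if (is.null(rows) || nrow(rows) == 0L) {
    return(structure(list(table = data.frame(), summary = data.frame()),
                     class = "error_report"))
  }
  need <- c("bowl", "quantity", "actual", "calculated")
  if (!all(need %in% names(rows))) {
    stop_bowl("rows must have columns ", paste(need, collapse = ", "))
  }
  err <- relative_error(rows$actual, rows$calculated)
  tab <- data.frame(rows[need],
                    error_pct = err,
                    error_pct_1dp = round_half_away(err, 1L))
  summ <- do.call(rbind, lapply(split(tab, tab$quantity), function(d) {
    data.frame(quantity = d$quantity[1],
               max_abs_error_pct = max(abs(d$error_pct_1dp)),
               median_error_pct = stats::median(d$error_pct_1dp))
  }))
  rownames(summ) <- NULL
  structure(list(table = tab, summary = summ), class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  if (nrow(x$table) == 0L) {
    cat("error_report: empty\n")
    return(invisible(x))
  }
  cat("error_report:\n")
  print(x$table, row.names = FALSE)
  cat("summary:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write / read an error report as CSV
#'
#' @param report an [build_error_report()] result.
#' @param path CSV path.
#' @export
write_error_report <- function(report, path) {
  utils::write.csv(report$table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_error_report
#' @export
read_error_report <- function(path) {
  build_error_report(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Render an error report as a Markdown table
#'
#' @param report an [build_error_report()] result.
#' @return character vector of Markdown lines.
#' @export
format_error_report <- function(report) {
  if (nrow(report$table) == 0L) return("(empty report)")
  tab <- report$table
  c("| bowl | quantity | actual | calculated | error (%) |",
    "|---|---|---|---|---|",
    sprintf("| %s | %s | %g | %g | %.1f |",
            tab$bowl, tab$quantity, tab$actual, tab$calculated,
            tab$error_pct_1dp),
    "",
    sprintf("max |error| = %.1f%%, median = %.1f%% (%s)",
            report$summary$max_abs_error_pct,
            report$summary$median_error_pct,
            report$summary$quantity))
}

#' Bench-validation measurements of nine round bowls
#'
#' Actual (ruler / graduated-cylinder) and image-reconstructed diameter,
#' depth and capacity of nine household bowls spanning roughly 290-850 mL,
#' together with their one-decimal relative-error cells, shipped as
#' a plain-text fixture for regression tests of the error arithmetic.
#'
#' @return data frame with columns `bowl`, `quantity`
#'   (`diameter_mm` / `depth_mm` / `capacity_ml`), `actual`, `calculated`,
#'   `reported_error_pct`.
#' @export
reference_bowls <- function() {
  utils::read.csv(system.file("extdata", "reference_bowls.csv",
                              package = "bowlrecon"),
                  stringsAsFactors = FALSE)
}
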
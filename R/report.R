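#' Results table in the standard report layout
#'
#' One row per scope; per category, the observed closed-door share to two
#' decimals and the empirical p as a percentage to two decimals, with an
#' asterisk marking significance at the configured level. All columns are
#' character so the written file is stable across platforms.
#'
#' @param results test-result tibble from [run_analysis()].
#' @return a wide character tibble.
#' @export
format_results_table <- function(results) {
  scopes <- unique(results$scope)
  cats <- unique(results$category)
  rows <- lapply(scopes, function(sc) {
    sub <- results[results$scope == sc, ]
    row <- list(scope = sc)
    for (cat in cats) {
      r <- sub[sub$category == cat, ]
      row[[paste0(cat, "_share")]] <- sprintf("%.2f", r$observed_share)
      row[[paste0(cat, "_p_pct")]] <-
        paste0(sprintf("%.2f", 100 * r$p_hat),
               if (r$significant) "*" else "")
    }
    as_tibble(row)
  })
  dplyr::bind_rows(rows)
}

#' Write the results table to CSV
#'
#' Byte-stable: identical results produce identical files.
#'
#' @param results test-result tibble from [run_analysis()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  readr::write_csv(format_results_table(results), path)
  invisible(path)
}

#' Render the results table as aligned text
#'
#' @param results test-result tibble from [run_analysis()].
#' @return a character vector of lines, invisibly; printed to the console.
#' @export
results_text <- function(results) {
  tab <- format_results_table(results)
  cats <- unique(results$category)
  header <- sprintf("%-8s", "scope")
  for (cat in cats) header <- paste0(header, sprintf(" %10s %8s", cat, "p%"))
  lines <- header
  for (i in seq_len(nrow(tab))) {
    line <- sprintf("%-8s", tab$scope[i])
    for (cat in cats) {
      line <- paste0(line, sprintf(" %10s %8s",
                                   tab[[paste0(cat, "_share")]][i],
                                   tab[[paste0(cat, "_p_pct")]][i]))
    }
    lines <- c(lines, line)
  }
  cat(lines, sep = "\n")
  cat("\n")
  invisible(lines)
}
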
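# Machine-readable reports.  All writers use fixed formatting and no
# timestamps so an identical configuration reproduces byte-identical
# files.

fmt6 <- function(x) sprintf("%.6f", x)

#' Write the connector detection report
#'
#' One CSV row per detected site: ordinal, occlusal/gingival minima slice
#' indices, station along the mid axis, initial area, obliquity.
#'
#' @param detection a `connector_detection` from [detect_connectors()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_detection_report <- function(detection, path) {
  rows <- vapply(detection$sites, function(s) {
    paste(s$ordinal, s$alpha, s$beta, fmt6(s$station), fmt6(s$a0),
          fmt6(s$obliquity_deg), sep = ",")
  }, "")
  writeLines(c("connector,alpha,beta,station_mm,a0_mm2,obliquity_deg", rows),
             path)
  invisible(path)
}

#' Write the slice area series (for area-curve plots)
#'
#' @param detection a `connector_detection`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_area_series <- function(detection, path) {
  s <- detection$series
  writeLines(c("index,station_mm,a_occ_mm2,a_gin_mm2",
               paste(s$index, fmt6(s$station), fmt6(s$a_occ),
                     fmt6(s$a_gin), sep = ",")),
             path)
  invisible(path)
}

#' Write an adjustment log
#'
#' @param results list of rows, each a list with `site`, `direction`,
#'   `target`, and either `result` (an `adjustment_result`) or `error`
#'   (message string).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_adjustment_log <- function(results, path) {
  hdr <- "site,direction,a0_mm2,a_input_mm2,a_final_mm2,k,iterations,achieved_mm2,status"
  rows <- vapply(results, function(r) {
    if (!is.null(r$error))
      return(paste(r$site, r$direction, "", fmt6(r$target), "", "", "", "",
                   paste0("error: ", gsub("[,\n]", ";", r$error)),
                   sep = ","))
    x <- r$result
    paste(r$site, r$direction, fmt6(x$a_initial), fmt6(x$target_area),
          fmt6(x$a_final), sprintf("%.8g", x$k), x$iterations,
          sprintf("%.6g", x$achieved), "ok", sep = ",")
  }, "")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write a Hausdorff QC report as a flat key-value record
#'
#' @param report a `hausdorff_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hausdorff_report <- function(report, path) {
  writeLines(c(paste0("max_distance_mm,", fmt6(report$max_distance)),
               paste0("mean_distance_mm,", fmt6(report$mean_distance)),
               paste0("sample_count,", report$sample_count),
               paste0("seed,", report$seed)),
             path)
  invisible(path)
}

#' Write connector ground truth as a sidecar CSV
#'
#' @param ground_truth data frame from the synthetic generators.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(ground_truth, path) {
  g <- ground_truth
  writeLines(c("connector,station_mm,height_mm,length_mm,area_mm2,exponent",
               paste(g$connector, fmt6(g$station), fmt6(g$height),
                     fmt6(g$length), fmt6(g$area), fmt6(g$exponent),
                     sep = ",")),
             path)
  invisible(path)
}

#' Read / write a flat key-value run configuration
#'
#' The CLI configuration format is flat `key = value` text; `#` starts a
#' comment.  Values are kept as strings; [run_config()] coerces and
#' validates.  A configuration round-trips losslessly.
#'
#' @param path file path.
#' @return named character vector (`read_config`); `path` invisibly
#'   (`write_config`).
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", lines))
  bad <- vapply(kv, length, 1L) != 3L
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  stats::setNames(vapply(kv, `[`, "", 3L), vapply(kv, `[`, "", 2L))
}

#' @rdname read_config
#' @param config named character vector or list of scalar values.
#' @export
write_config <- function(config, path) {
  vals <- vapply(config, function(x) as.character(x)[1], "")
  writeLines(paste(names(vals), "=", vals), path)
  invisible(path)
}
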
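# md5 of the shipped study table; guards against fixture corruption
TABLE1_MD5 <- "bdd9e088a5a9bf4cec3f86db5bd8c82b"

#' Load the embedded cadaveric study table
#'
#' Returns the 24 per-comparison records of the cadaveric validation
#' study (4 donors x 2 sides x 3 conditions: preintervention, post
#' spreader graft, post butterfly graft), each carrying the CT and aOCT
#' airway volumes, the Dice similarity coefficient and the Hausdorff
#' distance of the registered, field-of-view-matched pair.
#'
#' @param path CSV path; defaults to the packaged fixture (whose md5
#'   checksum is then asserted).
#' @return data frame of class `study_records` with columns `donor`,
#'   `side`, `condition`, `ct_volume_mm3`, `aoct_volume_mm3`, `dsc`,
#'   `hd_mm` and a key column `id` (`"d<donor>_<side>_<condition>"`).
#' @export
load_table1 <- function(path = NULL) {
  packaged <- is.null(path)
  if (packaged)
    path <- system.file("extdata", "table1.csv", package = "aoctair",
                        mustWork = TRUE)
  if (packaged && !identical(unname(tools::md5sum(path)), TABLE1_MD5))
    stop("study table fixture is corrupt (md5 mismatch)")
  rec <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("donor", "side", "condition", "ct_volume_mm3",
            "aoct_volume_mm3", "dsc", "hd_mm")
  if (!all(need %in% names(rec))) stop("study table is missing columns")
  if (nrow(rec) != 24L) stop("study table must have exactly 24 records")
  if (any(rec$dsc < 0 | rec$dsc > 1) ||
      any(rec$ct_volume_mm3 <= 0 | rec$aoct_volume_mm3 <= 0))
    stop("study table contains out-of-range values")
  rec$id <- sprintf("d%d_%s_%s", rec$donor, rec$side, rec$condition)
  class(rec) <- c("study_records", "data.frame")
  rec
}

#' Summary statistics of the study comparisons
#'
#' Per record, the volume difference is CT - aOCT and the percent
#' difference is 100 x (CT - aOCT) / CT; the summary reports the mean and
#' sample standard deviation (n - 1) of the differences, the percent
#' differences, the DSC and the HD over the non-excluded records. The
#' percent summary is the mean of per-row percentages, not the ratio of
#' mean volumes.
#'
#' @param records a `study_records` data frame from [load_table1].
#' @param exclude character vector of record `id`s to drop (e.g.
#'   `"d4_left_post_BFG"`); unknown ids are an error.
#' @return a `summary_stats` list with `mean_diff_mm3`, `sd_diff_mm3`,
#'   `mean_pct`, `sd_pct`, `mean_dsc`, `sd_dsc`, `mean_hd_mm`,
#'   `sd_hd_mm`, `n` and `excluded_records`.
#' @export
summarize_study <- function(records, exclude = character(0)) {
  stopifnot(inherits(records, "data.frame"))
  if (length(exclude)) {
    unknown <- setdiff(exclude, records$id)
    if (length(unknown))
      stop("unknown exclusion key(s): ", paste(unknown, collapse = ", "))
    records <- records[!records$id %in% exclude, , drop = FALSE]
  }
  if (nrow(records) < 2L)
    stop("fewer than 2 records left after exclusion")
  diff <- records$ct_volume_mm3 - records$aoct_volume_mm3
  pct <- 100 * diff / records$ct_volume_mm3
  structure(list(
    mean_diff_mm3 = mean(diff), sd_diff_mm3 = sd(diff),
    mean_pct = mean(pct), sd_pct = sd(pct),
    mean_dsc = mean(records$dsc), sd_dsc = sd(records$dsc),
    mean_hd_mm = mean(records$hd_mm), sd_hd_mm = sd(records$hd_mm),
    n = nrow(records), excluded_records = exclude),
    class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf(paste0(
    "<summary_stats> n = %d%s\n",
    "  volume difference: %.1f +/- %.1f mm^3 (%.1f +/- %.1f%% of CT)\n",
    "  DSC: %.2f +/- %.2f\n  HD: %.1f +/- %.1f mm\n"),
    x$n,
    if (length(x$excluded_records))
      paste0(" (excluded: ", paste(x$excluded_records, collapse = ", "), ")")
    else "",
    x$mean_diff_mm3, x$sd_diff_mm3, x$mean_pct, x$sd_pct,
    x$mean_dsc, x$sd_dsc, x$mean_hd_mm, x$sd_hd_mm))
  invisible(x)
}
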
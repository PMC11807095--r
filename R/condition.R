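#' Condition-level editing summary
#'
#' Summarizes a condition's replicates: the per-replicate on-target rate is
#' averaged (mean +/- SEM); the off-target summary is the per-replicate
#' mean rate over the significant off-target sites from [call_sites()],
#' averaged across replicates (the per-replicate sum over those sites is
#' reported alongside); and the on/off ratio divides the on-target mean by
#' the off-target mean. SEM is `sd/sqrt(n)`.
#'
#' @param tables List of `site_counts` tables, one per replicate.
#' @param calls A `site_calls` data.frame for this condition's contrast.
#' @param condition Condition label.
#' @return A one-row data.frame: `condition`, `n_replicates`,
#'   `on_target_mean`, `on_target_sem`, `n_significant_offtarget`,
#'   `off_target_mean`, `off_target_sem`, `off_target_sum_mean`,
#'   `on_off_ratio` (`NA` with `ratio_defined = FALSE` when no significant
#'   off-target editing), all rates as fractions, plus `*_percent` columns
#'   for the two means.
#' @export
summarize_condition <- function(tables, calls, condition = "condition") {
  if (inherits(tables, "data.frame")) tables <- list(tables)
  stopifnot(length(tables) >= 1L, inherits(calls, "data.frame"))
  n <- length(tables)
  on_r <- vapply(tables, function(t) t$rate[t$is_target], numeric(1))
  off_sites <- calls$position[calls$significant & !calls$is_target]
  if (length(off_sites)) {
    off_mean_r <- vapply(tables, function(t) {
      mean(t$rate[t$position %in% off_sites], na.rm = TRUE)
    }, numeric(1))
    off_sum_r <- vapply(tables, function(t) {
      sum(t$rate[t$position %in% off_sites], na.rm = TRUE)
    }, numeric(1))
  } else {
    off_mean_r <- off_sum_r <- rep(0, n)
  }
  sem <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0
  on_mean <- mean(on_r)
  off_mean <- mean(off_mean_r)
  ratio_defined <- off_mean > 0
  data.frame(
    condition = condition,
    n_replicates = n,
    on_target_mean = on_mean,
    on_target_sem = sem(on_r),
    on_target_percent = 100 * on_mean,
    n_significant_offtarget = length(off_sites),
    off_target_mean = off_mean,
    off_target_sem = sem(off_mean_r),
    off_target_percent = 100 * off_mean,
    off_target_sum_mean = mean(off_sum_r),
    on_off_ratio = if (ratio_defined) on_mean / off_mean else NA_real_,
    ratio_defined = ratio_defined,
    stringsAsFactors = FALSE
  )
}

#' Per-read bystander-free editing precision
#'
#' Among reads carrying the intended target A>G correction, the fraction
#' with no bystander A>G call at any other adenosine in the analysed
#' region: `P = n_clean / n_corrected`. A read is corrected when its
#' (unmasked) base at the target adenosine is G; it is clean when no other
#' region adenosine carries G (masked and gap columns are ignored, they
#' contribute no call either way).
#'
#' @param sample An `edit_sample` from [quantify_sample()] with
#'   `keep_calls = TRUE`, or a per-read call matrix as in its `calls` field.
#' @param ref An [amplicon_ref()].
#' @param region Optional integer vector of reference positions delimiting
#'   the analysed region; defaults to all reference adenosines.
#' @return A one-row data.frame: `n_corrected`, `n_clean`, `precision`
#'   (`NA` with `defined = FALSE` when no read is corrected),
#'   `precision_percent`.
#' @export
read_precision <- function(sample, ref, region = NULL) {
  calls <- if (inherits(sample, "edit_sample")) sample$calls else sample
  if (is.null(calls)) {
    stop("per-read calls unavailable; rerun quantify_sample(keep_calls = TRUE)")
  }
  adenosines <- ref$adenosine_positions
  if (!is.null(region)) adenosines <- intersect(adenosines, region)
  bystanders <- setdiff(adenosines, ref$target_pos)
  corrected <- !is.na(calls[, ref$target_pos]) &
    calls[, ref$target_pos] == "G"
  n_corrected <- sum(corrected)
  if (n_corrected == 0L) {
    return(data.frame(
      n_corrected = 0L, n_clean = 0L,
      precision = NA_real_, precision_percent = NA_real_,
      defined = FALSE
    ))
  }
  by_calls <- calls[corrected, bystanders, drop = FALSE]
  n_clean <- sum(rowSums(by_calls == "G", na.rm = TRUE) == 0L)
  p <- n_clean / n_corrected
  data.frame(
    n_corrected = n_corrected, n_clean = n_clean,
    precision = p, precision_percent = 100 * p,
    defined = TRUE
  )
}
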
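#' Build a dual-luciferase plate layout
#'
#' Helper constructing the layout data.frame the plate simulator and
#' normalization expect: technical duplicates per experimental condition
#' plus positive-control, negative-control and transfection-reagent-only
#' background wells.
#'
#' @param conditions Character vector of experimental condition names.
#' @param n_technical Technical replicates per condition (default 2).
#' @param n_control Wells per control role (default 2).
#' @return A data.frame with columns `well_id`, `condition`, `role`
#'   (`sample`, `positive_control`, `negative_control`, `background`) and
#'   `replicate`.
#' @export
plate_layout <- function(conditions, n_technical = 2L, n_control = 2L) {
  rows <- rbind(
    data.frame(
      condition = rep(conditions, each = n_technical),
      role = "sample",
      replicate = rep(seq_len(n_technical), times = length(conditions)),
      stringsAsFactors = FALSE
    ),
    data.frame(
      condition = rep(c("pos_ctrl", "neg_ctrl", "background"),
        each = n_control
      ),
      role = rep(
        c("positive_control", "negative_control", "background"),
        each = n_control
      ),
      replicate = rep(seq_len(n_control), times = 3L),
      stringsAsFactors = FALSE
    )
  )
  rows$well_id <- sprintf(
    "%s%02d", LETTERS[(seq_len(nrow(rows)) - 1L) %/% 12L + 1L],
    (seq_len(nrow(rows)) - 1L) %% 12L + 1L
  )
  rows[, c("well_id", "condition", "role", "replicate")]
}

#' Simulate a dual-luciferase reporter plate
#'
#' Draws raw Firefly/Renilla luminescence so that the standard
#' normalization (background subtraction, per-well Firefly/Renilla ratio,
#' duplicate averaging, scaling between negative- and positive-control
#' ratios) recovers the generative editing efficiencies in expectation, and
#' exactly when `noise_cv = 0`. Multiplicative noise is applied to the
#' per-well ratio (mean 1, CV `noise_cv`) and to Renilla expression, and an
#' additive background offset is applied to every well; background wells
#' carry only the offset.
#'
#' @param layout A layout data.frame as from [plate_layout()].
#' @param true_efficiencies Named numeric vector, condition -> generative
#'   editing efficiency (fraction; the positive-control ratio corresponds
#'   to 1, negative to 0).
#' @param dynamic_range Ratio of the positive-control to negative-control
#'   Firefly/Renilla ratio (default 20).
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (default 0).
#' @param seed Integer seed.
#' @param renilla_base Mean background-free Renilla luminescence.
#' @param neg_ratio Negative-control Firefly/Renilla ratio.
#' @param background_f,background_r Additive background luminescence.
#' @return A data.frame (`luciferase_plate`) with the layout columns plus
#'   `firefly_raw` and `renilla_raw`.
#' @export
simulate_plate <- function(layout, true_efficiencies, dynamic_range = 20,
                           noise_cv = 0, seed = 1L,
                           renilla_base = 1e5, neg_ratio = 0.05,
                           background_f = 200, background_r = 100) {
  for (role in c("positive_control", "negative_control", "background")) {
    if (!any(layout$role == role)) {
      stop("layout is missing wells with role '", role, "'")
    }
  }
  sample_conditions <- unique(layout$condition[layout$role == "sample"])
  missing_e <- setdiff(sample_conditions, names(true_efficiencies))
  if (length(missing_e)) {
    stop(
      "no true efficiency for condition(s): ",
      paste(missing_e, collapse = ", ")
    )
  }
  pos_ratio <- neg_ratio * dynamic_range
  n <- nrow(layout)
  withr_seed(seed, {
    noise1 <- if (noise_cv > 0) {
      pmax(stats::rnorm(n, 1, noise_cv), 0.01)
    } else {
      rep(1, n)
    }
    noise2 <- if (noise_cv > 0) {
      pmax(stats::rnorm(n, 1, noise_cv), 0.01)
    } else {
      rep(1, n)
    }
    ratio <- numeric(n)
    is_bg <- layout$role == "background"
    ratio[layout$role == "positive_control"] <- pos_ratio
    ratio[layout$role == "negative_control"] <- neg_ratio
    idx <- layout$role == "sample"
    e <- true_efficiencies[layout$condition[idx]]
    ratio[idx] <- neg_ratio + e * (pos_ratio - neg_ratio)
    renilla <- renilla_base * noise2
    firefly <- ratio * noise1 * renilla
    renilla[is_bg] <- 0
    firefly[is_bg] <- 0
    out <- layout
    out$firefly_raw <- firefly + background_f
    out$renilla_raw <- renilla + background_r
    class(out) <- c("luciferase_plate", "data.frame")
    out
  })
}

#' Subtract plate background luminescence
#'
#' Subtracts the per-channel mean of the transfection-reagent-only
#' background wells from every raw value. Values that would go negative are
#' floored at 0 and flagged.
#'
#' @param plate A `luciferase_plate` data.frame (columns `role`,
#'   `firefly_raw`, `renilla_raw`).
#' @return The plate with `firefly`, `renilla` (background-subtracted) and
#'   logical `floored` columns added.
#' @export
subtract_background <- function(plate) {
  bg <- plate$role == "background"
  if (!any(bg)) stop("no background wells on plate")
  f0 <- mean(plate$firefly_raw[bg])
  r0 <- mean(plate$renilla_raw[bg])
  f <- plate$firefly_raw - f0
  r <- plate$renilla_raw - r0
  plate$floored <- f < 0 | r < 0
  plate$firefly <- pmax(f, 0)
  plate$renilla <- pmax(r, 0)
  plate
}

#' Normalized editing efficiency from a dual-luciferase plate
#'
#' Computes the per-well Firefly/Renilla ratio, averages technical
#' duplicates per condition, and scales between the mean negative-control
#' ratio (efficiency 0) and mean positive-control ratio (efficiency 1):
#' `E = (r_cond - r_neg) / (r_pos - r_neg)`. Efficiencies outside
#' `[-0.05, 1.05]` are flagged, not clamped, since out-of-range values
#' indicate assay failure. Wells with non-positive Renilla after background
#' subtraction are excluded and flagged.
#'
#' @param plate A background-subtracted plate (see [subtract_background()]);
#'   if the background has not been subtracted yet it is subtracted first.
#' @return A data.frame with one row per experimental condition: `condition`,
#'   `raw_ratio` (duplicate-averaged Firefly/Renilla), `efficiency`,
#'   `efficiency_percent`, `n_wells`, `n_excluded`, `out_of_range`.
#' @export
editing_efficiency <- function(plate) {
  if (is.null(plate$firefly)) plate <- subtract_background(plate)
  usable <- plate$role != "background"
  excluded <- usable & plate$renilla <= 0
  wells <- plate[usable & !excluded, ]
  wells$ratio <- wells$firefly / wells$renilla
  r_pos <- mean(wells$ratio[wells$role == "positive_control"])
  r_neg <- mean(wells$ratio[wells$role == "negative_control"])
  if (!is.finite(r_pos) || !is.finite(r_neg)) {
    stop("control ratios unavailable (all control wells excluded?)")
  }
  if (r_pos == r_neg) {
    stop("degenerate dynamic range: positive and negative control ratios equal")
  }
  samp <- wells[wells$role == "sample", ]
  conditions <- unique(samp$condition)
  out <- do.call(rbind, lapply(conditions, function(cond) {
    r <- samp$ratio[samp$condition == cond]
    rc <- mean(r)
    e <- (rc - r_neg) / (r_pos - r_neg)
    data.frame(
      condition = cond,
      raw_ratio = rc,
      efficiency = e,
      efficiency_percent = 100 * e,
      n_wells = length(r),
      n_excluded = sum(excluded & plate$condition == cond),
      out_of_range = e < -0.05 || e > 1.05,
      stringsAsFactors = FALSE
    )
  }))
  attr(out, "control_ratios") <- c(negative = r_neg, positive = r_pos)
  out
}

#' Summarize replicate efficiencies as mean and SEM
#'
#' @param results A data.frame of per-plate [editing_efficiency()] outputs
#'   row-bound together (one biological replicate per plate).
#' @return A data.frame with `condition`, `mean_efficiency`, `sem`,
#'   `n_replicates`.
#' @export
summarize_efficiency <- function(results) {
  conditions <- unique(results$condition)
  do.call(rbind, lapply(conditions, function(cond) {
    e <- results$efficiency[results$condition == cond]
    data.frame(
      condition = cond,
      mean_efficiency = mean(e),
      sem = stats::sd(e) / sqrt(length(e)),
      n_replicates = length(e),
      stringsAsFactors = FALSE
    )
  }))
}

#' Read and write luciferase plate TSVs
#'
#' Plain-TSV ingest for plates exported from a reader: columns `well_id`,
#' `condition`, `role`, `replicate`, `firefly_raw`, `renilla_raw`.
#'
#' @param path TSV path.
#' @return A `luciferase_plate` data.frame.
#' @export
read_plate_tsv <- function(path) {
  plate <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c(
    "well_id", "condition", "role", "replicate", "firefly_raw", "renilla_raw"
  )
  missing_cols <- setdiff(needed, names(plate))
  if (length(missing_cols)) {
    stop("plate TSV is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (any(plate$firefly_raw < 0) || any(plate$renilla_raw < 0)) {
    stop("raw luminescence must be non-negative")
  }
  class(plate) <- c("luciferase_plate", "data.frame")
  plate
}

#' @rdname read_plate_tsv
#' @param plate A `luciferase_plate`.
#' @export
write_plate_tsv <- function(plate, path) {
  utils::write.table(plate, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
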
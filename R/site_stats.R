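#' Pool per-site allele counts across replicates
#'
#' Element-wise sums of the A and G counts at every site over all replicate
#' tables of a condition, the pooling used before exact testing.
#'
#' @param tables A list of `site_counts` data.frames sharing the same
#'   reference (identical `position` vectors).
#' @return A data.frame with `position`, `label`, `is_target`, `n_A`, `n_G`
#'   (pooled), `depth` (pooled `n_A + n_G + n_other`).
#' @export
pool_counts <- function(tables) {
  if (inherits(tables, "data.frame")) tables <- list(tables)
  stopifnot(length(tables) >= 1L)
  pos <- tables[[1]]$position
  for (t in tables[-1]) {
    if (!identical(t$position, pos)) {
      stop("all tables must share the same reference site set")
    }
  }
  out <- tables[[1]][, c("position", "label", "is_target")]
  out$n_A <- Reduce(`+`, lapply(tables, `[[`, "n_A"))
  out$n_G <- Reduce(`+`, lapply(tables, `[[`, "n_G"))
  out$depth <- Reduce(`+`, lapply(tables, `[[`, "depth"))
  out
}

#' Two-sided Fisher exact test for one site
#'
#' Tests association between condition (case vs control) and allele (G vs
#' A) in the 2x2 table of pooled counts. Two-sided p-value by summing the
#' hypergeometric probabilities of all tables (margins fixed) whose
#' probability does not exceed that of the observed table (the
#' `stats::fisher.test` convention, relative tie tolerance 1e-7). A zero
#' margin carries no information: p = 1 with a `degenerate` attribute.
#'
#' @param case_g,case_a Pooled G and A counts in the case condition.
#' @param control_g,control_a Pooled G and A counts in the control.
#' @return The two-sided p-value, with attribute `degenerate = TRUE` when
#'   a table margin is zero.
#' @export
fisher_site_test <- function(case_g, case_a, control_g, control_a) {
  counts <- c(case_g, case_a, control_g, control_a)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (case_g + case_a == 0 || control_g + control_a == 0 ||
    case_g + control_g == 0 || case_a + control_a == 0) {
    return(structure(1, degenerate = TRUE))
  }
  m <- matrix(counts, nrow = 2, byrow = TRUE)
  stats::fisher.test(m, alternative = "two.sided")$p.value
}

#' Benjamini-Hochberg step-up adjustment
#'
#' FDR step-up adjustment of a p-value vector, returned in input order:
#' with order statistics `p_(1) <= ... <= p_(m)`, the adjusted value at
#' rank `i` is `min_{k >= i} p_(k) m / k`, capped at 1.
#'
#' @param p Numeric vector of p-values in `(0, 1]`.
#' @return Adjusted values in input order.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Call editing sites against a pooled control
#'
#' Per-adenosine case/control comparison: pools replicate counts for each
#' arm, applies the two-sided Fisher exact test at every adenosine in the
#' amplicon, adjusts across all tested adenosines with Benjamini-Hochberg,
#' and flags sites with adjusted p below `alpha`. The target adenosine is
#' tested like every other site but labelled on-target; all remaining
#' flagged sites are off-target (bystander) calls.
#'
#' @param case_tables List of `site_counts` tables (case replicates).
#' @param control_tables List of `site_counts` tables (control replicates).
#' @param alpha Adjusted-p significance threshold (default 0.01).
#' @return A `site_calls` data.frame with one row per adenosine: `position`,
#'   `label`, `is_target`, `case_g`, `case_a`, `control_g`, `control_a`,
#'   `case_rate`, `control_rate`, `p`, `p_adj`, `significant`. The
#'   `"alpha"` and `"fdr_family_rate"` attributes record the threshold and
#'   the conventional 5% family rate alongside which it is reported.
#' @export
call_sites <- function(case_tables, control_tables, alpha = 0.01) {
  case <- pool_counts(case_tables)
  ctrl <- pool_counts(control_tables)
  if (!identical(case$position, ctrl$position)) {
    stop("case and control tables must share the same site set")
  }
  p <- vapply(seq_len(nrow(case)), function(i) {
    as.numeric(fisher_site_test(
      case$n_G[i], case$n_A[i], ctrl$n_G[i], ctrl$n_A[i]
    ))
  }, numeric(1))
  p_adj <- bh_adjust(p)
  out <- data.frame(
    position = case$position,
    label = case$label,
    is_target = case$is_target,
    case_g = case$n_G, case_a = case$n_A,
    control_g = ctrl$n_G, control_a = ctrl$n_A,
    case_rate = ifelse(case$n_G + case$n_A > 0,
      case$n_G / (case$n_G + case$n_A), NA_real_
    ),
    control_rate = ifelse(ctrl$n_G + ctrl$n_A > 0,
      ctrl$n_G / (ctrl$n_G + ctrl$n_A), NA_real_
    ),
    p = p,
    p_adj = p_adj,
    significant = p_adj < alpha,
    stringsAsFactors = FALSE
  )
  attr(out, "alpha") <- alpha
  attr(out, "fdr_family_rate") <- 0.05
  class(out) <- c("site_calls", "data.frame")
  out
}
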
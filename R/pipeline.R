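#' Run configuration for an end-to-end editing analysis
#'
#' Bundles everything one reproducible run needs: the reference, a sample
#' manifest (FASTQ per sample, condition, case/control role), thresholds
#' and the output directory. Round-trips through JSON unchanged.
#'
#' @param reference_fasta Path to the amplicon reference FASTA.
#' @param target_pos,guide_window Reference annotation, see [amplicon_ref()].
#' @param samples A data.frame with columns `sample_id`, `condition`,
#'   `role` (`"case"` or `"control"`), `fastq`.
#' @param out_dir Output directory (created if absent).
#' @param min_avg_q,min_base_q,min_identity Quantification thresholds.
#' @param alpha Adjusted-p significance threshold for site calling.
#' @return An object of class `run_config`.
#' @export
run_config <- function(reference_fasta, target_pos, guide_window, samples,
                       out_dir, min_avg_q = 30, min_base_q = 20,
                       min_identity = 0.8, alpha = 0.01) {
  needed <- c("sample_id", "condition", "role", "fastq")
  missing_cols <- setdiff(needed, names(samples))
  if (length(missing_cols)) {
    stop("sample manifest is missing: ", paste(missing_cols, collapse = ", "))
  }
  if (!all(samples$role %in% c("case", "control"))) {
    stop("sample roles must be 'case' or 'control'")
  }
  structure(
    list(
      reference_fasta = reference_fasta,
      target_pos = as.integer(target_pos),
      guide_window = as.integer(guide_window),
      samples = samples[, needed],
      out_dir = out_dir,
      min_avg_q = min_avg_q,
      min_base_q = min_base_q,
      min_identity = min_identity,
      alpha = alpha
    ),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param path JSON path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(
    unclass(config), path,
    auto_unbox = TRUE, digits = NA, dataframe = "columns"
  )
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(
    x$reference_fasta, x$target_pos, x$guide_window,
    as.data.frame(x$samples, stringsAsFactors = FALSE), x$out_dir,
    x$min_avg_q, x$min_base_q, x$min_identity, x$alpha
  )
}

#' Run the full editing analysis
#'
#' Orchestrates quantify -> call sites -> summarize -> precision over a
#' [run_config()]: every sample's FASTQ is quantified to a per-site TSV,
#' each case condition is tested against the pooled control replicates,
#' condition summaries and per-read precision are written, and a run
#' manifest (inputs, thresholds, file digests) is saved as JSON. Identical
#' config and inputs give identical outputs.
#'
#' @param config A [run_config()].
#' @param verbose Log stage progress to the console.
#' @return Invisibly, a list with `samples` (named list of `edit_sample`),
#'   `calls` (per-condition `site_calls`), `summaries` (data.frame),
#'   `precision` (data.frame) and `manifest`.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  missing_fq <- config$samples$fastq[!file.exists(config$samples$fastq)]
  if (length(missing_fq)) {
    stop("stage quantify: missing FASTQ file(s): ",
      paste(missing_fq, collapse = ", "))
  }
  if (!file.exists(config$reference_fasta)) {
    stop("stage quantify: missing reference FASTA: ", config$reference_fasta)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- read_reference_fasta(
    config$reference_fasta, config$target_pos, config$guide_window
  )

  samples <- list()
  for (i in seq_len(nrow(config$samples))) {
    sid <- config$samples$sample_id[i]
    s <- tryCatch(
      quantify_sample(
        config$samples$fastq[i], ref, sample_id = sid,
        min_avg_q = config$min_avg_q, min_base_q = config$min_base_q,
        min_identity = config$min_identity
      ),
      error = function(e) {
        stop("stage quantify failed for sample '", sid, "': ",
          conditionMessage(e))
      }
    )
    say(
      "quantify %s: %d reads in, %d analyzed (%d failed quality, %d failed alignment)",
      sid, s$report$n_input, s$report$n_analyzed,
      s$report$n_fail_avg_quality, s$report$n_fail_alignment
    )
    write_site_tsv(
      s,
      file.path(config$out_dir, paste0(sid, ".sites.tsv")),
      file.path(config$out_dir, paste0(sid, ".filter.json"))
    )
    samples[[sid]] <- s
  }

  manifest_s <- config$samples
  control_ids <- manifest_s$sample_id[manifest_s$role == "control"]
  if (length(control_ids) == 0L) stop("stage callsites: no control samples")
  control_tables <- lapply(samples[control_ids], `[[`, "sites")

  conditions <- unique(manifest_s$condition[manifest_s$role == "case"])
  calls <- list()
  summaries <- list()
  precision <- list()
  for (cond in conditions) {
    ids <- manifest_s$sample_id[
      manifest_s$condition == cond & manifest_s$role == "case"
    ]
    tables <- lapply(samples[ids], `[[`, "sites")
    cl <- call_sites(tables, control_tables, alpha = config$alpha)
    say(
      "callsites %s: %d/%d sites significant at adjusted p < %g",
      cond, sum(cl$significant), nrow(cl), config$alpha
    )
    utils::write.table(
      cl, file.path(config$out_dir, paste0(cond, ".site_calls.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    calls[[cond]] <- cl
    summaries[[cond]] <- summarize_condition(tables, cl, cond)
    prec <- do.call(rbind, lapply(ids, function(sid) {
      p <- read_precision(samples[[sid]], ref)
      cbind(sample_id = sid, condition = cond, p)
    }))
    precision[[cond]] <- prec
  }
  summaries <- do.call(rbind, summaries)
  precision <- do.call(rbind, precision)
  utils::write.table(
    summaries, file.path(config$out_dir, "condition_summary.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(
    precision, file.path(config$out_dir, "precision.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )

  outputs <- list.files(config$out_dir, full.names = TRUE)
  manifest <- list(
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("adarcall")),
    thresholds = config[c(
      "min_avg_q", "min_base_q", "min_identity", "alpha"
    )],
    input_digests = as.list(tools::md5sum(
      c(config$reference_fasta, config$samples$fastq)
    )),
    output_digests = as.list(tools::md5sum(outputs))
  )
  jsonlite::write_json(
    manifest, file.path(config$out_dir, "run_manifest.json"),
    auto_unbox = TRUE
  )
  invisible(list(
    samples = samples, calls = calls, summaries = summaries,
    precision = precision, manifest = manifest
  ))
}
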
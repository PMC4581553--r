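#' Run the full analysis pipeline
#'
#' Orchestrates quantification, exact-test contrasts, gene-action
#' classification, chromosome and GO enrichment, TE calls and (optionally)
#' qPCR concordance over one three-library experiment, and returns a
#' machine-readable summary. When no counts are supplied a synthetic
#' experiment is generated first, and the truth-based recovery report is
#' added to the summary.
#'
#' @param counts A `count_table`, or `NULL` to simulate.
#' @param annotation An `annotation` tibble (optional; enrichment and TE
#'   steps are skipped without it).
#' @param ct Optional qPCR Ct tibble (see [read_ct_table()]).
#' @param sim A `sim_config` used when `counts` is `NULL`.
#' @param min_count,min_rpkm Expression-call thresholds
#'   ([call_expressed()]).
#' @param alpha,min_log2fc DEG thresholds ([run_contrasts()]).
#' @param min_genes Minimum background genes per GO term ([go_enrich()]).
#' @param qpcr_calibrator,qpcr_contrast qPCR settings ([ddct_fold()],
#'   [qpcr_concordance()]).
#' @param seed Seed used for simulation (overrides `sim$seed` when given).
#' @return A `run_result` list: the intermediate tables (`expression`,
#'   `venn`, `de`, `dominance`, `mode_summary`, `chrom_scan`, `go`, `te`,
#'   `concordance`, `recovery` as available) and `summary`, a plain nested
#'   list ready for JSON serialisation.
#' @export
run_pipeline <- function(counts = NULL, annotation = NULL, ct = NULL,
                         sim = sim_config(), min_count = 5, min_rpkm = 0.5,
                         alpha = 0.05, min_log2fc = 1, min_genes = 3,
                         qpcr_calibrator = "P1", qpcr_contrast = "MP_vs_F1",
                         seed = NULL) {
  res <- list()
  truth <- NULL
  if (is.null(counts)) {
    simres <- simulate_hybrid(sim, seed = seed)
    counts <- simres$counts
    if (is.null(annotation)) annotation <- simres$annotation
    truth <- simres$truth
    res$sim <- simres
  }
  stopifnot(inherits(counts, "mp_count_table"))

  res$expression <- call_expressed(counts, min_count = min_count, min_rpkm = min_rpkm)
  res$venn <- venn_partition(res$expression)
  res$de <- run_contrasts(counts, alpha = alpha, min_log2fc = min_log2fc)
  res$dominance <- classify_modes(res$de, counts)
  res$mode_summary <- summarize_modes(res$dominance)

  if (!is.null(annotation)) {
    res$chrom_scan <- chromosome_scan(res$dominance, annotation)
    res$go <- go_enrich(unique(res$dominance$gene_id), annotation,
                        min_genes = min_genes)
    res$te <- classify_te(annotation, res$expression, res$de)
  }
  if (!is.null(ct)) {
    folds <- ddct_fold(ct, calibrator = qpcr_calibrator, samples = "F1")
    res$concordance <- qpcr_concordance(folds, res$de, contrast = qpcr_contrast)
  }
  if (!is.null(truth)) {
    res$recovery <- recovery_report(res$dominance, truth)
  }
  res$summary <- pipeline_summary(res, alpha = alpha)
  class(res) <- "mp_run_result"
  res
}

pipeline_summary <- function(res, alpha = 0.05) {
  expr <- res$expression
  deg_per_contrast <- res$de |>
    dplyr::filter(.data$contrast %in% c("P1_vs_F1", "P2_vs_F1", "MP_vs_F1")) |>
    dplyr::group_by(.data$contrast) |>
    dplyr::summarise(
      up = sum(.data$direction == "up_in_F1"),
      down = sum(.data$direction == "down_in_F1"),
      total = .data$up + .data$down,
      .groups = "drop"
    )
  s <- list(
    expressed = list(
      P1 = sum(expr$expressed_P1),
      P2 = sum(expr$expressed_P2),
      F1 = sum(expr$expressed_F1)
    ),
    venn = stats::setNames(as.list(res$venn$regions$n), res$venn$regions$region),
    silenced_in_hybrid = length(res$venn$silenced_in_hybrid),
    activated_in_hybrid = length(res$venn$activated_in_hybrid),
    deg_total = length(unique(res$de$gene_id[res$de$is_deg]))
  )
  s$contrasts <- purrr::map(
    stats::setNames(deg_per_contrast$contrast, deg_per_contrast$contrast),
    function(ct) {
      row <- deg_per_contrast[deg_per_contrast$contrast == ct, ]
      list(total = row$total, up = row$up, down = row$down)
    }
  )
  s$modes <- res$mode_summary |>
    dplyr::filter(.data$group != "rollup") |>
    (\(d) stats::setNames(purrr::map2(d$n, d$percent, ~ list(n = .x, percent = .y)),
                          d$mode))()
  rollup <- dplyr::filter(res$mode_summary, .data$group == "rollup")
  s$mode_rollup <- stats::setNames(
    purrr::map2(rollup$n, rollup$percent, ~ list(n = .x, percent = .y)),
    rollup$mode
  )
  if (!is.null(res$chrom_scan)) {
    hits <- dplyr::filter(res$chrom_scan, .data$fdr < alpha)
    s$chromosome_hits <- purrr::pmap(
      hits[c("unit", "gene_set_label", "k", "fdr")],
      function(unit, gene_set_label, k, fdr) {
        list(chromosome = unit, mode = gene_set_label, k = k, fdr = fdr)
      }
    )
  }
  if (!is.null(res$go)) {
    s$go_hits <- sum(res$go$fdr < alpha)
  }
  if (!is.null(res$te)) {
    s$te <- as.list(table(factor(res$te$regulation,
                                 levels = c("Active", "Inactive", "Up", "Down"))))
  }
  if (!is.null(res$concordance)) {
    s$qpcr <- list(agree = res$concordance$n_agree,
                   neutral = res$concordance$n_neutral,
                   n = res$concordance$n)
  }
  if (!is.null(res$recovery)) {
    s$recovery_accuracy <- res$recovery$accuracy
  }
  s
}

#' @export
print.mp_run_result <- function(x, ...) {
  s <- x$summary
  cat("midparent pipeline run\n")
  cat("  expressed: P1 ", s$expressed$P1, ", P2 ", s$expressed$P2,
      ", F1 ", s$expressed$F1, "\n", sep = "")
  cat("  DEGs: ", s$deg_total, "\n", sep = "")
  for (ct in names(s$contrasts)) {
    cc <- s$contrasts[[ct]]
    cat("  ", ct, ": ", cc$total, " (", cc$up, " up, ", cc$down, " down)\n", sep = "")
  }
  cat("  modes: ")
  cat(paste(names(s$modes), vapply(s$modes, function(m) m$n, numeric(1)),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write a pipeline summary as JSON
#'
#' @param run A `run_result` from [run_pipeline()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_summary <- function(run, path) {
  stopifnot(inherits(run, "mp_run_result"))
  jsonlite::write_json(run$summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
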
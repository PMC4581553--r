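#' Relative quantification by the 2^-ddCt method
#'
#' For each gene and sample, replicate Ct values are averaged on the Ct
#' scale, the reference-gene Ct is subtracted (`dCt = mean(ct_target) -
#' mean(ct_reference)`), the calibrator sample's dCt is subtracted again
#' (`ddCt`), and the fold change is `2^-ddCt`. A fold of 1 means the target
#' behaves exactly like the reference gene relative to the calibrator.
#'
#' @param ct A tibble of Ct records: columns `gene_id`, `sample`,
#'   `replicate`, `ct_target`, `ct_reference` (finite positive cycles).
#' @param calibrator The calibrator sample label (e.g. `"P1"`).
#' @param samples Samples to quantify; default every non-calibrator sample.
#' @return A `qpcr_folds` tibble: `gene_id`, `sample`, `dct`,
#'   `dct_calibrator`, `fold` (= 2^-ddCt).
#' @export
ddct_fold <- function(ct, calibrator, samples = NULL) {
  needed <- c("gene_id", "sample", "ct_target", "ct_reference")
  stopifnot(all(needed %in% names(ct)))
  bad <- !is.finite(ct$ct_target) | !is.finite(ct$ct_reference) |
    ct$ct_target <= 0 | ct$ct_reference <= 0
  if (any(bad)) {
    stop("non-finite or non-positive Ct value for gene ",
         ct$gene_id[which(bad)[1]], call. = FALSE)
  }
  dct <- ct |>
    dplyr::group_by(.data$gene_id, .data$sample) |>
    dplyr::summarise(dct = mean(.data$ct_target) - mean(.data$ct_reference),
                     .groups = "drop")
  cal <- dct |>
    dplyr::filter(.data$sample == calibrator) |>
    dplyr::select("gene_id", dct_calibrator = "dct")
  if (is.null(samples)) samples <- setdiff(unique(dct$sample), calibrator)
  missing_cal <- setdiff(unique(dct$gene_id[dct$sample %in% samples]), cal$gene_id)
  if (length(missing_cal) > 0) {
    stop("no calibrator (", calibrator, ") records for gene ",
         missing_cal[1], call. = FALSE)
  }
  out <- dct |>
    dplyr::filter(.data$sample %in% samples) |>
    dplyr::inner_join(cal, by = "gene_id") |>
    dplyr::mutate(fold = 2^-(.data$dct - .data$dct_calibrator))
  class(out) <- c("mp_qpcr_folds", class(out))
  out
}

#' Direction concordance between qPCR folds and transcriptome calls
#'
#' A gene agrees when the sign of its log2 qPCR fold matches the
#' transcriptome direction for the chosen contrast (fold > 1 with
#' `up_in_F1`, fold < 1 with `down_in_F1`). Genes whose fold is exactly 1 or
#' whose transcriptome direction is `none` carry no usable sign; they are
#' counted as non-agreements but reported separately as `neutral`.
#'
#' @param folds A `qpcr_folds` tibble from [ddct_fold()] (one row per gene
#'   for the sample of interest), or any data frame with `gene_id` and
#'   `fold`.
#' @param de A `detest` tibble.
#' @param contrast Which transcriptome contrast the folds mirror (default
#'   `"MP_vs_F1"`).
#' @return A `concordance` object: list with `table` (per-gene tibble:
#'   `gene_id`, `fold`, `direction`, `status` in agree/disagree/neutral),
#'   `n_agree`, `n_neutral`, `n` (shared genes).
#' @export
qpcr_concordance <- function(folds, de, contrast = "MP_vs_F1") {
  stopifnot(all(c("gene_id", "fold") %in% names(folds)))
  dir_tbl <- de |>
    dplyr::filter(.data$contrast == !!contrast) |>
    dplyr::select("gene_id", "direction")
  tbl <- dplyr::inner_join(tibble::as_tibble(folds)[c("gene_id", "fold")],
                           dir_tbl, by = "gene_id")
  if (nrow(tbl) == 0) {
    warning("no shared genes between qPCR folds and transcriptome results",
            call. = FALSE)
  }
  tbl <- dplyr::mutate(tbl, status = dplyr::case_when(
    fold == 1 | direction == "none" ~ "neutral",
    fold > 1 & direction == "up_in_F1" ~ "agree",
    fold < 1 & direction == "down_in_F1" ~ "agree",
    .default = "disagree"
  ))
  out <- list(table = tbl,
              n_agree = sum(tbl$status == "agree"),
              n_neutral = sum(tbl$status == "neutral"),
              n = nrow(tbl))
  class(out) <- "mp_concordance"
  out
}

#' @export
print.mp_concordance <- function(x, ...) {
  cat("qPCR/transcriptome direction concordance: ", x$n_agree, " of ", x$n,
      " genes agree (", x$n_neutral, " neutral)\n", sep = "")
  invisible(x)
}

#' Read a qPCR Ct table
#'
#' Tab-separated with columns `gene_id`, `sample`, `replicate`, `ct_target`,
#' `ct_reference`.
#'
#' @param path Path to the Ct TSV.
#' @return A tibble of Ct records.
#' @export
read_ct_table <- function(path) {
  stopifnot(file.exists(path))
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(
                    gene_id = readr::col_character(),
                    sample = readr::col_character(),
                    replicate = readr::col_integer(),
                    ct_target = readr::col_double(),
                    ct_reference = readr::col_double()
                  ))
}
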
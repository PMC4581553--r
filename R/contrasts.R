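#' Exact-test contrasts for the three-library design
#'
#' Runs the Audic-Claverie test for every gene in four contrasts:
#'
#' * `P1_vs_F1`, `P2_vs_F1` -- each parent against the hybrid, at the two
#'   libraries' own sizes;
#' * `MP_vs_F1` -- the additivity test: the F1 count against the expected
#'   *midparent* count, `round(((x_P1/N_P1 + x_P2/N_P2)/2) * N_F1)`, i.e. the
#'   mean parental rate rescaled to the F1's depth, tested at
#'   `N1 = N2 = N_F1`;
#' * `P1_vs_P2` -- the parents against each other, which the dominance
#'   classifier needs to order the parents.
#'
#' p-values are BH-adjusted within each contrast. `direction` is driven by
#' the FDR alone (`up_in_F1` / `down_in_F1` / `none` for the F1 contrasts,
#' `up_in_P2` / `down_in_P2` / `none` for the parent contrast). The RPKM
#' log2-fold filter acts only on DEG selection: a gene is flagged `is_deg`
#' when at least one of `P1_vs_F1` / `P2_vs_F1` is significant at `alpha`
#' *and* shows `|log2_ratio| >= min_log2fc` (log2 ratio of RPKM with
#' pseudocount 1, the knob that excludes statistically detectable but
#' biologically negligible shifts at high depth).
#'
#' @param counts A `count_table`.
#' @param alpha BH FDR threshold for significance (default 0.05).
#' @param min_log2fc Minimum absolute log2 RPKM ratio for DEG status
#'   (default 1; set 0 to disable).
#' @param midparent_rounding How the expected midparent count is made
#'   integer: `"round"` (default), `"floor"` or `"ceiling"`.
#' @return A `detest` tibble: `gene_id`, `contrast`, `x`, `y`, `p_value`,
#'   `fdr`, `log2_ratio`, `direction`, `is_deg` (gene-level flag replicated
#'   across the gene's rows). Thresholds are carried as attributes.
#' @export
run_contrasts <- function(counts, alpha = 0.05, min_log2fc = 1,
                          midparent_rounding = c("round", "floor", "ceiling")) {
  stopifnot(inherits(counts, "mp_count_table"))
  midparent_rounding <- match.arg(midparent_rounding)
  rounder <- switch(midparent_rounding, round = round, floor = floor, ceiling = ceiling)
  ls <- lib_sizes(counts)
  len <- counts$length_bp
  mp_count <- rounder(((counts$count_P1 / ls[["P1"]] +
                          counts$count_P2 / ls[["P2"]]) / 2) * ls[["F1"]])

  one <- function(contrast, x, y, N1, N2) {
    tibble::tibble(
      gene_id = counts$gene_id,
      contrast = contrast,
      x = as.numeric(x), y = as.numeric(y),
      p_value = ac_test(x, y, N1, N2),
      log2_ratio = log2((rpkm(y, len, N2) + 1) / (rpkm(x, len, N1) + 1))
    )
  }
  de <- dplyr::bind_rows(
    one("P1_vs_F1", counts$count_P1, counts$count_F1, ls[["P1"]], ls[["F1"]]),
    one("P2_vs_F1", counts$count_P2, counts$count_F1, ls[["P2"]], ls[["F1"]]),
    one("MP_vs_F1", mp_count, counts$count_F1, ls[["F1"]], ls[["F1"]]),
    one("P1_vs_P2", counts$count_P1, counts$count_P2, ls[["P1"]], ls[["P2"]])
  )
  de <- de |>
    dplyr::group_by(.data$contrast) |>
    dplyr::mutate(fdr = bh_fdr(.data$p_value)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      direction = dplyr::case_when(
        fdr >= alpha ~ "none",
        contrast == "P1_vs_P2" & log2_ratio > 0 ~ "up_in_P2",
        contrast == "P1_vs_P2" ~ "down_in_P2",
        log2_ratio > 0 ~ "up_in_F1",
        .default = "down_in_F1"
      )
    )
  deg_ids <- de |>
    dplyr::filter(.data$contrast %in% c("P1_vs_F1", "P2_vs_F1"),
                  .data$fdr < alpha, abs(.data$log2_ratio) >= min_log2fc) |>
    dplyr::pull(.data$gene_id) |>
    unique()
  de$is_deg <- de$gene_id %in% deg_ids
  attr(de, "alpha") <- alpha
  attr(de, "min_log2fc") <- min_log2fc
  class(de) <- c("mp_detest", class(de))
  de
}
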
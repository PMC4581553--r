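#' Midparent heterosis
#'
#' `MPH = (h - (P1+P2)/2) / ((P1+P2)/2) * 100 + 100`: the hybrid value as a
#' percentage of the midparent value, so midparent performance maps to 100,
#' values above 100 indicate positive heterosis and below 100 negative
#' heterosis.
#'
#' @param h Hybrid value(s) (expression or trait).
#' @param p1,p2 Parental values.
#' @return MPH in percent; errors if the midparent value is zero.
#' @examples
#' mph(15, 10, 10) # 150
#' @export
mph <- function(h, p1, p2) {
  mid <- (p1 + p2) / 2
  if (any(mid == 0)) stop("midparent value is zero; MPH undefined", call. = FALSE)
  (h - mid) / mid * 100 + 100
}

.modes <- c("ADD", "HPD", "LPD", "ODO", "UDO", "PPD", "NPD", "OTHER")
.nonadditive_modes <- c("HPD", "LPD", "ODO", "UDO", "PPD", "NPD")

#' Classify differentially expressed genes into gene-action modes
#'
#' Every DEG is assigned exactly one mode from the three signed exact-test
#' outcomes (F1 vs P1, F1 vs P2, F1 vs midparent; +1 = F1 significantly
#' higher, 0 = not significant, -1 = lower) plus the parents' relative order
#' (the P1-vs-P2 contrast). The decision tree, in order:
#'
#' 1. not significant vs midparent -> `ADD` (additivity);
#' 2. F1 significantly above both parents -> `ODO` (overdominance);
#' 3. below both -> `UDO` (underdominance);
#' 4. parents significantly different and F1 statistically indistinguishable
#'    from the higher parent -> `HPD` (high-parent dominance);
#' 5. ... from the lower parent -> `LPD` (low-parent dominance);
#' 6. F1 strictly between the parents (below the high, above the low) and
#'    significantly displaced from the midparent: above it -> `PPD`, below
#'    -> `NPD` (positive / negative partial dominance);
#' 7. anything else (e.g. parents not significantly different while the F1
#'    departs from the midparent but matches both parents) -> `OTHER`.
#'
#' "Indistinguishable" is operationalised as non-significance of the
#' corresponding contrast at the configured FDR; when the parents do not
#' differ significantly, HPD/LPD are unreachable by construction. MPH is
#' computed on RPKM values; genes whose parental RPKM midparent is exactly
#' zero get `NA` MPH.
#'
#' @param de A `detest` tibble from [run_contrasts()] (must contain all four
#'   contrasts).
#' @param counts The `count_table` the contrasts were run on (for RPKM and
#'   MPH).
#' @param genes Genes to classify; default the DEGs flagged in `de`.
#' @return A `dominance` tibble: `gene_id`, `mode`, `mph`, `sig_vs_P1`,
#'   `sig_vs_P2`, `sig_vs_MP`, `parent_order` (+1 if P1 is the significantly
#'   higher parent, -1 if P2, 0 if parents not significantly different).
#' @export
classify_modes <- function(de, counts, genes = NULL) {
  stopifnot(inherits(de, "mp_detest"), inherits(counts, "mp_count_table"))
  if (is.null(genes)) genes <- unique(de$gene_id[de$is_deg])
  if (length(genes) == 0) {
    out <- tibble::tibble(gene_id = character(), mode = character(), mph = numeric(),
                          sig_vs_P1 = integer(), sig_vs_P2 = integer(),
                          sig_vs_MP = integer(), parent_order = integer())
    class(out) <- c("mp_dominance", class(out))
    return(out)
  }
  wide <- de |>
    dplyr::filter(.data$gene_id %in% genes) |>
    dplyr::mutate(sig = dplyr::if_else(.data$direction == "none", 0L,
                                       dplyr::if_else(.data$log2_ratio > 0, 1L, -1L))) |>
    dplyr::select("gene_id", "contrast", "sig") |>
    tidyr::pivot_wider(names_from = "contrast", values_from = "sig")
  needed <- c("P1_vs_F1", "P2_vs_F1", "MP_vs_F1", "P1_vs_P2")
  if (!all(needed %in% names(wide)) || anyNA(wide[needed])) {
    missing_gene <- if (anyNA(wide[intersect(needed, names(wide))])) {
      wide$gene_id[which(!stats::complete.cases(wide[intersect(needed, names(wide))]))[1]]
    } else {
      genes[1]
    }
    stop("missing contrast result for gene ", missing_gene, call. = FALSE)
  }

  ls <- lib_sizes(counts)
  rk <- counts |>
    dplyr::filter(.data$gene_id %in% genes) |>
    dplyr::transmute(
      gene_id = .data$gene_id,
      rpkm_P1 = rpkm(.data$count_P1, .data$length_bp, ls[["P1"]]),
      rpkm_P2 = rpkm(.data$count_P2, .data$length_bp, ls[["P2"]]),
      rpkm_F1 = rpkm(.data$count_F1, .data$length_bp, ls[["F1"]])
    )

  out <- wide |>
    dplyr::left_join(rk, by = "gene_id") |>
    dplyr::mutate(
      # sig_vs_*: +1 when F1 is significantly higher; parent_order: +1 when
      # P1 is the significantly higher parent (P1_vs_P2 sign is "P2 higher")
      sig_vs_P1 = .data$P1_vs_F1,
      sig_vs_P2 = .data$P2_vs_F1,
      sig_vs_MP = .data$MP_vs_F1,
      parent_order = -.data$P1_vs_P2,
      sig_vs_high = dplyr::if_else(.data$parent_order > 0, .data$sig_vs_P1, .data$sig_vs_P2),
      sig_vs_low = dplyr::if_else(.data$parent_order > 0, .data$sig_vs_P2, .data$sig_vs_P1),
      mode = dplyr::case_when(
        sig_vs_MP == 0L ~ "ADD",
        sig_vs_P1 == 1L & sig_vs_P2 == 1L ~ "ODO",
        sig_vs_P1 == -1L & sig_vs_P2 == -1L ~ "UDO",
        parent_order != 0L & sig_vs_high == 0L ~ "HPD",
        parent_order != 0L & sig_vs_low == 0L ~ "LPD",
        parent_order != 0L & sig_vs_high == -1L & sig_vs_low == 1L & sig_vs_MP == 1L ~ "PPD",
        parent_order != 0L & sig_vs_high == -1L & sig_vs_low == 1L & sig_vs_MP == -1L ~ "NPD",
        .default = "OTHER"
      ),
      mid = (.data$rpkm_P1 + .data$rpkm_P2) / 2,
      mph = dplyr::if_else(.data$mid > 0,
                           (.data$rpkm_F1 - .data$mid) / .data$mid * 100 + 100,
                           NA_real_)
    ) |>
    dplyr::select("gene_id", "mode", "mph", "sig_vs_P1", "sig_vs_P2",
                  "sig_vs_MP", "parent_order")
  class(out) <- c("mp_dominance", class(out))
  out
}

#' Tabulate gene-action modes
#'
#' Counts and percentages (of all classified genes, to two decimals) per
#' mode, plus the three-row rollup: additive, nonadditive
#' (HPD + LPD + ODO + UDO + PPD + NPD) and other.
#'
#' @param calls A `dominance` tibble from [classify_modes()], or any data
#'   frame with a `mode` column.
#' @return A `mode_summary` tibble: `mode`, `n`, `percent`, `group`.
#' @export
summarize_modes <- function(calls) {
  stopifnot("mode" %in% names(calls))
  total <- nrow(calls)
  counts <- table(factor(calls$mode, levels = .modes))
  per_mode <- tibble::tibble(
    mode = .modes,
    n = as.integer(counts),
    percent = if (total > 0) round(as.integer(counts) / total * 100, 2) else 0,
    group = dplyr::case_when(
      .modes == "ADD" ~ "additive",
      .modes == "OTHER" ~ "other",
      .default = "nonadditive"
    )
  )
  rollup <- per_mode |>
    dplyr::group_by(mode = .data$group) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop") |>
    dplyr::mutate(percent = if (total > 0) round(.data$n / total * 100, 2) else 0,
                  group = "rollup") |>
    dplyr::arrange(factor(.data$mode, levels = c("additive", "nonadditive", "other")))
  out <- dplyr::bind_rows(per_mode, rollup)
  attr(out, "total") <- total
  class(out) <- c("mp_mode_summary", class(out))
  out
}
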
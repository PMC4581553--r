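#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Venn partition into a region table
#' @param x A `venn_partition` from [venn_partition()].
#' @param ... Unused.
#' @return Tibble: `region`, `n`.
#' @exportS3Method generics::tidy
tidy.mp_venn <- function(x, ...) {
  dplyr::select(x$regions, "region", "n")
}

#' One-row summary of a Venn partition
#' @param x A `venn_partition`.
#' @param ... Unused.
#' @return One-row tibble with region counts and the derived hybrid sets.
#' @exportS3Method generics::glance
glance.mp_venn <- function(x, ...) {
  wide <- tidyr::pivot_wider(tidy(x), names_from = "region", values_from = "n")
  dplyr::mutate(wide,
                n_expressed_any = x$n_expressed_any,
                silenced_in_hybrid = length(x$silenced_in_hybrid),
                activated_in_hybrid = length(x$activated_in_hybrid))
}

#' Per-mode recovery table from a recovery report
#' @param x A `recovery` object from [recovery_report()].
#' @param ... Unused.
#' @return Tibble: `true_mode`, `n_true`, `n_called`, `n_correct`,
#'   `recovery`.
#' @exportS3Method generics::tidy
tidy.mp_recovery <- function(x, ...) x$per_mode

#' One-row summary of a recovery report
#' @param x A `recovery` object.
#' @param ... Unused.
#' @return One-row tibble: `accuracy`, `n_called`, `min_recovery`.
#' @exportS3Method generics::glance
glance.mp_recovery <- function(x, ...) {
  tibble::tibble(
    accuracy = x$accuracy,
    n_called = sum(x$per_mode$n_called),
    min_recovery = suppressWarnings(min(x$per_mode$recovery, na.rm = TRUE))
  )
}

#' Per-gene concordance table
#' @param x A `concordance` object from [qpcr_concordance()].
#' @param ... Unused.
#' @return Tibble: `gene_id`, `fold`, `direction`, `status`.
#' @exportS3Method generics::tidy
tidy.mp_concordance <- function(x, ...) x$table

#' One-row concordance summary
#' @param x A `concordance` object.
#' @param ... Unused.
#' @return One-row tibble: `n_agree`, `n_neutral`, `n`, `agreement`.
#' @exportS3Method generics::glance
glance.mp_concordance <- function(x, ...) {
  tibble::tibble(n_agree = x$n_agree, n_neutral = x$n_neutral, n = x$n,
                 agreement = ifelse(x$n > 0, x$n_agree / x$n, NA_real_))
}

#' One-row summary of a dominance call set
#' @param x A `dominance` tibble from [classify_modes()].
#' @param ... Unused.
#' @return One-row tibble: total and additive/nonadditive/other counts.
#' @exportS3Method generics::glance
glance.mp_dominance <- function(x, ...) {
  s <- summarize_modes(x)
  rollup <- dplyr::filter(s, .data$group == "rollup")
  tibble::tibble(
    n = attr(s, "total"),
    additive = rollup$n[rollup$mode == "additive"],
    nonadditive = rollup$n[rollup$mode == "nonadditive"],
    other = rollup$n[rollup$mode == "other"]
  )
}
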
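#' Reads per kilobase per million mapped reads
#'
#' `RPKM = 1e9 * C / (N * L)` for a gene with `C` uniquely mapped reads and
#' length `L` bp in a library of `N` mapped reads: a within-sample abundance
#' normalised for gene length and sequencing depth.
#'
#' @param count Non-negative read count(s).
#' @param length_bp Gene length(s) in bp, at least 1.
#' @param lib_size Total mapped reads in the library, at least 1.
#' @return Non-negative RPKM value(s); zero iff the count is zero.
#' @examples
#' rpkm(100, 500, 2e7) # 10
#' @export
rpkm <- function(count, length_bp, lib_size) {
  if (any(length_bp < 1) || any(lib_size < 1)) {
    stop("length_bp and lib_size must be >= 1", call. = FALSE)
  }
  stopifnot(all(count >= 0))
  # double arithmetic: lib_size * length_bp overflows integer storage
  1e9 * as.numeric(count) / (as.numeric(lib_size) * as.numeric(length_bp))
}

#' Per-library expression calls
#'
#' A gene is called expressed in a library when its raw count reaches
#' `min_count` *and* its RPKM reaches `min_rpkm`: the count floor guards
#' against single stray reads in short genes, the RPKM floor keeps the rule
#' depth- and length-aware. Both thresholds are configurable.
#'
#' @param counts A `count_table` (see [count_table()]).
#' @param min_count Minimum raw count (default 5).
#' @param min_rpkm Minimum RPKM (default 0.5).
#' @return An `expression_table` tibble: `gene_id`, `rpkm_P1`, `rpkm_P2`,
#'   `rpkm_F1`, `expressed_P1`, `expressed_P2`, `expressed_F1`.
#' @export
call_expressed <- function(counts, min_count = 5, min_rpkm = 0.5) {
  stopifnot(inherits(counts, "mp_count_table"))
  ls <- lib_sizes(counts)
  out <- tibble::tibble(gene_id = counts$gene_id)
  for (lib in c("P1", "P2", "F1")) {
    cc <- counts[[paste0("count_", lib)]]
    rk <- rpkm(cc, counts$length_bp, ls[[lib]])
    out[[paste0("rpkm_", lib)]] <- rk
    out[[paste0("expressed_", lib)]] <- cc >= min_count & rk >= min_rpkm
  }
  attr(out, "thresholds") <- c(min_count = min_count, min_rpkm = min_rpkm)
  class(out) <- c("mp_expression", class(out))
  out
}

.venn_regions <- c("P1_only", "P2_only", "F1_only", "P1P2_only",
                   "P1F1_only", "P2F1_only", "all_three")

#' Seven-region partition of the expressed gene sets
#'
#' Partitions the genes expressed in at least one library into the seven
#' disjoint regions of the three-set Venn diagram, and derives the two sets
#' that track hybrid-specific behaviour: `silenced_in_hybrid` (expressed in
#' both parents but not in the F1 -- exactly the P1-and-P2-only region) and
#' `activated_in_hybrid` (expressed in the F1 but in neither parent -- the
#' F1-only region).
#'
#' @param expr An `expression_table` from [call_expressed()].
#' @return A `venn_partition` object: list with `regions` (tibble of region,
#'   `n`, and gene-id list), `silenced_in_hybrid` and `activated_in_hybrid`
#'   character vectors, and `n_expressed_any`.
#' @export
venn_partition <- function(expr) {
  stopifnot(all(c("expressed_P1", "expressed_P2", "expressed_F1") %in% names(expr)))
  p1 <- expr$expressed_P1
  p2 <- expr$expressed_P2
  f1 <- expr$expressed_F1
  region <- dplyr::case_when(
    p1 & p2 & f1 ~ "all_three",
    p1 & p2 & !f1 ~ "P1P2_only",
    p1 & !p2 & f1 ~ "P1F1_only",
    !p1 & p2 & f1 ~ "P2F1_only",
    p1 & !p2 & !f1 ~ "P1_only",
    !p1 & p2 & !f1 ~ "P2_only",
    !p1 & !p2 & f1 ~ "F1_only",
    .default = NA_character_
  )
  keep <- !is.na(region)
  ids <- split(expr$gene_id[keep], factor(region[keep], levels = .venn_regions))
  regions <- tibble::tibble(
    region = .venn_regions,
    n = as.integer(lengths(ids)),
    genes = unname(purrr::map(ids, as.character))
  )
  out <- list(
    regions = regions,
    silenced_in_hybrid = as.character(ids$P1P2_only),
    activated_in_hybrid = as.character(ids$F1_only),
    n_expressed_any = sum(keep)
  )
  class(out) <- "mp_venn"
  out
}

#' @export
print.mp_venn <- function(x, ...) {
  cat("Expressed-set partition (", x$n_expressed_any, " genes in >=1 library)\n", sep = "")
  print(dplyr::select(x$regions, "region", "n"))
  cat("silenced in hybrid: ", length(x$silenced_in_hybrid),
      " | activated in hybrid: ", length(x$activated_in_hybrid), "\n", sep = "")
  invisible(x)
}
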
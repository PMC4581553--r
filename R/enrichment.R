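#' Upper-tail hypergeometric enrichment of a gene set in a unit
#'
#' With a background of `N` genes of which `K` lie in the unit (a chromosome
#' or a GO term) and a query set of `n` genes of which `k` lie in the unit,
#' the enrichment p-value is the upper tail `P(X >= k)` of the
#' hypergeometric distribution -- the chance of drawing at least `k` unit
#' genes when `n` genes are sampled from the background without replacement.
#'
#' @param set_genes Character vector: the query gene set (must be within the
#'   background).
#' @param unit_genes Character vector: the genes in the unit.
#' @param background Character vector: the background universe (non-empty).
#' @param unit Optional label for the unit.
#' @param gene_set_label Optional label for the query set.
#' @return A one-row `enrichment` tibble: `unit`, `gene_set_label`, `k`,
#'   `K`, `n`, `N`, `p_value` (no FDR; that is added by the scan functions).
#' @examples
#' hypergeom_enrich(c("g1", "g2"), paste0("g", 1:5), paste0("g", 1:10))
#' @export
hypergeom_enrich <- function(set_genes, unit_genes, background,
                             unit = NA_character_, gene_set_label = NA_character_) {
  background <- unique(background)
  if (length(background) == 0) stop("background is empty", call. = FALSE)
  set_genes <- intersect(unique(set_genes), background)
  unit_genes <- intersect(unique(unit_genes), background)
  k <- length(intersect(set_genes, unit_genes))
  K <- length(unit_genes)
  n <- length(set_genes)
  N <- length(background)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- tibble::tibble(unit = unit, gene_set_label = gene_set_label,
                        k = k, K = K, n = n, N = N, p_value = p)
  class(out) <- c("mp_enrichment", class(out))
  out
}

#' Chromosome accumulation scan for dominance classes
#'
#' Tests every (chromosome, gene-action mode) pair for over-representation of
#' that mode's genes on that chromosome. The background is all classified
#' DEGs *with a chromosome assignment* -- the scan asks where expression
#' variation landed among DEGs, not whether a chromosome is expression-rich.
#' BH correction is applied across the whole scan. Per-subgenome totals
#' (A / C / unassigned counts per mode) are attached as the
#' `subgenome_totals` attribute.
#'
#' @param calls A `dominance` tibble (or any data frame with `gene_id` and
#'   `mode`).
#' @param annot An `annotation` tibble (see [annotation_table()]).
#' @param modes Modes to scan; default every mode present in `calls`.
#' @param include_unplaced Keep unplaced genes in the background (they can
#'   never fall in a chromosome unit); default `FALSE`.
#' @return An `enrichment` tibble with one row per (chromosome, mode),
#'   columns as in [hypergeom_enrich()] plus `fdr`, sorted by `fdr`.
#' @export
chromosome_scan <- function(calls, annot, modes = NULL, include_unplaced = FALSE) {
  stopifnot(all(c("gene_id", "mode") %in% names(calls)))
  joined <- dplyr::inner_join(
    tibble::as_tibble(calls)[c("gene_id", "mode")],
    tibble::as_tibble(annot)[c("gene_id", "chromosome", "subgenome")],
    by = "gene_id"
  )
  if (!include_unplaced) {
    joined <- dplyr::filter(joined, .data$chromosome != "unplaced")
  }
  if (is.null(modes)) modes <- sort(unique(joined$mode))
  background <- joined$gene_id
  chroms <- sort(unique(joined$chromosome))
  grid <- tidyr::expand_grid(chromosome = chroms, mode = modes)
  res <- purrr::pmap_dfr(grid, function(chromosome, mode) {
    hypergeom_enrich(
      set_genes = joined$gene_id[joined$mode == mode],
      unit_genes = joined$gene_id[joined$chromosome == chromosome],
      background = background,
      unit = chromosome, gene_set_label = mode
    )
  })
  res$fdr <- bh_fdr(res$p_value)
  res <- dplyr::arrange(res, .data$fdr, .data$p_value)
  attr(res, "subgenome_totals") <- joined |>
    dplyr::count(.data$subgenome, .data$mode, name = "n") |>
    tidyr::pivot_wider(names_from = "mode", values_from = "n", values_fill = 0L)
  class(res) <- c("mp_chrom_scan", "mp_enrichment", class(tibble::tibble()))
  res
}

#' Per-subgenome totals attached to a chromosome scan
#' @param scan Result of [chromosome_scan()].
#' @return Tibble of mode counts per subgenome (A, C, unassigned).
#' @export
subgenome_totals <- function(scan) {
  st <- attr(scan, "subgenome_totals")
  if (is.null(st)) stop("no subgenome totals attached", call. = FALSE)
  st
}

#' GO term over-representation in a gene set
#'
#' One upper-tail hypergeometric test per GO term annotating at least
#' `min_genes` background genes, BH-corrected across terms. Terms are taken
#' from the annotation's `go_terms` list column; no DAG propagation is
#' performed (a term's genes are exactly the genes directly annotated with
#' it).
#'
#' @param deg_set Character vector of query genes.
#' @param annot An `annotation` tibble with a `go_terms` list column.
#' @param background Character vector of background genes (default: all
#'   annotated genes in `annot`).
#' @param min_genes Minimum background genes per term (default 3), so
#'   singleton terms do not dominate the correction.
#' @param gene_set_label Label stored with each row.
#' @return An `enrichment` tibble (one row per tested term, with `fdr`),
#'   sorted by `fdr`; empty with a warning when no term is testable.
#' @export
go_enrich <- function(deg_set, annot, background = NULL, min_genes = 3,
                      gene_set_label = "DEG") {
  stopifnot(all(c("gene_id", "go_terms") %in% names(annot)))
  if (is.null(background)) background <- annot$gene_id
  background <- unique(background)
  ann <- annot[annot$gene_id %in% background, c("gene_id", "go_terms")]
  long <- tidyr::unnest(ann, "go_terms")
  if (nrow(long) == 0) {
    warning("no GO-annotated genes in the background", call. = FALSE)
    return(empty_enrichment())
  }
  term_sizes <- dplyr::count(long, .data$go_terms)
  terms <- term_sizes$go_terms[term_sizes$n >= min_genes]
  if (length(terms) == 0) {
    warning("no GO term reaches min_genes = ", min_genes, call. = FALSE)
    return(empty_enrichment())
  }
  res <- purrr::map_dfr(terms, function(tm) {
    hypergeom_enrich(
      set_genes = deg_set,
      unit_genes = long$gene_id[long$go_terms == tm],
      background = background,
      unit = tm, gene_set_label = gene_set_label
    )
  })
  res$fdr <- bh_fdr(res$p_value)
  res <- dplyr::arrange(res, .data$fdr, .data$p_value)
  class(res) <- c("mp_enrichment", class(tibble::tibble()))
  res
}

empty_enrichment <- function() {
  out <- tibble::tibble(unit = character(), gene_set_label = character(),
                        k = integer(), K = integer(), n = integer(),
                        N = integer(), p_value = numeric(), fdr = numeric())
  class(out) <- c("mp_enrichment", class(out))
  out
}

#' Term-by-set p-value matrix from enrichment results
#'
#' Binds several enrichment scans (e.g. GO enrichment of different DEG sets)
#' and pivots them into the wide unit-by-set matrix behind an enrichment
#' heat map.
#'
#' @param ... `enrichment` tibbles (or one list of them).
#' @param value `"p_value"` (default) or `"fdr"`.
#' @return A tibble with one row per unit and one column per gene-set label.
#' @export
enrichment_matrix <- function(..., value = c("p_value", "fdr")) {
  value <- match.arg(value)
  parts <- list(...)
  if (length(parts) == 1 && !is.data.frame(parts[[1]])) parts <- parts[[1]]
  dplyr::bind_rows(parts) |>
    dplyr::select("unit", "gene_set_label", dplyr::all_of(value)) |>
    tidyr::pivot_wider(names_from = "gene_set_label", values_from = dplyr::all_of(value))
}

#' Transposable-element regulation calls in the hybrid
#'
#' Classifies each TE-flagged gene by presence/absence shifts and by the
#' quantitative midparent contrast:
#'
#' * `Active`: expressed in the F1 but in neither parent (hybridization
#'   awakened it);
#' * `Inactive`: expressed in at least one parent but not in the F1;
#' * `Up` / `Down`: expressed in the F1 and in at least one parent, with a
#'   significant F1-vs-midparent shift up / down;
#' * anything else is unclassified and dropped with a message.
#'
#' @param annot An `annotation` tibble with `is_te`.
#' @param expr An `expression_table` from [call_expressed()].
#' @param de A `detest` tibble containing the `MP_vs_F1` contrast.
#' @return A `te_calls` tibble: `gene_id`, `regulation`, `chromosome`,
#'   `te_family`.
#' @export
classify_te <- function(annot, expr, de) {
  stopifnot(inherits(expr, "mp_expression"))
  te <- dplyr::filter(tibble::as_tibble(annot), .data$is_te)
  mp_dir <- de |>
    dplyr::filter(.data$contrast == "MP_vs_F1") |>
    dplyr::select("gene_id", mp_direction = "direction")
  out <- te |>
    dplyr::inner_join(tibble::as_tibble(expr), by = "gene_id") |>
    dplyr::left_join(mp_dir, by = "gene_id") |>
    dplyr::mutate(
      any_parent = .data$expressed_P1 | .data$expressed_P2,
      regulation = dplyr::case_when(
        expressed_F1 & !any_parent ~ "Active",
        !expressed_F1 & any_parent ~ "Inactive",
        expressed_F1 & any_parent & mp_direction == "up_in_F1" ~ "Up",
        expressed_F1 & any_parent & mp_direction == "down_in_F1" ~ "Down",
        .default = NA_character_
      )
    )
  dropped <- sum(is.na(out$regulation))
  if (dropped > 0) {
    message(dropped, " TE gene(s) fit no regulation class and were dropped")
  }
  out <- out |>
    dplyr::filter(!is.na(.data$regulation)) |>
    dplyr::select("gene_id", "regulation", "chromosome", "te_family")
  class(out) <- c("mp_te_calls", class(out))
  out
}
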
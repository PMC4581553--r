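#' Configuration for the three-library simulator
#'
#' Defaults mirror the study design shrunk to desk size: 5,000 genes, three
#' libraries of 2e6 mapped reads, gene-action mode mixture proportional to
#' the published dominance-pattern counts, 2-fold effect size, mild
#' negative-binomial overdispersion, assembly-like gene lengths (log-normal,
#' mean about 1.3 kb, floor 200 bp), chromosome weights matching the A/C/
#' unplaced split of the mapped DEGs, sparse GO annotation and a small
#' TE-flagged subset.
#'
#' @param n_genes Number of genes.
#' @param lib_sizes Named vector `c(P1=, P2=, F1=)` of total mapped reads.
#' @param mode_proportions Named fractions over the seven geometric modes
#'   (ADD, HPD, LPD, ODO, UDO, PPD, NPD); must sum to 1 (tolerance 1e-9).
#' @param effect_fold Fold separation (>= 1) between the parents, and the
#'   hybrid's excess beyond the outer parent for ODO/UDO.
#' @param base_rpkm_meanlog,base_rpkm_sdlog Log-normal parameters of the
#'   per-gene base abundance, in RPKM units (expected RPKM of the geometric
#'   mean parent).
#' @param dispersion Negative-binomial dispersion phi (variance
#'   `mu + phi*mu^2`); 0 gives Poisson counts.
#' @param length_meanlog,length_sdlog,min_length Gene-length log-normal
#'   parameters and floor in bp.
#' @param chromosome_weights Named sampling weights over A01..A10, C01..C09
#'   and `unplaced`.
#' @param injected_enrichment `NULL`, or `list(chromosome=, mode=, fold=)`
#'   to multiply that chromosome's weight by `fold` for genes of that mode
#'   (for testing the enrichment scan).
#' @param go_n_terms Number of GO terms; `go_mean_genes` mean genes per term
#'   (Poisson).
#' @param go_mean_genes See `go_n_terms`.
#' @param te_fraction Fraction of genes flagged as transposon-like.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 5000,
                       lib_sizes = c(P1 = 2e6, P2 = 2e6, F1 = 2e6),
                       mode_proportions = NULL,
                       effect_fold = 2,
                       base_rpkm_meanlog = log(100),
                       base_rpkm_sdlog = 1,
                       dispersion = 0.1,
                       length_meanlog = log(1300) - 0.5^2 / 2,
                       length_sdlog = 0.5,
                       min_length = 200,
                       chromosome_weights = NULL,
                       injected_enrichment = NULL,
                       go_n_terms = 50,
                       go_mean_genes = 25,
                       te_fraction = 0.005,
                       seed = 1L) {
  if (is.null(mode_proportions)) {
    # published dominance-pattern counts over the seven geometric modes
    counts <- c(ADD = 1840, HPD = 353, LPD = 191, ODO = 593,
                UDO = 193, PPD = 1635, NPD = 1981)
    mode_proportions <- counts / sum(counts)
  }
  geo_modes <- setdiff(.modes, "OTHER")
  if (!setequal(names(mode_proportions), geo_modes)) {
    stop("mode_proportions must name exactly: ", paste(geo_modes, collapse = ", "),
         call. = FALSE)
  }
  if (abs(sum(mode_proportions) - 1) > 1e-9 || any(mode_proportions < 0)) {
    stop("mode_proportions must be non-negative and sum to 1", call. = FALSE)
  }
  if (is.null(chromosome_weights)) {
    # A : C : unplaced mass 2894 : 2107 : 593, spread evenly within a subgenome
    chromosome_weights <- c(
      stats::setNames(rep(2894 / 10, 10), sprintf("A%02d", 1:10)),
      stats::setNames(rep(2107 / 9, 9), sprintf("C%02d", 1:9)),
      unplaced = 593
    )
  }
  stopifnot(effect_fold >= 1, dispersion >= 0, te_fraction >= 0, te_fraction <= 1,
            min_length >= 1, n_genes >= 1)
  lib_sizes <- resolve_lib_sizes(lib_sizes)
  if (!is.null(injected_enrichment)) {
    stopifnot(all(c("chromosome", "mode", "fold") %in% names(injected_enrichment)))
  }
  structure(list(
    n_genes = as.integer(n_genes), lib_sizes = lib_sizes,
    mode_proportions = mode_proportions[geo_modes], effect_fold = effect_fold,
    base_rpkm_meanlog = base_rpkm_meanlog, base_rpkm_sdlog = base_rpkm_sdlog,
    dispersion = dispersion, length_meanlog = length_meanlog,
    length_sdlog = length_sdlog, min_length = min_length,
    chromosome_weights = chromosome_weights,
    injected_enrichment = injected_enrichment,
    go_n_terms = as.integer(go_n_terms), go_mean_genes = go_mean_genes,
    te_fraction = te_fraction, seed = as.integer(seed)
  ), class = "mp_sim_config")
}

#' Simulate a three-library experiment with known truth
#'
#' Per gene: a base abundance is drawn log-normally, the two parents are
#' placed `effect_fold` apart around it (geometric mean preserved, high
#' parent chosen at random), and the hybrid rate follows the gene's true
#' mode: the parental mean for ADD, the high/low parent for HPD/LPD,
#' `effect_fold` beyond the outer parent for ODO/UDO, and the geometric
#' midpoint between the midparent and the high/low parent for PPD/NPD (which
#' keeps partial dominance strictly between the parents for any
#' `effect_fold` > 1). Expected counts are `rate * length_bp * lib_size`
#' with rate in RPKM * 1e-9 units, so a gene's expected RPKM equals its
#' configured abundance; counts are Poisson or negative binomial.
#'
#' @param config A `sim_config`.
#' @param seed Overrides `config$seed` when given.
#' @return A `sim_result` list: `counts` (a `count_table`), `annotation`
#'   (an `annotation` tibble), `truth` (tibble: `gene_id`, `true_mode`,
#'   expected counts `lambda_P1`, `lambda_P2`, `lambda_F1`, `chromosome`,
#'   `go_terms`, `is_te`), and `config`.
#' @export
simulate_hybrid <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "mp_sim_config"))
  if (is.null(seed)) seed <- config$seed
  withr::with_seed(seed, simulate_hybrid_impl(config))
}

simulate_hybrid_impl <- function(cfg) {
  n <- cfg$n_genes
  gene_id <- sprintf("g%05d", seq_len(n))
  len <- pmax(cfg$min_length,
              round(stats::rlnorm(n, cfg$length_meanlog, cfg$length_sdlog)))
  mode <- sample(names(cfg$mode_proportions), n, replace = TRUE,
                 prob = cfg$mode_proportions)
  base_rate <- stats::rlnorm(n, cfg$base_rpkm_meanlog, cfg$base_rpkm_sdlog) * 1e-9
  p1_high <- stats::runif(n) < 0.5
  sf <- sqrt(cfg$effect_fold)
  hi <- base_rate * sf
  lo <- base_rate / sf
  mid <- (hi + lo) / 2
  rate_F1 <- dplyr::case_when(
    mode == "ADD" ~ mid,
    mode == "HPD" ~ hi,
    mode == "LPD" ~ lo,
    mode == "ODO" ~ hi * cfg$effect_fold,
    mode == "UDO" ~ lo / cfg$effect_fold,
    mode == "PPD" ~ sqrt(mid * hi),
    mode == "NPD" ~ sqrt(mid * lo)
  )
  rate_P1 <- ifelse(p1_high, hi, lo)
  rate_P2 <- ifelse(p1_high, lo, hi)

  ls <- cfg$lib_sizes
  draw <- function(rate, N) {
    mu <- rate * len * N
    if (cfg$dispersion == 0) stats::rpois(n, mu)
    else stats::rnbinom(n, mu = mu, size = 1 / cfg$dispersion)
  }
  counts_tbl <- tibble::tibble(
    gene_id = gene_id, length_bp = as.numeric(len),
    count_P1 = as.numeric(draw(rate_P1, ls[["P1"]])),
    count_P2 = as.numeric(draw(rate_P2, ls[["P2"]])),
    count_F1 = as.numeric(draw(rate_F1, ls[["F1"]]))
  )

  chrom <- purrr::map2_chr(mode, seq_len(n), function(md, i) {
    w <- cfg$chromosome_weights
    inj <- cfg$injected_enrichment
    if (!is.null(inj) && md == inj$mode) {
      w[[inj$chromosome]] <- w[[inj$chromosome]] * inj$fold
    }
    sample(names(w), 1, prob = w)
  })

  go_terms <- rep(list(character(0)), n)
  if (cfg$go_n_terms > 0) {
    for (t in seq_len(cfg$go_n_terms)) {
      term <- sprintf("GO:%07d", t)
      size <- min(n, stats::rpois(1, cfg$go_mean_genes))
      if (size > 0) {
        members <- sample.int(n, size)
        for (i in members) go_terms[[i]] <- c(go_terms[[i]], term)
      }
    }
  }
  is_te <- stats::runif(n) < cfg$te_fraction
  te_families <- c("Retrotransposon", "En/Spm", "hAT", "Tam3-like", "Tto1")
  te_family <- ifelse(is_te, sample(te_families, n, replace = TRUE), NA_character_)

  annot <- annotation_table(gene_id, chrom, go_terms = go_terms,
                            is_te = is_te, te_family = te_family)
  truth <- tibble::tibble(
    gene_id = gene_id, true_mode = mode,
    lambda_P1 = rate_P1 * len * ls[["P1"]],
    lambda_P2 = rate_P2 * len * ls[["P2"]],
    lambda_F1 = rate_F1 * len * ls[["F1"]],
    chromosome = annot$chromosome, go_terms = annot$go_terms, is_te = is_te
  )
  out <- list(counts = count_table(counts_tbl, ls), annotation = annot,
              truth = truth, config = cfg)
  class(out) <- "mp_sim_result"
  out
}

#' Noise-free count table at the simulated expected values
#'
#' Rounds the truth table's expected counts into a `count_table`; classifying
#' these recovers the true modes exactly for sufficiently expressed genes,
#' which separates classifier geometry from sampling noise.
#'
#' @param sim A `sim_result` from [simulate_hybrid()].
#' @return A `count_table` of rounded expected counts.
#' @export
expected_counts <- function(sim) {
  stopifnot(inherits(sim, "mp_sim_result"))
  count_table(tibble::tibble(
    gene_id = sim$truth$gene_id,
    length_bp = sim$counts$length_bp,
    count_P1 = round(sim$truth$lambda_P1),
    count_P2 = round(sim$truth$lambda_P2),
    count_F1 = round(sim$truth$lambda_F1)
  ), lib_sizes(sim$counts))
}

#' Confusion matrix and per-mode recovery against simulated truth
#'
#' Compares dominance calls with the generator's truth table. Headline
#' recovery is restricted to genes that were actually classified (i.e.
#' passed the DEG filter), optionally within an expression stratum.
#'
#' @param calls A `dominance` tibble.
#' @param truth The `truth` tibble from [simulate_hybrid()].
#' @param min_expected_count Restrict to genes whose smallest expected count
#'   across the three libraries reaches this value (default 0 = no
#'   stratification).
#' @return A `recovery` object: list with `confusion` (true mode by called
#'   mode tibble), `per_mode` (tibble: `true_mode`, `n_true`, `n_called`,
#'   `n_correct`, `recovery`), and `accuracy` (overall, over called genes).
#' @export
recovery_report <- function(calls, truth, min_expected_count = 0) {
  stopifnot(all(c("gene_id", "mode") %in% names(calls)),
            all(c("gene_id", "true_mode") %in% names(truth)))
  if (!all(calls$gene_id %in% truth$gene_id)) {
    stop("calls contain gene_ids absent from the truth table", call. = FALSE)
  }
  strat <- truth
  if (min_expected_count > 0) {
    strat <- dplyr::filter(
      truth,
      pmin(.data$lambda_P1, .data$lambda_P2, .data$lambda_F1) >= min_expected_count
    )
  }
  joined <- dplyr::left_join(strat[c("gene_id", "true_mode")],
                             tibble::as_tibble(calls)[c("gene_id", "mode")],
                             by = "gene_id")
  called <- dplyr::filter(joined, !is.na(.data$mode))
  confusion <- called |>
    dplyr::count(.data$true_mode, .data$mode) |>
    tidyr::pivot_wider(names_from = "mode", values_from = "n", values_fill = 0L)
  per_mode <- joined |>
    dplyr::group_by(.data$true_mode) |>
    dplyr::summarise(
      n_true = dplyr::n(),
      n_called = sum(!is.na(.data$mode)),
      n_correct = sum(.data$mode == .data$true_mode, na.rm = TRUE),
      recovery = ifelse(.data$n_called > 0, .data$n_correct / .data$n_called, NA_real_),
      .groups = "drop"
    )
  out <- list(
    confusion = confusion,
    per_mode = per_mode,
    accuracy = if (nrow(called) > 0) mean(called$mode == called$true_mode) else NA_real_
  )
  class(out) <- "mp_recovery"
  out
}

#' @export
print.mp_recovery <- function(x, ...) {
  cat("Mode recovery (called genes): accuracy ",
      sprintf("%.3f", x$accuracy), "\n", sep = "")
  print(x$per_mode)
  invisible(x)
}

#' Write a simulated experiment to a directory
#'
#' Writes `counts.tsv` + `sizes.yaml`, `annot.tsv` and `truth.tsv`.
#'
#' @param sim A `sim_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "mp_sim_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(sim$counts, file.path(dir, "counts.tsv"),
                    file.path(dir, "sizes.yaml"))
  write_results(sim$annotation, file.path(dir, "annot.tsv"))
  write_results(sim$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
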
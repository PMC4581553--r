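# Small in-code fixtures shared across test files.

make_counts <- function(n = 3, lib = c(P1 = 1e6, P2 = 1e6, F1 = 1e6)) {
  count_table(tibble::tibble(
    gene_id = paste0("g", seq_len(n)),
    length_bp = rep(1000, n),
    count_P1 = seq_len(n) * 10,
    count_P2 = seq_len(n) * 20,
    count_F1 = seq_len(n) * 15
  ), lib_sizes = lib)
}

# A count table engineered so every contrast is decided exactly (huge counts,
# equal library sizes): each row's geometry forces one classifier branch.
make_mode_counts <- function() {
  count_table(tibble::tibble(
    gene_id = c("odo", "udo", "add", "hpd", "lpd", "ppd", "npd"),
    length_bp = 1000,
    count_P1 = c(10000, 10000, 10000, 10000, 10000, 10000, 10000),
    count_P2 = c(20000, 20000, 20000, 20000, 20000, 20000, 20000),
    count_F1 = c(80000, 2500, 15000, 20000, 10000, 17500, 12500)
  ), lib_sizes = c(P1 = 1e6, P2 = 1e6, F1 = 1e6))
}

# Hand-built detest tibble from signed outcomes, for direct decision-tree
# tests. s1/s2/sm: F1 vs P1 / P2 / midparent; sp: P1_vs_P2 outcome coded as
# +1 = P2 higher (the contrast's own sign), so parent_order = -sp.
make_de_from_signs <- function(s1, s2, sm, sp, gene_id = "g1") {
  row <- function(contrast, s, p2_contrast = FALSE) {
    tibble::tibble(
      gene_id = gene_id, contrast = contrast,
      x = 100, y = 100,
      p_value = ifelse(s == 0, 1, 1e-6),
      fdr = ifelse(s == 0, 1, 1e-6),
      log2_ratio = s * 1,
      direction = if (s == 0) "none" else if (p2_contrast) {
        ifelse(s > 0, "up_in_P2", "down_in_P2")
      } else {
        ifelse(s > 0, "up_in_F1", "down_in_F1")
      },
      is_deg = TRUE
    )
  }
  de <- dplyr::bind_rows(
    row("P1_vs_F1", s1), row("P2_vs_F1", s2), row("MP_vs_F1", sm),
    row("P1_vs_P2", sp, p2_contrast = TRUE)
  )
  class(de) <- c("mp_detest", class(de))
  attr(de, "alpha") <- 0.05
  de
}

make_sign_counts <- function(gene_id = "g1") {
  count_table(tibble::tibble(
    gene_id = gene_id, length_bp = 1000,
    count_P1 = 100, count_P2 = 200, count_F1 = 150
  ), lib_sizes = c(P1 = 1e6, P2 = 1e6, F1 = 1e6))
}

# Brute-force minimum-likelihood two-sided p, independent of ac_test's
# tail-sum implementation.
brute_minlike <- function(x, y, N1, N2, ymax = 5000) {
  pmf <- ac_probability(x, 0:ymax, N1, N2)
  sum(pmf[pmf <= ac_probability(x, y, N1, N2) * (1 + 1e-9)])
}
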
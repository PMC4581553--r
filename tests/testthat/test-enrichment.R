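test_that("hypergeometric p matches direct combinatorics on small cases", {
  # N=10, K=5, n=2, k=2: C(5,2)/C(10,2) = 10/45
  r <- hypergeom_enrich(c("g1", "g2"), paste0("g", 1:5), paste0("g", 1:10))
  expect_equal(r$p_value, 10 / 45)
  expect_equal(c(r$k, r$K, r$n, r$N), c(2, 5, 2, 10))
  # k = 0 with n > 0: upper tail is 1
  r0 <- hypergeom_enrich(c("g9", "g10"), paste0("g", 1:5), paste0("g", 1:10))
  expect_equal(r0$p_value, 1)
  # unit = background: forced p = 1
  r1 <- hypergeom_enrich(paste0("g", 1:4), paste0("g", 1:20), paste0("g", 1:20))
  expect_equal(r1$p_value, 1)
  expect_error(hypergeom_enrich("g1", "g1", character(0)), "background")
})

test_that("hypergeometric upper tail matches full enumeration for N <= 25", {
  for (N in c(3, 7, 12, 18, 25)) {
    bg <- paste0("g", seq_len(N))
    for (K in c(0, 1, N %/% 3, N %/% 2, N)) {
      for (n in c(1, N %/% 2, N)) {
        unit <- bg[seq_len(K)]
        # deterministic worst-case overlap: the first n genes
        set <- bg[seq_len(n)]
        k <- length(intersect(set, unit))
        got <- hypergeom_enrich(set, unit, bg)$p_value
        js <- k:min(K, n)
        want <- sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
        expect_equal(got, want, tolerance = 1e-12,
                     label = sprintf("N=%d K=%d n=%d", N, K, n))
      }
    }
  }
})

make_truth_calls <- function(sim) {
  calls <- tibble::tibble(gene_id = sim$truth$gene_id, mode = sim$truth$true_mode)
  class(calls) <- c("mp_dominance", class(calls))
  calls
}

test_that("an injected LPD excess is the chromosome scan's top hit", {
  cfg <- sim_config(n_genes = 4000, seed = 31,
                    injected_enrichment = list(chromosome = "A06",
                                               mode = "LPD", fold = 5))
  sim <- simulate_hybrid(cfg)
  scan <- chromosome_scan(make_truth_calls(sim), sim$annotation)
  top <- scan[which.min(scan$fdr), ]
  expect_equal(top$unit, "A06")
  expect_equal(top$gene_set_label, "LPD")
  expect_lt(top$fdr, 0.05)
})

test_that("shuffling class labels destroys an injected enrichment", {
  cfg <- sim_config(n_genes = 4000, seed = 31,
                    injected_enrichment = list(chromosome = "A06",
                                               mode = "LPD", fold = 5))
  sim <- simulate_hybrid(cfg)
  calls <- make_truth_calls(sim)
  set.seed(77)
  broken <- 0
  for (i in 1:20) {
    shuffled <- calls
    shuffled$mode <- sample(shuffled$mode)
    scan <- chromosome_scan(shuffled, sim$annotation)
    hit <- scan[scan$unit == "A06" & scan$gene_set_label == "LPD", ]
    if (hit$fdr > 0.05) broken <- broken + 1
  }
  expect_gte(broken, 19)
})

test_that("a uniform mode assignment yields no chromosome hits in most seeds", {
  hits <- vapply(1:5, function(s) {
    sim <- simulate_hybrid(sim_config(n_genes = 2500, seed = 100 + s))
    scan <- chromosome_scan(make_truth_calls(sim), sim$annotation)
    sum(scan$fdr < 0.05)
  }, numeric(1))
  expect_gte(sum(hits == 0), 4)
})

test_that("all genes on one chromosome makes every test p = 1", {
  calls <- tibble::tibble(gene_id = paste0("g", 1:40),
                          mode = rep(c("LPD", "HPD"), 20))
  annot <- annotation_table(paste0("g", 1:40), "A01")
  scan <- chromosome_scan(calls, annot)
  expect_true(all(scan$p_value == 1))
})

test_that("subgenome totals tally classified genes per complement", {
  sim <- simulate_hybrid(sim_config(n_genes = 1000, seed = 8))
  calls <- make_truth_calls(sim)
  scan <- chromosome_scan(calls, sim$annotation, include_unplaced = TRUE)
  st <- subgenome_totals(scan)
  expect_setequal(st$subgenome,
                  intersect(c("A", "C", "unassigned"), sim$annotation$subgenome))
  expect_equal(sum(dplyr::select(st, -"subgenome")), nrow(calls))
})

test_that("GO enrichment matches hand combinatorics and honours min_genes", {
  # 20-gene background, one 5-gene term, 4-gene query with k = 3
  bg <- paste0("g", 1:20)
  go <- rep(list(character(0)), 20)
  for (i in 1:5) go[[i]] <- "GO:0000001"
  for (i in 1:2) go[[i]] <- c(go[[i]], "GO:0000002") # below min_genes = 3
  annot <- annotation_table(bg, "A01", go_terms = go)
  res <- go_enrich(c("g1", "g2", "g3", "g20"), annot, min_genes = 3)
  expect_equal(res$unit, "GO:0000001") # the 2-gene term is excluded
  want <- (choose(5, 3) * choose(15, 1) + choose(5, 4) * choose(15, 0)) / choose(20, 4)
  expect_equal(res$p_value, want, tolerance = 1e-12)

  # a term annotating exactly the query and nothing else: minimal p for (n, N)
  go2 <- rep(list(character(0)), 20)
  for (i in 1:4) go2[[i]] <- "GO:0000009"
  annot2 <- annotation_table(bg, "A01", go_terms = go2)
  res2 <- go_enrich(paste0("g", 1:4), annot2, min_genes = 3)
  expect_equal(res2$p_value, 1 / choose(20, 4), tolerance = 1e-12)

  expect_warning(
    empty <- go_enrich("g1", annotation_table("g1", "A01")),
    "GO"
  )
  expect_equal(nrow(empty), 0)
})

test_that("enrichment matrices pivot unit by gene-set", {
  sim <- simulate_hybrid(sim_config(n_genes = 800, seed = 9))
  calls <- make_truth_calls(sim)
  a <- go_enrich(calls$gene_id[calls$mode == "ODO"], sim$annotation,
                 gene_set_label = "ODO")
  b <- go_enrich(calls$gene_id[calls$mode == "ADD"], sim$annotation,
                 gene_set_label = "ADD")
  m <- enrichment_matrix(a, b)
  expect_true(all(c("unit", "ODO", "ADD") %in% names(m)))
  expect_equal(nrow(m), length(union(a$unit, b$unit)))
})

test_that("TE regulation follows the presence/absence and midparent rules", {
  annot <- annotation_table(paste0("g", 1:6), "A01",
                            is_te = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
                            te_family = "En/Spm")
  expr <- tibble::tibble(
    gene_id = paste0("g", 1:6),
    rpkm_P1 = 1, rpkm_P2 = 1, rpkm_F1 = 1,
    expressed_P1 = c(FALSE, TRUE, TRUE, TRUE, FALSE, TRUE),
    expressed_P2 = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE),
    expressed_F1 = c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE)
  )
  class(expr) <- c("mp_expression", class(expr))
  de <- dplyr::bind_rows(lapply(paste0("g", 1:6), function(g) {
    tibble::tibble(gene_id = g, contrast = "MP_vs_F1", x = 10, y = 10,
                   p_value = 1e-9, fdr = 1e-9, log2_ratio = ifelse(g == "g4", 1, -1),
                   direction = ifelse(g == "g4", "up_in_F1", "down_in_F1"),
                   is_deg = TRUE)
  }))
  class(de) <- c("mp_detest", class(de))
  te <- suppressMessages(classify_te(annot, expr, de))
  got <- stats::setNames(te$regulation, te$gene_id)
  expect_equal(got[["g1"]], "Active")   # F1 only
  expect_equal(got[["g2"]], "Inactive") # parents only
  expect_equal(got[["g3"]], "Down")     # shared, shifted down vs midparent
  expect_equal(got[["g4"]], "Up")       # shared, shifted up
  expect_false("g5" %in% te$gene_id)    # expressed nowhere: unclassified
  expect_false("g6" %in% te$gene_id)    # not TE-flagged
  expect_false(any(duplicated(te$gene_id))) # one regulation per gene
})
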
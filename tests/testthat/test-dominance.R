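test_that("mph follows the midparent-as-100 convention", {
  expect_equal(mph(10, 10, 10), 100)
  expect_equal(mph(7.5, 5, 10), 100) # h at the midparent
  expect_equal(mph(15, 10, 10), 150)
  expect_equal(mph(5, 10, 10), 50)
  expect_error(mph(5, 1, -1), "midparent")
})

test_that("the decision tree maps signed outcomes to the published modes", {
  # sp is the P1_vs_P2 outcome: +1 = P2 significantly higher
  cases <- tibble::tribble(
    ~s1, ~s2, ~sm, ~sp, ~expected,
    0L, 0L, 0L, 0L, "ADD",
    0L, 1L, 0L, -1L, "ADD",   # additivity wins regardless of parent contrasts
    1L, 1L, 1L, 0L, "ODO",
    1L, 1L, 1L, -1L, "ODO",
    -1L, -1L, -1L, 1L, "UDO",
    0L, 1L, 1L, -1L, "HPD",   # P1 the high parent, F1 matches it
    1L, 0L, 1L, 1L, "HPD",    # P2 the high parent, F1 matches it
    0L, -1L, -1L, 1L, "LPD",  # P1 the low parent, F1 matches it
    -1L, 0L, -1L, -1L, "LPD", # P2 the low parent, F1 matches it
    -1L, 1L, 1L, -1L, "PPD",  # strictly between, above midparent
    -1L, 1L, -1L, -1L, "NPD", # strictly between, below midparent
    1L, 0L, 1L, 0L, "OTHER",  # parents n.s.: HPD/LPD unreachable
    -1L, 0L, -1L, 0L, "OTHER"
  )
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    call <- classify_modes(
      make_de_from_signs(cs$s1, cs$s2, cs$sm, cs$sp),
      make_sign_counts(), genes = "g1"
    )
    expect_equal(call$mode, cs$expected,
                 label = sprintf("case (%d,%d,%d,%d)", cs$s1, cs$s2, cs$sm, cs$sp))
  }
})

test_that("every signed-outcome combination yields exactly one mode", {
  grid <- expand.grid(s1 = -1:1, s2 = -1:1, sm = -1:1, sp = -1:1)
  modes <- vapply(seq_len(nrow(grid)), function(i) {
    classify_modes(make_de_from_signs(grid$s1[i], grid$s2[i], grid$sm[i], grid$sp[i]),
                   make_sign_counts(), genes = "g1")$mode
  }, character(1))
  expect_true(all(modes %in% c("ADD", "HPD", "LPD", "ODO", "UDO", "PPD", "NPD", "OTHER")))
  expect_equal(modes == "ADD", grid$sm == 0)
  expect_true(all(modes[grid$s1 == 1 & grid$s2 == 1 & grid$sm != 0] == "ODO"))
  expect_true(all(modes[grid$s1 == -1 & grid$s2 == -1 & grid$sm != 0] == "UDO"))
  expect_true(all(modes[grid$sp == 0 & grid$sm != 0] %in%
                    c("ODO", "UDO", "OTHER"))) # HPD/LPD need ordered parents
})

test_that("engineered exact count geometries land in their modes end to end", {
  counts <- make_mode_counts()
  de <- run_contrasts(counts, min_log2fc = 0)
  calls <- classify_modes(de, counts, genes = counts$gene_id)
  got <- stats::setNames(calls$mode, calls$gene_id)
  expect_equal(got[c("odo", "udo", "add", "hpd", "lpd", "ppd", "npd")],
               c(odo = "ODO", udo = "UDO", add = "ADD", hpd = "HPD",
                 lpd = "LPD", ppd = "PPD", npd = "NPD"))
  # MPH on RPKM: midparent of 10/20 RPKM-scale counts is 15, so F1 = 15000 -> 100
  expect_equal(calls$mph[calls$gene_id == "add"], 100)
  expect_equal(calls$mph[calls$gene_id == "odo"],
               (80 - 15) / 15 * 100 + 100)
})

test_that("a missing contrast is an error naming the gene", {
  de <- make_de_from_signs(1L, 1L, 1L, 0L)
  de_missing <- de[de$contrast != "MP_vs_F1", ]
  class(de_missing) <- class(de)
  expect_error(classify_modes(de_missing, make_sign_counts(), genes = "g1"), "g1")
})

test_that("mode summaries count, percentage and roll up correctly", {
  calls <- tibble::tibble(mode = c("ODO", "ODO", "ADD", "OTHER"))
  s <- summarize_modes(calls)
  expect_equal(s$n[s$mode == "ODO"], 2L)
  expect_equal(s$percent[s$mode == "ODO"], 50)
  rollup <- s[s$group == "rollup", ]
  expect_equal(rollup$n[rollup$mode == "nonadditive"], 2L)
  expect_equal(sum(s$n[s$group != "rollup"]), sum(rollup$n))
  # nonadditive total is exactly the sum of its six classes
  expect_equal(rollup$n[rollup$mode == "nonadditive"],
               sum(s$n[s$mode %in% c("HPD", "LPD", "ODO", "UDO", "PPD", "NPD")]))

  empty <- summarize_modes(tibble::tibble(mode = character(0)))
  expect_true(all(empty$n == 0))

  single <- summarize_modes(tibble::tibble(mode = "ODO"))
  expect_equal(single$percent[single$group == "rollup" & single$mode == "nonadditive"], 100)
})

test_that("classifier recovers every mode when effects are well powered", {
  cfg <- sim_config(n_genes = 3000, base_rpkm_meanlog = log(2000),
                    base_rpkm_sdlog = 0.5, dispersion = 0, seed = 7)
  sim <- simulate_hybrid(cfg)
  de <- run_contrasts(sim$counts, min_log2fc = 0)
  calls <- classify_modes(de, sim$counts)
  rec <- recovery_report(calls, sim$truth, min_expected_count = 2000)
  expect_true(all(rec$per_mode$recovery >= 0.9))
  expect_gt(rec$accuracy, 0.95)
})

test_that("noise-free expected counts recover well-powered modes exactly", {
  cfg <- sim_config(n_genes = 1500, base_rpkm_meanlog = log(2000),
                    base_rpkm_sdlog = 0.5, dispersion = 0, seed = 13)
  sim <- simulate_hybrid(cfg)
  exact <- expected_counts(sim)
  de <- run_contrasts(exact, min_log2fc = 0)
  calls <- classify_modes(de, exact, genes = exact$gene_id)
  rec <- recovery_report(calls, sim$truth, min_expected_count = 2000)
  expect_equal(rec$accuracy, 1)
  expect_true(all(rec$per_mode$recovery == 1))
})
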
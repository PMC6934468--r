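# small synthetic sweep_result for the pure bookkeeping operations
fake_sweep <- function(df, mode = "therapy") {
  df$kd <- df$koff / df$kon
  df$status <- "ok"
  structure(df, class = c("sweep_result", "data.frame"), mode = mode,
            n_failed = 0L)
}

test_that("the default grid has the documented shape", {
  g <- sweep_grid()
  expect_equal(nrow(grid_cells(g)), 6 * 7 * 3)
  expect_equal(g$amounts, 10^seq(0, 3, by = 0.5))
  expect_error(sweep_grid(amounts = c(10, 5)), "increasing")
  expect_error(sweep_grid(amounts = c(0.5, 10)), "increasing|\\[1, 1000\\]")
})

test_that("a sweep produces one record per cell, patient, tissue and metric", {
  cohort <- generate_cohort(cohort_spec(2, seed = 5L))
  g <- sweep_grid(combos = kinetics_combos()[c(4, 6), ],
                  amounts = c(10^1.5, 100), lambda_ints = 0.001,
                  mode = "imaging")
  sw <- run_sweep(cohort, g)
  expect_s3_class(sw, "sweep_result")
  expect_equal(nrow(sw), 2 * 2 * 2 * 9)  # combos x amounts x patients x panel
  expect_equal(attr(sw, "n_failed"), 0L)
  expect_equal(sw$kd, sw$koff / sw$kon)
  # order independence: a grid listing the combos in reverse order gives the
  # same canonical records
  g_rev <- sweep_grid(combos = kinetics_combos()[c(6, 4), ],
                      amounts = c(10^1.5, 100), lambda_ints = 0.001,
                      mode = "imaging")
  sw_rev <- run_sweep(cohort, g_rev)
  expect_equal(sw, sw_rev, ignore_attr = TRUE)
})

test_that("infeasible therapy cells are flagged and do not abort the sweep", {
  cohort <- generate_cohort(cohort_spec(1, seed = 5L))
  g <- sweep_grid(combos = kinetics_combos()[4, , drop = FALSE],
                  amounts = c(1, 100), lambda_ints = 0.001, mode = "therapy")
  sw <- run_sweep(cohort, g)
  expect_equal(attr(sw, "n_failed"), 1L)  # 1 nmol < ~10 nmol hot amount
  bad <- sw[sw$metric == "error", ]
  expect_equal(bad$amount, 1)
  expect_match(bad$status, "infeasible")
  expect_true(any(sw$metric == "dose_Gy" & sw$amount == 100))
})

test_that("fold change reduces to the identity and matches a hand-computed toy", {
  df <- expand.grid(patient = c("a", "b"), amount = c(1, 10),
                    stringsAsFactors = FALSE)
  df$kon <- 0.1; df$koff <- 0.01; df$lambda_int <- 0.001
  df$tissue <- "kidneys"; df$metric <- "dose_Gy"
  df$value <- c(1, 2, 2, 8)  # ratios 2 and 4
  sw <- fake_sweep(df)
  cell1 <- list(kon = 0.1, koff = 0.01, lambda_int = 0.001, amount = 1)
  cell10 <- list(kon = 0.1, koff = 0.01, lambda_int = 0.001, amount = 10)
  same <- fold_change(sw, "kidneys", "dose_Gy", cell1, cell1)
  expect_equal(same$mean, 1); expect_equal(same$sd, 0)
  fc <- fold_change(sw, "kidneys", "dose_Gy", cell1, cell10)
  expect_equal(fc$mean, 3)
  expect_equal(fc$sd, sqrt(2), tolerance = 1e-12)  # n-1 denominator
  expect_equal(fc$n, 2)
  # zero denominator excludes the patient with a warning
  sw$value[1] <- 0
  expect_warning(fc0 <- fold_change(sw, "kidneys", "dose_Gy", cell1, cell10),
                 "zero denominator")
  expect_equal(fc0$n, 1)
  expect_error(fold_change(sw, "kidneys", "dose_Gy", cell1,
                           list(kon = 9, koff = 1, lambda_int = 1,
                                amount = 1)), "not present")
})

test_that("find_optimum recovers a planted maximum and breaks ties downward", {
  df <- expand.grid(patient = c("a", "b"), amount = c(10, 100),
                    kon = c(0.01, 0.1), stringsAsFactors = FALSE)
  df$koff <- 0.01; df$lambda_int <- 0.001
  df$tissue <- "tumour_rest"; df$metric <- "t2k_ratio"
  df$value <- 1
  df$value[df$amount == 100 & df$kon == 0.1] <- 5  # planted max
  sw <- fake_sweep(df)
  opt <- find_optimum(sw, tissue = "tumour_rest")
  expect_equal(opt$amount, 100)
  expect_equal(opt$kon, 0.1)
  # tie everywhere: smallest amount, then smallest kon wins
  df$value <- 1
  opt_tie <- find_optimum(fake_sweep(df), tissue = "tumour_rest")
  expect_equal(opt_tie$amount, 10)
  expect_equal(opt_tie$kon, 0.01)
})

test_that("the tumour-to-kidney table has the documented layout", {
  cohort <- generate_cohort(cohort_spec(2, seed = 5L))
  g <- sweep_grid(combos = kinetics_combos()[c(4, 6), ],
                  amounts = 10^c(1.5, 2, 2.5), lambda_ints = c(0.01, 0.001),
                  mode = "therapy")
  sw <- run_sweep(cohort, g)
  tab <- tumour_to_kidney_table(sw)
  # combos x amounts x lambda_ints x groupings
  expect_equal(nrow(tab), 2 * 3 * 2 * 2)
  expect_true(all(tab$mean > 0))
  expect_equal(tab$n, rep(2, nrow(tab)))
  # exactly one flagged maximum per (lambda_int, group) column
  flags <- stats::aggregate(is_max ~ lambda_int + group, tab, sum)
  expect_true(all(flags$is_max == 1))
  expect_error(tumour_to_kidney_table(structure(sw, mode = "imaging")),
               "therapy")
})
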
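# Synthetic response tables let the analysis pipeline be tested without
# running the image model.
fake_responses <- function(n_units = 10L, n_families = 8L, seed = 1L,
                           constant = FALSE, model = "extended") {
  withr::with_seed(seed, {
    grid <- expand.grid(unit_id = sprintf("unit%02d", seq_len(n_units)),
                        family_id = sprintf("fam%02d", seq_len(n_families)),
                        stimulus = c("base", paste0("mp", 1:4), "nap"),
                        stringsAsFactors = FALSE)
    grid$model <- model
    grid$response <- if (constant) 0.5 else runif(nrow(grid), 0.05, 1)
    tibble::as_tibble(grid[, c("model", "unit_id", "family_id", "stimulus",
                               "response")])
  })
}

test_that("percent modulation follows the response-change formula", {
  expect_equal(percent_modulation(1, 1), 0)
  expect_equal(percent_modulation(2, 1), 50)
  expect_equal(percent_modulation(0.5, 0.6), -20)
  expect_true(is.na(percent_modulation(1e-9, 0.5)))
  expect_equal(percent_modulation(c(2, 4), c(1, 1)), c(50, 75))
})

test_that("responsiveness selection keeps the expected comparisons", {
  resp <- fake_responses()
  all_kept <- select_comparisons(resp, criterion = 0)
  expect_equal(nrow(all_kept), 10L * 8L)
  expect_error(select_comparisons(resp, criterion = 1.5), "no .* pair")

  # per-unit percentile rule keeps about the top half per unit
  kept <- select_comparisons(resp,
                             responsiveness_criterion("percentile",
                                                      quantile = 0.5,
                                                      floor = 0))
  expect_equal(nrow(kept), 10L * 4L)
  # threshold respects the absolute floor
  kept_floor <- select_comparisons(resp,
                                   responsiveness_criterion("percentile",
                                                            quantile = 0,
                                                            floor = 0.9))
  expect_true(all(kept_floor$r_base > 0.9))

  # the default preferred-stimulus rule keeps exactly one comparison per
  # unit, at its maximally driving family
  pref <- select_comparisons(resp, responsiveness_criterion())
  expect_equal(nrow(pref), 10L)
  expect_false(any(duplicated(pref$unit_id)))
  base <- dplyr::filter(resp, .data$stimulus == "base")
  best <- tapply(base$response, base$unit_id, max)
  expect_equal(as.numeric(best[pref$unit_id]), pref$r_base)
})

test_that("the modulation analysis pairs every kept comparison exactly
           once", {
  resp <- fake_responses(seed = 21)
  ana <- modulation_analysis(resp)
  expect_s3_class(ana$records, "tbl_df")
  expect_equal(nrow(ana$records), ana$summary$n_comparisons)
  expect_false(any(duplicated(ana$records[c("unit_id", "family_id")])))
  expect_true(all(c("delta_nap", "delta_mp1", "delta_mp2", "delta_mp3",
                    "delta_mp4") %in% names(ana$records)))
  expect_true(ana$summary$frac_nap_gt_mp >= 0 &&
                ana$summary$frac_nap_gt_mp <= 100)
  # deterministic given the response table
  ana2 <- modulation_analysis(resp)
  expect_identical(ana$records, ana2$records)
  expect_identical(ana$summary, ana2$summary)
  # spot-check one record against the formula
  rec <- ana$records[3, ]
  raw <- tidyr::pivot_wider(
    dplyr::filter(resp, .data$unit_id == rec$unit_id,
                  .data$family_id == rec$family_id),
    names_from = "stimulus", values_from = "response")
  expect_equal(rec$delta_nap, (raw$base - raw$nap) / raw$base * 100)
})

test_that("a constant encoder yields zero modulation and a flagged
           degenerate test", {
  resp <- fake_responses(constant = TRUE)
  ana <- modulation_analysis(resp, criterion = 0)
  expect_true(all(ana$records$delta_nap == 0))
  expect_equal(ana$summary$frac_nap_gt_mp, 0)
  expect_equal(ana$summary$wilcoxon_p, 1)
  expect_true(ana$summary$degenerate)
})

test_that("mixed-model tables are rejected and tidiers expose the results", {
  both <- dplyr::bind_rows(fake_responses(model = "original"),
                           fake_responses(model = "extended"))
  expect_error(modulation_analysis(both), "single model")
  ana <- modulation_analysis(fake_responses())
  expect_identical(tidy(ana), ana$records)
  expect_identical(glance(ana), ana$summary)
  p <- autoplot(ana)
  expect_s3_class(p, "ggplot")
})
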
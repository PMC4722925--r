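test_that("the study grid enumerates the full schedule design deterministically", {
  grid <- build_study_grid()
  # 3 doses x (1 continuous + 6 two-fraction + 2 x 3 multi-fraction)
  expect_identical(nrow(grid), 3L * (1L + 6L + 3L + 3L))
  expect_identical(grid, build_study_grid())

  has_row <- function(D, n, Tm) {
    any(grid$total_dose == D & grid$n_subfractions == n &
          grid$overall_time == Tm)
  }
  expect_true(has_row(4, 2, 240))
  expect_true(has_row(4, 8, 30))
  expect_true(has_row(6, 8, 240))
  # published spacing: interval reading for n = 2, session reading beyond
  expect_identical(unique(grid$spacing[grid$n_subfractions == 2]),
                   "start_to_start")
  expect_identical(unique(grid$spacing[grid$n_subfractions == 8]), "gap")
})

test_that("predict_grid populates every (scheme, line, method) row", {
  grid <- build_study_grid(total_doses = 4)
  res <- predict_grid(grid, list(f10b16, t4_1))
  expect_identical(nrow(res), nrow(grid) * 2L * 4L)
  expect_true(all(res$feasible))
  expect_false(any(is.na(res$survival)))

  # an infeasible scheme is flagged, not dropped
  bad <- rbind(grid,
               data.frame(total_dose = 4, n_subfractions = 8,
                          overall_time = 4, dose_rate = 0.81,
                          spacing = "gap"))
  res_bad <- predict_grid(bad, list(f10b16), methods = "mu")
  expect_identical(nrow(res_bad), nrow(bad))
  expect_identical(sum(!res_bad$feasible), 1L)
})

test_that("method behaviour across the grid matches the models' structure", {
  res <- predict_grid(build_study_grid(total_doses = 4),
                      list(f10b16, t4_1))

  # basic LQ is time-independent at fixed dose
  basic <- res[res$method == "basic", ]
  expect_identical(length(unique(round(basic$survival, 12))), 2L)

  # incomplete-repair survival rises with overall time at fixed (D, n)
  for (cl in c("F10B16", "4T1")) {
    for (n in c(2, 4, 8)) {
      s <- res[res$method == "mu" & res$cell_line == cl &
                 res$n_subfractions == n, ]
      s <- s[order(s$overall_time), ]
      expect_true(all(diff(s$survival) > 0))
    }
  }

  # the continuous-protraction model depends on overall time only, not on
  # how the dose is split
  br <- res[res$method == "brenner" & res$n_subfractions >= 2, ]
  for (cl in c("F10B16", "4T1")) {
    for (Tm in c(30, 60, 240)) {
      s <- br$survival[br$cell_line == cl & br$overall_time == Tm]
      expect_true(length(s) >= 3 && diff(range(s)) < 1e-12)
    }
  }
})

test_that("the published 4 Gy table is reproduced within tolerance", {
  rr <- reproduce_reference_table()
  expect_lte(attr(rr, "max_abs_diff"), 0.005)
  expect_lte(max(rr$abs_diff[rr$n_subfractions == 2]), 0.002)
  expect_identical(nrow(rr), 26L)
})

test_that("compare_methods ranks by agreement and flags empty overlap", {
  preds <- predict_grid(build_study_grid(total_doses = 4),
                        list(f10b16, t4_1))

  # self-comparison: the mu predictions as reference give zero error
  self_ref <- preds[preds$method == "mu", ]
  self_ref$experimental_mean <- self_ref$survival
  cmp_self <- compare_methods(preds, self_ref)
  expect_identical(cmp_self$best_method, "mu")
  expect_equal(cmp_self$by_method$rmse[cmp_self$by_method$method == "mu"],
               0, tolerance = 1e-15)

  # zero-noise simulated experiment: mu exact, the others not, on the
  # longer multi-subfraction schemes
  schemes <- list(fraction_scheme(4, 2, 240),
                  fraction_scheme(4, 4, 240, spacing = "gap"),
                  fraction_scheme(4, 8, 240, spacing = "gap"))
  sim <- simulate_survival_experiment(list(f10b16, t4_1), schemes,
                                      noise = noiseless())
  cmp_sim <- compare_methods(preds, sim)
  bm <- cmp_sim$by_method
  expect_equal(bm$rmse[bm$method == "mu"], 0, tolerance = 1e-12)
  expect_true(all(bm$rmse[bm$method != "mu"] > 0))

  # against the measured reference, the incomplete-repair model wins
  cmp_ref <- compare_methods(preds, reference_survival_table())
  expect_identical(cmp_ref$best_method, "mu")

  no_overlap <- data.frame(cell_line = "HeLa", n_subfractions = 3,
                           overall_time = 99, experimental_mean = 0.5)
  expect_error(compare_methods(preds, no_overlap),
               class = "lqfrac_usage_error")
})

test_that("the subfraction-effect report captures the sign structure", {
  preds <- predict_grid(build_study_grid(total_doses = 4),
                        list(f10b16, t4_1))
  rep_ <- subfraction_effect_report(preds)

  dir_of <- function(m, cl, Tm) {
    rep_$direction[rep_$method == m & rep_$cell_line == cl &
                     rep_$overall_time == Tm]
  }
  # short overall time: more subfractions -> less repair -> lower survival
  expect_identical(dir_of("mu", "F10B16", 30), rep("decrease", 2))
  expect_identical(dir_of("mu", "4T1", 30), rep("decrease", 2))
  # long overall time: more subfractions -> smaller per-pair interaction
  expect_identical(dir_of("mu", "F10B16", 240), rep("increase", 2))
  expect_identical(dir_of("mu", "4T1", 240), rep("increase", 2))
  # basic LQ ignores the split entirely
  expect_true(all(rep_$direction[rep_$method == "basic"] == "none"))
  # continuous-protraction model invariant to the split at fixed time
  expect_true(all(rep_$direction[rep_$method == "brenner"] == "none"))
})

test_that("result grids serialise deterministically", {
  preds <- predict_grid(build_study_grid(total_doses = 2),
                        list(f10b16))
  t1 <- withr::local_tempfile(fileext = ".csv")
  t2 <- withr::local_tempfile(fileext = ".csv")
  write_result_grid(preds, t1)
  write_result_grid(preds[sample(nrow(preds)), ], t2) # row order canonical
  expect_identical(readBin(t1, "raw", file.size(t1)),
                   readBin(t2, "raw", file.size(t2)))
  t3 <- withr::local_tempfile(fileext = ".json")
  write_result_json(preds, t3)
  back <- jsonlite::read_json(t3, simplifyVector = TRUE)
  expect_equal(back$survival, preds$survival, tolerance = 1e-12)
})
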
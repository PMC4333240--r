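test_that("configs round-trip through YAML losslessly", {
  cfg <- sim_config("test", input = list(fraction_pct = 0.25,
                                         form = "sqrt"),
                    adhesion = list(dl = 0.01))
  f <- tempfile(fileext = ".yaml")
  write_config(cfg, f)
  expect_identical(load_config(f), cfg)
})

test_that("unknown or malformed configuration keys are reported", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("profile: test", "inptu:", "  form: linear"), f)
  expect_error(load_config(f), "unknown keys.*inptu")
  writeLines(c("profile: test", "input:", "  frm: linear"), f)
  expect_error(load_config(f), "unknown keys.*input\\.frm")
  writeLines("profile: nope", f)
  expect_error(load_config(f), "unknown profile")
  expect_error(sim_config("test", input = list(form = "cubic")),
               "unknown input.form")
  expect_error(sim_config("test", dt_min = 7), "whole steps")
})

test_that("out-of-grid LTin input is flagged but allowed", {
  expect_warning(sim_config("test", input = list(fraction_pct = 0.01)),
                 "outside the explored")
  expect_warning(sim_config("test", input = list(fold = 6)),
                 "outside the explored")
  expect_silent(cfg <- sim_config("test", input = list(fraction_pct = 0.10)))
})

test_that("cell-count experiment table has the expected structure", {
  cfg <- test_cfg()
  tab <- cellcount_experiment(cfg, fractions = c(0.25, 0.45), folds = 2,
                              n_reps = 3, base_seed = 1)
  # three conditions x two responses
  expect_equal(nrow(tab), 6)
  expect_setequal(unique(tab$condition),
                  c("baseline", "fraction_0.25pct", "fold_2x"))
  # the baseline rows compare the baseline with itself: a = 0.5 exactly
  expect_equal(tab$a[tab$condition == "baseline"], c(0.5, 0.5))
  expect_equal(tab$category[tab$condition == "baseline"],
               c("none", "none"))
  # every row's category is consistent with its a
  expect_equal(tab$category, classify_effect(tab$a))
  expect_error(cellcount_experiment(cfg, n_reps = 1), "domain error")
})

test_that("default experiment grids give 13 conditions and 26 rows", {
  # structural check only: don't run the simulator, count the conditions
  fr <- sort(unique(c(seq(0.05, 0.45, by = 0.05), 0.45)))
  expect_length(fr, 9)                         # 8 reduced + baseline
  expect_equal(9 + 4, 13)                      # plus 2..5 fold
  expect_equal(13 * 2, 26)                     # two responses per condition
})

test_that("experiments are reproducible under the same base seed", {
  cfg <- test_cfg()
  t1 <- cellcount_experiment(cfg, fractions = 0.45, folds = 2, n_reps = 3,
                             base_seed = 11)
  t2 <- cellcount_experiment(cfg, fractions = 0.45, folds = 2, n_reps = 3,
                             base_seed = 11)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
})

test_that("degenerate no-input conditions compare cleanly with baseline", {
  cfg <- test_cfg()
  tab <- cellcount_experiment(cfg, fractions = c(0, 0.45), folds = integer(0),
                              n_reps = 3, base_seed = 3)
  sub <- tab[tab$condition == "fraction_0.00pct", ]
  expect_equal(nrow(sub), 2)
  expect_true(all(is.finite(sub$a)))
})

test_that("migration experiment enforces the linear baseline", {
  cfg <- test_cfg()
  expect_error(migration_experiment(cfg, forms = c("exponential", "sqrt"),
                                    n_reps = 3), "linear")
  expect_error(migration_experiment(cfg, forms = c("linear", "cubic"),
                                    n_reps = 3), "unknown input form")
  tab <- migration_experiment(cfg, forms = "linear", n_reps = 3,
                              base_seed = 2)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$a, c(0.5, 0.5))
})

test_that("all migration schedules inject the same cells by E15.5", {
  cfg <- test_cfg()
  area <- cfg$environment$width_um * cfg$environment$height_um
  n <- e155_count(cfg$input$fraction_pct / 100, area,
                  cfg$cells$motile_radius_um)
  for (form in c("linear", "exponential", "sqrt")) {
    s <- input_schedule(form, n, k = cfg$input$k_per_hour)
    expect_equal(floor(cumulative_input(24, s)), n)
  }
  tab <- migration_experiment(cfg, n_reps = 2, base_seed = 5)
  expect_equal(attr(tab, "n_e155"), n)
  expect_equal(nrow(tab), 6)  # 3 conditions x 2 responses
})

test_that("conditions must differ from baseline in a single subtree", {
  cfg <- test_cfg()
  bad <- cfg
  bad$dt_min <- 2
  expect_error(
    ppsim:::run_experiment(cfg, list(baseline = cfg, odd = bad),
                           baseline_label = "baseline", n_reps = 2,
                           base_seed = 1, varied_subtree = "input"),
    "differs from the baseline outside")
})

test_that("experiment tables write to CSV and refuse empty input", {
  cfg <- test_cfg()
  tab <- migration_experiment(cfg, forms = "linear", n_reps = 2,
                              base_seed = 8)
  f <- tempfile(fileext = ".csv")
  write_table(tab, f)
  back <- read.csv(f)
  expect_equal(nrow(back), 2)
  expect_equal(names(back),
               c("condition", "response", "a", "magnitude", "category",
                 "n_reps", "base_seed"))
  expect_error(write_table(tab[0, ], f), "empty")

  cond <- attr(tab, "distributions")[["linear"]]
  f2 <- tempfile(fileext = ".csv")
  write_condition(cond, f2)
  back2 <- read.csv(f2)
  expect_equal(names(back2),
               c("condition_label", "replicate_index", "seed", "patch_count",
                 "median_patch_area_um2", "total_cells_in"))
  expect_equal(nrow(back2), 2)
})

test_that("experiment plots render to files", {
  cfg <- test_cfg()
  tab <- migration_experiment(cfg, forms = "linear", n_reps = 2,
                              base_seed = 4)
  dir <- file.path(tempdir(), "ppsim-plots")
  paths <- plot(tab, dir = dir)
  expect_true(all(file.exists(paths)))
  expect_length(paths, 4)
})
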
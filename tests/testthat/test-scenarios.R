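test_that("presets differ from baseline in exactly the printed parameters", {
  base <- tidy(cc_params("baseline"))
  diffs <- function(name) {
    t2 <- tidy(cc_params(name))
    t2$parameter[t2$value != base$value]
  }
  expect_identical(diffs("rich_nutrient"), "a0")
  expect_identical(diffs("s_checkpoint"), "ka1")
  expect_identical(diffs("m_checkpoint"), "ka2")
  expect_equal(cc_params("rich_nutrient")$a0, 0.01)
  expect_equal(cc_params("s_checkpoint")$ka1, 1e-4)
  expect_equal(cc_params("m_checkpoint")$ka2, 1e-4)
  expect_equal(cc_params("baseline")[c("a0", "ka1", "ka2")],
               list(a0 = 0.001, ka1 = 0.001, ka2 = 0.001),
               ignore_attr = TRUE)
})

test_that("regimes are consistent with the bifurcation location", {
  # rich nutrient a0 = 0.01 > a0* ~ 0.0025 => limit cycle; baseline below
  rep_rich <- fx("rep_rich", run_scenario("rich_nutrient",
                                          plan = c("fixed_points", "regime")))
  rep_base <- fx("rep_base", run_scenario("baseline",
                                          plan = c("fixed_points", "regime")))
  expect_identical(rep_rich$regime, "limit_cycle")
  expect_identical(rep_base$regime, "excitable")
  expect_true(all(rep_rich$features$pass))
  expect_true(all(rep_base$features$pass))
})

test_that("scenario comparison reports regime and attractor changes", {
  rep_rich <- fx("rep_rich", run_scenario("rich_nutrient",
                                          plan = c("fixed_points", "regime")))
  rep_base <- fx("rep_base", run_scenario("baseline",
                                          plan = c("fixed_points", "regime")))
  # a report compared with itself is an empty diff
  expect_equal(nrow(compare_scenarios(rep_base, rep_base)), 0L)
  d <- compare_scenarios(rep_base, rep_rich)
  expect_true(any(grepl("excitable -> limit_cycle", d$change)))
  expect_true(any(d$aspect == "stable fixed points"))
})

test_that("the S-checkpoint creates a new stable state near its P3 vertex", {
  fp <- cc_fixed_points(cc_params("s_checkpoint"))
  vt <- fx("vt_chk", cc_vertices(cc_params("s_checkpoint")))
  stable <- fp[fp$stability == "stable", ]
  dd <- sqrt((stable$x - vt$x[1])^2 + (stable$y - vt$y[1])^2 + (stable$z - vt$z[1])^2)
  expect_true(any(dd < 0.2))
})

test_that("scenario reports serialize to structured text", {
  rep_base <- fx("rep_base", run_scenario("baseline",
                                          plan = c("fixed_points", "regime")))
  f <- tempfile(fileext = ".txt")
  write_scenario_report(rep_base, f)
  txt <- readLines(f)
  expect_true(any(grepl("regime: excitable", txt)))
  expect_true(any(grepl("P1", txt)))
})
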
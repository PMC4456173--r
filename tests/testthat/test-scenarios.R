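test_that("scenario builder lays out geometry and initial fields", {
  sc <- scenario(gap_mm = 8, gel_present = TRUE, bmp2_dose_ug = 5)
  st <- build_scenario(sc)
  # uniform encapsulated concentration = dose / gel volume
  gel <- st$masks$gel
  expect_true(any(gel))
  vol_cm3 <- sum(gel) * st$grid$area / 1000
  expect_equal(unique(st$bmp$g_gel[gel]), 5 * 1000 / vol_cm3)
  expect_equal(sum(st$bmp$g_gel[!gel]), 0)
  expect_equal(st$a[gel], rep(1, sum(gel)))
  # alginate fills the defect, cortex flanks it
  expect_equal(st$composition[gel, "alginate"], rep(1, sum(gel)))
  expect_true(any(st$masks$cortex))
  expect_false(any(st$masks$cortex & st$masks$defect))
  # host tissue starts at its homeostatic BMP-2 level, gel at zero
  g0 <- max(homeostatic_g(sc$thresholds$c_source, sc$bmp), sc$bmp$g_min)
  expect_equal(max(st$bmp$g), g0)
  expect_equal(sum(st$bmp$g[gel]), 0)
})

test_that("untreated scenarios carry no gel and the 2 mm case a callus", {
  st8 <- build_scenario(scenario(8, gel_present = FALSE, bmp2_dose_ug = 0))
  expect_equal(sum(st8$a), 0)
  expect_equal(sum(st8$bmp$g_gel), 0)
  expect_false(any(st8$masks$callus))
  # untreated critical defect is void in the gap
  expect_equal(sum(solid_fraction(st8$composition)[st8$masks$defect]), 0)

  st2 <- build_scenario(scenario(2, gel_present = FALSE, bmp2_dose_ug = 0))
  expect_true(any(st2$masks$callus))
  # small fracture gap starts as hematoma (granulation), not void
  expect_equal(st2$composition[st2$masks$defect, "granulation"],
               rep(1, sum(st2$masks$defect)))
  expect_error(scenario(8, gel_present = FALSE, bmp2_dose_ug = 5),
               "carrier")
  expect_error(scenario(gap_mm = 0), "positive")
})

test_that("short runs are deterministic and summaries well-formed", {
  sc <- scenario(8, TRUE, 5, horizon_days = 4, h = 0.5)
  s1 <- simulate_healing(sc)
  s2 <- simulate_healing(sc)
  expect_identical(s1$summary, s2$summary)
  expect_identical(s1$final$composition, s2$final$composition)
  s <- s1$summary
  expect_equal(nrow(s), 5L)               # ndays + 1
  expect_equal(s$day, 0:4)
  expect_true(all(s$bone_pct_defect >= 0 & s$bone_pct_defect <= 100))
  expect_true(all(s$cartilage_pct_defect >= 0 &
                    s$cartilage_pct_defect <= 100))
  expect_true(all(s$mean_a_defect >= 0 & s$mean_a_defect <= 1))
  expect_true(all(diff(s$mean_a_defect) <= 0))  # alginate monotone decay
})

test_that("report writes CSV, JSON and VTK artifacts reproducibly", {
  sc <- scenario(8, TRUE, 5, horizon_days = 3, h = 0.5)
  sim <- simulate_healing(sc, snapshot_days = 2)
  dir1 <- tempfile(); dir2 <- tempfile()
  p1 <- report(sim, dir1, "run")
  expect_true(all(file.exists(p1)))
  js <- jsonlite::read_json(file.path(dir1, "run_summary.json"))
  expect_true(all(c("final_bone_pct", "final_alginate_pct",
                    "week_cross_10pct", "scenario") %in% names(js)))
  expect_equal(js$scenario$bmp2_dose_ug, 5)
  # identical config => byte-identical CSV
  report(simulate_healing(sc, snapshot_days = 2), dir2, "run")
  expect_identical(readLines(file.path(dir1, "run_summary.csv")),
                   readLines(file.path(dir2, "run_summary.csv")))
  vtk <- readLines(file.path(dir1, "run_day002.vtk"), n = 4)
  expect_equal(vtk[3], "ASCII")
  unlink(c(dir1, dir2), recursive = TRUE)
})

test_that("week_of_crossing interpolates and handles non-union", {
  fake <- list(summary = data.frame(day = c(0, 7, 14),
                                    bone_pct_defect = c(0, 5, 15)))
  class(fake) <- "healing_sim"
  expect_equal(week_of_crossing(fake, 10), (7 + 7 * 5 / 10) / 7)
  never <- list(summary = data.frame(day = 0:3,
                                     bone_pct_defect = rep(0, 4)))
  class(never) <- "healing_sim"
  expect_true(is.na(week_of_crossing(never, 10)))
})

test_that("day-84 bone fraction is ordered empty <= gel-only <= gel+5ug", {
  b_empty <- tail(sim_empty()$summary$bone_pct_defect, 1)
  b_gel <- tail(sim_gel_only()$summary$bone_pct_defect, 1)
  b_5 <- tail(sim_5ug()$summary$bone_pct_defect, 1)
  expect_lte(b_empty, b_gel + 1e-9)
  expect_lte(b_gel, b_5)
  expect_gt(b_5, b_gel + 50)
})
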
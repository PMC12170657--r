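# Batch index computation, the discrepancy analysis, and the
# reproduction bundle.

test_that("computeIndicesReport handles SMILES files and failures", {
  tmp <- tempfile(fileext = ".smi")
  on.exit(unlink(tmp))
  writeLines(c("ethane\tCC", "propane\tCCC"), tmp)
  tabs <- computeIndicesReport(tmp, mode = "heavy")
  expect_equal(tabs$heavy$W, c(1, 4))

  writeLines(c("ethane\tCC", "broken\tC1CC"), tmp)
  err <- tryCatch(computeIndicesReport(tmp, mode = "heavy"), error = identity)
  expect_s3_class(err, "tcaQSPR_parse_error")
  expect_match(conditionMessage(err), "broken")
})

test_that("the builtin fixture report writes one CSV per mode", {
  out <- tempfile()
  on.exit(unlink(out, recursive = TRUE))
  computeIndicesReport(NULL, mode = "both", outDir = out)
  expect_true(file.exists(file.path(out, "indices_heavy.csv")))
  expect_true(file.exists(file.path(out, "indices_allh.csv")))
  back <- read.csv(file.path(out, "indices_allh.csv"))
  expect_equal(nrow(back), 15)
  expect_equal(back$W[back$drug == "DZM"], 2497)
})

test_that("discrepancyReport classifies every printed heavy row", {
  rep <- discrepancyReport(fixtureMolecules())
  expect_equal(nrow(rep), 75)   # 15 drugs x 5 indices
  cat1 <- unique(rep[, c("drug", "category", "suspect")])
  byDrug <- setNames(cat1$category, cat1$drug)
  expect_equal(unname(byDrug["ALP"]), "reproduced")
  expect_equal(unname(byDrug["AMX"]), "polar-h")
  expect_equal(unname(byDrug["FLX"]), "polar-h")
  expect_equal(unname(byDrug["DSP"]), "polar-h-except-harary")
  expect_equal(unname(byDrug["OZP"]), "unexplained")
  # the fixture suspect flag is exactly "not reproduced by the skeleton"
  expect_equal(cat1$suspect, cat1$category != "reproduced")
})

test_that("reproduce emits a complete, internally consistent bundle", {
  out <- tempfile()
  on.exit(unlink(out, recursive = TRUE))
  paths <- reproduce(out, seed = 42)
  need <- c("indices_heavy.csv", "indices_allh.csv",
            "correlations_heavy.csv", "correlations_allh.csv",
            "lr_report_heavy.csv", "lr_best_allh.csv",
            "svr_report_heavy.csv", "hyperparameters_allh.csv",
            "discrepancy_report.csv", "manifest.json")
  expect_true(all(file.exists(file.path(out, need))))
  # one actual-vs-predicted file per property per mode
  expect_equal(length(list.files(file.path(out, "predictions"))), 12)

  manifest <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(manifest$seed, 42)
  expect_equal(manifest$package, "tcaQSPR")
  expect_equal(unlist(manifest$grid$cost), c(10, 50, 100, 500))

  # the published heavy-mode LR row for boiling point
  lr <- read.csv(file.path(out, "lr_report_heavy.csv"))
  bp <- lr[lr$property == "BP" & lr$index == "H", ]
  expect_equal(bp$r2, 0.6692)
  expect_equal(bp$rmse, 37.3973)
  best <- read.csv(file.path(out, "lr_best_heavy.csv"))
  expect_equal(best$index[best$property == "BP"], "H")

  # predictions carry actual and both model predictions for all 15 drugs
  pred <- read.csv(file.path(out, "predictions", "BP_heavy.csv"))
  expect_equal(nrow(pred), 15)
  expect_true(all(c("actual", "lrPredicted", "svrPredicted") %in% names(pred)))
  expect_equal(sum(pred$heldOut), 3)
})
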
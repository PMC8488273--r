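test_that("experiment round-trips through the CSV writer and loader", {
  dat <- make_tiny_experiment()
  files <- write_experiment_files(dat)
  back <- load_experiment(files$behavior, files$measurements, timepoint = "h1")
  expect_equal(nrow(back$chicks), 6L)
  expect_equal(back$chicks$preference_score, dat$chicks$preference_score)
  expect_equal(back$measurements$relative_amount,
               dat$measurements$relative_amount)
  expect_equal(back$chicks$trained, dat$chicks$trained)
})

test_that("loader auto-detects tab-delimited input", {
  dat <- make_tiny_experiment()
  dir <- withr::local_tempdir()
  b <- file.path(dir, "behavior.tsv")
  m <- file.path(dir, "measurements.tsv")
  write.table(dat$chicks, b, sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(dat$measurements, m, sep = "\t", row.names = FALSE, quote = FALSE)
  back <- load_experiment(b, m)
  expect_equal(back$chicks$preference_score, dat$chicks$preference_score)
})

test_that("schema and parse failures name the offending column and row", {
  dat <- make_tiny_experiment()
  files <- write_experiment_files(dat)
  dir <- files$dir

  broken <- dat$chicks
  names(broken)[names(broken) == "batch_id"] <- "hatch"
  bpath <- file.path(dir, "bad_behavior.csv")
  write.csv(broken, bpath, row.names = FALSE)
  expect_error(load_experiment(bpath, files$measurements),
               regexp = "batch_id", class = "schema_error")

  bad_meas <- dat$measurements
  bad_meas$relative_amount <- as.character(bad_meas$relative_amount)
  bad_meas$relative_amount[3] <- "oops"
  mpath <- file.path(dir, "bad_measurements.csv")
  write.csv(bad_meas, mpath, row.names = FALSE)
  expect_error(load_experiment(files$behavior, mpath),
               regexp = "row 3", class = "parse_error")
})

test_that("validation rejects malformed designs", {
  dat <- make_tiny_experiment()

  ch <- dat$chicks
  ch$preference_score[ch$chick_id == "c3"] <- 60  # untrained with a score
  expect_error(experiment_data(ch, dat$measurements),
               class = "validation_error")

  ch <- dat$chicks
  ch$preference_score[1] <- 80  # approaches say 75
  expect_error(experiment_data(ch, dat$measurements),
               regexp = "c1", class = "validation_error")

  ch <- dat$chicks
  ch$preference_score[1] <- 75.3  # within the 0.5-unit tolerance
  expect_silent(experiment_data(ch, dat$measurements))

  ch <- dat$chicks
  ch$approach_test_alt_m[1] <- NA
  ch$preference_score[1] <- 104
  expect_error(experiment_data(ch, dat$measurements),
               regexp = "\\[0, 100\\]", class = "validation_error")

  me <- dat$measurements
  me <- rbind(me, me[1, ])  # duplicate (chick, region, hemisphere, measure)
  expect_error(experiment_data(dat$chicks, me), class = "duplication_error")

  me <- dat$measurements
  me$chick_id[1] <- "ghost"
  expect_error(experiment_data(dat$chicks, me), class = "validation_error")

  ch <- dat$chicks[dat$chicks$trained, ]  # batches lack untrained controls
  me <- dat$measurements[dat$measurements$chick_id %in% ch$chick_id, ]
  expect_error(experiment_data(ch, me), class = "validation_error")
  expect_silent(experiment_data(ch, me, check_batches = FALSE))
})

test_that("ratio measures are derived, never loaded, and zero approach flags the chick", {
  dat <- make_tiny_experiment()
  me <- dat$measurements
  me$measure[1] <- "P416_over_Total"
  expect_silent(experiment_data(dat$chicks, me))  # constructor may carry ratios
  files <- write_experiment_files(experiment_data(dat$chicks, me))
  expect_error(load_experiment(files$behavior, files$measurements),
               class = "validation_error")

  ch <- dat$chicks
  ch$approach_test_train_m[1] <- 0
  ch$approach_test_alt_m[1] <- 0
  ch$preference_score[1] <- NA
  x <- experiment_data(ch, dat$measurements)
  expect_true("c1" %in% x$metadata$undefined_score)
  expect_true(is.na(x$chicks$preference_score[1]))
})

test_that("derive_ratio_measures computes the three ratios and is idempotent", {
  chicks <- data.frame(chick_id = c("c1", "c2", "c3"), batch_id = "b1",
                       trained = c(TRUE, TRUE, FALSE))
  meas <- data.frame(
    chick_id = rep(c("c1", "c2", "c3"), each = 3),
    region = "IMM", hemisphere = "left",
    measure = rep(c("Total", "P416", "P527"), 3),
    relative_amount = c(2.0, 1.0, 0.9,   1.5, 0.9, 0.9,   1.0, 0.5, 0.25))
  dat <- experiment_data(chicks, meas)
  out <- derive_ratio_measures(dat)
  m <- out$measurements
  expect_equal(nrow(m), 18L)  # 3 chicks x (3 base + 3 ratios)
  get <- function(chick, measure) {
    m$relative_amount[m$chick_id == chick & m$measure == measure]
  }
  expect_equal(get("c1", "P416_over_Total"), 0.5)
  expect_equal(get("c2", "P527_over_P416"), 1.0)
  expect_equal(get("c3", "P527_over_Total"), 0.25)

  again <- derive_ratio_measures(out)
  expect_equal(nrow(again$measurements), 18L)
})

test_that("chicks missing a component get no ratio rows", {
  chicks <- data.frame(chick_id = c("c1", "c2", "c3"), batch_id = "b1",
                       trained = c(TRUE, TRUE, FALSE))
  meas <- data.frame(
    chick_id = rep(c("c1", "c2", "c3"), each = 3),
    region = "IMM", hemisphere = "left",
    measure = rep(c("Total", "P416", "P527"), 3),
    relative_amount = seq(0.5, by = 0.1, length.out = 9))
  meas <- meas[!(meas$chick_id == "c2" & meas$measure == "P416"), ]
  dat <- experiment_data(chicks, meas)
  out <- suppressMessages(derive_ratio_measures(dat))
  m <- out$measurements
  # 3 ratio rows per complete chick; c2 contributes none
  expect_equal(sum(m$measure %in% c("P416_over_Total", "P527_over_Total",
                                    "P527_over_P416")), 6L)
  expect_false(any(m$chick_id == "c2" &
                     m$measure %in% c("P416_over_Total", "P527_over_P416")))
  expect_match(attr(m, "ratio_log"), "missing component")
})

test_that("results table writes the block layout and re-loads bit-exactly", {
  cfg <- scenario_presets("paper-like-1h", scenario = "learning", seed = 12)
  res <- suppressMessages(run_analysis(generate_experiment(cfg)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_results_table(res, path)
  back <- read_results_table(path)
  expect_equal(nrow(back), nrow(res))
  for (col in names(res)) {
    expect_identical(back[[col]], res[[col]], label = col)
  }
  header <- readLines(path, n = 1)
  expect_match(header, "statistic")
  expect_match(header, "IMM.left.Total.h1", fixed = TRUE)

  empty <- res[0, ]
  class(empty) <- c("results_table", "data.frame")
  write_results_table(empty, path)
  expect_equal(readLines(path)[1], "statistic")
  expect_equal(nrow(read_results_table(path)), 0L)
})
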
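test_that("pattern files round-trip losslessly at double precision", {
  p <- generate_random_pattern(3000, 3.217, seed = 5, pattern_id = 7L)
  f <- withr::local_tempfile(fileext = ".txt")
  write_pattern(p, f)
  q <- read_pattern(f)
  expect_identical(q$phases, p$phases)
  expect_identical(q$frequency_hz, p$frequency_hz)
  expect_identical(q$pattern_id, p$pattern_id)
})

test_that("corrupt pattern files are rejected with a validation error", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("#pattern_id 1", "#n_units 2", "#frequency_hz 3",
               "1.0", "7.0"), f)
  expect_error(read_pattern(f), "2\\*pi")
  writeLines(c("#pattern_id 1", "#n_units 3", "#frequency_hz 3", "1.0"), f)
  expect_error(read_pattern(f), "declares")
})

test_that("weight matrices round-trip through binary + sidecar and TSV export", {
  pats <- generate_pattern_set(2, 80, 5, seed = 6)
  J <- build_connectivity(pats)
  f <- withr::local_tempfile(fileext = ".bin")
  write_weights(J, f)
  K <- read_weights(f)
  expect_identical(K$weights, J$weights)
  expect_identical(K$pattern_ids, J$pattern_ids)
  expect_equal(K$params$a_p, J$params$a_p)
  g <- withr::local_tempfile(fileext = ".tsv.gz")
  write_weights_tsv(J, g)
  tsv <- read.table(gzfile(g), header = TRUE)
  expect_equal(nrow(tsv), sum(J$weights != 0))
  expect_equal(J$weights[cbind(tsv$i, tsv$j)], tsv$J, tolerance = 1e-14)
})

test_that("spike trains round-trip in order with 0-based units on disk", {
  tr <- small_replay()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_spike_train(tr, f)
  raw <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(min(raw$unit), min(tr$unit) - 1L)
  back <- read_spike_train(f)
  expect_equal(back$time_ms, tr$time_ms)
  expect_identical(back$unit, tr$unit)
  expect_identical(back$source, tr$source)
  expect_identical(train_n_units(back), train_n_units(tr))
})

test_that("spike-train reader validates ordering, range, and source labels", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("time_ms\tunit\tsource", "5\t0\tnet", "1\t1\tnet"), f)
  expect_error(read_spike_train(f), "ordered")
  writeLines(c("time_ms\tunit\tsource", "1\t0\tweird"), f)
  expect_error(read_spike_train(f), "source")
})

test_that("manifests record checksums that match the files", {
  d <- withr::local_tempdir()
  out <- file.path(d, "x.txt")
  writeLines("abc", out)
  mf <- file.path(d, "manifest.json")
  write_manifest(mf, config = list(a = 1), seeds = list(master = 3),
                 files = out)
  m <- jsonlite::read_json(mf, simplifyVector = TRUE)
  expect_equal(unname(unlist(m$checksums)), unname(tools::md5sum(out)))
  expect_equal(m$seeds$master, 3)
})

test_that("the CLI pipeline generate -> build -> simulate -> analyze runs end to end", {
  d <- withr::local_tempdir()
  pdir <- file.path(d, "pats")
  expect_equal(run_cli(c("generate-patterns", "--n", "100", "--freq", "8",
                         "--p", "1", "--seed", "1", "--out", pdir)), 0L)
  pf <- file.path(pdir, "pattern_001.txt")
  expect_true(file.exists(pf))
  wf <- file.path(d, "J.bin")
  expect_equal(run_cli(c("build-connectivity", "--pattern-file", pf,
                         "--out", wf)), 0L)
  tf <- file.path(d, "train.tsv")
  expect_equal(run_cli(c("simulate", "--weights", wf, "--theta", "2",
                         "--duration-ms", "900", "--cue-pattern", pf,
                         "--seed", "1", "--out", tf)), 0L)
  expect_equal(run_cli(c("analyze", "--train", tf, "--pattern-file", pf,
                         "--out", file.path(d, "res"))), 0L)
  summ <- jsonlite::read_json(file.path(d, "res_summary.json"),
                              simplifyVector = TRUE)
  expect_true(summ$regime %in% c("retrieval", "spurious", "silent"))
  expect_true(file.exists(file.path(d, "res_overlaps.tsv")))
  # the toy network retrieves its single stored pattern
  expect_equal(summ$regime, "retrieval")
})

test_that("the CLI fails cleanly on bad input", {
  d <- withr::local_tempdir()
  bad <- file.path(d, "bad.txt")
  writeLines(c("#pattern_id 1", "#n_units 1", "#frequency_hz 3", "7.0"), bad)
  expect_equal(run_cli(c("build-connectivity", "--pattern-file", bad,
                         "--out", file.path(d, "J.bin"))), 1L)
  expect_equal(run_cli(c("nonsense")), 1L)
  expect_equal(run_cli(c("simulate")), 1L)
})
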
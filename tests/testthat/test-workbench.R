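# I/O, synthetic generator, harnesses and the CLI

test_that("FASTA and raw text preprocessing follows the stated rules", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">h", "acgT"), fa)
  txt <- read_and_preprocess_fasta(fa)
  expect_equal(txt$string, "ACGT$")
  expect_equal(txt$n, 5L)
  expect_equal(txt$sigma, 5L)

  raw <- withr::local_tempfile(fileext = ".txt")
  writeLines("AGCATAATTTAACTAAG", raw)
  expect_equal(read_and_preprocess_fasta(raw)$string, FIG1)

  multi <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "AC", "gt", ">b", "TT"), multi)
  expect_equal(read_and_preprocess_fasta(multi)$string, "ACGTTT$")
  expect_error(read_and_preprocess_fasta(multi, concatenate = FALSE), "multi-record")

  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines("AC$GT", bad)
  expect_error(read_and_preprocess_fasta(bad), "sentinel")
  empty <- withr::local_tempfile(fileext = ".fa")
  writeLines(">only-a-header", empty)
  expect_error(read_and_preprocess_fasta(empty), "no sequence")
})

test_that("preprocessing is idempotent modulo the sentinel", {
  fa <- withr::local_tempfile(fileext = ".txt")
  writeLines("agCATtag", fa)
  once <- read_and_preprocess_fasta(fa)
  again <- withr::local_tempfile(fileext = ".txt")
  writeLines(sub("\\$$", "", once$string), again)
  expect_equal(read_and_preprocess_fasta(again)$string, once$string)
})

test_that("synthetic generator is deterministic and model-faithful", {
  expect_equal(generate_synthetic("run", 4L, alphabet = "A")$string, "AAAA$")
  a <- generate_synthetic("uniform", 100L, seed = 1L)
  b <- generate_synthetic("uniform", 100L, seed = 1L)
  expect_identical(a$string, b$string)
  expect_false(identical(a$string, generate_synthetic("uniform", 100L, seed = 2L)$string))
  for (m in c("markov", "repeat_heavy"))
    expect_identical(generate_synthetic(m, 60L, seed = 3L)$string,
                     generate_synthetic(m, 60L, seed = 3L)$string)
  expect_error(generate_synthetic("uniform", 10L, alphabet = c("A", "$")), "sentinel")
  # generator calls leave the caller's RNG untouched
  withr::with_seed(99L, {
    before <- .Random.seed
    generate_synthetic("uniform", 10L, seed = 5L)
    expect_identical(.Random.seed, before)
  })
})

test_that("equivalence suite summarises and enforces the invariants", {
  suite <- run_equivalence_suite(sizes = c(10L, 30L), reps = 1L, seed = 11L)
  expect_true(nrow(suite) >= 7L)   # 2 models x sizes + adversarial
  expect_equal(suite$base_suffixes, suite$n)
  expect_true(all(suite$base_paths <= suite$sigma_n_bound))
})

test_that("scaling study enforces preconditions and fits slopes", {
  expect_error(run_scaling_study("bs_linear", c(10, 100, 1000)), "at least 4")
  expect_error(run_scaling_study("bs_linear", c(10, 20, 30, 40)), "orders of magnitude")
  rep <- run_scaling_study(c("bs_linear", "bs_algorithm1"),
                           c(100L, 400L, 1200L, 3000L), seed = 5L)
  expect_equal(nrow(rep$points), 8L)
  expect_equal(nrow(rep$fits), 2L)
  expect_true(all(is.finite(rep$fits$slope)))
})

test_that("CLI build prints consistent structural counts", {
  out <- capture.output(status <- ot_cli(c("build", "--text", "AGCATAATTTAACTAAG")))
  expect_equal(status, 0L)
  kv <- do.call(rbind, strsplit(out, "\t"))
  vals <- stats::setNames(as.integer(kv[, 2]), kv[, 1])
  expect_equal(unname(vals["leaf_nodes"]), 18L)
  expect_equal(unname(vals["internal_nodes"]), 10L)
  expect_equal(unname(vals["oshr_leaf_nodes"] + vals["oshr_internal_nodes"]),
               unname(vals["internal_nodes"]))
})

test_that("CLI query prints occurrence positions", {
  out <- capture.output(status <- ot_cli(c("query", "--text", "AGCATAATTTAACTAAG",
                                           "--pattern", "TAA")))
  expect_equal(status, 0L)
  expect_equal(out[1L], "4 9 13")
})

test_that("CLI verify --quick lists the internal-node labels", {
  out <- capture.output(status <- ot_cli(c("verify", "--quick", "--text",
                                           "AGCATAATTTAACTAAG")))
  expect_equal(status, 0L)
  labs <- setdiff(out, c("verify\tOK", ""))
  expect_length(labs, 10L)
  expect_setequal(labs, c("<root>", "A", "AA", "AG", "AT", "C", "G", "T", "TAA", "TT"))
})

test_that("CLI synth writes the requested string", {
  out <- withr::local_tempfile(fileext = ".txt")
  status <- suppressMessages(ot_cli(c("synth", "--model", "run", "--length", "4",
                                      "--alphabet", "A", "--out", out)))
  expect_equal(status, 0L)
  expect_equal(readLines(out), "AAAA$")
})

test_that("CLI output is byte-identical across repeated runs", {
  run1 <- capture.output(ot_cli(c("base-suffixes", "--text", "AGCATAATTTAACTAAG",
                                  "--algo", "a3")))
  run2 <- capture.output(ot_cli(c("base-suffixes", "--text", "AGCATAATTTAACTAAG",
                                  "--algo", "a3")))
  expect_identical(run1, run2)
})

test_that("CLI rejects unknown subcommands and bad flags with status 2", {
  expect_equal(suppressMessages(ot_cli("frobnicate")), 2L)
  expect_equal(suppressMessages(ot_cli(character(0))), 2L)
  expect_equal(suppressMessages(ot_cli(c("query", "--text", "AC"))), 2L)  # no pattern
  expect_equal(suppressMessages(ot_cli(c("build", "--input", "/nonexistent/x"))), 2L)
})
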
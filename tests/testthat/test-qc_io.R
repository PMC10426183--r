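test_that("both record formats round-trip the builtin fixtures", {
  fx <- builtinSeries()
  for (r in records(fx)) {
    for (fmt in c("record-json", "log-dialect")) {
      p <- withr::local_tempfile(fileext = if (fmt == "record-json") ".json" else ".log")
      writeRecord(r, p, fmt)
      expect_record_equal(readRecord(p, fmt), r)
    }
  }
})

test_that("both record formats round-trip randomized records", {
  for (seed in 1:100) {
    r <- randomRecord(seed, nAtoms = 2 + seed %% 12)
    p <- withr::local_tempfile()
    fmt <- if (seed %% 2 == 0) "record-json" else "log-dialect"
    writeRecord(r, p, fmt)
    expect_record_equal(readRecord(p, fmt), r)
  }
})

test_that("absent optional sections stay absent through a round-trip", {
  r <- compoundRecord("min", "C6H6", provenance = "minimal")
  for (fmt in c("record-json", "log-dialect")) {
    p <- withr::local_tempfile()
    writeRecord(r, p, fmt)
    back <- readRecord(p, fmt)
    expect_null(orbitals(back))
    expect_null(charges(back))
    expect_null(vibrations(back))
    expect_null(rigidBodyOf(back))
  }
})

test_that("malformed inputs are rejected with clear errors", {
  p <- withr::local_tempfile()
  file.create(p)
  expect_error(readRecord(p, "log-dialect"), "empty file")
  expect_error(readRecord(p, "record-json"), "malformed")
  # orbital block with only one side of the gap
  writeLines(c(" Entering postdft log, compound x",
               " Stoichiometry    CH4",
               " Alpha  occ. eigenvalues --  -0.5  -0.4"), p)
  expect_error(readRecord(p, "log-dialect"), "both frontier energies")
  # charge states with unequal atom counts
  writeLines(c(" Entering postdft log, compound x",
               " Stoichiometry    CH4",
               " Mulliken charges (cation):",
               "   1  C  0.5",
               "   2  H  0.5",
               " Sum of Mulliken charges (cation) = 1.0",
               " Mulliken charges (neutral):",
               "   1  C  0.0",
               " Sum of Mulliken charges (neutral) = 0.0",
               " Mulliken charges (anion):",
               "   1  C  -0.5",
               "   2  H  -0.5",
               " Sum of Mulliken charges (anion) = -1.0"), p)
  expect_error(readRecord(p, "log-dialect"), "unequal atom counts")
  expect_error(readRecord(file.path(tempdir(), "does-not-exist.json")),
               "no such file")
})

test_that("the log reader ignores junk lines without misassigning blocks", {
  r <- randomRecord(424242, nAtoms = 7)
  p <- withr::local_tempfile()
  writeRecord(r, p, "log-dialect")
  lines <- readLines(p)
  set.seed(8)
  junk <- c(" SCF Done: E(RB3LYP) = -1523.43", " ------------------",
            " Random chatter 1 2 3", "", " Charge = 0 Multiplicity = 1",
            " Eigenvalues of the overlap matrix", " 42")
  for (i in 1:20) {
    pos <- sample(length(lines) + 1, length(junk), replace = TRUE)
    fuzzed <- lines
    for (j in order(pos, decreasing = TRUE))
      fuzzed <- append(fuzzed, junk[j], after = pos[j] - 1)
    pf <- withr::local_tempfile()
    writeLines(fuzzed, pf)
    expect_record_equal(readRecord(pf, "log-dialect"), r)
  }
})

test_that("report writers emit identical values in CSV and JSON", {
  tab <- data.frame(id = c("6a", "6b"), eta = c(0.062935, 0.064575),
                    omega = c(0.51262, 0.50023))
  pc <- withr::local_tempfile(fileext = ".csv")
  pj <- withr::local_tempfile(fileext = ".json")
  writeReport(tab, pc, "csv", metadata = list(run = "demo"))
  writeReport(tab, pj, "json", metadata = list(run = "demo"))
  csvBack <- utils::read.csv(pc, comment.char = "#")
  jsonBack <- jsonlite::read_json(pj, simplifyVector = TRUE)$rows
  expect_equal(csvBack$eta, tab$eta)
  expect_equal(jsonBack$eta, tab$eta)
  expect_equal(csvBack$omega, jsonBack$omega)
  # metadata header records the mass-table version
  expect_true(any(grepl("mass_tables_version", readLines(pc))))
  expect_error(writeReport(data.frame(), pc), "nonempty")
})
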
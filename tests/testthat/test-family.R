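test_that("the bundled seven-person family file parses with names attached", {
  fam <- readFdata(simpsonsPath())
  expect_s4_class(fam, "Family")
  expect_identical(length(fam), 7L)
  expect_identical(familyKeys(fam), c("*", "*C", "*o1", "*a2", "*a3", "*P", "*M"))
  expect_identical(familyRecords(fam)$name,
                   c("Homer Simpson", "Marge Simpson", "Bart Simpson",
                     "Lisa Simpson", "Maggie Simpson", "Abe Simpson",
                     "Mona Simpson"))
  expect_identical(nrow(familyDiagnostics(fam)), 0L)
})

test_that("comments and blank lines are omitted; malformed lines are rejected with line numbers", {
  fam <- readFdata(textConnection(c("# only", "", "   ", "# comments")))
  expect_identical(length(fam), 0L)

  expect_error(readFdata(textConnection(c("*\tA", "*o1"))), class = "TabColumnError")
  expect_error(readFdata(textConnection("*o1\ta\tb")), class = "TabColumnError")
  expect_error(readFdata(textConnection(c("*\tA", "o1\tB"))), class = "ForeignOrigin")
  err <- tryCatch(readFdata(textConnection(c("*\tA", "*Oo1\tB"))), fcodeError = identity)
  expect_s3_class(err, "InvalidFcode")
  expect_match(conditionMessage(err), "line 2")
})

test_that("duplicate normalized codes are errors unless downgraded", {
  lines <- c("*\tA", "*a1M3\tB", "*C3\tB2")  # *a1M3 normalizes to *C3
  expect_error(readFdata(textConnection(lines)), class = "DuplicateFcode")
  fam <- readFdata(textConnection(lines), allowDuplicates = TRUE)
  expect_identical(length(fam), 2L)
  expect_true(any(grepl("duplicate", familyDiagnostics(fam)$message)))
})

test_that("FDATA writing is canonical and the read/write cycle is the identity", {
  fam <- readFdata(simpsonsPath())
  tf <- withr::local_tempfile(fileext = ".fdata")
  writeFdata(fam, tf)
  # byte-equal to the original data lines (the fixture is already canonical)
  orig <- readLines(simpsonsPath())
  orig <- orig[nzchar(trimws(orig)) & !startsWith(trimws(orig), "#")]
  expect_identical(readLines(tf), orig)
  fam2 <- readFdata(tf)
  expect_identical(familyKeys(fam2), familyKeys(fam))
  expect_identical(familyRecords(fam2), familyRecords(fam))
})

test_that("unknown orders survive the round trip", {
  fam <- Family(c("*", "*P?", "*O?o2"), c("a", "b", "c"))
  tf <- withr::local_tempfile()
  writeFdata(fam, tf)
  fam2 <- readFdata(tf)
  expect_identical(familyKeys(fam2), c("*", "*P?", "*O?o2"))
})

test_that("extended TSV round-trips the optional person metadata", {
  fam <- Family(c("*", "*C"), c("Ana", "Bea"),
                nickname = c("An", ""), birthdate = c("1970-01-02", ""),
                biography = c("Likes long walks and archives", ""))
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeFamilyTsv(fam, tf)
  fam2 <- readFamilyTsv(tf)
  expect_identical(familyRecords(fam2), familyRecords(fam))

  # FDATA-equivalent TSV of the bundled family gives the same records
  fam3 <- readFdata(simpsonsPath())
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  writeFamilyTsv(fam3, tf2)
  expect_identical(familyRecords(readFamilyTsv(tf2)), familyRecords(fam3))
})

test_that("TSV header must be a prefix of the known columns", {
  expect_error(readFamilyTsv(textConnection(c("fcode\tname\tshoesize", "*\tA"))),
               class = "HeaderMismatch")
  expect_error(readFamilyTsv(textConnection(c("name\tfcode", "*\tA"))),
               class = "HeaderMismatch")
  # missing trailing columns are fine
  fam <- readFamilyTsv(textConnection(c("fcode\tname", "*\tAna")))
  expect_identical(length(fam), 1L)
  expect_identical(familyRecords(fam)$biography, "")
})

test_that("OC metadata directives are written and read back", {
  fam <- Family(c("*", "*O2"), c("Ana", "Bo"), ocMeta = list(sex = "female", order = 1L))
  tf <- withr::local_tempfile()
  writeFdata(fam, tf)
  fam2 <- readFdata(tf)
  expect_identical(familyOcMeta(fam2), list(sex = "female", order = 1L))
})

test_that("file and TSV round trips hold on generated families", {
  for (s in 1:40) {
    fm <- randomFamily(genConfig(s, nPeople = 8))
    tf <- tempfile()
    writeFdata(fm, tf)
    fm2 <- readFdata(tf)
    expect_identical(familyKeys(fm2), familyKeys(fm))
    expect_identical(familyRecords(fm2)$name, familyRecords(fm)$name)
    tf2 <- tempfile()
    writeFamilyTsv(fm, tf2)
    expect_identical(familyRecords(readFamilyTsv(tf2)), familyRecords(fm))
    unlink(c(tf, tf2))
  }
})
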
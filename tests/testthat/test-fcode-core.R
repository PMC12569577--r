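test_that("parsing decomposes codes into layers with symbols and orders", {
  f <- parseFcode("*PO1a1")
  expect_s4_class(f, "Fcode")
  expect_identical(f@symbols, c("*", "P", "O", "a"))
  expect_identical(f@orders, c(NA_integer_, NA_integer_, 1L, 1L))

  expect_identical(fcodeDepth("*"), 0L)
  expect_identical(renderFcode(parseFcode("*O3o1a3")), "*O3o1a3")

  u <- parseFcode("*P?")
  expect_true(u@unknown[2])
  expect_identical(renderFcode(u), "*P?")
})

test_that("parse errors carry the specific failure class", {
  expect_error(parseFcode("*Oo1"), class = "MissingOrder")
  expect_error(parseFcode(""), class = "MissingOrigin")
  expect_error(parseFcode("PO1"), class = "MissingOrigin")
  expect_error(parseFcode("*Z2"), class = "IllegalSymbol")
  expect_error(parseFcode("**"), class = "IllegalSymbol")
  expect_error(parseFcode("*P0"), class = "BadOrder")
  expect_error(parseFcode("*3"), class = "BadOrder")
  expect_error(parseFcode("*P?3"), class = "BadOrder")
})

test_that("strict mode enforces terminal-only numbering of parenthood/spousehood", {
  # interior concrete number and unnumbered terminal both violate
  expect_error(parseFcode("*P3M", strict = TRUE), class = "StrictNumberViolation")
  expect_error(parseFcode("*P", strict = TRUE), class = "StrictNumberViolation")
  expect_error(parseFcode("*C", strict = TRUE), class = "StrictNumberViolation")
  # valid strict spellings
  expect_s4_class(parseFcode("*PM3", strict = TRUE), "Fcode")
  expect_s4_class(parseFcode("*C3", strict = TRUE), "Fcode")
  expect_s4_class(parseFcode("*P?", strict = TRUE), "Fcode")
  # lenient accepts and preserves interior numbers; canonical render drops them
  expect_identical(renderFcode(parseFcode("*P3M")), "*P3M")
  expect_identical(renderFcode(parseFcode("*P3M"), canonical = TRUE), "*PM")
})

test_that("positions are prefixes from the OC", {
  f <- parseFcode("*PMA2O1")
  expect_identical(renderFcode(fcodePosition(f, 0)), "*")
  expect_identical(renderFcode(fcodePosition(f, 1)), "*P")
  expect_identical(renderFcode(fcodePosition(f, 2)), "*PM")
  expect_identical(renderFcode(fcodePosition(f, 3)), "*PMA2")
  expect_identical(renderFcode(fcodePosition(f, 4)), "*PMA2O1")
  expect_identical(fcodeDepth(f), 4L)
  expect_error(fcodePosition(f, 5), class = "IndexOutOfRange")
  expect_error(fcodePosition(f, -1), class = "IndexOutOfRange")
})

test_that("lineage desexes and strips numbers; type is its upper layer", {
  expect_identical(fcodeLineage("*PO1a1"), "*XHh")
  expect_identical(fcodeType("*PO1a1"), "h")
  expect_identical(fcodeLineage("*"), "*")
  expect_identical(fcodeType("*"), "*")
  expect_identical(fcodeLineage("*C3"), "*C")
  expect_identical(fcodeType("*MO4"), "H")
  expect_identical(fcodeDepth("*MM4"), 2L)
})

test_that("round-trip and structural invariants hold over random codes", {
  strictCodes <- randomFcode(genConfig(2024, maxDepth = 6), n = 400)
  set.seed(515)
  lenientCodes <- vapply(1:400, function(i) randomLenientCode(), character(1L))
  for (cc in c(strictCodes, lenientCodes)) {
    f <- parseFcode(cc)
    expect_identical(renderFcode(f), cc)
    lin <- fcodeLineage(f)
    expect_identical(nchar(lin), fcodeDepth(f) + 1L)
    expect_identical(fcodeType(f), substr(lin, nchar(lin), nchar(lin)))
    expect_identical(renderFcode(fcodePosition(f, fcodeDepth(f))), cc)
    expect_identical(renderFcode(fcodePosition(f, 0)), "*")
  }
})

test_that("order compatibility treats absent and unknown as wildcards", {
  expect_true(fcodeMatches("*P", "*P3"))
  expect_true(fcodeMatches("*P?", "*P3"))
  expect_false(fcodeMatches("*P2", "*P3"))
  expect_false(fcodeMatches("*P", "*M"))
  expect_false(fcodeMatches("*P", "*PM"))
})
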
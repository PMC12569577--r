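# The eight printed wrong/right rewrites, used in several blocks below.
TABLE1 <- list(
  c("*CC", "CC", "*"),
  c("*a1M3", "hX", "*C3"),
  c("*O1M3", "HX", "*M3"),
  c("*MC", "XC", "*P?"),
  c("*Ca1", "Ch", "*a1"),
  c("*a1O2", "hH", "*o2"),
  c("*O2O3", "HH", "*O3"),
  c("*Po1", "Xh", "*O1")
)

test_that("pattern scan reports each redundant adjacency left to right", {
  m <- findWrongPatterns("*a1M3")
  expect_identical(m$pattern, "hX")
  expect_identical(m$startLayer, 1L)

  expect_identical(nrow(findWrongPatterns("*MM4")), 0L)

  m2 <- findWrongPatterns("*PC1o2")
  expect_identical(m2$pattern, c("XC", "Ch"))
  expect_identical(m2$startLayer, c(1L, 2L))
})

test_that("each published rewrite is reproduced by its single fix", {
  for (row in TABLE1) {
    m <- findWrongPatterns(row[1])
    m <- m[m$pattern == row[2], ]
    expect_identical(nrow(m), 1L, info = row[1])
    expect_identical(renderFcode(applyFix(row[1], m[1, ])), row[3], info = row[1])
  }
})

test_that("a fix applied to a non-matching position is rejected", {
  m <- findWrongPatterns("*a1M3")
  expect_error(applyFix("*MM4", m[1, ]), class = "StaleMatch")
})

test_that("normalization reaches the shortest path, deletions first", {
  # the spouse layer is deleted rather than the parent rewritten
  expect_identical(renderFcode(normalizeFcode("*PC1o2")), "*Po2")
  expect_identical(renderFcode(normalizeFcode("*MM4")), "*MM4")
  expect_identical(renderFcode(normalizeFcode("*CC")), "*")
  # chained fixes: hX first, then rescan finds nothing more
  once <- applyFix("*a1M3O2", findWrongPatterns("*a1M3O2")[1, ])
  expect_identical(nrow(findWrongPatterns(once)), 0L)
  expect_identical(renderFcode(normalizeFcode("*a1M3O2")), renderFcode(once))
  expect_identical(renderFcode(once), "*C3O2")
})

test_that("the parent's-child pattern is kept by default and rewritten on request", {
  kept <- normalizeFcode("*Po1")
  expect_identical(renderFcode(kept), "*Po1")
  expect_match(normalizationWarnings(kept), "OC")
  rewritten <- normalizeFcode("*Po1", xh = "rewrite")
  expect_identical(renderFcode(rewritten), "*O1")
  expect_length(normalizationWarnings(rewritten), 0L)
})

test_that("exactly the eight reducible adjacencies are found, matching a brute-force pedigree oracle", {
  # Independent oracle: a concrete three-generation pedigree. A two-step
  # lineage pair is reducible iff, for every person, everyone reachable by
  # the two steps is already reachable in at most one step.
  parents <- list(
    F = c("A1", "A2"), FB = c("A1", "A2"), FB2 = c("A1", "A2"),
    M = c("B1", "B2"), MS = c("B1", "B2"),
    C1 = c("F", "M"), C2 = c("F", "M"), C3 = c("F", "M"),
    G1 = c("C2", "C2W")
  )
  spouses <- list(A1 = "A2", A2 = "A1", B1 = "B2", B2 = "B1", F = "M", M = "F",
                  C2 = "C2W", C2W = "C2", FB = "FBW", FBW = "FB")
  ppl <- unique(c(names(parents), unlist(parents), names(spouses)))
  childrenOf <- function(p) names(Filter(function(x) p %in% x, parents))
  sibsOf <- function(p) {
    pa <- parents[[p]]
    if (is.null(pa)) return(character())
    setdiff(names(Filter(function(x) setequal(x, pa), parents)), p)
  }
  rel <- list(
    X = function(p) if (is.null(parents[[p]])) character() else parents[[p]],
    C = function(p) if (is.null(spouses[[p]])) character() else spouses[[p]],
    H = sibsOf,
    h = childrenOf
  )
  reducible <- function(a, b) {
    for (p in ppl) {
      twoStep <- unique(unlist(lapply(rel[[a]](p), rel[[b]])))
      oneStep <- unique(c(p, unlist(lapply(rel, function(f) f(p)))))
      if (length(setdiff(twoStep, oneStep))) return(FALSE)
    }
    TRUE
  }
  expectedWrong <- character()
  for (a in c("X", "C", "H", "h")) for (b in c("X", "C", "H", "h")) {
    if (reducible(a, b)) expectedWrong <- c(expectedWrong, paste0(a, b))
  }
  got <- enumerateWrongPairs()
  expect_length(got, 8L)
  expect_setequal(got, expectedWrong)
  expect_false("XX" %in% got)
  expect_false("hh" %in% got)
})

test_that("normalization terminates, shortens, and is idempotent on arbitrary codes", {
  set.seed(77)
  for (i in 1:600) {
    cc <- randomLenientCode()
    for (mode in c("keep", "rewrite")) {
      n1 <- renderFcode(normalizeFcode(cc, xh = mode))
      expect_identical(renderFcode(normalizeFcode(n1, xh = mode)), n1)
      expect_lte(fcodeDepth(n1), fcodeDepth(cc))
      left <- findWrongPatterns(n1)
      if (mode == "rewrite") {
        expect_identical(nrow(left), 0L)
      } else {
        expect_true(all(left$pattern == "Xh"))
        actionable <- findWrongPatterns(cc)
        actionable <- actionable[actionable$pattern != "Xh", ]
        if (nrow(actionable)) expect_lt(fcodeDepth(n1), fcodeDepth(cc))
      }
    }
  }
})
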
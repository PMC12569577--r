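test_that("the OC's direct relationships cover children, spouse and parents", {
  fam <- readFdata(simpsonsPath())
  rel <- directRelationships(fam, "*")
  expect_identical(sort(rel$children$fcode), c("*a2", "*a3", "*o1"))
  expect_identical(rel$spouses$fcode, "*C")
  expect_identical(rel$father$fcode, "*P")
  expect_identical(rel$mother$fcode, "*M")
  expect_identical(nrow(rel$siblings), 0L)

  relP <- directRelationships(fam, "*P")
  expect_identical(relP$children$fcode, "*")
  expect_identical(nrow(relP$father), 0L)
  expect_identical(relP$spouses$fcode, "*M")  # co-parents form a couple

  relA <- directRelationships(fam, "*a2")
  expect_identical(sort(relA$siblings$fcode), c("*a3", "*o1"))
  expect_identical(relA$father$fcode, "*")
  expect_identical(relA$mother$fcode, "*C")

  expect_error(directRelationships(fam, "*MM2"), class = "UnknownPerson")
})

test_that("siblings share known parents", {
  fam <- Family(c("*", "*P", "*O1"), c("kid", "dad", "bro"))
  rel <- directRelationships(fam, "*O1")
  expect_identical(rel$father$fcode, "*P")
  relDad <- directRelationships(fam, "*P")
  expect_setequal(relDad$children$fcode, c("*", "*O1"))
})

test_that("a position without an order unifies with a unique concrete record", {
  fam <- Family(c("*", "*P3", "*PM"), c("a", "dad", "gran"))
  g <- buildKinshipGraph(fam)
  expect_identical(kinNodes(g)$key, c("*", "*P3", "*PM"))
  # and the wildcard spelling resolves to the concrete node
  rel <- directRelationships(fam, "*P")
  expect_identical(rel$person$fcode, "*P3")
  expect_identical(rel$mother$fcode, "*PM")
})

test_that("contradictory records are rejected, ambiguous ones flagged", {
  expect_error(buildKinshipGraph(Family(c("*", "*P1", "*P2"), c("a", "b", "c"))),
               class = "InconsistentFamily")
  # "*P" vs "*P?" might be one person: kept apart with a diagnostic
  g <- buildKinshipGraph(Family(c("*", "*P?", "*PM"), c("a", "b", "c")))
  expect_identical(nrow(kinNodes(g)), 4L)
  expect_true(any(grepl("ambiguous", g@metadata$diagnostics)))
})

test_that("search matches substrings case-insensitively and regexes on request", {
  fam <- readFdata(simpsonsPath())
  expect_identical(nrow(searchFamily(fam, "simpson", field = "name")), 7L)
  expect_identical(searchFamily(fam, "*a", field = "fcode")$fcode, c("*a2", "*a3"))
  expect_identical(nrow(searchFamily(fam, "zzz")), 0L)
  expect_identical(searchFamily(fam, "^\\*a[0-9]$", field = "fcode", regex = TRUE)$fcode,
                   c("*a2", "*a3"))
  expect_identical(searchFamily(fam, "Bart", field = "any")$fcode, "*o1")
  expect_error(searchFamily(fam, "(", regex = TRUE), class = "BadRegex")
  expect_error(searchFamily(fam, ""), class = "BadRegex")
})

test_that("re-rooting at the spouse re-encodes every person through her", {
  fam <- readFdata(simpsonsPath())
  rb <- rebaseFamily(fam, "*C")
  got <- stats::setNames(familyKeys(rb), familyRecords(rb)$name)
  expect_identical(got[["Marge Simpson"]], "*")
  expect_identical(got[["Homer Simpson"]], "*C")
  expect_identical(got[["Bart Simpson"]], "*o1")
  expect_identical(got[["Lisa Simpson"]], "*a2")
  expect_identical(got[["Maggie Simpson"]], "*a3")
  expect_identical(got[["Abe Simpson"]], "*CP")
  expect_identical(got[["Mona Simpson"]], "*CM")
  expect_identical(familyOcMeta(rb), list())
})

test_that("re-rooting at a child keeps the two unknown-sex parents distinct", {
  fam <- readFdata(simpsonsPath())
  rb <- rebaseFamily(fam, "*o1")
  got <- stats::setNames(familyKeys(rb), familyRecords(rb)$name)
  expect_identical(got[["Bart Simpson"]], "*")
  expect_setequal(unname(got[c("Homer Simpson", "Marge Simpson")]), c("*X", "*X?"))
  expect_identical(length(rb), 7L)
})

test_that("re-rooting at the current OC is the identity", {
  fam <- readFdata(simpsonsPath())
  expect_identical(sort(familyKeys(rebaseFamily(fam, "*"))), sort(familyKeys(fam)))
  for (s in 1:25) {
    fm <- randomFamily(genConfig(s, nPeople = 8))
    expect_identical(sort(familyKeys(rebaseFamily(fm, "*"))), sort(familyKeys(fm)))
  }
})

test_that("re-rooting away and back recovers every person up to sex and order loss", {
  for (s in 1:25) {
    fm <- randomFamily(genConfig(100 + s, nPeople = 8))
    k <- familyKeys(fm)
    nm <- familyRecords(fm)$name
    r1 <- rebaseFamily(fm, k[min(2, length(k))])
    expect_identical(length(r1), length(fm))
    oc0 <- familyKeys(r1)[familyRecords(r1)$name == nm[1]][1]
    r2 <- rebaseFamily(r1, oc0)
    expect_identical(length(r2), length(fm))
    for (x in familyKeys(r2)) {
      expect_true(any(vapply(k, codesCompatible, logical(1L), a = x)), info = x)
    }
  }
  expect_error(rebaseFamily(readFdata(simpsonsPath()), "*MM1"),
               class = "UnknownPerson")
})

test_that("graph edge tables are mutually consistent", {
  for (s in c(3, 14, 27)) {
    g <- buildKinshipGraph(randomFamily(genConfig(s, nPeople = 10)))
    ed <- kinEdges(g)
    sib <- ed[ed$type == "sibling", ]
    spo <- ed[ed$type == "spouse", ]
    # symmetric relations stored once per pair
    both <- rbind(as.matrix(unname(sib[, 1:2])), as.matrix(unname(sib[, 2:1])))
    expect_false(any(duplicated(both)))
    # sibling transitivity within a sibship
    adj <- split(c(sib$to, sib$from), c(sib$from, sib$to))
    for (a in names(adj)) for (b in adj[[a]]) {
      expect_setequal(union(b, adj[[b]]), union(a, adj[[a]]))
    }
    # every person is connected to the OC node
    expect_true(igraph::is_connected(igraph::as_undirected(g@graph)))
  }
})
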
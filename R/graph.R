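# Kinship-graph construction. Every prefix (position) of every record code
# denotes a person; positions are unified across records by canonical code
# equality, with a non-concrete birth order acting as a wildcard against a
# concrete one when exactly one concrete candidate exists (the weakest rule
# that unifies "*P" with "*P3"). Relationship edges come from the layers
# themselves plus closure rules for the implications a human reader takes
# for granted.

# Canonicalized prefix of fl with k non-origin layers: interior concrete
# parenthood/spousehood numbers are dropped (they are not part of the
# canonical spelling); '?' marks are kept, since they can be the only
# feature distinguishing two unknown-order parents.
.positionFl <- function(fl, k) {
  idx <- seq_len(k + 1L)
  p <- list(sym = fl$sym[idx], ord = fl$ord[idx], unk = fl$unk[idx])
  n <- k + 1L
  ps <- .CATEGORY[p$sym] %in% c("parenthood", "spousehood")
  interior <- ps & seq_len(n) < n
  p$ord[interior] <- NA_integer_
  p
}

# Identity key: the canonical spelling of the (already canonicalized)
# position. "*P" and "*P?" are distinct keys here; the wildcard-merge step
# decides whether they denote one person.
.identityKey <- function(fl) .renderFl(fl)

.hasWildcard <- function(fl) {
  n <- length(fl$sym)
  mand <- .CATEGORY[fl$sym] %in% .NUMBERED_CATEGORIES
  ps <- .CATEGORY[fl$sym] %in% c("parenthood", "spousehood")
  nonconcrete <- is.na(fl$ord)
  any(nonconcrete & (mand | (ps & seq_len(n) == n)))
}

#' Build the kinship graph of a family
#'
#' Creates one node per distinct person position across all records and the
#' typed edges (`parent`, `sibling`, `spouse`) implied by the layers, then
#' closes the obvious implications: siblings share their known parents (and
#' sibling-hood is transitive within a sibship), children of one parent are
#' siblings, the two co-parents of a child are linked as a couple, and a
#' parent's spouse is also a parent. Fails with `InconsistentFamily` when
#' the records force more than one father, more than one mother, or more
#' than two parents onto one person.
#'
#' @param fam a [Family-class] object.
#' @return a [KinshipGraph-class] object.
#' @examples
#' fam <- Family(c("*", "*C", "*o1", "*a2"), c("Ho", "Ma", "Ba", "Li"))
#' kinNodes(buildKinshipGraph(fam))
#' @export
buildKinshipGraph <- function(fam) {
  layersList <- fam@metadata$layers
  nrec <- length(layersList)
  diagnostics <- character()

  # ---- collect positions -------------------------------------------------
  keyFl <- list()                       # key -> layer list (first seen)
  chains <- vector("list", nrec)        # record -> vector of position keys
  for (i in seq_len(nrec)) {
    fl <- layersList[[i]]
    d <- .flDepth(fl)
    ch <- character(d + 1L)
    for (k in 0:d) {
      p <- .positionFl(fl, k)
      key <- .identityKey(p)
      ch[k + 1L] <- key
      if (is.null(keyFl[[key]])) keyFl[[key]] <- p
    }
    chains[[i]] <- ch
  }
  keys <- names(keyFl) %||% character()
  recKeys <- vapply(chains, function(ch) ch[length(ch)], character(1L))
  if (!length(keys)) {
    return(new("KinshipGraph",
               nodes = data.frame(key = character(), name = character(),
                                  sex = character(), order = integer(),
                                  spouseIndex = integer(), isRecord = logical(),
                                  recIdx = integer(), stringsAsFactors = FALSE),
               edges = data.frame(from = character(), to = character(),
                                  type = character(), stringsAsFactors = FALSE),
               graph = igraph::make_empty_graph(directed = TRUE),
               metadata = list(diagnostics = character(), parents = list(),
                               sibs = list(), spouses = list())))
  }

  # ---- wildcard unification ---------------------------------------------
  # A position with a non-concrete order merges into a compatible fully
  # concrete position when exactly one such candidate exists. Two records
  # are distinct persons by construction (duplicates are rejected), so a
  # record never merges into another record; and a wildcard never merges
  # into another wildcard ("*P" and "*P?" may or may not be one person --
  # they are kept apart and the ambiguity surfaces as a diagnostic).
  resolve <- stats::setNames(keys, keys)
  if (length(keys) > 1L) {
    for (key in keys) {
      fl <- keyFl[[key]]
      if (!.hasWildcard(fl)) next
      cand <- character()
      for (other in keys) {
        if (other == key) next
        if (.hasWildcard(keyFl[[other]])) next
        if (key %in% recKeys && other %in% recKeys) next
        if (.flCompatible(fl, keyFl[[other]])) cand <- c(cand, other)
      }
      if (length(cand) == 1L) {
        resolve[[key]] <- cand
      } else if (length(cand) > 1L) {
        diagnostics <- c(diagnostics, sprintf(
          "position \"%s\" matches several concrete candidates (%s); kept distinct",
          key, paste(cand, collapse = ", ")))
      }
    }
  }
  finalKeys <- sort(unique(unname(resolve[keys])))
  nodeOf <- match(unname(resolve[keys]), finalKeys)
  names(nodeOf) <- keys
  n <- length(finalKeys)

  # ---- node attributes ---------------------------------------------------
  sex <- character(n); ord <- rep(NA_integer_, n); spIdx <- rep(NA_integer_, n)
  for (j in seq_len(n)) {
    fl <- keyFl[[finalKeys[j]]] %||% .scanFcode(finalKeys[j])
    last <- length(fl$sym)
    s <- fl$sym[last]
    sex[j] <- .SEXOF[[s]]
    if (!is.na(fl$ord[last])) {
      if (.CATEGORY[[s]] == "spousehood") spIdx[j] <- fl$ord[last] else ord[j] <- fl$ord[last]
    }
    if (s == "*") {
      sex[j] <- fam@ocMeta$sex %||% "unknown"
      ord[j] <- fam@ocMeta$order %||% NA_integer_
    }
  }
  name <- rep("", n); isRecord <- rep(FALSE, n); recIdx <- rep(NA_integer_, n)
  for (i in seq_len(nrec)) {
    ch <- chains[[i]]
    j <- nodeOf[[ch[length(ch)]]]
    if (isRecord[j]) {
      diagnostics <- c(diagnostics, sprintf(
        "records \"%s\" and \"%s\" denote the same person; first name kept",
        fam@records$fcode[recIdx[j]], fam@records$fcode[i]))
    } else {
      isRecord[j] <- TRUE
      recIdx[j] <- i
      name[j] <- fam@records$name[i]
    }
  }

  # ---- direct edges ------------------------------------------------------
  parents <- rep(list(integer()), n)
  sibs <- rep(list(integer()), n)
  spouses <- rep(list(integer()), n)
  addPair <- function(lst, a, b) {
    lst[[a]] <- unique(c(lst[[a]], b)); lst[[b]] <- unique(c(lst[[b]], a)); lst
  }
  for (i in seq_len(nrec)) {
    fl <- layersList[[i]]
    ch <- chains[[i]]
    for (k in seq_len(.flDepth(fl))) {
      u <- nodeOf[[ch[k]]]; v <- nodeOf[[ch[k + 1L]]]
      if (u == v) next
      switch(.CATEGORY[[fl$sym[k + 1L]]],
        parenthood = parents[[u]] <- unique(c(parents[[u]], v)),
        sonship = parents[[v]] <- unique(c(parents[[v]], u)),
        brotherhood = sibs <- addPair(sibs, u, v),
        spousehood = spouses <- addPair(spouses, u, v)
      )
    }
  }

  # ---- closure fixpoint --------------------------------------------------
  sizes <- function() sum(lengths(parents)) + sum(lengths(sibs)) + sum(lengths(spouses))
  repeat {
    before <- sizes()
    # sibling transitivity: connected components of the sibling relation
    seen <- rep(FALSE, n)
    for (s in seq_len(n)) {
      if (seen[s] || !length(sibs[[s]])) next
      comp <- s; queue <- s; seen[s] <- TRUE
      while (length(queue)) {
        cur <- queue[1L]; queue <- queue[-1L]
        for (nb in sibs[[cur]]) if (!seen[nb]) {
          seen[nb] <- TRUE; comp <- c(comp, nb); queue <- c(queue, nb)
        }
      }
      shared <- unique(unlist(parents[comp]))
      for (m in comp) {
        sibs[[m]] <- setdiff(comp, m)
        parents[[m]] <- unique(c(parents[[m]], setdiff(shared, m)))
      }
    }
    # children of one parent are siblings
    for (p in seq_len(n)) {
      kids <- which(vapply(parents, function(x) p %in% x, logical(1L)))
      if (length(kids) > 1L)
        for (a in kids) sibs[[a]] <- unique(c(sibs[[a]], setdiff(kids, a)))
    }
    # co-parents of a child form a couple; a parent's spouse is a parent
    for (c_ in seq_len(n)) {
      ps <- parents[[c_]]
      if (length(ps) == 2L) spouses <- addPair(spouses, ps[1L], ps[2L])
      for (p in ps) parents[[c_]] <- unique(c(parents[[c_]], setdiff(spouses[[p]], c_)))
    }
    if (sizes() == before) break
  }

  # ---- consistency -------------------------------------------------------
  # Two parents whose codes are layer-compatible (they differ only in
  # non-concrete orders, e.g. "*P" and "*P?") may still be one person the
  # records could not pin down: tolerated with a diagnostic. Incompatible
  # codes are genuinely different people, so two of them in the same
  # father/mother role -- or more than two parents -- is a contradiction.
  identityClasses <- function(idx) {
    cls <- list()
    for (i in idx) {
      placed <- FALSE
      for (ci in seq_along(cls)) {
        if (any(vapply(cls[[ci]], function(o)
          .flCompatible(keyFl[[finalKeys[i]]] %||% .scanFcode(finalKeys[i]),
                        keyFl[[finalKeys[o]]] %||% .scanFcode(finalKeys[o])),
          logical(1L)))) {
          cls[[ci]] <- c(cls[[ci]], i); placed <- TRUE; break
        }
      }
      if (!placed) cls[[length(cls) + 1L]] <- i
    }
    cls
  }
  for (j in seq_len(n)) {
    ps <- parents[[j]]
    if (length(ps) < 2L) next
    bad <- length(identityClasses(ps)) > 2L ||
      length(identityClasses(ps[sex[ps] == "male"])) > 1L ||
      length(identityClasses(ps[sex[ps] == "female"])) > 1L
    if (bad)
      .fcodeStop("InconsistentFamily",
                 "person \"%s\" has contradictory parents: %s",
                 finalKeys[j], paste(finalKeys[ps], collapse = ", "))
    if (length(ps) > 2L || sum(sex[ps] == "male") > 1L || sum(sex[ps] == "female") > 1L)
      diagnostics <- c(diagnostics, sprintf(
        "person \"%s\" has ambiguous parents (%s): some may be the same person",
        finalKeys[j], paste(finalKeys[ps], collapse = ", ")))
  }

  # ---- assemble ----------------------------------------------------------
  nodes <- data.frame(key = finalKeys, name = name, sex = sex, order = ord,
                      spouseIndex = spIdx, isRecord = isRecord, recIdx = recIdx,
                      stringsAsFactors = FALSE)
  ef <- character(); et <- character(); eto <- character()
  for (j in seq_len(n)) {
    for (p in parents[[j]]) { ef <- c(ef, finalKeys[p]); eto <- c(eto, finalKeys[j]); et <- c(et, "parent") }
    for (s in sibs[[j]]) if (s > j) { ef <- c(ef, finalKeys[j]); eto <- c(eto, finalKeys[s]); et <- c(et, "sibling") }
    for (s in spouses[[j]]) if (s > j) { ef <- c(ef, finalKeys[j]); eto <- c(eto, finalKeys[s]); et <- c(et, "spouse") }
  }
  edges <- data.frame(from = ef, to = eto, type = et, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = finalKeys))
  new("KinshipGraph", nodes = nodes, edges = edges, graph = g,
      metadata = list(diagnostics = diagnostics, parents = parents,
                      sibs = sibs, spouses = spouses))
}

#' @rdname buildKinshipGraph
#' @param g a [KinshipGraph-class] object.
#' @export
kinNodes <- function(g) g@nodes

#' @rdname buildKinshipGraph
#' @export
kinEdges <- function(g) g@edges

#' @export
setMethod("show", "KinshipGraph", function(object) {
  cat(sprintf("KinshipGraph: %d persons, %d edges (%s)\n",
              nrow(object@nodes), nrow(object@edges),
              paste(sprintf("%d %s", table(object@edges$type),
                            names(table(object@edges$type))), collapse = ", ")))
  invisible(object)
})

.asGraph <- function(x) {
  if (is(x, "KinshipGraph")) x else buildKinshipGraph(x)
}

# Resolve a code to a node index: exact identity-key match first, then a
# unique wildcard-compatible candidate.
.resolveNode <- function(g, code) {
  fl <- .flNormalize(.asFl(code), "keep")$fl
  fl <- .positionFl(fl, .flDepth(fl))
  key <- .identityKey(fl)
  j <- match(key, g@nodes$key)
  if (!is.na(j)) return(j)
  cand <- integer()
  for (j2 in seq_len(nrow(g@nodes))) {
    if (.flCompatible(fl, .scanFcode(g@nodes$key[j2]))) cand <- c(cand, j2)
  }
  if (length(cand) == 1L) return(cand)
  .fcodeStop("UnknownPerson", "no person \"%s\" in this family",
             if (is.character(code)) code else .renderFl(fl))
}

# Father/mother slots: male parent -> father, female -> mother; remaining
# unknown-sex parents fill the free slots in sorted-key order, father first.
.parentSlots <- function(g, j) {
  ps <- g@metadata$parents[[j]]
  father <- mother <- NA_integer_
  males <- ps[g@nodes$sex[ps] == "male"]
  females <- ps[g@nodes$sex[ps] == "female"]
  if (length(males)) father <- males[1L]
  if (length(females)) mother <- females[1L]
  rest <- setdiff(ps, c(males, females))
  rest <- rest[order(g@nodes$key[rest])]
  for (r in rest) {
    if (is.na(father)) father <- r
    else if (is.na(mother)) mother <- r
  }
  list(father = father, mother = mother)
}

.nodeSummary <- function(g, idx) {
  idx <- idx[!is.na(idx)]
  idx <- idx[order(g@nodes$key[idx])]
  data.frame(fcode = g@nodes$key[idx], name = g@nodes$name[idx],
             stringsAsFactors = FALSE)
}

#' Direct relationships of one person
#'
#' Summarizes a person's father, mother, siblings, spouses and children as
#' they appear in the kinship graph, each as a `(fcode, name)` table
#' (non-record persons implied by the codes carry an empty name). When the
#' sexes of the two parents are unrecorded (typical for the OC and a
#' `C`-coded spouse), the slots are filled deterministically in sorted code
#' order, father first.
#'
#' @param fam a [Family-class] or prebuilt [KinshipGraph-class] object.
#' @param code the person's Fcode (object or string); resolved through the
#'   same wildcard rule as node identity.
#' @return list with elements `person`, `father`, `mother`, `siblings`,
#'   `spouses`, `children`.
#' @export
directRelationships <- function(fam, code) {
  g <- .asGraph(fam)
  j <- .resolveNode(g, code)
  slots <- .parentSlots(g, j)
  kids <- which(vapply(g@metadata$parents, function(x) j %in% x, logical(1L)))
  list(
    person = .nodeSummary(g, j),
    father = .nodeSummary(g, slots$father),
    mother = .nodeSummary(g, slots$mother),
    siblings = .nodeSummary(g, g@metadata$sibs[[j]]),
    spouses = .nodeSummary(g, g@metadata$spouses[[j]]),
    children = .nodeSummary(g, kids)
  )
}

#' Search a family by code or name
#'
#' Case-insensitive substring search over the records, in file order. With
#' `regex = TRUE` the query is interpreted as a regular expression instead
#' (an invalid one fails with `BadRegex`).
#'
#' @param fam a [Family-class] object.
#' @param query non-empty search string.
#' @param field `"fcode"`, `"name"` or `"any"`.
#' @param regex interpret `query` as a regular expression.
#' @return the matching rows of [familyRecords()], with the canonical code
#'   in `fcode`.
#' @export
searchFamily <- function(fam, query, field = c("any", "fcode", "name"),
                         regex = FALSE) {
  field <- match.arg(field)
  if (!is.character(query) || length(query) != 1L || !nzchar(query))
    .fcodeStop("BadRegex", "the search query must be a non-empty string")
  keys <- familyKeys(fam)
  nm <- fam@records$name
  matchVec <- function(x) {
    if (regex) {
      tryCatch(suppressWarnings(grepl(query, x, ignore.case = TRUE, perl = TRUE)),
               error = function(e) .fcodeStop("BadRegex", "invalid regular expression \"%s\": %s",
                                              query, conditionMessage(e)))
    } else {
      grepl(tolower(query), tolower(x), fixed = TRUE)
    }
  }
  hit <- switch(field,
    fcode = matchVec(keys),
    name = matchVec(nm),
    any = matchVec(keys) | matchVec(nm)
  )
  out <- fam@records[hit, , drop = FALSE]
  out$fcode <- keys[hit]
  rownames(out) <- NULL
  out
}

#' Re-root a family at a new origin of coordinates
#'
#' Re-encodes every person relative to a new reference person: a
#' breadth-first shortest path from the new OC to each record node is
#' translated layer by layer (parent edges to `P`/`M`/`X` by known sex,
#' child edges to `o`/`a`/`h`, sibling edges to `O`/`A`/`H`, spouse edges
#' to `C`), numbers emitted where known and `?` where a number is required
#' but unrecorded, and each resulting code is normalized. The original OC's
#' own sex and birth order are not recorded by the format, so codes passing
#' through it use unsexed symbols unless the family carries OC metadata.
#'
#' @param fam a [Family-class] object.
#' @param newOc Fcode (object or string) of the new reference person.
#' @return a [Family-class] object over the same persons; unreachable
#'   records are dropped with a diagnostic.
#' @export
rebaseFamily <- function(fam, newOc) {
  g <- .asGraph(fam)
  start <- .resolveNode(g, newOc)
  keys <- g@nodes$key
  n <- nrow(g@nodes)
  parents <- g@metadata$parents; sibs <- g@metadata$sibs; spouses <- g@metadata$spouses
  childrenOf <- lapply(seq_len(n), function(j)
    which(vapply(parents, function(x) j %in% x, logical(1L))))
  adj <- lapply(seq_len(n), function(j)
    sort(unique(c(parents[[j]], sibs[[j]], spouses[[j]], childrenOf[[j]]))))
  encodeStep <- function(u, v) {
    if (v %in% parents[[u]]) {
      s <- switch(g@nodes$sex[v], male = "P", female = "M", "X")
      list(sym = s, ord = g@nodes$order[v], unk = FALSE)
    } else if (u %in% parents[[v]]) {
      s <- switch(g@nodes$sex[v], male = "o", female = "a", "h")
      o <- g@nodes$order[v]
      list(sym = s, ord = o, unk = is.na(o))
    } else if (v %in% sibs[[u]]) {
      s <- switch(g@nodes$sex[v], male = "O", female = "A", "H")
      o <- g@nodes$order[v]
      list(sym = s, ord = o, unk = is.na(o))
    } else if (v %in% spouses[[u]]) {
      list(sym = "C", ord = g@nodes$spouseIndex[v], unk = FALSE)
    } else {
      .fcodeStop("Disconnected", "no edge between \"%s\" and \"%s\"", keys[u], keys[v])
    }
  }

  # Breadth-first distances from the new OC, deterministic (nodes are in
  # sorted-key order, so neighbor order is reproducible).
  dist <- rep(NA_integer_, n)
  dist[start] <- 0L
  queue <- start
  while (length(queue)) {
    u <- queue[1L]; queue <- queue[-1L]
    for (v in adj[[u]]) if (is.na(dist[v])) {
      dist[v] <- dist[u] + 1L; queue <- c(queue, v)
    }
  }

  # Assign every reachable node a code built from an already-encoded
  # neighbor one step closer to the OC, so a person's code extends the code
  # of the person it is reached through. Records claim their codes before
  # implied positions at the same distance. When the natural code is taken
  # by a distinct person (two co-parents of unrecorded sex both encode as
  # "*X"), the other predecessors and then same-distance neighbors (e.g.
  # the spouse edge, giving "*XC" -> "*X?") are tried.
  ordNodes <- setdiff(order(dist, !g@nodes$isRecord, seq_len(n), na.last = NA), start)
  flOf <- vector("list", n)
  codeOf <- rep(NA_character_, n)
  flOf[[start]] <- list(sym = "*", ord = NA_integer_, unk = FALSE)
  codeOf[start] <- "*"
  diagnostics <- character(); dropped <- character()
  tryEncode <- function(v, cand) {
    for (u in cand) {
      if (is.na(codeOf[u])) next
      st <- encodeStep(u, v)
      fl <- .flNormalize(list(sym = c(flOf[[u]]$sym, st$sym),
                              ord = c(flOf[[u]]$ord, st$ord),
                              unk = c(flOf[[u]]$unk, st$unk)), "keep")$fl
      cc <- .renderFl(fl, canonical = TRUE)
      if (!cc %in% codeOf) {
        flOf[[v]] <<- fl; codeOf[v] <<- cc
        return(TRUE)
      }
    }
    FALSE
  }
  for (v in ordNodes) {
    nb <- adj[[v]]
    tryEncode(v, c(nb[!is.na(dist[nb]) & dist[nb] == dist[v] - 1L],
                   nb[!is.na(dist[nb]) & dist[nb] == dist[v]]))
  }
  # Nodes whose every candidate code was claimed by a distinct person may
  # become encodable once a later neighbor (e.g. a spouse) has a code that
  # disambiguates them; retry until no progress.
  repeat {
    pending <- ordNodes[is.na(codeOf[ordNodes])]
    progress <- FALSE
    for (v in pending) progress <- tryEncode(v, adj[[v]]) || progress
    if (!progress || !length(pending)) break
  }
  for (v in ordNodes) {
    if (is.na(codeOf[v]) && g@nodes$isRecord[v]) {
      dropped <- c(dropped, keys[v])
      diagnostics <- c(diagnostics, sprintf(
        "record \"%s\" cannot be encoded distinctly from \"%s\"; dropped",
        keys[v], keys[start]))
    }
  }

  outCode <- character(); outRec <- integer()
  for (i in seq_len(nrow(fam@records))) {
    j <- match(i, g@nodes$recIdx)
    if (is.na(j)) next  # merged into another record at graph build
    if (is.na(dist[j])) {
      dropped <- c(dropped, keys[j])
      diagnostics <- c(diagnostics, sprintf(
        "record \"%s\" is unreachable from \"%s\"; dropped", keys[j], keys[start]))
      next
    }
    if (is.na(codeOf[j])) next  # already diagnosed above
    outCode <- c(outCode, codeOf[j])
    outRec <- c(outRec, i)
  }
  r <- fam@records
  outName <- r$name[outRec]; outNick <- r$nickname[outRec]
  outBirth <- r$birthdate[outRec]; outBio <- r$biography[outRec]
  if (!g@nodes$isRecord[start]) {
    outCode <- c("*", outCode); outName <- c("", outName)
    outNick <- c("", outNick); outBirth <- c("", outBirth); outBio <- c("", outBio)
    diagnostics <- c(diagnostics,
                     sprintf("new OC \"%s\" is not a record; synthesized", keys[start]))
  }
  ocMeta <- list()
  if (g@nodes$sex[start] %in% c("male", "female")) ocMeta$sex <- g@nodes$sex[start]
  if (!is.na(g@nodes$order[start])) ocMeta$order <- g@nodes$order[start]
  out <- .assembleFamily(outCode, outName, outNick, outBirth, outBio,
                         ocMeta, .newDiag(), allowDuplicates = TRUE)
  out@metadata$rebaseDiagnostics <- diagnostics
  out@metadata$dropped <- dropped
  out
}
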
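# Seeded random generation of valid Fcodes and consistent families. Codes
# are built as random walks over the ALLOWED lineage adjacencies -- the
# complement of the eight redundant patterns -- and then sexed and numbered,
# so every draw is valid and a normalization fixpoint by construction.

.ALLOWED_NEXT <- list(
  "*" = c("X", "C", "H", "h"),
  X = c("X", "H"),   # parent's parent, parent's sibling
  C = c("X", "H"),   # spouse's parent, spouse's sibling
  H = c("C", "h"),   # sibling's spouse, sibling's child
  h = c("C", "h")    # child's spouse, child's child
)

.FIRST_NAMES <- c(
  "Ada", "Bruno", "Carla", "Denis", "Elsa", "Fermin", "Greta", "Hugo",
  "Irene", "Jonas", "Klara", "Luis", "Marta", "Nilo", "Olga", "Pablo",
  "Queralt", "Rosa", "Simon", "Teresa", "Ugo", "Vera", "Wim", "Xenia",
  "Yago", "Zoe", "Aitor", "Berta", "Celso", "Dora", "Eloi", "Fina"
)

.SURNAMES <- c(
  "Alonso", "Blanco", "Castro", "Duarte", "Estevez", "Ferreiro", "Gondar",
  "Herrero", "Iglesias", "Juncal", "Lamas", "Meixide", "Novoa", "Otero",
  "Pereira", "Quiroga"
)

#' Configuration for the random generators
#'
#' Bundles the knobs of [randomFcode()] and [randomFamily()]. A single
#' integer seed governs all randomness; the generators never touch the
#' caller's global random state. The defaults describe a small interview-
#' scale family: a dozen people within four relationship steps of the
#' reference person, sibships of up to four.
#'
#' @param seed integer seed; identical seed and configuration give
#'   byte-identical output.
#' @param maxDepth maximum number of layers per code.
#' @param nPeople target number of records per family.
#' @param maxChildren largest birth order drawn for a sibship.
#' @param spouseProb,siblingProb relative weights of extending a family
#'   with a spouse or a sibling rather than a parent or child.
#' @return a validated `GenConfig` list.
#' @export
genConfig <- function(seed, maxDepth = 4L, nPeople = 12L, maxChildren = 4L,
                      spouseProb = 0.5, siblingProb = 0.5) {
  seed <- as.integer(seed)
  stopifnot(length(seed) == 1L, !is.na(seed),
            maxDepth >= 0L, nPeople >= 1L, maxChildren >= 1L,
            spouseProb >= 0, spouseProb <= 1, siblingProb >= 0, siblingProb <= 1)
  structure(list(seed = seed, maxDepth = as.integer(maxDepth),
                 nPeople = as.integer(nPeople), maxChildren = as.integer(maxChildren),
                 spouseProb = spouseProb, siblingProb = siblingProb),
            class = "GenConfig")
}

.sexify <- function(lineageSym, unsexedProb = 0.1) {
  sexed <- switch(lineageSym,
    X = c("P", "M"), H = c("O", "A"), h = c("o", "a"), C = "C")
  if (lineageSym != "C" && stats::runif(1L) < unsexedProb) lineageSym
  else sexed[sample.int(length(sexed), 1L)]
}

#' Generate random pattern-free Fcodes
#'
#' Draws `n` strict-mode valid codes of depth at most `maxDepth` by random
#' walk over the eight allowed lineage adjacencies, then assigning sexes
#' and birth orders. Outputs contain no redundant pattern, so they are
#' fixpoints of [normalizeFcode()]. Deterministic for a given
#' configuration.
#'
#' @param cfg a [genConfig()] object.
#' @param n number of codes to draw from the seeded stream.
#' @return character vector of code strings.
#' @examples
#' randomFcode(genConfig(1), n = 3)
#' @export
randomFcode <- function(cfg, n = 1L) {
  stopifnot(inherits(cfg, "GenConfig"))
  .withSeed(cfg$seed, {
    vapply(seq_len(n), function(i) {
      d <- sample.int(cfg$maxDepth + 1L, 1L) - 1L
      lin <- character(d)
      prev <- "*"
      for (k in seq_len(d)) {
        nxt <- .ALLOWED_NEXT[[prev]]
        lin[k] <- nxt[sample.int(length(nxt), 1L)]
        prev <- lin[k]
      }
      parts <- character(d)
      for (k in seq_len(d)) {
        s <- .sexify(lin[k])
        cat_ <- .CATEGORY[[s]]
        ordstr <- ""
        if (cat_ %in% .NUMBERED_CATEGORIES) {
          ordstr <- if (stats::runif(1L) < 0.1) "?" else
            as.character(sample.int(cfg$maxChildren, 1L))
        } else if (k == d) {
          # terminal parenthood/spousehood must be numbered in strict form
          ordstr <- if (stats::runif(1L) < 0.3) "?" else
            as.character(sample.int(cfg$maxChildren, 1L))
        }
        parts[k] <- paste0(s, ordstr)
      }
      paste0("*", paste0(parts, collapse = ""))
    }, character(1L))
  })
}

#' Generate a random consistent family
#'
#' Grows a family record by record from the OC: each step picks an
#' existing person and attaches a parent, child, sibling or spouse through
#' an allowed lineage adjacency, with per-person bookkeeping that keeps
#' sibling birth orders distinct within a sibship, at most one father, one
#' mother and one spouse per person. All codes are pattern-free and
#' distinct after normalization, the resulting file re-reads without
#' errors, and [buildKinshipGraph()] accepts it. If the constraints make
#' `nPeople` unreachable the best effort is returned with the
#' `infeasible` flag set in the family metadata.
#'
#' @param cfg a [genConfig()] object.
#' @return a [Family-class] object.
#' @examples
#' fam <- randomFamily(genConfig(7, nPeople = 6))
#' familyKeys(fam)
#' @export
randomFamily <- function(cfg) {
  stopifnot(inherits(cfg, "GenConfig"))
  .withSeed(cfg$seed, {
    surname <- .SURNAMES[sample.int(length(.SURNAMES), 1L)]
    rname <- function() paste(.FIRST_NAMES[sample.int(length(.FIRST_NAMES), 1L)], surname)
    codes <- "*"
    names_ <- rname()
    fls <- list(list(sym = "*", ord = NA_integer_, unk = FALSE))
    parentUsed <- list(); spouseUsed <- character()
    sibUsed <- list(); childUsed <- list()
    attempts <- 0L
    while (length(codes) < cfg$nPeople && attempts < 60L * cfg$nPeople) {
      attempts <- attempts + 1L
      b <- sample.int(length(codes), 1L)
      base <- codes[b]; bfl <- fls[[b]]
      if (.flDepth(bfl) >= cfg$maxDepth) next
      lastLin <- .DESEX[[bfl$sym[length(bfl$sym)]]]
      opts <- .ALLOWED_NEXT[[lastLin]]
      w <- numeric(length(opts))
      for (k in seq_along(opts)) {
        w[k] <- switch(opts[k],
          X = if (length(setdiff(c("P", "M"), parentUsed[[base]])) > 0L) 1 else 0,
          C = if (!(base %in% spouseUsed)) cfg$spouseProb else 0,
          H = if (length(setdiff(seq_len(cfg$maxChildren), sibUsed[[base]])) > 0L)
                cfg$siblingProb else 0,
          h = if (length(setdiff(seq_len(cfg$maxChildren), childUsed[[base]])) > 0L)
                1 else 0
        )
      }
      if (sum(w) == 0) next
      pick <- opts[sample.int(length(opts), 1L, prob = w)]
      layer <- switch(pick,
        X = {
          s <- setdiff(c("P", "M"), parentUsed[[base]])
          s <- s[sample.int(length(s), 1L)]
          parentUsed[[base]] <- c(parentUsed[[base]], s)
          list(sym = s, ord = NA_integer_, unk = FALSE)
        },
        C = {
          spouseUsed <- c(spouseUsed, base)
          list(sym = "C", ord = NA_integer_, unk = FALSE)
        },
        H = {
          free <- setdiff(seq_len(cfg$maxChildren), sibUsed[[base]])
          o <- free[sample.int(length(free), 1L)]
          sibUsed[[base]] <- c(sibUsed[[base]], o)
          s <- .sexify("H", unsexedProb = 0.05)
          list(sym = s, ord = as.integer(o), unk = FALSE)
        },
        h = {
          free <- setdiff(seq_len(cfg$maxChildren), childUsed[[base]])
          o <- free[sample.int(length(free), 1L)]
          childUsed[[base]] <- c(childUsed[[base]], o)
          s <- .sexify("h", unsexedProb = 0.05)
          list(sym = s, ord = as.integer(o), unk = FALSE)
        }
      )
      nfl <- list(sym = c(bfl$sym, layer$sym), ord = c(bfl$ord, layer$ord),
                  unk = c(bfl$unk, layer$unk))
      code <- .renderFl(nfl, canonical = TRUE)
      if (code %in% codes) next
      codes <- c(codes, code)
      names_ <- c(names_, rname())
      fls <- c(fls, list(nfl))
    }
    fam <- .assembleFamily(codes, names_, rep("", length(codes)),
                           rep("", length(codes)), rep("", length(codes)),
                           list(), .newDiag())
    if (length(codes) < cfg$nPeople) {
      fam@metadata$infeasible <- TRUE
      fam@metadata$diagnostics <- rbind(fam@metadata$diagnostics, .newDiag(
        NA_integer_, "", sprintf("only %d of %d people reachable under constraints",
                                 length(codes), cfg$nPeople)))
    }
    fam
  })
}
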
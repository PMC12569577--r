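# The eight redundant two-layer lineage adjacencies and their repairs. A
# pattern names the desexed symbols of two consecutive non-origin layers;
# each fix removes one or two layers, so rewriting always shortens the code.
#
#   CC  spouse's spouse is the person themselves ...... delete both layers
#   hX  child's parent is one's partner ................ substitute C
#   HX  sibling's parent is one's own parent ........... delete the H layer
#   XC  parent's partner is the other parent ........... substitute sex-switched X
#   Ch  partner's child is one's own child ............. delete the C layer
#   hH  child's sibling is one's own child ............. substitute sonship
#   HH  sibling's sibling is one's own sibling ......... delete the first H
#   Xh  parent's child is a sibling (or the OC) ........ substitute brotherhood
.FIXES <- list(
  CC = "delete_pair",
  hX = "substitute",
  HX = "delete_first",
  XC = "substitute",
  Ch = "delete_first",
  hH = "substitute",
  HH = "delete_first",
  Xh = "substitute"
)

# Deletion fixes never lose or invent order information, so the normalizer
# applies them before any substitution.
.DELETION_PATTERNS <- c("CC", "HX", "Ch", "HH")

.flFindPatterns <- function(fl) {
  lin <- .flLineage(fl)
  n <- length(lin)
  out <- list(pattern = character(), startLayer = integer(), fixKind = character())
  if (n >= 3L) {
    for (i in 2L:(n - 1L)) {
      pid <- paste0(lin[i], lin[i + 1L])
      if (pid %in% names(.FIXES)) {
        out$pattern <- c(out$pattern, pid)
        out$startLayer <- c(out$startLayer, i - 1L)
        out$fixKind <- c(out$fixKind, .FIXES[[pid]])
      }
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

# Replace layers i..(i+1) of fl with the (possibly empty) replacement layers.
.flSplice <- function(fl, i, sym = character(), ord = integer(), unk = logical()) {
  keepL <- seq_len(i - 1L)
  keepR <- if (i + 2L <= length(fl$sym)) (i + 2L):length(fl$sym) else integer()
  list(
    sym = c(fl$sym[keepL], sym, fl$sym[keepR]),
    ord = c(fl$ord[keepL], ord, fl$ord[keepR]),
    unk = c(fl$unk[keepL], unk, fl$unk[keepR])
  )
}

.flApplyFix <- function(fl, pattern, startLayer) {
  i <- startLayer + 1L  # absolute index of the first layer of the pair
  n <- length(fl$sym)
  if (startLayer < 1L || i + 1L > n ||
      paste0(.DESEX[fl$sym[i]], .DESEX[fl$sym[i + 1L]]) != pattern)
    .fcodeStop("StaleMatch", "pattern %s does not match \"%s\" at layer %d",
               pattern, .renderFl(fl), startLayer)
  switch(pattern,
    CC = .flSplice(fl, i),
    HX = ,
    Ch = ,
    HH = {
      # delete the first layer of the pair
      keep <- setdiff(seq_len(n), i)
      list(sym = fl$sym[keep], ord = fl$ord[keep], unk = fl$unk[keep])
    },
    hX = # child + that child's parent  ->  one's partner, keeping the
         # parent layer's birth order
      .flSplice(fl, i, "C", fl$ord[i + 1L], fl$unk[i + 1L]),
    XC = { # parent + partner -> the other parent; its birth order is lost
      s <- c(P = "M", M = "P", X = "X")[[fl$sym[i]]]
      .flSplice(fl, i, s, NA_integer_, TRUE)
    },
    hH = { # child + sibling -> one's own child, sex and order from the sibling
      s <- c(O = "o", A = "a", H = "h")[[fl$sym[i + 1L]]]
      .flSplice(fl, i, s, fl$ord[i + 1L], fl$unk[i + 1L])
    },
    Xh = { # parent + child -> one's sibling, sex and order from the child
      s <- c(o = "O", a = "A", h = "H")[[fl$sym[i + 1L]]]
      .flSplice(fl, i, s, fl$ord[i + 1L], fl$unk[i + 1L])
    }
  )
}

.flNormalize <- function(fl, xh = "keep") {
  repeat {
    ps <- .flFindPatterns(fl)
    if (xh == "keep" && nrow(ps)) ps <- ps[ps$pattern != "Xh", , drop = FALSE]
    if (!nrow(ps)) break
    del <- ps[ps$pattern %in% .DELETION_PATTERNS, , drop = FALSE]
    m <- if (nrow(del)) del[1L, ] else ps[1L, ]
    fl <- .flApplyFix(fl, m$pattern, m$startLayer)
  }
  warnings <- character()
  if (xh == "keep") {
    left <- .flFindPatterns(fl)
    left <- left[left$pattern == "Xh", , drop = FALSE]
    if (nrow(left))
      warnings <- sprintf(
        "pattern Xh at layer %d of \"%s\" left in place: check whether the resulting fcode is the OC",
        left$startLayer, .renderFl(fl))
  }
  list(fl = fl, warnings = warnings)
}

#' Locate the redundant patterns of an Fcode
#'
#' Converts the code to its lineage and scans every adjacent pair of
#' non-origin layers against the eight redundant ("wrong") patterns, each
#' of which admits a strictly shorter encoding of the same person. Matches
#' are reported left to right; an empty result means the code already uses
#' a shortest path.
#'
#' @param f an [Fcode-class] object or code string.
#' @return data.frame with columns `pattern` (e.g. `"hX"`), `startLayer`
#'   (index of the first layer of the pair; the OC is layer 0) and
#'   `fixKind`.
#' @examples
#' findWrongPatterns("*a1M3")   # hX at layer 1
#' findWrongPatterns("*MM4")    # none: a grandparent is irreducible
#' @export
findWrongPatterns <- function(f) .flFindPatterns(.asFl(f))

#' Apply one pattern fix
#'
#' Rewrites the matched layer pair according to its repair rule (see
#' [findWrongPatterns()]), returning a strictly shorter code. Substitution
#' fixes inherit sex and birth order from the surviving semantic role:
#' `hX` keeps the parent layer's number on the new `C` layer, `hH`/`Xh`
#' keep the second layer's sex and number, and `XC` switches the parent's
#' sex and, its number being unrecoverable, marks the order unknown (`?`).
#'
#' @param f an [Fcode-class] object or code string.
#' @param match one row of the data.frame returned by
#'   [findWrongPatterns()] (or any list with `pattern` and `startLayer`).
#' @return an [Fcode-class] object.
#' @examples
#' m <- findWrongPatterns("*a1M3")
#' renderFcode(applyFix("*a1M3", m[1, ]))  # "*C3"
#' @export
applyFix <- function(f, match) {
  .flToFcode(.flApplyFix(.asFl(f), as.character(match$pattern)[1L],
                         as.integer(match$startLayer)[1L]))
}

#' Normalize an Fcode to its shortest-path form
#'
#' Repeatedly detects and repairs redundant patterns until none remains,
#' so that the connection between the OC and the encoded person is as
#' direct as possible. Deletion fixes (`CC`, `HX`, `Ch`, `HH`) are applied
#' before substitution fixes, leftmost first within each class; this
#' ordering reproduces e.g. `"*PC1o2"` to `"*Po2"` (the spouse layer is
#' dropped rather than the parent rewritten). Each fix removes at least
#' one layer, so at most `fcodeDepth(f)` fixes are ever applied.
#'
#' The `Xh` pattern (parent's child) is special: rewriting it to a
#' brotherhood layer is only valid if the resulting person is not the OC
#' themselves, which the code string cannot decide. With `xh = "keep"`
#' (default) such patterns are left in place and reported as warnings;
#' `xh = "rewrite"` applies the repair unconditionally.
#'
#' @param f an [Fcode-class] object or code string.
#' @param xh `"keep"` or `"rewrite"`.
#' @return the normalized [Fcode-class] object; warnings (if any) are
#'   attached as an attribute and retrievable with
#'   [normalizationWarnings()].
#' @examples
#' renderFcode(normalizeFcode("*PC1o2"))            # "*Po2"
#' renderFcode(normalizeFcode("*Po1", xh = "rewrite"))  # "*O1"
#' @export
normalizeFcode <- function(f, xh = c("keep", "rewrite")) {
  xh <- match.arg(xh)
  res <- .flNormalize(.asFl(f), xh)
  out <- .flToFcode(res$fl)
  attr(out, "warnings") <- res$warnings
  out
}

#' @rdname normalizeFcode
#' @param x the result of [normalizeFcode()].
#' @export
normalizationWarnings <- function(x) attr(x, "warnings") %||% character()

#' Enumerate the redundant lineage adjacencies
#'
#' Scans all 16 ordered pairs of lineage symbols over `{X, C, H, h}`
#' against the reduction rules and returns the pattern identifiers that
#' admit a shorter equivalent encoding. Exactly eight exist; the other
#' eight adjacencies (grandparent `XX`, grandchild `hh`, in-laws `CX`/`hC`,
#' uncle `XH`, nephew `Hh`, sibling-in-law `HC`/`CH`) are irreducible.
#'
#' @return character vector of pattern ids.
#' @export
enumerateWrongPairs <- function() {
  pairs <- as.vector(t(outer(.LINEAGE_SYMBOLS, .LINEAGE_SYMBOLS, paste0)))
  pairs[pairs %in% names(.FIXES)]
}
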
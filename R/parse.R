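# Internal layer representation: a plain list(sym, ord, unk) mirroring the
# Fcode slots. Hot paths (normalization over thousands of codes, graph
# construction) work on these lists; the S4 object is the API surface.

.flFromFcode <- function(f) list(sym = f@symbols, ord = f@orders, unk = f@unknown)

.flToFcode <- function(fl) new("Fcode", symbols = fl$sym, orders = fl$ord, unknown = fl$unk)

.flDepth <- function(fl) length(fl$sym) - 1L

# Tokenize one Fcode string. Raises classed errors: MissingOrigin,
# IllegalSymbol, BadOrder, MissingOrder.
.scanFcode <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    .fcodeStop("MissingOrigin", "an Fcode is a non-empty string starting with '*'")
  if (substr(text, 1L, 1L) != "*")
    .fcodeStop("MissingOrigin", "Fcode \"%s\" does not start with the origin symbol '*'", text)
  toks <- regmatches(text, gregexpr("[*PMXCOAHoah](?:[0-9]+|\\?)?", text))[[1L]]
  if (!identical(paste0(toks, collapse = ""), text)) {
    # Locate the first character not absorbed by the token scan.
    i <- 1L
    for (t in toks) {
      if (substr(text, i, i + nchar(t) - 1L) != t) break
      i <- i + nchar(t)
    }
    bad <- substr(text, i, i)
    if (grepl("[0-9+-]", bad))
      .fcodeStop("BadOrder", "malformed birth order at position %d of \"%s\"", i, text)
    .fcodeStop("IllegalSymbol", "symbol \"%s\" at position %d of \"%s\" is not in the Fcode legend",
               bad, i, text)
  }
  sym <- substr(toks, 1L, 1L)
  rest <- substring(toks, 2L)
  unk <- rest == "?"
  has <- nzchar(rest) & !unk
  if (any(grepl("^0", rest[has])))
    .fcodeStop("BadOrder", "birth order 0 (or leading zero) in \"%s\": orders are positive", text)
  ord <- rep(NA_integer_, length(toks))
  ord[has] <- as.integer(rest[has])
  if (any(sym[-1L] == "*"))
    .fcodeStop("IllegalSymbol", "origin symbol '*' may only appear as layer 0 in \"%s\"", text)
  if (nzchar(rest[1L]))
    .fcodeStop("BadOrder", "the origin layer '*' never carries a birth order (\"%s\")", text)
  mand <- .CATEGORY[sym] %in% .NUMBERED_CATEGORIES
  miss <- mand & is.na(ord) & !unk
  if (any(miss))
    .fcodeStop("MissingOrder",
               "layer %d (\"%s\") of \"%s\": brotherhood/sonship layers must carry a number or '?'",
               which(miss)[1L] - 1L, sym[which(miss)[1L]], text)
  list(sym = sym, ord = ord, unk = unk)
}

# Consideration-2 check: parenthood/spousehood layers are numbered only at
# the final layer (and, there, must carry a number or '?'). An interior '?'
# is tolerated: it marks an unknown, not a numeration, and is how two
# same-sex (or unknown-sex) parents stay distinguishable inside a code.
.checkStrict <- function(fl, text = .renderFl(fl)) {
  n <- length(fl$sym)
  ps <- .CATEGORY[fl$sym] %in% c("parenthood", "spousehood")
  numbered <- !is.na(fl$ord) | fl$unk
  idx <- seq_len(n)
  badInterior <- ps & !is.na(fl$ord) & idx < n
  badTerminal <- ps & !numbered & idx == n
  if (any(badInterior))
    .fcodeStop("StrictNumberViolation",
               "strict mode: interior parenthood/spousehood layer %d of \"%s\" carries a number",
               which(badInterior)[1L] - 1L, text)
  if (any(badTerminal))
    .fcodeStop("StrictNumberViolation",
               "strict mode: terminal parenthood/spousehood layer of \"%s\" lacks a number or '?'",
               text)
  invisible(fl)
}

.renderFl <- function(fl, canonical = FALSE) {
  ordstr <- ifelse(fl$unk, "?", ifelse(is.na(fl$ord), "", as.character(fl$ord)))
  if (canonical) {
    # drop interior concrete parenthood/spousehood numbers; keep '?', which
    # may be the only mark distinguishing two unknown-order parents
    n <- length(fl$sym)
    ps <- .CATEGORY[fl$sym] %in% c("parenthood", "spousehood")
    ordstr[ps & !fl$unk & seq_len(n) < n] <- ""
  }
  paste0(fl$sym, ordstr, collapse = "")
}

# Coerce character or Fcode input to the internal layer list (lenient).
.asFl <- function(x) {
  if (is(x, "Fcode")) return(.flFromFcode(x))
  if (is.character(x) && length(x) == 1L) return(.scanFcode(x))
  .fcodeStop("InvalidFcode", "expected an Fcode object or a single code string")
}

#' Parse an Fcode string
#'
#' Turns a kinship-path string such as `"*PO1a1"` into an [Fcode-class]
#' object, validating it against the legend and the numbering rules:
#' brotherhood and sonship layers must always be numbered (or carry `?`),
#' and, in strict mode, parenthood/spousehood layers are numbered exactly
#' when they are the final layer.
#'
#' The default lenient mode (used for file reading) accepts interior
#' parenthood/spousehood numbers and preserves them; the canonical renderer
#' ([renderFcode()] with `canonical = TRUE`) emits the strict spelling.
#'
#' @param text a single code string, e.g. `"*MM4"`.
#' @param strict logical; enforce the terminal-only numbering rule.
#' @return an [Fcode-class] object.
#' @examples
#' parseFcode("*PO1a1")
#' parseFcode("*P?")          # unknown birth order
#' try(parseFcode("*Oo1"))    # brotherhood layer without a number
#' @export
parseFcode <- function(text, strict = FALSE) {
  fl <- .scanFcode(text)
  if (strict) .checkStrict(fl, text)
  .flToFcode(fl)
}

#' Render an Fcode back to its string form
#'
#' Inverse of [parseFcode()]: `parseFcode(renderFcode(f))` reproduces `f`,
#' and rendering a parsed canonical string reproduces it byte for byte.
#' Unknown orders render as `?`. With `canonical = TRUE` interior
#' parenthood/spousehood numbers are dropped (the strict-form spelling used
#' when writing files); an absent terminal number is left absent, never
#' invented.
#'
#' @param f an [Fcode-class] object (or a code string, returned normalized
#'   in spelling only).
#' @param canonical logical; emit the strict-form spelling.
#' @return a single character string.
#' @export
renderFcode <- function(f, canonical = FALSE) {
  .renderFl(.asFl(f), canonical = canonical)
}

#' Depth of an Fcode
#'
#' The number of non-origin layers: the kinship distance between the OC and
#' the encoded person. The OC itself (`"*"`) has depth 0.
#'
#' @param f an [Fcode-class] object or code string.
#' @return a non-negative integer.
#' @examples
#' fcodeDepth("*MM4")  # 2
#' @export
fcodeDepth <- function(f) .flDepth(.asFl(f))

#' Position: the prefix of an Fcode at a given layer
#'
#' Position `k` of an Fcode is layer `k` together with all downward layers
#' to the OC, i.e. the prefix holding `k` non-origin layers. Position 0 is
#' always `"*"`; position `depth(f)` is the code itself.
#'
#' @param f an [Fcode-class] object or code string.
#' @param k integer in `0:fcodeDepth(f)`.
#' @return an [Fcode-class] object.
#' @examples
#' renderFcode(fcodePosition("*PMA2O1", 2))  # "*PM"
#' @export
fcodePosition <- function(f, k) {
  fl <- .asFl(f)
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 0L || k > .flDepth(fl))
    .fcodeStop("IndexOutOfRange", "position %s outside 0..%d", as.character(k), .flDepth(fl))
  idx <- seq_len(k + 1L)
  .flToFcode(list(sym = fl$sym[idx], ord = fl$ord[idx], unk = fl$unk[idx]))
}

.flLineage <- function(fl) unname(.DESEX[fl$sym])

#' Lineage of an Fcode
#'
#' The lineage is the code with birth-order numbers removed and every sexed
#' symbol replaced by its unknown-sex counterpart (`P`/`M` to `X`, `O`/`A`
#' to `H`, `o`/`a` to `h`). It has exactly one symbol per layer and drives
#' the wrong-pattern scan of [findWrongPatterns()].
#'
#' @param f an [Fcode-class] object or code string.
#' @return a single character string, e.g. `"*XHh"`.
#' @examples
#' fcodeLineage("*PO1a1")  # "*XHh"
#' @export
fcodeLineage <- function(f) paste0(.flLineage(.asFl(f)), collapse = "")

#' Type of an Fcode
#'
#' The type is the upper (last) layer of the code's lineage: the desexed
#' category of the encoded person relative to the previous position.
#'
#' @param f an [Fcode-class] object or code string.
#' @return a single character (`"*"`, `"X"`, `"C"`, `"H"` or `"h"`).
#' @examples
#' fcodeType("*PO1a1")  # "h"
#' @export
fcodeType <- function(f) {
  lin <- .flLineage(.asFl(f))
  lin[length(lin)]
}

# Layer-wise compatibility: symbols equal; orders equal or at least one of
# them not a concrete number. Used for common-ancestor matching and person
# identity.
.flCompatible <- function(a, b) {
  if (length(a$sym) != length(b$sym)) return(FALSE)
  if (!all(a$sym == b$sym)) return(FALSE)
  both <- !is.na(a$ord) & !is.na(b$ord)
  all(a$ord[both] == b$ord[both])
}

#' Do two Fcodes denote a compatible position?
#'
#' Layer-by-layer comparison: symbols must be equal and the birth orders
#' must be equal wherever both are concrete; an absent or unknown (`?`)
#' order matches anything. This is the matching rule used by
#' [commonAncestor()] and by person identity in [buildKinshipGraph()], and
#' it makes `"*P"` compatible with `"*P3"`.
#'
#' @param a,b [Fcode-class] objects or code strings.
#' @return logical.
#' @export
fcodeMatches <- function(a, b) .flCompatible(.asFl(a), .asFl(b))

#' @describeIn parseFcode display method.
#' @param object an `Fcode` object.
#' @export
setMethod("show", "Fcode", function(object) {
  fl <- .flFromFcode(object)
  cat(sprintf("Fcode \"%s\" (depth %d, lineage %s)\n",
              .renderFl(fl), .flDepth(fl), paste0(.flLineage(fl), collapse = "")))
  invisible(object)
})

#' @export
setMethod("as.character", "Fcode", function(x, ...) renderFcode(x))
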
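#' @import methods
NULL

#' Fcode: a kinship path rooted at the origin of coordinates
#'
#' An `Fcode` is an ordered sequence of relationship layers read left to
#' right from the origin of coordinates (OC, written `*`). Each layer is one
#' legend symbol (`P`/`M`/`X` parenthood, `C` spousehood, `O`/`A`/`H`
#' brotherhood, `o`/`a`/`h` sonship) plus an optional birth-order number.
#' Brotherhood and sonship layers always carry a number, or `?` when the
#' order is not recorded.
#'
#' Internally the object stores three parallel vectors: the layer symbols,
#' the concrete birth orders (`NA` when none) and a logical flag marking
#' orders recorded as unknown (`?`). Construct with [parseFcode()].
#'
#' @slot symbols character vector of layer symbols, `"*"` first.
#' @slot orders integer vector of birth orders, `NA` where no concrete
#'   number is present.
#' @slot unknown logical vector, `TRUE` where the order is `?`.
#' @seealso [parseFcode()], [renderFcode()], [fcodeDepth()], [fcodeLineage()]
#' @exportClass Fcode
setClass("Fcode", representation(
  symbols = "character",
  orders = "integer",
  unknown = "logical"
))

setValidity("Fcode", function(object) {
  s <- object@symbols
  o <- object@orders
  u <- object@unknown
  if (length(s) != length(o) || length(s) != length(u))
    return("symbols, orders and unknown must have equal length")
  if (length(s) == 0L) return("an Fcode has at least the origin layer")
  if (s[1L] != "*") return("layer 0 must be the origin symbol '*'")
  if (any(s[-1L] == "*")) return("only layer 0 may be the origin symbol")
  if (!all(s %in% .LEGEND)) return("symbol outside the Fcode legend")
  if (any(!is.na(o) & o < 1L)) return("birth orders must be positive")
  if (any(!is.na(o) & u)) return("a layer cannot be both numbered and '?'")
  mand <- .CATEGORY[s] %in% .NUMBERED_CATEGORIES
  if (any(mand & is.na(o) & !u))
    return("brotherhood/sonship layers must carry a number or '?'")
  if (!is.na(o[1L]) || u[1L]) return("the origin layer never carries a number")
  TRUE
})

#' Family: a set of named Fcode records sharing one origin of coordinates
#'
#' The in-memory form of an FDATA file (see [readFdata()]): one record per
#' person, each holding an Fcode and a name, optionally a nickname, birth
#' date and biography (the extended TSV columns). All records share the same
#' OC, and no two records may have the same normalized code.
#'
#' @slot records data.frame with columns `fcode`, `name`, `nickname`,
#'   `birthdate`, `biography`. `fcode` keeps the as-read (lenient,
#'   normalized-spelling) code; the canonical index keys are in `metadata`.
#' @slot ocMeta list with optional `sex` (`"male"`/`"female"`) and `order`
#'   (birth order) of the OC person; the code string itself cannot record
#'   them.
#' @slot metadata list: `keys` (canonical normalized code per record),
#'   `layers` (parsed normalized layers per record), `diagnostics`
#'   (line-numbered notes from I/O), plus flags set by other operations.
#' @seealso [readFdata()], [Family()], [buildKinshipGraph()]
#' @exportClass Family
setClass("Family", representation(
  records = "data.frame",
  ocMeta = "list",
  metadata = "list"
))

setValidity("Family", function(object) {
  r <- object@records
  need <- c("fcode", "name", "nickname", "birthdate", "biography")
  if (!all(need %in% names(r))) return("records lack required columns")
  k <- object@metadata$keys
  if (length(k) != nrow(r)) return("one canonical key per record required")
  if (anyDuplicated(k)) return("duplicated normalized fcodes in records")
  TRUE
})

#' KinshipGraph: person nodes and typed relationship edges of a Family
#'
#' Built by [buildKinshipGraph()]. One node per distinct person position
#' across all records (positions denoting the same person are unified), and
#' edges of type `parent` (directed parent to child), `sibling` and `spouse`
#' (symmetric). Closure rules propagate the obvious implications: siblings
#' share parents, co-parents of a child form a couple, a parent's spouse is
#' a parent, and children of one parent are siblings.
#'
#' @slot nodes data.frame: `key` (canonical position code), `name`, `sex`,
#'   `order` (birth order when known), `spouseIndex`, `isRecord`.
#' @slot edges data.frame: `from`, `to`, `type` (node keys).
#' @slot graph the underlying `igraph` object used for traversal.
#' @slot metadata list of diagnostics.
#' @exportClass KinshipGraph
setClass("KinshipGraph", representation(
  nodes = "data.frame",
  edges = "data.frame",
  graph = "ANY",
  metadata = "list"
))

#' AncestorResult: common ancestor and divergent sections of an Fcode pair
#'
#' Produced by [commonAncestor()]. The common ancestor of two codes sharing
#' an OC is their last position of matching layers; the unmatched suffixes
#' are the divergent sections. No common ancestor exists when a spousehood
#' (`C`) layer occurs in either divergent section. When one exists, the
#' inbreeding coefficient is `F = 0.5 ^ (dsA + dsB)` for the two divergent
#' depths.
#'
#' @slot hasCommonAncestor logical.
#' @slot ancestor the ancestor position as an [Fcode-class] object, or
#'   `NULL`.
#' @slot divergentA,divergentB the unmatched layer suffixes, rendered
#'   without the leading `*`.
#' @slot dsA,dsB integer depths of the divergent sections.
#' @slot F numeric inbreeding coefficient; `NA` when no common ancestor.
#' @seealso [commonAncestor()], [inbreedingCoefficient()]
#' @exportClass AncestorResult
setClass("AncestorResult", representation(
  hasCommonAncestor = "logical",
  ancestor = "ANY",
  divergentA = "character",
  divergentB = "character",
  dsA = "integer",
  dsB = "integer",
  F = "numeric"
))

setValidity("AncestorResult", function(object) {
  if (object@dsA < 0L || object@dsB < 0L) return("divergent depths are non-negative")
  if (object@hasCommonAncestor && is.na(object@F)) return("F required with an ancestor")
  if (!is.na(object@F) && (object@F < 0 || object@F > 1)) return("F must lie in [0, 1]")
  TRUE
})
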
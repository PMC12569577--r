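# Common ancestor of two codes sharing an OC: the last position of matching
# layers, valid only while no spousehood (C) layer occurs among the
# unmatched layers. The unmatched suffixes are the divergent sections; their
# depths drive the inbreeding coefficient F = 0.5^(dsA + dsB).

.layerMatch <- function(a, b, i) {
  if (a$sym[i] != b$sym[i]) return(FALSE)
  if (!is.na(a$ord[i]) && !is.na(b$ord[i])) return(a$ord[i] == b$ord[i])
  TRUE
}

.flCommonAncestor <- function(fa, fb) {
  na <- length(fa$sym); nb <- length(fb$sym)
  L <- 1L
  while (L < min(na, nb) && .layerMatch(fa, fb, L + 1L)) L <- L + 1L
  idx <- seq_len(L)
  # the ancestor position keeps the more informative (concrete) order
  anc <- list(
    sym = fa$sym[idx],
    ord = ifelse(!is.na(fa$ord[idx]), fa$ord[idx], fb$ord[idx]),
    unk = fa$unk[idx] & fb$unk[idx]
  )
  anc$unk <- anc$unk & is.na(anc$ord)
  divA <- list(sym = fa$sym[-idx], ord = fa$ord[-idx], unk = fa$unk[-idx])
  divB <- list(sym = fb$sym[-idx], ord = fb$ord[-idx], unk = fb$unk[-idx])
  hasC <- any(divA$sym == "C") || any(divB$sym == "C")
  dsA <- na - L; dsB <- nb - L
  renderDiv <- function(d) {
    if (!length(d$sym)) return("")
    paste0(d$sym, ifelse(d$unk, "?", ifelse(is.na(d$ord), "", as.character(d$ord))),
           collapse = "")
  }
  list(has = !hasC, anc = anc, divA = renderDiv(divA), divB = renderDiv(divB),
       dsA = dsA, dsB = dsB,
       F = if (!hasC) 0.5^(dsA + dsB) else NA_real_)
}

#' Common ancestor and divergent sections of two Fcodes
#'
#' Both codes are normalized (`xh = "keep"`) and compared layer by layer
#' from the OC: two layers match when their symbols are equal and their
#' birth orders are equal or at least one of them is absent or unknown
#' (so `"*P3"` matches the first layer of `"*PMO1a1"`). The last matching
#' position is the common-ancestor candidate; it is a true common ancestor
#' only if no spousehood (`C`) layer occurs in either unmatched suffix.
#'
#' @param a,b [Fcode-class] objects or code strings sharing the same OC.
#' @return an [AncestorResult-class] object.
#' @examples
#' commonAncestor("*P3", "*PMO1a1")
#' @export
commonAncestor <- function(a, b) {
  fa <- .flNormalize(.asFl(a), "keep")$fl
  fb <- .flNormalize(.asFl(b), "keep")$fl
  r <- .flCommonAncestor(fa, fb)
  new("AncestorResult",
      hasCommonAncestor = r$has,
      ancestor = if (r$has) .flToFcode(r$anc) else NULL,
      divergentA = r$divA, divergentB = r$divB,
      dsA = as.integer(r$dsA), dsB = as.integer(r$dsB),
      F = r$F)
}

#' Inbreeding coefficient of an Fcode pair
#'
#' Evaluates `F = (1/2) ^ (dsA + dsB)` for the depths of the two divergent
#' sections when a common ancestor exists (see [commonAncestor()]), and
#' returns `0` otherwise, so that pairwise matrices can be computed without
#' exception handling; use [hasCommonAncestor()] on the [commonAncestor()]
#' result to distinguish "unrelated" from a vanishing coefficient. The
#' formula is the package's path-length estimate from two isolated codes:
#' it considers the single encoded common-ancestor position only.
#'
#' @inheritParams commonAncestor
#' @return a number in `[0, 1]`; `1` only for codes naming the same
#'   position.
#' @examples
#' inbreedingCoefficient("*P3", "*PMO1a1")  # 0.125, first cousins
#' @export
inbreedingCoefficient <- function(a, b) {
  fa <- .flNormalize(.asFl(a), "keep")$fl
  fb <- .flNormalize(.asFl(b), "keep")$fl
  r <- .flCommonAncestor(fa, fb)
  if (r$has) r$F else 0
}

#' @rdname commonAncestor
#' @param x an [AncestorResult-class] object.
#' @export
hasCommonAncestor <- function(x) x@hasCommonAncestor

#' @rdname commonAncestor
#' @export
commonAncestorCode <- function(x) {
  if (!x@hasCommonAncestor) return(NA_character_)
  renderFcode(x@ancestor)
}

#' @rdname commonAncestor
#' @export
divergentSections <- function(x) c(x@divergentA, x@divergentB)

#' @rdname commonAncestor
#' @export
divergentDepths <- function(x) c(x@dsA, x@dsB)

#' @rdname commonAncestor
#' @export
inbreedingF <- function(x) x@F

#' @export
setMethod("show", "AncestorResult", function(object) {
  if (object@hasCommonAncestor) {
    cat(sprintf("Common ancestor: %s\n", renderFcode(object@ancestor)))
    cat(sprintf("Divergent sections: (\"%s\", \"%s\"), depths (%d, %d)\n",
                object@divergentA, object@divergentB, object@dsA, object@dsB))
    cat(sprintf("F = %g\n", object@F))
  } else {
    cat("No common ancestor (spousehood layer in a divergent section)\n")
    cat(sprintf("Divergent sections: (\"%s\", \"%s\"), depths (%d, %d)\n",
                object@divergentA, object@divergentB, object@dsA, object@dsB))
  }
  invisible(object)
})
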
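# Deterministic, pure exporters: Graphviz DOT tree, dictionary-style HTML
# report, and 6-column LINKAGE/PED pedigree lines.

#' Render a family as a Graphviz DOT tree
#'
#' One box per person labeled with name and code; couples with children
#' meet at a point-shaped junction node from which child edges descend;
#' childless couples are joined by a dashed edge; a single known parent
#' connects directly to the child. Node ordering is sorted by canonical
#' code, so output is byte-identical across runs. The text renders with any
#' Graphviz installation (`dot -Tpdf`); no renderer is invoked here.
#'
#' @param fam a [Family-class] object.
#' @return a single character string of DOT source.
#' @export
toDot <- function(fam) {
  g <- .asGraph(fam)
  nd <- g@nodes
  n <- nrow(nd)
  id <- sprintf("p%d", seq_len(n) - 1L)
  label <- ifelse(nzchar(nd$name), paste0(nd$name, "\\n", nd$key), nd$key)
  out <- c(
    "digraph pedigree {",
    "  rankdir=TB;",
    "  node [shape=box, fontname=\"Helvetica\"];",
    sprintf("  %s [label=\"%s\"];", id, .escapeDot(label))
  )
  parents <- g@metadata$parents
  spouses <- g@metadata$spouses
  # group children by their (sorted) parent set
  famOf <- vapply(seq_len(n), function(j) {
    ps <- sort(parents[[j]])
    if (length(ps)) paste(ps, collapse = "_") else ""
  }, character(1L))
  unions <- sort(unique(famOf[famOf != "" & vapply(
    seq_len(n), function(j) length(parents[[j]]) == 2L, logical(1L))]))
  uid <- stats::setNames(sprintf("u%d", seq_along(unions) - 1L), unions)
  if (length(unions)) {
    out <- c(out, "  node [shape=point, width=0.08];",
             sprintf("  %s;", unname(uid)))
    for (u in unions) {
      ps <- as.integer(strsplit(u, "_", fixed = TRUE)[[1L]])
      out <- c(out, sprintf("  %s -> %s [dir=none];", id[ps], uid[[u]]))
      kids <- which(famOf == u)
      out <- c(out, sprintf("  %s -> %s;", uid[[u]], id[sort(kids)]))
    }
  }
  # single known parent: direct edge
  for (j in seq_len(n)) {
    if (length(parents[[j]]) == 1L)
      out <- c(out, sprintf("  %s -> %s;", id[parents[[j]]], id[j]))
  }
  # childless couples: dashed marriage edge
  inUnion <- unique(unlist(lapply(unions, function(u)
    as.integer(strsplit(u, "_", fixed = TRUE)[[1L]]))))
  for (j in seq_len(n)) {
    for (s in spouses[[j]]) {
      if (s <= j) next
      if (j %in% inUnion && s %in% inUnion &&
          any(famOf == paste(sort(c(j, s)), collapse = "_"))) next
      out <- c(out, sprintf("  %s -> %s [dir=none, style=dashed];", id[j], id[s]))
    }
  }
  paste0(c(out, "}"), collapse = "\n")
}

#' Render a family as a dictionary-style HTML report
#'
#' One anchor-identified entry per record, listing the person's direct
#' relationships; every relationship that corresponds to another record is
#' an intra-document link to that entry, so the report can be browsed like
#' a dictionary. Persons implied by the codes but not recorded appear as
#' plain text.
#'
#' @param fam a [Family-class] object.
#' @return a single character string of HTML.
#' @export
toHtmlReport <- function(fam) {
  g <- .asGraph(fam)
  nd <- g@nodes
  recOf <- nd$recIdx                    # node -> record index or NA
  nodeOfRec <- match(seq_len(length(fam)), recOf)
  anchor <- function(i) sprintf("person-%d", i)
  refHtml <- function(j) {
    lbl <- .escapeHtml(if (nzchar(nd$name[j])) sprintf("%s (%s)", nd$name[j], nd$key[j])
                       else nd$key[j])
    if (!is.na(recOf[j])) sprintf("<a href=\"#%s\">%s</a>", anchor(recOf[j]), lbl)
    else lbl
  }
  li <- function(what, js) {
    js <- js[!is.na(js)]
    if (!length(js)) return(character())
    js <- js[order(nd$key[js])]
    sprintf("      <li>%s: %s</li>", what,
            paste(vapply(js, refHtml, character(1L)), collapse = ", "))
  }
  body <- character()
  for (i in seq_len(length(fam))) {
    j <- nodeOfRec[i]
    slots <- .parentSlots(g, j)
    kids <- which(vapply(g@metadata$parents, function(x) j %in% x, logical(1L)))
    head_ <- .escapeHtml(if (nzchar(nd$name[j])) nd$name[j] else "(unnamed)")
    body <- c(body,
      sprintf("  <section id=\"%s\">", anchor(i)),
      sprintf("    <h2>%s <code>%s</code></h2>", head_, .escapeHtml(nd$key[j])),
      "    <ul>",
      li("Father", slots$father),
      li("Mother", slots$mother),
      li("Siblings", g@metadata$sibs[[j]]),
      li("Spouse", g@metadata$spouses[[j]]),
      li("Children", kids),
      "    </ul>",
      "  </section>")
  }
  paste0(c(
    "<!DOCTYPE html>",
    "<html lang=\"en\">",
    "<head>",
    "  <meta charset=\"utf-8\"/>",
    "  <title>Family report</title>",
    "  <style>body{font-family:sans-serif;max-width:45em;margin:auto}code{background:#eee}</style>",
    "</head>",
    "<body>",
    sprintf("  <h1>Family report (%d entries)</h1>", length(fam)),
    body,
    "</body>",
    "</html>"
  ), collapse = "\n")
}

#' Export a family as LINKAGE/PED pedigree lines
#'
#' One whitespace-delimited 6-column line per person: family id, individual
#' id (the canonical code), father id, mother id (`"0"` when unknown), sex
#' (`1` male, `2` female, `0` unknown -- notably the OC, whose sex the
#' format does not record unless OC metadata is present) and phenotype
#' `"0"`. Besides the records, any person referenced as a parent gets a
#' line, so parent references always resolve within the file.
#'
#' @param fam a [Family-class] object.
#' @param familyId the family identifier written in column 1.
#' @return a single character string of PED text.
#' @export
toPed <- function(fam, familyId = "FAM1") {
  g <- .asGraph(fam)
  nd <- g@nodes
  parents <- g@metadata$parents
  keep <- which(nd$isRecord)
  repeat {
    more <- setdiff(unique(unlist(parents[keep])), keep)
    if (!length(more)) break
    keep <- c(keep, more)
  }
  keep <- sort(keep)
  sexCode <- c(male = "1", female = "2", unknown = "0")
  lines <- vapply(keep, function(j) {
    slots <- .parentSlots(g, j)
    paste(familyId, nd$key[j],
          if (is.na(slots$father)) "0" else nd$key[slots$father],
          if (is.na(slots$mother)) "0" else nd$key[slots$mother],
          sexCode[[nd$sex[j]]], "0", sep = "\t")
  }, character(1L))
  paste0(lines, collapse = "\n")
}
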
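# FDATA is the two-column, tab-separated family file: one person per line
# (Fcode, then name), '#' comment lines and blank lines ignored, every code
# sharing the one origin of coordinates. The extended TSV adds nickname,
# birthdate and biography columns behind a header row.

.TSV_HEADER <- c("fcode", "name", "nickname", "birthdate", "biography")

.emptyRecords <- function() {
  data.frame(fcode = character(), name = character(), nickname = character(),
             birthdate = character(), biography = character(),
             stringsAsFactors = FALSE)
}

.newDiag <- function(line = integer(), code = character(), message = character()) {
  data.frame(line = as.integer(line), code = code, message = message,
             stringsAsFactors = FALSE)
}

# Shared assembly: parse (lenient), normalize (xh = keep), key on the
# canonical strict render, reject or flag duplicate keys.
.assembleFamily <- function(fcode, name, nickname, birthdate, biography,
                            ocMeta, diagnostics, lines = rep(NA_integer_, length(fcode)),
                            allowDuplicates = FALSE) {
  n <- length(fcode)
  layers <- vector("list", n)
  keys <- character(n)
  for (i in seq_len(n)) {
    fl <- tryCatch(.scanFcode(fcode[i]), fcodeError = function(e) {
      where <- if (is.na(lines[i])) "" else sprintf(" (line %d)", lines[i])
      .fcodeStop("InvalidFcode", "invalid Fcode \"%s\"%s: %s", fcode[i], where,
                 conditionMessage(e))
    })
    nfl <- .flNormalize(fl, "keep")$fl
    layers[[i]] <- nfl
    keys[i] <- .renderFl(nfl, canonical = TRUE)
    if (keys[i] != fcode[i])
      diagnostics <- rbind(diagnostics, .newDiag(lines[i], fcode[i],
        sprintf("normalized to \"%s\"", keys[i])))
    if (!nzchar(name[i]))
      diagnostics <- rbind(diagnostics, .newDiag(lines[i], fcode[i], "empty name"))
  }
  dup <- duplicated(keys)
  if (any(dup)) {
    if (!allowDuplicates)
      .fcodeStop("DuplicateFcode",
                 "duplicate normalized Fcode \"%s\"%s", keys[which(dup)[1L]],
                 if (is.na(lines[which(dup)[1L]])) "" else sprintf(" (line %d)", lines[which(dup)[1L]]))
    diagnostics <- rbind(diagnostics, .newDiag(lines[dup], fcode[dup],
      "duplicate normalized Fcode: first occurrence kept"))
    keep <- !dup
    fcode <- fcode[keep]; name <- name[keep]; nickname <- nickname[keep]
    birthdate <- birthdate[keep]; biography <- biography[keep]
    layers <- layers[keep]; keys <- keys[keep]
  }
  rec <- data.frame(fcode = fcode, name = name, nickname = nickname,
                    birthdate = birthdate, biography = biography,
                    stringsAsFactors = FALSE)
  new("Family", records = rec, ocMeta = ocMeta,
      metadata = list(keys = keys, layers = layers, diagnostics = diagnostics))
}

#' Construct a Family from vectors of codes and names
#'
#' The programmatic counterpart of [readFdata()]: builds the family data
#' model from parallel vectors. Codes are parsed leniently and normalized
#' (`xh = "keep"`); two records with the same normalized code are an error
#' unless `allowDuplicates` downgrades them to a kept-first diagnostic.
#'
#' @param fcode character vector of Fcode strings sharing the OC `*`.
#' @param name,nickname,birthdate,biography character vectors recycled to
#'   the length of `fcode`.
#' @param ocMeta optional list with `sex` (`"male"`/`"female"`) and
#'   `order` (birth order) of the OC person, metadata the code string
#'   itself cannot carry.
#' @param allowDuplicates keep the first of two records with equal
#'   normalized codes instead of failing.
#' @return a [Family-class] object.
#' @examples
#' fam <- Family(c("*", "*C", "*o1"), c("Ana", "Bea", "Carl"))
#' familyKeys(fam)
#' @export
Family <- function(fcode, name = "", nickname = "", birthdate = "",
                   biography = "", ocMeta = list(), allowDuplicates = FALSE) {
  n <- length(fcode)
  rec <- function(x) {
    x <- as.character(x)
    if (length(x) == 1L) rep(x, n) else x
  }
  .assembleFamily(as.character(fcode), rec(name), rec(nickname), rec(birthdate),
                  rec(biography), ocMeta, .newDiag(),
                  allowDuplicates = allowDuplicates)
}

.readLinesAny <- function(con) {
  x <- readLines(con, warn = FALSE, encoding = "UTF-8")
  sub("\r$", "", x)
}

# Optional OC-metadata directive inside comments: "# @oc sex=male order=2".
.parseOcDirective <- function(line) {
  m <- regmatches(line, regexec("^#\\s*@oc\\b(.*)$", line))[[1L]]
  if (!length(m)) return(NULL)
  out <- list()
  sx <- regmatches(m[2L], regexec("sex=(male|female)", m[2L]))[[1L]]
  if (length(sx)) out$sex <- sx[2L]
  od <- regmatches(m[2L], regexec("order=([0-9]+)", m[2L]))[[1L]]
  if (length(od)) out$order <- as.integer(od[2L])
  out
}

#' Read an FDATA family file
#'
#' Parses the two-column tab-separated family format: each non-omitted line
#' holds an Fcode and a name. Empty lines and lines starting with `#` are
#' omitted; a comment of the form `# @oc sex=male order=2` (written by
#' [writeFdata()] when present) records the OC person's own sex and birth
#' order, which no code string can encode. Codes are parsed leniently and
#' normalized; line-numbered diagnostics are kept on the returned object
#' (see [familyDiagnostics()]).
#'
#' @param con a file path or connection.
#' @param allowDuplicates keep the first of two records whose normalized
#'   codes collide instead of failing with `DuplicateFcode`.
#' @return a [Family-class] object.
#' @seealso [writeFdata()], [readFamilyTsv()]
#' @export
readFdata <- function(con, allowDuplicates = FALSE) {
  lines <- .readLinesAny(con)
  ocMeta <- list()
  fcode <- character(); name <- character(); lineNo <- integer()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) next
    if (startsWith(trimws(ln), "#")) {
      d <- .parseOcDirective(trimws(ln))
      if (length(d)) ocMeta <- utils::modifyList(ocMeta, d)
      next
    }
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) != 2L)
      .fcodeStop("TabColumnError",
                 "line %d: expected 2 tab-separated columns, found %d", i, length(parts))
    if (substr(parts[1L], 1L, 1L) != "*")
      .fcodeStop("ForeignOrigin",
                 "line %d: Fcode \"%s\" does not start at the origin '*'", i, parts[1L])
    fcode <- c(fcode, parts[1L]); name <- c(name, parts[2L]); lineNo <- c(lineNo, i)
  }
  .assembleFamily(fcode, name, rep("", length(fcode)), rep("", length(fcode)),
                  rep("", length(fcode)), ocMeta, .newDiag(), lines = lineNo,
                  allowDuplicates = allowDuplicates)
}

#' Write a Family as an FDATA file
#'
#' Emits one tab-separated `fcode<TAB>name` line per record, using the
#' canonical strict-form code (the family's normalized index key). Reading
#' the output back reproduces the records. OC metadata, when present, is
#' written as a `# @oc` comment directive.
#'
#' @param fam a [Family-class] object.
#' @param con a file path or connection.
#' @return invisibly, the lines written.
#' @export
writeFdata <- function(fam, con) {
  lines <- character()
  if (length(fam@ocMeta)) {
    bits <- c(
      if (!is.null(fam@ocMeta$sex)) sprintf("sex=%s", fam@ocMeta$sex),
      if (!is.null(fam@ocMeta$order)) sprintf("order=%d", fam@ocMeta$order)
    )
    if (length(bits)) lines <- sprintf("# @oc %s", paste(bits, collapse = " "))
  }
  lines <- c(lines, paste0(familyKeys(fam), "\t", fam@records$name))
  writeLines(lines, con, useBytes = TRUE)
  invisible(lines)
}

#' Read an extended TSV family file
#'
#' The TSV format extends FDATA with a header row and up to three optional
#' person-metadata columns: `fcode`, `name`, `nickname`, `birthdate`,
#' `biography`. Trailing columns may be missing on read; a header naming
#' any other column fails with `HeaderMismatch`. Comment (`#`) and blank
#' lines are ignored as in FDATA.
#'
#' @inheritParams readFdata
#' @return a [Family-class] object.
#' @export
readFamilyTsv <- function(con, allowDuplicates = FALSE) {
  lines <- .readLinesAny(con)
  ocMeta <- list()
  keep <- logical(length(lines))
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, "#")) {
      d <- .parseOcDirective(ln)
      if (length(d)) ocMeta <- utils::modifyList(ocMeta, d)
      next
    }
    keep[i] <- TRUE
  }
  idx <- which(keep)
  if (!length(idx))
    return(.assembleFamily(character(), character(), character(), character(),
                           character(), ocMeta, .newDiag()))
  header <- strsplit(lines[idx[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L || length(header) > length(.TSV_HEADER) ||
      !identical(header, .TSV_HEADER[seq_along(header)]))
    .fcodeStop("HeaderMismatch",
               "TSV header must be a prefix of \"%s\"; got \"%s\"",
               paste(.TSV_HEADER, collapse = "\t"), lines[idx[1L]])
  rows <- idx[-1L]
  cols <- matrix("", nrow = length(rows), ncol = length(.TSV_HEADER))
  for (j in seq_along(rows)) {
    parts <- strsplit(lines[rows[j]], "\t", fixed = TRUE)[[1L]]
    if (length(parts) > length(header))
      .fcodeStop("TabColumnError", "line %d: more fields than header columns", rows[j])
    cols[j, seq_along(parts)] <- parts
  }
  if (length(rows) && any(substr(cols[, 1L], 1L, 1L) != "*"))
    .fcodeStop("ForeignOrigin", "line %d: Fcode does not start at the origin '*'",
               rows[which(substr(cols[, 1L], 1L, 1L) != "*")[1L]])
  .assembleFamily(cols[, 1L], cols[, 2L], cols[, 3L], cols[, 4L], cols[, 5L],
                  ocMeta, .newDiag(), lines = rows, allowDuplicates = allowDuplicates)
}

#' Write a Family as an extended TSV file
#'
#' Emits the five-column header and one row per record (canonical codes,
#' missing metadata as empty fields). Round-trips through
#' [readFamilyTsv()].
#'
#' @inheritParams writeFdata
#' @return invisibly, the lines written.
#' @export
writeFamilyTsv <- function(fam, con) {
  r <- fam@records
  lines <- character()
  if (length(fam@ocMeta)) {
    bits <- c(
      if (!is.null(fam@ocMeta$sex)) sprintf("sex=%s", fam@ocMeta$sex),
      if (!is.null(fam@ocMeta$order)) sprintf("order=%d", fam@ocMeta$order)
    )
    if (length(bits)) lines <- sprintf("# @oc %s", paste(bits, collapse = " "))
  }
  lines <- c(lines,
             paste(.TSV_HEADER, collapse = "\t"),
             paste(familyKeys(fam), r$name, r$nickname, r$birthdate, r$biography,
                   sep = "\t"))
  writeLines(lines, con, useBytes = TRUE)
  invisible(lines)
}

#' @rdname Family
#' @param fam a [Family-class] object.
#' @export
familyRecords <- function(fam) fam@records

#' @rdname Family
#' @export
familyKeys <- function(fam) fam@metadata$keys

#' @rdname Family
#' @export
familyDiagnostics <- function(fam) fam@metadata$diagnostics %||% .newDiag()

#' @rdname Family
#' @export
familyOcMeta <- function(fam) fam@ocMeta

#' @describeIn Family number of records.
#' @param x a `Family` object.
#' @export
setMethod("length", "Family", function(x) nrow(x@records))

#' @export
setMethod("show", "Family", function(object) {
  n <- length(object)
  ocIdx <- match("*", familyKeys(object))
  oc <- if (!is.na(ocIdx)) object@records$name[ocIdx] else "<not recorded>"
  cat(sprintf("Family with %d record%s (OC: %s)\n", n, if (n == 1L) "" else "s", oc))
  if (n) {
    shown <- utils::head(seq_len(n), 8L)
    cat(paste0("  ", format(familyKeys(object)[shown]), "  ",
               object@records$name[shown], collapse = "\n"), "\n")
    if (n > 8L) cat(sprintf("  ... and %d more\n", n - 8L))
  }
  invisible(object)
})
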
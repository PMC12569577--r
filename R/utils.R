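# Classed conditions so callers can test on the failure kind rather than on
# message text. Every error raised by the package carries class "fcodeError"
# plus a specific class such as "MissingOrder" or "InconsistentFamily".
.fcodeStop <- function(class, msg, ...) {
  if (length(list(...))) msg <- sprintf(msg, ...)
  stop(structure(
    class = c(class, "fcodeError", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

# Run `code` under a fixed RNG seed without disturbing the caller's random
# state (no global side effects; see GenConfig contract).
.withSeed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.escapeHtml <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

.escapeDot <- function(x) gsub('"', '\\\\"', x)
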
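# The Fcode legend. Four direct-relationship categories plus the origin of
# coordinates (OC, "*"). Parenthood, brotherhood and sonship each exist in a
# male, female and unknown-sex spelling; spousehood (C) carries no sex marker.
.LEGEND <- c("*", "P", "M", "X", "C", "O", "A", "H", "o", "a", "h")

.CATEGORY <- c(
  "*" = "origin",
  P = "parenthood", M = "parenthood", X = "parenthood",
  C = "spousehood",
  O = "brotherhood", A = "brotherhood", H = "brotherhood",
  o = "sonship", a = "sonship", h = "sonship"
)

.SEXOF <- c(
  "*" = "unknown", C = "unknown",
  P = "male", M = "female", X = "unknown",
  O = "male", A = "female", H = "unknown",
  o = "male", a = "female", h = "unknown"
)

# Desexed counterparts used to build lineages.
.DESEX <- c(
  "*" = "*",
  P = "X", M = "X", X = "X",
  C = "C",
  O = "H", A = "H", H = "H",
  o = "h", a = "h", h = "h"
)

.LINEAGE_SYMBOLS <- c("X", "C", "H", "h")

# Categories whose layers must always carry a birth-order number (or "?").
.NUMBERED_CATEGORIES <- c("brotherhood", "sonship")
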
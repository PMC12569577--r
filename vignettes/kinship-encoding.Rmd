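---
title: "Kinship path encoding: model, normalization and inbreeding estimate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinship path encoding: model, normalization and inbreeding estimate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcodetools)
```

## The encoding model

An Fcode writes one person as a *path of relationship layers* starting at a
reference person, the origin of coordinates (OC), written `*`. Each layer is
a letter for one of four direct-relationship categories, optionally followed
by a birth-order number:

| category    | sexed symbols      | desexed | meaning of a layer        |
|-------------|--------------------|---------|---------------------------|
| parenthood  | `P` father, `M` mother | `X` | parent of the previous position |
| spousehood  | `C`                | `C`     | spouse/partner            |
| brotherhood | `O` brother, `A` sister | `H` | sibling                   |
| sonship     | `o` son, `a` daughter  | `h` | child                     |

So `*MM4` is the OC's maternal grandmother, fourth among her siblings. The
number of non-origin layers is the code's **depth**; the prefix with `k`
layers is **position** `k`; replacing symbols by their desexed counterparts
and deleting numbers gives the **lineage** (e.g. `*PO1a1` → `*XHh`), whose
last symbol is the code's **type**.

Two numbering rules shape the grammar. Brotherhood and sonship layers must
always carry a number, or `?` when the order is real but unrecorded
(`parseFcode("*Oo1")` is an error; `*O?o1` is not). Parenthood and
spousehood layers are numbered only when they are the final layer. The
package separates the two concerns: `parseFcode(strict = TRUE)` enforces the
terminal-only rule, while the default lenient mode (used by all file
readers) accepts interior numbers and preserves them; `renderFcode(f,
canonical = TRUE)` emits the strict spelling. One deliberate refinement: an
interior `?` is *kept* by the canonical form and tolerated by strict
parsing. It marks an unknown rather than a numeration, and it can be the
only feature separating two paths — `*X?M` (mother of *the other*
unknown-sex parent) must not collapse onto `*XM`.

## Shortest-path normalization

A code must connect the OC to the encoded person by the most direct path.
Working on lineages, exactly eight two-layer adjacencies admit a shorter
equivalent encoding; `enumerateWrongPairs()` scans all sixteen ordered
pairs over `{X, C, H, h}` and returns them:

```{r}
enumerateWrongPairs()
```

Each has a prescribed repair (`findWrongPatterns()` / `applyFix()`): the
loop `CC` deletes both layers; `HX`, `Ch` and `HH` delete one redundant
layer; `hX`, `XC`, `hH` and `Xh` substitute a single layer, inheriting sex
and birth order from the surviving semantic role. `XC` (a parent's partner
is the other parent) is the one case where the order is unrecoverable, so
it emits `?`: `*MC` → `*P?`.

`normalizeFcode()` iterates fixes to a fixpoint. Two policies matter:

* **Deletions before substitutions, leftmost first.** Deletion fixes never
  lose or invent order information, and this order is required for
  `*PC1o2` → `*Po2` (deleting the spouse layer) rather than `*M?o2`
  (rewriting the parent first). Termination is structural — every fix
  removes at least one layer — and the result is idempotent.
* **`Xh` is kept by default.** Rewriting a parent's child to a sibling is
  only correct if that child is not the OC themselves, which the code
  string cannot decide (the OC's own birth order is not recorded). With
  `xh = "keep"` the pattern is reported as a warning carrying exactly that
  caveat; `xh = "rewrite"` applies it unconditionally, for callers who know
  the person is not the OC or who want canonical graph keys.

## Families, the kinship graph and person identity

An FDATA file is a set of named codes sharing one OC: two tab-separated
columns (code, name), `#` comments and blank lines ignored. The extended
TSV adds `nickname`, `birthdate`, `biography` columns behind a header. The
OC's own sex and birth order — which no code can express — may be stored
in an `# @oc sex=... order=...` comment directive; everything else about a
person is carried by the code itself.

`buildKinshipGraph()` turns a family into person nodes and typed edges.
Every prefix of every record denotes a person, and prefixes are unified by
canonical code equality with a wildcard rule for orders: a position with a
non-concrete order merges into a compatible fully concrete one when
exactly one such candidate exists (`*P` unifies with a lone `*P3`). Three
boundary decisions close genuinely open corners: a record never merges
into another record (records are distinct by construction); a wildcard
never merges into another wildcard (`*P` and `*P?` may or may not be one
person — they stay apart, with a diagnostic); and the consistency check
errors only on layer-*incompatible* same-role parents (`*P1` vs `*P2` is a
contradiction, `*P` vs `*P?` merely an ambiguity).

Edges come from the layers plus closure rules a human reader applies
without thinking: siblings share their known parents and sibling-hood is
transitive within a sibship; children of one parent are siblings; the two
co-parents of a child form a couple; a parent's spouse is also a parent.
Father/mother slots are assigned by sex where known; when both parents'
sexes are unrecorded (typically the OC and a `C`-coded spouse), the slots
are filled deterministically in sorted-code order, father first — a
reporting convention, not an inference.

## Re-rooting

`rebaseFamily()` re-encodes every person relative to a new OC. Codes are
assigned in breadth-first order, each person's code extending the code of
the person they are reached through (parent edges become `P`/`M`/`X` by
known sex, child edges `o`/`a`/`h`, sibling edges `O`/`A`/`H`, spouse
edges `C`; mandatory numbers fall back to `?`), then normalized. When two
distinct persons would receive the same string — two co-parents of
unrecorded sex both encode as `*X` — the later one is re-routed through an
already-encoded neighbor, e.g. via the spouse edge to `*XC`, which
normalizes to the distinct `*X?`; retry passes handle chains of such
collisions. Re-rooting is therefore total on connected families (and every
family sharing an OC is connected through it), but it is *lossy by
design*: the format cannot record the original OC's sex or birth order, so
codes through it use unsexed symbols and `?` orders unless OC metadata is
present. Re-rooting away and back recovers every person up to exactly that
loss.

## The inbreeding estimate

For two codes sharing an OC, the common ancestor is the last position of
matching layers — symbols equal, orders equal or at least one of them
unrecorded — provided no spousehood layer occurs among the unmatched
layers (marrying in creates no blood relation). The unmatched suffixes are
the divergent sections, and with their depths `dsA`, `dsB` the estimate is

$$F = \left(\tfrac{1}{2}\right)^{ds_A + ds_B}.$$

```{r}
commonAncestor("*P3", "*PMO1a1")
```

Both codes are normalized before comparison, so equivalent spellings give
identical results; a consequence worth knowing is that `*Co1` (a
partner's child) first rewrites to `*o1` and *does* share ancestry with
`*P`. Two deliberate simplifications relative to the classical Wright
path-counting coefficient: the exponent carries no `+1` term, and no
summation over multiple common ancestors is attempted — a pair of isolated
codes exposes a single shared prefix, so the estimate uses exactly that
path. `inbreedingCoefficient()` is total: it returns `0` when there is no
common ancestor (the flag lives on the `commonAncestor()` result), so
pairwise matrices need no exception handling.

## The random generator

`randomFcode()` draws codes by walking the *allowed*-adjacency automaton —
the complement of the eight redundant patterns — and only then assigning
sexes and numbers, so every draw is strict-valid and a normalization
fixpoint by construction, rather than by rejection sampling.
`randomFamily()` grows a family from the OC one relative at a time under
per-person bookkeeping: sibling birth orders distinct within a sibship, at
most one father, one mother and one spouse per person. A single integer
seed drives everything through a private RNG scope (the caller's
`.Random.seed` is untouched), and equal seeds give byte-identical FDATA
output.

Defaults describe a small interview-scale family: 12 people within 4
relationship steps of the reference person, sibships of up to 4 children,
spouse and sibling extensions half as likely as parent/child ones. These
are the package's own choices — no distributional targets exist for this
kind of data — and they are documented rather than tuned. What the
generator deliberately does *not* emulate: age structure and mortality,
remarriage and step-relations, multi-OC files, name collisions with real
persons (names come from a bundled invented word list). Tests passing on
generated families therefore certify the algebra of the encoding, not
demographic realism.

## Exporters and numerical corners

`toDot()` (Graphviz source; couples meet at point-shaped junctions,
children descend from them), `toHtmlReport()` (one anchor-identified entry
per record; relationships link to entries, implied non-record persons stay
plain text) and `toPed()` (6-column LINKAGE/PED; parents referenced get
lines of their own, unknown ids are `0`, sexes `1`/`2`/`0`) are pure
functions of the family, with sorted-key node ordering so output is
byte-identical across runs. PDF rendering is delegated to an external
`dot` call by the user, keeping the package dependency-light.

Degenerate inputs are first-class: the one-record family `*`, empty
families (valid empty report), codes of depth 0, `?` wherever a mandatory
number is unrecorded. Ties are always broken lexicographically on
canonical codes. The test suite exercises the invariants at scale —
10,000 seeded codes through the normalizer and 1,000 seeded families of 8
through the full file/graph/re-rooting/inbreeding pipeline — sizes chosen
to probe every automaton transition and closure rule many times over.

## Known limitations

Sex is attached to symbols, so a person reached only through unsexed
paths exports to PED with sex `0`; two records that differ only in
non-concrete orders (`*P` vs `*P?`) are reported as ambiguity, never
silently merged; step- and adoptive relations are outside the model (the
`Ch` repair equates a partner's child with one's own child, as the
encoding prescribes); and the inbreeding value is the printed
divergent-section estimate, not a full pedigree-loop coefficient.
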
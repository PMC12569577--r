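# fcodetools

Kinship data in fields that work from interviews and narrative records —
psychiatry, clinical genetics intake, sociology, historical demography —
rarely arrives as a tidy pedigree. People are mentioned out of order, some
relatives are only "a brother of the mother", and classical genealogical
numbering systems (Ahnentafel, Register) need the whole dataset organized
before anything can be encoded, while computational pedigree formats
(LINKAGE/PED) are not meant to be written by hand during an interview.

`fcodetools` implements a path-based kinship notation that bridges the
two. Every person is a short string — an *Fcode* — read from a reference
person, the origin of coordinates `*`: one letter per relationship step
(`P`/`M` father/mother, `O`/`A` brother/sister, `o`/`a` son/daughter, `C`
spouse; `X`/`H`/`h` when sex is unknown), with birth-order numbers where
relevant, `?` where a number exists but is unrecorded. `*MM4` is the
maternal grandmother, fourth among her siblings. Codes can be written one
at a time, in any order, and carry their meaning alone.

The package provides, around that notation:

* a validating **parser/renderer** (strict and lenient numbering modes)
  and the structural operations: depth, position, lineage, type;
* a **normalizer** that repairs the eight redundant path patterns
  (`*a1M3` → `*C3`, `*PC1o2` → `*Po2`, ...) so every code uses the
  shortest path;
* **family files**: the two-column tab-separated FDATA format and an
  extended TSV, with round-trip guarantees and line-numbered diagnostics;
* a **kinship graph** with person-identity unification, relationship
  queries, substring/regex search, and re-rooting of a whole family at a
  new reference person;
* the **inbreeding estimate** from a pair of codes: with divergent-section
  depths `dsA` and `dsB` below the last matching position (valid when no
  spouse layer occurs among the unmatched layers),

  F = (1/2)^(dsA + dsB);

* a seeded **random generator** of valid codes and consistent families;
* exporters to **Graphviz DOT**, a linked **HTML report**, and
  **LINKAGE/PED**; plus a command-line interface over all of it.

## Worked example

The family file bundled with the package (`inst/extdata/simpsons.fdata`)
is plain text — `#` comments, then `code<TAB>name` lines:

```r
library(fcodetools)
fam <- readFdata(system.file("extdata", "simpsons.fdata", package = "fcodetools"))
fam
#> Family with 7 records (OC: Homer Simpson)
#>   *    Homer Simpson
#>   *C   Marge Simpson
#>   *o1  Bart Simpson
#>   *a2  Lisa Simpson
#>   *a3  Maggie Simpson
#>   *P   Abe Simpson
#>   *M   Mona Simpson
```

Relationship queries work through the kinship graph, which also infers
what the codes only imply (Lisa's siblings are never written down; they
follow from the shared parents):

```r
directRelationships(fam, "*a2")$siblings
#>   fcode           name
#> 1   *a3 Maggie Simpson
#> 2   *o1   Bart Simpson
```

Normalization shortens redundant paths — the father's partner's second
son is simply the father's second son:

```r
renderFcode(normalizeFcode("*PC1o2"))
#> [1] "*Po2"
```

Re-rooting rewrites every code relative to a new reference person:

```r
rb <- rebaseFamily(fam, "*C")   # Marge becomes the origin
paste(familyKeys(rb), familyRecords(rb)$name)
#> [1] "*C Homer Simpson"   "* Marge Simpson"    "*o1 Bart Simpson"
#> [4] "*a2 Lisa Simpson"   "*a3 Maggie Simpson" "*CP Abe Simpson"
#> [7] "*CM Mona Simpson"
```

And two codes alone suffice for the inbreeding estimate. `*P3` (the
father) and `*PMO1a1` (the father's mother's brother's daughter) diverge
below `*P3` by 0 and 3 layers:

```r
commonAncestor("*P3", "*PMO1a1")
#> Common ancestor: *P3
#> Divergent sections: ("", "MO1a1"), depths (0, 3)
#> F = 0.125
```

`F = (1/2)^(3+0) = 0.125`, the familiar first-cousin value.

The same operations are available from a shell (quote the `*`):

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "fcode.R", package = "fcodetools"))') \
    inbreeding "*P3" "*PMO1a1"
```

## Vignette

`vignettes/kinship-encoding.Rmd` documents the encoding model, the
normalization rules and their ordering, person identity in the kinship
graph, what re-rooting can and cannot preserve, the inbreeding estimate's
relation to classical path counting, and the random generator's scope.
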
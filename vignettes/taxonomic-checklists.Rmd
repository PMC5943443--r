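---
title: "Managing taxonomic checklists as linked tables"
author: "taxotables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Managing taxonomic checklists as linked tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxotables)
```

## The problem

Floristic checklists — the species lists behind vegetation-plot databases —
are usually kept as flat tables in which a name *is* the taxon. That
representation cannot say that *Papyrus antiquorum* Willd. and *Cyperus
papyrus* L. denote the same plant, nor that two databases using the same
name mean different circumscriptions. When names are overwritten during
"standardisation", the link back to the original record is lost for good.

`taxotables` instead separates four things that flat tables conflate:

* a **taxon usage name** — any application of a name string plus authority,
  accepted or synonym (`taxonNames` table);
* a **taxon concept** — the circumscribed taxon itself, carrying exactly one
  accepted name, optionally a rank, a parent concept and a taxon view
  (`taxonConcepts` table);
* a **taxon view** — the bibliographic reference that fixes the
  circumscription (`taxonViews` table);
* **taxon traits** — attributes of concepts, not of names
  (`taxonTraits` table; it may cover only a subset of concepts).

A `TaxonList` S4 object holds the four tables plus a **rank ladder**, the
user-defined ordered sequence of taxonomic levels (lowest first, e.g.
`species < genus < family`) against which parent–child relations are
checked. Hierarchy is optional: unranked concepts are legal and exempt from
rank-order checking, but never from referential checks.

## The validity model

"Valid" has one meaning in this package: `validateChecklist()` returns zero
rows. The engine is a closed set of ten rules — duplicated usage ids (V1),
duplicated concept ids (V2), duplicated combinations, i.e. same name with
the same author after whitespace normalization (V3), names orphaned of
their concept (V4), orphaned trait records (V5), broken accepted-name
pointers (V6), missing parents (V7), ranks off the ladder (V8), a child not
strictly lower than its ranked parent (V9), and dangling view references
(V10). The report is deterministically ordered (rule, then first offending
id) so it diffs cleanly under version control.

Two deliberate design points:

* The S4 `validObject()` check enforces only *structural* sanity (columns
  and types), so broken lists can exist as objects. Direct slot
  manipulation is allowed; audit with `validateChecklist()` and repair with
  `cleanChecklist()`.
* V9 uses *strict* ladder positions ("at least one level lower"), so equal
  parent/child ranks violate; a ranked child under an unranked parent is
  permitted — the both-ranked case is the only one the ordering rule can
  decide, and cycles among unranked concepts are caught by an explicit
  cycle check in `addParent()` instead.

`cleanChecklist()` repairs, to a fixed point, exactly the violations that
need no editorial judgement: orphaned names and trait records are dropped,
dangling parent and view pointers nulled, nameless concepts removed. One
repair goes beyond pure removal: a concept that still has names but a
broken accepted-name pointer gets it re-pointed at its lowest usage id,
because removal would cascade into discarding intact names; the lowest id
is the oldest surviving name under the never-reuse id policy. Duplicated
combinations (V3) and rank-order breaches (V8/V9) are *reported, never
auto-resolved*: choosing which duplicate to keep is an editorial act.

## Editing under safety restrictions

All editing functions (`addConcept()`, `addSynonym()`, `setAcceptedName()`,
`changeConcept()`, `addParent()`, `addLevel()`, `setTraits()`, `addView()`,
`setView()`) take a valid list and return a valid list; preconditions are
checked before anything is touched, and because R passes objects by value a
rejected edit leaves the caller's object bit-identical. The restrictions
mirror curatorial practice: only synonyms may move between concepts, and a
new accepted name must already be a synonym of its concept — so every name
keeps its identity (id, string, authority) for its whole life.
Two smaller choices: promoting the *current* accepted name is an error
rather than a no-op (it almost always signals caller confusion), and new
ids are always `max(existing) + 1`, never reused, so callers can compute
the ids an edit will assign.

```{r}
x <- easplistMini()
x <- addConcept(x, data.frame(full_name = "Cyperus dives",
                              author = "Delile"),
                rank = "species", parentID = 54)
x <- setTraits(x, 206, list(life_form = "reed_plant"))
printConceptSummary(x, 206)
```

## Querying

`subsetTaxa()` replaces free-form host-language expressions with a
structured query — table, column, operator, value — which trades power for
portability (it works identically from the command line) and testability.
Conjunction is composition of calls. `contains` is case-insensitive
substring matching (mirroring interactive lookup); `equals` is exact and
case-sensitive. `keepParents` pulls *all* transitive ancestors, not just
direct parents, so extracting a species brings its full lineage up to the
family; `keepChildren` symmetrical for descendants. The output always
contains every name, trait record and referenced view of the retained
concepts, the full rank ladder, and has parent pointers that leave the
retained set nulled — so subsetting can never produce an invalid object.

```{r}
lineage <- subsetTaxa(x, "names", "full_name", "contains", "papyrus",
                      keepParents = TRUE)
lineage
```

## Import, persistence, backups

* `flatToTaxonList()` ingests one-row-per-name synonymy tables (or a bare
  vector of accepted names). Errors are collected with row numbers. Extra
  columns become trait variables, read from the accepted row of each
  concept. A `rank` column requires the ladder to be passed explicitly —
  rank *order* is user knowledge the data cannot carry.
* `readTurboveg()` reads the Turboveg species-list dialect (DBF): one flat
  `species` table whose `VALID_NR` points from synonym to accepted row,
  plus an optional `ecodbase` attribute table keyed by the accepted name's
  number. When the synonym flag and `VALID_NR` disagree, `VALID_NR` wins —
  it is the pointer that carries structure — and the conflict is reported.
  Dangling pointers are dropped with a warning (or fatal with
  `strict = TRUE`). Views and hierarchy do not exist in this dialect, so
  none are invented. The default column map
  (`SPECIES_NR`/`ABBREVIAT`/`AUTHOR`/`SYNONYM`/`VALID_NR`) is overridable
  because installations vary, and the encoding is an explicit argument
  (default latin-1) since DBF headers are unreliable. The DBF layer itself
  (`readDBF()`/`writeDBF()`) is implemented in-package — a deliberately
  minimal dBase III subset, C/N/L fields only.
* `writeArchive()`/`readArchive()` persist a list as a zip of four CSV
  tables plus a JSON metadata member (rank ladder, per-column classes,
  format version). Round trips are exact at the value level. To make them
  exact at the *byte* level too (identical inputs give identical files),
  member timestamps inside the zip are pinned to a fixed epoch. One
  normalization follows from CSV: the model never stores the empty string —
  it is converted to `NA` at construction, and an "empty authority" is
  `NA`.
* `backupChecklist()`/`loadLast()` write date-stamped archives
  (`base_YYYY-MM-DD.zip`, then `_1`, `_2`, … within a day) and restore the
  newest, selected purely by filename parsing — modification times are
  ignored for portability across file systems.

## The synthetic-data generator

`generateFixture()` states a small but structurally complete world: a
three-level hierarchy (families → genera → species), synonyms drawn per
species as a Bernoulli event, one trait variable with a handful of states,
and one taxon view. The defaults — 2 families, 4 genera, 20 species,
synonym rate 0.3, a three-state `life_form` trait, 1 view — are the
desk-scale example conditions used across the test-suite; trait coverage
defaults to 0.7 because real trait tables cover only part of a checklist,
and about 15 % of concepts are left without a view for the same reason.
Names are built from syllable tables: pronounceable, provably unique (words
are drawn without replacement from a 66³ space) and plainly synthetic —
no generated list can be mistaken for authoritative taxonomy. Identical
seeds give identical lists down to the archive bytes; the caller's RNG
state is restored afterwards.

What the generator does *not* emulate: homonyms (same combination under
different authors), infraspecific ranks, rank gaps (species attached
directly to families), non-Latin-1 name strings, and real authority
abbreviation practice. A green property over generated fixtures therefore
establishes referential and hierarchical correctness, not robustness to
every nomenclatural oddity in wild data.

The hand-coded `easplistMini()` complements it: a fixed three-concept
lineage (Cyperaceae → *Cyperus* → *C. papyrus* L., concept id 206, one
synonym, one view) used as the worked example; the species id is fixed at
206 and the surrounding ids are arbitrary. It ships without trait records —
inserting the papyrus life form is part of the worked example itself.

## Numerical and interface choices

* Combination uniqueness normalizes whitespace only; comparison stays
  case-sensitive because letter case is meaningful in botanical names.
  Authority strings are compared verbatim (`"L."` ≠ `"Linnaeus"`) —
  authority canonicalization is out of scope.
* Whether `summary()`'s trait figure counts variables or covered concepts
  is ambiguous in common usage; `checklistStats()` counts *variables*
  (columns), documented on the function.
* `addLevel()` positions are 1-based (position of the new label in the
  resulting ladder), matching R indexing.
* Integer queries in `conceptSummary()` are exact id lookups; text queries
  are substring scans over accepted names *and* synonyms. The empty result
  is a legitimate answer, distinct from a malformed-query error.
* The CLI exposes read-only and constructive operations (`validate`,
  `summary`, `subset`, `convert`, `backup`, `restore`, `fixtures`) but no
  destructive edits; those belong in scripts where they can be reviewed.
  Exit codes: 0 success, 1 validation failure, 2 usage error.

## Known limitations

No nomenclatural parsing (genus/epithet/rank are not extracted from name
strings), no fuzzy duplicate detection, no merging or splitting of
concepts, no regex queries, no writing of Turboveg DBFs, and no live
database connection — the relational schema lives in memory and in the
archive format only.
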
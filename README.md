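# taxotables

Relational management of taxonomic checklists in R.

Floristic checklists — the species lists behind vegetation-plot databases —
are commonly stored as flat tables in which a name *is* the taxon. That
loses exactly the information curation needs: that several names (one
accepted, the rest synonyms) can denote the same **taxon concept**, that a
concept's circumscription is fixed by a bibliographic reference (its
**taxon view**), and that concepts sit in a parent–child hierarchy over
user-defined ranks. `taxotables` models a checklist as an S4 `TaxonList`
holding four linked tables —

```
taxonNames     usage_id • concept_id • full_name • author
taxonConcepts  concept_id • accepted_name_id • parent_id • rank • view_id
taxonViews     view_id • author • year • title • …
taxonTraits    concept_id • one column per trait variable
```

— plus a rank ladder (e.g. `species < genus < family`). On top of the model
it provides:

* an exhaustive **validity-rule engine** (`validateChecklist()`: duplicated
  ids and combinations, orphaned entries, broken accepted-name pointers,
  rank-order breaches, …) and `cleanChecklist()` to repair every violation
  that needs no editorial decision;
* **safe editing** (`addConcept()`, `addSynonym()`, `setAcceptedName()`,
  `changeConcept()`, `addParent()`, `addLevel()`, `setTraits()`,
  `addView()`, `setView()`) — valid in, valid out, with curatorial
  restrictions such as "only synonyms may move between concepts";
* **hierarchy-aware querying** (`subsetTaxa()` with `keepChildren` /
  `keepParents`, `getParents()`, `getChildren()`, `acceptedName()`,
  `synonyms()`, `conceptSummary()`);
* **import** of flat synonymy tables (`flatToTaxonList()`) and of
  Turboveg-dialect species lists in DBF form (`readTurboveg()`, with an
  in-package dBase III reader/writer);
* **persistence**: a zip-of-CSV archive format (`writeArchive()` /
  `readArchive()`) and date-stamped backups (`backupChecklist()` /
  `loadLast()`);
* a seeded **synthetic-checklist generator** (`generateFixture()`) and a
  worked mini example (`easplistMini()`);
* a thin **command line** (`inst/exec/taxotables`, or `checklistCLI()`
  in-process) with `validate`, `summary`, `subset`, `convert`, `backup`,
  `restore` and `fixtures` subcommands.

## Worked example

```r
library(taxotables)

x <- easplistMini()                 # Cyperaceae -> Cyperus -> C. papyrus (id 206)
x <- setTraits(x, 206, list(life_form = "reed_plant"))
printConceptSummary(x, 206)
#> concept 206
#>   accepted name: Cyperus papyrus L. 
#>   taxon view: Sedgwick T. (2010) Annotated checklist of East African sedges (synthetic) 
#>   synonyms: Papyrus antiquorum Willd. 
#>   rank: species 
#>   parent: Cyperus L. 

lineage <- subsetTaxa(x, "names", "full_name", "contains", "papyrus",
                      keepParents = TRUE)
lineage
#> TaxonList object
#>   taxon usage names: 4
#>   taxon concepts:    3
#>   trait variables:   1
#>   taxon views:       1
#>   parent-child relationships: yes
#>   rank ladder (lowest first): species < genus < family
```

The subset seeds on every usage name containing "papyrus" (the synonym
*Papyrus antiquorum* matches too), maps matches to their concepts, and
`keepParents` pulls the full lineage — species, genus and family, three
concepts — while keeping the result a valid checklist.

```r
nrow(validateChecklist(lineage))
#> [1] 0
```

## Acceptance script

`scripts/acceptance.R` exercises the package end to end from a clean
session: the worked lineage extraction above, seeded synthetic-checklist
generation and validation, an archive write/read round trip, a timestamped
backup and restore, and a Turboveg-dialect write/read round trip. Run it
from the repository root against the installed package:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
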
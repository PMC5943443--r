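# Structured subsetting with hierarchy expansion, and the navigation
# primitives underneath it.

test_that("substring subset with keepParents retrieves the full lineage", {
  x <- easplistMini()
  out <- subsetTaxa(x, "names", "full_name", "contains", "papyrus",
                    keepParents = TRUE)
  expect_identical(checklistStats(out)$n_concepts, 3L)
  expect_setequal(taxonConcepts(out)$concept_id, c(1L, 54L, 206L))
  expect_identical(nrow(validateChecklist(out)), 0L)
  # all names of retained concepts come along, synonym included
  expect_true("Papyrus antiquorum" %in% taxonNames(out)$full_name)
  # without the flag only the seed concept remains, parent pointer nulled
  seedOnly <- subsetTaxa(x, "names", "full_name", "contains", "papyrus")
  expect_identical(checklistStats(seedOnly)$n_concepts, 1L)
  expect_true(is.na(taxonConcepts(seedOnly)$parent_id))
  expect_identical(nrow(validateChecklist(seedOnly)), 0L)
})

test_that("a query matching nothing yields an empty but valid list", {
  out <- subsetTaxa(easplistMini(), "names", "full_name", "contains",
                    "zzzznothing", keepChildren = TRUE, keepParents = TRUE)
  expect_identical(checklistStats(out)$n_concepts, 0L)
  expect_identical(nrow(validateChecklist(out)), 0L)
  expect_identical(taxonRanks(out), taxonRanks(easplistMini()))
})

test_that("queries can target the concepts and traits tables", {
  x <- setTraits(easplistMini(), 206, list(life_form = "reed_plant"))
  byTrait <- subsetTaxa(x, "traits", "life_form", "equals", "reed_plant")
  expect_identical(taxonConcepts(byTrait)$concept_id, 206L)
  byRank <- subsetTaxa(x, "concepts", "rank", "in_set",
                       c("genus", "family"))
  expect_setequal(taxonConcepts(byRank)$concept_id, c(1L, 54L))
  byId <- subsetTaxa(x, "concepts", "concept_id", "less_than", 100,
                     keepChildren = TRUE)
  expect_setequal(taxonConcepts(byId)$concept_id, c(1L, 54L, 206L))
  expect_error(subsetTaxa(x, "names", "nope", "equals", 1), "no column")
  expect_error(subsetTaxa(x, "names", "full_name", "less_than", 1),
               "numeric column")
  expect_error(subsetTaxa(x, "names", "usage_id", "contains", "1"),
               "text column")
})

test_that("equals is case-sensitive, contains is not", {
  x <- easplistMini()
  expect_identical(
    checklistStats(subsetTaxa(x, "names", "full_name", "equals",
                              "cyperus papyrus"))$n_concepts, 0L)
  expect_identical(
    checklistStats(subsetTaxa(x, "names", "full_name", "contains",
                              "CYPERUS PAP"))$n_concepts, 1L)
})

test_that("expansion equals brute-force reachability and is monotone", {
  withr::with_seed(31, {
    for (seed in 1:4) {
      g <- generateFixture(nFamilies = 2, nGenera = 5, nSpecies = 15,
                           seed = seed)
      nm <- taxonNames(g)
      pats <- unique(unlist(lapply(nm$full_name, function(s) {
        substring(s, 1:(nchar(s) - 3), 4:nchar(s))
      })))
      pats <- resample(pats, min(40L, length(pats)))
      for (p in pats) {
        seedSet <- sort(taxonConcepts(
          subsetTaxa(g, "names", "full_name", "contains", p))$concept_id)
        down <- sort(taxonConcepts(
          subsetTaxa(g, "names", "full_name", "contains", p,
                     keepChildren = TRUE))$concept_id)
        both <- sort(taxonConcepts(
          subsetTaxa(g, "names", "full_name", "contains", p,
                     keepChildren = TRUE, keepParents = TRUE))$concept_id)
        expect_identical(seedSet, oracleSubsetConcepts(g, p, FALSE, FALSE))
        expect_identical(down, oracleSubsetConcepts(g, p, TRUE, FALSE))
        expect_identical(both, oracleSubsetConcepts(g, p, TRUE, TRUE))
        # monotone: seed set within every flagged variant
        expect_true(all(seedSet %in% down))
        expect_true(all(down %in% both))
      }
    }
  })
})

test_that("subset output is always valid and idempotent for name queries", {
  withr::with_seed(17, {
    g <- generateFixture(seed = 8)
    for (p in c("a", "lu", "xa", "zz")) {
      for (kc in c(FALSE, TRUE)) for (kp in c(FALSE, TRUE)) {
        out <- subsetTaxa(g, "names", "full_name", "contains", p,
                          keepChildren = kc, keepParents = kp)
        expect_identical(nrow(validateChecklist(out)), 0L)
        again <- subsetTaxa(out, "names", "full_name", "contains", p,
                            keepChildren = kc, keepParents = kp)
        expect_true(tablesIdentical(again, out))
      }
    }
  })
})

test_that("parent and child traversal follow the fixture pointers", {
  x <- easplistMini()
  expect_identical(getParents(x, 206), c(54L, 1L))
  expect_identical(getParents(x, 1), integer())
  expect_identical(getChildren(x, 1), 54L)
  expect_identical(getChildren(x, 1, recursive = TRUE),
                   sort(c(54L, 206L)))
  expect_identical(getChildren(x, 206), integer())
  expect_error(getParents(x, 999), "unknown concept")
  expect_error(getChildren(x, 999), "unknown concept")
})

test_that("acceptedName and synonyms partition a concept's names", {
  x <- easplistMini()
  expect_identical(acceptedName(x, 206)$full_name, "Cyperus papyrus")
  expect_identical(acceptedName(x, 206)$author, "L.")
  expect_identical(nrow(synonyms(x, 1)), 0L)
  g <- generateFixture(seed = 5)
  for (cid in taxonConcepts(g)$concept_id) {
    expect_identical(nrow(synonyms(g, cid)) + 1L,
                     sum(taxonNames(g)$concept_id == cid))
  }
  expect_error(acceptedName(x, 999), "unknown concept")
})
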
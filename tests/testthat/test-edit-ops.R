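# Editing functions: every accepted edit preserves validity; every rejected
# edit throws before touching anything.

test_that("addConcept creates one concept and one accepted name per input", {
  x <- easplistMini()
  x2 <- addConcept(x, data.frame(full_name = "Cyperus dives",
                                 author = "Delile"),
                   rank = "species", parentID = 54L)
  expect_identical(checklistStats(x2)$n_concepts, 4L)
  expect_identical(checklistStats(x2)$n_names, 5L)
  expect_identical(nrow(validateChecklist(x2)), 0L)
  newId <- max(taxonConcepts(x)$concept_id) + 1L  # deterministic: 207
  expect_identical(acceptedName(x2, newId)$full_name, "Cyperus dives")
  expect_identical(getParents(x2, newId), c(54L, 1L))

  # several at once, character-vector form
  x3 <- addConcept(x, c("Abcus unus", "Abcus duo"))
  expect_identical(checklistStats(x3)$n_concepts, 5L)

  # duplicated combination is rejected, naming the clashing usage id
  expect_error(addConcept(x, data.frame(full_name = "Cyperus papyrus",
                                        author = "L.")),
               "usage_id 3")
  # rank not strictly below the parent's rank
  expect_error(addConcept(x, data.frame(full_name = "Cyperus novus",
                                        author = "L."),
                          rank = "species", parentID = 206L),
               "rank order")
  # unknown rank / parent / view
  expect_error(addConcept(x, "Novus totus", rank = "tribe"), "unknown rank")
  expect_error(addConcept(x, "Novus totus", parentID = 888L),
               "unknown parent")
  expect_error(addConcept(x, "Novus totus", viewID = 888L), "unknown view")
})

test_that("addSynonym links a new name without touching the accepted one", {
  x <- easplistMini()
  before <- acceptedName(x, 206)
  x2 <- addSynonym(x, 206, "Papyrus domesticus", "Kunth")
  expect_identical(nrow(synonyms(x2, 206)), 2L)
  expect_identical(acceptedName(x2, 206), before)
  expect_identical(nrow(validateChecklist(x2)), 0L)
  # the same synonym twice is a duplicate combination
  expect_error(addSynonym(x2, 206, "Papyrus domesticus", "Kunth"),
               "duplicated combination")
  expect_error(addSynonym(x, 999L, "Nope nope"), "unknown concept")
})

test_that("setAcceptedName swaps roles and is an involution", {
  x <- easplistMini()  # concept 206: accepted usage 3, synonym usage 4
  x2 <- setAcceptedName(x, 206, 4L)
  expect_identical(acceptedName(x2, 206)$full_name, "Papyrus antiquorum")
  # the former accepted name is now listed among the synonyms
  expect_identical(synonyms(x2, 206)$full_name, "Cyperus papyrus")
  expect_identical(conceptSummary(x2, 206)[[1]]$synonyms$full_name,
                   "Cyperus papyrus")
  # name rows were neither created nor deleted
  expect_identical(checklistStats(x2)$n_names, checklistStats(x)$n_names)
  # double swap restores the original state
  expect_true(tablesIdentical(setAcceptedName(x2, 206, 3L), x))

  # a name of a different concept is rejected with guidance
  expect_error(setAcceptedName(x, 206, 2L), "changeConcept")
  # re-accepting the current accepted name surfaces a caller mistake
  expect_error(setAcceptedName(x, 206, 3L), "already the accepted name")
})

test_that("changeConcept moves synonyms and preserves name identity", {
  x <- addSynonym(easplistMini(), 206, "Cyperus falsus", "Steud.")
  uid <- synonyms(x, 206)$usage_id[synonyms(x, 206)$full_name ==
                                     "Cyperus falsus"]
  x2 <- changeConcept(x, uid, 54L)
  expect_false("Cyperus falsus" %in% synonyms(x2, 206)$full_name)
  expect_true("Cyperus falsus" %in% synonyms(x2, 54)$full_name)
  expect_identical(checklistStats(x2)$n_names, checklistStats(x)$n_names)
  moved <- taxonNames(x2)[taxonNames(x2)$usage_id == uid, ]
  expect_identical(moved$full_name, "Cyperus falsus")
  expect_identical(moved$author, "Steud.")
  expect_identical(nrow(validateChecklist(x2)), 0L)

  # accepted names must not move
  expect_error(changeConcept(x, 3L, 54L), "only allowed for synonyms")
  expect_error(changeConcept(x, uid, 999L), "unknown target")
})

test_that("addParent wires hierarchies and refuses cycles and inversions", {
  x <- easplistMini()
  y <- addConcept(x, "Cyperus solitarius", rank = "species")
  newId <- max(taxonConcepts(x)$concept_id) + 1L
  expect_identical(getParents(y, newId), integer())
  y2 <- addParent(y, newId, 54L)
  expect_identical(getParents(y2, newId), c(54L, 1L))

  expect_error(addParent(x, 54L, 54L), "cycle")
  expect_error(addParent(x, 1L, 206L), "cycle")   # family under its grandchild
  # genus under an unrelated species: pure rank-order breach, no cycle
  z <- addConcept(x, "Lonelius species", rank = "species")
  expect_error(addParent(z, 54L, newId), "rank order")
  expect_error(addParent(x, 206L, 999L), "unknown concept")

  # unranked concepts can only be caught by the explicit cycle check
  a <- addConcept(TaxonList(), c("Unranked alpha", "Unranked beta"))
  a <- addParent(a, 1L, 2L)
  expect_error(addParent(a, 2L, 1L), "cycle")
})

test_that("addLevel inserts without disturbing existing pairs", {
  x <- easplistMini()
  x2 <- addLevel(x, "subspecies", 1L)
  expect_identical(taxonRanks(x2),
                   c("subspecies", "species", "genus", "family"))
  expect_identical(nrow(validateChecklist(x2)), 0L)
  x3 <- addLevel(x, "tribe", 3L)  # between genus and family
  expect_identical(taxonRanks(x3), c("species", "genus", "tribe", "family"))
  expect_identical(nrow(validateChecklist(x3)), 0L)
  expect_error(addLevel(x, "genus", 1L), "already on the ladder")
  expect_error(addLevel(x, "form", 9L), "position")
})

test_that("traits and views upsert and stay referentially sound", {
  x <- easplistMini()
  x2 <- setTraits(x, 206, list(life_form = "reed_plant"))
  expect_identical(taxonTraits(x2)$life_form, "reed_plant")
  expect_identical(checklistStats(x2)$n_trait_variables, 1L)
  # upsert: same concept again extends the schema, no second record
  x3 <- setTraits(x2, 206, list(height_m = 4))
  expect_identical(nrow(taxonTraits(x3)), 1L)
  expect_identical(checklistStats(x3)$n_trait_variables, 2L)
  expect_error(setTraits(x, 999L, list(life_form = "herb")),
               "unknown concept")

  x4 <- addView(x, list(author = "Auth B.", year = 2021L,
                        title = "Second synthetic view"))
  newView <- max(taxonViews(x)$view_id) + 1L
  x5 <- setView(x4, c(1L, 54L, 206L), newView)
  expect_identical(unique(taxonConcepts(x5)$view_id), newView)
  expect_identical(nrow(validateChecklist(x5)), 0L)
  expect_error(setView(x, 206L, 999L), "unknown view")
})

test_that("random applicable edits always preserve validity", {
  # desk-scale version; the acceptance test runs the full 1,000-edit sweep
  withr::with_seed(2024, {
    x <- generateFixture(seed = 11)
    for (step in 1:40) {
      x <- randomEdit(x, step)$x
      expect_identical(nrow(validateChecklist(x)), 0L)
    }
    for (i in 1:20) {
      r <- rejectedEdit(x)
      expect_true(r$threw, info = r$kind)
      expect_true(r$unchanged, info = r$kind)
    }
  })
})

test_that("edits demand a valid input list", {
  broken <- easplistMini()
  broken@taxonConcepts <- taxonConcepts(broken)[-2L, , drop = FALSE]
  expect_error(addSynonym(broken, 206, "X y"), "requires a valid list")
})
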
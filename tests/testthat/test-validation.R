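# The rule engine and clean().

test_that("a valid list yields an empty, stable report", {
  x <- easplistMini()
  v <- validateChecklist(x)
  expect_identical(nrow(v), 0L)
  expect_named(v, c("rule", "ids", "message"))
  # pure function: repeated calls identical
  expect_identical(validateChecklist(x), v)
})

test_that("duplicated combinations are reported with both usage ids", {
  x <- easplistMini()
  nm <- taxonNames(x)
  x@taxonNames <- padRbind(nm, data.frame(
    usage_id = 99L, concept_id = 54L,
    full_name = "Cyperus  papyrus ",  # extra whitespace still collides
    author = "L.", stringsAsFactors = FALSE))
  v <- validateChecklist(x)
  expect_identical(v$rule, "V3_DUP_COMBINATION")
  expect_identical(v$ids[[1]], c(3L, 99L))
})

test_that("same name with a different author is not a duplicate", {
  x <- addSynonym(easplistMini(), 54, "Cyperus papyrus", "Auct.")
  expect_identical(nrow(validateChecklist(x)), 0L)
})

test_that("equal parent and child ranks violate the strict ordering", {
  x <- easplistMini()
  cp <- taxonConcepts(x)
  cp$rank[cp$concept_id == 206L] <- "genus"  # same rank as its parent
  x@taxonConcepts <- cp
  v <- validateChecklist(x)
  expect_identical(v$rule, "V9_RANK_ORDER")
  expect_identical(v$ids[[1]][1], 206L)
})

test_that("a ranked child under an unranked parent is legal", {
  x <- easplistMini()
  cp <- taxonConcepts(x)
  cp$rank[cp$concept_id == 54L] <- NA_character_
  x@taxonConcepts <- cp
  expect_identical(nrow(validateChecklist(x)), 0L)
})

test_that("each injected defect is flagged as exactly that rule", {
  # desk-scale version of the defect-injection suite (the acceptance test
  # runs the full 100-fixtures-per-rule sweep)
  withr::with_seed(101, {
    for (rule in allRules) {
      for (i in 1:10) {
        g <- generateFixture(seed = i)
        broken <- injectDefect(g, rule)
        v <- validateChecklist(broken)
        expect_identical(unique(v$rule), rule,
                         info = paste(rule, "fixture", i))
      }
    }
  })
})

test_that("violation report is deterministically ordered", {
  withr::with_seed(7, {
    g <- generateFixture(seed = 3)
    broken <- injectDefect(injectDefect(injectDefect(g, "V7_MISSING_PARENT"),
                                        "V4_ORPHANED_NAME"),
                           "V10_DANGLING_VIEW")
    v <- validateChecklist(broken)
    expect_identical(v, validateChecklist(broken))
    # rules appear in the fixed V1..V10 sequence
    codes <- c("V4_ORPHANED_NAME", "V7_MISSING_PARENT", "V10_DANGLING_VIEW")
    expect_identical(unique(v$rule), codes)
  })
})

test_that("clean() is the identity on valid lists and repairs orphans", {
  x <- easplistMini()
  expect_true(tablesIdentical(cleanChecklist(x), x))

  # delete the genus concept by hand: the species' parent pointer is nulled,
  # the genus' name row is dropped, nothing else changes
  broken <- x
  cp <- taxonConcepts(x)
  broken@taxonConcepts <- cp[cp$concept_id != 54L, , drop = FALSE]
  cleaned <- cleanChecklist(broken)
  expect_identical(nrow(validateChecklist(cleaned)), 0L)
  expect_identical(sort(taxonConcepts(cleaned)$concept_id), c(1L, 206L))
  expect_true(is.na(
    taxonConcepts(cleaned)$parent_id[
      taxonConcepts(cleaned)$concept_id == 206L]))
  expect_false("Cyperus" %in% taxonNames(cleaned)$full_name)

  # orphaned trait record is dropped, concepts untouched
  x2 <- setTraits(x, 206, list(life_form = "reed_plant"))
  tr <- taxonTraits(x2)
  tr$concept_id[1] <- 9999L
  x2@taxonTraits <- tr
  cleaned2 <- cleanChecklist(x2)
  expect_identical(nrow(taxonTraits(cleaned2)), 0L)
  expect_identical(checklistStats(cleaned2)$n_concepts, 3L)
})

test_that("clean() repairs every orphan class and is idempotent", {
  withr::with_seed(55, {
    for (rule in orphanRules) {
      for (i in 1:10) {
        g <- generateFixture(seed = 20 + i)
        cleaned <- cleanChecklist(injectDefect(g, rule))
        v <- validateChecklist(cleaned)
        expect_false(rule %in% v$rule, info = rule)
        expect_true(tablesIdentical(cleanChecklist(cleaned), cleaned),
                    info = rule)
      }
    }
  })
})

test_that("clean() refuses to resolve duplicated combinations", {
  withr::with_seed(9, {
    g <- generateFixture(seed = 4)
    broken <- injectDefect(g, "V3_DUP_COMBINATION")
    cleaned <- cleanChecklist(broken)
    expect_identical(unique(validateChecklist(cleaned)$rule),
                     "V3_DUP_COMBINATION")
  })
})
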
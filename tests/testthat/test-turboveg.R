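# Turboveg-dialect species-list import and the fixture writer.

writeSpeciesDBF <- function(df, dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE)
  p <- file.path(dir, "species.dbf")
  writeDBF(df, p)
  p
}

test_that("accepted rows become concepts, synonyms attach via valid_nr", {
  sp <- data.frame(
    SPECIES_NR = c(1L, 2L, 3L, 4L, 5L),
    ABBREVIAT = c("Aus aus", "Bus bus", "Cus cus", "Aus alter",
                  "Bus alter"),
    AUTHOR = c("L.", "Willd.", NA, "Kunth", "Steud."),
    SYNONYM = c(FALSE, FALSE, FALSE, TRUE, TRUE),
    VALID_NR = c(1L, 2L, 3L, 1L, 2L),
    stringsAsFactors = FALSE)
  x <- readTurboveg(writeSpeciesDBF(sp))
  s <- checklistStats(x)
  expect_identical(s$n_concepts, 3L)
  expect_identical(s$n_names, 5L)
  expect_identical(synonyms(x, 1)$full_name, "Aus alter")
  expect_identical(acceptedName(x, 2)$full_name, "Bus bus")
  # Turboveg cannot express views or hierarchy
  expect_identical(s$n_views, 0L)
  expect_false(s$has_parent_child)
  expect_identical(taxonRanks(x), character())
  expect_identical(nrow(validateChecklist(x)), 0L)
})

test_that("dangling valid_nr is dropped with a report, or fatal in strict mode", {
  sp <- data.frame(
    SPECIES_NR = c(1L, 2L),
    ABBREVIAT = c("Aus aus", "Ghostus ghost"),
    AUTHOR = NA_character_,
    SYNONYM = c(FALSE, TRUE),
    VALID_NR = c(1L, 77L),
    stringsAsFactors = FALSE)
  p <- writeSpeciesDBF(sp)
  expect_warning(x <- readTurboveg(p), "species_nr 2")
  expect_identical(checklistStats(x)$n_names, 1L)
  expect_error(suppressWarnings(readTurboveg(p, strict = TRUE)),
               "species_nr 2")
})

test_that("valid_nr wins over a conflicting synonym flag, with a report", {
  sp <- data.frame(
    SPECIES_NR = c(1L, 2L),
    ABBREVIAT = c("Aus aus", "Aus alter"),
    AUTHOR = NA_character_,
    SYNONYM = c(TRUE, TRUE),       # row 1 flagged synonym but self-pointing
    VALID_NR = c(1L, 1L),
    stringsAsFactors = FALSE)
  expect_message(x <- readTurboveg(writeSpeciesDBF(sp)), "species_nr 1")
  expect_identical(checklistStats(x)$n_concepts, 1L)
  expect_identical(checklistStats(x)$n_names, 2L)
})

test_that("attribute tables become trait records keyed by accepted names", {
  dir <- tempfile()
  dir.create(dir)
  sp <- data.frame(
    SPECIES_NR = c(1L, 2L, 3L),
    ABBREVIAT = c("Aus aus", "Bus bus", "Aus alter"),
    AUTHOR = NA_character_,
    SYNONYM = c(FALSE, FALSE, TRUE),
    VALID_NR = c(1L, 2L, 1L),
    stringsAsFactors = FALSE)
  eco <- data.frame(
    SPECIES_NR = c(1L, 3L),  # 3 is a synonym number: dropped with a warning
    LIFE_FORM = c("herb", "tree"),
    stringsAsFactors = FALSE)
  writeDBF(sp, file.path(dir, "species.dbf"))
  writeDBF(eco, file.path(dir, "ecodbase.dbf"))
  expect_warning(
    x <- readTurboveg(file.path(dir, "species.dbf"),
                      file.path(dir, "ecodbase.dbf")),
    "species_nr 3")
  expect_identical(checklistStats(x)$n_trait_variables, 1L)
  expect_identical(taxonTraits(x)$concept_id, 1L)
  expect_identical(taxonTraits(x)$LIFE_FORM, "herb")
})

test_that("column mapping is configurable", {
  sp <- data.frame(
    NUMMER = c(1L, 2L),
    NAAM = c("Aus aus", "Aus alter"),
    AUT = NA_character_,
    SYN = c(FALSE, TRUE),
    GELDIG = c(1L, 1L),
    stringsAsFactors = FALSE)
  x <- readTurboveg(writeSpeciesDBF(sp),
                    columnMap = list(species_nr = "NUMMER", name = "NAAM",
                                     author = "AUT", synonym_flag = "SYN",
                                     valid_nr = "GELDIG"))
  expect_identical(checklistStats(x)$n_concepts, 1L)
  expect_error(readTurboveg(writeSpeciesDBF(sp)), "lacks mapped column")
})

test_that("fixture write + read recovers the concept/name partition", {
  withr::with_seed(77, {
    g <- flattenForTurboveg(generateFixture(nFamilies = 1, nGenera = 2,
                                            nSpecies = 10, seed = 13))
    d <- tempfile()
    paths <- writeTurbovegFixture(g, d)
    back <- readTurboveg(paths[["species"]],
                         if ("ecodbase" %in% names(paths))
                           paths[["ecodbase"]])
    expect_identical(conceptPartition(back), conceptPartition(g))
    # traits carried through on the accepted-name key
    expect_identical(checklistStats(back)$n_trait_variables,
                     checklistStats(g)$n_trait_variables)
  })
})

test_that("hierarchy-bearing fixtures warn that structure is dropped", {
  g <- generateFixture(seed = 3)
  d <- tempfile()
  expect_warning(paths <- writeTurbovegFixture(g, d), "dropped")
  back <- readTurboveg(paths[["species"]])
  expect_false(checklistStats(back)$has_parent_child)
  expect_identical(conceptPartition(back),
                   conceptPartition(flattenForTurboveg(g)))
})

test_that("an empty list writes a readable empty DBF pair", {
  d <- tempfile()
  paths <- writeTurbovegFixture(TaxonList(), d)
  back <- readTurboveg(paths[["species"]])
  expect_identical(checklistStats(back)$n_concepts, 0L)
})
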
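# Built-in example data and a seeded synthetic-checklist generator, so every
# part of the package is testable without downloading anything.

#' A miniature East-African-style sedge checklist
#'
#' Hand-coded three-level example: family Cyperaceae (concept 1) → genus
#' *Cyperus* (concept 54) → species *Cyperus papyrus* L. with concept id 206
#' and one synonym (*Papyrus antiquorum* Willd.). The rank ladder is
#' `c("species", "genus", "family")` and one taxon view (a synthetic
#' checklist citation) covers all three concepts. The species id 206 is
#' fixed; the surrounding ids are arbitrary. The list carries no trait
#' records — a life form for the papyrus sedge is typically inserted with
#' `setTraits(x, 206, list(life_form = "reed_plant"))` before reporting.
#'
#' @return A valid `TaxonList` with 3 concepts and 4 usage names.
#' @examples
#' x <- easplistMini()
#' acceptedName(x, 206)
#' @export
easplistMini <- function() {
  nm <- data.frame(
    usage_id = c(1L, 2L, 3L, 4L),
    concept_id = c(1L, 54L, 206L, 206L),
    full_name = c("Cyperaceae", "Cyperus", "Cyperus papyrus",
                  "Papyrus antiquorum"),
    author = c("Juss.", "L.", "L.", "Willd."),
    stringsAsFactors = FALSE)
  cp <- data.frame(
    concept_id = c(1L, 54L, 206L),
    accepted_name_id = c(1L, 2L, 3L),
    parent_id = c(NA_integer_, 1L, 54L),
    rank = c("family", "genus", "species"),
    view_id = c(1L, 1L, 1L),
    stringsAsFactors = FALSE)
  vw <- data.frame(
    view_id = 1L,
    author = "Sedgwick T.",  # synthetic citation, not a real reference
    year = 2010L,
    title = "Annotated checklist of East African sedges (synthetic)",
    stringsAsFactors = FALSE)
  TaxonList(taxonNames = nm, taxonConcepts = cp, taxonViews = vw,
            rankLadder = c("species", "genus", "family"))
}

# Syllable inventory for pronounceable synthetic names; 66^3 three-syllable
# words keep every generated name unique and obviously non-authoritative.
nameSyllables <- c(
  "ba", "be", "bi", "bo", "bu", "ca", "ce", "ci", "co", "cu",
  "da", "de", "di", "do", "du", "fa", "fe", "fi", "fo", "fu",
  "ga", "ge", "gi", "go", "gu", "la", "le", "li", "lo", "lu",
  "ma", "me", "mi", "mo", "mu", "na", "ne", "ni", "no", "nu",
  "pa", "pe", "pi", "po", "pu", "ra", "re", "ri", "ro", "ru",
  "sa", "se", "si", "so", "su", "ta", "te", "ti", "to", "tu",
  "va", "ve", "vi", "vo", "vu", "xa")

syntheticAuthors <- c("L.", "Willd.", "Delile", "Kunth", "Steud.", "Boeckeler",
                      "(L.) Beauv.", "Vahl", "Lam.", "Roxb.")

# word for a 0-based index in base-length(nameSyllables), 3 syllables
wordFromIndex <- function(idx) {
  b <- length(nameSyllables)
  s1 <- idx %% b
  s2 <- (idx %/% b) %% b
  s3 <- idx %/% (b * b)
  paste0(nameSyllables[s3 + 1L], nameSyllables[s2 + 1L],
         nameSyllables[s1 + 1L])
}

capitalize <- function(s) {
  paste0(toupper(substr(s, 1L, 1L)), substr(s, 2L, nchar(s)))
}

#' Generate a synthetic taxonomic checklist
#'
#' Seed-deterministic generator of a valid three-level checklist (families →
#' genera → species). Names are built from syllable tables — pronounceable,
#' globally unique, and plainly synthetic. Each genus is attached to a
#' random family and each species to a random genus; per accepted species a
#' synonym is drawn with probability `synonymRate`. Trait values are sampled
#' from `traitSchema` for a subset of species concepts (coverage
#' `traitCoverage` — the traits table is allowed to cover only some
#' concepts). Each concept gets one of `viewCount` synthetic views (a few
#' are deliberately left without a view). Defaults are the desk-scale
#' example conditions used throughout the test-suite: 2 families, 4 genera,
#' 20 species, synonym rate 0.3, one life-form trait with 3 states, 1 view.
#'
#' Identical arguments (including `seed`) yield identical lists; the
#' caller's RNG state is left untouched.
#'
#' @param nFamilies,nGenera,nSpecies Level sizes (each >= 1).
#' @param synonymRate Per-species synonym probability in `[0, 1]`.
#' @param traitSchema Named list mapping trait variable -> vector of possible
#'   values; `NULL` or empty for no traits.
#' @param viewCount Number of synthetic taxon views (>= 0).
#' @param seed Integer seed.
#' @param traitCoverage Fraction of species concepts that receive a trait
#'   record.
#' @return A valid `TaxonList`.
#' @examples
#' x <- generateFixture(seed = 42)
#' nrow(validateChecklist(x))  # 0
#' @export
generateFixture <- function(nFamilies = 2L, nGenera = 4L, nSpecies = 20L,
                            synonymRate = 0.3,
                            traitSchema = list(life_form = c("reed_plant",
                                                             "herb",
                                                             "tree")),
                            viewCount = 1L, seed = 1L,
                            traitCoverage = 0.7) {
  stopifnot(nFamilies >= 1L, nGenera >= 1L, nSpecies >= 1L,
            synonymRate >= 0, synonymRate <= 1, viewCount >= 0L,
            traitCoverage >= 0, traitCoverage <= 1)
  withSeed(seed, {
    space <- length(nameSyllables)^3
    # words needed: families + genera + species epithets + synonym material
    maxWords <- nFamilies + nGenera + nSpecies + 2L * nSpecies
    if (maxWords > space) {
      stop("infeasible fixture spec: ", maxWords,
           " unique name words needed, only ", space, " generable",
           call. = FALSE)
    }
    widx <- sample.int(space, maxWords) - 1L
    words <- vapply(widx, wordFromIndex, "")
    famWords <- words[seq_len(nFamilies)]
    genWords <- words[nFamilies + seq_len(nGenera)]
    epiWords <- words[nFamilies + nGenera + seq_len(nSpecies)]
    synWords <- words[nFamilies + nGenera + nSpecies +
                        seq_len(2L * nSpecies)]

    famIds <- seq_len(nFamilies)
    genIds <- nFamilies + seq_len(nGenera)
    spIds <- nFamilies + nGenera + seq_len(nSpecies)
    genParent <- resample(famIds, nGenera, replace = TRUE)
    spParent <- resample(genIds, nSpecies, replace = TRUE)

    famNames <- paste0(capitalize(famWords), "aceae")
    genNames <- capitalize(genWords)
    spNames <- paste(genNames[spParent - nFamilies], epiWords)

    hasSyn <- stats::runif(nSpecies) < synonymRate
    nSyn <- sum(hasSyn)
    synNames <- if (nSyn) {
      paste(capitalize(synWords[seq_len(nSyn)]),
            synWords[nSyn + seq_len(nSyn)])
    } else character()

    nCore <- nFamilies + nGenera + nSpecies
    uid <- seq_len(nCore + nSyn)
    nm <- data.frame(
      usage_id = uid,
      concept_id = c(famIds, genIds, spIds, spIds[hasSyn]),
      full_name = c(famNames, genNames, spNames, synNames),
      author = resample(syntheticAuthors, nCore + nSyn, replace = TRUE),
      stringsAsFactors = FALSE)

    viewIds <- if (viewCount) seq_len(viewCount) else integer()
    conceptView <- if (viewCount) {
      v <- resample(viewIds, nCore, replace = TRUE)
      v[stats::runif(nCore) < 0.15] <- NA_integer_  # some concepts unviewed
      v
    } else rep(NA_integer_, nCore)
    cp <- data.frame(
      concept_id = c(famIds, genIds, spIds),
      accepted_name_id = seq_len(nCore),
      parent_id = c(rep(NA_integer_, nFamilies), genParent, spParent),
      rank = rep(c("family", "genus", "species"),
                 c(nFamilies, nGenera, nSpecies)),
      view_id = as.integer(conceptView),
      stringsAsFactors = FALSE)

    vw <- if (viewCount) {
      data.frame(view_id = viewIds,
                 author = paste0("Author ", LETTERS[(viewIds - 1L) %% 26L + 1L],
                                 "."),
                 year = 1990L + viewIds,
                 title = paste("Synthetic regional checklist no.", viewIds),
                 stringsAsFactors = FALSE)
    } else emptyTaxonViews()

    tr <- emptyTaxonTraits()
    if (length(traitSchema)) {
      covered <- spIds[stats::runif(nSpecies) < traitCoverage]
      if (length(covered)) {
        tr <- data.frame(concept_id = covered, stringsAsFactors = FALSE)
        for (v in names(traitSchema)) {
          tr[[v]] <- resample(traitSchema[[v]], length(covered),
                              replace = TRUE)
        }
      }
    }

    TaxonList(taxonNames = nm, taxonConcepts = cp, taxonViews = vw,
              taxonTraits = tr,
              rankLadder = c("species", "genus", "family"))
  })
}
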
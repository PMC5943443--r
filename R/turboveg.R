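# Turboveg keeps a species list as one flat DBF table ("species"): names and
# their accepted/synonym structure in a single table, an accepted name being
# a row whose valid_nr points at itself, a synonym a row whose valid_nr
# points at its accepted row. Taxon attributes live in a companion table
# ("ecodbase") keyed by the accepted name's species number. Taxon views and
# hierarchies are not represented in Turboveg at all, so an import carries
# names, concepts and traits only.

defaultTurbovegMap <- function() {
  list(species_nr = "SPECIES_NR", name = "ABBREVIAT", author = "AUTHOR",
       synonym_flag = "SYNONYM", valid_nr = "VALID_NR")
}

#' Import a Turboveg-dialect species list
#'
#' Reads the species DBF (and optionally the attribute/"ecodbase" DBF) and
#' assembles a valid `TaxonList`:
#'
#' * a row is *accepted* when its `valid_nr` equals its own `species_nr`;
#'   when `valid_nr` is missing the `synonym_flag` decides. When both are
#'   present and disagree, `valid_nr` wins (it is the pointer that carries
#'   the structure) and the conflict is reported via `message()`.
#' * accepted rows become concepts (`concept_id` = `species_nr`); synonyms
#'   attach to the concept of their `valid_nr`.
#' * attribute rows become trait records, keyed by the species number of the
#'   accepted name; rows keyed to unknown or synonym numbers are dropped with
#'   a warning.
#' * synonyms whose `valid_nr` resolves to no accepted row are dropped with a
#'   warning listing their species numbers (default), or abort the import
#'   when `strict = TRUE`.
#' * no taxon views and no hierarchy are created; the rank ladder is empty.
#'
#' @param speciesPath Path to the species `.dbf`.
#' @param attributePath Optional path to the attribute `.dbf`; its
#'   `species_nr` column (same mapped name) keys records, all other columns
#'   become trait variables.
#' @param columnMap Named list overriding the default Turboveg column names
#'   (`species_nr = "SPECIES_NR"`, `name = "ABBREVIAT"`,
#'   `author = "AUTHOR"`, `synonym_flag = "SYNONYM"`,
#'   `valid_nr = "VALID_NR"`) — installations vary.
#' @param encoding DBF text encoding (default `"latin1"`).
#' @param strict Fail instead of dropping rows with dangling `valid_nr`.
#' @return A valid `TaxonList`.
#' @export
readTurboveg <- function(speciesPath, attributePath = NULL,
                         columnMap = list(), encoding = "latin1",
                         strict = FALSE) {
  map <- utils::modifyList(defaultTurbovegMap(), as.list(columnMap))
  sp <- readDBF(speciesPath, encoding = encoding)
  need <- c(map$species_nr, map$name)
  if (!all(need %in% names(sp))) {
    stop("species table lacks mapped column(s): ",
         paste(setdiff(need, names(sp)), collapse = ", "), call. = FALSE)
  }
  nr <- asIntCol(sp[[map$species_nr]], map$species_nr)
  validNr <- if (map$valid_nr %in% names(sp)) {
    asIntCol(sp[[map$valid_nr]], map$valid_nr)
  } else rep(NA_integer_, nrow(sp))
  synFlag <- if (map$synonym_flag %in% names(sp)) {
    as.logical(sp[[map$synonym_flag]])
  } else rep(NA, nrow(sp))

  isAccepted <- ifelse(!is.na(validNr), validNr == nr,
                       !is.na(synFlag) & !synFlag)
  isAccepted[is.na(isAccepted)] <- FALSE
  conflict <- !is.na(validNr) & !is.na(synFlag) &
    ((validNr == nr) == synFlag)
  if (any(conflict)) {
    message("synonym flag conflicts with valid_nr for species_nr ",
            paste(nr[conflict], collapse = ", "),
            "; honoring valid_nr")
  }

  acceptedNr <- nr[isAccepted]
  concept <- ifelse(isAccepted, nr, validNr)
  dangling <- !isAccepted & (is.na(concept) | !concept %in% acceptedNr)
  if (any(dangling)) {
    ids <- paste(nr[dangling], collapse = ", ")
    if (strict) {
      stop("synonym(s) with unresolvable valid_nr (species_nr ", ids, ")",
           call. = FALSE)
    }
    warning("dropping synonym(s) with unresolvable valid_nr (species_nr ",
            ids, ")", call. = FALSE)
  }
  keep <- !dangling
  auth <- if (map$author %in% names(sp)) asChrCol(sp[[map$author]])
          else rep(NA_character_, nrow(sp))
  nm <- data.frame(usage_id = nr[keep], concept_id = concept[keep],
                   full_name = normString(sp[[map$name]])[keep],
                   author = auth[keep], stringsAsFactors = FALSE)
  cp <- data.frame(concept_id = acceptedNr, accepted_name_id = acceptedNr,
                   parent_id = rep(NA_integer_, length(acceptedNr)),
                   rank = rep(NA_character_, length(acceptedNr)),
                   view_id = rep(NA_integer_, length(acceptedNr)),
                   stringsAsFactors = FALSE)

  tr <- emptyTaxonTraits()
  if (!is.null(attributePath)) {
    eco <- readDBF(attributePath, encoding = encoding)
    if (!map$species_nr %in% names(eco)) {
      stop("attribute table lacks column ", map$species_nr, call. = FALSE)
    }
    key <- asIntCol(eco[[map$species_nr]], map$species_nr)
    ok <- key %in% acceptedNr
    if (any(!ok)) {
      warning("dropping attribute record(s) not keyed to an accepted name ",
              "(species_nr ", paste(key[!ok], collapse = ", "), ")",
              call. = FALSE)
    }
    vars <- setdiff(names(eco), map$species_nr)
    if (length(vars) && any(ok)) {
      tr <- data.frame(concept_id = key[ok], stringsAsFactors = FALSE)
      for (v in vars) tr[[v]] <- eco[[v]][ok]
    }
  }

  out <- TaxonList(taxonNames = nm, taxonConcepts = cp, taxonTraits = tr)
  v <- validateChecklist(out)
  if (nrow(v)) {
    stop("Turboveg import produced an invalid list:\n  ",
         paste(v$message, collapse = "\n  "), call. = FALSE)
  }
  out
}

#' Write a TaxonList as a Turboveg-dialect fixture
#'
#' Emits the two-DBF layout [readTurboveg()] consumes: `species.dbf`
#' (species_nr = usage id, name, author, synonym flag, valid_nr = accepted
#' usage id of the name's concept) and, when the list has trait variables,
#' `ecodbase.dbf` keyed by the accepted name's species number. Taxon views,
#' ranks and parent-child relationships cannot be represented in this
#' dialect; when present they are dropped with a warning.
#'
#' @param x A valid `TaxonList`.
#' @param dir Output directory (created if needed).
#' @param encoding DBF text encoding (default `"latin1"`).
#' @return Named character vector of written paths (`species`, and
#'   `ecodbase` when traits exist).
#' @export
writeTurbovegFixture <- function(x, dir, encoding = "latin1") {
  assertValid(x, "writeTurbovegFixture")
  if (any(!is.na(x@taxonConcepts$parent_id)) ||
      any(!is.na(x@taxonConcepts$rank)) || nrow(x@taxonViews)) {
    warning("Turboveg species lists carry no hierarchy, ranks or taxon ",
            "views; these are dropped", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nm <- x@taxonNames
  cp <- x@taxonConcepts
  accOf <- cp$accepted_name_id[match(nm$concept_id, cp$concept_id)]
  sp <- data.frame(SPECIES_NR = nm$usage_id,
                   ABBREVIAT = nm$full_name,
                   AUTHOR = nm$author,
                   SYNONYM = nm$usage_id != accOf,
                   VALID_NR = accOf,
                   stringsAsFactors = FALSE)
  sp <- sp[order(sp$SPECIES_NR), , drop = FALSE]
  paths <- c(species = file.path(dir, "species.dbf"))
  writeDBF(sp, paths[["species"]], encoding = encoding)
  tr <- x@taxonTraits
  if (ncol(tr) > 1L && nrow(tr)) {
    eco <- data.frame(
      SPECIES_NR = cp$accepted_name_id[match(tr$concept_id, cp$concept_id)],
      stringsAsFactors = FALSE)
    for (v in setdiff(names(tr), "concept_id")) eco[[v]] <- tr[[v]]
    eco <- eco[order(eco$SPECIES_NR), , drop = FALSE]
    paths[["ecodbase"]] <- file.path(dir, "ecodbase.dbf")
    writeDBF(eco, paths[["ecodbase"]], encoding = encoding)
  }
  invisible(paths)
}
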
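# Editing functions. Every one of them takes a valid list, checks its
# preconditions before touching anything, and returns a valid list; because R
# has copy semantics, a rejected edit (error) leaves the caller's object
# bit-identical — the transactional contract comes for free.

# ancestor chain of `id` following parent pointers; errors on a cycle.
ancestorChain <- function(cp, id) {
  out <- integer()
  cur <- id
  n <- nrow(cp)
  while (TRUE) {
    p <- cp$parent_id[match(cur, cp$concept_id)]
    if (is.na(p)) break
    if (p %in% c(out, id) || length(out) > n) {
      stop("cycle detected in parent-child relationships at concept ", p,
           call. = FALSE)
    }
    out <- c(out, p)
    cur <- p
  }
  out
}

rankPos <- function(x, rank) match(rank, x@rankLadder)

checkRankBelowParent <- function(x, childRank, parentID) {
  if (is.na(childRank) || is.na(parentID)) return(invisible(TRUE))
  prank <- x@taxonConcepts$rank[match(parentID, x@taxonConcepts$concept_id)]
  if (is.na(prank)) return(invisible(TRUE))  # unranked parent is legal
  if (rankPos(x, childRank) >= rankPos(x, prank)) {
    stop("rank order breach: '", childRank,
         "' is not strictly below parent's rank '", prank, "'",
         call. = FALSE)
  }
  invisible(TRUE)
}

checkComboAbsent <- function(x, full_name, author) {
  nm <- x@taxonNames
  key <- comboKey(full_name, author)
  clash <- nm$usage_id[comboKey(nm$full_name, nm$author) %in% key]
  if (length(clash)) {
    stop("duplicated combination: '", formatName(normString(full_name[1L]),
                                                 author[1L]),
         "' already present as usage_id ", paste(clash, collapse = ","),
         " (same name with same author)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Add taxon concepts with their accepted names
#'
#' Creates, for each input name, one new concept and one new usage name (the
#' concept's accepted name), with fresh ids assigned deterministically as
#' max(existing id) + 1. All inputs share the optional `rank`, `viewID` and
#' `parentID`.
#'
#' @param x A valid `TaxonList`.
#' @param names Accepted names to add: a data.frame with columns `full_name`
#'   and `author`, or a character vector of names (authority `NA`).
#' @param rank Optional rank label; must be on the ladder and strictly below
#'   the parent's rank when both are ranked.
#' @param viewID Optional existing view id.
#' @param parentID Optional existing parent concept id.
#' @return The updated `TaxonList`. New concept ids are
#'   `max(concept_id) + 1, ...` in input order (computable by the caller; ids
#'   are never reused).
#' @examples
#' x <- easplistMini()
#' x2 <- addConcept(x, data.frame(full_name = "Cyperus dives",
#'                                author = "Delile"),
#'                  rank = "species", parentID = 54)
#' checklistStats(x2)$n_concepts  # 4
#' @export
addConcept <- function(x, names, rank = NA_character_, viewID = NA_integer_,
                       parentID = NA_integer_) {
  assertValid(x, "addConcept")
  if (is.character(names)) {
    names <- data.frame(full_name = names, author = NA_character_,
                        stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(names), all(c("full_name") %in% colnames(names)),
            nrow(names) >= 1L)
  if (!"author" %in% colnames(names)) names$author <- NA_character_
  full <- normString(names$full_name)
  auth <- asChrCol(names$author)
  if (anyDuplicated(comboKey(full, auth))) {
    stop("input names contain duplicated combinations", call. = FALSE)
  }
  for (i in seq_along(full)) checkComboAbsent(x, full[i], auth[i])
  rank <- as.character(rank)
  if (!is.na(rank) && !rank %in% x@rankLadder) {
    stop("unknown rank '", rank, "' (not on the ladder)", call. = FALSE)
  }
  parentID <- as.integer(parentID)
  if (!is.na(parentID) && !parentID %in% x@taxonConcepts$concept_id) {
    stop("unknown parent concept ", parentID, call. = FALSE)
  }
  viewID <- as.integer(viewID)
  if (!is.na(viewID) && !viewID %in% x@taxonViews$view_id) {
    stop("unknown view ", viewID, call. = FALSE)
  }
  checkRankBelowParent(x, rank, parentID)

  n <- length(full)
  newCids <- nextIds(x@taxonConcepts$concept_id, n)
  newUids <- nextIds(x@taxonNames$usage_id, n)
  nm <- data.frame(usage_id = newUids, concept_id = newCids,
                   full_name = full, author = auth, stringsAsFactors = FALSE)
  cpNew <- data.frame(concept_id = newCids, accepted_name_id = newUids,
                      parent_id = rep(parentID, n), rank = rep(rank, n),
                      view_id = rep(viewID, n), stringsAsFactors = FALSE)
  x@taxonNames <- bindKeepCols(x@taxonNames, nm)
  x@taxonConcepts <- bindKeepCols(x@taxonConcepts, cpNew)
  assertValid(x, "addConcept[post]")
  x
}

# rbind two data.frames whose column sets may differ (extra user columns are
# kept and padded with NA).
bindKeepCols <- function(a, b) {
  for (cc in setdiff(names(a), names(b))) b[[cc]] <- rep(NA, nrow(b))
  for (cc in setdiff(names(b), names(a))) a[[cc]] <- rep(NA, nrow(a))
  out <- rbind(a, b[names(a)])
  rownames(out) <- NULL
  out
}

#' Add a synonym to an existing concept
#'
#' Adds one usage name linked to `conceptID` without touching the accepted
#' name. The combination must be absent from the whole names table.
#'
#' @param x A valid `TaxonList`.
#' @param conceptID Existing concept id.
#' @param fullName The combination (without authority).
#' @param author Authority string, `NA` when absent.
#' @return The updated `TaxonList` (one more name row; the new `usage_id` is
#'   max(usage_id) + 1).
#' @export
addSynonym <- function(x, conceptID, fullName, author = NA_character_) {
  assertValid(x, "addSynonym")
  conceptID <- as.integer(conceptID)
  if (!conceptID %in% x@taxonConcepts$concept_id) {
    stop("unknown concept ", conceptID, call. = FALSE)
  }
  fullName <- normString(fullName)
  author <- asChrCol(author)
  checkComboAbsent(x, fullName, author)
  nm <- data.frame(usage_id = nextIds(x@taxonNames$usage_id),
                   concept_id = conceptID, full_name = fullName,
                   author = author, stringsAsFactors = FALSE)
  x@taxonNames <- bindKeepCols(x@taxonNames, nm)
  assertValid(x, "addSynonym[post]")
  x
}

#' Promote a synonym to accepted name
#'
#' The new accepted name must already be a synonym of the same concept; the
#' former accepted name becomes a synonym. No name rows are created or
#' deleted, so each name keeps its id, string and authority.
#'
#' @param x A valid `TaxonList`.
#' @param conceptID Existing concept id.
#' @param usageID A `usage_id` currently listed as a synonym of `conceptID`.
#'   Passing a name of a different concept is rejected (move it first with
#'   [changeConcept()]); passing the current accepted name is rejected as a
#'   probable caller mistake rather than silently ignored.
#' @return The updated `TaxonList`.
#' @export
setAcceptedName <- function(x, conceptID, usageID) {
  assertValid(x, "setAcceptedName")
  conceptID <- as.integer(conceptID)
  usageID <- as.integer(usageID)
  cp <- x@taxonConcepts
  ci <- match(conceptID, cp$concept_id)
  if (is.na(ci)) stop("unknown concept ", conceptID, call. = FALSE)
  ni <- match(usageID, x@taxonNames$usage_id)
  if (is.na(ni)) stop("unknown usage name ", usageID, call. = FALSE)
  if (x@taxonNames$concept_id[ni] != conceptID) {
    stop("usage name ", usageID, " belongs to concept ",
         x@taxonNames$concept_id[ni], ", not ", conceptID,
         "; use changeConcept() to move synonyms first", call. = FALSE)
  }
  if (cp$accepted_name_id[ci] == usageID) {
    stop("usage name ", usageID, " is already the accepted name of concept ",
         conceptID, call. = FALSE)
  }
  cp$accepted_name_id[ci] <- usageID
  x@taxonConcepts <- cp
  assertValid(x, "setAcceptedName[post]")
  x
}

#' Move a synonym to another concept
#'
#' Only synonyms may move: re-linking preserves the identity of the name
#' (its `usage_id`, string and authority); only the concept link changes.
#'
#' @param x A valid `TaxonList`.
#' @param usageID A synonym's `usage_id` (moving an accepted name is
#'   rejected; demote it first with [setAcceptedName()]).
#' @param targetConceptID Existing concept id, different from the current one.
#' @return The updated `TaxonList`.
#' @export
changeConcept <- function(x, usageID, targetConceptID) {
  assertValid(x, "changeConcept")
  usageID <- as.integer(usageID)
  targetConceptID <- as.integer(targetConceptID)
  nm <- x@taxonNames
  ni <- match(usageID, nm$usage_id)
  if (is.na(ni)) stop("unknown usage name ", usageID, call. = FALSE)
  if (!targetConceptID %in% x@taxonConcepts$concept_id) {
    stop("unknown target concept ", targetConceptID, call. = FALSE)
  }
  if (usageID %in% x@taxonConcepts$accepted_name_id) {
    stop("usage name ", usageID, " is an accepted name; moving names ",
         "amongst concepts is only allowed for synonyms — first demote it ",
         "with setAcceptedName()", call. = FALSE)
  }
  if (nm$concept_id[ni] == targetConceptID) {
    stop("usage name ", usageID, " already belongs to concept ",
         targetConceptID, call. = FALSE)
  }
  nm$concept_id[ni] <- targetConceptID
  x@taxonNames <- nm
  assertValid(x, "changeConcept[post]")
  x
}

#' Set parent-child relationships
#'
#' Assigns `parentID` as parent of each concept in `childIDs`. For every
#' ranked child the parent's rank (when present) must be strictly higher on
#' the ladder; the assignment must not create a cycle — checked explicitly,
#' because unranked concepts are exempt from rank ordering and could
#' otherwise loop.
#'
#' @param x A valid `TaxonList`.
#' @param childIDs Integer vector of existing concept ids.
#' @param parentID Existing concept id.
#' @return The updated `TaxonList`.
#' @examples
#' x <- easplistMini()
#' getParents(x, 206)  # c(54, 1): genus then family
#' @export
addParent <- function(x, childIDs, parentID) {
  assertValid(x, "addParent")
  childIDs <- as.integer(childIDs)
  parentID <- as.integer(parentID)
  cp <- x@taxonConcepts
  missing <- setdiff(c(childIDs, parentID), cp$concept_id)
  if (length(missing)) {
    stop("unknown concept(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  anc <- c(parentID, ancestorChain(cp, parentID))
  for (ch in childIDs) {
    if (ch %in% anc) {
      stop("cycle: concept ", ch, " would become its own ancestor",
           call. = FALSE)
    }
    checkRankBelowParent(x, cp$rank[match(ch, cp$concept_id)], parentID)
  }
  cp$parent_id[match(childIDs, cp$concept_id)] <- parentID
  x@taxonConcepts <- cp
  assertValid(x, "addParent[post]")
  x
}

#' Insert a rank label into the ladder
#'
#' Inserts `rankLabel` so that it ends up at ladder position `position`
#' (1-based, 1 = lowest rank; existing labels at or above shift up). Because
#' rank-order checking uses strict ladder positions, inserting a level
#' between two existing ones can never break an existing parent-child pair —
#' this is re-asserted after the insertion.
#'
#' @param x A valid `TaxonList`.
#' @param rankLabel New label, not already on the ladder.
#' @param position Target position in the resulting ladder,
#'   `1 <= position <= length(ladder) + 1`.
#' @return The updated `TaxonList`.
#' @export
addLevel <- function(x, rankLabel, position) {
  assertValid(x, "addLevel")
  rankLabel <- as.character(rankLabel)
  position <- as.integer(position)
  ladder <- x@rankLadder
  if (rankLabel %in% ladder) {
    stop("rank '", rankLabel, "' is already on the ladder", call. = FALSE)
  }
  if (is.na(position) || position < 1L || position > length(ladder) + 1L) {
    stop("position must be between 1 and ", length(ladder) + 1L,
         call. = FALSE)
  }
  x@rankLadder <- append(ladder, rankLabel, after = position - 1L)
  assertValid(x, "addLevel[post]")
  x
}

#' Set or extend a concept's trait record
#'
#' Upserts the trait record of `conceptID`; new variable names extend the
#' trait table schema (all tables are user-extensible), existing variables
#' are overwritten for this concept only. At most one record per concept.
#'
#' @param x A valid `TaxonList`.
#' @param conceptID Existing concept id.
#' @param values Named list/vector of trait values, e.g.
#'   `list(life_form = "reed_plant")`.
#' @return The updated `TaxonList`.
#' @export
setTraits <- function(x, conceptID, values) {
  assertValid(x, "setTraits")
  conceptID <- as.integer(conceptID)
  if (!conceptID %in% x@taxonConcepts$concept_id) {
    stop("unknown concept ", conceptID, call. = FALSE)
  }
  values <- as.list(values)
  if (!length(values) || is.null(names(values)) || any(names(values) == "")) {
    stop("'values' must be a non-empty named list", call. = FALSE)
  }
  tr <- x@taxonTraits
  for (v in setdiff(names(values), names(tr))) {
    tr[[v]] <- rep(NA, nrow(tr))
  }
  ri <- match(conceptID, tr$concept_id)
  if (is.na(ri)) {
    tr <- bindKeepCols(tr, data.frame(concept_id = conceptID,
                                      stringsAsFactors = FALSE))
    ri <- nrow(tr)
  }
  for (v in names(values)) tr[[v]][ri] <- values[[v]]
  x@taxonTraits <- tr
  assertValid(x, "setTraits[post]")
  x
}

#' Add a taxon view
#'
#' Registers a bibliographic reference; its id is max(view_id) + 1
#' (deterministic, so the caller can compute it). The view starts
#' unreferenced; attach it to concepts with [setView()].
#'
#' @param x A valid `TaxonList`.
#' @param citation Named list with at least `author`, `year`, `title`; extra
#'   fields extend the views table.
#' @return The updated `TaxonList`.
#' @export
addView <- function(x, citation) {
  assertValid(x, "addView")
  citation <- as.list(citation)
  if (!all(c("author", "year", "title") %in% names(citation))) {
    stop("citation needs at least author, year and title", call. = FALSE)
  }
  row <- data.frame(view_id = nextIds(x@taxonViews$view_id),
                    stringsAsFactors = FALSE)
  for (f in names(citation)) row[[f]] <- citation[[f]]
  vw <- bindKeepCols(x@taxonViews, row)
  tt <- normalizeTables(x@taxonNames, x@taxonConcepts, vw, x@taxonTraits)
  x@taxonViews <- tt$views
  assertValid(x, "addView[post]")
  x
}

#' Attach a taxon view to concepts
#'
#' @param x A valid `TaxonList`.
#' @param conceptIDs Integer vector of existing concept ids.
#' @param viewID Existing view id.
#' @return The updated `TaxonList`.
#' @export
setView <- function(x, conceptIDs, viewID) {
  assertValid(x, "setView")
  conceptIDs <- as.integer(conceptIDs)
  viewID <- as.integer(viewID)
  if (!viewID %in% x@taxonViews$view_id) {
    stop("unknown view ", viewID, call. = FALSE)
  }
  missing <- setdiff(conceptIDs, x@taxonConcepts$concept_id)
  if (length(missing)) {
    stop("unknown concept(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cp <- x@taxonConcepts
  cp$view_id[match(conceptIDs, cp$concept_id)] <- viewID
  x@taxonConcepts <- cp
  assertValid(x, "setView[post]")
  x
}
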
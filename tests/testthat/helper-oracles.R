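# Shared helpers: brute-force oracles (kept independent of the package
# internals they check), defect injectors for the validity rules, and small
# comparison utilities.

# ---- comparison utilities --------------------------------------------------

tablesIdentical <- function(a, b) {
  identical(taxonNames(a), taxonNames(b)) &&
    identical(taxonConcepts(a), taxonConcepts(b)) &&
    identical(taxonViews(a), taxonViews(b)) &&
    identical(taxonTraits(a), taxonTraits(b)) &&
    identical(taxonRanks(a), taxonRanks(b))
}

# pad-and-rbind for injectors (mirrors nothing in the package on purpose;
# plain base R)
padRbind <- function(tbl, row) {
  for (cc in setdiff(names(tbl), names(row))) row[[cc]] <- NA
  out <- rbind(tbl, row[names(tbl)])
  rownames(out) <- NULL
  out
}

# ---- brute-force hierarchy oracle -----------------------------------------

# ancestors by naive recursive pointer-following on the raw concepts table
oracleAncestors <- function(cp, id) {
  p <- cp$parent_id[cp$concept_id == id]
  if (length(p) != 1L || is.na(p)) return(integer())
  c(p, oracleAncestors(cp, p))
}

# descendants by exhaustive edge scanning
oracleDescendants <- function(cp, id) {
  out <- integer()
  frontier <- id
  repeat {
    kids <- cp$concept_id[!is.na(cp$parent_id) & cp$parent_id %in% frontier]
    kids <- setdiff(kids, c(out, id))
    if (!length(kids)) break
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

# expected concept set of a substring query, per the subset contract
oracleSubsetConcepts <- function(x, pattern, keepChildren, keepParents) {
  nm <- taxonNames(x)
  cp <- taxonConcepts(x)
  hit <- grepl(tolower(pattern), tolower(nm$full_name), fixed = TRUE)
  keep <- unique(nm$concept_id[hit])
  if (keepChildren) {
    keep <- unique(c(keep, unlist(lapply(keep, oracleDescendants, cp = cp))))
  }
  if (keepParents) {
    keep <- unique(c(keep, unlist(lapply(keep, oracleAncestors, cp = cp))))
  }
  sort(as.integer(keep))
}

# every substring of s with length >= minLen
allSubstrings <- function(s, minLen = 4L) {
  n <- nchar(s)
  if (n < minLen) return(character())
  unlist(lapply(minLen:n, function(L) substring(s, 1:(n - L + 1L),
                                                L:n)))
}

# ---- defect injectors ------------------------------------------------------

# Each injector mutates a VALID list (via direct slot access) so that
# exactly one rule is broken; chosen victims are deterministic under the
# caller's RNG state.
injectDefect <- function(x, rule) {
  nm <- taxonNames(x)
  cp <- taxonConcepts(x)
  freshName <- paste("Zyzzyva", paste(sample(letters, 8L, TRUE),
                                      collapse = ""))
  switch(rule,
    V1_DUP_USAGE_ID = {
      row <- data.frame(usage_id = nm$usage_id[1L],
                        concept_id = resample1(cp$concept_id),
                        full_name = freshName, author = "L.",
                        stringsAsFactors = FALSE)
      x@taxonNames <- padRbind(nm, row)
    },
    V2_DUP_CONCEPT_ID = {
      x@taxonConcepts <- padRbind(cp, cp[resample1(seq_len(nrow(cp))), ,
                                         drop = FALSE])
    },
    V3_DUP_COMBINATION = {
      victim <- nm[resample1(seq_len(nrow(nm))), , drop = FALSE]
      row <- data.frame(usage_id = max(nm$usage_id) + 1L,
                        concept_id = resample1(cp$concept_id),
                        full_name = victim$full_name,
                        author = victim$author, stringsAsFactors = FALSE)
      x@taxonNames <- padRbind(nm, row)
    },
    V4_ORPHANED_NAME = {
      row <- data.frame(usage_id = max(nm$usage_id) + 1L,
                        concept_id = max(cp$concept_id) + 1000L,
                        full_name = freshName, author = "L.",
                        stringsAsFactors = FALSE)
      x@taxonNames <- padRbind(nm, row)
    },
    V5_ORPHANED_TRAIT = {
      x@taxonTraits <- padRbind(taxonTraits(x), data.frame(
        concept_id = max(cp$concept_id) + 1000L, stringsAsFactors = FALSE))
    },
    V6_MISSING_ACCEPTED = {
      i <- resample1(seq_len(nrow(cp)))
      cp$accepted_name_id[i] <- max(nm$usage_id) + 1000L
      x@taxonConcepts <- cp
    },
    V7_MISSING_PARENT = {
      i <- resample1(seq_len(nrow(cp)))
      cp$parent_id[i] <- max(cp$concept_id) + 1000L
      x@taxonConcepts <- cp
    },
    V8_UNKNOWN_RANK = {
      i <- resample1(seq_len(nrow(cp)))
      cp$rank[i] <- "tribe"
      x@taxonConcepts <- cp
    },
    V9_RANK_ORDER = {
      # lift a genus to its parent's rank: no longer strictly below family
      cand <- which(cp$rank == "genus" & !is.na(cp$parent_id))
      i <- resample1(cand)
      cp$rank[i] <- "family"
      x@taxonConcepts <- cp
    },
    V10_DANGLING_VIEW = {
      i <- resample1(seq_len(nrow(cp)))
      cp$view_id[i] <- max(c(0L, taxonViews(x)$view_id)) + 1000L
      x@taxonConcepts <- cp
    },
    stop("unknown rule ", rule))
  x
}

resample1 <- function(x) x[sample.int(length(x), 1L)]

allRules <- c("V1_DUP_USAGE_ID", "V2_DUP_CONCEPT_ID", "V3_DUP_COMBINATION",
              "V4_ORPHANED_NAME", "V5_ORPHANED_TRAIT", "V6_MISSING_ACCEPTED",
              "V7_MISSING_PARENT", "V8_UNKNOWN_RANK", "V9_RANK_ORDER",
              "V10_DANGLING_VIEW")
orphanRules <- c("V4_ORPHANED_NAME", "V5_ORPHANED_TRAIT",
                 "V6_MISSING_ACCEPTED", "V7_MISSING_PARENT",
                 "V10_DANGLING_VIEW")

# ---- turboveg partition oracle --------------------------------------------

# the concept/name partition of a list: per concept, the sorted set of
# name+author strings and which of them is accepted (ids are allowed to
# change across a Turboveg round trip; the partition is the invariant)
conceptPartition <- function(x) {
  nm <- taxonNames(x)
  cp <- taxonConcepts(x)
  combo <- paste(nm$full_name, ifelse(is.na(nm$author), "", nm$author))
  acceptedUsage <- cp$accepted_name_id[match(nm$concept_id, cp$concept_id)]
  tag <- paste0(combo, ifelse(nm$usage_id == acceptedUsage, " [acc]", ""))
  parts <- split(tag, nm$concept_id)
  parts <- lapply(parts, sort)
  unname(parts[order(vapply(parts, `[`, "", 1L))])
}

# a hierarchy-free, view-free list as Turboveg can represent it
flattenForTurboveg <- function(x) {
  cp <- taxonConcepts(x)
  cp$parent_id <- NA_integer_
  cp$rank <- NA_character_
  cp$view_id <- NA_integer_
  x@taxonConcepts <- cp
  x@taxonViews <- taxonViews(x)[0L, , drop = FALSE]
  x@rankLadder <- character()
  x
}

# ---- random applicable edits (for the edit-safety property) ----------------

# Applies one randomly chosen applicable edit; returns list(x = new list,
# kind = label). Relies only on exported surface.
randomEdit <- function(x, step) {
  cp <- taxonConcepts(x)
  nm <- taxonNames(x)
  accepted <- cp$accepted_name_id
  synRows <- nm[!nm$usage_id %in% accepted, , drop = FALSE]
  kinds <- c("addConcept", "addSynonym", "setTraits", "addView", "addLevel")
  if (nrow(synRows)) kinds <- c(kinds, "setAcceptedName", "changeConcept")
  genera <- cp$concept_id[cp$rank == "genus" & !is.na(cp$rank)]
  species <- cp$concept_id[cp$rank == "species" & !is.na(cp$rank)]
  if (length(genera) && length(species)) kinds <- c(kinds, "addParent")
  if (nrow(taxonViews(x))) kinds <- c(kinds, "setView")
  kind <- resample1(kinds)
  fresh <- paste0("Novum", step, "x",
                  paste(sample(letters, 6L, TRUE), collapse = ""))
  x2 <- switch(kind,
    addConcept = addConcept(x, data.frame(full_name = fresh, author = "L."),
                            rank = "species",
                            parentID = if (length(genera))
                              resample1(genera) else NA_integer_),
    addSynonym = addSynonym(x, resample1(cp$concept_id), fresh, "Willd."),
    setAcceptedName = {
      r <- synRows[resample1(seq_len(nrow(synRows))), , drop = FALSE]
      setAcceptedName(x, r$concept_id, r$usage_id)
    },
    changeConcept = {
      r <- synRows[resample1(seq_len(nrow(synRows))), , drop = FALSE]
      targets <- setdiff(cp$concept_id, r$concept_id)
      changeConcept(x, r$usage_id, resample1(targets))
    },
    addParent = addParent(x, resample1(species), resample1(genera)),
    addLevel = addLevel(x, paste0("level", step),
                        sample.int(length(taxonRanks(x)) + 1L, 1L)),
    setTraits = setTraits(x, resample1(cp$concept_id),
                          list(life_form = "herb")),
    addView = addView(x, list(author = paste0("Auth", step), year = 2000L,
                              title = paste("Synthetic view", step))),
    setView = setView(x, resample1(cp$concept_id),
                      resample1(taxonViews(x)$view_id)))
  list(x = x2, kind = kind)
}

# one deliberately invalid edit; must throw and leave `x` untouched
rejectedEdit <- function(x) {
  cp <- taxonConcepts(x)
  nm <- taxonNames(x)
  kind <- resample1(c("dupCombo", "moveAccepted", "selfParent",
                      "unknownConcept", "badRank"))
  before <- x
  err <- tryCatch({
    switch(kind,
      dupCombo = {
        r <- nm[resample1(seq_len(nrow(nm))), , drop = FALSE]
        addSynonym(x, resample1(cp$concept_id), r$full_name, r$author)
      },
      moveAccepted = {
        uid <- resample1(cp$accepted_name_id)
        own <- nm$concept_id[nm$usage_id == uid]
        changeConcept(x, uid, resample1(setdiff(cp$concept_id, own)))
      },
      selfParent = {
        cid <- resample1(cp$concept_id)
        addParent(x, cid, cid)
      },
      unknownConcept = addSynonym(x, max(cp$concept_id) + 999L, "Nope nope"),
      badRank = addConcept(x, data.frame(full_name = "Bad rankus",
                                         author = "L."),
                           rank = "tribe_not_on_ladder"))
    NULL
  }, error = function(e) e)
  list(threw = !is.null(err), unchanged = tablesIdentical(x, before),
       kind = kind)
}
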
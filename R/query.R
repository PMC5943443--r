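# Querying and navigation: structured subsetting with hierarchy expansion,
# parent/child traversal, accepted-name and synonym lookup.

#' Ancestors of a concept
#'
#' Follows `parent_id` pointers from `conceptID` to a root.
#'
#' @param x A `TaxonList` with an acyclic hierarchy.
#' @param conceptID Existing concept id.
#' @return Integer vector of ancestor concept ids, nearest first; empty for a
#'   root.
#' @examples
#' getParents(easplistMini(), 206)  # genus, then family
#' @export
getParents <- function(x, conceptID) {
  conceptID <- as.integer(conceptID)
  if (!conceptID %in% x@taxonConcepts$concept_id) {
    stop("unknown concept ", conceptID, call. = FALSE)
  }
  ancestorChain(x@taxonConcepts, conceptID)
}

#' Children of a concept
#'
#' @param x A `TaxonList` with an acyclic hierarchy.
#' @param conceptID Existing concept id.
#' @param recursive When `TRUE`, all transitive descendants; otherwise direct
#'   children only.
#' @return Sorted integer vector of concept ids (never includes
#'   `conceptID` itself).
#' @export
getChildren <- function(x, conceptID, recursive = FALSE) {
  conceptID <- as.integer(conceptID)
  cp <- x@taxonConcepts
  if (!conceptID %in% cp$concept_id) {
    stop("unknown concept ", conceptID, call. = FALSE)
  }
  direct <- cp$concept_id[!is.na(cp$parent_id) & cp$parent_id == conceptID]
  if (!recursive) return(sort(direct))
  out <- integer()
  frontier <- direct
  while (length(frontier)) {
    out <- c(out, frontier)
    frontier <- cp$concept_id[!is.na(cp$parent_id) &
                                cp$parent_id %in% frontier]
    frontier <- setdiff(frontier, out)
  }
  sort(out)
}

#' Accepted name and synonyms of a concept
#'
#' `acceptedName()` returns the single accepted combination of a concept;
#' `synonyms()` returns every other usage name of the concept, ordered by
#' `usage_id`.
#'
#' @param x A valid `TaxonList`.
#' @param conceptID Existing concept id.
#' @return One-row (`acceptedName`) or zero-or-more-row (`synonyms`)
#'   data.frame with columns `usage_id`, `full_name`, `author`.
#' @examples
#' acceptedName(easplistMini(), 206)  # Cyperus papyrus L.
#' @export
acceptedName <- function(x, conceptID) {
  conceptID <- as.integer(conceptID)
  ci <- match(conceptID, x@taxonConcepts$concept_id)
  if (is.na(ci)) stop("unknown concept ", conceptID, call. = FALSE)
  uid <- x@taxonConcepts$accepted_name_id[ci]
  out <- x@taxonNames[x@taxonNames$usage_id == uid,
                      c("usage_id", "full_name", "author"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname acceptedName
#' @export
synonyms <- function(x, conceptID) {
  conceptID <- as.integer(conceptID)
  ci <- match(conceptID, x@taxonConcepts$concept_id)
  if (is.na(ci)) stop("unknown concept ", conceptID, call. = FALSE)
  uid <- x@taxonConcepts$accepted_name_id[ci]
  nm <- x@taxonNames
  out <- nm[nm$concept_id == conceptID & nm$usage_id != uid,
            c("usage_id", "full_name", "author"), drop = FALSE]
  out <- out[order(out$usage_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

subsetOperators <- c("equals", "contains", "less_than", "greater_than",
                     "in_set")

# Apply one structured predicate to a column; returns a logical row mask.
applyPredicate <- function(col, op, value) {
  switch(op,
    equals = !is.na(col) & col == value,
    contains = {
      if (!is.character(col)) {
        stop("'contains' requires a text column", call. = FALSE)
      }
      !is.na(col) & grepl(tolower(as.character(value)), tolower(col),
                          fixed = TRUE)
    },
    less_than = {
      if (!is.numeric(col)) {
        stop("'less_than' requires a numeric column", call. = FALSE)
      }
      !is.na(col) & col < as.numeric(value)
    },
    greater_than = {
      if (!is.numeric(col)) {
        stop("'greater_than' requires a numeric column", call. = FALSE)
      }
      !is.na(col) & col > as.numeric(value)
    },
    in_set = !is.na(col) & col %in% value,
    stop("unknown operator '", op, "'; use one of: ",
         paste(subsetOperators, collapse = ", "), call. = FALSE))
}

#' Subset a checklist by a structured query
#'
#' Builds the seed set of concepts matched by a predicate on one of the
#' tables (a matched name or trait record selects its concept), optionally
#' expands it with all transitive descendants (`keepChildren`) and/or all
#' transitive ancestors (`keepParents`), and returns a new valid `TaxonList`
#' containing exactly the expanded concept set, *all* names of those
#' concepts, their trait records, the views they reference and the full rank
#' ladder. Parent pointers leading outside the retained set are nulled so the
#' output always validates.
#'
#' Text `contains` matching is case-insensitive substring containment;
#' `equals` is exact and case-sensitive; `less_than`/`greater_than` compare
#' numerically; `in_set` tests membership in a vector of values.
#'
#' @param x A valid `TaxonList`.
#' @param table One of `"names"`, `"concepts"`, `"traits"`.
#' @param column Column name in the selected table.
#' @param op One of `"equals"`, `"contains"`, `"less_than"`,
#'   `"greater_than"`, `"in_set"`.
#' @param value Comparison literal (or vector, for `in_set`).
#' @param keepChildren Keep all transitive descendants of matched concepts.
#' @param keepParents Keep all transitive ancestors of matched concepts.
#' @return A valid `TaxonList`; empty (but valid) when nothing matches.
#' @examples
#' out <- subsetTaxa(easplistMini(), "names", "full_name", "contains",
#'                   "papyrus", keepParents = TRUE)
#' checklistStats(out)$n_concepts  # 3: species, genus, family
#' @export
subsetTaxa <- function(x, table, column, op, value,
                       keepChildren = FALSE, keepParents = FALSE) {
  table <- match.arg(table, c("names", "concepts", "traits"))
  tbl <- switch(table, names = x@taxonNames, concepts = x@taxonConcepts,
                traits = x@taxonTraits)
  if (!column %in% names(tbl)) {
    stop("no column '", column, "' in table '", table, "'", call. = FALSE)
  }
  mask <- applyPredicate(tbl[[column]], op, value)
  seed <- unique(tbl$concept_id[mask])
  seed <- seed[seed %in% x@taxonConcepts$concept_id]

  cp <- x@taxonConcepts
  keep <- seed
  if (keepChildren && length(keep)) {
    frontier <- keep
    while (length(frontier)) {
      frontier <- cp$concept_id[!is.na(cp$parent_id) &
                                  cp$parent_id %in% frontier]
      frontier <- setdiff(frontier, keep)
      keep <- c(keep, frontier)
    }
  }
  if (keepParents && length(keep)) {
    pmap <- cp$parent_id[match(keep, cp$concept_id)]
    frontier <- setdiff(stats::na.omit(pmap), keep)
    while (length(frontier)) {
      keep <- c(keep, frontier)
      frontier <- stats::na.omit(cp$parent_id[match(frontier,
                                                    cp$concept_id)])
      frontier <- setdiff(frontier, keep)
    }
  }

  cpOut <- cp[cp$concept_id %in% keep, , drop = FALSE]
  cpOut$parent_id[!cpOut$parent_id %in% cpOut$concept_id] <- NA_integer_
  nmOut <- x@taxonNames[x@taxonNames$concept_id %in% keep, , drop = FALSE]
  trOut <- x@taxonTraits[x@taxonTraits$concept_id %in% keep, , drop = FALSE]
  vwOut <- x@taxonViews[x@taxonViews$view_id %in%
                          stats::na.omit(cpOut$view_id), , drop = FALSE]
  rownames(cpOut) <- NULL; rownames(nmOut) <- NULL
  rownames(trOut) <- NULL; rownames(vwOut) <- NULL
  out <- x
  out@taxonNames <- nmOut
  out@taxonConcepts <- cpOut
  out@taxonViews <- vwOut
  out@taxonTraits <- trOut
  out
}
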
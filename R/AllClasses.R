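#' @import methods
NULL

# Empty prototypes for the four linked tables. Extra user columns are allowed
# on every table; these are the mandatory ones.
emptyTaxonNames <- function() {
  data.frame(usage_id = integer(), concept_id = integer(),
             full_name = character(), author = character(),
             stringsAsFactors = FALSE)
}

emptyTaxonConcepts <- function() {
  data.frame(concept_id = integer(), accepted_name_id = integer(),
             parent_id = integer(), rank = character(), view_id = integer(),
             stringsAsFactors = FALSE)
}

emptyTaxonViews <- function() {
  data.frame(view_id = integer(), author = character(), year = integer(),
             title = character(), stringsAsFactors = FALSE)
}

emptyTaxonTraits <- function() {
  data.frame(concept_id = integer(), stringsAsFactors = FALSE)
}

#' TaxonList: a relational model for taxonomic checklists
#'
#' A `TaxonList` holds a taxonomic list as four linked column-oriented tables
#' plus a rank ladder:
#'
#' * `taxonNames` — taxon usage names (accepted names and synonyms). Columns
#'   `usage_id`, `concept_id`, `full_name` (the combination, without
#'   authority), `author` (authority string, `NA` when absent).
#' * `taxonConcepts` — one row per taxon concept. Columns `concept_id`,
#'   `accepted_name_id` (the `usage_id` of the accepted name), `parent_id`
#'   (optional parent concept), `rank` (optional rank label), `view_id`
#'   (optional taxon view).
#' * `taxonViews` — bibliographic references fixing concept circumscriptions.
#'   Columns `view_id`, `author`, `year`, `title` (extensible).
#' * `taxonTraits` — at most one attribute record per concept; column
#'   `concept_id` plus one column per trait variable. Coverage of all
#'   concepts is not required.
#' * `rankLadder` — rank labels ordered from lowest (position 1) to highest.
#'
#' Separating names from concepts keeps every historical name usage
#' traceable: a concept may carry many names but exactly one accepted name,
#' and synonymy is a property of the links, not of the name strings.
#'
#' The S4 validity method enforces only structural sanity (mandatory columns
#' present with the right types, unique ladder labels), so that broken lists
#' can be represented, inspected with [validateChecklist()] and repaired with
#' [cleanChecklist()]. Referential-integrity and hierarchy rules live in the
#' rule engine, not in `validObject()`.
#'
#' @slot taxonNames data.frame of taxon usage names.
#' @slot taxonConcepts data.frame of taxon concepts.
#' @slot taxonViews data.frame of taxon views.
#' @slot taxonTraits data.frame of taxon attributes.
#' @slot rankLadder character vector of rank labels, lowest first.
#'
#' @seealso [TaxonList()], [validateChecklist()], [checklistStats()]
#' @name TaxonList-class
#' @rdname TaxonList-class
#' @exportClass TaxonList
setClass("TaxonList",
         slots = c(taxonNames = "data.frame",
                   taxonConcepts = "data.frame",
                   taxonViews = "data.frame",
                   taxonTraits = "data.frame",
                   rankLadder = "character"),
         prototype = list(taxonNames = emptyTaxonNames(),
                          taxonConcepts = emptyTaxonConcepts(),
                          taxonViews = emptyTaxonViews(),
                          taxonTraits = emptyTaxonTraits(),
                          rankLadder = character()))

structuralProblems <- function(object) {
  msg <- character()
  need <- function(tbl, tblname, cols, classes) {
    for (i in seq_along(cols)) {
      if (!cols[i] %in% names(tbl)) {
        msg <<- c(msg, sprintf("table '%s' lacks mandatory column '%s'",
                               tblname, cols[i]))
      } else if (!inherits(tbl[[cols[i]]], classes[i])) {
        msg <<- c(msg, sprintf("column '%s.%s' must be of class %s",
                               tblname, cols[i], classes[i]))
      }
    }
  }
  need(object@taxonNames, "taxonNames",
       c("usage_id", "concept_id", "full_name", "author"),
       c("integer", "integer", "character", "character"))
  need(object@taxonConcepts, "taxonConcepts",
       c("concept_id", "accepted_name_id", "parent_id", "rank", "view_id"),
       c("integer", "integer", "integer", "character", "integer"))
  need(object@taxonViews, "taxonViews", "view_id", "integer")
  need(object@taxonTraits, "taxonTraits", "concept_id", "integer")
  if (anyDuplicated(object@rankLadder)) {
    msg <- c(msg, "rank ladder labels must be unique")
  }
  if (any(is.na(object@rankLadder))) {
    msg <- c(msg, "rank ladder labels must not be NA")
  }
  ranks <- object@taxonConcepts[["rank"]]
  if (!is.null(ranks) && any(!is.na(ranks)) && length(object@rankLadder) == 0L) {
    msg <- c(msg, "rank ladder is empty although concepts carry ranks")
  }
  msg
}

setValidity("TaxonList", function(object) {
  msg <- structuralProblems(object)
  if (length(msg)) msg else TRUE
})

# Normalize the four tables: integer id columns, ""->NA in character columns,
# clean row names. Keeps extra user columns untouched apart from ""->NA.
normalizeTables <- function(names_tbl, concepts, views, traits) {
  fixChr <- function(tbl) {
    for (cc in names(tbl)) {
      if (is.character(tbl[[cc]]) || is.factor(tbl[[cc]]))
        tbl[[cc]] <- asChrCol(tbl[[cc]])
    }
    tbl
  }
  intify <- function(tbl, cols) {
    for (cc in intersect(cols, names(tbl)))
      tbl[[cc]] <- asIntCol(tbl[[cc]], cc)
    tbl
  }
  names_tbl <- intify(fixChr(as.data.frame(names_tbl)),
                      c("usage_id", "concept_id"))
  concepts <- intify(fixChr(as.data.frame(concepts)),
                     c("concept_id", "accepted_name_id", "parent_id",
                       "view_id"))
  views <- intify(fixChr(as.data.frame(views)), c("view_id", "year"))
  traits <- intify(fixChr(as.data.frame(traits)), "concept_id")
  # optional columns of taxonConcepts may be missing on input
  for (cc in c("parent_id", "view_id")) {
    if (!cc %in% names(concepts)) concepts[[cc]] <- rep(NA_integer_,
                                                        nrow(concepts))
  }
  if (!"rank" %in% names(concepts))
    concepts$rank <- rep(NA_character_, nrow(concepts))
  if (!"author" %in% names(names_tbl))
    names_tbl$author <- rep(NA_character_, nrow(names_tbl))
  rownames(names_tbl) <- NULL
  rownames(concepts) <- NULL
  rownames(views) <- NULL
  rownames(traits) <- NULL
  list(names = names_tbl, concepts = concepts, views = views,
       traits = traits)
}

#' Construct a TaxonList
#'
#' With no arguments this returns the empty prototype: zero rows in all four
#' tables and an empty rank ladder (and it is trivially valid). Tables passed
#' in are normalized — id columns coerced to integer, empty strings to `NA`,
#' missing optional columns (`parent_id`, `rank`, `view_id`, `author`) added
#' as all-`NA` — but the referential-integrity rules are *not* enforced here;
#' run [validateChecklist()] for that.
#'
#' @param taxonNames data.frame of usage names
#'   (`usage_id`, `concept_id`, `full_name`, `author`).
#' @param taxonConcepts data.frame of concepts (`concept_id`,
#'   `accepted_name_id`, and optionally `parent_id`, `rank`, `view_id`).
#' @param taxonViews data.frame of taxon views (`view_id` plus citation
#'   columns).
#' @param taxonTraits data.frame of taxon attributes (`concept_id` plus one
#'   column per trait variable).
#' @param rankLadder character vector of rank labels, lowest rank first.
#' @return A `TaxonList` object.
#' @examples
#' x <- TaxonList()
#' checklistStats(x)$n_concepts  # 0
#' @export
TaxonList <- function(taxonNames = emptyTaxonNames(),
                      taxonConcepts = emptyTaxonConcepts(),
                      taxonViews = emptyTaxonViews(),
                      taxonTraits = emptyTaxonTraits(),
                      rankLadder = character()) {
  tt <- normalizeTables(taxonNames, taxonConcepts, taxonViews, taxonTraits)
  new("TaxonList", taxonNames = tt$names, taxonConcepts = tt$concepts,
      taxonViews = tt$views, taxonTraits = tt$traits,
      rankLadder = as.character(rankLadder))
}

#' @describeIn TaxonList-class Compact report of table sizes, hierarchy and
#'   ladder, in the style of `summary()` on the whole list.
#' @param object A `TaxonList`.
#' @exportMethod show
setMethod("show", "TaxonList", function(object) {
  s <- checklistStats(object)
  cat("TaxonList object\n")
  cat(sprintf("  taxon usage names: %d\n", s$n_names))
  cat(sprintf("  taxon concepts:    %d\n", s$n_concepts))
  cat(sprintf("  trait variables:   %d\n", s$n_trait_variables))
  cat(sprintf("  taxon views:       %d\n", s$n_views))
  cat(sprintf("  parent-child relationships: %s\n",
              if (s$has_parent_child) "yes" else "no"))
  if (length(s$rank_labels)) {
    cat("  rank ladder (lowest first):",
        paste(s$rank_labels, collapse = " < "), "\n")
  } else {
    cat("  rank ladder: none\n")
  }
  invisible(NULL)
})
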
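#' Whole-list summary statistics
#'
#' Counts computed directly from the table row counts: number of usage names,
#' of taxon concepts, of trait *variables* (columns of the traits table other
#' than `concept_id` — not the number of concepts carrying a record), number
#' of taxon views, whether any parent-child relationship is present, and the
#' rank ladder.
#'
#' @param x A `TaxonList`.
#' @return A list with elements `n_names`, `n_concepts`, `n_trait_variables`,
#'   `n_views`, `has_parent_child`, `rank_labels`.
#' @examples
#' s <- checklistStats(easplistMini())
#' s$n_names      # 4
#' s$n_concepts   # 3
#' @export
setGeneric("checklistStats", function(x) standardGeneric("checklistStats"))

#' @rdname checklistStats
#' @export
setMethod("checklistStats", "TaxonList", function(x) {
  list(n_names = nrow(x@taxonNames),
       n_concepts = nrow(x@taxonConcepts),
       n_trait_variables = max(0L, ncol(x@taxonTraits) - 1L),
       n_views = nrow(x@taxonViews),
       has_parent_child = any(!is.na(x@taxonConcepts$parent_id)),
       rank_labels = x@rankLadder)
})

#' @describeIn checklistStats `summary()` prints the same figures.
#' @param object A `TaxonList`.
#' @param ... ignored.
#' @exportMethod summary
setMethod("summary", "TaxonList", function(object, ...) {
  show(object)
  invisible(checklistStats(object))
})

formatName <- function(full_name, author) {
  if (is.na(author) || author == "") full_name
  else paste(full_name, author)
}

formatCitation <- function(viewRow) {
  parts <- c(viewRow$author,
             if (!is.null(viewRow$year) && !is.na(viewRow$year))
               paste0("(", viewRow$year, ")"),
             viewRow$title)
  parts <- parts[!is.na(parts) & nzchar(parts)]
  paste(parts, collapse = " ")
}

#' Per-concept summaries
#'
#' Queried by concept id (integer: exact match, singleton or empty) or by
#' name (character: every concept whose accepted name *or* any synonym
#' contains the query as a case-insensitive substring). Each summary reports
#' the accepted name, taxon view citation, synonyms, taxonomic rank and the
#' parent concept's accepted name. An empty result means "no matching
#' concept"; a malformed query is an error.
#'
#' @param x A valid `TaxonList`.
#' @param query integer concept id or non-empty character string.
#' @return A list of per-concept summaries (ordered by concept id), each a
#'   list with `concept_id`, `accepted_name` (list of `full_name`, `author`),
#'   `view` (citation string or `NULL`), `synonyms` (data.frame `usage_id`,
#'   `full_name`, `author`), `rank` (or `NA`), `parent` (parent's accepted
#'   name as list, or `NULL`).
#' @examples
#' cs <- conceptSummary(easplistMini(), 206)
#' cs[[1]]$accepted_name$full_name  # "Cyperus papyrus"
#' @export
setGeneric("conceptSummary", function(x, query) standardGeneric("conceptSummary"))

#' @rdname conceptSummary
#' @export
setMethod("conceptSummary", "TaxonList", function(x, query) {
  if (length(query) != 1L || is.na(query)) {
    stop("'query' must be a single concept id or a non-empty string",
         call. = FALSE)
  }
  nm <- x@taxonNames
  cp <- x@taxonConcepts
  if (is.numeric(query)) {
    ids <- cp$concept_id[cp$concept_id == as.integer(query)]
  } else if (is.character(query)) {
    if (!nzchar(query)) stop("'query' must be non-empty", call. = FALSE)
    # substring containment, case-insensitive, no regex semantics
    hit <- grepl(tolower(query), tolower(nm$full_name), fixed = TRUE)
    ids <- sort(unique(nm$concept_id[hit]))
    ids <- ids[ids %in% cp$concept_id]
  } else {
    stop("'query' must be integer or character", call. = FALSE)
  }
  lapply(sort(ids), function(cid) {
    crow <- cp[cp$concept_id == cid, , drop = FALSE]
    own <- nm[nm$concept_id == cid, , drop = FALSE]
    acc <- own[own$usage_id == crow$accepted_name_id, , drop = FALSE]
    syn <- own[own$usage_id != crow$accepted_name_id, , drop = FALSE]
    syn <- syn[order(syn$usage_id), c("usage_id", "full_name", "author"),
               drop = FALSE]
    rownames(syn) <- NULL
    view <- NULL
    if (!is.na(crow$view_id)) {
      vrow <- x@taxonViews[x@taxonViews$view_id == crow$view_id, ,
                           drop = FALSE]
      if (nrow(vrow) == 1L) view <- formatCitation(as.list(vrow))
    }
    parent <- NULL
    if (!is.na(crow$parent_id) && crow$parent_id %in% cp$concept_id) {
      prow <- cp[cp$concept_id == crow$parent_id, , drop = FALSE]
      pacc <- nm[nm$usage_id == prow$accepted_name_id, , drop = FALSE]
      if (nrow(pacc) == 1L) {
        parent <- list(concept_id = prow$concept_id,
                       full_name = pacc$full_name, author = pacc$author)
      }
    }
    list(concept_id = cid,
         accepted_name = list(full_name = acc$full_name,
                              author = acc$author),
         view = view,
         synonyms = syn,
         rank = crow$rank,
         parent = parent)
  })
})

#' Print a concept summary the way it is shown on the console
#'
#' @param x A `TaxonList`.
#' @param query as in [conceptSummary()].
#' @return Invisibly, the list of summaries.
#' @export
printConceptSummary <- function(x, query) {
  res <- conceptSummary(x, query)
  if (!length(res)) {
    cat("no matching concept\n")
    return(invisible(res))
  }
  for (s in res) {
    cat(sprintf("concept %d\n", s$concept_id))
    cat("  accepted name:",
        formatName(s$accepted_name$full_name, s$accepted_name$author), "\n")
    cat("  taxon view:", if (is.null(s$view)) "none" else s$view, "\n")
    if (nrow(s$synonyms)) {
      syn <- apply(s$synonyms, 1L,
                   function(r) formatName(r[["full_name"]], r[["author"]]))
      cat("  synonyms:", paste(syn, collapse = "; "), "\n")
    } else cat("  synonyms: none\n")
    cat("  rank:", if (is.na(s$rank)) "none" else s$rank, "\n")
    cat("  parent:",
        if (is.null(s$parent)) "none"
        else formatName(s$parent$full_name, s$parent$author), "\n")
  }
  invisible(res)
}
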
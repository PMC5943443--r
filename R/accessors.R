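# Accessor generics. Replacement forms re-normalize and re-run the
# structural validity check only, so slots can be manipulated directly (and
# broken deliberately) and then audited with validateChecklist() / repaired
# with cleanChecklist().

#' Access the tables of a TaxonList
#'
#' Getter/setter pairs for the four tables. Setters normalize the incoming
#' table (integer ids, `""` to `NA`) and check structure, but deliberately do
#' not enforce referential integrity: direct manipulation is allowed, and
#' [validateChecklist()] / [cleanChecklist()] audit and repair afterwards.
#'
#' @param x A `TaxonList`.
#' @param value Replacement data.frame.
#' @return The table (getter) or the updated `TaxonList` (setter).
#' @name taxonNames
#' @aliases taxonNames taxonNames<- taxonConcepts taxonConcepts<-
#'   taxonViews taxonViews<- taxonTraits taxonTraits<-
NULL

#' @rdname taxonNames
#' @export
setGeneric("taxonNames", function(x) standardGeneric("taxonNames"))
#' @rdname taxonNames
#' @export
setMethod("taxonNames", "TaxonList", function(x) x@taxonNames)

#' @rdname taxonNames
#' @export
setGeneric("taxonNames<-", function(x, value) standardGeneric("taxonNames<-"))
#' @rdname taxonNames
#' @export
setMethod("taxonNames<-", "TaxonList", function(x, value) {
  tt <- normalizeTables(value, x@taxonConcepts, x@taxonViews, x@taxonTraits)
  x@taxonNames <- tt$names
  validObject(x)
  x
})

#' @rdname taxonNames
#' @export
setGeneric("taxonConcepts", function(x) standardGeneric("taxonConcepts"))
#' @rdname taxonNames
#' @export
setMethod("taxonConcepts", "TaxonList", function(x) x@taxonConcepts)

#' @rdname taxonNames
#' @export
setGeneric("taxonConcepts<-",
           function(x, value) standardGeneric("taxonConcepts<-"))
#' @rdname taxonNames
#' @export
setMethod("taxonConcepts<-", "TaxonList", function(x, value) {
  tt <- normalizeTables(x@taxonNames, value, x@taxonViews, x@taxonTraits)
  x@taxonConcepts <- tt$concepts
  validObject(x)
  x
})

#' @rdname taxonNames
#' @export
setGeneric("taxonViews", function(x) standardGeneric("taxonViews"))
#' @rdname taxonNames
#' @export
setMethod("taxonViews", "TaxonList", function(x) x@taxonViews)

#' @rdname taxonNames
#' @export
setGeneric("taxonViews<-", function(x, value) standardGeneric("taxonViews<-"))
#' @rdname taxonNames
#' @export
setMethod("taxonViews<-", "TaxonList", function(x, value) {
  tt <- normalizeTables(x@taxonNames, x@taxonConcepts, value, x@taxonTraits)
  x@taxonViews <- tt$views
  validObject(x)
  x
})

#' @rdname taxonNames
#' @export
setGeneric("taxonTraits", function(x) standardGeneric("taxonTraits"))
#' @rdname taxonNames
#' @export
setMethod("taxonTraits", "TaxonList", function(x) x@taxonTraits)

#' @rdname taxonNames
#' @export
setGeneric("taxonTraits<-", function(x, value) standardGeneric("taxonTraits<-"))
#' @rdname taxonNames
#' @export
setMethod("taxonTraits<-", "TaxonList", function(x, value) {
  tt <- normalizeTables(x@taxonNames, x@taxonConcepts, x@taxonViews, value)
  x@taxonTraits <- tt$traits
  validObject(x)
  x
})

#' Get or set the rank ladder
#'
#' The rank ladder is the user-defined ordered sequence of taxonomic levels,
#' lowest rank first (e.g. `c("species", "genus", "family")`). Parent-child
#' relationships are checked against it: a child must sit strictly lower than
#' its (ranked) parent.
#'
#' The setter rejects a ladder that (a) repeats a label, (b) drops a rank
#' still assigned to some concept, or (c) would invert the strict ordering of
#' an existing ranked parent-child pair.
#'
#' @param x A `TaxonList`.
#' @param value character vector of unique rank labels, lowest first.
#' @return Getter: the ladder. Setter: the updated `TaxonList`.
#' @examples
#' x <- easplistMini()
#' taxonRanks(x)
#' @name taxonRanks
#' @aliases taxonRanks taxonRanks<-
NULL

#' @rdname taxonRanks
#' @export
setGeneric("taxonRanks", function(x) standardGeneric("taxonRanks"))
#' @rdname taxonRanks
#' @export
setMethod("taxonRanks", "TaxonList", function(x) x@rankLadder)

#' @rdname taxonRanks
#' @export
setGeneric("taxonRanks<-", function(x, value) standardGeneric("taxonRanks<-"))
#' @rdname taxonRanks
#' @export
setMethod("taxonRanks<-", "TaxonList", function(x, value) {
  value <- as.character(value)
  if (anyDuplicated(value)) {
    stop("rank ladder labels must be unique", call. = FALSE)
  }
  used <- unique(stats::na.omit(x@taxonConcepts$rank))
  missing <- setdiff(used, value)
  if (length(missing)) {
    stop("new ladder drops rank(s) still in use: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cand <- x
  cand@rankLadder <- value
  viol <- validateChecklist(cand)
  bad <- viol[viol$rule %in% c("V8_UNKNOWN_RANK", "V9_RANK_ORDER"), ,
              drop = FALSE]
  if (nrow(bad)) {
    stop("new ladder inverts the rank order of existing parent-child ",
         "pair(s): ", paste(bad$message, collapse = "; "), call. = FALSE)
  }
  cand
})
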
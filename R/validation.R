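# The rule engine. Ten closed rules; "valid" means the engine reports
# nothing. Kept separate from the S4 validity method so that broken lists can
# exist as objects, be audited, and be repaired.

ruleCodes <- c("V1_DUP_USAGE_ID", "V2_DUP_CONCEPT_ID", "V3_DUP_COMBINATION",
               "V4_ORPHANED_NAME", "V5_ORPHANED_TRAIT", "V6_MISSING_ACCEPTED",
               "V7_MISSING_PARENT", "V8_UNKNOWN_RANK", "V9_RANK_ORDER",
               "V10_DANGLING_VIEW")

emptyViolations <- function() {
  data.frame(rule = character(), ids = I(list()), message = character(),
             stringsAsFactors = FALSE)
}

violation <- function(rule, ids, message) {
  data.frame(rule = rule, ids = I(list(as.integer(ids))), message = message,
             stringsAsFactors = FALSE)
}

#' Check the validity rules of a taxonomic list
#'
#' Audits an arbitrary (possibly broken) `TaxonList` against the closed rule
#' set below and returns *all* violations; it never throws. An empty result
#' is exactly what "valid" means throughout the package.
#'
#' * **V1_DUP_USAGE_ID** duplicated `usage_id` in the names table.
#' * **V2_DUP_CONCEPT_ID** duplicated `concept_id` in the concepts table.
#' * **V3_DUP_COMBINATION** duplicated combination — same name with the same
#'   author, after trimming/collapsing whitespace (case-sensitive; a missing
#'   author equals the empty authority).
#' * **V4_ORPHANED_NAME** a name whose `concept_id` matches no concept.
#' * **V5_ORPHANED_TRAIT** a trait record whose `concept_id` matches no
#'   concept.
#' * **V6_MISSING_ACCEPTED** a concept whose `accepted_name_id` is absent
#'   from the names table or points to a name of a different concept.
#' * **V7_MISSING_PARENT** a `parent_id` matching no concept.
#' * **V8_UNKNOWN_RANK** a rank label not on the ladder.
#' * **V9_RANK_ORDER** a child whose rank is not strictly lower than its
#'   parent's rank (checked only when both carry ranks; "at least one level
#'   lower", so equal ranks violate too).
#' * **V10_DANGLING_VIEW** a `view_id` matching no view.
#'
#' Violations are deterministically ordered by rule code and then by first
#' offending id, so reports diff cleanly under version control.
#'
#' @param x A `TaxonList`, possibly broken.
#' @return data.frame with columns `rule` (character), `ids` (list column of
#'   integer vectors of offending ids) and `message`; zero rows iff valid.
#' @seealso [cleanChecklist()] to repair orphan-class violations.
#' @examples
#' nrow(validateChecklist(easplistMini()))  # 0
#' @export
setGeneric("validateChecklist", function(x) standardGeneric("validateChecklist"))

#' @rdname validateChecklist
#' @export
setMethod("validateChecklist", "TaxonList", function(x) {
  nm <- x@taxonNames
  cp <- x@taxonConcepts
  vw <- x@taxonViews
  tr <- x@taxonTraits
  out <- list()

  dupGroups <- function(keys, ids) {
    tab <- split(ids, keys)
    tab[vapply(tab, length, 1L) > 1L]
  }

  # V1: duplicated usage ids (offending ids = the duplicated id value)
  d <- unique(nm$usage_id[duplicated(nm$usage_id)])
  for (id in sort(d)) {
    out[[length(out) + 1L]] <- violation(
      "V1_DUP_USAGE_ID", id, sprintf("usage_id %d occurs %d times", id,
                                     sum(nm$usage_id == id)))
  }

  # V2: duplicated concept ids
  d <- unique(cp$concept_id[duplicated(cp$concept_id)])
  for (id in sort(d)) {
    out[[length(out) + 1L]] <- violation(
      "V2_DUP_CONCEPT_ID", id, sprintf("concept_id %d occurs %d times", id,
                                       sum(cp$concept_id == id)))
  }

  # V3: duplicated combinations (one violation per group, all usage ids)
  if (nrow(nm)) {
    grp <- dupGroups(comboKey(nm$full_name, nm$author), nm$usage_id)
    if (length(grp)) {
      grp <- grp[order(vapply(grp, min, 1L))]
      for (g in grp) {
        first <- nm[nm$usage_id == min(g), , drop = FALSE][1L, ]
        out[[length(out) + 1L]] <- violation(
          "V3_DUP_COMBINATION", sort(g),
          sprintf("combination '%s' duplicated by usage ids %s",
                  formatName(first$full_name, first$author),
                  paste(sort(g), collapse = ",")))
      }
    }
  }

  # V4: names pointing to missing concepts
  bad <- nm$usage_id[!nm$concept_id %in% cp$concept_id]
  for (id in sort(bad)) {
    out[[length(out) + 1L]] <- violation(
      "V4_ORPHANED_NAME", id,
      sprintf("name %d references a non-existent concept", id))
  }

  # V5: trait records pointing to missing concepts
  bad <- tr$concept_id[!tr$concept_id %in% cp$concept_id]
  for (id in sort(bad)) {
    out[[length(out) + 1L]] <- violation(
      "V5_ORPHANED_TRAIT", id,
      sprintf("trait record references non-existent concept %d", id))
  }

  # V6: accepted name missing or owned by another concept
  if (nrow(cp)) {
    ix <- match(cp$accepted_name_id, nm$usage_id)
    ok <- !is.na(cp$accepted_name_id) & !is.na(ix) &
      nm$concept_id[ifelse(is.na(ix), 1L, ix)] == cp$concept_id
    for (id in sort(cp$concept_id[!ok])) {
      out[[length(out) + 1L]] <- violation(
        "V6_MISSING_ACCEPTED", id,
        sprintf("concept %d lacks a usable accepted name", id))
    }
  }

  # V7: dangling parents
  bad <- cp$concept_id[!is.na(cp$parent_id) &
                         !cp$parent_id %in% cp$concept_id]
  for (id in sort(bad)) {
    out[[length(out) + 1L]] <- violation(
      "V7_MISSING_PARENT", id,
      sprintf("concept %d has a non-existent parent", id))
  }

  # V8: ranks off the ladder
  bad <- cp$concept_id[!is.na(cp$rank) & !cp$rank %in% x@rankLadder]
  for (id in sort(bad)) {
    out[[length(out) + 1L]] <- violation(
      "V8_UNKNOWN_RANK", id,
      sprintf("concept %d carries a rank not on the ladder", id))
  }

  # V9: child not strictly lower than parent (both ranked, parent resolvable)
  if (nrow(cp)) {
    pix <- match(cp$parent_id, cp$concept_id)
    childPos <- match(cp$rank, x@rankLadder)
    parentPos <- match(cp$rank[pix], x@rankLadder)
    bad <- which(!is.na(pix) & !is.na(childPos) & !is.na(parentPos) &
                   childPos >= parentPos)
    for (i in bad[order(cp$concept_id[bad])]) {
      out[[length(out) + 1L]] <- violation(
        "V9_RANK_ORDER", c(cp$concept_id[i], cp$parent_id[i]),
        sprintf("concept %d (rank %s) is not strictly below parent %d (rank %s)",
                cp$concept_id[i], cp$rank[i], cp$parent_id[i],
                cp$rank[pix[i]]))
    }
  }

  # V10: dangling views
  bad <- cp$concept_id[!is.na(cp$view_id) & !cp$view_id %in% vw$view_id]
  for (id in sort(bad)) {
    out[[length(out) + 1L]] <- violation(
      "V10_DANGLING_VIEW", id,
      sprintf("concept %d references a non-existent view", id))
  }

  if (!length(out)) return(emptyViolations())
  res <- do.call(rbind, out)
  ord <- order(match(res$rule, ruleCodes),
               vapply(res$ids, function(v) v[1L], 1L))
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  res
})

# TRUE iff the rule engine reports nothing.
isValidChecklist <- function(x) nrow(validateChecklist(x)) == 0L

# Internal guard used by every editing function.
assertValid <- function(x, caller) {
  v <- validateChecklist(x)
  if (nrow(v)) {
    stop(caller, "() requires a valid list; run validateChecklist() — ",
         nrow(v), " violation(s) found, first: ", v$message[1L],
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Repair orphan-class violations
#'
#' Removes or repairs, iteratively until a fixed point, everything that makes
#' a list invalid *without* requiring an editorial decision:
#'
#' * names referencing missing concepts are dropped (V4);
#' * trait records referencing missing concepts are dropped (V5);
#' * parent references to missing concepts are nulled — the concept is kept
#'   (V7);
#' * view references to missing views are nulled (V10);
#' * concepts without any name row are dropped — they can never satisfy the
#'   accepted-name rule (V6);
#' * a concept that still has names but whose `accepted_name_id` is broken
#'   gets it re-pointed at the lowest `usage_id` among its own names (V6) —
#'   removal would cascade into discarding intact names.
#'
#' Duplicated combinations (V3), duplicated ids (V1/V2), unknown ranks (V8)
#' and rank-order breaches (V9) require editorial decisions and are reported
#' by [validateChecklist()], never silently resolved. `cleanChecklist` is
#' idempotent and leaves an already-valid list unchanged.
#'
#' @param x A `TaxonList`, possibly broken.
#' @return A `TaxonList` with no violations of classes V4, V5, V6, V7, V10.
#' @export
setGeneric("cleanChecklist", function(x) standardGeneric("cleanChecklist"))

#' @rdname cleanChecklist
#' @export
setMethod("cleanChecklist", "TaxonList", function(x) {
  repeat {
    changed <- FALSE
    nm <- x@taxonNames
    cp <- x@taxonConcepts
    tr <- x@taxonTraits

    keep <- nm$concept_id %in% cp$concept_id
    if (!all(keep)) {
      nm <- nm[keep, , drop = FALSE]; changed <- TRUE
    }
    keep <- tr$concept_id %in% cp$concept_id
    if (!all(keep)) {
      tr <- tr[keep, , drop = FALSE]; changed <- TRUE
    }
    bad <- !is.na(cp$parent_id) & !cp$parent_id %in% cp$concept_id
    if (any(bad)) {
      cp$parent_id[bad] <- NA_integer_; changed <- TRUE
    }
    bad <- !is.na(cp$view_id) & !cp$view_id %in% x@taxonViews$view_id
    if (any(bad)) {
      cp$view_id[bad] <- NA_integer_; changed <- TRUE
    }
    keep <- cp$concept_id %in% nm$concept_id
    if (!all(keep)) {
      cp <- cp[keep, , drop = FALSE]; changed <- TRUE
    }
    # repair broken accepted-name pointers on surviving concepts
    if (nrow(cp)) {
      ix <- match(cp$accepted_name_id, nm$usage_id)
      ok <- !is.na(cp$accepted_name_id) & !is.na(ix) &
        nm$concept_id[ifelse(is.na(ix), 1L, ix)] == cp$concept_id
      if (any(!ok)) {
        for (i in which(!ok)) {
          own <- nm$usage_id[nm$concept_id == cp$concept_id[i]]
          cp$accepted_name_id[i] <- min(own)
        }
        changed <- TRUE
      }
    }

    rownames(nm) <- NULL; rownames(cp) <- NULL; rownames(tr) <- NULL
    x@taxonNames <- nm
    x@taxonConcepts <- cp
    x@taxonTraits <- tr
    if (!changed) break
  }
  x
})
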
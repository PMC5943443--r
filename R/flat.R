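# Import of flat synonymy tables: one row per usage name, concepts encoded
# by a shared concept id and an accepted flag.

flatReserved <- c("taxon_concept_id", "taxon_usage_id", "full_name",
                  "author", "is_accepted", "rank", "parent_concept_id")

#' Build a TaxonList from a flat synonymy table
#'
#' Accepts either a character vector of accepted names (each becomes its own
#' concept, no synonyms, authority `NA`) or a data.frame with one row per
#' usage name:
#'
#' * `taxon_concept_id` (integer, required) — rows sharing an id form one
#'   concept;
#' * `is_accepted` (logical, required) — exactly one `TRUE` row per concept;
#' * `full_name` (required) and `author`;
#' * `taxon_usage_id` (optional) — missing ids are auto-assigned max+1;
#' * `rank` (optional) — requires `ranks` (the ladder) to be given;
#' * `parent_concept_id` (optional) — read from the accepted row of each
#'   concept;
#' * any further column becomes a trait variable, taken from the accepted row
#'   of each concept (all-`NA` records are dropped).
#'
#' Import errors (zero or multiple accepted rows for a concept, duplicated
#' combinations, dangling parent ids, duplicated explicit usage ids) are
#' reported with the offending row numbers.
#'
#' @param x Character vector of accepted names, or data.frame as above.
#' @param ranks Rank ladder (lowest first); required when `x` has a `rank`
#'   column.
#' @return A valid `TaxonList` (no views; hierarchy only via
#'   `parent_concept_id`).
#' @examples
#' flatToTaxonList(c("Cyperus papyrus", "Cyperus dives"))
#' @export
flatToTaxonList <- function(x, ranks = character()) {
  if (is.character(x)) {
    x <- data.frame(taxon_concept_id = seq_along(x), full_name = x,
                    author = NA_character_, is_accepted = TRUE,
                    stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(x))
  req <- c("taxon_concept_id", "full_name", "is_accepted")
  if (!all(req %in% names(x))) {
    stop("flat table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(x)
  if (!n) return(TaxonList(rankLadder = ranks))
  cid <- asIntCol(x$taxon_concept_id, "taxon_concept_id")
  acc <- as.logical(x$is_accepted)
  full <- normString(x$full_name)
  auth <- if ("author" %in% names(x)) asChrCol(x$author)
          else rep(NA_character_, n)
  if (any(is.na(cid)) || any(is.na(acc))) {
    stop("rows ", paste(which(is.na(cid) | is.na(acc)), collapse = ", "),
         ": taxon_concept_id and is_accepted must not be missing",
         call. = FALSE)
  }

  errs <- character()
  nAcc <- tapply(acc, cid, sum)
  for (bad in names(nAcc)[nAcc != 1L]) {
    inConcept <- cid == as.integer(bad)
    rows <- if (nAcc[[bad]] > 1L) which(inConcept & acc) else which(inConcept)
    errs <- c(errs, sprintf(
      "concept %s has %d accepted rows (rows %s)", bad, nAcc[[bad]],
      paste(rows, collapse = ",")))
  }
  key <- comboKey(full, auth)
  for (k in unique(key[duplicated(key)])) {
    errs <- c(errs, sprintf("duplicated combination in rows %s",
                            paste(which(key == k), collapse = ",")))
  }
  uid <- if ("taxon_usage_id" %in% names(x)) {
    asIntCol(x$taxon_usage_id, "taxon_usage_id")
  } else rep(NA_integer_, n)
  dupu <- unique(uid[!is.na(uid)][duplicated(uid[!is.na(uid)])])
  for (u in dupu) {
    errs <- c(errs, sprintf("duplicated taxon_usage_id %d in rows %s", u,
                            paste(which(!is.na(uid) & uid == u),
                                  collapse = ",")))
  }
  pid <- if ("parent_concept_id" %in% names(x)) {
    asIntCol(x$parent_concept_id, "parent_concept_id")
  } else rep(NA_integer_, n)
  bad <- which(!is.na(pid) & !pid %in% cid)
  if (length(bad)) {
    errs <- c(errs, sprintf(
      "rows %s: parent_concept_id not present as a concept in the table",
      paste(bad, collapse = ",")))
  }
  rk <- if ("rank" %in% names(x)) asChrCol(x$rank) else rep(NA_character_, n)
  if (any(!is.na(rk)) && !length(ranks)) {
    stop("the table carries ranks; supply the rank ladder via 'ranks'",
         call. = FALSE)
  }
  if (length(errs)) {
    stop("flat-table import failed:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  }

  if (any(is.na(uid))) uid[is.na(uid)] <- nextIds(uid, sum(is.na(uid)))

  nm <- data.frame(usage_id = uid, concept_id = cid, full_name = full,
                   author = auth, stringsAsFactors = FALSE)
  accIdx <- which(acc)
  cp <- data.frame(concept_id = cid[accIdx], accepted_name_id = uid[accIdx],
                   parent_id = pid[accIdx], rank = rk[accIdx],
                   view_id = NA_integer_, stringsAsFactors = FALSE)
  traitCols <- setdiff(names(x), flatReserved)
  tr <- emptyTaxonTraits()
  if (length(traitCols)) {
    tr <- data.frame(concept_id = cid[accIdx], stringsAsFactors = FALSE)
    for (cc in traitCols) tr[[cc]] <- x[[cc]][accIdx]
    allNA <- apply(as.data.frame(tr[traitCols]), 1L,
                   function(r) all(is.na(r)))
    tr <- tr[!allNA, , drop = FALSE]
  }
  out <- TaxonList(taxonNames = nm, taxonConcepts = cp, taxonTraits = tr,
                   rankLadder = ranks)
  v <- validateChecklist(out)
  if (nrow(v)) {
    stop("flat-table import produced an invalid list:\n  ",
         paste(v$message, collapse = "\n  "), call. = FALSE)
  }
  out
}
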
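# Native persistence: a zip container holding the four tables as CSV plus a
# JSON metadata member carrying the rank ladder, column classes and a format
# version. Round trips are exact at the value level (ids as integers, NA as
# empty fields; the model never holds "" — see TaxonList()).

archiveFormat <- "taxotables-archive"
archiveVersion <- 1L
archiveMembers <- c("names.csv", "concepts.csv", "views.csv", "traits.csv",
                    "metadata.json")

colClassOf <- function(tbl) vapply(tbl, function(col) class(col)[1L], "")

writeTableCSV <- function(tbl, path) {
  utils::write.csv(tbl, path, row.names = FALSE, na = "")
}

readTableCSV <- function(path, classes) {
  tbl <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (!identical(sort(names(tbl)), sort(names(classes)))) {
    stop("archive table ", basename(path), " has unexpected columns",
         call. = FALSE)
  }
  tbl <- tbl[names(classes)]
  for (cc in names(classes)) {
    v <- tbl[[cc]]
    v[v == ""] <- NA
    tbl[[cc]] <- switch(classes[[cc]],
                        integer = as.integer(v),
                        numeric = as.numeric(v),
                        logical = as.logical(v),
                        character = v,
                        v)
  }
  tbl
}

#' Write a TaxonList to its native archive
#'
#' The archive is a zip file containing `names.csv`, `concepts.csv`,
#' `views.csv`, `traits.csv` (comma-delimited, header row, UTF-8, missing
#' values as empty fields) and `metadata.json` (format tag, version, rank
#' ladder, per-column classes). Member timestamps are pinned to a fixed
#' epoch, so identical lists produce byte-identical archives.
#'
#' @param x A valid `TaxonList`.
#' @param path Output path (conventionally `.zip`).
#' @return `path`, invisibly.
#' @seealso [readArchive()], [backupChecklist()]
#' @export
writeArchive <- function(x, path) {
  assertValid(x, "writeArchive")
  tmp <- tempfile("taxarchive")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  tabs <- list(`names.csv` = x@taxonNames, `concepts.csv` = x@taxonConcepts,
               `views.csv` = x@taxonViews, `traits.csv` = x@taxonTraits)
  for (f in names(tabs)) writeTableCSV(tabs[[f]], file.path(tmp, f))
  meta <- list(format = archiveFormat, version = archiveVersion,
               ranks = as.list(x@rankLadder),
               columns = lapply(tabs, function(t) as.list(colClassOf(t))))
  jsonlite::write_json(meta, file.path(tmp, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  members <- file.path(tmp, archiveMembers)
  Sys.setFileTime(members, as.POSIXct("2020-01-01 00:00:00", tz = "UTC"))
  if (file.exists(path)) unlink(path)
  zip::zip(normalizePath(path, mustWork = FALSE), archiveMembers,
           root = tmp, include_directories = FALSE, mode = "cherry-pick")
  invisible(path)
}

#' Read a TaxonList from its native archive
#'
#' Restores all four tables (column order, classes and ids included) and the
#' rank ladder. A missing member or a format/version mismatch is an error.
#' With `check = TRUE` (default) the restored list is audited with
#' [validateChecklist()] and violations abort the read; `check = FALSE`
#' returns the list as stored so it can be audited or repaired.
#'
#' @param path Archive path written by [writeArchive()].
#' @param check Audit the restored list (default `TRUE`).
#' @return A `TaxonList`.
#' @export
readArchive <- function(path, check = TRUE) {
  if (!file.exists(path)) stop("no such archive: ", path, call. = FALSE)
  tmp <- tempfile("taxarchive")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  got <- tryCatch(zip::zip_list(path)$filename,
                  error = function(e) stop("corrupt archive: ", path,
                                           call. = FALSE))
  missing <- setdiff(archiveMembers, got)
  if (length(missing)) {
    stop("archive is missing member(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  zip::unzip(path, files = archiveMembers, exdir = tmp)
  meta <- jsonlite::read_json(file.path(tmp, "metadata.json"))
  if (!identical(meta$format, archiveFormat)) {
    stop("not a ", archiveFormat, " file: ", path, call. = FALSE)
  }
  if (!identical(as.integer(meta$version), archiveVersion)) {
    stop("unsupported archive version ", meta$version, call. = FALSE)
  }
  tabs <- lapply(c("names.csv", "concepts.csv", "views.csv", "traits.csv"),
                 function(f) {
                   classes <- unlist(meta$columns[[f]])
                   readTableCSV(file.path(tmp, f), classes)
                 })
  out <- TaxonList(taxonNames = tabs[[1L]], taxonConcepts = tabs[[2L]],
                   taxonViews = tabs[[3L]], taxonTraits = tabs[[4L]],
                   rankLadder = unlist(meta$ranks, use.names = FALSE))
  if (check) {
    v <- validateChecklist(out)
    if (nrow(v)) {
      stop("archive fails validation:\n  ",
           paste(v$message, collapse = "\n  "), call. = FALSE)
    }
  }
  out
}

backupPattern <- function(baseName) {
  paste0("^", gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", baseName),
         "_(\\d{4}-\\d{2}-\\d{2})(?:_(\\d+))?\\.zip$")
}

#' Timestamped backups
#'
#' `backupChecklist()` writes the list as a native archive named
#' `<base>_<YYYY-MM-DD>.zip`; when that file already exists the name gets a
#' suffix `_1`, `_2`, ... (first free slot). `loadLast()` scans a directory
#' for backups of `baseName`, picks the latest date and, within a date, the
#' highest suffix (no suffix sorts below `_1`), and restores it. Selection
#' parses filenames only — file modification times are ignored for
#' portability.
#'
#' @param x A valid `TaxonList`.
#' @param basePath Path prefix, e.g. `"backups/easplist"`; directory part
#'   must exist or is created.
#' @param date Stamp date (default today); exposed so tests can exercise the
#'   date ordering.
#' @return `backupChecklist()`: the written filename, invisibly.
#' @export
backupChecklist <- function(x, basePath, date = Sys.Date()) {
  dir <- dirname(basePath)
  base <- basename(basePath)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- format(as.Date(date), "%Y-%m-%d")
  cand <- file.path(dir, paste0(base, "_", stamp, ".zip"))
  k <- 0L
  while (file.exists(cand)) {
    k <- k + 1L
    cand <- file.path(dir, paste0(base, "_", stamp, "_", k, ".zip"))
  }
  writeArchive(x, cand)
  invisible(cand)
}

#' @rdname backupChecklist
#' @param directory Directory to scan.
#' @param baseName Backup base name (the `<base>` part of the filenames).
#' @param check Passed to [readArchive()].
#' @return `loadLast()`: the restored `TaxonList`.
#' @export
loadLast <- function(directory, baseName, check = TRUE) {
  files <- list.files(directory)
  m <- regmatches(files, regexec(backupPattern(baseName), files))
  hit <- vapply(m, length, 1L) == 3L
  if (!any(hit)) {
    stop("no backup found for '", baseName, "' in ", directory,
         call. = FALSE)
  }
  files <- files[hit]
  dates <- as.Date(vapply(m[hit], `[`, "", 2L))
  sufStr <- vapply(m[hit], `[`, "", 3L)
  sufs <- integer(length(sufStr))
  sufs[sufStr != ""] <- as.integer(sufStr[sufStr != ""])
  ord <- order(dates, sufs, decreasing = TRUE)
  readArchive(file.path(directory, files[ord[1L]]), check = check)
}
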
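# Minimal dBase III (DBF) reader and writer, covering the subset the
# Turboveg species-list dialect uses: character (C), numeric (N, integral)
# and logical (L) fields, no memo files, no deleted-record recovery. Written
# in-package because no DBF-capable package is available in the dependency
# stack; this is I/O plumbing, not a general xBase implementation.

#' Read a dBase III (DBF) table
#'
#' Supports character (`C`), numeric (`N`) and logical (`L`) fields. Records
#' flagged as deleted are skipped. Character fields are trimmed and decoded
#' from `encoding`; empty strings become `NA` (consistent with the rest of
#' the package). `N` fields without decimals are returned as integer when
#' they fit.
#'
#' @param path Path to a `.dbf` file.
#' @param encoding Text encoding of character fields (DBF headers are
#'   unreliable, so this is explicit); default `"latin1"`, the usual
#'   Turboveg setting.
#' @return A data.frame.
#' @export
readDBF <- function(path, encoding = "latin1") {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 33L) stop("not a DBF file: ", path, call. = FALSE)
  u8 <- function(i) as.integer(raw[i])
  u16 <- function(i) u8(i) + 256L * u8(i + 1L)
  u32 <- function(i) u8(i) + 256L * (u8(i + 1L) + 256L *
                                       (u8(i + 2L) + 256L * u8(i + 3L)))
  nRec <- u32(5L)
  headerSize <- u16(9L)
  recSize <- u16(11L)
  nFields <- (headerSize - 33L) %/% 32L
  if (nFields < 1L) stop("DBF file declares no fields: ", path,
                         call. = FALSE)
  fields <- vector("list", nFields)
  for (f in seq_len(nFields)) {
    off <- 32L * f + 1L  # 1-based offset of this descriptor
    nameBytes <- raw[off:(off + 10L)]
    nz <- which(nameBytes == as.raw(0L))
    nm <- rawToChar(if (length(nz)) nameBytes[seq_len(min(nz) - 1L)]
                    else nameBytes)
    fields[[f]] <- list(name = nm,
                        type = rawToChar(raw[off + 11L]),
                        length = u8(off + 16L),
                        decimals = u8(off + 17L))
  }
  fieldNames <- vapply(fields, `[[`, "", "name")
  lens <- vapply(fields, `[[`, 0L, "length")

  cols <- lapply(fields, function(fd) rep(NA_character_, nRec))
  keep <- rep(TRUE, nRec)
  pos <- headerSize + 1L
  for (r in seq_len(nRec)) {
    if (pos + recSize - 1L > length(raw)) {
      stop("truncated DBF file: ", path, call. = FALSE)
    }
    if (raw[pos] == charToRaw("*")) keep[r] <- FALSE
    p <- pos + 1L
    for (f in seq_len(nFields)) {
      bytes <- raw[p:(p + lens[f] - 1L)]
      bytes[bytes == as.raw(0L)] <- as.raw(32L)  # stray NULs -> blanks
      val <- iconv(rawToChar(bytes), from = encoding, to = "UTF-8")
      cols[[f]][r] <- val
      p <- p + lens[f]
    }
    pos <- pos + recSize
  }
  out <- data.frame(matrix(nrow = sum(keep), ncol = 0L))
  for (f in seq_len(nFields)) {
    v <- trimws(cols[[f]][keep])
    fd <- fields[[f]]
    out[[fd$name]] <- switch(fd$type,
      C = asChrCol(v),
      N = if (fd$decimals == 0L) {
        suppressWarnings(as.integer(v))
      } else suppressWarnings(as.numeric(v)),
      L = c(`T` = TRUE, `Y` = TRUE, `F` = FALSE, `N` = FALSE)[v],
      asChrCol(v))
  }
  names(out) <- fieldNames
  rownames(out) <- NULL
  out
}

#' Write a data.frame as a dBase III (DBF) table
#'
#' Integer/numeric columns become `N` fields, logicals `L`, everything else
#' `C` (encoded to `encoding`, width = longest value, capped at 254 bytes).
#' `NA` is written as blanks (`?` for logicals), the convention [readDBF()]
#' reads back as `NA`.
#'
#' @param df A data.frame.
#' @param path Output `.dbf` path.
#' @param encoding Encoding for character fields (default `"latin1"`).
#' @return `path`, invisibly.
#' @export
writeDBF <- function(df, path, encoding = "latin1") {
  stopifnot(is.data.frame(df))
  if (any(nchar(names(df)) > 10L)) {
    stop("DBF field names are limited to 10 characters: ",
         paste(names(df)[nchar(names(df)) > 10L], collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(df)
  # encode per-cell to raw bytes up front: mixing declared encodings through
  # paste()/formatC() silently re-encodes, so all padding is done on bytes
  encRaw <- function(s) {
    out <- iconv(s, from = "UTF-8", to = encoding, sub = "?", toRaw = TRUE)
    lapply(out, function(b) if (is.null(b)) raw() else b)
  }
  padRaw <- function(cells, len) {
    lapply(cells, function(b) {
      if (length(b) > len) b <- b[seq_len(len)]  # over-long cells truncated
      c(b, rep(as.raw(32L), len - length(b)))
    })
  }
  colSpec <- lapply(df, function(col) {
    if (is.logical(col)) {
      s <- ifelse(is.na(col), "?", ifelse(col, "T", "F"))
      list(type = "L", len = 1L, cells = lapply(s, charToRaw))
    } else if (is.numeric(col)) {
      s <- ifelse(is.na(col), "",
                  format(col, trim = TRUE, scientific = FALSE))
      len <- max(1L, nchar(s, type = "bytes"))
      # numbers are right-justified, blank-padded on the left
      list(type = "N", len = len,
           cells = lapply(formatC(s, width = len, flag = " "), charToRaw))
    } else {
      cells <- encRaw(ifelse(is.na(col), "", as.character(col)))
      len <- min(254L, max(1L, lengths(cells)))
      list(type = "C", len = len, cells = padRaw(cells, len))
    }
  })
  lens <- vapply(colSpec, `[[`, 0L, "len")
  recSize <- 1L + sum(lens)
  headerSize <- 32L + 32L * length(colSpec) + 1L

  con <- file(path, "wb")
  on.exit(close(con))
  wByte <- function(x) writeBin(as.raw(x), con)
  # header: dBase III, a fixed date stamp (determinism), counts and sizes
  wByte(0x03); wByte(c(120L, 1L, 1L))
  writeBin(as.integer(n), con, size = 4L, endian = "little")
  writeBin(as.integer(headerSize), con, size = 2L, endian = "little")
  writeBin(as.integer(recSize), con, size = 2L, endian = "little")
  wByte(rep(0L, 20L))
  for (i in seq_along(colSpec)) {
    nmBytes <- charToRaw(names(df)[i])  # field names are 10-char ASCII
    writeBin(c(nmBytes, rep(as.raw(0L), 11L - length(nmBytes))), con)
    writeBin(charToRaw(colSpec[[i]]$type), con)
    wByte(rep(0L, 4L))
    wByte(colSpec[[i]]$len)
    wByte(0L)  # decimal count: integral N fields only
    wByte(rep(0L, 14L))
  }
  wByte(0x0D)
  for (r in seq_len(n)) {
    writeBin(charToRaw(" "), con)  # not deleted
    for (i in seq_along(colSpec)) {
      writeBin(colSpec[[i]]$cells[[r]], con)
    }
  }
  wByte(0x1A)
  invisible(path)
}
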
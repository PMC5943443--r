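# Internal helpers shared across the package. Nothing here is exported.

# Whitespace normalization used for combination-uniqueness: trim and collapse
# internal runs; case is preserved (epithet case is meaningful).
normString <- function(x) {
  gsub("[[:space:]]+", " ", trimws(as.character(x)))
}

# Key identifying a combination (full name + authority). NA author counts as
# the empty authority so "L." != NA but NA == "".
comboKey <- function(full_name, author) {
  a <- ifelse(is.na(author), "", normString(author))
  paste0(normString(full_name), "\x1f", a)
}

# Coerce a column to integer, failing loudly on non-integral values.
asIntCol <- function(x, what) {
  if (is.integer(x)) return(x)
  if (is.logical(x) && all(is.na(x))) return(as.integer(x))
  xn <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & (is.na(xn) | xn != round(xn))
  if (any(bad)) {
    stop("column '", what, "' must hold integer identifiers", call. = FALSE)
  }
  as.integer(xn)
}

# Character column with "" normalized to NA (archives cannot distinguish them).
asChrCol <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & x == ""] <- NA_character_
  x
}

# Next free id(s) on a table column: max + 1, never reusing ids.
nextIds <- function(existing, n = 1L) {
  base <- if (length(existing) == 0L || all(is.na(existing))) 0L
          else max(existing, na.rm = TRUE)
  seq.int(base + 1L, length.out = n)
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  }, add = TRUE)
  set.seed(seed)
  expr
}

# sample() without the length-1 surprise.
resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}
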
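#' Read a genotype matrix file
#'
#' Reads the three grid formats the pipeline touches and returns the common
#' in-memory container. Dialects:
#'
#' * **genepop** — title line, locus names (one per line or comma-separated),
#'   `POP` separators, then `id , 0101 0202 ...`. Allele field width (2 or 3
#'   digits) is auto-detected from token length; `00`/`000` is missing.
#' * **structure** — header row of locus names, two rows per individual:
#'   `id [pop] a1 ... aL`; `-9` is missing. Set `has_pop` if a population
#'   column is present.
#' * **csv** — canonical for this package: one row per individual, metadata
#'   columns `id,population,morphology,sex,x,y,material` (any subset beyond
#'   `id`), then two columns per locus named `LOCUS.1`/`LOCUS.2`; empty cell
#'   is missing. Lossless for metadata the grid formats drop.
#'
#' @param path File path.
#' @param format One of `"genepop"`, `"structure"`, `"csv"`.
#' @param has_pop For STRUCTURE files: does column 2 hold a population label?
#' @return A [wh_dataset()].
#' @export
read_dataset <- function(path, format = c("csv", "genepop", "structure"),
                         has_pop = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         genepop   = read_genepop(path),
         structure = read_structure(path, has_pop = has_pop),
         csv       = read_csv_dataset(path))
}

#' Write a genotype matrix file
#'
#' Inverse of [read_dataset()]; `read_dataset(write_dataset(ds))` round-trips
#' genotypes bit-identically (CSV also round-trips metadata). GenePop refuses
#' allele codes that do not fit its 2- or 3-digit field.
#'
#' @param ds A [wh_dataset()].
#' @param path Output path.
#' @param format One of `"csv"`, `"genepop"`, `"structure"`.
#' @param has_pop Write a population column in STRUCTURE output.
#' @export
write_dataset <- function(ds, path, format = c("csv", "genepop", "structure"),
                          has_pop = TRUE) {
  stopifnot(inherits(ds, "wh_dataset"))
  format <- match.arg(format)
  switch(format,
         genepop   = write_genepop(ds, path),
         structure = write_structure(ds, path, has_pop = has_pop),
         csv       = write_csv_dataset(ds, path))
  invisible(NULL)
}

parse_err <- function(line, msg) stop(sprintf("parse error at line %d: %s", line, msg))

read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) stop("parse error: genepop file needs a title and locus names")
  lines <- sub("\\s+$", "", lines)
  # locus names: lines 2.. until first POP; a single comma-separated line allowed
  i <- 2L
  loci <- character(0)
  while (i <= length(lines) && !grepl("^\\s*pop\\s*$", lines[i], ignore.case = TRUE)) {
    loci <- c(loci, trimws(strsplit(lines[i], ",")[[1]]))
    i <- i + 1L
  }
  loci <- loci[nzchar(loci)]
  if (!length(loci)) parse_err(2L, "no locus names before first POP")
  if (anyDuplicated(loci)) parse_err(2L, "duplicated locus names")
  ids <- character(0); pops <- character(0)
  rows <- list(); pop_idx <- 0L
  while (i <= length(lines)) {
    if (grepl("^\\s*pop\\s*$", lines[i], ignore.case = TRUE)) {
      pop_idx <- pop_idx + 1L; i <- i + 1L; next
    }
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    parts <- strsplit(lines[i], ",")[[1]]
    if (length(parts) < 2L) parse_err(i, "expected 'id , genotypes'")
    id <- trimws(parts[1])
    toks <- strsplit(trimws(paste(parts[-1], collapse = ",")), "\\s+")[[1]]
    if (length(toks) != length(loci))
      parse_err(i, sprintf("expected %d genotype tokens, found %d",
                           length(loci), length(toks)))
    wid <- unique(nchar(toks))
    if (length(wid) != 1L || !wid %in% c(4L, 6L))
      parse_err(i, "genotype tokens must be uniformly 4 (2-digit) or 6 (3-digit) characters")
    half <- wid / 2L
    a <- as.integer(substr(toks, 1L, half))
    b <- as.integer(substr(toks, half + 1L, wid))
    if (anyNA(a) || anyNA(b)) parse_err(i, "non-numeric allele code")
    a[a == 0L] <- NA; b[b == 0L] <- NA
    if (any(xor(is.na(a), is.na(b)))) parse_err(i, "half-missing genotype (one allele 0)")
    ids <- c(ids, id); pops <- c(pops, paste0("pop", pop_idx))
    rows[[length(rows) + 1L]] <- list(a = a, b = b)
    i <- i + 1L
  }
  if (anyDuplicated(ids)) stop("parse error: duplicated individual IDs")
  A <- do.call(rbind, lapply(rows, `[[`, "a"))
  B <- do.call(rbind, lapply(rows, `[[`, "b"))
  if (is.null(A)) { A <- matrix(NA_integer_, 0, length(loci)); B <- A }
  rownames(A) <- ids; colnames(A) <- loci
  wh_dataset(A, B, data.frame(id = ids, population = pops,
                              stringsAsFactors = FALSE))
}

write_genepop <- function(ds, path) {
  mx <- suppressWarnings(max(c(ds$a, ds$b), na.rm = TRUE))
  digits <- if (is.finite(mx) && mx > 99L) 3L else 2L
  if (is.finite(mx) && mx >= 10^digits)
    stop("allele code ", mx, " exceeds the genepop ", digits, "-digit field width")
  if (any(c(ds$a, ds$b) < 1L, na.rm = TRUE))
    stop("genepop requires positive allele codes (0 is reserved for missing)")
  fmt <- function(x) {
    x[is.na(x)] <- 0L
    formatC(x, width = digits, flag = "0")
  }
  pops <- if ("population" %in% names(ds$meta)) as.character(ds$meta$population)
          else rep("pop1", length(ds$ids))
  out <- c("wildhyb genepop export", ds$loci)
  for (p in unique(pops)) {
    out <- c(out, "POP")
    for (i in which(pops == p)) {
      toks <- paste0(fmt(ds$a[i, ]), fmt(ds$b[i, ]))
      out <- c(out, paste0(ds$ids[i], " , ", paste(toks, collapse = " ")))
    }
  }
  if (!length(ds$ids)) out <- c(out, "POP")
  writeLines(out, path)
}

read_structure <- function(path, has_pop = TRUE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("parse error: empty structure file")
  loci <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (anyDuplicated(loci)) parse_err(1L, "duplicated locus names")
  body <- lines[-1]
  if (length(body) %% 2L != 0L)
    stop("parse error: structure two-row file has an odd number of genotype rows")
  nmeta <- if (has_pop) 2L else 1L
  ids <- character(0); pops <- character(0)
  A <- list(); B <- list()
  for (j in seq_len(length(body) / 2L)) {
    r1 <- strsplit(trimws(body[2L * j - 1L]), "\\s+")[[1]]
    r2 <- strsplit(trimws(body[2L * j]), "\\s+")[[1]]
    ln <- 2L * j  # line number within body + header offset
    if (length(r1) != nmeta + length(loci) || length(r2) != nmeta + length(loci))
      parse_err(ln + 1L, sprintf("expected %d columns", nmeta + length(loci)))
    if (r1[1] != r2[1]) parse_err(ln + 1L, "two-row pair has mismatching IDs")
    a <- suppressWarnings(as.integer(r1[-seq_len(nmeta)]))
    b <- suppressWarnings(as.integer(r2[-seq_len(nmeta)]))
    if (anyNA(a) || anyNA(b)) parse_err(ln + 1L, "non-numeric allele code")
    a[a == -9L] <- NA; b[b == -9L] <- NA
    if (any(xor(is.na(a), is.na(b))))
      parse_err(ln + 1L, "half-missing genotype (single -9)")
    ids <- c(ids, r1[1])
    pops <- c(pops, if (has_pop) r1[2] else "pop1")
    A[[j]] <- a; B[[j]] <- b
  }
  if (anyDuplicated(ids)) stop("parse error: duplicated individual IDs")
  A <- do.call(rbind, A); B <- do.call(rbind, B)
  if (is.null(A)) { A <- matrix(NA_integer_, 0, length(loci)); B <- A }
  rownames(A) <- ids; colnames(A) <- loci
  wh_dataset(A, B, data.frame(id = ids, population = pops,
                              stringsAsFactors = FALSE))
}

write_structure <- function(ds, path, has_pop = TRUE) {
  pops <- if ("population" %in% names(ds$meta)) as.character(ds$meta$population)
          else rep("1", length(ds$ids))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(ds$loci, collapse = " "), con)
  rowtxt <- function(id, pop, al) {
    al[is.na(al)] <- -9L
    paste(c(id, if (has_pop) pop, al), collapse = " ")
  }
  for (i in seq_along(ds$ids)) {
    writeLines(rowtxt(ds$ids[i], pops[i], ds$a[i, ]), con)
    writeLines(rowtxt(ds$ids[i], pops[i], ds$b[i, ]), con)
  }
}

META_COLS <- c("id", "population", "morphology", "sex", "x", "y", "material",
               "family")

read_csv_dataset <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"id" %in% names(df)) stop("parse error: csv dataset needs an 'id' column")
  gcols <- grep("\\.[12]$", names(df), value = TRUE)
  loci <- unique(sub("\\.[12]$", "", gcols))
  for (l in loci) {
    need <- paste0(l, c(".1", ".2"))
    if (!all(need %in% names(df)))
      stop("parse error: locus ", l, " lacks one of its two allele columns")
  }
  if (!length(loci)) stop("parse error: no LOCUS.1/LOCUS.2 genotype columns found")
  A <- sapply(loci, function(l) as.integer(df[[paste0(l, ".1")]]))
  B <- sapply(loci, function(l) as.integer(df[[paste0(l, ".2")]]))
  if (length(df$id) == 1L) { A <- matrix(A, 1L); B <- matrix(B, 1L) }
  if (!length(df$id)) { A <- matrix(NA_integer_, 0, length(loci)); B <- A }
  rownames(A) <- df$id; colnames(A) <- loci
  meta <- df[intersect(META_COLS, names(df))]
  wh_dataset(A, B, meta)
}

write_csv_dataset <- function(ds, path) {
  meta <- ds$meta[intersect(META_COLS, names(ds$meta))]
  gm <- matrix(NA_integer_, nrow(ds$a), 2L * length(ds$loci))
  gm[, seq_along(ds$loci) * 2L - 1L] <- ds$a
  gm[, seq_along(ds$loci) * 2L] <- ds$b
  colnames(gm) <- as.vector(rbind(paste0(ds$loci, ".1"), paste0(ds$loci, ".2")))
  g <- as.data.frame(gm)
  utils::write.csv(cbind(meta, g), path, row.names = FALSE, na = "")
}

#' Read or write a long-format coordinates table
#'
#' Individuals sampled several times have several rows; columns `id,x,y`
#' (optional `date`). Used by [pair_distances()].
#'
#' @param path CSV path.
#' @return Data frame with columns `id`, `x`, `y`.
#' @export
read_coordinates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "x", "y") %in% names(df)))
    stop("coordinates file needs columns id,x,y")
  df
}
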
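#' Multilocus genotype dataset
#'
#' The common currency of the pipeline: an individuals x loci grid of
#' codominant genotypes plus per-individual metadata. Each genotype is an
#' unordered pair of integer allele codes; a pair is either fully called or
#' fully missing (`NA`). Allele codes are opaque integers (typically fragment
#' lengths in bp).
#'
#' @param a,b Integer matrices (individuals x loci) holding the two allele
#'   codes per genotype. Row names are individual IDs, column names locus
#'   names. `NA` marks missing; `is.na(a)` must equal `is.na(b)`.
#' @param meta Data frame of per-individual metadata with at least column
#'   `id` matching `rownames(a)`. Recognised columns: `population`,
#'   `morphology` ("catus", "silvestris" or "unknown"), `sex` ("F", "M" or
#'   "unknown"), `x`, `y` (projected metres), `material`
#'   ("blood", "hair", "feces"), `family` (pedigree label from simulators).
#' @return An object of class `wh_dataset` with elements `a`, `b` (pairs
#'   stored in canonical order `a <= b`), `loci`, `ids`, `meta`.
#' @export
wh_dataset <- function(a, b, meta = NULL) {
  a <- as.matrix(a); b <- as.matrix(b)
  storage.mode(a) <- "integer"; storage.mode(b) <- "integer"
  if (!identical(dim(a), dim(b)))
    stop("allele matrices 'a' and 'b' must have identical dimensions")
  if (!identical(unname(is.na(a)), unname(is.na(b))))
    stop("half-missing genotypes are invalid: both alleles present or both missing")
  if (is.null(dimnames(a))) dimnames(a) <- list(NULL, NULL)
  if (is.null(dimnames(b))) dimnames(b) <- list(NULL, NULL)
  if (is.null(rownames(a)) && nrow(a))
    rownames(a) <- paste0("ind", seq_len(nrow(a)))
  if (is.null(colnames(a)) && ncol(a))
    colnames(a) <- paste0("L", seq_len(ncol(a)))
  dimnames(b) <- dimnames(a)
  ids <- rownames(a) %||% character(0)
  if (anyDuplicated(ids)) stop("duplicated individual IDs")
  if (anyDuplicated(colnames(a))) stop("duplicated locus names")
  # canonical unordered storage: a <= b
  swap <- !is.na(a) & a > b
  if (any(swap)) {
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  }
  if (is.null(meta)) meta <- data.frame(id = ids, stringsAsFactors = FALSE)
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (!"id" %in% names(meta)) stop("meta must contain an 'id' column")
  if (!setequal(meta$id, ids) || anyDuplicated(meta$id))
    stop("meta$id must match the dataset's individual IDs exactly")
  meta <- meta[match(ids, meta$id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(
    list(a = a, b = b, loci = colnames(a) %||% character(0), ids = ids,
         meta = meta),
    class = "wh_dataset"
  )
}

#' @export
print.wh_dataset <- function(x, ...) {
  cat(sprintf("<wh_dataset> %d individuals x %d loci\n",
              length(x$ids), length(x$loci)))
  miss <- mean(is.na(x$a))
  cat(sprintf("  missing genotypes: %.1f%%\n", 100 * miss))
  if ("population" %in% names(x$meta)) {
    tab <- table(x$meta$population)
    cat("  populations:", paste(sprintf("%s (%d)", names(tab), tab),
                                collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.wh_dataset <- function(x) c(length(x$ids), length(x$loci))

#' Subset a dataset by individuals and/or loci
#'
#' @param ds A [wh_dataset()].
#' @param individuals,loci Character, integer or logical index vectors;
#'   `NULL` keeps everything.
#' @return A `wh_dataset`.
#' @export
subset_dataset <- function(ds, individuals = NULL, loci = NULL) {
  stopifnot(inherits(ds, "wh_dataset"))
  ii <- if (is.null(individuals)) seq_along(ds$ids) else individuals
  if (is.character(ii)) ii <- match(ii, ds$ids)
  ll <- if (is.null(loci)) seq_along(ds$loci) else loci
  if (is.character(ll)) ll <- match(ll, ds$loci)
  if (anyNA(ii)) stop("unknown individual ID in subset")
  if (anyNA(ll)) stop("unknown locus name in subset")
  wh_dataset(ds$a[ii, ll, drop = FALSE], ds$b[ii, ll, drop = FALSE],
             ds$meta[if (is.logical(ii)) which(ii) else ii, , drop = FALSE])
}

#' Combine datasets over the same locus panel
#'
#' @param ... `wh_dataset` objects sharing an identical locus panel.
#' @return A `wh_dataset` stacking all individuals.
#' @export
bind_datasets <- function(...) {
  dss <- list(...)
  if (length(dss) == 1L && is.list(dss[[1]]) && !inherits(dss[[1]], "wh_dataset"))
    dss <- dss[[1]]
  stopifnot(length(dss) >= 1L, all(vapply(dss, inherits, TRUE, "wh_dataset")))
  loci <- dss[[1]]$loci
  for (d in dss) if (!identical(d$loci, loci))
    stop("datasets must share an identical locus panel")
  metas <- lapply(dss, `[[`, "meta")
  cols <- Reduce(union, lapply(metas, names))
  metas <- lapply(metas, function(m) {
    for (cl in setdiff(cols, names(m))) m[[cl]] <- NA
    m[cols]
  })
  wh_dataset(do.call(rbind, lapply(dss, `[[`, "a")),
             do.call(rbind, lapply(dss, `[[`, "b")),
             do.call(rbind, metas))
}

#' Per-population allele frequencies
#'
#' Sample allele frequencies from called genotypes, per locus, within each
#' population (or over the whole dataset).
#'
#' @param ds A [wh_dataset()].
#' @param by Metadata column to group by, or `NULL` for a single pooled group.
#' @param exclude Individual IDs to leave out (used e.g. for leave-pair-out
#'   relatedness).
#' @return Named list (one element per group) of named lists (one per locus)
#'   of named frequency vectors; names are allele codes as characters.
#' @export
allele_freqs <- function(ds, by = "population", exclude = NULL) {
  stopifnot(inherits(ds, "wh_dataset"))
  keep <- !(ds$ids %in% exclude)
  groups <- if (is.null(by)) rep("all", length(ds$ids)) else as.character(ds$meta[[by]])
  out <- list()
  for (g in unique(groups[keep])) {
    sel <- keep & groups == g
    out[[g]] <- lapply(seq_along(ds$loci), function(l) {
      al <- c(ds$a[sel, l], ds$b[sel, l])
      al <- al[!is.na(al)]
      if (!length(al)) return(numeric(0))
      tab <- table(al)
      stats::setNames(as.numeric(tab) / sum(tab), names(tab))
    })
    names(out[[g]]) <- ds$loci
  }
  out
}

#' Extract one individual's genotype vectors
#'
#' @param ds A [wh_dataset()].
#' @param id Individual ID or index.
#' @return List with integer vectors `a` and `b` (canonical order), named by
#'   locus.
#' @export
genotype_of <- function(ds, id) {
  i <- if (is.character(id)) match(id, ds$ids) else id
  if (is.na(i)) stop("unknown individual: ", id)
  list(a = stats::setNames(ds$a[i, ], ds$loci),
       b = stats::setNames(ds$b[i, ], ds$loci))
}
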
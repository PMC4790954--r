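#' @keywords internal
CALL_CODES <- c("AA", "AB", "BB")

#' Construct a genotype table
#'
#' The central container for an F2 family genotyped at biallelic SNP markers:
#' a marker-by-individual matrix of co-dominant calls (`"AA"`, `"AB"`, `"BB"`,
#' `NA` for missing) together with per-call read depths and per-marker
#' metadata.  The selfed F1 progenitor, when genotyped alongside the progeny,
#' is flagged by its sample id so that downstream intercross-marker calling
#' can condition on its heterozygosity.
#'
#' @param calls Character matrix (markers x individuals) with values `"AA"`,
#'   `"AB"`, `"BB"` or `NA`; rownames are marker ids, colnames sample ids.
#' @param depths Integer matrix of the same dimensions; per-call read depth,
#'   `0` when unknown.
#' @param markers A data frame with columns `id`, `chrom`, `pos`, `ref`, `alt`
#'   (one row per marker, same order as `calls`).  Missing columns are filled
#'   with `NA`.
#' @param progenitor Sample id of the F1 progenitor, or `NULL` if absent.
#'
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(calls, depths = NULL, markers = NULL,
                           progenitor = NULL) {
  stopifnot(is.matrix(calls))
  if (is.null(colnames(calls))) {
    colnames(calls) <- paste0("ind", seq_len(ncol(calls)))
  }
  if (is.null(rownames(calls))) {
    rownames(calls) <- paste0("m", seq_len(nrow(calls)))
  }
  if (anyDuplicated(colnames(calls))) {
    stop("sample ids must be unique", call. = FALSE)
  }
  bad <- !is.na(calls) & !(calls %in% CALL_CODES)
  if (any(bad)) {
    stop("calls contain codes outside {AA, AB, BB, NA}: ",
         paste(unique(calls[bad]), collapse = ", "), call. = FALSE)
  }
  if (is.null(depths)) {
    depths <- matrix(0L, nrow(calls), ncol(calls),
                     dimnames = dimnames(calls))
  }
  storage.mode(depths) <- "integer"
  stopifnot(identical(dim(depths), dim(calls)))
  if (any(depths < 0, na.rm = TRUE)) stop("depths must be non-negative", call. = FALSE)
  dimnames(depths) <- dimnames(calls)
  if (is.null(markers)) {
    markers <- tibble::tibble(id = rownames(calls), chrom = NA_character_,
                              pos = NA_integer_, ref = NA_character_,
                              alt = NA_character_)
  } else {
    markers <- tibble::as_tibble(markers)
    for (col in c("chrom", "ref", "alt")) {
      if (is.null(markers[[col]])) markers[[col]] <- NA_character_
    }
    if (is.null(markers[["pos"]])) markers[["pos"]] <- NA_integer_
    stopifnot(identical(as.character(markers$id), rownames(calls)))
  }
  if (!is.null(progenitor)) {
    if (!progenitor %in% colnames(calls)) {
      stop("progenitor '", progenitor, "' not among samples: ",
           paste(utils::head(colnames(calls), 10), collapse = ", "),
           call. = FALSE)
    }
  }
  structure(
    list(calls = calls, depths = depths, markers = markers,
         progenitor = progenitor %||% NA_character_),
    class = "genotype_table"
  )
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("<genotype_table> %d markers x %d individuals\n",
              nrow(x$calls), ncol(x$calls)))
  if (!is.na(x$progenitor)) cat("  progenitor:", x$progenitor, "\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$calls)

#' Long-format view of a genotype table
#'
#' @param x A `genotype_table`.
#' @param ... Unused.
#' @return A tibble with one row per (marker, individual) call.
#' @importFrom tibble as_tibble
#' @method as_tibble genotype_table
#' @export
as_tibble.genotype_table <- function(x, ...) {
  tibble::tibble(
    marker = rep(rownames(x$calls), times = ncol(x$calls)),
    sample = rep(colnames(x$calls), each = nrow(x$calls)),
    call = ifelse(is.na(as.vector(x$calls)), "MISSING", as.vector(x$calls)),
    depth = as.vector(x$depths)
  )
}

#' Subset a genotype table
#'
#' @param x A `genotype_table`.
#' @param markers Marker ids or indices to keep (default all).
#' @param samples Sample ids or indices to keep (default all).
#' @return A `genotype_table`.
#' @export
gt_subset <- function(x, markers = NULL, samples = NULL) {
  mi <- if (is.null(markers)) seq_len(nrow(x$calls)) else markers
  si <- if (is.null(samples)) seq_len(ncol(x$calls)) else samples
  calls <- x$calls[mi, si, drop = FALSE]
  prog <- if (!is.na(x$progenitor) && x$progenitor %in% colnames(calls)) {
    x$progenitor
  } else NULL
  mk <- x$markers[match(rownames(calls), x$markers$id), , drop = FALSE]
  genotype_table(calls, x$depths[mi, si, drop = FALSE], mk, prog)
}

#' Drop the progenitor column, returning the progeny-only table
#' @param x A `genotype_table`.
#' @return A `genotype_table` without the progenitor sample.
#' @export
gt_progeny <- function(x) {
  if (is.na(x$progenitor)) return(x)
  keep <- setdiff(colnames(x$calls), x$progenitor)
  gt_subset(x, samples = keep)
}

#' Genotype counts per marker
#'
#' Tallies AA/AB/BB calls per marker over the progeny (the progenitor column,
#' if flagged, is excluded).
#'
#' @param x A `genotype_table`.
#' @return A tibble with columns `marker`, `n_AA`, `n_AB`, `n_BB`, `n_missing`.
#' @export
gt_counts <- function(x) {
  p <- gt_progeny(x)
  cnt <- function(code) rowSums(p$calls == code, na.rm = TRUE)
  tibble::tibble(
    marker = rownames(p$calls),
    n_AA = cnt("AA"), n_AB = cnt("AB"), n_BB = cnt("BB"),
    n_missing = rowSums(is.na(p$calls))
  )
}
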
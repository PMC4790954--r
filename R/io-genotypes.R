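#' Read genotype calls from a VCF file
#'
#' Parses a VCF 4.x file into a [genotype_table()].  Only biallelic SNP
#' records are kept; multi-allelic and indel records are skipped (their count
#' is reported in a message and in `attr(, "n_skipped")`).  GT fields are
#' mapped `0/0 -> AA`, `0/1` or `1/0 -> AB`, `1/1 -> BB`, `./. -> missing`;
#' phased separators (`|`) are treated like unphased ones, since phase in a
#' selfed-F1 design is not trusted.  Per-call depth is taken from `DP` when
#' present, otherwise from the sum of `AD`, otherwise `0`.
#'
#' @param path Path to a VCF file (optionally gzipped).
#' @param progenitor_id Sample id of the F1 progenitor; must be present in the
#'   VCF header.
#' @return A `genotype_table` with attribute `n_skipped` (records dropped as
#'   non-biallelic-SNP).
#' @export
read_vcf <- function(path, progenitor_id = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1]
  if (!is.null(progenitor_id) && !progenitor_id %in% samples) {
    stop("progenitor '", progenitor_id, "' not in VCF samples: ",
         paste(samples, collapse = ", "), call. = FALSE)
  }
  fix <- vcf@fix
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  biallelic_snp <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    !grepl(",", alt, fixed = TRUE)
  n_skipped <- sum(!biallelic_snp)
  if (n_skipped > 0) {
    message(n_skipped, " non-biallelic-SNP record(s) skipped")
  }
  vcf <- vcf[biallelic_snp, ]
  fix <- vcf@fix
  gt <- vcfR::extract.gt(vcf, element = "GT")
  calls <- matrix(NA_character_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  core <- sub("^([0-9.]+)[/|]([0-9.]+).*$", "\\1\\2", gt)
  calls[core %in% "00"] <- "AA"
  calls[core %in% c("01", "10")] <- "AB"
  calls[core %in% "11"] <- "BB"
  fmt <- vcf@gt[, 1]
  depths <- matrix(0L, nrow(gt), ncol(gt))
  if (any(grepl("DP", fmt))) {
    dp <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
    depths <- ifelse(is.na(dp), 0L, as.integer(dp))
  } else if (any(grepl("AD", fmt))) {
    ad <- vcfR::extract.gt(vcf, element = "AD")
    sum_ad <- function(s) {
      if (is.na(s)) return(0L)
      as.integer(sum(suppressWarnings(as.numeric(strsplit(s, ",")[[1]])),
                     na.rm = TRUE))
    }
    depths <- matrix(vapply(ad, sum_ad, integer(1)), nrow(ad), ncol(ad))
  }
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], "_", fix[, "POS"])[is.na(ids) | ids == "."]
  ids <- make.unique(ids)
  rownames(calls) <- ids
  markers <- tibble::tibble(
    id = ids, chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"]
  )
  out <- genotype_table(calls, depths, markers, progenitor_id)
  attr(out, "n_skipped") <- n_skipped
  out
}

IUPAC_HET <- c(R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC")

#' Read genotype calls from a TASSEL hapmap file
#'
#' Reads the tab-delimited hapmap format (11 fixed columns followed by one
#' column per sample, diploid genotypes as single IUPAC letters).  Homozygote
#' letters map to `AA`/`BB` according to the site's declared allele pair,
#' ambiguity letters (R, Y, S, W, K, M) map to `AB`, and `N` to missing.
#' A call letter inconsistent with the site's alleles is set missing with a
#' warning.  Depths are not represented in hapmap and are set to 0.
#'
#' @inheritParams read_vcf
#' @return A `genotype_table`.
#' @export
read_hapmap <- function(path, progenitor_id = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                          comment.char = "")
  names(df)[1] <- sub("^#?", "", names(df)[1])
  fixed_n <- 11L
  samples <- names(df)[-seq_len(fixed_n)]
  if (!is.null(progenitor_id) && !progenitor_id %in% samples) {
    stop("progenitor '", progenitor_id, "' not in hapmap samples: ",
         paste(samples, collapse = ", "), call. = FALSE)
  }
  alleles <- strsplit(df$alleles, "/", fixed = TRUE)
  a1 <- toupper(vapply(alleles, `[`, "", 1))
  a2 <- toupper(vapply(alleles, `[`, "", 2))
  raw <- toupper(as.matrix(df[, samples, drop = FALSE]))
  m <- nrow(raw)
  calls <- matrix(NA_character_, m, length(samples),
                  dimnames = list(df[[1]], samples))
  het_ok <- vapply(seq_len(m), function(i) {
    pair <- paste(sort(c(a1[i], a2[i])), collapse = "")
    names(IUPAC_HET)[match(pair, IUPAC_HET)]
  }, NA_character_)
  n_bad <- 0L
  for (i in seq_len(m)) {
    row <- raw[i, ]
    calls[i, row == a1[i]] <- "AA"
    calls[i, row == a2[i]] <- "BB"
    if (!is.na(het_ok[i])) calls[i, row == het_ok[i]] <- "AB"
    unknown <- !(row %in% c(a1[i], a2[i], het_ok[i], "N", "NN"))
    if (any(unknown)) {
      n_bad <- n_bad + sum(unknown)
    }
  }
  if (n_bad > 0) {
    warning(n_bad, " call(s) inconsistent with declared site alleles set to missing")
  }
  markers <- tibble::tibble(
    id = df[[1]], chrom = df$chrom, pos = as.integer(df$pos),
    ref = a1, alt = a2
  )
  genotype_table(calls, NULL, markers, progenitor_id)
}

LOC_CODE <- c(AA = "hh", AB = "hk", BB = "kk")

#' Write intercross markers to a loc-style mapping file
#'
#' Exports markers in the text layout used by interval-mapping software for
#' an hk x hk (intercross) cross: one line per marker, the marker name, the
#' segregation type `<hkxhk>`, then per-individual codes `hh`/`hk`/`kk`/`--`.
#' A header records population name, type and dimensions.  Reading the file
#' back with [read_loc()] restores the calls exactly.
#'
#' @param table A `genotype_table` (progeny only; the progenitor column, if
#'   flagged, is dropped on export).
#' @param marker_ids Markers to export; default all.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mapping_file <- function(table, marker_ids = NULL, path) {
  p <- gt_progeny(table)
  marker_ids <- marker_ids %||% rownames(p$calls)
  missing_ids <- setdiff(marker_ids, rownames(p$calls))
  if (length(missing_ids)) {
    stop("markers not in table: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  if (length(marker_ids) == 0L) {
    warning("no markers selected; writing header-only file")
  }
  calls <- p$calls[marker_ids, , drop = FALSE]
  if (!identical(attr(table, "marker_type"), "hkxhk") && length(marker_ids)) {
    ## a marker that never segregates cannot be intercross (hk x hk) coded
    n_classes <- vapply(seq_len(nrow(calls)), function(i) {
      length(unique(calls[i, !is.na(calls[i, ])]))
    }, integer(1))
    if (any(n_classes < 2)) {
      stop("markers not intercross-coded (fewer than two genotype classes): ",
           paste(marker_ids[n_classes < 2], collapse = ", "), call. = FALSE)
    }
  }
  n_ind <- ncol(calls)
  lines <- c(
    "; loc-style intercross marker export",
    "name = hetlink",
    "popt = F2",
    paste0("nloc = ", length(marker_ids)),
    paste0("nind = ", n_ind)
  )
  for (i in seq_along(marker_ids)) {
    codes <- LOC_CODE[calls[i, ]]
    codes[is.na(codes)] <- "--"
    lines <- c(lines,
               paste0(marker_ids[i], " <hkxhk>"),
               paste(strwrap(paste(codes, collapse = " "), width = 60),
                     collapse = "\n"))
  }
  lines <- c(lines, "", "individual names:", colnames(calls))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a loc-style mapping file back into a genotype table
#'
#' @param path Path written by [write_mapping_file()].
#' @return A `genotype_table` (depths 0, no progenitor).
#' @export
read_loc <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^;", lines)]
  get_num <- function(key) {
    as.integer(sub(".*=\\s*", "", lines[grepl(paste0("^", key, "\\s*="), lines)][1]))
  }
  nloc <- get_num("nloc")
  nind <- get_num("nind")
  ind_at <- which(lines == "individual names:")
  ind_names <- if (length(ind_at)) {
    nm <- lines[(ind_at + 1):length(lines)]
    nm[nzchar(nm)][seq_len(nind)]
  } else paste0("ind", seq_len(nind))
  marker_at <- grep("<hkxhk>", lines, fixed = TRUE)
  ids <- sub("\\s*<hkxhk>.*$", "", lines[marker_at])
  calls <- matrix(NA_character_, nloc, nind, dimnames = list(ids, ind_names))
  inv <- c(hh = "AA", hk = "AB", kk = "BB")
  stop_at <- c(marker_at[-1], if (length(ind_at)) ind_at else length(lines) + 1)
  for (k in seq_along(marker_at)) {
    body <- lines[(marker_at[k] + 1):(stop_at[k] - 1)]
    toks <- unlist(strsplit(paste(body, collapse = " "), "\\s+"))
    toks <- toks[nzchar(toks)][seq_len(nind)]
    calls[k, ] <- unname(inv[toks])
  }
  genotype_table(calls)
}

#' Read a phenotype table
#'
#' Reads a delimited text file (first column sample id, remaining columns
#' traits) into a tibble.  Columns containing only 0/1/missing are flagged as
#' binary; a Shapiro-Wilk normality screen is run per quantitative trait and
#' attached (informational only).  An optional natural-log transform can be
#' requested per trait.
#'
#' @param path Path to a CSV/TSV file (delimiter sniffed from the header).
#' @param log_traits Character vector of trait names to log-transform
#'   (values must be positive).
#' @return A tibble (first column `sample`), with attributes `binary`
#'   (named logical) and `normality` (tibble of Shapiro-Wilk W and p).
#' @export
read_phenotypes <- function(path, log_traits = character()) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else if (grepl(";", header)) ";" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  names(df)[1] <- "sample"
  if (anyDuplicated(df$sample)) {
    stop("duplicate sample ids: ",
         paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(names(df))) stop("duplicate trait names", call. = FALSE)
  out <- tibble::as_tibble(df)
  out$sample <- as.character(out$sample)
  traits <- setdiff(names(out), "sample")
  for (tr in traits) out[[tr]] <- as.numeric(out[[tr]])
  for (tr in log_traits) {
    if (!tr %in% traits) stop("unknown trait: ", tr, call. = FALSE)
    if (any(out[[tr]] <= 0, na.rm = TRUE)) {
      stop("log transform requires positive values: ", tr, call. = FALSE)
    }
    out[[tr]] <- log(out[[tr]])
  }
  is_bin <- vapply(traits, function(tr) {
    v <- out[[tr]]
    all(is.na(v) | v %in% c(0, 1)) && !all(is.na(v))
  }, logical(1))
  norm <- purrr::map_dfr(traits[!is_bin], function(tr) {
    v <- out[[tr]][!is.na(out[[tr]])]
    if (length(unique(v)) < 3 || length(v) < 3 || length(v) > 5000) {
      return(tibble::tibble(trait = tr, W = NA_real_, p = NA_real_))
    }
    sw <- stats::shapiro.test(v)
    tibble::tibble(trait = tr, W = unname(sw$statistic), p = sw$p.value)
  })
  attr(out, "binary") <- is_bin
  attr(out, "normality") <- norm
  out
}
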
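#' Read a genotype table from CSV or GenePop
#'
#' The CSV dialect is a header row `sample_id,sample_type,sex,
#' individual_label,replicate,<locus>_a,<locus>_b,...` with missing
#' genotypes as blank (or 0) in both allele cells.  GenePop files follow
#' the 4.x dialect with 2- or 3-digit allele coding auto-detected from
#' field width; `00`/`000` encodes a missing allele.  GenePop carries no
#' sample metadata, so `sample_type` defaults to `"scat"` and `sex` to
#' `"unknown"` on read.
#'
#' @param path file path.
#' @param format `"csv"` or `"genepop"`; default guessed from the file
#'   extension (`.gen`/`.genepop` vs anything else).
#' @return a [genotype_table()].
#' @export
read_genotype_table <- function(path, format = c("auto", "csv", "genepop")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(gen|genepop)$", path, ignore.case = TRUE))
      "genepop" else "csv"
  }
  switch(format, csv = read_gt_csv(path), genepop = read_gt_genepop(path))
}

#' Write a genotype table to CSV or GenePop
#'
#' CSV writes round-trip exactly (`read(write(t))` equals `t`).  GenePop
#' writes round-trip the loci, sample ids and genotypes; the metadata
#' columns cannot be represented in the format.  Missing genotypes are
#' written as blanks in CSV and zero-coded alleles in GenePop.
#'
#' @param table a [genotype_table()].
#' @param path output file path.
#' @param format `"csv"` or `"genepop"`.
#' @param title GenePop title line.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(table, path, format = c("csv", "genepop"),
                                 title = "scatgen genotype export") {
  stopifnot(inherits(table, "genotype_table"))
  format <- match.arg(format)
  if (nrow(table) == 0L) {
    stop("refusing to write a table with no records", call. = FALSE)
  }
  if (format == "csv") {
    out <- as.data.frame(table)
    utils::write.csv(out, path, row.names = FALSE, na = "")
  } else {
    write_gt_genepop(table, path, title)
  }
  invisible(path)
}

read_gt_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"), check.names = FALSE)
  loci <- infer_loci(names(df))
  genotype_table(df, loci)
}

read_gt_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3L) stop("not a genepop file: ", path, call. = FALSE)
  is_pop <- grepl("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  first_pop <- which(is_pop)[1L]
  if (is.na(first_pop) || first_pop < 3L) {
    stop("genepop file has no Pop line after the locus list", call. = FALSE)
  }
  # locus names: one per line, or comma-separated on a single line
  locus_lines <- trimws(lines[2:(first_pop - 1L)])
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]

  rec_lines <- lines[seq(first_pop, length(lines))]
  rec_lines <- rec_lines[!grepl("^\\s*pop\\s*$", rec_lines, ignore.case = TRUE)]
  if (!length(rec_lines)) stop("genepop file has no sample records", call. = FALSE)

  ids <- character(length(rec_lines))
  allele_mat <- matrix(NA_integer_, nrow = length(rec_lines),
                       ncol = 2L * length(loci))
  for (i in seq_along(rec_lines)) {
    parts <- strsplit(rec_lines[i], ",")[[1L]]
    if (length(parts) < 2L) {
      stop("malformed genepop record line: ", rec_lines[i], call. = FALSE)
    }
    ids[i] <- trimws(parts[1L])
    fields <- strsplit(trimws(paste(parts[-1L], collapse = " ")), "\\s+")[[1L]]
    if (length(fields) != length(loci)) {
      stop(sprintf("sample %s has %d genotype fields for %d loci",
                   ids[i], length(fields), length(loci)), call. = FALSE)
    }
    widths <- nchar(fields)
    if (!all(widths %in% c(4L, 6L)) || length(unique(widths)) != 1L) {
      stop(sprintf("sample %s: genotype fields must be uniformly 4 (2-digit) or 6 (3-digit) characters",
                   ids[i]), call. = FALSE)
    }
    d <- widths[1L] / 2L
    a <- as.integer(substr(fields, 1L, d))
    b <- as.integer(substr(fields, d + 1L, 2L * d))
    half <- xor(a == 0L, b == 0L)
    if (any(half)) {
      stop(sprintf("half-called genotype: sample %s, locus %s",
                   ids[i], loci[which(half)[1L]]), call. = FALSE)
    }
    allele_mat[i, seq(1L, ncol(allele_mat), 2L)] <- a
    allele_mat[i, seq(2L, ncol(allele_mat), 2L)] <- b
  }
  df <- data.frame(sample_id = ids, sample_type = "scat",
                   stringsAsFactors = FALSE)
  colnames(allele_mat) <- as.vector(rbind(paste0(loci, "_a"), paste0(loci, "_b")))
  genotype_table(cbind(df, as.data.frame(allele_mat)), loci)
}

write_gt_genepop <- function(table, path, title) {
  loci <- gt_loci(table)
  alleles <- unlist(lapply(loci, function(l) gt_locus_matrix(table, l)))
  max_allele <- suppressWarnings(max(alleles, na.rm = TRUE))
  if (!is.finite(max_allele)) max_allele <- 1L
  if (max_allele > 999L) {
    stop("allele label ", max_allele,
         " too wide for genepop 3-digit coding", call. = FALSE)
  }
  digits <- if (max_allele > 99L) 3L else 2L
  fmt <- function(a) {
    a[is.na(a)] <- 0L
    formatC(a, width = digits, flag = "0")
  }
  lines <- c(title, loci, "Pop")
  for (i in seq_len(nrow(table))) {
    fields <- vapply(loci, function(l) {
      g <- gt_genotype(table, i, l)
      paste0(fmt(g[1L]), fmt(g[2L]))
    }, character(1L))
    lines <- c(lines, paste0(table$sample_id[i], ", ", paste(fields, collapse = " ")))
  }
  writeLines(lines, path)
  invisible(path)
}
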
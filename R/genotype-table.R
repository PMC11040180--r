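#' Multilocus codominant genotype tables
#'
#' A `genotype_table` stores samples-by-loci codominant genotypes together
#' with the sample metadata used throughout the package.  It is a plain
#' `data.frame` with metadata columns `sample_id`, `sample_type`
#' (`"blood"` or `"scat"`), `sex` (`"male"`, `"female"`, `"unknown"`),
#' `individual_label` (links matched samples; `NA` when unknown) and
#' `replicate` (PCR replicate number, `NA` for consensus/reference rows),
#' followed by two integer allele columns per locus named `<locus>_a` and
#' `<locus>_b`.  Allele labels are positive integers (fragment sizes in
#' bp, assumed pre-binned).  A missing genotype has both alleles `NA`:
#' a genotype is either fully called or fully missing, never half.
#' Allele pairs are stored sorted ascending, so `(124, 120)` and
#' `(120, 124)` are the same genotype.
#'
#' @param data a data.frame with the columns described above.  `sex`,
#'   `individual_label` and `replicate` are optional and default to
#'   `"unknown"` / `NA`.
#' @param loci character vector of locus names, in panel order.  Defaults
#'   to the loci inferred from paired `_a`/`_b` columns of `data`.
#' @return an object of class `genotype_table`.
#' @examples
#' gt <- genotype_table(data.frame(
#'   sample_id = c("s1", "s2"), sample_type = "blood",
#'   L1_a = c(120L, 120L), L1_b = c(124L, 120L)))
#' gt_loci(gt)
#' @export
genotype_table <- function(data, loci = NULL) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "sample_type") %in% names(data))) {
    stop("data must have sample_id and sample_type columns", call. = FALSE)
  }
  if (is.null(loci)) loci <- infer_loci(names(data))
  if (length(loci) < 1L) stop("no loci found", call. = FALSE)

  if (!"sex" %in% names(data)) data$sex <- "unknown"
  if (!"individual_label" %in% names(data)) data$individual_label <- NA_character_
  if (!"replicate" %in% names(data)) data$replicate <- NA_integer_

  data$sample_id <- as.character(data$sample_id)
  data$sample_type <- as.character(data$sample_type)
  data$sex <- as.character(data$sex)
  data$sex[is.na(data$sex)] <- "unknown"
  data$individual_label <- as.character(data$individual_label)
  data$replicate <- as.integer(data$replicate)

  bad_type <- setdiff(unique(data$sample_type), c("blood", "scat"))
  if (length(bad_type)) {
    stop("unknown sample_type: ", paste(bad_type, collapse = ", "), call. = FALSE)
  }
  bad_sex <- setdiff(unique(data$sex), c("male", "female", "unknown"))
  if (length(bad_sex)) {
    stop("unknown sex: ", paste(bad_sex, collapse = ", "), call. = FALSE)
  }

  allele_cols <- as.vector(rbind(paste0(loci, "_a"), paste0(loci, "_b")))
  missing_cols <- setdiff(allele_cols, names(data))
  if (length(missing_cols)) {
    stop("missing allele columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }

  meta <- c("sample_id", "sample_type", "sex", "individual_label", "replicate")
  data <- data[, c(meta, allele_cols), drop = FALSE]

  for (loc in loci) {
    a <- suppressWarnings(as.integer(data[[paste0(loc, "_a")]]))
    b <- suppressWarnings(as.integer(data[[paste0(loc, "_b")]]))
    # 0 is an accepted missing encoding on input
    a[!is.na(a) & a == 0L] <- NA_integer_
    b[!is.na(b) & b == 0L] <- NA_integer_
    half <- xor(is.na(a), is.na(b))
    if (any(half)) {
      stop(sprintf("half-called genotype: sample %s, locus %s",
                   data$sample_id[which(half)[1L]], loc), call. = FALSE)
    }
    if (any(!is.na(a) & (a < 0L | b < 0L))) {
      stop("allele labels must be positive integers (locus ", loc, ")",
           call. = FALSE)
    }
    swap <- !is.na(a) & a > b
    if (any(swap)) {
      tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    }
    data[[paste0(loc, "_a")]] <- a
    data[[paste0(loc, "_b")]] <- b
  }

  structure(data, loci = loci, class = c("genotype_table", "data.frame"))
}

infer_loci <- function(cols) {
  meta <- c("sample_id", "sample_type", "sex", "individual_label", "replicate")
  allele_cols <- setdiff(cols, meta)
  if (length(allele_cols) %% 2L != 0L) {
    stop("odd number of allele columns: each locus needs <locus>_a and <locus>_b",
         call. = FALSE)
  }
  a_cols <- grep("_a$", allele_cols, value = TRUE)
  loci <- sub("_a$", "", a_cols)
  unmatched <- c(setdiff(paste0(loci, "_b"), allele_cols),
                 setdiff(allele_cols, c(paste0(loci, "_a"), paste0(loci, "_b"))))
  if (length(unmatched)) {
    stop("unpaired allele columns: ", paste(unmatched, collapse = ", "),
         call. = FALSE)
  }
  loci
}

#' @rdname genotype_table
#' @param x a `genotype_table`.
#' @export
gt_loci <- function(x) {
  stopifnot(inherits(x, "genotype_table"))
  attr(x, "loci")
}

#' @rdname genotype_table
#' @param i row index (single sample record).
#' @param locus locus name.
#' @return `gt_genotype()`: length-2 integer vector of sorted alleles,
#'   or `c(NA, NA)` when missing.
#' @export
gt_genotype <- function(x, i, locus) {
  c(x[[paste0(locus, "_a")]][i], x[[paste0(locus, "_b")]][i])
}

# n x 2 integer matrix of one locus's genotypes
gt_locus_matrix <- function(x, locus) {
  cbind(a = x[[paste0(locus, "_a")]], b = x[[paste0(locus, "_b")]])
}

# logical matrix samples x loci: TRUE where genotype is missing
gt_missing <- function(x) {
  loci <- gt_loci(x)
  out <- vapply(loci, function(loc) is.na(x[[paste0(loc, "_a")]]),
                logical(nrow(x)))
  if (nrow(x) == 1L) out <- matrix(out, nrow = 1L, dimnames = list(NULL, loci))
  out
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d record(s), %d loci (%s)\n", nrow(x),
              length(gt_loci(x)), paste(utils::head(gt_loci(x), 4L), collapse = ", ")))
  cat(sprintf("  sample types: %s\n",
              paste(names(table(x$sample_type)), table(x$sample_type),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Structural validation findings for a genotype table
#'
#' Reports (never raises) machine-readable findings: duplicated sample ids
#' within the same replicate, loci missing in every record, and allele
#' pairs stored out of ascending order (the constructor repairs these, so
#' they can only appear in hand-edited tables).
#'
#' @param table a `genotype_table`.
#' @return a data.frame with columns `kind`, `sample_id`, `locus`,
#'   `detail`; zero rows for a clean table.
#' @export
validate_table <- function(table) {
  stopifnot(inherits(table, "genotype_table"))
  loci <- gt_loci(table)
  findings <- list()
  add <- function(kind, sample_id = NA_character_, locus = NA_character_, detail = "") {
    findings[[length(findings) + 1L]] <<- data.frame(
      kind = kind, sample_id = sample_id, locus = locus, detail = detail,
      stringsAsFactors = FALSE)
  }

  key <- paste(table$sample_id, table$replicate, sep = "\r")
  dup <- unique(table$sample_id[duplicated(key)])
  for (id in dup) add("duplicate_id", sample_id = id,
                      detail = "sample_id repeated at the same replicate index")

  miss <- gt_missing(table)
  for (loc in loci[colSums(!miss) == 0L]) {
    add("dead_locus", locus = loc, detail = "locus missing in every record")
  }

  for (loc in loci) {
    g <- gt_locus_matrix(table, loc)
    bad <- which(!is.na(g[, 1L]) & g[, 1L] > g[, 2L])
    for (i in bad) add("unsorted_alleles", sample_id = table$sample_id[i],
                       locus = loc, detail = "allele pair not ascending")
  }

  if (length(findings)) do.call(rbind, findings) else
    data.frame(kind = character(), sample_id = character(),
               locus = character(), detail = character(),
               stringsAsFactors = FALSE)
}
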
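#' Multiple-tubes consensus genotype across PCR replicates
#'
#' An allele is confirmed when it appears in at least `min_confirm`
#' non-missing replicates.  A heterozygote is called when exactly two
#' alleles are confirmed; a homozygote when one allele is confirmed and
#' no second allele was observed in any replicate (a competing allele
#' seen even once leaves the call ambiguous, hence missing - the
#' conservative multiple-tubes practice, since a singly-seen second
#' allele may be the dropout survivor of a true heterozygote); three or
#' more confirmed alleles are conflicting, hence missing.  With a single
#' replicate that replicate is returned as-is.  The rule is invariant to
#' replicate order.
#'
#' @param replicates list of length-2 allele vectors (missing =
#'   `c(NA, NA)`), or an n x 2 matrix with one replicate per row.
#' @param min_confirm replicates required to confirm an allele
#'   (default 2, the classic multiple-tubes threshold).
#' @return length-2 integer vector (sorted), or `c(NA, NA)`.
#' @export
consensus_genotype <- function(replicates, min_confirm = 2L) {
  if (is.matrix(replicates)) {
    replicates <- lapply(seq_len(nrow(replicates)), function(i) replicates[i, ])
  }
  if (!length(replicates)) stop("empty replicate list", call. = FALSE)
  if (length(replicates) == 1L) {
    g <- replicates[[1L]]
    return(if (anyNA(g)) c(NA_integer_, NA_integer_) else sort(as.integer(g)))
  }
  present <- lapply(replicates, function(g) {
    if (anyNA(g)) integer() else unique(as.integer(g))
  })
  tab <- table(unlist(present))
  if (!length(tab)) return(c(NA_integer_, NA_integer_))
  confirmed <- as.integer(names(tab)[tab >= min_confirm])
  if (length(confirmed) == 2L) return(sort(confirmed))
  if (length(confirmed) == 1L && length(tab) == 1L) {
    return(c(confirmed, confirmed))
  }
  c(NA_integer_, NA_integer_)
}

#' Collapse replicate rows of a genotype table into consensus records
#'
#' Applies [consensus_genotype()] per sample and locus across all rows
#' sharing a `sample_id`.  Metadata is taken from the first row of each
#' sample; `replicate` is set to `NA` in the output.
#'
#' @param table a [genotype_table()] with replicate rows.
#' @param min_confirm passed to [consensus_genotype()].
#' @return a [genotype_table()] with one row per sample, in order of
#'   first appearance.
#' @export
consensus_table <- function(table, min_confirm = 2L) {
  stopifnot(inherits(table, "genotype_table"))
  loci <- gt_loci(table)
  ids <- unique(table$sample_id)
  rows <- lapply(ids, function(id) {
    sub <- table[table$sample_id == id, , drop = FALSE]
    row <- sub[1L, , drop = FALSE]
    row$replicate <- NA_integer_
    for (loc in loci) {
      g <- consensus_genotype(gt_locus_matrix(sub, loc), min_confirm)
      row[[paste0(loc, "_a")]] <- g[1L]
      row[[paste0(loc, "_b")]] <- g[2L]
    }
    as.data.frame(row)
  })
  genotype_table(do.call(rbind, rows), loci)
}

#' Compare one reference record against one scat record, per locus
#'
#' Each locus is scored `unreadable` (either side missing), `match`
#' (equal unordered allele pairs) or `mismatch`.  A mismatch where the
#' reference is heterozygous and the scat is homozygous for one of the
#' reference alleles is classified `dropout_like` (the classic allelic
#' dropout signature); any other allele-level disagreement is
#' `false_allele`.
#'
#' @param reference,scat single-row [genotype_table()]s (or a row of
#'   one) on the same locus panel.
#' @return data.frame with columns `locus`, `status`, `mismatch_kind`.
#' @export
compare_pair <- function(reference, scat) {
  stopifnot(inherits(reference, "genotype_table"),
            inherits(scat, "genotype_table"),
            nrow(reference) == 1L, nrow(scat) == 1L)
  if (!identical(gt_loci(reference), gt_loci(scat))) {
    stop("reference and scat tables have different locus panels", call. = FALSE)
  }
  loci <- gt_loci(reference)
  status <- character(length(loci))
  kind <- rep(NA_character_, length(loci))
  for (j in seq_along(loci)) {
    r <- gt_genotype(reference, 1L, loci[j])
    s <- gt_genotype(scat, 1L, loci[j])
    if (anyNA(r) || anyNA(s)) {
      status[j] <- "unreadable"
    } else if (identical(r, s)) {
      status[j] <- "match"
    } else {
      status[j] <- "mismatch"
      ref_het <- r[1L] != r[2L]
      scat_hom <- s[1L] == s[2L]
      kind[j] <- if (ref_het && scat_hom && s[1L] %in% r)
        "dropout_like" else "false_allele"
    }
  }
  data.frame(locus = loci, status = status, mismatch_kind = kind,
             stringsAsFactors = FALSE)
}

#' Paired blood-versus-scat genotyping-error profile
#'
#' Links scat samples to blood references via `individual_label` and
#' scores every scat record against its reference with [compare_pair()].
#' Scat tables with replicate rows are collapsed with [consensus_table()]
#' first.  Per-sample percentages are counts over the L-locus panel:
#' `missing_pct` (unreadable comparisons), `dropout_like_pct`
#' (reference-het observed homozygous) and `false_allele_pct` (any other
#' discordance), each times 100/L and rounded half-up to 2 decimals.
#'
#' Per-locus rates aggregate across all pairs with their denominators:
#' `ado_rate` = dropout-like events / readable comparisons with a
#' heterozygous reference; `fa_rate` = false-allele events / readable
#' comparisons.  `p_ado_hat` and `p_fa_hat` invert the generative
#' observation model to per-event probabilities: `p_fa_hat` is the
#' mismatch rate among homozygous-reference readable comparisons (where
#' dropout is invisible and every false allele produces a non-dropout
#' signature), and `p_ado_hat` corrects the heterozygous-reference
#' dropout-like rate for false alleles that mimic dropout and for the
#' exclusion of double-dropout (unreadable) comparisons.
#'
#' @param reference_table blood [genotype_table()] carrying
#'   `individual_label`.
#' @param scat_table scat [genotype_table()]; may contain replicates.
#' @param min_confirm consensus threshold for replicate collapsing.
#' @return list of class `error_profile` with data.frames `per_sample`
#'   and `per_locus`, plus `n_pairs`.
#' @export
error_profile <- function(reference_table, scat_table, min_confirm = 2L) {
  stopifnot(inherits(reference_table, "genotype_table"),
            inherits(scat_table, "genotype_table"))
  if (!identical(gt_loci(reference_table), gt_loci(scat_table))) {
    stop("reference and scat tables have different locus panels", call. = FALSE)
  }
  loci <- gt_loci(reference_table)
  L <- length(loci)
  if (any(!is.na(scat_table$replicate)) || anyDuplicated(scat_table$sample_id)) {
    scat_table <- consensus_table(scat_table, min_confirm)
  }
  linked <- !is.na(scat_table$individual_label) &
    scat_table$individual_label %in% reference_table$individual_label
  if (!any(linked)) {
    stop("no scat sample is linked to a blood reference by individual_label",
         call. = FALSE)
  }
  scat_table <- scat_table[linked, , drop = FALSE]

  per_sample <- list()
  het_n <- het_ado <- readable_n <- fa_n <- hom_n <- hom_fa <- fa_to_hom_possible <-
    stats::setNames(numeric(L), loci)
  n_alleles_seen <- stats::setNames(integer(L), loci)
  for (loc in loci) {
    pooled <- c(gt_locus_matrix(reference_table, loc),
                gt_locus_matrix(scat_table, loc))
    n_alleles_seen[loc] <- length(unique(stats::na.omit(pooled)))
  }

  for (i in seq_len(nrow(scat_table))) {
    lab <- scat_table$individual_label[i]
    ref_i <- which(reference_table$individual_label == lab)[1L]
    cmp <- compare_pair(reference_table[ref_i, , drop = FALSE],
                        scat_table[i, , drop = FALSE])
    n_miss <- sum(cmp$status == "unreadable")
    n_do <- sum(cmp$status == "mismatch" & cmp$mismatch_kind == "dropout_like")
    n_fa <- sum(cmp$status == "mismatch" & cmp$mismatch_kind == "false_allele")
    per_sample[[i]] <- data.frame(
      sample_id = scat_table$sample_id[i], individual_label = lab,
      n_loci = L,
      missing_pct = round_half_up(100 * n_miss / L),
      dropout_like_pct = round_half_up(100 * n_do / L),
      false_allele_pct = round_half_up(100 * n_fa / L),
      stringsAsFactors = FALSE)

    for (j in seq_len(L)) {
      loc <- loci[j]
      if (cmp$status[j] == "unreadable") next
      readable_n[loc] <- readable_n[loc] + 1
      r <- gt_genotype(reference_table, ref_i, loc)
      if (r[1L] != r[2L]) {
        het_n[loc] <- het_n[loc] + 1
        if (cmp$status[j] == "mismatch" && cmp$mismatch_kind[j] == "dropout_like") {
          het_ado[loc] <- het_ado[loc] + 1
        }
      } else {
        hom_n[loc] <- hom_n[loc] + 1
        if (cmp$status[j] == "mismatch") hom_fa[loc] <- hom_fa[loc] + 1
      }
      if (cmp$status[j] == "mismatch" && cmp$mismatch_kind[j] == "false_allele") {
        fa_n[loc] <- fa_n[loc] + 1
      }
    }
  }

  rate <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  ado_rate <- rate(het_ado, het_n)
  fa_rate <- rate(fa_n, readable_n)
  p_fa_hat <- rate(hom_fa, hom_n)
  # invert d_obs = d0 (1 - f) + (1 - d0) f / (k - 1); d0 = 2p / (1 + p)
  k <- pmax(n_alleles_seen, 2L)
  f <- ifelse(is.na(p_fa_hat), 0, p_fa_hat)
  d_obs <- ado_rate
  denom <- 1 - f - f / (k - 1)
  d0 <- (d_obs - f / (k - 1)) / ifelse(denom > 0, denom, NA_real_)
  d0 <- pmin(pmax(d0, 0), 1)
  p_ado_hat <- d0 / (2 - d0)

  per_locus <- data.frame(
    locus = loci,
    n_het_comparisons = as.integer(het_n),
    ado_events = as.integer(het_ado),
    ado_rate = ado_rate,
    n_readable_comparisons = as.integer(readable_n),
    fa_events = as.integer(fa_n),
    fa_rate = fa_rate,
    n_hom_comparisons = as.integer(hom_n),
    p_ado_hat = p_ado_hat,
    p_fa_hat = p_fa_hat,
    row.names = NULL, stringsAsFactors = FALSE)

  structure(list(per_sample = do.call(rbind, per_sample),
                 per_locus = per_locus,
                 n_pairs = nrow(scat_table)),
            class = "error_profile")
}

#' @export
print.error_profile <- function(x, ...) {
  cat(sprintf("error_profile over %d blood-scat pair(s)\n", x$n_pairs))
  print(x$per_sample)
  invisible(x)
}

#' Per-locus amplification success percentage
#'
#' Fraction of samples with a non-missing consensus genotype at the
#' locus, as a percentage rounded half-up to 2 decimals.  Replicate rows
#' are collapsed to consensus per sample first.
#'
#' @param table a [genotype_table()].
#' @param locus locus name.
#' @param min_confirm consensus threshold when replicates are present.
#' @return numeric percentage in `[0, 100]`.
#' @export
amplification_success <- function(table, locus, min_confirm = 2L) {
  stopifnot(inherits(table, "genotype_table"))
  if (!locus %in% gt_loci(table)) {
    stop("unknown locus: ", locus, call. = FALSE)
  }
  if (any(!is.na(table$replicate))) {
    table <- consensus_table(table, min_confirm)
  }
  g <- gt_locus_matrix(table, locus)
  round_half_up(100 * mean(!is.na(g[, 1L])))
}
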
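#' Probability of identity for unrelated individuals
#'
#' Probability that two unrelated Hardy-Weinberg individuals share a
#' genotype at the locus:
#' `P_ID = sum p_i^4 + sum_{i<j} (2 p_i p_j)^2 = 2 (sum p_i^2)^2 - sum p_i^4`.
#'
#' @param freqs allele-frequency vector summing to 1 (or an
#'   [allele_frequencies()] list).
#' @return probability in `(0, 1]`.
#' @export
pid_unrelated <- function(freqs) {
  p <- if (is.list(freqs)) freqs$freq else freqs
  check_freqs(p)
  2 * sum(p^2)^2 - sum(p^4)
}

#' Probability of identity for full siblings
#'
#' `P_IDsib = 0.25 + 0.5 sum p_i^2 + 0.5 (sum p_i^2)^2 - 0.25 sum p_i^4`,
#' the probability that two full sibs share a genotype under
#' Hardy-Weinberg; always at least [pid_unrelated()].
#'
#' @inheritParams pid_unrelated
#' @return probability in `(0, 1]`.
#' @export
pid_sib <- function(freqs) {
  p <- if (is.list(freqs)) freqs$freq else freqs
  check_freqs(p)
  s2 <- sum(p^2)
  0.25 + 0.5 * s2 + 0.5 * s2^2 - 0.25 * sum(p^4)
}

#' Conservative per-locus match probability
#'
#' Assumes the target animal is homozygous for the most common allele,
#' giving match probability `max(p)^2`; the multilocus value is the
#' product across loci.
#'
#' @inheritParams pid_unrelated
#' @return probability in `(0, 1]`.
#' @export
pid_conservative <- function(freqs) {
  p <- if (is.list(freqs)) freqs$freq else freqs
  check_freqs(p)
  max(p)^2
}

#' Second-parent exclusion probability (P_E2)
#'
#' Probability that a random unrelated Hardy-Weinberg individual is
#' genetically excluded as the second parent of a random offspring whose
#' first parent is known.  Defined - and computed - by exact enumeration:
#' for every known-parent genotype, transmitted maternal allele and
#' paternal allele (drawn from the population), the offspring genotype
#' fixes the set of alleles a true second parent must carry; a candidate
#' carrying none of them is excluded, with probability
#' `(1 - sum of that set's frequencies)^2`.
#'
#' @inheritParams pid_unrelated
#' @return probability in `[0, 1)`; 0 at a monomorphic locus.
#' @export
pe2 <- function(freqs) {
  p <- if (is.list(freqs)) freqs$freq else freqs
  check_freqs(p)
  k <- length(p)
  if (k == 1L) return(0)
  total <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      # ordered parental genotype (i, j), prob p_i p_j; maternal allele
      # is the first slot (each ordered pair enumerated once covers the
      # 1/2 transmission weight)
      w_mother <- p[i] * p[j]
      m <- i
      for (z in seq_len(k)) {
        off <- sort(c(m, z))
        # alleles z2 a true second parent could have contributed, given
        # the known parent {i, j} and offspring `off`
        compatible <- vapply(seq_len(k), function(z2) {
          any(vapply(c(i, j), function(mm) {
            identical(sort(c(mm, z2)), off)
          }, logical(1L)))
        }, logical(1L))
        p_not_excluded <- 1 - (1 - sum(p[compatible]))^2
        total <- total + w_mother * p[z] * (1 - p_not_excluded)
      }
    }
  }
  total
}

# closed-form P_E2 (Jamieson & Taylor); used as an independent
# cross-check of the enumeration in the test-suite
pe2_closed_form <- function(p) {
  a2 <- sum(p^2); a3 <- sum(p^3); a4 <- sum(p^4); a5 <- sum(p^5)
  1 - 2 * a2 + a3 + 2 * a4 - 3 * a5 - 2 * a2^2 + 3 * a2 * a3
}

#' Per-locus identity and exclusion power from a genotype table
#'
#' Computes `pid_unrelated`, `pid_sib`, `pid_conservative` and `pe2`
#' from the observed allele frequencies of each locus.
#'
#' @param table a [genotype_table()] (replicates collapsed first).
#' @param min_confirm consensus threshold when replicates are present.
#' @return data.frame, one row per locus.
#' @export
identity_power <- function(table, min_confirm = 2L) {
  stopifnot(inherits(table, "genotype_table"))
  if (any(!is.na(table$replicate))) table <- consensus_table(table, min_confirm)
  rows <- lapply(gt_loci(table), function(loc) {
    af <- tryCatch(allele_frequencies(table, loc), error = function(e) NULL)
    if (is.null(af)) {
      return(data.frame(locus = loc, pid_unrelated = NA_real_,
                        pid_sib = NA_real_, pid_conservative = NA_real_,
                        pe2 = NA_real_, stringsAsFactors = FALSE))
    }
    data.frame(locus = loc,
               pid_unrelated = pid_unrelated(af$freq),
               pid_sib = pid_sib(af$freq),
               pid_conservative = pid_conservative(af$freq),
               pe2 = pe2(af$freq), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cumulative multilocus identity and exclusion power
#'
#' Running products of per-locus `pid_unrelated`, `pid_sib` and
#' `pid_conservative` over a stated locus order (loci assumed unlinked),
#' and the combined non-exclusion `1 - prod(1 - pe2)` for exclusion.
#'
#' @param power per-locus data.frame from [identity_power()].
#' @param order character vector, a permutation of a subset of
#'   `power$locus`.
#' @return data.frame with one row per panel prefix.
#' @export
cumulative_power <- function(power, order = power$locus) {
  if (!all(order %in% power$locus)) {
    stop("unknown locus in order: ",
         paste(setdiff(order, power$locus), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(order)) stop("order contains duplicates", call. = FALSE)
  idx <- match(order, power$locus)
  data.frame(
    n_loci = seq_along(order),
    locus_added = order,
    cum_pid_unrelated = cumprod(power$pid_unrelated[idx]),
    cum_pid_sib = cumprod(power$pid_sib[idx]),
    cum_pid_conservative = cumprod(power$pid_conservative[idx]),
    cum_pe2 = 1 - cumprod(1 - power$pe2[idx]),
    stringsAsFactors = FALSE)
}

#' Minimal discriminating panel by PIC ranking
#'
#' Ranks loci by descending PIC (ties broken lexicographically by locus
#' name) and repeatedly drops the lowest-PIC remaining locus, recording
#' the cumulative `pid_unrelated` and `pid_sib` of each remaining panel
#' - the sequential-exclusion trajectory used to judge when a panel is
#' no longer able to detect identity.  The minimal panel is the smallest
#' prefix of the PIC-descending ranking whose cumulative `pid_sib` is at
#' or below `pid_threshold` (the sibling criterion is the conservative
#' convention in noninvasive genetics).  When even the full panel fails
#' the threshold, the full panel is returned flagged `met = FALSE`.
#'
#' @param stats data.frame with columns `locus` and `PIC` (e.g. from
#'   [locus_stats()]).
#' @param power data.frame from [identity_power()] on the same loci.
#' @param pid_threshold maximum acceptable cumulative `pid_sib`
#'   (default 0.01).
#' @return list with `ranking` (PIC-descending locus order),
#'   `trajectory` (panel size, dropped locus, remaining-panel cumulative
#'   pids), `minimal_panel`, `achieved_pid_sib`, `met`.
#' @export
min_panel_by_pic <- function(stats, power, pid_threshold = 0.01) {
  stopifnot(all(c("locus", "PIC") %in% names(stats)),
            all(c("locus", "pid_unrelated", "pid_sib") %in% names(power)))
  if (pid_threshold <= 0 || pid_threshold >= 1) {
    stop("pid_threshold must be in (0, 1)", call. = FALSE)
  }
  stats <- stats[!is.na(stats$PIC), , drop = FALSE]
  if (!nrow(stats)) stop("no loci with a PIC value", call. = FALSE)
  ranking <- stats$locus[order(-stats$PIC, stats$locus)]
  idx <- match(ranking, power$locus)
  if (anyNA(idx)) stop("power table is missing ranked loci", call. = FALSE)
  pu <- power$pid_unrelated[idx]
  ps <- power$pid_sib[idx]

  n <- length(ranking)
  # panel of size s is the top-s prefix of the ranking; dropping the
  # lowest-PIC remaining locus moves from size s+1 to size s
  pref_pu <- cumprod(pu)
  pref_ps <- cumprod(ps)
  trajectory <- data.frame(
    panel_size = seq(n, 1L),
    dropped_locus = c(NA_character_, rev(ranking)[seq_len(n - 1L)]),
    cum_pid_unrelated = pref_pu[seq(n, 1L)],
    cum_pid_sib = pref_ps[seq(n, 1L)],
    stringsAsFactors = FALSE)

  meets <- which(pref_ps <= pid_threshold)
  if (length(meets)) {
    size <- min(meets)
    list(ranking = ranking, trajectory = trajectory,
         minimal_panel = ranking[seq_len(size)],
         achieved_pid_sib = pref_ps[size], met = TRUE)
  } else {
    list(ranking = ranking, trajectory = trajectory,
         minimal_panel = ranking,
         achieved_pid_sib = pref_ps[n], met = FALSE)
  }
}
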
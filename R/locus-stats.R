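#' Observed allele frequencies at a locus
#'
#' Counts gene copies (two per homozygote, one per heterozygote allele)
#' over readable genotypes; missing genotypes are excluded.
#'
#' @param table a [genotype_table()].
#' @param locus locus name.
#' @return list with `locus`, `alleles`, `counts`, `freq`, `n_copies`
#'   (2 x readable genotypes) and `n_genotypes`.
#' @export
allele_frequencies <- function(table, locus) {
  stopifnot(inherits(table, "genotype_table"))
  if (!locus %in% gt_loci(table)) stop("unknown locus: ", locus, call. = FALSE)
  g <- gt_locus_matrix(table, locus)
  copies <- c(g[, 1L], g[, 2L])
  copies <- copies[!is.na(copies)]
  if (!length(copies)) {
    stop("no readable genotypes at locus ", locus, call. = FALSE)
  }
  tab <- table(copies)
  alleles <- as.integer(names(tab))
  counts <- as.integer(tab)
  list(locus = locus, alleles = alleles, counts = counts,
       freq = counts / sum(counts), n_copies = sum(counts),
       n_genotypes = length(copies) / 2L)
}

#' Observed and unbiased expected heterozygosity
#'
#' `Ho` is the fraction of readable genotypes that are heterozygous.
#' `He` is Nei's unbiased estimator `2n/(2n - 1) * (1 - sum(p_i^2))`
#' with `n` readable genotypes - the small-sample correction matters at
#' the 4-13 samples per group typical of pilot panels.
#'
#' @inheritParams allele_frequencies
#' @return named numeric vector `c(Ho =, He =)`.
#' @export
heterozygosity <- function(table, locus) {
  af <- allele_frequencies(table, locus)
  g <- gt_locus_matrix(table, locus)
  ok <- !is.na(g[, 1L])
  ho <- mean(g[ok, 1L] != g[ok, 2L])
  n <- af$n_genotypes
  he <- if (n > 0.5) (2 * n / (2 * n - 1)) * (1 - sum(af$freq^2)) else 0
  c(Ho = ho, He = max(he, 0))
}

#' Polymorphic information content (Botstein)
#'
#' `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`.  Values above 0.6
#' are conventionally treated as highly informative.
#'
#' @param freqs allele-frequency vector summing to 1, or the list
#'   returned by [allele_frequencies()].
#' @return PIC value in `[0, 1)`.
#' @export
pic <- function(freqs) {
  p <- if (is.list(freqs)) freqs$freq else freqs
  check_freqs(p)
  s2 <- sum(p^2)
  s4 <- sum(p^4)
  1 - s2 - (s2^2 - s4)
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a random subsample of `g` gene
#' copies (FSTAT convention):
#' `Ar = sum_i [1 - choose(2N - N_i, g) / choose(2N, g)]`, with
#' `choose(a, b) = 0` when `a < b`.  At `g = 2N` this is the observed
#' allele count; a monomorphic locus gives 1 for any valid `g`.
#'
#' @param counts integer vector of allele copy counts, or an
#'   [allele_frequencies()] list.
#' @param g rarefaction size in gene copies, `1 <= g <= sum(counts)`.
#' @return expected allele count in `[1, length(counts)]`.
#' @export
allelic_richness <- function(counts, g) {
  if (is.list(counts)) counts <- counts$counts
  stopifnot(is.numeric(counts), all(counts >= 0))
  counts <- counts[counts > 0]
  n2 <- sum(counts)
  if (g < 1 || g > n2) {
    stop("rarefaction size g must be in [1, ", n2, "]", call. = FALSE)
  }
  # exp(lchoose) for numerical range; lchoose(a, b) = -Inf when a < b
  p_absent <- exp(lchoose(n2 - counts, g) - lchoose(n2, g))
  sum(1 - p_absent)
}

#' EM estimate of the null-allele frequency at a locus
#'
#' Fits a Hardy-Weinberg model with visible alleles `p_1..p_k` plus one
#' null allele of frequency `r` by expectation-maximization: an observed
#' homozygote `i/i` is a mixture of true `i/i` (weight `p_i^2`) and
#' `i/null` (weight `2 p_i r`); blank genotypes are treated as potential
#' `null/null` homozygotes (the "including blanks" convention, an
#' interpretive choice appropriate for scat data where blanks plausibly
#' are nulls or failures).  Heterozygotes contribute their two visible
#' copies directly.  Iterates until the largest frequency change falls
#' below `tol` or `max_iter` is reached; non-convergence is flagged, not
#' raised.
#'
#' @inheritParams allele_frequencies
#' @param tol convergence tolerance on frequencies (default 1e-8).
#' @param max_iter iteration cap (default 10000).
#' @param include_blanks count missing genotypes as candidate null/null
#'   homozygotes (default TRUE).
#' @return list with `r` (null-allele frequency), `freq` (visible-allele
#'   frequencies, summing to `1 - r` with `r`), `iterations`,
#'   `converged`.
#' @export
null_allele_em <- function(table, locus, tol = 1e-8, max_iter = 10000L,
                           include_blanks = TRUE) {
  stopifnot(inherits(table, "genotype_table"))
  if (!locus %in% gt_loci(table)) stop("unknown locus: ", locus, call. = FALSE)
  g <- gt_locus_matrix(table, locus)
  n_blank <- if (include_blanks) sum(is.na(g[, 1L])) else 0L
  g <- g[!is.na(g[, 1L]), , drop = FALSE]
  if (nrow(g) + n_blank == 0L) {
    stop("no genotypes (readable or blank) at locus ", locus, call. = FALSE)
  }
  if (nrow(g) == 0L) {
    return(list(r = 1, freq = numeric(), alleles = integer(),
                iterations = 0L, converged = TRUE))
  }
  alleles <- sort(unique(c(g)))
  k <- length(alleles)
  ai <- match(g[, 1L], alleles)
  bi <- match(g[, 2L], alleles)
  is_hom <- ai == bi
  hom_counts <- tabulate(ai[is_hom], nbins = k)
  het_copy_counts <- tabulate(c(ai[!is_hom], bi[!is_hom]), nbins = k)
  n_geno <- nrow(g) + n_blank
  total_copies <- 2 * n_geno

  # init: observed copy shares, small null mass
  p <- (2 * hom_counts + het_copy_counts)
  p <- p / sum(p) * 0.95
  r <- 0.05
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    # E-step: apportion homozygote copies between i/i and i/null
    w <- ifelse(p + 2 * r > 0, p / (p + 2 * r), 1)
    copies <- het_copy_counts + hom_counts * (1 + w)
    null_copies <- sum(hom_counts * (1 - w)) + 2 * n_blank
    # M-step
    p_new <- copies / total_copies
    r_new <- null_copies / total_copies
    delta <- max(abs(c(p_new - p, r_new - r)))
    p <- p_new
    r <- r_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  # EM approaches the r = 0 boundary sublinearly, so the delta criterion
  # can stop at a small spurious r.  With no blanks, compare against the
  # boundary fit (gene-count frequencies, r = 0) and snap when the
  # boundary likelihood is at least as high.
  loglik <- function(p, r) {
    hom_p <- p^2 + 2 * p * r
    het_tab <- table(paste(pmin(ai, bi)[!is_hom], pmax(ai, bi)[!is_hom]))
    het_ll <- 0
    if (length(het_tab)) {
      idx <- do.call(rbind, strsplit(names(het_tab), " "))
      pi1 <- p[as.integer(idx[, 1L])]
      pi2 <- p[as.integer(idx[, 2L])]
      het_ll <- sum(as.integer(het_tab) * log(2 * pi1 * pi2))
    }
    hom_ll <- sum(hom_counts[hom_counts > 0] * log(hom_p[hom_counts > 0]))
    blank_ll <- if (n_blank > 0) n_blank * log(r^2) else 0
    het_ll + hom_ll + blank_ll
  }
  if (n_blank == 0L && r > 0) {
    p_gc <- (2 * hom_counts + het_copy_counts) / (2 * nrow(g))
    if (loglik(p_gc, 0) >= loglik(p, r) - 1e-12) {
      p <- p_gc
      r <- 0
      converged <- TRUE
    }
  }
  list(r = r, freq = p, alleles = alleles, iterations = iter,
       converged = converged)
}

#' Exact-conditional Hardy-Weinberg test
#'
#' Tests departure from Hardy-Weinberg genotype proportions conditional
#' on the observed allele counts.  The statistic is the conditional
#' probability of the genotype array given the allele counts (Levene's
#' distribution); the p-value is the total probability of arrays no more
#' probable than the observed one.  Diallelic loci with at most
#' `enumerate_below` gene copies are evaluated by full enumeration over
#' heterozygote counts; everything else by Monte Carlo shuffling of gene
#' copies under a fixed seed.  Asymptotic chi-square approximations are
#' deliberately avoided: the target sample sizes are far too small.
#'
#' @inheritParams allele_frequencies
#' @param n_permutations Monte Carlo shuffles (default 2000).
#' @param seed integer seed for the Monte Carlo branch.
#' @param enumerate_below gene-copy ceiling for the exact diallelic
#'   branch (default 50).
#' @return list with `p` (p-value), `method` (`"enumeration"`,
#'   `"monte_carlo"` or `"untestable"`), `n_genotypes`.  A monomorphic
#'   locus returns `p = 1` flagged untestable.
#' @export
hwe_test <- function(table, locus, n_permutations = 2000L, seed = 1L,
                     enumerate_below = 50L) {
  stopifnot(inherits(table, "genotype_table"))
  g <- gt_locus_matrix(table, locus)
  g <- g[!is.na(g[, 1L]), , drop = FALSE]
  n <- nrow(g)
  if (n < 2L) stop("need at least 2 readable genotypes at ", locus, call. = FALSE)
  alleles <- sort(unique(c(g)))
  k <- length(alleles)
  if (k == 1L) {
    return(list(p = 1, method = "untestable", n_genotypes = n))
  }
  ai <- match(g[, 1L], alleles)
  bi <- match(g[, 2L], alleles)
  allele_counts <- tabulate(c(ai, bi), nbins = k)

  log_cond_prob <- function(ai, bi, n, allele_counts) {
    # Levene: P({n_ij} | {n_i}) = n! 2^h prod n_i! / (prod n_ij! (2n)!)
    key <- paste(pmin(ai, bi), pmax(ai, bi))
    n_ij <- table(key)
    h <- sum(ai != bi)
    lfactorial(n) + h * log(2) + sum(lfactorial(allele_counts)) -
      sum(lfactorial(as.integer(n_ij))) - lfactorial(2 * n)
  }
  obs <- log_cond_prob(ai, bi, n, allele_counts)
  eps <- 1e-9

  if (k == 2L && 2L * n <= enumerate_below) {
    n1 <- allele_counts[1L]
    hets <- seq(n1 %% 2L, min(allele_counts), by = 2L)
    probs <- vapply(hets, function(h) {
      n11 <- (n1 - h) / 2L
      n22 <- n - n11 - h
      exp(lfactorial(n) + h * log(2) + sum(lfactorial(allele_counts)) -
            (lfactorial(n11) + lfactorial(h) + lfactorial(n22)) -
            lfactorial(2 * n))
    }, numeric(1L))
    p_obs <- exp(obs)
    p_val <- sum(probs[probs <= p_obs * (1 + eps)])
    return(list(p = min(p_val, 1), method = "enumeration", n_genotypes = n))
  }

  copies <- c(ai, bi)
  p_val <- with_seed(seed, {
    hits <- 0L
    for (b in seq_len(n_permutations)) {
      perm <- sample(copies)
      pa <- perm[seq_len(n)]
      pb <- perm[n + seq_len(n)]
      if (log_cond_prob(pa, pb, n, allele_counts) <= obs + eps) hits <- hits + 1L
    }
    (hits + 1) / (n_permutations + 1)
  })
  list(p = p_val, method = "monte_carlo", n_genotypes = n)
}

#' Per-locus diversity and quality statistics
#'
#' Computes, for every locus of a genotype table: observed allele count,
#' `Ho`, unbiased `He`, `PIC`, rarefied allelic richness `Ar`, the EM
#' null-allele frequency and the exact-conditional HWE p-value.
#' Replicate rows are collapsed to consensus first.  Raw p-values are
#' reported without multiple-testing correction; the locus count is in
#' the output so users can correct downstream.
#'
#' @param table a [genotype_table()].
#' @param g rarefaction size in gene copies; `NULL` uses the smallest
#'   per-locus readable gene-copy total in `table` (so loci are
#'   comparable within the table).
#' @param n_permutations,seed passed to [hwe_test()].
#' @param min_confirm consensus threshold when replicates are present.
#' @return data.frame, one row per locus, with the rarefaction size used
#'   recorded in column `Ar_g`.
#' @export
locus_stats <- function(table, g = NULL, n_permutations = 2000L, seed = 1L,
                        min_confirm = 2L) {
  stopifnot(inherits(table, "genotype_table"))
  if (any(!is.na(table$replicate))) table <- consensus_table(table, min_confirm)
  loci <- gt_loci(table)
  afs <- lapply(loci, function(loc) {
    tryCatch(allele_frequencies(table, loc), error = function(e) NULL)
  })
  copy_totals <- vapply(afs, function(a) if (is.null(a)) NA_real_ else a$n_copies,
                        numeric(1L))
  if (is.null(g)) g <- min(copy_totals, na.rm = TRUE)
  rows <- lapply(seq_along(loci), function(j) {
    loc <- loci[j]
    af <- afs[[j]]
    if (is.null(af)) {
      return(data.frame(locus = loc, n_genotypes = 0L, n_alleles = NA_integer_,
                        Ho = NA_real_, He = NA_real_, PIC = NA_real_,
                        Ar = NA_real_, Ar_g = g, null_r = NA_real_,
                        hwe_p = NA_real_, stringsAsFactors = FALSE))
    }
    het <- heterozygosity(table, loc)
    em <- null_allele_em(table, loc)
    hw <- if (af$n_genotypes >= 2L)
      hwe_test(table, loc, n_permutations, seed = seed + j)
    else list(p = NA_real_)
    data.frame(
      locus = loc, n_genotypes = af$n_genotypes,
      n_alleles = length(af$alleles),
      Ho = het[["Ho"]], He = het[["He"]], PIC = pic(af$freq),
      Ar = allelic_richness(af$counts, min(g, af$n_copies)), Ar_g = g,
      null_r = em$r, hwe_p = hw$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Locus statistics split by sample type
#'
#' Runs [locus_stats()] separately on the blood and scat records of a
#' table (the paired reporting structure of marker-validation studies),
#' using a common rarefaction size: the smallest readable gene-copy
#' total across both groups and all loci.
#'
#' @inheritParams locus_stats
#' @return data.frame with a leading `sample_type` column.
#' @export
locus_stats_by_type <- function(table, n_permutations = 2000L, seed = 1L,
                                min_confirm = 2L) {
  stopifnot(inherits(table, "genotype_table"))
  if (any(!is.na(table$replicate))) table <- consensus_table(table, min_confirm)
  types <- intersect(c("blood", "scat"), unique(table$sample_type))
  g <- min(unlist(lapply(types, function(ty) {
    sub <- table[table$sample_type == ty, , drop = FALSE]
    vapply(gt_loci(table), function(loc) {
      2 * sum(!is.na(sub[[paste0(loc, "_a")]]))
    }, numeric(1L))
  })))
  g <- max(g, 2)
  out <- lapply(types, function(ty) {
    sub <- table[table$sample_type == ty, , drop = FALSE]
    cbind(sample_type = ty,
          locus_stats(sub, g = g, n_permutations = n_permutations, seed = seed),
          stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
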
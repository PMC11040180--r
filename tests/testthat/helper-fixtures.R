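# fixture builders used across the suite; everything is generated in code

# genotype table from a compact spec: genos[[sample]][[locus]] = c(a, b) or NA
make_gt <- function(genos, loci, sample_type = "blood", sex = NULL,
                    individual_label = NULL, replicate = NULL) {
  n <- length(genos)
  ids <- names(genos) %||% sprintf("s%d", seq_len(n))
  df <- data.frame(sample_id = ids,
                   sample_type = rep_len(sample_type, n),
                   stringsAsFactors = FALSE)
  if (!is.null(sex)) df$sex <- rep_len(sex, n)
  if (!is.null(individual_label)) df$individual_label <- rep_len(individual_label, n)
  if (!is.null(replicate)) df$replicate <- rep_len(replicate, n)
  for (j in seq_along(loci)) {
    a <- vapply(genos, function(g) {
      v <- g[[j]]
      if (length(v) < 2L || anyNA(v)) NA_integer_ else as.integer(v[1L])
    }, integer(1L))
    b <- vapply(genos, function(g) {
      v <- g[[j]]
      if (length(v) < 2L || anyNA(v)) NA_integer_ else as.integer(v[2L])
    }, integer(1L))
    df[[paste0(loci[j], "_a")]] <- a
    df[[paste0(loci[j], "_b")]] <- b
  }
  genotype_table(df, loci)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# single-locus table from a vector of genotype pairs
one_locus_gt <- function(pairs, locus = "L1", sample_type = "blood") {
  genos <- lapply(pairs, function(p) list(p))
  names(genos) <- sprintf("s%d", seq_along(pairs))
  make_gt(genos, locus, sample_type = sample_type)
}

# all frequency vectors with k parts on a 1/steps grid (positive parts)
freq_grid <- function(k, steps = 20L) {
  if (k == 1L) return(list(1))
  grid <- list()
  recurse <- function(prefix, remaining, parts_left) {
    if (parts_left == 1L) {
      if (remaining >= 1L) grid[[length(grid) + 1L]] <<- c(prefix, remaining)
      return()
    }
    for (v in seq_len(remaining - parts_left + 1L)) {
      recurse(c(prefix, v), remaining - v, parts_left - 1L)
    }
  }
  recurse(integer(), steps, k)
  lapply(grid, function(g) g / steps)
}

# enumeration oracle: P_ID as sum over the genotype distribution squared
pid_unrelated_oracle <- function(p) {
  k <- length(p)
  total <- 0
  for (i in seq_len(k)) {
    for (j in seq(i, k)) {
      gp <- if (i == j) p[i]^2 else 2 * p[i] * p[j]
      total <- total + gp^2
    }
  }
  total
}

# enumeration oracle: P_IDsib via parental genotype pairs and the
# distribution of offspring genotypes (each parent transmits one of its
# two alleles with probability 1/2)
pid_sib_oracle <- function(p) {
  k <- length(p)
  total <- 0
  for (a in seq_len(k)) for (b in seq_len(k)) {
    for (c in seq_len(k)) for (d in seq_len(k)) {
      w <- p[a] * p[b] * p[c] * p[d]  # ordered parental genotypes
      # four equally likely offspring allele pairs
      offs <- rbind(c(a, c), c(a, d), c(b, c), c(b, d))
      key <- paste(pmin(offs[, 1], offs[, 2]), pmax(offs[, 1], offs[, 2]))
      total <- total + w * sum((table(key) / 4)^2)
    }
  }
  total
}

# exhaustive rarefaction oracle: mean allele count over all g-subsets
allelic_richness_oracle <- function(counts, g) {
  copies <- rep(seq_along(counts), counts)
  subs <- utils::combn(length(copies), g)
  mean(apply(subs, 2L, function(idx) length(unique(copies[idx]))))
}
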
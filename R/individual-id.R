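#' Locus-wise mismatch counts between two sample records
#'
#' Compares two records over the loci readable in both (missing loci are
#' skipped, never counted as mismatches).  A mismatch where one side is
#' heterozygous and the other homozygous for one of its alleles is
#' counted `dropout_explained` - applied symmetrically, since in
#' scat-versus-scat comparisons either side may have dropped an allele.
#'
#' @param a,b single-row [genotype_table()]s on a shared panel.
#' @return named integer vector `c(compared =, mismatched =,
#'   dropout_explained =)`; `compared = 0` when the readable loci are
#'   disjoint.
#' @export
genotype_mismatch <- function(a, b) {
  stopifnot(inherits(a, "genotype_table"), inherits(b, "genotype_table"),
            nrow(a) == 1L, nrow(b) == 1L)
  if (!identical(gt_loci(a), gt_loci(b))) {
    stop("records have different locus panels", call. = FALSE)
  }
  compared <- mismatched <- dropout <- 0L
  for (loc in gt_loci(a)) {
    ga <- gt_genotype(a, 1L, loc)
    gb <- gt_genotype(b, 1L, loc)
    if (anyNA(ga) || anyNA(gb)) next
    compared <- compared + 1L
    if (identical(ga, gb)) next
    mismatched <- mismatched + 1L
    a_het <- ga[1L] != ga[2L]
    b_het <- gb[1L] != gb[2L]
    if ((a_het && !b_het && gb[1L] %in% ga) ||
        (b_het && !a_het && ga[1L] %in% gb)) {
      dropout <- dropout + 1L
    }
  }
  c(compared = compared, mismatched = mismatched,
    dropout_explained = dropout)
}

#' Assign query genotypes to reference individuals
#'
#' Each query (scat) record is compared against every reference; a
#' reference qualifies when at least `min_overlap` loci are readable on
#' both sides, at most `max_mismatch` loci disagree, every counted
#' mismatch is dropout-explained, and - when both sexes are known - the
#' sexes agree (a sex mismatch is a hard veto).  Exactly one qualifying
#' reference gives `decision = "assigned"`; two or more give
#' `"ambiguous"` (never force-assigned); none gives `"new_individual"`
#' (a candidate for [cluster_new_individuals()]), unless the query
#' overlapped fewer than `min_overlap` loci with every reference, which
#' gives `"insufficient_data"`.
#'
#' @param queries a [genotype_table()] of query records (replicates are
#'   collapsed to consensus first).
#' @param references a [genotype_table()] carrying `individual_label`.
#' @param min_overlap minimum readable-in-both loci (default 5, the size
#'   of a minimal informative microsatellite panel).
#' @param max_mismatch maximum tolerated (dropout-explained) mismatches
#'   (default 1).
#' @param min_confirm consensus threshold for replicate collapsing.
#' @return data.frame with one row per query: `query_id`, `assigned_to`,
#'   `compared_loci`, `mismatched_loci`, `dropout_explained`,
#'   `n_candidates`, `decision`.
#' @export
match_to_references <- function(queries, references, min_overlap = 5L,
                                max_mismatch = 1L, min_confirm = 2L) {
  stopifnot(inherits(queries, "genotype_table"),
            inherits(references, "genotype_table"))
  if (nrow(references) == 0L) stop("empty reference set", call. = FALSE)
  if (any(is.na(references$individual_label))) {
    stop("all references must carry individual_label", call. = FALSE)
  }
  if (any(!is.na(queries$replicate)) || anyDuplicated(queries$sample_id)) {
    queries <- consensus_table(queries, min_confirm)
  }
  rows <- lapply(seq_len(nrow(queries)), function(i) {
    q <- queries[i, , drop = FALSE]
    best <- NULL
    candidates <- character()
    max_compared <- 0L
    for (j in seq_len(nrow(references))) {
      r <- references[j, , drop = FALSE]
      mm <- genotype_mismatch(q, r)
      max_compared <- max(max_compared, mm[["compared"]])
      if (mm[["compared"]] < min_overlap) next
      sex_known <- q$sex != "unknown" && r$sex != "unknown"
      if (sex_known && q$sex != r$sex) next
      if (mm[["mismatched"]] > max_mismatch) next
      if (mm[["mismatched"]] > mm[["dropout_explained"]]) next
      candidates <- c(candidates, r$individual_label)
      if (is.null(best) || mm[["mismatched"]] < best$mm[["mismatched"]]) {
        best <- list(label = r$individual_label, mm = mm)
      }
    }
    candidates <- unique(candidates)
    decision <- if (max_compared < min_overlap) "insufficient_data"
      else if (length(candidates) == 1L) "assigned"
      else if (length(candidates) >= 2L) "ambiguous"
      else "new_individual"
    data.frame(
      query_id = q$sample_id,
      assigned_to = if (decision == "assigned") best$label else NA_character_,
      compared_loci = if (!is.null(best)) best$mm[["compared"]] else max_compared,
      mismatched_loci = if (!is.null(best)) best$mm[["mismatched"]] else NA_integer_,
      dropout_explained = if (!is.null(best)) best$mm[["dropout_explained"]] else NA_integer_,
      n_candidates = length(candidates),
      decision = decision, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cluster unassigned queries into putative new individuals
#'
#' Builds a graph joining query pairs that satisfy the same rule as
#' [match_to_references()] (overlap, mismatch budget, dropout-explained
#' mismatches, sex compatibility); clusters are the connected components
#' labelled `NEW_1..NEW_k` in order of first sample appearance.
#' Singleton components are single-scat individuals.  Components that
#' are not cliques (a ~ b, b ~ c but a !~ c) are flagged `chain_merge`.
#'
#' @param unassigned a [genotype_table()] of unassigned queries.
#' @inheritParams match_to_references
#' @return data.frame `sample_id`, `cluster`, `chain_merge`.
#' @export
cluster_new_individuals <- function(unassigned, min_overlap = 5L,
                                    max_mismatch = 1L, min_confirm = 2L) {
  stopifnot(inherits(unassigned, "genotype_table"))
  if (any(!is.na(unassigned$replicate)) || anyDuplicated(unassigned$sample_id)) {
    unassigned <- consensus_table(unassigned, min_confirm)
  }
  n <- nrow(unassigned)
  if (n == 0L) {
    return(data.frame(sample_id = character(), cluster = character(),
                      chain_merge = logical(), stringsAsFactors = FALSE))
  }
  linked <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      a <- unassigned[i, , drop = FALSE]
      b <- unassigned[j, , drop = FALSE]
      sex_known <- a$sex != "unknown" && b$sex != "unknown"
      if (sex_known && a$sex != b$sex) next
      mm <- genotype_mismatch(a, b)
      if (mm[["compared"]] >= min_overlap &&
          mm[["mismatched"]] <= max_mismatch &&
          mm[["mismatched"]] == mm[["dropout_explained"]]) {
        linked[i, j] <- linked[j, i] <- TRUE
      }
    }
  }
  graph <- igraph::graph_from_adjacency_matrix(linked, mode = "undirected")
  comp <- igraph::components(graph)$membership
  # relabel components in order of first appearance
  order_first <- unique(comp)
  cluster_id <- match(comp, order_first)
  chain <- vapply(seq_len(n), function(i) {
    members <- which(cluster_id == cluster_id[i])
    others <- setdiff(members, i)
    length(others) > 0L && !all(linked[i, others])
  }, logical(1L))
  data.frame(sample_id = unassigned$sample_id,
             cluster = sprintf("NEW_%d", cluster_id),
             chain_merge = chain, stringsAsFactors = FALSE)
}

#' Squared codominant genotypic distance between two records
#'
#' Per locus readable in both records, the standard codominant distance
#' convention: same genotype 0; one shared allele (het-het or het-hom) 1;
#' het-het with no shared allele 2; hom versus het with no shared allele
#' 3; different homozygotes 4.  Locus values are summed and scaled by
#' `panel size / compared loci` to offset missing data.  The result is a
#' squared distance: `d(a, a) = 0` and symmetry hold, the triangle
#' inequality is not guaranteed.
#'
#' @param a,b single-row [genotype_table()]s on a shared panel.
#' @return scalar squared distance; `NA` (flagged by attribute
#'   `undefined`) when no locus is readable in both.
#' @export
codominant_distance <- function(a, b) {
  stopifnot(inherits(a, "genotype_table"), inherits(b, "genotype_table"),
            nrow(a) == 1L, nrow(b) == 1L)
  if (!identical(gt_loci(a), gt_loci(b))) {
    stop("records have different locus panels", call. = FALSE)
  }
  loci <- gt_loci(a)
  total <- 0
  compared <- 0L
  for (loc in loci) {
    ga <- gt_genotype(a, 1L, loc)
    gb <- gt_genotype(b, 1L, loc)
    if (anyNA(ga) || anyNA(gb)) next
    compared <- compared + 1L
    total <- total + codom_locus_distance(ga, gb)
  }
  if (compared == 0L) {
    return(structure(NA_real_, undefined = TRUE))
  }
  total * length(loci) / compared
}

codom_locus_distance <- function(ga, gb) {
  if (identical(ga, gb)) return(0)
  a_het <- ga[1L] != ga[2L]
  b_het <- gb[1L] != gb[2L]
  shared <- length(intersect(ga, gb)) > 0L
  if (a_het && b_het) {
    if (shared) 1 else 2
  } else if (a_het || b_het) {
    if (shared) 1 else 3
  } else {
    4  # different homozygotes
  }
}

#' Pairwise squared codominant distance matrix
#'
#' @param table a [genotype_table()] (replicates collapsed first).
#' @param min_confirm consensus threshold when replicates are present.
#' @return symmetric matrix of squared distances with sample ids as
#'   dimnames; `NA` entries mark pairs with no shared readable locus.
#' @export
codominant_distance_matrix <- function(table, min_confirm = 2L) {
  stopifnot(inherits(table, "genotype_table"))
  if (any(!is.na(table$replicate)) || anyDuplicated(table$sample_id)) {
    table <- consensus_table(table, min_confirm)
  }
  n <- nrow(table)
  d <- matrix(0, n, n, dimnames = list(table$sample_id, table$sample_id))
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      d[i, j] <- d[j, i] <- codominant_distance(table[i, , drop = FALSE],
                                                table[j, , drop = FALSE])
    }
  }
  d
}

#' Principal coordinates analysis of a squared-distance matrix
#'
#' Classical metric scaling: the squared-distance matrix is
#' double-centered (`-0.5 * J D2 J`) and eigendecomposed; coordinates
#' are returned for positive-eigenvalue axes sorted descending, with the
#' percentage of (positive) variance per axis.  Negative eigenvalues -
#' which arise because the codominant distance is not guaranteed
#' Euclidean - are reported, not silently dropped.  With genotype data
#' carrying missing loci the ordination should be read as exploratory.
#'
#' @param d2 symmetric matrix of squared distances with zero diagonal
#'   (no `NA`s).
#' @return list with `points` (n x m coordinate matrix), `eig` (all
#'   eigenvalues, descending), `pct_var` (percent of positive-eigenvalue
#'   variance per returned axis).
#' @export
pcoa <- function(d2) {
  if (!is.matrix(d2) || nrow(d2) != ncol(d2)) {
    stop("d2 must be a square matrix", call. = FALSE)
  }
  if (anyNA(d2)) stop("d2 contains NA distances", call. = FALSE)
  if (max(abs(d2 - t(d2))) > 1e-8) stop("d2 is not symmetric", call. = FALSE)
  if (any(abs(diag(d2)) > 1e-8)) stop("d2 diagonal must be zero", call. = FALSE)
  n <- nrow(d2)
  j <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * j %*% d2 %*% j
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  pos <- which(e$values > max(e$values, 0) * 1e-12 & e$values > 0)
  if (!length(pos)) {
    return(list(points = matrix(0, n, 1L, dimnames = list(rownames(d2), "Axis1")),
                eig = e$values, pct_var = 100))
  }
  pts <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]),
                                                 nrow = length(pos))
  dimnames(pts) <- list(rownames(d2), paste0("Axis", seq_along(pos)))
  list(points = pts, eig = e$values,
       pct_var = 100 * e$values[pos] / sum(e$values[pos]))
}
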
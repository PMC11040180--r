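test_that("genotype_mismatch skips missing loci and classifies dropout", {
  loci <- sprintf("L%d", 1:9)
  full <- lapply(1:9, function(i) c(100 + 2 * i, 102 + 2 * i))
  a <- make_gt(list(q = full), loci, sample_type = "scat")
  expect_identical(genotype_mismatch(a, a),
                   c(compared = 9L, mismatched = 0L, dropout_explained = 0L))
  # two loci missing on one side: compared drops, no mismatch
  partial <- full; partial[[1]] <- NA; partial[[2]] <- NA
  b <- make_gt(list(q = partial), loci, sample_type = "scat")
  expect_identical(genotype_mismatch(a, b),
                   c(compared = 7L, mismatched = 0L, dropout_explained = 0L))
  # one dropout-like discordance among 8 compared
  do_g <- full; do_g[[1]] <- NA; do_g[[3]] <- rep(full[[3]][1], 2)
  d <- make_gt(list(q = do_g), loci, sample_type = "scat")
  expect_identical(genotype_mismatch(a, d),
                   c(compared = 8L, mismatched = 1L, dropout_explained = 1L))
  # disjoint readable loci: compared 0, no error
  left <- full; left[5:9] <- list(NA, NA, NA, NA, NA)
  right <- full; right[1:4] <- list(NA, NA, NA, NA)
  expect_identical(
    genotype_mismatch(make_gt(list(q = left), loci, sample_type = "scat"),
                      make_gt(list(q = right), loci, sample_type = "scat"))[["compared"]],
    0L)
})

test_that("queries assign, go ambiguous, or flag insufficient data", {
  loci <- sprintf("L%d", 1:9)
  ka <- lapply(1:9, function(i) c(100 + 2 * i, 102 + 2 * i))
  ha <- lapply(1:9, function(i) c(140 + 2 * i, 142 + 2 * i))
  refs <- make_gt(list(Ka = ka, Ha = ha), loci, individual_label = c("Ka", "Ha"))

  q_exact <- make_gt(list(q1 = ka), loci, sample_type = "scat")
  m <- match_to_references(q_exact, refs)
  expect_identical(m$decision, "assigned")
  expect_identical(m$assigned_to, "Ka")

  # one dropout-explained mismatch still assigns
  ka_do <- ka; ka_do[[4]] <- rep(ka[[4]][2], 2)
  m <- match_to_references(make_gt(list(q = ka_do), loci, sample_type = "scat"),
                           refs)
  expect_identical(m$decision, "assigned")

  # two hard (false-allele) mismatches to every reference: new individual
  ka_fa <- ka; ka_fa[[1]] <- ka[[1]] + 20; ka_fa[[2]] <- ka[[2]] + 20
  m <- match_to_references(make_gt(list(q = ka_fa), loci, sample_type = "scat"),
                           refs)
  expect_identical(m$decision, "new_individual")

  # readable at 3 loci only with min_overlap 5
  few <- ka; few[4:9] <- rep(list(NA), 6)
  m <- match_to_references(make_gt(list(q = few), loci, sample_type = "scat"),
                           refs)
  expect_identical(m$decision, "insufficient_data")

  # two identical references: ambiguous, never force-assigned
  refs2 <- make_gt(list(Ka = ka, Kb = ka), loci,
                   individual_label = c("Ka", "Kb"))
  m <- match_to_references(q_exact, refs2)
  expect_identical(m$decision, "ambiguous")
  expect_true(is.na(m$assigned_to))

  expect_error(match_to_references(q_exact, refs[0, , drop = FALSE]),
               "empty reference")
})

test_that("sex metadata acts as a hard veto on assignment", {
  loci <- sprintf("L%d", 1:6)
  g <- lapply(1:6, function(i) c(100 + 2 * i, 102 + 2 * i))
  refs <- make_gt(list(Ka = g), loci, sex = "female", individual_label = "Ka")
  q_m <- make_gt(list(q = g), loci, sample_type = "scat", sex = "male")
  q_u <- make_gt(list(q = g), loci, sample_type = "scat", sex = "unknown")
  expect_identical(match_to_references(q_m, refs)$decision, "new_individual")
  expect_identical(match_to_references(q_u, refs)$decision, "assigned")
})

test_that("clustering labels components in first-appearance order", {
  loci <- sprintf("L%d", 1:6)
  gA <- lapply(1:6, function(i) c(100 + 2 * i, 102 + 2 * i))
  gB <- lapply(1:6, function(i) c(120 + 2 * i, 122 + 2 * i))
  gC <- lapply(1:6, function(i) c(160 + 4 * i, 162 + 4 * i))
  cl <- cluster_new_individuals(
    make_gt(list(s1 = gA, s2 = gB, s3 = gA, s4 = gC), loci,
            sample_type = "scat"))
  expect_identical(cl$cluster, c("NEW_1", "NEW_2", "NEW_1", "NEW_3"))
  expect_false(any(cl$chain_merge))
  # three mutually distinct queries: three singletons
  cl3 <- cluster_new_individuals(
    make_gt(list(a = gA, b = gB, c = gC), loci, sample_type = "scat"))
  expect_identical(length(unique(cl3$cluster)), 3L)
})

test_that("chained near-matches merge into one flagged component", {
  loci <- sprintf("L%d", 1:6)
  base <- lapply(1:6, function(i) c(100 + 2 * i, 102 + 2 * i))
  # b differs from a by one dropout-like locus; c differs from b by a
  # different dropout-like locus; a-c differ at two loci (still within
  # budget?) - make a-c fail by exceeding max_mismatch
  a <- base
  b <- base; b[[1]] <- rep(base[[1]][1], 2)
  c_ <- base; c_[[1]] <- rep(base[[1]][1], 2); c_[[2]] <- rep(base[[2]][1], 2)
  d <- base; d[[1]] <- rep(base[[1]][1], 2); d[[2]] <- rep(base[[2]][1], 2)
  d[[3]] <- rep(base[[3]][1], 2)
  cl <- cluster_new_individuals(
    make_gt(list(a = a, c2 = c_, d = d), loci, sample_type = "scat"),
    max_mismatch = 1L)
  # a ~ nothing directly except via c2? a-c2: 2 mismatches -> no edge;
  # c2-d: 1 mismatch -> edge; a alone
  expect_identical(length(unique(cl$cluster)), 2L)
  chain <- cluster_new_individuals(
    make_gt(list(a = a, b = b, c2 = c_), loci, sample_type = "scat"),
    max_mismatch = 1L)
  # a~b and b~c2 but a!~c2: one component of three, flagged on the ends
  expect_identical(length(unique(chain$cluster)), 1L)
  expect_true(any(chain$chain_merge))
})

test_that("codominant distances follow the convention table", {
  loci <- "L1"
  d <- function(x, y) {
    codominant_distance(make_gt(list(q = list(x)), loci, sample_type = "scat"),
                        make_gt(list(q = list(y)), loci, sample_type = "scat"))
  }
  expect_equal(d(c(1, 2), c(1, 2)), 0)
  expect_equal(d(c(1, 1), c(1, 1)), 0)
  expect_equal(d(c(1, 2), c(1, 3)), 1)
  expect_equal(d(c(1, 2), c(1, 1)), 1)
  expect_equal(d(c(1, 2), c(3, 4)), 2)
  expect_equal(d(c(1, 1), c(2, 3)), 3)
  expect_equal(d(c(1, 1), c(2, 2)), 4)
})

test_that("distance matrix scales for missingness and flags undefined pairs", {
  loci <- c("L1", "L2")
  gt <- make_gt(list(a = list(c(1, 1), c(5, 6)),
                     b = list(c(2, 2), NA),
                     c = list(NA, c(5, 6))), loci, sample_type = "scat")
  dm <- codominant_distance_matrix(gt)
  expect_equal(dm["a", "b"], 4 * 2 / 1)   # one compared locus, panel of 2
  expect_equal(dm["a", "c"], 0)
  expect_true(is.na(dm["b", "c"]))        # disjoint readable loci
  expect_equal(dm, t(dm))
  expect_true(all(diag(dm) == 0))
})

test_that("pcoa recovers Euclidean configurations and handles degeneracy", {
  # 3-4-5 right triangle: squared distances embed exactly
  d2 <- matrix(c(0, 9, 16, 9, 0, 25, 16, 25, 0), 3, 3)
  res <- pcoa(d2)
  rec <- unname(as.matrix(stats::dist(res$points))^2)
  expect_equal(rec, d2, tolerance = 1e-9, ignore_attr = TRUE)
  expect_true(all(res$pct_var > 0))
  # cross-check against classical scaling in stats::cmdscale
  cmd <- stats::cmdscale(sqrt(d2), k = 2, eig = TRUE)
  rec_cmd <- unname(as.matrix(stats::dist(cmd$points))^2)
  expect_equal(rec, rec_cmd, tolerance = 1e-9, ignore_attr = TRUE)
  # all-zero matrix: all points at the origin
  res0 <- pcoa(matrix(0, 3, 3))
  expect_true(all(abs(res0$points) < 1e-12))
  # duplicated sample gives coincident coordinates
  d2d <- matrix(c(0, 0, 4, 0, 0, 4, 4, 4, 0), 3, 3)
  resd <- pcoa(d2d)
  expect_equal(resd$points[1, ], resd$points[2, ], tolerance = 1e-9)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("matched scats assign correctly and never wrongly across seeds", {
  correct <- integer(0); total <- integer(0); wrong <- 0L
  for (s in 1:5) {
    ds <- generate_dataset(sim_config(seed = s))
    cons <- consensus_table(ds$scat)
    m <- match_to_references(cons, ds$reference)
    truth_map <- ds$truth$scat_individual
    assigned <- m[m$decision == "assigned", , drop = FALSE]
    wrong <- wrong + sum(assigned$assigned_to != truth_map[assigned$query_id])
    matched <- m[m$query_id %in% ds$scat$sample_id[!is.na(ds$scat$individual_label)], ,
                 drop = FALSE]
    correct <- c(correct, sum(matched$decision == "assigned" &
                                matched$assigned_to == truth_map[matched$query_id]))
    total <- c(total, nrow(matched))
  }
  expect_identical(wrong, 0L)
  expect_gte(sum(correct) / sum(total), 0.95)
})

test_that("assignment is invariant to query order", {
  ds <- generate_dataset(sim_config(seed = 3, n_unmatched_scats = 10L))
  cons <- consensus_table(ds$scat)
  m1 <- match_to_references(cons, ds$reference)
  rev_cons <- genotype_table(as.data.frame(cons)[rev(seq_len(nrow(cons))), ,
                                                 drop = FALSE],
                             gt_loci(cons))
  m2 <- match_to_references(rev_cons, ds$reference)
  m2 <- m2[match(m1$query_id, m2$query_id), ]
  expect_equal(m1$decision, m2$decision)
  expect_equal(m1$assigned_to, m2$assigned_to)
})
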
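test_that("sim_config validates its inputs and demands a seed", {
  expect_error(sim_config(), "seed")
  expect_error(sim_config(seed = 1, p_ado = 1.5), "probabilities")
  expect_error(sim_config(seed = 1, alleles_per_locus = 0L), ">= 1")
  expect_error(sim_config(seed = 1, n_replicates = 6), "between 1 and 5")
  cfg <- sim_config(seed = 1)
  expect_length(cfg$alleles_per_locus, cfg$n_loci)
  expect_length(cfg$p_fail, cfg$n_loci)
})

test_that("allele frequencies normalize, append nulls, and are seed-stable", {
  cfg <- sim_config(seed = 7, n_loci = 3, alleles_per_locus = c(1L, 4L, 3L),
                    null_freq = c(0, 0, 0.2),
                    n_scat_per_individual = 1L)
  f <- simulate_allele_frequencies(cfg)
  expect_equal(f[[1]]$freq, 1)              # single allele, r = 0
  for (fl in f) expect_equal(sum(fl$freq), 1, tolerance = 1e-12)
  # appended null allele carries exactly r and visible mass is rescaled
  expect_false(is.na(f[[3]]$null_allele))
  expect_equal(f[[3]]$freq[length(f[[3]]$freq)], 0.2)
  expect_length(f[[3]]$alleles, 4L)
  f2 <- simulate_allele_frequencies(cfg)
  expect_identical(f, f2)                   # same seed, same draw
})

test_that("simulated genotypes follow the locus frequencies under HWE", {
  cfg <- sim_config(seed = 11, n_loci = 2, alleles_per_locus = c(1L, 2L),
                    dirichlet_concentration = 1e9,  # ~equifrequent
                    null_freq = 0, n_scat_per_individual = 1L)
  f <- simulate_allele_frequencies(cfg)
  truth <- simulate_individuals(f, 10000L, seed = 2)
  # monomorphic locus: everyone homozygous for that allele
  g1 <- truth$genotypes[[1]]
  expect_true(all(g1 == f[[1]]$alleles))
  # two equifrequent alleles: het fraction within 3 SE of 1/2
  g2 <- truth$genotypes[[2]]
  het <- mean(g2[, 1] != g2[, 2])
  p <- f[[2]]$freq
  expected <- 2 * p[1] * p[2]
  se <- sqrt(expected * (1 - expected) / 10000)
  expect_lt(abs(het - expected), 3 * se)
  expect_identical(truth, simulate_individuals(f, 10000L, seed = 2))
})

test_that("observation process honors forced error regimes", {
  cfg0 <- sim_config(seed = 5, n_loci = 2, alleles_per_locus = 3L,
                     null_freq = 0, p_fail = 0, p_ado = 0, p_fa = 0,
                     n_scat_per_individual = 1L)
  f <- simulate_allele_frequencies(cfg0)
  truth <- simulate_individuals(f, 1L, seed = 3)
  genos <- lapply(truth$genotypes, function(m) m[1, ])

  # all error probabilities 0: observation equals truth, empty event log
  obs <- simulate_observation(genos, f, cfg0, "scat", "q", seed = 9)
  for (loc in names(genos)) {
    for (r in seq_len(nrow(obs$observations))) {
      expect_identical(gt_genotype(obs$observations, r, loc),
                       as.integer(sort(genos[[loc]])))
    }
  }
  expect_identical(nrow(obs$events), 0L)

  # p_fail = 1: everything missing in every replicate
  cfg_fail <- sim_config(seed = 5, n_loci = 2, alleles_per_locus = 3L,
                         null_freq = 0, p_fail = 1, p_ado = 0, p_fa = 0,
                         n_scat_per_individual = 1L)
  obs <- simulate_observation(genos, f, cfg_fail, "scat", "q", seed = 9)
  expect_true(all(is.na(as.matrix(obs$observations[paste0(names(genos), "_a")]))))
  expect_true(all(obs$events$event == "fail"))

  # p_ado = 1 on a heterozygote: both alleles drop, missing + dropout events
  het_geno <- list(L01 = c(f[[1]]$alleles[1], f[[1]]$alleles[2]),
                   L02 = c(f[[2]]$alleles[1], f[[2]]$alleles[1]))
  cfg_ado <- sim_config(seed = 5, n_loci = 2, alleles_per_locus = 3L,
                        null_freq = 0, p_fail = 0, p_ado = 1, p_fa = 0,
                        n_scat_per_individual = 1L)
  obs <- simulate_observation(het_geno, f, cfg_ado, "scat", "q", seed = 9)
  expect_true(all(is.na(obs$observations$L01_a)))
  expect_true(all(obs$events$event == "dropout"))
  # homozygous locus untouched by dropout
  expect_false(anyNA(obs$observations$L02_a))
})

test_that("single-allele dropout leaves a homozygote for a true allele", {
  cfg <- sim_config(seed = 5, n_loci = 1, alleles_per_locus = 4L,
                    null_freq = 0, p_fail = 0, p_ado = 0.5, p_fa = 0,
                    n_replicates = 5L, n_scat_per_individual = 1L)
  f <- simulate_allele_frequencies(cfg)
  truth <- c(f[[1]]$alleles[1], f[[1]]$alleles[2])
  obs <- simulate_observation(list(L01 = truth), f, cfg, "scat", "q", seed = 31)
  for (r in seq_len(5)) {
    g <- gt_genotype(obs$observations, r, "L01")
    if (anyNA(g)) next
    expect_true(all(g %in% truth))
  }
})

test_that("null alleles mask carriers in blood and scat alike", {
  cfg <- sim_config(seed = 13, n_loci = 1, alleles_per_locus = 2L,
                    null_freq = 0.5, p_fail = 0, p_ado = 0, p_fa = 0,
                    n_scat_per_individual = 1L)
  f <- simulate_allele_frequencies(cfg)
  null_lab <- f[[1]]$null_allele
  vis <- setdiff(f[[1]]$alleles, null_lab)[1]
  # het with null appears homozygous for the visible allele
  obs <- simulate_observation(list(L01 = c(vis, null_lab)), f, cfg, "blood",
                              "b", seed = 2)
  expect_identical(gt_genotype(obs$observations, 1, "L01"),
                   as.integer(c(vis, vis)))
  expect_identical(obs$events$event, "null_mask")
  # null/null is missing
  obs <- simulate_observation(list(L01 = c(null_lab, null_lab)), f, cfg,
                              "blood", "b", seed = 2)
  expect_true(all(is.na(gt_genotype(obs$observations, 1, "L01"))))
})

test_that("generate_dataset reproduces the study sampling design", {
  cfg <- sim_config(seed = 17)
  ds <- generate_dataset(cfg)
  expect_identical(nrow(ds$reference), 8L)            # one blood per individual
  expect_identical(length(unique(ds$scat$sample_id)), 13L + 70L)
  matched <- unique(ds$scat$sample_id[!is.na(ds$scat$individual_label)])
  expect_identical(length(matched), 13L)              # 2 + 2 + 2 + 7
  # unmatched scats keep their owner only in the truth set
  unmatched <- setdiff(unique(ds$scat$sample_id), matched)
  expect_true(all(is.na(ds$scat$individual_label[ds$scat$sample_id %in% unmatched])))
  expect_true(all(unmatched %in% names(ds$truth$scat_individual)))
  expect_true(all(ds$truth$scat_individual[unmatched] %in%
                    ds$truth$genotypes$ids))
  # determinism: same config, same triple
  ds2 <- generate_dataset(cfg)
  expect_identical(as.data.frame(ds$reference), as.data.frame(ds2$reference))
  expect_identical(as.data.frame(ds$scat), as.data.frame(ds2$scat))
  expect_identical(ds$truth$event_log, ds2$truth$event_log)
  # no unmatched scats on request
  cfg0 <- sim_config(seed = 17, n_unmatched_scats = 0L)
  ds0 <- generate_dataset(cfg0)
  expect_true(all(!is.na(ds0$scat$individual_label)))
})

test_that("every truth/observation discrepancy is covered by the event log", {
  cfg <- sim_config(seed = 23, n_individuals = 4L,
                    n_scat_per_individual = 2L, n_unmatched_scats = 5L)
  ds <- generate_dataset(cfg)
  log_keys <- unique(with(ds$truth$event_log,
                          paste(sample_id, locus, replicate)))
  for (i in seq_len(nrow(ds$scat))) {
    sid <- ds$scat$sample_id[i]
    owner <- ds$truth$scat_individual[[sid]]
    genos <- ds$truth$genotypes
    oi <- match(owner, genos$ids)
    for (loc in gt_loci(ds$scat)) {
      obs <- gt_genotype(ds$scat, i, loc)
      tru <- sort(genos$genotypes[[loc]][oi, ])
      if (identical(obs, as.integer(tru))) next
      key <- paste(sid, loc, ds$scat$replicate[i])
      expect_true(key %in% log_keys,
                  label = sprintf("discrepancy at %s explained", key))
    }
  }
})

test_that("empirical dropout frequency matches the per-allele rate", {
  # many replicates of a known heterozygote: P(exactly one allele drops,
  # observation readable) = 2 p (1 - p)
  p_ado <- 0.3
  cfg <- sim_config(seed = 29, n_loci = 1, alleles_per_locus = 4L,
                    null_freq = 0, p_fail = 0, p_ado = p_ado, p_fa = 0,
                    n_replicates = 5L, n_scat_per_individual = 1L)
  f <- simulate_allele_frequencies(cfg)
  truth <- c(f[[1]]$alleles[1], f[[1]]$alleles[2])
  n <- 0L; dropouts <- 0L
  for (s in 1:600) {
    obs <- simulate_observation(list(L01 = truth), f, cfg, "scat", "q",
                                seed = s)
    for (r in seq_len(5)) {
      g <- gt_genotype(obs$observations, r, "L01")
      n <- n + 1L
      if (!anyNA(g) && g[1] == g[2]) dropouts <- dropouts + 1L
    }
  }
  expected <- 2 * p_ado * (1 - p_ado)
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(dropouts / n - expected), 3 * se)
})
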
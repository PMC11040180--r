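#' Simulation configuration for the synthetic scat-genotyping generator
#'
#' Defines the study design emulated by [generate_dataset()]: a small set
#' of reference individuals sampled by blood, a subset of them with
#' matched scat samples, and a larger set of field-collected scats from
#' additional unknown individuals.  Scat observations pass through a
#' four-stage error process (null-allele masking, locus amplification
#' failure, allelic dropout, false alleles) replicated over up to five
#' PCRs per sample.
#'
#' Defaults mirror the study design the package was calibrated on: a
#' 9-locus feline microsatellite panel with 2-6 alleles per locus, 8
#' reference individuals of which four have matched scats (2, 2, 2 and 7
#' scats), 70 field scats from 6 additional cats, and 5 PCR replicates
#' per scat.  The per-replicate error probabilities (`p_fail = 0.15`,
#' `p_ado = 0.20`, `p_fa = 0.05`) are chosen once so that
#' single-replicate scat observations show per-sample
#' missing/dropout/false-allele percentages inside the ranges reported
#' for wild felid scat panels, while the five-replicate consensus
#' workflow keeps matched scats assignable to their reference; the
#' null-allele frequency defaults to 0.10 at the first locus and 0
#' elsewhere.
#'
#' @param n_loci number of loci.
#' @param alleles_per_locus integer scalar or per-locus vector of visible
#'   allele counts (2-6 typical for dinucleotide microsatellites).
#' @param locus_names panel locus names.
#' @param dirichlet_concentration symmetric Dirichlet concentration for
#'   allele-frequency draws; larger is more even.
#' @param n_individuals number of reference (blood-sampled) individuals.
#' @param n_scat_per_individual matched scats per reference individual
#'   (scalar or vector of length `n_individuals`).
#' @param n_unmatched_scats field scats from non-reference individuals.
#' @param n_extra_individuals unknown individuals generating the
#'   unmatched scats.
#' @param p_fail per-replicate, per-locus amplification failure
#'   probability (scalar or per-locus).
#' @param p_ado per-allele dropout probability given a heterozygote.
#' @param p_fa per-locus false-allele probability.
#' @param null_freq per-locus frequency of a non-amplifying (null)
#'   allele; 0 disables.
#' @param n_replicates PCR replicates per scat sample (1-5).
#' @param blood_p_fail,blood_p_ado,blood_p_fa error overrides for blood
#'   samples (default 0: blood treated as error-free; null-allele masking
#'   still applies, being a template property).
#' @param seed integer seed; mandatory.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_loci = 9L,
                       alleles_per_locus = c(5L, 3L, 4L, 4L, 2L, 6L, 4L, 4L, 5L),
                       locus_names = NULL,
                       dirichlet_concentration = 3,
                       n_individuals = 8L,
                       n_scat_per_individual = c(2L, 2L, 2L, 7L, 0L, 0L, 0L, 0L),
                       n_unmatched_scats = 70L,
                       n_extra_individuals = 6L,
                       p_fail = 0.15,
                       p_ado = 0.20,
                       p_fa = 0.05,
                       null_freq = c(0.10, rep(0, 8L)),
                       n_replicates = 5L,
                       blood_p_fail = 0, blood_p_ado = 0, blood_p_fa = 0,
                       seed) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("sim_config requires an explicit seed", call. = FALSE)
  }
  n_loci <- as.integer(n_loci)
  if (n_loci < 1L) stop("n_loci must be positive", call. = FALSE)
  # the study-panel vectors only apply at the default panel size
  if (n_loci != 9L) {
    if (missing(alleles_per_locus)) alleles_per_locus <- 4L
    if (missing(null_freq)) null_freq <- 0
  }
  if (missing(n_scat_per_individual) && n_individuals != 8L) {
    n_scat_per_individual <- 2L
  }
  rec <- function(x, n) {
    if (length(x) == 1L) rep(x, n)
    else if (length(x) == n) x
    else stop("per-locus parameter has length ", length(x),
              ", expected 1 or ", n, call. = FALSE)
  }
  alleles_per_locus <- as.integer(rec(alleles_per_locus, n_loci))
  if (any(alleles_per_locus < 1L)) {
    stop("alleles_per_locus must be >= 1", call. = FALSE)
  }
  if (is.null(locus_names)) {
    locus_names <- sprintf("L%02d", seq_len(n_loci))
  }
  if (length(locus_names) != n_loci || anyDuplicated(locus_names)) {
    stop("locus_names must be ", n_loci, " unique names", call. = FALSE)
  }
  n_individuals <- as.integer(n_individuals)
  if (n_individuals < 1L) stop("n_individuals must be positive", call. = FALSE)
  n_scat_per_individual <- as.integer(
    if (length(n_scat_per_individual) == 1L)
      rep(n_scat_per_individual, n_individuals) else n_scat_per_individual)
  if (length(n_scat_per_individual) != n_individuals ||
      any(n_scat_per_individual < 0L)) {
    stop("n_scat_per_individual must be non-negative, one per individual",
         call. = FALSE)
  }
  cfg <- list(
    n_loci = n_loci,
    alleles_per_locus = alleles_per_locus,
    locus_names = locus_names,
    dirichlet_concentration = dirichlet_concentration,
    n_individuals = n_individuals,
    n_scat_per_individual = n_scat_per_individual,
    n_unmatched_scats = as.integer(n_unmatched_scats),
    n_extra_individuals = as.integer(n_extra_individuals),
    p_fail = rec(p_fail, n_loci),
    p_ado = rec(p_ado, n_loci),
    p_fa = rec(p_fa, n_loci),
    null_freq = rec(null_freq, n_loci),
    n_replicates = as.integer(n_replicates),
    blood_p_fail = rec(blood_p_fail, n_loci),
    blood_p_ado = rec(blood_p_ado, n_loci),
    blood_p_fa = rec(blood_p_fa, n_loci),
    seed = as.integer(seed))
  for (f in c("p_fail", "p_ado", "p_fa", "null_freq",
              "blood_p_fail", "blood_p_ado", "blood_p_fa")) {
    if (!is_probability(cfg[[f]])) {
      stop(f, " must be probabilities in [0, 1]", call. = FALSE)
    }
  }
  if (cfg$n_replicates < 1L || cfg$n_replicates > 5L) {
    stop("n_replicates must be between 1 and 5", call. = FALSE)
  }
  if (cfg$n_unmatched_scats > 0L && cfg$n_extra_individuals < 1L) {
    stop("unmatched scats require n_extra_individuals >= 1", call. = FALSE)
  }
  if (dirichlet_concentration <= 0) {
    stop("dirichlet_concentration must be positive", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Read a simulation configuration from a YAML file
#'
#' Keys are the arguments of [sim_config()].
#'
#' @param path YAML file path.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(sim_config, vals)
}

#' Draw true allele frequencies for a simulated panel
#'
#' Per locus, visible-allele frequencies are a symmetric Dirichlet draw.
#' When `null_freq > 0` one extra, non-amplifying allele is appended at
#' fixed frequency r and the visible frequencies are rescaled to 1 - r.
#' Allele labels are even fragment sizes in bp (dinucleotide ladder).
#'
#' @param config a [sim_config()].
#' @return an object of class `allele_freqs`: one entry per locus with
#'   fields `locus`, `alleles`, `freq`, `null_allele` (label or `NA`).
#' @export
simulate_allele_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    out <- lapply(seq_len(config$n_loci), function(i) {
      k <- config$alleles_per_locus[i]
      labels <- 100L + 10L * i + 2L * seq_len(k)
      f <- stats::rgamma(k, shape = config$dirichlet_concentration)
      f <- f / sum(f)
      r <- config$null_freq[i]
      null_allele <- NA_integer_
      if (r > 0) {
        null_allele <- max(labels) + 2L
        labels <- c(labels, null_allele)
        f <- c(f * (1 - r), r)
      }
      list(locus = config$locus_names[i], alleles = labels, freq = f,
           null_allele = null_allele)
    })
    names(out) <- config$locus_names
    structure(out, class = "allele_freqs")
  })
}

#' Draw multilocus genotypes for n individuals under Hardy-Weinberg
#'
#' Each individual's genotype at each locus is two independent draws from
#' that locus's allele-frequency vector (null allele included when
#' present).
#'
#' @param freqs an `allele_freqs` object.
#' @param n number of individuals.
#' @param seed integer seed.
#' @param ids optional individual labels (default `ind_01`, ...).
#' @return class `true_genotypes`: list with `ids` and `genotypes`, the
#'   latter a per-locus `n x 2` matrix of sorted allele labels.
#' @export
simulate_individuals <- function(freqs, n, seed, ids = NULL) {
  stopifnot(inherits(freqs, "allele_freqs"), n >= 1L)
  if (is.null(ids)) ids <- sprintf("ind_%02d", seq_len(n))
  stopifnot(length(ids) == n)
  with_seed(seed, {
    genotypes <- lapply(freqs, function(fl) {
      idx <- sample.int(length(fl$alleles), size = 2L * n, replace = TRUE,
                        prob = fl$freq)
      draws <- matrix(fl$alleles[idx], ncol = 2L)
      cbind(pmin(draws[, 1L], draws[, 2L]), pmax(draws[, 1L], draws[, 2L]))
    })
    names(genotypes) <- names(freqs)
    structure(list(ids = ids, genotypes = genotypes),
              class = "true_genotypes")
  })
}

# one individual's true genotype as a named list locus -> c(a, b)
true_genotype_of <- function(truth, id) {
  i <- match(id, truth$ids)
  stopifnot(!is.na(i))
  lapply(truth$genotypes, function(m) m[i, ])
}

#' Simulate the observation of one sample's genotypes
#'
#' Applies the scat observation process to one individual's true
#' multilocus genotype, per PCR replicate and locus, in a fixed order:
#' (1) null-allele masking - a heterozygote carrying the null allele
#' appears homozygous for the other allele, a null/null homozygote is
#' missing; (2) with `p_fail` the locus fails outright; (3) each allele
#' of a (post-null) heterozygote drops independently with `p_ado` - both
#' dropping gives a missing call; (4) with `p_fa` one allele is replaced
#' by a uniformly chosen different allele from the locus's visible set.
#' Blood samples use the `blood_*` rates (0 by default) but are still
#' subject to null masking.
#'
#' @param genotypes named list locus -> length-2 allele vector (one
#'   individual's truth), e.g. from [true_genotype_of()] internals or
#'   [simulate_individuals()].
#' @param freqs the `allele_freqs` the truth was drawn from (identifies
#'   null alleles and the visible allele set).
#' @param config a [sim_config()].
#' @param sample_type `"blood"` or `"scat"`.
#' @param sample_id id recorded in the output rows and event log.
#' @param seed integer seed.
#' @param n_replicates number of replicates (defaults to
#'   `config$n_replicates` for scat, 1 for blood).
#' @return list with `observations` (a [genotype_table()] with one row
#'   per replicate) and `events` (data.frame `sample_id`, `locus`,
#'   `replicate`, `event`, `detail`).
#' @export
simulate_observation <- function(genotypes, freqs, config,
                                 sample_type = c("scat", "blood"),
                                 sample_id = "sample", seed,
                                 n_replicates = NULL) {
  sample_type <- match.arg(sample_type)
  stopifnot(inherits(config, "sim_config"))
  if (is.null(n_replicates)) {
    n_replicates <- if (sample_type == "blood") 1L else config$n_replicates
  }
  with_seed(seed, {
    observe_sample(genotypes, freqs, config, sample_type, sample_id,
                   n_replicates)
  })
}

# core observation process; assumes RNG state is already seeded
observe_sample <- function(genotypes, freqs, config, sample_type,
                           sample_id, n_replicates) {
  loci <- config$locus_names
  blood <- sample_type == "blood"
  p_fail <- if (blood) config$blood_p_fail else config$p_fail
  p_ado <- if (blood) config$blood_p_ado else config$p_ado
  p_fa <- if (blood) config$blood_p_fa else config$p_fa

  events <- list()
  log_event <- function(locus, rep, event, detail = "") {
    events[[length(events) + 1L]] <<- data.frame(
      sample_id = sample_id, locus = locus, replicate = rep,
      event = event, detail = detail, stringsAsFactors = FALSE)
  }

  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    row <- list(sample_id = sample_id, sample_type = sample_type,
                replicate = r)
    for (j in seq_along(loci)) {
      loc <- loci[j]
      g <- genotypes[[loc]]
      fl <- freqs[[loc]]
      visible <- fl$alleles[!fl$alleles %in% fl$null_allele]

      # (1) null-allele masking (template property, fires every replicate)
      if (!is.na(fl$null_allele) && any(g == fl$null_allele)) {
        if (all(g == fl$null_allele)) {
          log_event(loc, r, "null_mask", "null/null -> missing")
          row[[paste0(loc, "_a")]] <- NA_integer_
          row[[paste0(loc, "_b")]] <- NA_integer_
          next
        }
        other <- g[g != fl$null_allele][1L]
        log_event(loc, r, "null_mask",
                  sprintf("het with null -> homozygous %d", other))
        g <- c(other, other)
      }
      # (2) whole-locus amplification failure
      if (stats::runif(1L) < p_fail[j]) {
        log_event(loc, r, "fail", "locus failed to amplify")
        row[[paste0(loc, "_a")]] <- NA_integer_
        row[[paste0(loc, "_b")]] <- NA_integer_
        next
      }
      # (3) allelic dropout on heterozygotes
      if (g[1L] != g[2L]) {
        drop <- stats::runif(2L) < p_ado[j]
        if (all(drop)) {
          log_event(loc, r, "dropout", "both alleles dropped -> missing")
          row[[paste0(loc, "_a")]] <- NA_integer_
          row[[paste0(loc, "_b")]] <- NA_integer_
          next
        }
        if (any(drop)) {
          kept <- g[!drop][1L]
          log_event(loc, r, "dropout",
                    sprintf("allele %d dropped", g[drop][1L]))
          g <- c(kept, kept)
        }
      }
      # (4) false allele: replace one allele with a different visible one
      if (length(visible) > 1L && stats::runif(1L) < p_fa[j]) {
        pos <- sample.int(2L, 1L)
        candidates <- visible[visible != g[pos]]
        new_allele <- if (length(candidates) == 1L) candidates else
          sample(candidates, 1L)
        log_event(loc, r, "false_allele",
                  sprintf("allele %d replaced by %d", g[pos], new_allele))
        g[pos] <- new_allele
      }
      g <- sort(g)
      row[[paste0(loc, "_a")]] <- g[1L]
      row[[paste0(loc, "_b")]] <- g[2L]
    }
    rows[[r]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  obs <- do.call(rbind, rows)
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(sample_id = character(), locus = character(),
               replicate = integer(), event = character(),
               detail = character(), stringsAsFactors = FALSE)
  list(observations = genotype_table(obs, loci), events = events)
}

#' Generate a full synthetic blood + scat dataset with ground truth
#'
#' Draws allele frequencies and true genotypes, then emits one blood
#' record per reference individual, the configured matched scats (sharing
#' the reference's `individual_label`), and unmatched field scats from
#' additional individuals whose labels are withheld from the scat table
#' but retained in the truth set.
#'
#' @param config a [sim_config()].
#' @return list of class `scat_dataset` with elements `reference` and
#'   `scat` ([genotype_table()]s) and `truth` (frequencies, true
#'   genotypes incl. the extra individuals, `scat_individual` map,
#'   `sexes`, `event_log`, config echo).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  freqs <- simulate_allele_frequencies(config)
  n_total <- config$n_individuals + config$n_extra_individuals
  truth <- simulate_individuals(freqs, n_total, seed = config$seed + 1L)

  with_seed(config$seed + 2L, {
    sexes <- sample(c("male", "female"), n_total, replace = TRUE)
    names(sexes) <- truth$ids
    ref_ids <- truth$ids[seq_len(config$n_individuals)]
    extra_ids <- setdiff(truth$ids, ref_ids)

    ref_rows <- list(); scat_rows <- list(); event_rows <- list()
    scat_individual <- character()

    for (i in seq_along(ref_ids)) {
      id <- ref_ids[i]
      genos <- true_genotype_of(truth, id)
      obs <- observe_sample(genos, freqs, config, "blood", id, 1L)
      b <- as.data.frame(obs$observations)
      b$sex <- sexes[id]; b$individual_label <- id; b$replicate <- NA_integer_
      ref_rows[[length(ref_rows) + 1L]] <- b
      event_rows[[length(event_rows) + 1L]] <- obs$events

      for (s in seq_len(config$n_scat_per_individual[i])) {
        sid <- sprintf("%s_s%d", id, s)
        obs <- observe_sample(genos, freqs, config, "scat", sid,
                              config$n_replicates)
        sc <- as.data.frame(obs$observations)
        sc$sex <- sexes[id]; sc$individual_label <- id
        scat_rows[[length(scat_rows) + 1L]] <- sc
        event_rows[[length(event_rows) + 1L]] <- obs$events
        scat_individual[sid] <- id
      }
    }

    if (config$n_unmatched_scats > 0L) {
      owners <- sample(extra_ids, config$n_unmatched_scats, replace = TRUE)
      for (s in seq_len(config$n_unmatched_scats)) {
        sid <- sprintf("field_%03d", s)
        genos <- true_genotype_of(truth, owners[s])
        obs <- observe_sample(genos, freqs, config, "scat", sid,
                              config$n_replicates)
        sc <- as.data.frame(obs$observations)
        sc$sex <- sexes[owners[s]]; sc$individual_label <- NA_character_
        scat_rows[[length(scat_rows) + 1L]] <- sc
        event_rows[[length(event_rows) + 1L]] <- obs$events
        scat_individual[sid] <- owners[s]
      }
    }

    reference <- genotype_table(do.call(rbind, ref_rows), config$locus_names)
    scat_df <- if (length(scat_rows)) do.call(rbind, scat_rows) else
      as.data.frame(reference)[0, , drop = FALSE]
    scat <- genotype_table(scat_df, config$locus_names)
    event_log <- do.call(rbind, event_rows)
    structure(list(
      reference = reference,
      scat = scat,
      truth = list(frequencies = freqs, genotypes = truth,
                   scat_individual = scat_individual, sexes = sexes,
                   event_log = event_log, config = config)),
      class = "scat_dataset")
  })
}
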
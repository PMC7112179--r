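# Seeded synthetic-data generators. Every generator is a pure function of
# (config, seed): it seeds the RNG from `config$seed` plus a fixed
# per-generator offset, so the whole pipeline is reproducible and each
# stage can be regenerated independently. Generated data always come with
# truth tables so recovery tests never re-derive the planted signal.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators with defaults that
#' reproduce the structure of the study inputs: four tissues (seedling
#' reference plus three male-lineage stages) with four replicates each,
#' 18.3% of TEs within 2 kb of a gene, negative-binomial counts with
#' male-lineage TE activation, an optional coupling between a gene's
#' expression rank and the activation probability of its neighboring TEs,
#' and beta-binomial per-ear seed counts whose intra-ear correlation is
#' calibrated to a Pearson dispersion of about 1.8 at the default ear
#' sizes (380-1305 seeds per ear, so four ears per allele give totals in
#' the observed 1,522-5,219 range).
#'
#' @param seed integer RNG seed.
#' @param n_chrom,n_genes,n_tes annotation sizes.
#' @param te_family_mix named fractions summing to 1; family labels follow
#'   the three-letter TE code (RL* = LTR, DT* = DNA, RIL = LINE,
#'   RST = SINE).
#' @param tissue_design data.frame `tissue`, `n_replicates`.
#' @param nb_mean_log_mu,nb_log_sd log-normal baseline of feature means.
#' @param nb_dispersion NB dispersion (size = 1/dispersion).
#' @param te_activation named list tissue -> `c(fraction, log2_effect)`.
#' @param te_silent_fraction fraction of TEs with negligible baseline
#'   expression (these populate the not-covered category).
#' @param coupling_kappa strength of the rank-dependent activation coupling
#'   for near-gene TEs in activated tissues; 0 = no coupling (null).
#' @param proximity_fraction fraction of TEs planted within 2 kb of a gene.
#' @param gene_specific_fraction,gene_specific_log2 fraction of genes with
#'   a preferred tissue and the log2 boost they get there.
#' @param ears_per_allele,seeds_per_ear_range transmission-assay design.
#' @param true_rates named vector allele -> true transmission rate; when
#'   `NULL`, 56 alleles at 0.5 split 35/11/10 over the vegetative cell,
#'   sperm cell and seedling classes.
#' @param overdispersion_rho intra-ear correlation of the beta-binomial;
#'   when `NULL`, calibrated with [rho_for_phi()] for phi = 1.8.
#'
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L, n_chrom = 5L, n_genes = 1000L,
                       n_tes = 800L,
                       te_family_mix = c(RLG = 0.25, RLC = 0.20, RLX = 0.15,
                                         DTM = 0.10, DTA = 0.05, DTC = 0.05,
                                         DTH = 0.05, DHH = 0.08, RIL = 0.05,
                                         RST = 0.02),
                       tissue_design = data.frame(
                         tissue = c("seedling", "microspore", "pollen",
                                    "sperm_cell"),
                         n_replicates = 4L),
                       nb_mean_log_mu = log(50), nb_log_sd = 1,
                       nb_dispersion = 0.1,
                       te_activation = list(
                         microspore = c(fraction = 0.15, log2_effect = 2),
                         pollen = c(fraction = 0.12, log2_effect = 2),
                         sperm_cell = c(fraction = 0.10, log2_effect = 2)),
                       te_silent_fraction = 0.40,
                       coupling_kappa = 1,
                       proximity_fraction = 0.183,
                       gene_specific_fraction = 0.5,
                       gene_specific_log2 = 3,
                       ears_per_allele = 4L,
                       seeds_per_ear_range = c(380L, 1305L),
                       true_rates = NULL,
                       overdispersion_rho = NULL) {
  stopifnot(abs(sum(te_family_mix) - 1) < 1e-6,
            proximity_fraction >= 0, proximity_fraction <= 1,
            te_silent_fraction >= 0, te_silent_fraction <= 1,
            coupling_kappa >= 0, nb_dispersion > 0,
            length(seeds_per_ear_range) == 2,
            seeds_per_ear_range[1] <= seeds_per_ear_range[2])
  if (is.null(overdispersion_rho))
    overdispersion_rho <- rho_for_phi(1.8, mean(seeds_per_ear_range))
  stopifnot(overdispersion_rho >= 0, overdispersion_rho < 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Intra-ear correlation for a target Pearson dispersion
#'
#' Under the beta-binomial, the Pearson dispersion of an ear of size `n`
#' has expectation `1 + (n - 1) * rho`; inverting at the mean ear size
#' gives the correlation that produces a pooled dispersion of about
#' `phi` at the generator's defaults.
#'
#' @param phi target Pearson dispersion (> 1).
#' @param mean_ear_size average seeds per ear.
#' @return The intra-ear correlation `rho`.
#' @export
rho_for_phi <- function(phi, mean_ear_size) {
  stopifnot(phi >= 1, mean_ear_size > 1)
  (phi - 1) / (mean_ear_size - 1)
}

#' Generate a synthetic genome annotation
#'
#' Genes and TEs are placed without overlap: each chromosome is a shuffled
#' sequence of units (a gene, optionally with a near TE attached at a gap
#' drawn uniformly from 0-1999 bp, or a distal TE) separated by at least
#' 2.5 kb, so planted near/distal status is exact under the 2 kb rule. A
#' centromere is placed at the middle of each chromosome. One isoform per
#' gene is recorded with transcript length 60% of the gene body.
#'
#' @param config a [sim_config].
#' @return A [genome_annotation].
#' @export
gen_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_genes <- config$n_genes; n_tes <- config$n_tes
  fams <- sample(names(config$te_family_mix), n_tes, replace = TRUE,
                 prob = config$te_family_mix)
  n_near <- round(config$proximity_fraction * n_tes)
  te_near <- c(rep(TRUE, n_near), rep(FALSE, n_tes - n_near))

  gene_chrom <- sort(rep_len(seq_len(config$n_chrom), n_genes))
  # each gene offers an upstream and a downstream slot for a near TE
  if (n_near > 2L * n_genes)
    stop("more near TEs requested than available gene-adjacent slots")
  slots <- if (n_near > 0) sample.int(2L * n_genes, n_near) else integer(0)
  host_gene <- ceiling(slots / 2)
  upstream <- slots %% 2L == 1L
  distal_chrom <- rep_len(seq_len(config$n_chrom), n_tes - n_near)

  gene_len <- sample(2000:5000, n_genes, replace = TRUE)
  te_len <- pmax(200L, round(exp(stats::rnorm(n_tes, log(1500), 0.8))))

  genes <- data.frame(gene_id = sprintf("gene%04d", seq_len(n_genes)),
                      chrom = paste0("chr", gene_chrom),
                      start = NA_integer_, end = NA_integer_, strand = "+")
  tes <- data.frame(te_id = sprintf("TE%04d", seq_len(n_tes)),
                    chrom = NA_character_, start = NA_integer_,
                    end = NA_integer_, strand = "+", family = fams)
  near_gap <- sample(0:1999, n_near, replace = TRUE)

  spacer <- 2500L
  for (ch in seq_len(config$n_chrom)) {
    g_idx <- which(gene_chrom == ch)
    d_idx <- which(!te_near)[distal_chrom == ch]
    units <- c(paste0("g", g_idx), paste0("t", d_idx))
    units <- sample(units)
    pos <- 1L
    for (u in units) {
      i <- as.integer(substring(u, 2))
      if (startsWith(u, "g")) {
        up <- which(host_gene == i & upstream)    # near TEs occupy the
        dn <- which(host_gene == i & !upstream)   # first n_near TE slots
        for (a in up) {
          tes$start[a] <- pos
          tes$end[a] <- pos + te_len[a] - 1L
          pos <- tes$end[a] + 1L + near_gap[a]
        }
        genes$start[i] <- pos
        genes$end[i] <- pos + gene_len[i] - 1L
        pos <- genes$end[i] + 1L
        for (a in dn) {
          tes$start[a] <- pos + near_gap[a]
          tes$end[a] <- tes$start[a] + te_len[a] - 1L
          pos <- tes$end[a] + 1L
        }
      } else {
        tes$chrom[i] <- paste0("chr", ch)
        tes$start[i] <- pos
        tes$end[i] <- pos + te_len[i] - 1L
        pos <- tes$end[i] + 1L
      }
      pos <- pos + spacer + sample(0:2000, 1L)
    }
  }
  # near TEs inherit the chromosome of their host gene
  tes$chrom[seq_len(n_near)] <- genes$chrom[host_gene]

  ends <- tapply(c(genes$end, tes$end), c(genes$chrom, tes$chrom), max)
  chrom_lengths <- stats::setNames(as.integer(ends * 1.1), names(ends))
  cen_w <- pmax(1000L, round(chrom_lengths * 0.02))
  centromeres <- data.frame(
    chrom = names(chrom_lengths),
    start = as.integer(round(chrom_lengths / 2)),
    end = as.integer(round(chrom_lengths / 2) + cen_w))
  chrom_lengths <- pmax(chrom_lengths, centromeres$end + 10L)

  transcripts <- data.frame(
    gene_id = genes$gene_id,
    isoform_id = paste0(genes$gene_id, "_T01"),
    transcript_length_bp = as.integer(round(gene_len * 0.6)))
  genome_annotation(genes, tes, centromeres = centromeres,
                    chrom_lengths = chrom_lengths,
                    transcripts = transcripts)
}

#' Generate synthetic gene and TE counts with planted structure
#'
#' Per-feature baseline means are log-normal; a configured fraction of
#' genes gets a preferred tissue with a log2 boost, and TEs are activated
#' (multiplied by `2^log2_effect`) in the tissues named in
#' `te_activation`. With `coupling_kappa > 0` the activation probability
#' of a near-gene TE in an activated tissue scales with its neighbor
#' gene's expression percentile in that tissue,
#' `p = fraction * (1 + kappa * percentile)` (capped at 1), which plants
#' the monotone gene-TE neighborhood association; `kappa = 0` is the null.
#' Replicate counts are negative binomial. A `te_silent_fraction` of TEs
#' is given a negligible baseline so the not-covered category is populated.
#'
#' @param config a [sim_config].
#' @param annotation a [gen_annotation()] result.
#' @return A list: `counts` (a [count_matrix] over genes then TEs),
#'   `truth` (list with `activated` data.frame `te_id`, `tissue`;
#'   `gene_preferred` data.frame `gene_id`, `tissue`; `mu` matrix of
#'   planted means).
#' @export
gen_counts <- function(config, annotation) {
  stopifnot(inherits(config, "sim_config"),
            inherits(annotation, "genome_annotation"))
  set.seed(config$seed + 1L)
  genes <- annotation$genes$gene_id
  tes <- annotation$tes$te_id
  tissues <- config$tissue_design$tissue
  n_g <- length(genes); n_t <- length(tes)

  base_g <- exp(stats::rnorm(n_g, config$nb_mean_log_mu, config$nb_log_sd))
  base_t <- exp(stats::rnorm(n_t, config$nb_mean_log_mu, config$nb_log_sd))
  silent <- stats::runif(n_t) < config$te_silent_fraction
  base_t[silent] <- 0.05

  pref <- rep(NA_character_, n_g)
  chosen <- stats::runif(n_g) < config$gene_specific_fraction
  pref[chosen] <- sample(tissues, sum(chosen), replace = TRUE)

  mu <- matrix(0, n_g + n_t, length(tissues),
               dimnames = list(c(genes, tes), tissues))
  for (t in tissues) {
    gmu <- base_g * ifelse(!is.na(pref) & pref == t,
                           2^config$gene_specific_log2, 1)
    mu[seq_len(n_g), t] <- gmu
  }

  prox <- classify_proximity(annotation)
  te_to_gene <- rep(NA_character_, n_t)
  for (g in names(prox$gene_te_map)) {
    for (te in prox$gene_te_map[[g]]) {
      i <- match(te, tes)
      if (is.na(te_to_gene[i])) te_to_gene[i] <- g
    }
  }

  activated <- data.frame(te_id = character(0), tissue = character(0))
  for (t in tissues) {
    tmu <- base_t
    act_cfg <- config$te_activation[[t]]
    if (!is.null(act_cfg)) {
      frac <- act_cfg[["fraction"]]
      eff <- act_cfg[["log2_effect"]]
      # gene expression percentile in this tissue (1 = highest)
      grank <- rank(mu[seq_len(n_g), t], ties.method = "first")
      pct <- stats::setNames((grank - 1) / max(n_g - 1, 1), genes)
      p_act <- rep(frac, n_t)
      near_i <- which(!is.na(te_to_gene) & !silent)
      p_act[near_i] <- pmin(
        1, frac * (1 + config$coupling_kappa * pct[te_to_gene[near_i]]))
      p_act[silent] <- 0
      act <- stats::runif(n_t) < p_act
      tmu[act] <- tmu[act] * 2^eff
      if (any(act))
        activated <- rbind(activated,
                           data.frame(te_id = tes[act], tissue = t))
    }
    mu[n_g + seq_len(n_t), t] <- tmu
  }

  reps <- config$tissue_design$n_replicates
  samples <- data.frame(
    sample_id = unlist(mapply(function(t, r) paste0(t, "_", seq_len(r)),
                              tissues, reps, SIMPLIFY = FALSE)),
    tissue = rep(tissues, reps),
    replicate = unlist(lapply(reps, seq_len)))
  size <- 1 / config$nb_dispersion
  vals <- vapply(seq_len(nrow(samples)), function(j) {
    m <- mu[, samples$tissue[j]]
    stats::rnbinom(length(m), mu = m, size = size)
  }, numeric(nrow(mu)))
  rownames(vals) <- rownames(mu)
  samples$library_size <- round(colSums(vals) * 1.15)
  list(counts = count_matrix(vals, samples),
       truth = list(
         activated = activated,
         gene_preferred = data.frame(gene_id = genes, tissue = pref),
         mu = mu))
}

#' Generate multi-mapped read placements
#'
#' Each read draws a multiplicity (number of equally best-scoring candidate
#' loci) from `multiplicity_probs`; each locus lands inside a random TE
#' with probability `in_te_prob`, else in unannotated background near the
#' start of a random chromosome.
#'
#' @param config a [sim_config].
#' @param annotation a [genome_annotation].
#' @param n_reads number of reads, default 500.
#' @param multiplicity_probs named numeric vector: probability of each
#'   multiplicity (names are the multiplicities).
#' @param in_te_prob probability a candidate locus falls inside a TE.
#' @return data.frame `read_id`, `chrom`, `start`, `end` (one row per
#'   candidate locus).
#' @export
gen_placements <- function(config, annotation, n_reads = 500L,
                           multiplicity_probs = c(`1` = 0.7, `2` = 0.15,
                                                  `4` = 0.1, `10` = 0.05),
                           in_te_prob = 0.8) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  tes <- annotation$tes
  mult <- as.integer(sample(names(multiplicity_probs), n_reads,
                            replace = TRUE, prob = multiplicity_probs))
  read_id <- rep(sprintf("read%05d", seq_len(n_reads)), mult)
  n_loci <- sum(mult)
  in_te <- stats::runif(n_loci) < in_te_prob
  te_pick <- sample.int(nrow(tes), n_loci, replace = TRUE)
  loc_len <- 100L
  start <- integer(n_loci); end <- integer(n_loci)
  chrom <- character(n_loci)
  for (i in seq_len(n_loci)) {
    if (in_te[i]) {
      te <- tes[te_pick[i], ]
      s_max <- max(te$start, te$end - loc_len + 1L)
      start[i] <- te$start + sample.int(max(s_max - te$start, 1L), 1L) - 1L
      end[i] <- min(start[i] + loc_len - 1L, te$end)
      chrom[i] <- te$chrom
    } else {
      # background: positions below the first feature of the chromosome
      # are not guaranteed feature-free, which is fine -- unassigned mass
      # is measured, not assumed
      ch <- sample(names(annotation$chrom_lengths), 1L)
      start[i] <- sample.int(1000L, 1L)
      end[i] <- start[i] + loc_len - 1L
      chrom[i] <- ch
    }
  }
  data.frame(read_id = read_id, chrom = chrom, start = start, end = end)
}

default_allele_info <- function(config) {
  n_vc <- 35L; n_sc <- 11L; n_sl <- 10L
  cls <- c(rep("vegetative_cell", n_vc), rep("sperm_cell", n_sc),
           rep("seedling", n_sl))
  n <- length(cls)
  info <- data.frame(
    allele_id = sprintf("allele%02d", seq_len(n)),
    gene_id = sprintf("geneT%02d", seq_len(n)),
    expression_class = cls,
    log2_fpkm = round(stats::runif(n, 3, 13), 2),
    true_rate = 0.5)
  if (!is.null(config$true_rates)) {
    idx <- match(names(config$true_rates), info$allele_id)
    if (anyNA(idx)) stop("true_rates names must match allele ids")
    info$true_rate[idx] <- unname(config$true_rates)
  }
  info
}

#' Generate beta-binomial per-ear seed counts
#'
#' Each allele gets `ears_per_allele` ears spread over
#' `ceiling(ears_per_allele / 2)` plants; ear sizes are uniform over
#' `seeds_per_ear_range`; the marked count of an ear of size `n` and true
#' rate `p` is binomial with a beta-distributed ear-level rate of mean `p`
#' and intra-ear correlation `overdispersion_rho` (beta-binomial), so the
#' variance is `n p (1-p) (1 + (n-1) rho)`.
#'
#' @param config a [sim_config].
#' @param allele_info optional data.frame `allele_id`, `gene_id`,
#'   `expression_class`, `log2_fpkm`, `true_rate`; defaults to 56 alleles
#'   at rate 0.5 split 35/11/10 across the vegetative cell, sperm cell and
#'   seedling classes, overridden by `config$true_rates`.
#' @param direction cross direction label for the generated ears.
#' @return data.frame of ear observations (see [qc_ears()]) with the
#'   allele metadata columns attached; the `true_rate` column is the truth
#'   table.
#' @export
gen_ear_counts <- function(config, allele_info = NULL, direction = "male") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  if (is.null(allele_info)) allele_info <- default_allele_info(config)
  rho <- config$overdispersion_rho
  k <- config$ears_per_allele
  rng <- config$seeds_per_ear_range
  out <- do.call(rbind, lapply(seq_len(nrow(allele_info)), function(i) {
    p <- allele_info$true_rate[i]
    n_tot <- sample(rng[1]:rng[2], k, replace = TRUE)
    p_ear <- if (rho > 0) {
      stats::rbeta(k, p * (1 - rho) / rho, (1 - p) * (1 - rho) / rho)
    } else rep(p, k)
    data.frame(
      allele_id = allele_info$allele_id[i],
      gene_id = allele_info$gene_id[i],
      expression_class = allele_info$expression_class[i],
      log2_fpkm = allele_info$log2_fpkm[i],
      plant_id = paste0(allele_info$allele_id[i], "_p",
                        rep(seq_len(ceiling(k / 2)), each = 2)[seq_len(k)]),
      ear_id = paste0(allele_info$allele_id[i], "_e", seq_len(k)),
      direction = direction, marker = "GFP",
      n_marked = stats::rbinom(k, n_tot, p_ear), n_total = n_tot,
      true_rate = p)
  }))
  rownames(out) <- NULL
  out
}

#' Generate fertilization-outcome and seed-census tables
#'
#' Ovule outcomes per pollen-parent group are multinomial over the six
#' fertilization categories; per-ear small-seed counts are binomial with
#' group-specific rates.
#'
#' @param config a [sim_config].
#' @param outcome_probs named list group -> probability vector of length 6
#'   (order: one synergid x both/endosperm-only/embryo-only, then both
#'   synergids x the same), summing to 1.
#' @param n_ovules named vector group -> ovules assessed.
#' @param census_design data.frame `genotype_group`, `n_ears`,
#'   `seeds_per_ear`, `small_rate`.
#' @return A list with `fertilization` (data.frame in the
#'   [fertilization_outcome_test()] layout) and `census` (data.frame of
#'   per-ear seed censuses).
#' @export
gen_phenotypes <- function(config,
                           outcome_probs = list(
                             wild_type = c(1, 0, 0, 0, 0, 0),
                             mutant = c(0.5, 0.17, 0.17, 0, 0, 0.16)),
                           n_ovules = c(wild_type = 28L, mutant = 12L),
                           census_design = data.frame(
                             genotype_group = c("control_a", "control_b",
                                                "mutant_het", "mutant_hom"),
                             n_ears = 6L, seeds_per_ear = 300L,
                             small_rate = c(0.02, 0.02, 0.05, 0.10))) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 4L)
  bad <- vapply(outcome_probs, function(p)
    length(p) != 6 || abs(sum(p) - 1) > 1e-8, TRUE)
  if (any(bad)) stop("outcome probabilities must be length 6 and sum to 1")
  cols <- c("one_syn_both", "one_syn_endosperm_only", "one_syn_embryo_only",
            "both_syn_both", "both_syn_endosperm_only",
            "both_syn_embryo_only")
  fert <- do.call(rbind, lapply(names(outcome_probs), function(g) {
    counts <- stats::rmultinom(1, n_ovules[[g]], outcome_probs[[g]])[, 1]
    df <- data.frame(group = g)
    df[cols] <- as.list(counts)
    df
  }))
  census <- do.call(rbind, lapply(seq_len(nrow(census_design)), function(i) {
    d <- census_design[i, ]
    small <- stats::rbinom(d$n_ears, d$seeds_per_ear, d$small_rate)
    data.frame(ear_id = paste0(d$genotype_group, "_e", seq_len(d$n_ears)),
               genotype_group = d$genotype_group,
               n_small = small, n_normal = d$seeds_per_ear - small,
               seedless_area_pct = round(
                 100 * stats::rbeta(d$n_ears, 2,
                                    2 / pmax(d$small_rate, 1e-3) ), 2))
  }))
  rownames(census) <- NULL
  list(fertilization = fert, census = census)
}
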
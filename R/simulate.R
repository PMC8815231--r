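#' Configure a synthetic tumor cohort
#'
#' Builds and validates the parameter set for [simulate_cohort()]. The
#' generator emulates the structure of an exome-sequenced gastric tumor
#' cohort: two microsatellite classes with very different mutation burdens
#' (MSS low, MSIH high), mutations placed on genes proportionally to coding
#' length, missense/truncation class labels, exponential survival under
#' proportional hazards with optional planted protective or deleterious gene
#' sets, independent exponential right-censoring, and RSEM-like per-gene mean
#' expression values.
#'
#' @param n_samples Number of tumors in the cohort.
#' @param frac_msih Proportion of tumors labeled MSIH (microsatellite
#'   instability-high); the rest are MSS.
#' @param n_genes Number of genes in the simulated exome.
#' @param n_family_genes Number of genes flagged as the family of interest.
#'   Family gene symbols are a random (seeded) subset of all symbols, so the
#'   family is exchangeable with background genes under a null configuration.
#' @param gene_length_range Integer pair: coding length (bases) is drawn
#'   uniformly from this range.
#' @param mut_rate_mss,mut_rate_msih Expected somatic mutations per megabase
#'   of coding sequence per sample for MSS and MSIH tumors;
#'   `mut_rate_msih` must exceed `mut_rate_mss`.
#' @param frac_truncation Probability a mutation is truncating (nonsense,
#'   frameshift, splice); otherwise it is missense.
#' @param effect_sets List of planted survival effects. Each element is a
#'   list with `genes` (integer indices into the family gene list, or family
#'   gene symbols) and `log_hr` (log hazard ratio applied to samples carrying
#'   at least one qualifying mutation in the set).
#' @param effect_class Which mutation class activates an effect set:
#'   `"any"` (default), `"truncation"`, or `"missense"`.
#' @param family_rate_multiplier Relative mutation rate of family genes
#'   (per base) versus background; 1 is the null. Mutation placement weights
#'   are coding length times this multiplier for family genes.
#' @param baseline_hazard Event rate per month for an unaffected sample.
#' @param censoring_rate Rate per month of the independent exponential
#'   censoring process.
#' @param expression_range Numeric pair: per-gene mean expression (RSEM
#'   scale) is drawn uniformly from this range.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration.
#'
#' @return A validated object of class `sim_config`.
#' @seealso [simulate_cohort()], [write_cohort()]
#' @export
sim_config <- function(n_samples = 300L,
                       frac_msih = 0.22,
                       n_genes = 500L,
                       n_family_genes = 40L,
                       gene_length_range = c(1000L, 6000L),
                       mut_rate_mss = 2,
                       mut_rate_msih = 20,
                       frac_truncation = 0.3,
                       effect_sets = list(),
                       effect_class = c("any", "truncation", "missense"),
                       family_rate_multiplier = 1,
                       baseline_hazard = 0.02,
                       censoring_rate = 0.0086,
                       expression_range = c(0, 2000),
                       seed = 1L) {
  cfg <- list(
    n_samples = n_samples, frac_msih = frac_msih, n_genes = n_genes,
    n_family_genes = n_family_genes, gene_length_range = gene_length_range,
    mut_rate_mss = mut_rate_mss, mut_rate_msih = mut_rate_msih,
    frac_truncation = frac_truncation, effect_sets = effect_sets,
    effect_class = match.arg(effect_class),
    family_rate_multiplier = family_rate_multiplier,
    baseline_hazard = baseline_hazard, censoring_rate = censoring_rate,
    expression_range = expression_range, seed = seed
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  bad <- function(field, why) {
    stopf("invalid simulation configuration: field '%s' %s", field, why)
  }
  if (!is_count(cfg$n_samples) || cfg$n_samples < 1) {
    bad("n_samples", "must be a positive integer")
  }
  if (!is_proportion(cfg$frac_msih)) bad("frac_msih", "must lie in [0, 1]")
  if (!is_count(cfg$n_genes) || cfg$n_genes < 1) {
    bad("n_genes", "must be a positive integer")
  }
  if (!is_count(cfg$n_family_genes) || cfg$n_family_genes < 1) {
    bad("n_family_genes", "must be a positive integer")
  }
  if (cfg$n_family_genes > cfg$n_genes) {
    bad("n_family_genes", "cannot exceed n_genes")
  }
  glr <- cfg$gene_length_range
  if (length(glr) != 2L || any(!is.finite(glr)) || any(glr < 3) ||
      glr[1] > glr[2]) {
    bad("gene_length_range", "must be an increasing pair of lengths >= 3")
  }
  if (!is_positive_scalar(cfg$mut_rate_mss)) {
    bad("mut_rate_mss", "must be strictly positive")
  }
  if (!is_positive_scalar(cfg$mut_rate_msih)) {
    bad("mut_rate_msih", "must be strictly positive")
  }
  if (cfg$mut_rate_msih <= cfg$mut_rate_mss) {
    bad("mut_rate_msih", "must exceed mut_rate_mss")
  }
  if (!is_proportion(cfg$frac_truncation)) {
    bad("frac_truncation", "must lie in [0, 1]")
  }
  if (!is.list(cfg$effect_sets)) bad("effect_sets", "must be a list")
  for (es in cfg$effect_sets) {
    if (!is.list(es) || is.null(es$genes) || is.null(es$log_hr) ||
        length(es$genes) < 1L || !is.finite(es$log_hr)) {
      bad("effect_sets", "entries need non-empty 'genes' and finite 'log_hr'")
    }
    if (is.numeric(es$genes) &&
        (any(es$genes < 1) || any(es$genes > cfg$n_family_genes) ||
         any(es$genes != floor(es$genes)))) {
      bad("effect_sets", "numeric gene indices must address family genes")
    }
  }
  if (!is_positive_scalar(cfg$family_rate_multiplier)) {
    bad("family_rate_multiplier", "must be strictly positive")
  }
  if (!is_positive_scalar(cfg$baseline_hazard)) {
    bad("baseline_hazard", "must be strictly positive")
  }
  if (!is_positive_scalar(cfg$censoring_rate)) {
    bad("censoring_rate", "must be strictly positive")
  }
  er <- cfg$expression_range
  if (length(er) != 2L || any(!is.finite(er)) || any(er < 0) ||
      er[1] > er[2]) {
    bad("expression_range", "must be an increasing pair of nonnegative reals")
  }
  if (!is_count(abs(cfg$seed))) bad("seed", "must be an integer")
  invisible(cfg)
}

trunc_classes_sim <- c("Nonsense_Mutation", "Frame_Shift_Del",
                       "Frame_Shift_Ins", "Splice_Site")

#' Simulate a tumor cohort with MAF-style mutations and survival outcomes
#'
#' Draws one synthetic cohort under a [sim_config()]. Per-sample mutation
#' counts are Poisson with expectation (class rate per Mb) x (total coding
#' megabases); each mutation lands on gene *g* with probability proportional
#' to *g*'s coding length (times `family_rate_multiplier` for family genes);
#' mutation class is truncating with probability `frac_truncation`, else
#' missense; protein positions are uniform over the protein length
#' (coding length / 3, floored, 1-based). Survival time is exponential with
#' rate `baseline_hazard * exp(sum of active planted log hazard ratios)`;
#' censoring is an independent exponential; observed time is the minimum,
#' rounded to 0.1 months. Deterministic given the seed.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `sim_cohort` with elements
#'   * `maf`: data frame with columns `Hugo_Symbol`, `Tumor_Sample_Barcode`,
#'     `Variant_Classification`, `Protein_position` (`"pos/protein_length"`);
#'   * `clinical`: data frame `sample`, `os_months`, `os_event`,
#'     `msi_status`, `age`, `stage`;
#'   * `expression`: data frame `gene`, `mean_rsem`;
#'   * `genes`: data frame `gene`, `coding_length`, `in_family`;
#'   * `truth`: planted parameters for recovery tests — per-sample
#'     `msi_status` and latent `hazard_multiplier`, the resolved
#'     `effect_sets` (gene symbols plus log hazard ratio), per-gene length
#'     and family flag, and the configuration.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  local_seed(config$seed, {
    n <- config$n_samples
    ng <- config$n_genes

    gene <- sprintf("G%04d", seq_len(ng))
    len <- sample(seq.int(config$gene_length_range[1],
                          config$gene_length_range[2]),
                  ng, replace = TRUE)
    prot_len <- pmax(1L, len %/% 3L)
    family_idx <- sort(sample.int(ng, config$n_family_genes))
    in_family <- seq_len(ng) %in% family_idx
    family_genes <- gene[family_idx]

    # resolve planted effect sets against the family gene list
    effect_sets <- lapply(config$effect_sets, function(es) {
      g <- if (is.numeric(es$genes)) family_genes[es$genes] else es$genes
      if (!all(g %in% family_genes)) {
        stopf("invalid simulation configuration: field 'effect_sets' %s",
              "references genes outside the family")
      }
      list(genes = g, log_hr = es$log_hr)
    })

    mean_rsem <- round(stats::runif(ng, config$expression_range[1],
                                    config$expression_range[2]), 1)

    sample_id <- sprintf("S%04d", seq_len(n))
    msi <- ifelse(stats::runif(n) < config$frac_msih, "MSIH", "MSS")
    genome_mb <- sum(len) / 1e6
    rate <- ifelse(msi == "MSIH", config$mut_rate_msih, config$mut_rate_mss)
    n_mut <- stats::rpois(n, rate * genome_mb)
    total <- sum(n_mut)

    w <- len * ifelse(in_family, config$family_rate_multiplier, 1)
    gidx <- sample.int(ng, total, replace = TRUE, prob = w)
    is_trunc <- stats::runif(total) < config$frac_truncation
    vclass <- ifelse(is_trunc,
                     trunc_classes_sim[sample.int(4L, total, replace = TRUE)],
                     "Missense_Mutation")
    pos <- 1L + as.integer(floor(stats::runif(total) * prot_len[gidx]))

    mut_sample <- rep(sample_id, n_mut)
    maf <- data.frame(
      Hugo_Symbol = gene[gidx],
      Tumor_Sample_Barcode = mut_sample,
      Variant_Classification = vclass,
      Protein_position = sprintf("%d/%d", pos, prot_len[gidx]),
      stringsAsFactors = FALSE
    )

    # planted hazards: a set is active in a sample carrying >= 1 qualifying
    # mutation in any of its genes
    qualifies <- switch(config$effect_class,
                        any = rep(TRUE, total),
                        truncation = is_trunc,
                        missense = !is_trunc)
    log_mult <- numeric(n)
    for (es in effect_sets) {
      hit <- qualifies & (gene[gidx] %in% es$genes)
      active <- sample_id %in% unique(mut_sample[hit])
      log_mult <- log_mult + es$log_hr * active
    }
    hazard_multiplier <- exp(log_mult)

    t_event <- stats::rexp(n, rate = config$baseline_hazard * hazard_multiplier)
    t_cens <- stats::rexp(n, rate = config$censoring_rate)
    os_months <- round(pmin(t_event, t_cens), 1)
    os_event <- as.integer(t_event <= t_cens)

    age <- pmin(95L, pmax(25L, as.integer(round(stats::rnorm(n, 66, 10)))))
    stage <- sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                    prob = c(0.2, 0.3, 0.3, 0.2))

    clinical <- data.frame(
      sample = sample_id, os_months = os_months, os_event = os_event,
      msi_status = msi, age = age, stage = stage, stringsAsFactors = FALSE
    )
    genes_tab <- data.frame(
      gene = gene, coding_length = as.integer(len), in_family = in_family,
      stringsAsFactors = FALSE
    )
    expression <- data.frame(gene = gene, mean_rsem = mean_rsem,
                             stringsAsFactors = FALSE)
    truth <- list(
      samples = data.frame(sample = sample_id, msi_status = msi,
                           hazard_multiplier = hazard_multiplier,
                           stringsAsFactors = FALSE),
      effect_sets = effect_sets,
      genes = genes_tab,
      config = config
    )
    structure(list(maf = maf, clinical = clinical, expression = expression,
                   genes = genes_tab, truth = truth),
              class = "sim_cohort")
  })
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d samples (%d MSIH), %d genes (%d family), %d mutations\n",
    nrow(x$clinical), sum(x$clinical$msi_status == "MSIH"),
    nrow(x$genes), sum(x$genes$in_family), nrow(x$maf)))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits the tab-separated tables the readers in the package consume
#' (`maf.tsv`, `clinical.tsv`, `expression.tsv`, `genes.tsv`) plus
#' `truth.json` holding the planted parameters. Output is byte-identical for
#' identical cohorts.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(maf = file.path(dir, "maf.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             expression = file.path(dir, "expression.tsv"),
             genes = file.path(dir, "genes.tsv"),
             truth = file.path(dir, "truth.json"))
  wt <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  wt(cohort$maf, paths["maf"])
  wt(cohort$clinical, paths["clinical"])
  wt(cohort$expression, paths["expression"])
  wt(cohort$genes, paths["genes"])
  truth <- cohort$truth
  jsonlite::write_json(
    list(samples = truth$samples,
         effect_sets = lapply(truth$effect_sets, function(es)
           list(genes = as.list(es$genes), log_hr = es$log_hr)),
         genes = truth$genes),
    paths["truth"], auto_unbox = TRUE, digits = 10
  )
  invisible(paths)
}

#' Simulate germline variant protein positions
#'
#' Draws variant positions on a protein of length `floor(gene_length / 3)`,
#' uniformly except for an optional recurrent hotspot that receives extra
#' weight (emulating, e.g., a recurring nonsense position in a
#' collagenopathy variant database). With hotspot weight *w* and protein
#' length *L*, the hotspot position is drawn with probability
#' `w + (1 - w) / L`.
#'
#' @param gene_length Coding length in bases.
#' @param n_variants Number of variant positions to draw (>= 1).
#' @param hotspot_position Optional 1-based protein position of the hotspot.
#' @param hotspot_weight Extra probability mass on the hotspot, in [0, 1].
#' @param seed Integer seed.
#' @return Integer vector of 1-based protein positions.
#' @export
simulate_germline_variants <- function(gene_length, n_variants,
                                       hotspot_position = NULL,
                                       hotspot_weight = 0,
                                       seed = 1L) {
  if (!is_count(gene_length) || gene_length < 3) {
    stopf("gene_length must be a positive integer >= 3")
  }
  if (!is_count(n_variants) || n_variants < 1) {
    stopf("n_variants must be a positive integer")
  }
  if (!is_proportion(hotspot_weight)) {
    stopf("hotspot_weight must lie in [0, 1]")
  }
  prot_len <- gene_length %/% 3
  if (!is.null(hotspot_position)) {
    if (!is_count(hotspot_position) || hotspot_position < 1 ||
        hotspot_position > prot_len) {
      stopf("hotspot_position %s is outside the protein (length %d)",
            format(hotspot_position), prot_len)
    }
  } else if (hotspot_weight > 0) {
    stopf("hotspot_weight > 0 requires hotspot_position")
  }
  local_seed(seed, {
    pos <- 1L + as.integer(floor(stats::runif(n_variants) * prot_len))
    if (!is.null(hotspot_position) && hotspot_weight > 0) {
      hot <- stats::runif(n_variants) < hotspot_weight
      pos[hot] <- as.integer(hotspot_position)
    }
    pos
  })
}
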
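#' Simulation settings for a synthetic immunotherapy cohort
#'
#' Bundles everything the generators need to emulate the statistical
#' structure of the analysis: a two-class expression cohort with a planted
#' fraction of differentially expressed (DE) genes, per-sample mutation
#' tables with controllable non-synonymous burden, gene-level copy-number
#' matrices with controllable magnitude (hence controllable CIN score),
#' purity values, and exponential survival with a class-linked hazard.
#'
#' @param n_genes number of genes.
#' @param n_samples_per_class samples per class (responders and
#'   non-responders each get this many).
#' @param frac_de fraction of genes with a planted response effect, in
#'   `[0, 1]`.
#' @param effect_size mean log2 shift added to DE genes in responders, in
#'   units of `noise_sd`.
#' @param noise_sd per-gene Gaussian noise SD on the log2 scale (> 0).
#' @param n_driver_genes size of the simulated driver-gene universe
#'   mutations fall on.
#' @param burden_range integer interval `c(lo, hi)` for per-sample
#'   non-synonymous mutation counts (uniform draw).
#' @param cna_magnitude SD of simulated gene-level GISTIC2 values (>= 0);
#'   the expected CIN score is `n_genes * cna_magnitude^2`.
#' @param hazard_ratio multiplier applied to the baseline survival hazard
#'   for planted responders (> 0; values below 1 give responders longer
#'   survival, as seen for high-IS patients).
#' @param seed master integer seed; each generator derives its own stream
#'   as `seed + k` with k = 0 (expression), 1 (mutations), 2 (copy number),
#'   3 (clinical).
#' @return a `simulation_config` list, validated.
#' @export
simulation_config <- function(n_genes = 2000,
                              n_samples_per_class = 25,
                              frac_de = 0.05,
                              effect_size = 2,
                              noise_sd = 1,
                              n_driver_genes = 100,
                              burden_range = c(0, 400),
                              cna_magnitude = 1,
                              hazard_ratio = 2,
                              seed = 1) {
  stopifnot(
    n_genes >= 1, n_samples_per_class >= 1, n_driver_genes >= 1,
    frac_de >= 0, frac_de <= 1,
    noise_sd > 0, cna_magnitude >= 0, hazard_ratio > 0,
    length(burden_range) == 2L, burden_range[1L] >= 0,
    burden_range[2L] >= burden_range[1L]
  )
  config <- list(
    n_genes = as.integer(n_genes),
    n_samples_per_class = as.integer(n_samples_per_class),
    frac_de = frac_de,
    effect_size = effect_size,
    noise_sd = noise_sd,
    n_driver_genes = as.integer(n_driver_genes),
    burden_range = as.integer(round(burden_range)),
    cna_magnitude = cna_magnitude,
    hazard_ratio = hazard_ratio,
    seed = as.integer(seed)
  )
  class(config) <- "simulation_config"
  config
}

sim_ids <- function(config) {
  n <- 2L * config$n_samples_per_class
  list(
    genes = sprintf("gene_%05d", seq_len(config$n_genes)),
    samples = sprintf("sample_%04d", seq_len(n)),
    # first half responders, second half non-responders
    response = rep(c("responder", "non_responder"),
                   each = config$n_samples_per_class)
  )
}

#' Simulate a two-class expression cohort with planted DE genes
#'
#' Gene g, sample j gets
#' `baseline_g + effect_size * noise_sd * [g in DE] * [j responder] + N(0, noise_sd^2)`
#' with baselines drawn once per gene from N(7, 1) on the log2 scale
#' (typical microarray magnitudes; irrelevant after centering). Response
#' labels are stored in the annotations; the planted DE gene set is
#' returned for recovery tests.
#'
#' @param config a [simulation_config()].
#' @param de_genes optional character vector fixing the planted DE gene
#'   set, e.g. to simulate an independent validation cohort in which the
#'   same genes respond; default draws `frac_de * n_genes` genes at random.
#' @return list with `expr` (an [ExpressionMatrix] whose annotations carry
#'   the `response` label) and `de_genes` (character vector of planted DE
#'   gene ids, possibly empty).
#' @export
simulate_expression <- function(config, de_genes = NULL) {
  set.seed(config$seed + 0L)
  ids <- sim_ids(config)
  if (is.null(de_genes)) {
    n_de <- floor(config$frac_de * config$n_genes)
    if (config$frac_de > 0 && n_de < 1) {
      warning("frac_de * n_genes < 1: no DE genes planted")
    }
    de_genes <- if (n_de >= 1) sample(ids$genes, n_de) else character(0)
  } else {
    stopifnot(all(de_genes %in% ids$genes))
  }
  baseline <- stats::rnorm(config$n_genes, mean = 7, sd = 1)
  n_samples <- length(ids$samples)
  shift <- outer(ids$genes %in% de_genes, ids$response == "responder") *
    config$effect_size * config$noise_sd
  values <- baseline +
    shift +
    matrix(stats::rnorm(config$n_genes * n_samples, sd = config$noise_sd),
           nrow = config$n_genes)
  dimnames(values) <- list(ids$genes, ids$samples)
  ann <- data.frame(sample_id = ids$samples, response = ids$response,
                    stringsAsFactors = FALSE)
  list(expr = ExpressionMatrix(values, annotations = ann),
       de_genes = sort(de_genes))
}

#' Simulate a per-sample somatic mutation table
#'
#' Each sample draws its non-synonymous count uniformly from
#' `burden_range`, spread over the driver-gene universe. Classifications
#' are drawn from a fixed mix — 70% missense, 10% nonsense, 5% splice-site,
#' 15% frameshift/in-frame indel — and a silent record is added per
#' non-synonymous one with probability 0.4, so that category accounting in
#' [count_burden()] is exercised.
#'
#' @param config a [simulation_config()].
#' @return mutation `data.frame` (`sample_id`, `gene_symbol`,
#'   `variant_classification`), one row per called variant. Samples with
#'   zero draws simply have no rows; pass the full roster to
#'   [count_burden()] to get their zero counts.
#' @export
simulate_mutations <- function(config) {
  set.seed(config$seed + 1L)
  ids <- sim_ids(config)
  drivers <- sprintf("DRV%03d", seq_len(config$n_driver_genes))
  ns_classes <- c(Missense_Mutation = 0.70, Nonsense_Mutation = 0.10,
                  Splice_Site = 0.05, Frame_Shift_Del = 0.075,
                  Frame_Shift_Ins = 0.05, In_Frame_Del = 0.025)
  lo <- config$burden_range[1L]
  hi <- config$burden_range[2L]
  counts <- lo + sample.int(hi - lo + 1L, length(ids$samples),
                            replace = TRUE) - 1L
  rows <- lapply(seq_along(ids$samples), function(j) {
    k <- counts[j]
    if (k == 0L) return(NULL)
    cls <- sample(names(ns_classes), k, replace = TRUE, prob = ns_classes)
    n_silent <- stats::rbinom(1L, k, 0.4)
    data.frame(
      sample_id = ids$samples[j],
      gene_symbol = sample(drivers, k + n_silent, replace = TRUE),
      variant_classification = c(cls, rep("Silent", n_silent)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(sample_id = character(0), gene_symbol = character(0),
                      variant_classification = character(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Simulate a gene-level copy-number (GISTIC2-like) matrix
#'
#' Values are iid `N(0, cna_magnitude^2)`, so the CIN score (sum of squared
#' values per sample) has expectation `n_genes * cna_magnitude^2`. No
#' segment structure is simulated: the CIN statistic consumes gene-level
#' values only.
#'
#' @param config a [simulation_config()].
#' @return numeric genes x samples matrix.
#' @export
simulate_cna <- function(config) {
  set.seed(config$seed + 2L)
  ids <- sim_ids(config)
  values <- matrix(stats::rnorm(config$n_genes * length(ids$samples),
                                sd = config$cna_magnitude),
                   nrow = config$n_genes,
                   dimnames = list(ids$genes, ids$samples))
  values
}

#' Simulate a clinical table with class-linked exponential survival
#'
#' Event times are exponential with baseline rate 1/365 per day, multiplied
#' by `hazard_ratio` for planted responders; censoring times are uniform on
#' (0, 1095] days (a three-year accrual window); purity is uniform on
#' (0.5, 1].
#'
#' @param config a [simulation_config()].
#' @param response optional named character vector of planted class labels
#'   (`"responder"`/`"non_responder"`) per sample id, e.g. taken from
#'   [simulate_expression()] annotations; defaults to the config's own
#'   layout so all generators agree.
#' @return clinical `data.frame` with `sample_id`, `survival_time`,
#'   `event`, `response`, `cancer_type`, `purity`, `msi_status`,
#'   `viral_status`.
#' @export
simulate_clinical <- function(config, response = NULL) {
  set.seed(config$seed + 3L)
  ids <- sim_ids(config)
  if (is.null(response)) {
    response <- stats::setNames(ids$response, ids$samples)
  }
  samples <- names(response)
  check_unique_ids(samples, "sample")
  base_rate <- 1 / 365
  rate <- base_rate * ifelse(response == "responder", config$hazard_ratio, 1)
  event_time <- stats::rexp(length(samples), rate = rate)
  censor_time <- stats::runif(length(samples), 0, 1095)
  out <- data.frame(
    sample_id = samples,
    survival_time = pmin(event_time, censor_time),
    event = as.integer(event_time <= censor_time),
    response = as.character(response),
    cancer_type = "SYNTH",
    purity = stats::runif(length(samples), 0.5, 1),
    msi_status = NA_character_,
    viral_status = NA_character_,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  validate_clinical(out)
}

#' Simulate a full cohort
#'
#' Convenience wrapper calling all four generators with consistent ids and
#' labels.
#'
#' @param config a [simulation_config()].
#' @return list with `expr`, `de_genes`, `mutations`, `cna`, `clinical`.
#' @export
simulate_cohort <- function(config) {
  e <- simulate_expression(config)
  labels <- stats::setNames(e$expr$annotations$response,
                            e$expr$annotations$sample_id)
  list(
    expr = e$expr,
    de_genes = e$de_genes,
    mutations = simulate_mutations(config),
    cna = simulate_cna(config),
    clinical = simulate_clinical(config, response = labels)
  )
}
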
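#' Specification of a synthetic gene panel
#'
#' Gene-level scores are drawn once per panel: intolerance scores from a
#' normal distribution (RVIS-like scores are roughly standardized around 0)
#' and publication weights from an exponential distribution (literature
#' counts are strongly right-skewed).
#'
#' @param n_genes Panel size (default 50, desk-speed; use 691 for runs that
#'   match the published panel size).
#' @param intolerance_mean,intolerance_sd Normal parameters for the
#'   intolerance score (defaults 0 and 1).
#' @param pubweight_mean Mean of the exponential publication weight
#'   (default 5).
#' @return A list of class `panel_spec`.
#' @export
panel_spec <- function(n_genes = 50L, intolerance_mean = 0,
                       intolerance_sd = 1, pubweight_mean = 5) {
  stop_if_not(n_genes >= 1, "n_genes must be >= 1")
  stop_if_not(intolerance_sd >= 0 && pubweight_mean > 0,
              "invalid score distribution parameters")
  structure(list(n_genes = as.integer(n_genes),
                 intolerance_mean = intolerance_mean,
                 intolerance_sd = intolerance_sd,
                 pubweight_mean = pubweight_mean),
            class = "panel_spec")
}

#' Generate a reproducible synthetic gene panel
#'
#' @param spec A [panel_spec()].
#' @param seed Integer seed.
#' @return A [gene_panel()] with genes named `G0001`, `G0002`, ...
#' @export
generate_panel <- function(spec = panel_spec(), seed = 1L) {
  with_seed(derive_seed(seed, "panel"), {
    gene_panel(sprintf("G%04d", seq_len(spec$n_genes)),
               rnorm(spec$n_genes, spec$intolerance_mean, spec$intolerance_sd),
               rexp(spec$n_genes, rate = 1 / spec$pubweight_mean))
  })
}

#' Baseline per-(gene, class) Poisson rates
#'
#' Class-level mean counts emulate variant calls over the full genomic span
#' of long disease-associated loci (the regime in which the 9-class
#' histogram is informative: intronic, upstream and downstream records
#' dominate, splicing calls are rare). At human heterozygosity
#' (roughly one variant record per 500 bp of covered sequence) a
#' 50-150 kb disease gene carries on the order of 100-300 records, which is
#' what the class means below sum to (about 200 per gene). Per-gene
#' multipliers (log-normal, sd 0.5) emulate locus length and capture
#' variability.
#'
#' @param n_genes Number of panel genes.
#' @param vocabulary Class vocabulary (rates are per class, in order).
#' @param seed Integer seed.
#' @return Matrix (n_genes x |vocabulary|) of Poisson rates.
#' @export
default_base_rates <- function(n_genes,
                               vocabulary = default_variant_classes(),
                               seed = 1L) {
  class_means <- c("exonic" = 4, "UTR3" = 3, "UTR5" = 1.5,
                   "ncRNA exonic" = 1.5, "ncRNA intronic" = 20,
                   "upstream" = 10, "downstream" = 10,
                   "intronic" = 150, "splicing" = 0.5)
  means <- class_means[vocabulary]
  means[is.na(means)] <- 2  # non-canonical vocabularies get a flat rate
  with_seed(derive_seed(seed, "rates"), {
    gene_size <- rlnorm(n_genes, meanlog = 0, sdlog = 0.5)
    out <- outer(gene_size, unname(means))
    dimnames(out) <- list(NULL, vocabulary)
    out
  })
}

#' Specification of one synthetic center
#'
#' Describes the stochastic model of a center's cohort: class counts for
#' sample i, class c, gene g are Poisson with rate
#' `base_rates[g, c] * batch_factor[c] * effect_size^(case_i and g in
#' signal_genes)`. The per-class `batch_factor` is a center-wide systematic
#' shift emulating sequencing-era batch effects; with
#' `confound_with_label = TRUE` it is applied to cases only, reproducing
#' the pathological case/control sequencing confound seen in early exome
#' cohorts.
#'
#' @param center_id Center identifier.
#' @param n_cases,n_controls Cohort composition.
#' @param signal_genes Integer indices of panel genes carrying disease
#'   signal.
#' @param effect_size Multiplicative rate factor (>= 1) applied to case
#'   counts on signal genes (default 1: null model).
#' @param batch_factor Per-class multiplicative vector (default all 1).
#' @param base_rates Optional (G x 9) rate matrix; defaults to
#'   [default_base_rates()] derived from `seed`.
#' @param confound_with_label Apply the batch factor to cases only.
#' @param seed Integer seed.
#' @return A list of class `center_spec`.
#' @export
center_spec <- function(center_id, n_cases, n_controls,
                        signal_genes = integer(), effect_size = 1,
                        batch_factor = NULL, base_rates = NULL,
                        confound_with_label = FALSE, seed = 1L) {
  stop_if_not(n_cases >= 0 && n_controls >= 0 && n_cases + n_controls >= 1,
              "center must contain at least one sample")
  stop_if_not(effect_size >= 1, "effect_size must be >= 1")
  if (!is.null(base_rates))
    stop_if_not(all(base_rates >= 0), "base rates must be >= 0")
  if (!is.null(batch_factor))
    stop_if_not(all(batch_factor > 0), "batch factors must be > 0")
  structure(list(center_id = as.character(center_id),
                 n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 signal_genes = as.integer(signal_genes),
                 effect_size = effect_size,
                 batch_factor = batch_factor,
                 base_rates = base_rates,
                 confound_with_label = confound_with_label,
                 seed = as.integer(seed)),
            class = "center_spec")
}

#' Generate one center's synthetic cohort
#'
#' Draws the Poisson class-count tensor described by the [center_spec()],
#' attaches the panel scores as feature rows 10-11, and labels cases 1.
#' With `emit_variants = TRUE` the realized counts are also materialized as
#' per-sample annotated-variant records (synthetic positions), so the full
#' variant-table -> tensor encoder path can be exercised; re-encoding these
#' records reproduces the tensor exactly.
#'
#' @param spec A [center_spec()].
#' @param panel A [gene_panel()].
#' @param vocabulary Class vocabulary.
#' @param emit_variants Also return per-sample [annotated_variants()]
#'   tables in attribute `variants`.
#' @return A [cohort_dataset()]; cases first, then controls.
#' @export
generate_center_cohort <- function(spec, panel,
                                   vocabulary = default_variant_classes(),
                                   emit_variants = FALSE) {
  G <- nrow(panel)
  C <- length(vocabulary)
  n <- spec$n_cases + spec$n_controls
  labels <- rep(c(1L, 0L), c(spec$n_cases, spec$n_controls))
  rates <- spec$base_rates %||% default_base_rates(G, vocabulary, spec$seed)
  stop_if_not(all(dim(rates) == c(G, C)),
              "base_rates must be (panel size x vocabulary size)")
  batch <- spec$batch_factor %||% rep(1, C)
  stop_if_not(length(batch) == C,
              "batch_factor must have one entry per class")
  signal <- spec$signal_genes
  stop_if_not(all(signal >= 1 & signal <= G), "signal gene index out of panel")
  tensor <- array(0, dim = c(n, C + 2, G))
  with_seed(derive_seed(spec$seed, "cohort", spec$center_id), {
    for (i in seq_len(n)) {
      lam <- rates                                   # G x C
      if (!spec$confound_with_label || labels[i] == 1L)
        lam <- lam * rep(batch, each = G)
      if (labels[i] == 1L && length(signal) > 0)
        lam[signal, ] <- lam[signal, ] * spec$effect_size
      counts <- matrix(rpois(G * C, lam), G, C)
      tensor[i, seq_len(C), ] <- t(counts)
    }
  })
  tensor[, C + 1, ] <- matrix(panel$intolerance, n, G, byrow = TRUE)
  tensor[, C + 2, ] <- matrix(panel$pubweight, n, G, byrow = TRUE)
  ids <- sprintf("%s_%s%03d", spec$center_id,
                 ifelse(labels == 1L, "case", "ctrl"),
                 c(seq_len(spec$n_cases), seq_len(spec$n_controls)))
  cohort <- cohort_dataset(tensor, labels, spec$center_id, ids, panel,
                           vocabulary)
  if (emit_variants)
    attr(cohort, "variants") <- counts_to_variants(cohort)
  cohort
}

# Materialize a cohort's count tensor as per-sample annotated-variant
# records with synthetic coordinates (chromosome "syn", consecutive
# positions). Used to exercise the encoder path end to end.
counts_to_variants <- function(cohort) {
  voc <- cohort$vocabulary
  C <- length(voc)
  genes <- cohort$panel$gene
  lapply(seq_len(n_samples(cohort)), function(i) {
    counts <- cohort$tensor[i, seq_len(C), , drop = TRUE]  # C x G
    k <- as.integer(counts)
    gene <- rep(rep(genes, each = C), k)
    cls <- rep(rep(voc, times = length(genes)), k)
    total <- sum(k)
    annotated_variants(chrom = rep("syn", total),
                       pos = seq_len(total),
                       ref = rep("A", total), alt = rep("T", total),
                       gene = gene, class = cls, vocabulary = voc)
  })
}

#' Write per-sample Annovar-style variant tables for a cohort
#'
#' Emits the synthetic variant records of [generate_center_cohort()] as
#' tab-separated variant-function tables (class, gene, chrom, start, end,
#' ref, alt), one file per sample, so the table-reading path can be run on
#' synthetic data.
#'
#' @param variant_lists List of [annotated_variants()] tables.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Character vector of file paths, invisibly.
#' @export
write_annovar_tables <- function(variant_lists, dir, prefix = "sample") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(variant_lists))
  for (i in seq_along(variant_lists)) {
    v <- variant_lists[[i]]
    paths[i] <- file.path(dir, sprintf("%s_%03d.variant_function", prefix, i))
    lines <- sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s",
                     v$class, v$gene, v$chrom, v$pos, v$pos, v$ref, v$alt)
    writeLines(lines, paths[i])
  }
  invisible(paths)
}

#' Generate the three-center benchmark constellation
#'
#' Convenience wrapper reproducing the structure of the multi-center
#' benchmark: three centers of 56 (42 cases / 14 controls), 66 (51/15) and
#' 111 (64/47) samples sharing one panel and baseline rates, with planted
#' signal genes and mild per-center batch effects (log-normal per-class
#' factors, sd `batch_sd`).
#'
#' @param panel A [gene_panel()] (default: generated 50-gene panel).
#' @param n_signal Number of planted signal genes (default 10).
#' @param effect_size Case rate multiplier on signal genes (default 2.5).
#' @param batch_sd Log-sd of the per-center per-class batch factors
#'   (default 0.1).
#' @param seed Integer seed.
#' @return List of three [cohort_dataset()] objects.
#' @export
generate_three_centers <- function(panel = NULL, n_signal = 10L,
                                   effect_size = 2.5, batch_sd = 0.1,
                                   seed = 1L) {
  if (is.null(panel)) panel <- generate_panel(panel_spec(50L), seed)
  G <- nrow(panel)
  voc <- default_variant_classes()
  rates <- default_base_rates(G, voc, seed)
  signal <- with_seed(derive_seed(seed, "signal"),
                      sort(sample.int(G, n_signal)))
  sizes <- list(A = c(42L, 14L), B = c(51L, 15L), C = c(64L, 47L))
  lapply(names(sizes), function(id) {
    batch <- with_seed(derive_seed(seed, "batch", id),
                       rlnorm(length(voc), 0, batch_sd))
    sp <- center_spec(paste0("center", id), sizes[[id]][1], sizes[[id]][2],
                      signal_genes = signal, effect_size = effect_size,
                      batch_factor = batch, base_rates = rates,
                      seed = derive_seed(seed, "center", id))
    generate_center_cohort(sp, panel, voc)
  })
}
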
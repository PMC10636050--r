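#' Construct a cohort dataset
#'
#' The unit of client data in the federated protocol: an (N, 11, G) feature
#' tensor, binary case/control labels, sample ids and a center id. The panel
#' and vocabulary travel with the tensor so the gene/class coordinate order
#' is never ambiguous.
#'
#' @param tensor Numeric array of shape (N, 11, G).
#' @param labels Integer vector of N labels, 1 = case, 0 = control.
#' @param center_id Center identifier string.
#' @param sample_ids Character vector of N unique sample ids.
#' @param panel The [gene_panel()] defining the G gene columns.
#' @param vocabulary The class vocabulary defining rows 1..9.
#' @return An object of class `cohort_dataset`.
#' @export
cohort_dataset <- function(tensor, labels, center_id, sample_ids, panel,
                           vocabulary = default_variant_classes()) {
  check_vocabulary(vocabulary)
  stop_if_not(inherits(panel, "gene_panel"), "panel must be a gene_panel")
  stop_if_not(is.array(tensor) && length(dim(tensor)) == 3,
              "tensor must be a 3-d array (N, features, genes)")
  n_feat <- length(vocabulary) + 2
  stop_if_not(dim(tensor)[2] == n_feat,
              sprintf("tensor must have %d feature rows", n_feat))
  stop_if_not(dim(tensor)[3] == nrow(panel),
              "tensor gene axis must match panel size")
  labels <- as.integer(labels)
  stop_if_not(all(labels %in% c(0L, 1L)), "labels must be 0 (control) or 1 (case)")
  stop_if_not(dim(tensor)[1] == length(labels),
              "one label per sample required")
  stop_if_not(length(sample_ids) == length(labels),
              "one sample id per sample required")
  count_rows <- tensor[, seq_along(vocabulary), , drop = FALSE]
  stop_if_not(all(count_rows >= 0), "class-count entries must be non-negative")
  structure(list(tensor = tensor, labels = labels,
                 center_id = as.character(center_id),
                 sample_ids = as.character(sample_ids),
                 panel = panel, vocabulary = vocabulary),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset> center '%s': %d samples (%d cases / %d controls), %d genes x %d features\n",
              x$center_id, length(x$labels), sum(x$labels),
              sum(x$labels == 0), dim(x$tensor)[3], dim(x$tensor)[2]))
  invisible(x)
}

#' Number of samples in a cohort
#' @param x A `cohort_dataset`.
#' @return Integer sample count.
#' @export
n_samples <- function(x) {
  stop_if_not(inherits(x, "cohort_dataset"), "x must be a cohort_dataset")
  length(x$labels)
}

#' Encode a multi-sample cohort into a feature tensor
#'
#' Stacks [encode_sample()] matrices for a list of per-sample variant tables
#' into the (N, 11, G) tensor consumed by the model.
#'
#' @param variant_lists List of N [annotated_variants()] tables.
#' @param labels Binary labels (1 = case), one per sample.
#' @param panel A [gene_panel()].
#' @param center_id Center identifier (default "cohort").
#' @param sample_ids Optional sample ids (default S1..SN).
#' @param vocabulary Class vocabulary.
#' @return A [cohort_dataset()].
#' @export
encode_cohort <- function(variant_lists, labels, panel,
                          center_id = "cohort", sample_ids = NULL,
                          vocabulary = default_variant_classes()) {
  stop_if_not(length(variant_lists) == length(labels),
              "need one variant table per label")
  n <- length(variant_lists)
  G <- nrow(panel)
  tensor <- array(0, dim = c(n, length(vocabulary) + 2, G))
  for (i in seq_len(n))
    tensor[i, , ] <- encode_sample(variant_lists[[i]], panel, vocabulary)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  cohort_dataset(tensor, labels, center_id, sample_ids, panel, vocabulary)
}

#' Write / read a cohort to a portable on-disk container
#'
#' JSON with the tensor, labels, sample ids and the panel and vocabulary
#' recorded as metadata; `read_cohort()` restores an identical object.
#'
#' @param cohort A [cohort_dataset()].
#' @param path Output path (conventionally `.json`).
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns the restored [cohort_dataset()].
#' @export
write_cohort <- function(cohort, path) {
  stop_if_not(inherits(cohort, "cohort_dataset"), "not a cohort_dataset")
  obj <- list(format = "fedgi-cohort-v1",
              center_id = cohort$center_id,
              vocabulary = cohort$vocabulary,
              panel = list(gene = cohort$panel$gene,
                           intolerance = cohort$panel$intolerance,
                           pubweight = cohort$panel$pubweight),
              sample_ids = cohort$sample_ids,
              labels = cohort$labels,
              dim = dim(cohort$tensor),
              tensor = as.numeric(cohort$tensor))
  # I(17) significant digits: doubles survive the text round trip exactly
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  stop_if_not(identical(obj$format, "fedgi-cohort-v1"),
              "not a fedgi cohort container")
  tensor <- array(obj$tensor, dim = obj$dim)
  panel <- gene_panel(obj$panel$gene, obj$panel$intolerance,
                      obj$panel$pubweight)
  cohort_dataset(tensor, obj$labels, obj$center_id, obj$sample_ids,
                 panel, obj$vocabulary)
}

#' Subset a cohort by sample index
#' @param cohort A [cohort_dataset()].
#' @param idx Integer sample indices to keep.
#' @param center_id Optional new center id (defaults to the original).
#' @return A [cohort_dataset()] with the selected samples.
#' @export
subset_cohort <- function(cohort, idx, center_id = cohort$center_id) {
  cohort_dataset(cohort$tensor[idx, , , drop = FALSE], cohort$labels[idx],
                 center_id, cohort$sample_ids[idx], cohort$panel,
                 cohort$vocabulary)
}

#' Pool several cohorts that share a panel
#' @param cohorts List of [cohort_dataset()] objects with identical panels
#'   and vocabularies.
#' @param center_id Identifier for the pooled cohort.
#' @return A single pooled [cohort_dataset()].
#' @export
merge_cohorts <- function(cohorts, center_id = "pooled") {
  stop_if_not(length(cohorts) >= 1, "need at least one cohort")
  ref <- cohorts[[1]]
  for (co in cohorts) {
    stop_if_not(identical(co$panel$gene, ref$panel$gene),
                "cohorts must share the same panel")
    stop_if_not(identical(co$vocabulary, ref$vocabulary),
                "cohorts must share the same vocabulary")
  }
  tensor <- do.call(abind3, lapply(cohorts, `[[`, "tensor"))
  cohort_dataset(tensor,
                 unlist(lapply(cohorts, `[[`, "labels")),
                 center_id,
                 make.unique(unlist(lapply(cohorts, `[[`, "sample_ids"))),
                 ref$panel, ref$vocabulary)
}

# bind 3-d arrays along the first (sample) axis
abind3 <- function(...) {
  arrays <- list(...)
  d <- dim(arrays[[1]])
  n <- sum(vapply(arrays, function(a) dim(a)[1], 0L))
  out <- array(0, dim = c(n, d[2], d[3]))
  at <- 1L
  for (a in arrays) {
    k <- dim(a)[1]
    out[at:(at + k - 1L), , ] <- a
    at <- at + k
  }
  out
}

#' Partition a cohort into folds
#'
#' `split_random()` shuffles samples and deals them into `n_folds` nearly
#' equal parts; `split_stratified()` shuffles cases and controls separately
#' and deals each class round-robin, so per-fold case counts differ by at
#' most 1 from N_cases / n_folds.
#'
#' @param cohort A [cohort_dataset()].
#' @param n_folds Number of folds (2 <= n_folds <= N).
#' @param seed Integer seed controlling the shuffle.
#' @return List of `n_folds` disjoint [cohort_dataset()] folds covering the
#'   input exactly.
#' @export
split_random <- function(cohort, n_folds, seed = 1L) {
  n <- n_samples(cohort)
  stop_if_not(n_folds >= 2 && n_folds <= n,
              "n_folds must be between 2 and the number of samples")
  perm <- with_seed(seed, sample.int(n))
  # deal contiguous chunks of the permutation: fold sizes differ by <= 1
  fold_of <- integer(n)
  sizes <- rep(n %/% n_folds, n_folds) + (seq_len(n_folds) <= n %% n_folds)
  fold_of[perm] <- rep.int(seq_len(n_folds), sizes)
  lapply(seq_len(n_folds), function(f)
    subset_cohort(cohort, which(fold_of == f),
                  center_id = paste0(cohort$center_id, "_fold", f)))
}

#' @rdname split_random
#' @export
split_stratified <- function(cohort, n_folds, seed = 1L) {
  n <- n_samples(cohort)
  stop_if_not(n_folds >= 2 && n_folds <= n,
              "n_folds must be between 2 and the number of samples")
  fold_of <- integer(n)
  with_seed(seed, {
    offset <- 0L
    for (lab in c(1L, 0L)) {
      members <- which(cohort$labels == lab)
      members <- members[sample.int(length(members))]
      # continue the round-robin across classes so total fold sizes stay
      # within 1 of each other, as per-class counts already do
      fold_of[members] <-
        ((offset + seq_along(members) - 1L) %% n_folds) + 1L
      offset <- (offset + length(members)) %% n_folds
    }
  })
  lapply(seq_len(n_folds), function(f)
    subset_cohort(cohort, which(fold_of == f),
                  center_id = paste0(cohort$center_id, "_fold", f)))
}
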
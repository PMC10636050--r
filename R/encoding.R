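#' Canonical functional variant-class vocabulary
#'
#' The nine functional classes assigned by Annovar-style gene-based
#' annotation, in the fixed order used as the histogram coordinate order of
#' the per-gene feature vector. The order is part of the encoding contract:
#' changing it permutes the first nine rows of every feature tensor.
#'
#' @return Character vector of 9 unique class names.
#' @export
#' @examples
#' default_variant_classes()
default_variant_classes <- function() {
  c("exonic", "UTR3", "UTR5", "ncRNA exonic", "ncRNA intronic",
    "upstream", "downstream", "intronic", "splicing")
}

check_vocabulary <- function(vocabulary) {
  stop_if_not(is.character(vocabulary) && length(vocabulary) >= 1,
              "vocabulary must be a non-empty character vector")
  stop_if_not(!anyDuplicated(vocabulary), "vocabulary names must be unique")
  vocabulary
}

#' Construct a gene panel
#'
#' A gene panel fixes the set and the order of genes used by the encoder and
#' by the final layer of the gene-modular network. Each gene carries two
#' scores: an intolerance-to-variation score (RVIS-like, typically centered
#' near 0) and a non-negative disease publication weight (literature
#' association strength).
#'
#' @param gene Character vector of unique gene symbols.
#' @param intolerance Numeric intolerance scores, one per gene.
#' @param pubweight Numeric publication weights, one per gene (>= 0).
#' @return A `data.frame` of class `gene_panel` with columns `gene`,
#'   `intolerance`, `pubweight`. Row order is the feature-column order.
#' @export
#' @examples
#' gene_panel(c("NOD2", "IL23R"), c(-1.2, 0.3), c(50, 12))
gene_panel <- function(gene, intolerance, pubweight) {
  stop_if_not(length(gene) >= 1, "panel must contain at least one gene")
  stop_if_not(!anyDuplicated(gene), "gene symbols must be unique")
  stop_if_not(length(intolerance) == length(gene) &&
              length(pubweight) == length(gene),
              "scores must have one entry per gene")
  intolerance <- as.numeric(intolerance)
  pubweight <- as.numeric(pubweight)
  if (anyNA(intolerance) || anyNA(pubweight)) {
    warning("missing panel scores imputed to 0")
    intolerance[is.na(intolerance)] <- 0
    pubweight[is.na(pubweight)] <- 0
  }
  stop_if_not(all(pubweight >= 0), "publication weights must be >= 0")
  structure(data.frame(gene = as.character(gene),
                       intolerance = intolerance,
                       pubweight = pubweight,
                       stringsAsFactors = FALSE),
            class = c("gene_panel", "data.frame"))
}

#' Read a gene panel from a tab-separated file
#'
#' Expected columns: gene symbol, intolerance score, publication weight.
#' A header line is detected (non-numeric second field) and skipped.
#'
#' @param path Path to a TSV file.
#' @return A [gene_panel()].
#' @export
read_gene_panel <- function(path) {
  raw <- read.delim(path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = "character")
  stop_if_not(ncol(raw) >= 3, "panel file needs 3 tab-separated columns")
  if (nrow(raw) > 0 && is.na(suppressWarnings(as.numeric(raw[1, 2]))))
    raw <- raw[-1, , drop = FALSE]
  gene_panel(raw[[1]],
             suppressWarnings(as.numeric(raw[[2]])),
             suppressWarnings(as.numeric(raw[[3]])))
}

#' Construct an annotated-variant table
#'
#' One row per (variant, gene) incidence for a single sample. Variants whose
#' class is not in the vocabulary are dropped from the table but tallied in
#' the `unknown_classes` attribute, so nothing is silently discarded.
#'
#' @param chrom,pos,ref,alt,gene,class Parallel vectors describing variants;
#'   `pos` is the 1-based position (VCF convention).
#' @param vocabulary Class vocabulary; see [default_variant_classes()].
#' @return A `data.frame` of class `annotated_variants` with attribute
#'   `unknown_classes` (named integer tally of off-vocabulary classes).
#' @export
annotated_variants <- function(chrom, pos, ref, alt, gene, class,
                               vocabulary = default_variant_classes()) {
  check_vocabulary(vocabulary)
  n <- length(gene)
  stop_if_not(all(lengths(list(chrom, pos, ref, alt, class)) == n),
              "variant fields must have equal lengths")
  pos <- as.integer(pos)
  stop_if_not(n == 0 || all(pos >= 1, na.rm = TRUE),
              "positions must be >= 1 (1-based VCF convention)")
  df <- data.frame(chrom = as.character(chrom), pos = pos,
                   ref = as.character(ref), alt = as.character(alt),
                   gene = as.character(gene), class = as.character(class),
                   stringsAsFactors = FALSE)
  known <- df$class %in% vocabulary
  unknown <- table(df$class[!known])
  out <- df[known, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            unknown_classes = stats::setNames(as.integer(unknown),
                                              names(unknown)),
            class = c("annotated_variants", "data.frame"))
}

# Split an Annovar gene field ("GENE1;GENE2", "GENE1(dist=12),GENE2") into
# clean symbols: one record per gene (fan-out).
split_gene_field <- function(x) {
  parts <- strsplit(x, "[;,]")
  lapply(parts, function(p) unique(sub("\\(.*\\)$", "", trimws(p))))
}

#' Read an Annovar-style variant-function table for one sample
#'
#' The expected dialect is tab-separated with columns: functional class,
#' gene(s), chromosome, start, end, ref allele, alt allele. A variant
#' annotated to several genes (";" or "," separated) yields one record per
#' gene. Classes outside the vocabulary are counted in the result's
#' `unknown_classes` attribute rather than silently dropped.
#'
#' @param path Path to the tab-separated table.
#' @param vocabulary Class vocabulary; see [default_variant_classes()].
#' @return An [annotated_variants()] table.
#' @export
read_annovar_table <- function(path, vocabulary = default_variant_classes()) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    warning("empty variant table: ", path)
    return(annotated_variants(character(), integer(), character(),
                              character(), character(), character(),
                              vocabulary))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 7)
  if (length(bad) > 0)
    stop(sprintf("malformed line %d in %s: expected >= 7 tab-separated fields",
                 bad[1], path), call. = FALSE)
  cls <- vapply(fields, `[[`, "", 1L)
  genes <- split_gene_field(vapply(fields, `[[`, "", 2L))
  chrom <- vapply(fields, `[[`, "", 3L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 4L)))
  if (anyNA(start))
    stop(sprintf("malformed line %d in %s: non-integer start position",
                 which(is.na(start))[1], path), call. = FALSE)
  ref <- vapply(fields, `[[`, "", 6L)
  alt <- vapply(fields, `[[`, "", 7L)
  k <- lengths(genes)
  idx <- rep.int(seq_along(lines), k)
  annotated_variants(chrom[idx], start[idx], ref[idx], alt[idx],
                     unlist(genes), cls[idx], vocabulary)
}

#' Read variants from a VCF file with a user-supplied annotation map
#'
#' For synthetic or pre-annotated data the gene and functional class are not
#' in the VCF itself; `class_map` supplies them, keyed on
#' (chrom, pos, ref, alt). VCF records absent from the map are tallied as
#' unknown (class `".unmapped"`).
#'
#' @param path Path to an uncompressed VCF (v4.x) file.
#' @param class_map `data.frame` with columns `chrom`, `pos`, `ref`, `alt`,
#'   `gene`, `class`.
#' @param vocabulary Class vocabulary.
#' @return An [annotated_variants()] table.
#' @export
read_vcf_variants <- function(path, class_map,
                              vocabulary = default_variant_classes()) {
  stop_if_not(all(c("chrom", "pos", "ref", "alt", "gene", "class") %in%
                  names(class_map)),
              "class_map needs columns chrom, pos, ref, alt, gene, class")
  stop_if_not(requireNamespace("VariantAnnotation", quietly = TRUE),
              "read_vcf_variants() requires the VariantAnnotation package")
  vcf <- VariantAnnotation::expand(VariantAnnotation::readVcf(path))
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomeInfoDb::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- as.character(VariantAnnotation::alt(vcf))
  key <- paste(chrom, pos, ref, alt, sep = "\r")
  map_key <- paste(class_map$chrom, class_map$pos, class_map$ref,
                   class_map$alt, sep = "\r")
  hit <- match(key, map_key)
  gene <- ifelse(is.na(hit), ".", class_map$gene[hit])
  cls <- ifelse(is.na(hit), ".unmapped", class_map$class[hit])
  annotated_variants(chrom, pos, ref, alt, gene, cls, vocabulary)
}

#' Per-gene histogram of variant classes
#'
#' Counts how many of one sample's variants fall on `gene` in each class of
#' the vocabulary, in vocabulary order. This is the mutational-damage
#' histogram forming the first 9 coordinates of the gene feature vector.
#'
#' @param variants An [annotated_variants()] table for one sample.
#' @param gene Gene symbol.
#' @param vocabulary Class vocabulary.
#' @return Named integer vector, one count per vocabulary class.
#' @export
build_gene_histogram <- function(variants, gene,
                                 vocabulary = default_variant_classes()) {
  check_vocabulary(vocabulary)
  on_gene <- variants$class[variants$gene == gene]
  counts <- tabulate(match(on_gene, vocabulary), nbins = length(vocabulary))
  stats::setNames(as.integer(counts), vocabulary)
}

#' Encode one sample as an (|vocabulary|+2) x G feature matrix
#'
#' Column g is the feature vector of panel gene g: the class-count histogram
#' followed by the gene's intolerance score and publication weight. Columns
#' follow panel order. Variants on genes outside the panel are ignored but
#' tallied in the `n_off_panel` attribute.
#'
#' @param variants An [annotated_variants()] table for one sample.
#' @param panel A [gene_panel()].
#' @param vocabulary Class vocabulary.
#' @return Numeric matrix (11 x G under the default vocabulary) with
#'   attribute `n_off_panel`.
#' @export
encode_sample <- function(variants, panel,
                          vocabulary = default_variant_classes()) {
  check_vocabulary(vocabulary)
  stop_if_not(inherits(panel, "gene_panel"), "panel must be a gene_panel")
  G <- nrow(panel)
  gi <- match(variants$gene, panel$gene)
  ci <- match(variants$class, vocabulary)
  keep <- !is.na(gi) & !is.na(ci)
  counts <- matrix(0, nrow = length(vocabulary), ncol = G)
  if (any(keep)) {
    tab <- table(factor(ci[keep], levels = seq_along(vocabulary)),
                 factor(gi[keep], levels = seq_len(G)))
    counts <- matrix(as.numeric(tab), nrow = length(vocabulary))
  }
  out <- rbind(counts, panel$intolerance, panel$pubweight)
  dimnames(out) <- list(c(vocabulary, "intolerance", "pubweight"),
                        panel$gene)
  attr(out, "n_off_panel") <- sum(is.na(gi) & !is.na(ci))
  out
}
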
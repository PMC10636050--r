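test_that("annovar tables parse with fan-out and unknown-class tallying", {
  path <- withr::local_tempfile(fileext = ".variant_function")
  writeLines(c(
    "exonic\tNOD2\t16\t50745926\t50745926\tC\tT",
    "splicing\tGENE1;GENE2\t1\t100\t100\tA\tG",
    "intergenic\tNONE\t2\t500\t500\tG\tC"), path)
  v <- read_annovar_table(path)
  expect_s3_class(v, "annotated_variants")
  # 1 record for NOD2 + 2 for the multi-gene line; intergenic dropped
  expect_equal(nrow(v), 3)
  expect_equal(v$gene, c("NOD2", "GENE1", "GENE2"))
  expect_equal(v$class[1], "exonic")
  expect_equal(v$pos[1], 50745926L)
  expect_equal(attr(v, "unknown_classes"), c(intergenic = 1L))
})

test_that("annovar parser rejects malformed lines and warns on empty files", {
  bad <- withr::local_tempfile()
  writeLines(c("exonic\tNOD2\t16\t1\t1\tC\tT", "exonic\tonly-two-fields"), bad)
  expect_error(read_annovar_table(bad), "line 2")
  empty <- withr::local_tempfile()
  writeLines(character(), empty)
  expect_warning(v <- read_annovar_table(empty), "empty")
  expect_equal(nrow(v), 0)
})

test_that("gene histograms count per class in vocabulary order", {
  voc <- default_variant_classes()
  v <- annotated_variants(
    chrom = rep("1", 8), pos = 1:8, ref = rep("A", 8), alt = rep("T", 8),
    gene = c("GENE1", "GENE1", "GENE1", "GENE3", "GENE3", "GENE3", "GENE3", "GENE2"),
    class = c("exonic", "exonic", "splicing",
              "intronic", "intronic", "intronic", "UTR3", "exonic"))
  expect_equal(unname(build_gene_histogram(v, "GENE1")),
               c(2, 0, 0, 0, 0, 0, 0, 0, 1))
  expect_equal(unname(build_gene_histogram(v, "ABSENT")), rep(0L, 9))
  # 3 intronic + 1 UTR3
  expect_equal(unname(build_gene_histogram(v, "GENE3")),
               c(0, 1, 0, 0, 0, 0, 0, 3, 0))
  # naive loop cross-check
  naive <- vapply(voc, function(cl)
    sum(v$gene == "GENE3" & v$class == cl), 0L)
  expect_equal(build_gene_histogram(v, "GENE3"), naive)
})

test_that("encode_sample builds 11 x G matrices with score rows", {
  panel <- tiny_panel(3)
  empty <- annotated_variants(character(), integer(), character(),
                              character(), character(), character())
  m <- encode_sample(empty, panel)
  expect_equal(dim(m), c(11, 3))
  expect_true(all(m[1:9, ] == 0))
  expect_equal(unname(m[10, ]), panel$intolerance)
  expect_equal(unname(m[11, ]), panel$pubweight)

  v <- annotated_variants(
    chrom = rep("1", 5), pos = 1:5, ref = rep("A", 5), alt = rep("T", 5),
    gene = c("GENE1", "GENE1", "GENE2", "GENE2", "OFFPANEL"),
    class = c("exonic", "intronic", "exonic", "exonic", "exonic"))
  m <- encode_sample(v, panel)
  expect_equal(unname(m[, "GENE1"]),
               c(1, 0, 0, 0, 0, 0, 0, 1, 0, panel$intolerance[1], panel$pubweight[1]))
  expect_equal(m[["exonic", "GENE2"]], 2)
  expect_equal(attr(m, "n_off_panel"), 1L)
})

test_that("encoding is variant-order invariant and conserves counts", {
  co <- tiny_cohort(3, 3, n_genes = 5, seed = 9)
  vl <- fedgi:::counts_to_variants(co)
  panel <- co$panel
  for (i in seq_along(vl)) {
    v <- vl[[i]]
    m1 <- encode_sample(v, panel)
    perm <- sample(nrow(v))
    m2 <- encode_sample(v[perm, ], panel)
    expect_identical(m1[1:9, ], m2[1:9, ])
    expect_equal(sum(m1[1:9, ]), sum(v$gene %in% panel$gene))
  }
})

test_that("encode_cohort stacks samples and round-trips through disk", {
  panel <- tiny_panel(4)
  v <- annotated_variants("1", 10, "A", "T", "GENE2", "exonic")
  vl <- list(v, v, v, v)
  co <- encode_cohort(vl, c(1, 0, 1, 0), panel, center_id = "X")
  expect_equal(dim(co$tensor), c(4, 11, 4))
  expect_error(encode_cohort(vl, c(1, 0, 2, 0), panel), "labels")

  path <- withr::local_tempfile(fileext = ".json")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_identical(back$tensor, co$tensor)
  expect_identical(back$labels, co$labels)
  expect_identical(back$panel$gene, co$panel$gene)
  expect_identical(back$sample_ids, co$sample_ids)
})

test_that("panel order defines the tensor's gene axis", {
  co <- tiny_cohort(2, 2, n_genes = 6, seed = 4)
  vl <- fedgi:::counts_to_variants(co)
  perm <- c(3, 1, 6, 2, 5, 4)
  shuf <- gene_panel(co$panel$gene[perm], co$panel$intolerance[perm],
                     co$panel$pubweight[perm])
  co2 <- encode_cohort(vl, co$labels, shuf)
  expect_equal(co2$tensor, co$tensor[, , perm, drop = FALSE])
})

test_that("score rows are constant across samples for a fixed panel", {
  co <- tiny_cohort(5, 5, n_genes = 4, seed = 2)
  for (row in 10:11)
    expect_equal(apply(co$tensor[, row, ], 2, function(x) length(unique(x))),
                 rep(1L, 4))
})

test_that("gene panels validate, impute missing scores, and read from TSV", {
  expect_error(gene_panel(c("A", "A"), c(1, 2), c(1, 2)), "unique")
  expect_warning(p <- gene_panel(c("A", "B"), c(1, NA), c(2, 3)), "imputed")
  expect_equal(p$intolerance[2], 0)

  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tintolerance\tpubweight",
               "NOD2\t-1.28\t245", "IL23R\t0.33\t118"), path)
  p <- read_gene_panel(path)
  expect_equal(p$gene, c("NOD2", "IL23R"))
  expect_equal(p$pubweight, c(245, 118))
})

test_that("VCF ingestion joins a class map and tallies unmapped records", {
  skip_if_not_installed("VariantAnnotation")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=16>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "16\t50745926\t.\tC\tT\t50\tPASS\t.",
    "16\t50756540\t.\tG\tA,C\t50\tPASS\t.",
    "16\t99\t.\tT\tG\t50\tPASS\t."), path)
  class_map <- data.frame(
    chrom = c("16", "16", "16"), pos = c(50745926, 50756540, 50756540),
    ref = c("C", "G", "G"), alt = c("T", "A", "C"),
    gene = c("NOD2", "NOD2", "NOD2"),
    class = c("exonic", "intronic", "UTR3"))
  v <- read_vcf_variants(path, class_map)
  expect_equal(nrow(v), 3)  # multi-allelic expanded; unmapped record dropped
  expect_equal(sort(v$class), c("UTR3", "exonic", "intronic"))
  expect_equal(attr(v, "unknown_classes"), c(.unmapped = 1L))
})
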
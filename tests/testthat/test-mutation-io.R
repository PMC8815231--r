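write_maf_fixture <- function(lines) {
  path <- tempfile(fileext = ".maf")
  writeLines(lines, path)
  path
}

maf_header <- "Hugo_Symbol\tTumor_Sample_Barcode\tVariant_Classification\tProtein_position"

test_that("read_maf parses records, positions, and sample restrictions", {
  path <- write_maf_fixture(c(
    maf_header,
    "COL7A1\tS1\tNonsense_Mutation\t2029/2944",
    "COL1A1\tS2\tMissense_Mutation\t150/1464",
    "COL5A2\tS3\tSilent\t."
  ))
  on.exit(unlink(path))
  rec <- read_maf(path)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$gene, c("COL7A1", "COL1A1", "COL5A2"))
  expect_equal(rec$protein_position, c(2029L, 150L, NA))
  expect_equal(rec$mutation_class, c("truncation", "missense", "other"))

  rec2 <- read_maf(path, allowed_samples = c("S1", "S3"))
  expect_false("S2" %in% rec2$sample)
  expect_equal(nrow(rec2), 2)
})

test_that("read_maf parses HGVSp-style positions and reports bad headers", {
  path <- write_maf_fixture(c(
    "Hugo_Symbol\tTumor_Sample_Barcode\tVariant_Classification\tHGVSp_Short",
    "COL7A1\tS1\tNonsense_Mutation\tp.R2029*"
  ))
  on.exit(unlink(path))
  expect_equal(read_maf(path)$protein_position, 2029L)

  bad <- write_maf_fixture(c("Hugo_Symbol\tVariant_Classification",
                             "G1\tSilent"))
  on.exit(unlink(bad), add = TRUE)
  expect_error(read_maf(bad), "Tumor_Sample_Barcode")

  empty <- write_maf_fixture(maf_header)
  on.exit(unlink(empty), add = TRUE)
  expect_warning(rec <- read_maf(empty), "no records")
  expect_equal(nrow(rec), 0)
})

test_that("variant classes map to missense / truncation / other", {
  expect_equal(classify_mutation("Nonsense_Mutation"), "truncation")
  expect_equal(classify_mutation("Frame_Shift_Del"), "truncation")
  expect_equal(
    classify_mutation(c("Missense_Mutation", "Splice_Site", "Silent",
                        "In_Frame_Del", "Nonstop_Mutation",
                        "Translation_Start_Site", "Frame_Shift_Ins",
                        "3'UTR")),
    c("missense", "truncation", "other", "other", "truncation",
      "truncation", "truncation", "other"))
  expect_message(out <- classify_mutation("Totally_New_Class"), "unknown")
  expect_equal(out, "other")
})

test_that("mutation matrix is binary, class-filtered, and matches hand tabulation", {
  rec <- data.frame(
    gene = c("A", "A", "B", "B", "C", "C", "C"),
    sample = c("s1", "s1", "s1", "s2", "s3", "s3", "s4"),
    variant_class = c("Missense_Mutation", "Missense_Mutation",
                      "Nonsense_Mutation", "Silent", "Frame_Shift_Del",
                      "Missense_Mutation", "Splice_Site"),
    stringsAsFactors = FALSE
  )
  samples <- c("s1", "s2", "s3", "s4", "s5")
  genes <- c("A", "B", "C", "D")

  m_any <- build_mutation_matrix(rec, samples, genes,
                                 classes = c("missense", "truncation"))
  truth <- matrix(0L, 5, 4, dimnames = list(samples, genes))
  truth["s1", "A"] <- 1L; truth["s1", "B"] <- 1L
  truth["s3", "C"] <- 1L; truth["s4", "C"] <- 1L
  expect_identical(m_any$indicator, truth)

  # class filter: only truncating records count
  m_tr <- build_mutation_matrix(rec, samples, genes, classes = "truncation")
  expect_equal(sum(m_tr$indicator), 3)
  expect_equal(unname(m_tr$indicator["s1", "A"]), 0L)

  # doubled records stay binary
  expect_equal(max(m_any$indicator), 1L)

  # a missense-only record never reaches a truncation-only matrix
  m0 <- build_mutation_matrix(rec[1, ], samples, genes,
                              classes = "truncation")
  expect_equal(sum(m0$indicator), 0)

  # records for samples outside the cohort are ignored with a note
  expect_message(
    m_drop <- build_mutation_matrix(rec, c("s1", "s2"), genes),
    "outside the cohort")
  expect_equal(nrow(m_drop$indicator), 2)

  expect_error(build_mutation_matrix(rec, c("s1", "s1"), genes), "duplicate")
})

test_that("alteration frequencies are mutated-sample fractions", {
  rec <- data.frame(gene = c("A", "A", "A"), sample = c("s1", "s1", "s2"),
                    variant_class = rep("Missense_Mutation", 3),
                    stringsAsFactors = FALSE)
  m <- build_mutation_matrix(rec, sprintf("s%d", 1:25), c("A", "B"))
  f <- alteration_frequency(m)
  expect_equal(unname(f["A"]), 0.08)
  expect_equal(unname(f["B"]), 0)
})

test_that("gene profiles aggregate counts, lengths, and family flags", {
  rec <- data.frame(
    gene = c(rep("A", 5), "B"),
    sample = c("s1", "s1", "s2", "s3", "s3", "s9"),
    variant_class = rep("Missense_Mutation", 6),
    stringsAsFactors = FALSE
  )
  prof <- gene_profiles(rec, c(A = 1000, B = 500, C = 2000),
                        family_genes = c("A", "C"))
  pa <- prof[prof$gene == "A", ]
  expect_equal(pa$n_mutations, 5)
  expect_equal(pa$n_mutated_samples, 3)
  expect_equal(pa$normalized_rate, 0.005)
  expect_true(pa$in_family)
  pc <- prof[prof$gene == "C", ]
  expect_equal(pc$n_mutations, 0)
  expect_false(prof$in_family[prof$gene == "B"])
  expect_error(gene_profiles(rec, c(A = 0, B = 500)), "positive")
  expect_warning(gene_profiles(rec, c(A = 1000)), "without a length")
})

test_that("matrix TSV round-trips through write_mutation_matrix", {
  rec <- data.frame(gene = c("A", "B"), sample = c("s1", "s2"),
                    variant_class = rep("Missense_Mutation", 2),
                    stringsAsFactors = FALSE)
  m <- build_mutation_matrix(rec, c("s1", "s2", "s3"), c("A", "B"))
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_mutation_matrix(m, path)
  back <- utils::read.delim(path, check.names = FALSE)
  expect_equal(back$sample, m$samples)
  expect_equal(as.matrix(back[, m$genes]),
               m$indicator, ignore_attr = TRUE)
})

test_that("matrices rebuilt from written MAF files match generator internals", {
  co <- make_null_cohort(seed = 17, n_samples = 60, n_genes = 50)
  dir <- tempfile("rt")
  on.exit(unlink(dir, recursive = TRUE))
  write_cohort(co, dir)
  rec <- read_maf(file.path(dir, "maf.tsv"))
  m_file <- build_mutation_matrix(rec, co$clinical$sample, co$genes$gene,
                                  classes = c("missense", "truncation"))
  m_mem <- build_mutation_matrix(records_of(co), co$clinical$sample,
                                 co$genes$gene,
                                 classes = c("missense", "truncation"))
  expect_identical(m_file$indicator, m_mem$indicator)

  # per-class matrices union to the all-class matrix
  m_all <- build_mutation_matrix(rec, co$clinical$sample, co$genes$gene,
                                 classes = c("missense", "truncation",
                                             "other"))
  m_mis <- build_mutation_matrix(rec, co$clinical$sample, co$genes$gene,
                                 classes = "missense")
  m_tru <- build_mutation_matrix(rec, co$clinical$sample, co$genes$gene,
                                 classes = "truncation")
  m_oth <- build_mutation_matrix(rec, co$clinical$sample, co$genes$gene,
                                 classes = "other")
  union <- pmin(m_mis$indicator + m_tru$indicator + m_oth$indicator, 1L)
  expect_identical(union, m_all$indicator)
})
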
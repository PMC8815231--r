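#' Classify MAF variant classes into missense / truncation / other
#'
#' Truncating variants are those predicted to produce a shortened protein or
#' no protein product at all: nonsense, frameshift (insertion or deletion),
#' splice-site, nonstop and translation-start-site changes. Missense is the
#' MAF `Missense_Mutation` class. Everything else (silent, UTR, intronic,
#' in-frame indels, RNA, ...) maps to `other`; strings outside the MC3 MAF
#' vocabulary also map to `other` and are reported once per distinct string.
#'
#' @param variant_class Character vector of MAF `Variant_Classification`
#'   strings.
#' @return Character vector with levels `missense`, `truncation`, `other`.
#' @export
classify_mutation <- function(variant_class) {
  if (length(variant_class) == 0L) return(character(0))
  if (any(is.na(variant_class) | variant_class == "")) {
    stopf("variant_class must be non-empty strings")
  }
  truncating <- c("Nonsense_Mutation", "Frame_Shift_Del", "Frame_Shift_Ins",
                  "Splice_Site", "Nonstop_Mutation", "Translation_Start_Site")
  known_other <- c("Silent", "Intron", "3'UTR", "5'UTR", "3'Flank", "5'Flank",
                   "In_Frame_Del", "In_Frame_Ins", "RNA", "IGR",
                   "Targeted_Region", "De_novo_Start_InFrame",
                   "De_novo_Start_OutOfFrame", "Splice_Region")
  out <- rep("other", length(variant_class))
  out[variant_class == "Missense_Mutation"] <- "missense"
  out[variant_class %in% truncating] <- "truncation"
  unknown <- setdiff(unique(variant_class),
                     c("Missense_Mutation", truncating, known_other))
  if (length(unknown) > 0L) {
    message("classify_mutation: unknown variant class(es) mapped to 'other': ",
            paste(unknown, collapse = ", "))
  }
  out
}

# Parse protein positions from either a numeric value, a slash-delimited
# "pos/protein_length" token, or an HGVSp-style string ("p.G2029*"): the
# first run of digits is the residue. Unparseable entries give NA.
parse_protein_position <- function(x) {
  if (is.numeric(x)) {
    pos <- suppressWarnings(as.integer(x))
  } else {
    x <- as.character(x)
    m <- regexpr("[0-9]+", x)
    pos <- rep(NA_integer_, length(x))
    hit <- which(!is.na(x) & m > 0L)
    if (length(hit) > 0L) {
      pos[hit] <- as.integer(substr(x[hit], m[hit],
                                    m[hit] + attr(m, "match.length")[hit] - 1L))
    }
  }
  pos[!is.na(pos) & pos < 1L] <- NA_integer_
  pos
}

#' Read a MAF-style somatic mutation table
#'
#' Expects a tab-separated file with at least `Hugo_Symbol`,
#' `Tumor_Sample_Barcode` and `Variant_Classification` columns (the MC3 MAF
#' dialect; gzip-compressed files are read transparently; `#` comment lines
#' are skipped). Protein positions are parsed from a `Protein_position`
#' column (numeric or `"pos/length"`) or, failing that, from `HGVSp_Short`.
#'
#' @param path Path to the MAF file.
#' @param allowed_samples Optional character vector; rows whose barcode is
#'   not in this set are dropped.
#' @param normalize_barcodes If `TRUE`, barcodes are truncated to their first
#'   15 characters (TCGA sample-level identity) before matching and output.
#'   Default `FALSE`: exact string identity.
#' @return Data frame of mutation records with columns `gene`, `sample`,
#'   `variant_class`, `protein_position` (NA when unparseable) and the
#'   derived `mutation_class` (see [classify_mutation()]).
#' @export
read_maf <- function(path, allowed_samples = NULL, normalize_barcodes = FALSE) {
  if (!file.exists(path)) stopf("MAF file not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE, comment.char = "#",
                          quote = "")
  required <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stopf("MAF is missing required column(s): %s",
          paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0L) {
    warnf("MAF file %s has a header but no records", path)
    return(data.frame(gene = character(0), sample = character(0),
                      variant_class = character(0),
                      protein_position = integer(0),
                      mutation_class = character(0),
                      stringsAsFactors = FALSE))
  }
  sample <- df$Tumor_Sample_Barcode
  if (normalize_barcodes) sample <- substr(sample, 1L, 15L)
  pos <- if ("Protein_position" %in% names(df)) {
    parse_protein_position(df$Protein_position)
  } else if ("HGVSp_Short" %in% names(df)) {
    parse_protein_position(df$HGVSp_Short)
  } else {
    rep(NA_integer_, nrow(df))
  }
  rec <- data.frame(gene = df$Hugo_Symbol, sample = sample,
                    variant_class = df$Variant_Classification,
                    protein_position = pos, stringsAsFactors = FALSE)
  if (any(rec$gene == "" | rec$sample == "")) {
    stopf("MAF contains empty gene symbols or sample barcodes")
  }
  if (!is.null(allowed_samples)) {
    if (normalize_barcodes) allowed_samples <- substr(allowed_samples, 1L, 15L)
    rec <- rec[rec$sample %in% allowed_samples, , drop = FALSE]
    rownames(rec) <- NULL
  }
  rec$mutation_class <- classify_mutation(rec$variant_class)
  rec
}

#' Read a clinical table
#'
#' Tab-separated with at least `sample`, `os_months`, `os_event` columns
#' (as written by [write_cohort()]).
#' @param path File path.
#' @return Data frame.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stopf("clinical file not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  required <- c("sample", "os_months", "os_event")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stopf("clinical table is missing required column(s): %s",
          paste(missing, collapse = ", "))
  }
  df
}

#' Read a per-gene mean expression table (columns `gene`, `mean_rsem`)
#' @param path File path.
#' @return Data frame.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stopf("expression file not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  missing <- setdiff(c("gene", "mean_rsem"), names(df))
  if (length(missing) > 0L) {
    stopf("expression table is missing required column(s): %s",
          paste(missing, collapse = ", "))
  }
  df
}

#' Read a gene annotation table (columns `gene`, `coding_length`,
#' optionally `in_family`)
#' @param path File path.
#' @return Data frame.
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) stopf("gene table not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  missing <- setdiff(c("gene", "coding_length"), names(df))
  if (length(missing) > 0L) {
    stopf("gene table is missing required column(s): %s",
          paste(missing, collapse = ", "))
  }
  df
}

#' Build a binary sample-by-gene mutation indicator matrix
#'
#' `indicator[s, g]` is 1 iff sample *s* carries at least one mutation in
#' gene *g* whose class is in `classes`. Samples without any record appear
#' as all-zero rows; records for samples outside `samples` are ignored (a
#' count is reported), as are records for genes outside `genes`.
#'
#' @param records Mutation records ([read_maf()] output, or any data frame
#'   with `gene`, `sample` and either `mutation_class` or `variant_class`).
#' @param samples Character vector of sample barcodes (duplicate-free).
#' @param genes Character vector of gene symbols (duplicate-free).
#' @param classes Mutation classes to count; subset of
#'   `c("missense", "truncation", "other")`.
#' @return Object of class `mutation_matrix`: list with `samples`, `genes`,
#'   binary `indicator` matrix, and the `classes` used.
#' @export
build_mutation_matrix <- function(records, samples, genes,
                                  classes = c("missense", "truncation")) {
  if (length(samples) == 0L || anyDuplicated(samples) > 0L) {
    stopf("samples must be non-empty and duplicate-free")
  }
  if (length(genes) == 0L || anyDuplicated(genes) > 0L) {
    stopf("genes must be non-empty and duplicate-free")
  }
  if (!all(classes %in% c("missense", "truncation", "other"))) {
    stopf("classes must be a subset of missense/truncation/other")
  }
  records <- normalize_records(records)
  cls <- if ("mutation_class" %in% names(records)) {
    records$mutation_class
  } else {
    classify_mutation(records$variant_class)
  }
  keep <- cls %in% classes & records$gene %in% genes
  rec <- records[keep, , drop = FALSE]
  unknown_sample <- !(rec$sample %in% samples)
  if (any(unknown_sample)) {
    message(sprintf(
      "build_mutation_matrix: %d record(s) for sample(s) outside the cohort ignored",
      sum(unknown_sample)))
    rec <- rec[!unknown_sample, , drop = FALSE]
  }
  ind <- matrix(0L, nrow = length(samples), ncol = length(genes),
                dimnames = list(samples, genes))
  if (nrow(rec) > 0L) {
    ind[cbind(match(rec$sample, samples), match(rec$gene, genes))] <- 1L
  }
  structure(list(samples = samples, genes = genes, indicator = ind,
                 classes = classes),
            class = "mutation_matrix")
}

#' @export
print.mutation_matrix <- function(x, ...) {
  cat(sprintf("Mutation matrix: %d samples x %d genes (classes: %s); %d nonzero cells\n",
              length(x$samples), length(x$genes),
              paste(x$classes, collapse = "+"), sum(x$indicator)))
  invisible(x)
}

#' Write a mutation indicator matrix as a samples-by-genes TSV
#'
#' First column `sample`, one 0/1 column per gene.
#'
#' @param matrix A [build_mutation_matrix()] result.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_mutation_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "mutation_matrix"))
  df <- data.frame(sample = matrix$samples, matrix$indicator,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Per-gene alteration frequency
#'
#' Fraction of cohort samples carrying at least one qualifying mutation in
#' each gene.
#'
#' @param matrix A [build_mutation_matrix()] result.
#' @return Named numeric vector of proportions in [0, 1], one per gene.
#' @export
alteration_frequency <- function(matrix) {
  stopifnot(inherits(matrix, "mutation_matrix"))
  colSums(matrix$indicator) / length(matrix$samples)
}

#' Per-gene mutation profiles with size-normalized rates
#'
#' Aggregates mutation records per gene: number of mutation events, number
#' of distinct mutated samples, coding length, the length-normalized rate
#' (events per coding base) and the family membership flag. Genes present in
#' `gene_lengths` but absent from the records get zero counts; genes in the
#' records but missing a length entry are excluded with a warning.
#'
#' @param records Mutation records (see [build_mutation_matrix()]).
#' @param gene_lengths Named numeric vector of coding lengths, or a data
#'   frame with columns `gene` and `coding_length`.
#' @param family_genes Character vector of family gene symbols.
#' @param classes Mutation classes to count (default: all).
#' @return Data frame with columns `gene`, `n_mutations`,
#'   `n_mutated_samples`, `coding_length`, `normalized_rate`, `in_family`.
#' @export
gene_profiles <- function(records, gene_lengths, family_genes = character(0),
                          classes = c("missense", "truncation", "other")) {
  if (is.data.frame(gene_lengths)) {
    lens <- stats::setNames(gene_lengths$coding_length, gene_lengths$gene)
  } else {
    lens <- gene_lengths
  }
  if (is.null(names(lens)) || any(names(lens) == "")) {
    stopf("gene_lengths must be named by gene symbol")
  }
  if (any(!is.finite(lens) | lens <= 0)) {
    stopf("coding lengths must be strictly positive")
  }
  records <- normalize_records(records)
  cls <- if ("mutation_class" %in% names(records)) {
    records$mutation_class
  } else {
    classify_mutation(records$variant_class)
  }
  rec <- records[cls %in% classes, , drop = FALSE]
  no_length <- setdiff(unique(rec$gene), names(lens))
  if (length(no_length) > 0L) {
    warnf("gene_profiles: %d gene(s) without a length entry excluded (%s%s)",
          length(no_length), paste(utils::head(no_length, 5), collapse = ", "),
          if (length(no_length) > 5) ", ..." else "")
    rec <- rec[rec$gene %in% names(lens), , drop = FALSE]
  }
  genes <- names(lens)
  n_mut <- table(factor(rec$gene, levels = genes))
  n_samp <- table(factor(unique(rec[, c("gene", "sample")])$gene,
                         levels = genes))
  data.frame(
    gene = genes,
    n_mutations = as.integer(n_mut),
    n_mutated_samples = as.integer(n_samp),
    coding_length = as.numeric(lens),
    normalized_rate = as.integer(n_mut) / as.numeric(lens),
    in_family = genes %in% family_genes,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
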
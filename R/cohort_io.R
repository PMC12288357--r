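# Plain-text cohort I/O (TSV/CSV with a '#' schema-version header line),
# phenotype index derivation, repeated-measurement averaging, and SNP-panel
# zygosity calling. Missing values are written as empty fields; "NA" is
# accepted on read, never written.

io_header <- function(kind) paste0("# twinmeth ", kind, " v1")

check_header <- function(path, kind) {
  if (!file.exists(path)) stop("input file not found: ", path)
  first <- readLines(path, n = 1L)
  if (!startsWith(first, paste0("# twinmeth ", kind)))
    stop("'", path, "' does not look like a twinmeth ", kind,
         " file (missing schema header)")
}

write_table_with_header <- function(df, path, kind, sep) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(io_header(kind), con)
  utils::write.table(df, con, sep = sep, quote = FALSE, na = "",
                     row.names = FALSE)
}

read_table_with_header <- function(path, kind, sep, colClasses = NA) {
  check_header(path, kind)
  utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    quote = "", na.strings = c("", "NA"),
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = colClasses)
}

#' Write / read a methylation beta-value matrix (TSV)
#'
#' Rows are CpG ids, columns sample ids; values must lie in \[0, 1\] or be
#' missing. The first line is a schema-version header starting with `#`.
#'
#' @param mat Numeric matrix with CpG rownames and sample colnames.
#' @param path File path.
#' @return `write_methylation` returns `path` invisibly; `read_methylation`
#'   the validated matrix.
#' @export
write_methylation <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  validate_beta(mat)
  df <- data.frame(cpg_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_table_with_header(df, path, "methylation", "\t")
  invisible(path)
}

#' @rdname write_methylation
#' @export
read_methylation <- function(path) {
  df <- read_table_with_header(path, "methylation", "\t")
  if (names(df)[1L] != "cpg_id") stop("first column must be 'cpg_id'")
  if (anyDuplicated(df$cpg_id)) stop("duplicate CpG ids in ", path)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- df$cpg_id
  validate_beta(mat)
  mat
}

validate_beta <- function(mat) {
  bad <- which(!is.na(mat) & (mat < 0 | mat > 1), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("beta value out of [0, 1] at row '", rownames(mat)[bad[1, 1]],
         "', column '", colnames(mat)[bad[1, 2]], "': ",
         mat[bad[1, , drop = FALSE]])
  invisible(mat)
}

pheno_columns <- function() {
  c("sample_id", "pair_id", "zygosity", "age", "sex", "weight", "height",
    "wc", "hc", "bmi", "whr", "smoking", "drinking")
}

#' Write / read a phenotype table (CSV)
#'
#' Column dictionary: `sample_id`, `pair_id`, `zygosity` (MZ/DZ), `age`
#' (years), `sex` (M/F), `weight` (kg), `height` (m), `wc`/`hc` (cm), `bmi`
#' (kg/m^2), `whr` (unitless ratio), `smoking`/`drinking`
#' (current/former/never). Missing values are empty fields.
#'
#' @param pheno data.frame with the columns above.
#' @param path File path.
#' @export
write_phenotypes <- function(pheno, path) {
  missing_cols <- setdiff(pheno_columns(), names(pheno))
  if (length(missing_cols)) stop("phenotype table lacks column(s): ",
                                 paste(missing_cols, collapse = ", "))
  write_table_with_header(pheno[, pheno_columns()], path, "phenotypes", ",")
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  df <- read_table_with_header(path, "phenotypes", ",")
  missing_cols <- setdiff(pheno_columns(), names(df))
  if (length(missing_cols)) stop("phenotype table lacks column(s): ",
                                 paste(missing_cols, collapse = ", "))
  bad <- setdiff(stats::na.omit(unique(df$zygosity)), c("MZ", "DZ"))
  if (length(bad)) stop("invalid zygosity value(s): ",
                        paste(bad, collapse = ", "))
  bad <- setdiff(stats::na.omit(unique(df$sex)), c("M", "F"))
  if (length(bad)) stop("invalid sex value(s): ", paste(bad, collapse = ", "))
  for (cc in c("smoking", "drinking")) {
    bad <- setdiff(stats::na.omit(unique(df[[cc]])),
                   c("current", "former", "never"))
    if (length(bad)) stop("invalid ", cc, " value(s): ",
                          paste(bad, collapse = ", "))
  }
  df
}

#' Write / read a genotype table (TSV, SNPs x samples, values 0/1/2)
#' @param geno Integer matrix with SNP rownames and sample colnames.
#' @param path File path.
#' @export
write_genotypes <- function(geno, path) {
  stopifnot(is.matrix(geno), !is.null(rownames(geno)), !is.null(colnames(geno)))
  df <- data.frame(snp_id = rownames(geno), geno, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_table_with_header(df, path, "genotypes", "\t")
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  df <- read_table_with_header(path, "genotypes", "\t")
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "integer"
  rownames(mat) <- df$snp_id
  bad <- which(!is.na(mat) & !(mat %in% 0:2), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("genotype not in {0,1,2} at row '", rownames(mat)[bad[1, 1]],
         "', column '", colnames(mat)[bad[1, 2]], "'")
  mat
}

#' Write / read a meQTL map (two-column TSV: snp, cpg)
#' @param meqtl data.frame with columns `snp` and `cpg`.
#' @param path File path.
#' @export
write_meqtl <- function(meqtl, path) {
  stopifnot(all(c("snp", "cpg") %in% names(meqtl)))
  write_table_with_header(meqtl[, c("snp", "cpg")], path, "meqtl", "\t")
  invisible(path)
}

#' @rdname write_meqtl
#' @export
read_meqtl <- function(path) {
  df <- read_table_with_header(path, "meqtl", "\t",
                               colClasses = c("character", "character"))
  if (!identical(names(df), c("snp", "cpg")))
    stop("meQTL file must have columns snp, cpg")
  df
}

#' Write / read a one-column SNP list (text)
#' @param snps Character vector of SNP ids.
#' @param path File path.
#' @export
write_snp_list <- function(snps, path) {
  writeLines(c(io_header("snplist"), snps), path)
  invisible(path)
}

#' @rdname write_snp_list
#' @export
read_snp_list <- function(path) {
  check_header(path, "snplist")
  x <- readLines(path)
  x[!startsWith(x, "#") & nzchar(x)]
}

#' Write / read a CpG annotation table (TSV)
#'
#' Columns: `cpg`, `chr`, `position` (1-based, as in array manifests),
#' `gene`, `locus`, `enhancer` (TRUE/FALSE).
#' @param ann data.frame with the columns above.
#' @param path File path.
#' @export
write_annotation <- function(ann, path) {
  cols <- c("cpg", "chr", "position", "gene", "locus", "enhancer")
  missing_cols <- setdiff(cols, names(ann))
  if (length(missing_cols)) stop("annotation lacks column(s): ",
                                 paste(missing_cols, collapse = ", "))
  write_table_with_header(ann[, cols], path, "annotation", "\t")
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  df <- read_table_with_header(path, "annotation", "\t")
  cols <- c("cpg", "chr", "position", "gene", "locus", "enhancer")
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols)) stop("annotation lacks column(s): ",
                                 paste(missing_cols, collapse = ", "))
  df$enhancer <- as.logical(df$enhancer)
  df
}

#' Write / read a simulation truth table (TSV)
#' @param truth data.frame as produced by [simulate_cohort()].
#' @param path File path.
#' @export
write_truth <- function(truth, path) {
  write_table_with_header(truth, path, "truth", "\t")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) read_table_with_header(path, "truth", "\t")

#' Write / read a whole cohort as a directory of text files
#'
#' Writes `methylation.tsv`, `phenotypes.csv` and, when present,
#' `truth.tsv`, `genotypes.tsv`, `meqtl.tsv`, `gwas.txt`.
#' @param cohort A `twin_cohort`.
#' @param dir Directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_methylation(cohort$beta, file.path(dir, "methylation.tsv"))
  write_phenotypes(cohort$pheno, file.path(dir, "phenotypes.csv"))
  if (!is.null(cohort$truth)) write_truth(cohort$truth,
                                          file.path(dir, "truth.tsv"))
  if (!is.null(cohort$genotypes))
    write_genotypes(cohort$genotypes, file.path(dir, "genotypes.tsv"))
  if (!is.null(cohort$meqtl)) write_meqtl(cohort$meqtl,
                                          file.path(dir, "meqtl.tsv"))
  if (!is.null(cohort$gwas)) write_snp_list(cohort$gwas,
                                            file.path(dir, "gwas.txt"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  p <- function(f) file.path(dir, f)
  cohort <- list(beta = read_methylation(p("methylation.tsv")),
                 pheno = read_phenotypes(p("phenotypes.csv")),
                 truth = if (file.exists(p("truth.tsv"))) read_truth(p("truth.tsv")),
                 genotypes = if (file.exists(p("genotypes.tsv")))
                   read_genotypes(p("genotypes.tsv")),
                 meqtl = if (file.exists(p("meqtl.tsv"))) read_meqtl(p("meqtl.tsv")),
                 gwas = if (file.exists(p("gwas.txt"))) read_snp_list(p("gwas.txt")),
                 config = NULL)
  structure(cohort, class = "twin_cohort")
}

#' Average repeated anthropometric measurements
#'
#' Two measurements: their mean (with a warning when they differ by more than
#' `discrepancy_limit`, since the protocol then called for a third). Three
#' measurements: the mean of the two closest values; when the two candidate
#' pairs are equally close (symmetric spacing) both contain the median and
#' the median itself is returned (it equals the average of the tied pair
#' means).
#'
#' @param measures Numeric vector of 2 or 3 finite values.
#' @param discrepancy_limit Difference (same units) above which a third
#'   measurement was expected (default 1, i.e. 1 cm).
#' @return Single numeric value.
#' @examples
#' average_repeated(c(100.0, 100.4))        # 100.2
#' average_repeated(c(100.0, 101.5, 100.4)) # 100.2
#' @export
average_repeated <- function(measures, discrepancy_limit = 1) {
  if (!is.numeric(measures) || !all(is.finite(measures)))
    stop("measurements must be finite numbers")
  if (length(measures) == 2L) {
    if (abs(diff(measures)) > discrepancy_limit)
      warning("two measurements differ by more than ", discrepancy_limit,
              "; a third measurement was expected")
    return(mean(measures))
  }
  if (length(measures) != 3L) stop("need 2 or 3 measurements")
  v <- sort(measures)
  d_lo <- v[2] - v[1]; d_hi <- v[3] - v[2]
  if (abs(d_lo - d_hi) < 1e-12) return(v[2])
  if (d_lo < d_hi) mean(v[1:2]) else mean(v[2:3])
}

#' Derive BMI and WHR from raw anthropometrics
#'
#' Fills `bmi = weight / height^2` and `whr = wc / hc`. Heights outside
#' 0.5-2.5 m trigger a unit-error warning (centimetres suspected). Existing
#' values that disagree with the derived ones beyond 1e-6 are overwritten
#' with a warning.
#'
#' @param pheno data.frame with `weight` (kg), `height` (m), `wc`, `hc` (cm);
#'   `bmi`/`whr` columns are created or overwritten.
#' @return The data.frame with `bmi` and `whr` filled.
#' @export
derive_indices <- function(pheno) {
  h <- pheno$height
  if (any(!is.na(h) & (h < 0.5 | h > 2.5)))
    warning("height outside 0.5-2.5 m: values look like centimetres ",
            "(unit error?)")
  bmi <- pheno$weight / pheno$height^2
  whr <- pheno$wc / pheno$hc
  for (nm in c("bmi", "whr")) {
    new <- if (nm == "bmi") bmi else whr
    if (!is.null(pheno[[nm]])) {
      diffs <- abs(pheno[[nm]] - new)
      if (any(!is.na(diffs) & diffs > 1e-6))
        warning("existing ", nm, " values inconsistent with derived ones; ",
                "overwriting")
    }
    pheno[[nm]] <- new
  }
  pheno
}

#' Call zygosity from a SNP panel
#'
#' Compares the two twins' genotypes at SNPs typed in both; the pair is
#' called MZ iff the identity fraction strictly exceeds `threshold` and at
#' least `min_snps` SNPs were compared (otherwise `indeterminate` when the
#' comparison is underpowered).
#'
#' @param g1,g2 Genotype vectors (0/1/2, NA allowed) for the two twins.
#' @param threshold Identity fraction above which the pair is MZ (default 0.9).
#' @param min_snps Minimum number of compared SNPs (default 30).
#' @return List `n_snps_compared`, `identity_fraction`, `call`
#'   (`"MZ"`, `"DZ"` or `"indeterminate"`).
#' @examples
#' call_zygosity(rep(1, 59), c(rep(1, 54), rep(0, 5)))$call # "MZ" (54/59)
#' @export
call_zygosity <- function(g1, g2, threshold = 0.9, min_snps = 30L) {
  if (length(g1) != length(g2)) stop("genotype vectors differ in length")
  ok <- !is.na(g1) & !is.na(g2)
  n <- sum(ok)
  frac <- if (n > 0) sum(g1[ok] == g2[ok]) / n else NA_real_
  call <- if (n < min_snps) "indeterminate"
  else if (frac > threshold) "MZ" else "DZ"
  list(n_snps_compared = n, identity_fraction = frac, call = call)
}

#' Call zygosity for every pair in a cohort
#'
#' @param genotypes SNPs x samples matrix.
#' @param pheno Phenotype table with `sample_id` and `pair_id`.
#' @inheritParams call_zygosity
#' @return data.frame `pair_id, n_snps_compared, identity_fraction, call`.
#' @export
call_zygosity_pairs <- function(genotypes, pheno, threshold = 0.9,
                                min_snps = 30L) {
  pidx <- pair_index(pheno)
  rows <- lapply(names(pidx), function(pid) {
    ii <- pidx[[pid]]
    z <- call_zygosity(genotypes[, pheno$sample_id[ii[1]]],
                       genotypes[, pheno$sample_id[ii[2]]],
                       threshold, min_snps)
    data.frame(pair_id = pid, n_snps_compared = z$n_snps_compared,
               identity_fraction = z$identity_fraction, call = z$call,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
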
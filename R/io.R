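#' Read a log2 abundance matrix (proteins x samples)
#'
#' Reads a TSV (or CSV) table whose header row holds sample ids and whose
#' first column holds protein ids, typically `"Symbol|UniProtAccession"`
#' strings.  Empty cells and the token `"NA"` become missing values.
#'
#' @param path File path.
#' @param sep Field delimiter; tab by default, use `","` for CSV.
#' @return Numeric matrix with protein row names and sample column names;
#'   `NA` marks missing quantifications.
#' @export
read_abundance_matrix <- function(path, sep = "\t") {
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "", na.strings = c("NA", ""))
  if (ncol(raw) < 2L) stop("abundance table needs a protein id column plus >=1 sample")
  ids <- raw[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate protein ids: ", paste(dup, collapse = ", "))
  samples <- colnames(raw)[-1L]
  dup <- unique(samples[duplicated(samples)])
  if (length(dup))
    stop("duplicate sample ids: ", paste(dup, collapse = ", "))
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell at row %d (protein '%s'), column '%s'",
                 bad[1L, 1L], ids[bad[1L, 1L]], samples[bad[1L, 2L]]))
  dimnames(num) <- list(ids, samples)
  check_abundance_matrix(num, basename(path))
  num
}

#' Write an abundance matrix as TSV
#'
#' Inverse of [read_abundance_matrix()]: first column `Protein`, one column
#' per sample, missing values written as `NA`.
#'
#' @param x Numeric matrix with dimnames.
#' @param path Output path.
#' @param sep Field delimiter.
#' @export
write_abundance_matrix <- function(x, path, sep = "\t") {
  check_abundance_matrix(x)
  df <- data.frame(Protein = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Drop proteins with too much missingness
#'
#' Retains proteins whose missing fraction is strictly below
#' `max_missing_fraction` (so a protein missing in exactly half of the
#' samples is dropped at the 0.50 default).  Row order is preserved.
#'
#' @param x Abundance matrix.
#' @param max_missing_fraction Strict upper bound on the per-protein
#'   fraction of missing samples, in `[0, 1]`.
#' @export
filter_missingness <- function(x, max_missing_fraction = 0.50) {
  check_abundance_matrix(x)
  if (!is.numeric(max_missing_fraction) || max_missing_fraction < 0 ||
      max_missing_fraction > 1)
    stop("max_missing_fraction must be in [0, 1]")
  frac <- rowMeans(is.na(x))
  x[frac < max_missing_fraction, , drop = FALSE]
}

#' Read cell-type marker sets from a GMT file
#'
#' Standard GMT: one tab-separated line per set, `name<TAB>description<TAB>`
#' then one gene symbol per field.  Symbols are uppercased on read.
#'
#' @param path GMT file path.
#' @return Named list of character vectors of marker symbols.
#' @export
read_marker_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("malformed GMT line %d: fewer than 3 fields", i))
    sets[[f[1L]]] <- unique(toupper(trimws(f[-(1:2)])))
  }
  sets
}

#' Write marker sets as GMT
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional per-set description strings.
#' @export
write_marker_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  desc <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-level association table (columns GENE, P)
#'
#' One table per GWAS study; symbols uppercased on read.
#'
#' @param path TSV path with header columns `GENE` and `P`.
#' @return `data.frame` with columns `GENE` (character) and `P` (numeric).
#' @export
read_gene_pvalues <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!all(c("GENE", "P") %in% colnames(df)))
    stop("gene p-value table must have columns GENE and P: ", path)
  data.frame(GENE = toupper(trimws(as.character(df$GENE))),
             P = as.numeric(df$P), stringsAsFactors = FALSE)
}

#' Read a biofluid differential-abundance table
#'
#' @param path TSV with header columns `protein`, `log2FC`, `p`.
#' @return `data.frame` with those three columns; protein symbols uppercased.
#' @export
read_biofluid_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("protein", "log2FC", "p")
  if (!all(need %in% colnames(df)))
    stop("biofluid table must have columns protein, log2FC, p: ", path)
  data.frame(protein = toupper(trimws(as.character(df$protein))),
             log2FC = as.numeric(df$log2FC), p = as.numeric(df$p),
             stringsAsFactors = FALSE)
}

#' Write any result table as TSV
#' @param x `data.frame`.
#' @param path Output path.
#' @export
write_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a sample design table (sample, batch, is_gis)
#' @param path TSV with header columns `sample`, `batch`, `is_gis`.
#' @export
read_batch_design <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("sample", "batch", "is_gis")
  if (!all(need %in% colnames(df)))
    stop("design table must have columns sample, batch, is_gis: ", path)
  df$sample <- as.character(df$sample)
  df$batch <- as.character(df$batch)
  df$is_gis <- as.logical(df$is_gis)
  df
}

#' Read a sample trait table
#' @param path TSV with a `sample` column plus trait columns (diagnosis,
#'   age, sex, PMI, CERAD, Braak, CAA, gliosis, APOE4).
#' @export
read_sample_traits <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"sample" %in% colnames(df)) stop("trait table must have a sample column")
  df$sample <- as.character(df$sample)
  df
}
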
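#' Construct a probe-by-sample omics matrix
#'
#' An `omics_matrix` is the basic data container of the package: a numeric
#' probe-by-sample matrix of SNP-array intensities tagged with the modality
#' it measures (genotype signal or DNA-methylation signal).  Probe and
#' sample identifiers are carried as row and column names and must be
#' unique.  Missing measurements are stored as `NA`, never as zero; zero
#' substitution is an explicit downstream step
#' ([substitute_missing_with_zero()]).
#'
#' @param values Numeric matrix with probe identifiers as row names and
#'   sample identifiers as column names.
#' @param modality Either `"genotype"` or `"methylation"`.
#' @return An object of class `omics_matrix`: a list with elements
#'   `values`, `modality`.
#' @examples
#' m <- omics_matrix(matrix(1:6, 3, 2,
#'   dimnames = list(c("p1", "p2", "p3"), c("s1", "s2"))), "genotype")
#' probe_ids(m)
#' @export
omics_matrix <- function(values, modality = c("genotype", "methylation")) {
  modality <- match.arg(modality)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have probe row names and sample column names",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe identifiers", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers", call. = FALSE)
  structure(list(values = values, modality = modality),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix [%s]: %d probes x %d samples (%d missing)\n",
              x$modality, nrow(x$values), ncol(x$values),
              sum(is.na(x$values))))
  invisible(x)
}

#' @rdname omics_matrix
#' @param x An `omics_matrix`.
#' @export
probe_ids <- function(x) rownames(x$values)

#' @rdname omics_matrix
#' @export
sample_ids <- function(x) colnames(x$values)

#' Sample design table
#'
#' Maps each sample to its subject and tissue class.  The tissue classes
#' are ordered `blood < normal < tumor`; their integer codes (1, 2, 3) are
#' the ordinal response used by the correlation and PLS selectors.
#'
#' @param sample_id,subject_id Character vectors of equal length.
#' @param tissue Character or factor; values must be among
#'   `"blood"`, `"normal"`, `"tumor"`.
#' @return A `data.frame` of class `sample_design` with columns
#'   `sample_id`, `subject_id`, `tissue` (ordered factor).
#' @seealso [tissue_code()]
#' @export
sample_design <- function(sample_id, subject_id, tissue) {
  sample_id <- as.character(sample_id)
  subject_id <- as.character(subject_id)
  if (anyDuplicated(sample_id))
    stop("duplicate sample identifiers in design", call. = FALSE)
  tissue <- as.character(tissue)
  bad <- setdiff(unique(tissue), tissue_levels())
  if (length(bad))
    stop("unknown tissue class: ", paste(bad, collapse = ", "),
         call. = FALSE)
  d <- data.frame(sample_id = sample_id, subject_id = subject_id,
                  tissue = factor(tissue, levels = tissue_levels(),
                                  ordered = TRUE),
                  stringsAsFactors = FALSE)
  class(d) <- c("sample_design", "data.frame")
  d
}

tissue_levels <- function() c("blood", "normal", "tumor")

#' Ordinal tissue class code
#'
#' Returns the integer class code y for each sample of an omics matrix:
#' 1 for blood, 2 for normal tissue, 3 for tumor, in the column order of
#' the matrix (or the order of `sample_ids` when given directly).
#'
#' @param design A [sample_design()] table.
#' @param samples Character vector of sample identifiers; every sample
#'   must have a design entry.
#' @return Integer vector in `{1, 2, 3}` named by sample.
#' @export
tissue_code <- function(design, samples) {
  i <- match(samples, design$sample_id)
  if (anyNA(i))
    stop("samples missing from design: ",
         paste(samples[is.na(i)], collapse = ", "), call. = FALSE)
  stats::setNames(as.integer(design$tissue[i]), samples)
}

#' Tissue factor for a set of samples
#'
#' @inheritParams tissue_code
#' @return Factor with levels blood, normal, tumor.
#' @export
tissue_of <- function(design, samples) {
  i <- match(samples, design$sample_id)
  if (anyNA(i))
    stop("samples missing from design: ",
         paste(samples[is.na(i)], collapse = ", "), call. = FALSE)
  factor(as.character(design$tissue[i]), levels = tissue_levels())
}

#' Read a probe-by-sample matrix from TSV
#'
#' The expected dialect is a header row `probe_id<TAB>sample1<TAB>...`
#' followed by one row per probe.  Empty cells, `NA` and `NaN` are read as
#' missing values (not zero).
#'
#' @param path Path to a TSV file.
#' @param modality Passed to [omics_matrix()].
#' @return An `omics_matrix`.
#' @export
read_matrix <- function(path, modality = c("genotype", "methylation")) {
  modality <- match.arg(modality)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, fill = FALSE,
                           na.strings = c("", "NA", "NaN"),
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2)
    stop("matrix file must have a probe_id column and >=1 sample column",
         call. = FALSE)
  ids <- tab[[1]]
  if (anyDuplicated(ids))
    stop("duplicate probe identifiers in ", path, call. = FALSE)
  if (anyDuplicated(colnames(tab)[-1]))
    stop("duplicate sample identifiers in ", path, call. = FALSE)
  vals <- vapply(tab[-1], as.numeric, numeric(nrow(tab)))
  vals <- matrix(vals, nrow = nrow(tab),
                 dimnames = list(ids, colnames(tab)[-1]))
  omics_matrix(vals, modality)
}

#' Write a probe-by-sample matrix as TSV
#'
#' Inverse of [read_matrix()]; missing values are written as `NA` so the
#' round trip preserves missingness.
#'
#' @param x An `omics_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path) {
  stopifnot(inherits(x, "omics_matrix"))
  tab <- data.frame(probe_id = probe_ids(x), x$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read / write a sample design table (TSV)
#'
#' Dialect: `sample_id<TAB>subject_id<TAB>tissue`.
#'
#' @param path Path to a TSV file.
#' @return For `read_design`, a [sample_design()] table.
#' @export
read_design <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, fill = FALSE,
                           stringsAsFactors = FALSE)
  need <- c("sample_id", "subject_id", "tissue")
  if (!all(need %in% colnames(tab)))
    stop("design file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  sample_design(tab$sample_id, tab$subject_id, tab$tissue)
}

#' @rdname read_design
#' @param design A [sample_design()] table.
#' @export
write_design <- function(design, path) {
  utils::write.table(as.data.frame(design)[c("sample_id", "subject_id",
                                             "tissue")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Replace missing values by zero
#'
#' The decomposition step operates on complete matrices; missing array
#' measurements are replaced by exact zeros beforehand.  The operation is
#' idempotent and leaves non-missing entries untouched.
#'
#' @param x An `omics_matrix`.
#' @return An `omics_matrix` without missing entries.
#' @export
substitute_missing_with_zero <- function(x) {
  stopifnot(inherits(x, "omics_matrix"))
  if (anyNA(x$values)) x$values[is.na(x$values)] <- 0
  x
}

#' Restrict two modalities to their common probe universe
#'
#' Both matrices are restricted to the probes they share, in identical
#' (lexicographic) order, so that downstream set intersections refer to
#' one probe universe.  The two matrices must cover the same samples;
#' the second matrix's columns are reordered to match the first.
#'
#' @param a,b `omics_matrix` objects covering the same samples.
#' @return List with elements `a` and `b`, aligned.
#' @export
align_modalities <- function(a, b) {
  stopifnot(inherits(a, "omics_matrix"), inherits(b, "omics_matrix"))
  if (!setequal(sample_ids(a), sample_ids(b)))
    stop("sample identifier sets differ between modalities", call. = FALSE)
  common <- sort(intersect(probe_ids(a), probe_ids(b)))
  if (length(common) == 0)
    stop("modalities share no probe identifiers", call. = FALSE)
  a$values <- a$values[common, , drop = FALSE]
  b$values <- b$values[common, sample_ids(a), drop = FALSE]
  list(a = a, b = b)
}

#' Read / write binary compound fingerprints (TSV)
#'
#' Dialect: `compound_id<TAB>bitstring` where the bitstring is a
#' fixed-length string of 0/1 characters.
#'
#' @param path Path to a TSV file.
#' @return For `read_fingerprints`, a `fingerprint_set` (see
#'   [fingerprint_set()]).
#' @export
read_fingerprints <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, fill = FALSE,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (!all(c("compound_id", "bitstring") %in% colnames(tab)))
    stop("fingerprint file must have columns compound_id, bitstring",
         call. = FALSE)
  if (nrow(tab) == 0)
    return(fingerprint_set(matrix(0L, 0, 0)))
  bits <- strsplit(tab$bitstring, "")
  n_bits <- unique(lengths(bits))
  if (length(n_bits) != 1)
    stop("fingerprints have unequal bit lengths", call. = FALSE)
  mat <- do.call(rbind, lapply(bits, function(b) as.integer(b)))
  rownames(mat) <- tab$compound_id
  fingerprint_set(mat)
}

#' @rdname read_fingerprints
#' @param fp A `fingerprint_set`.
#' @export
write_fingerprints <- function(fp, path) {
  stopifnot(inherits(fp, "fingerprint_set"))
  tab <- data.frame(compound_id = rownames(fp$bits),
                    bitstring = apply(fp$bits, 1, paste, collapse = ""),
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
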
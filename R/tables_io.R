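#' @importFrom utils read.delim write.table
NULL

#' Default column schema for spectral-count TSV files
#'
#' Maps TSV columns onto the fields of a [spectral_counts()] table. Count
#' columns are recognised by `count_pattern`, a regular expression with two
#' capture groups: the sample label and the replicate index. Deposited
#' datasets with other layouts can be read by supplying a modified schema.
#'
#' @return A list with elements `accession`, `gene` (column names) and
#'   `count_pattern` (regex for count columns).
#' @export
count_schema <- function(accession = "accession", gene = "gene",
                         count_pattern = "^(.+)_rep([0-9]+)$") {
  list(accession = accession, gene = gene, count_pattern = count_pattern)
}

#' Spectral-count table
#'
#' Per-protein MS/MS spectral counts across replicated pulldown samples.
#' Exactly one sample is the control pulldown (a housekeeping mRNA such as
#' *Actin*, used to flag pan RNA-binding and background proteins); the
#' remaining samples are bait pulldowns (the mRNAs of interest).
#'
#' @param accession Character vector of protein accessions (unique, non-empty).
#' @param gene Character vector of gene symbols, same length as `accession`.
#' @param counts Integer matrix of non-negative spectral counts, one row per
#'   protein and one column per (sample, replicate) pair. Column names must
#'   follow `<sample>_rep<k>`.
#' @param control Name of the control sample; must match one sample label in
#'   the column names.
#' @return An object of class `spectral_counts`: a list with elements
#'   `accession`, `gene`, `counts`, `samples` (per-column sample label),
#'   `replicates` (per-column replicate index), `sample_order` and `control`.
#' @examples
#' counts <- matrix(
#'   c(20L, 15L, 0L, 1L, 0L, 0L, 0L),
#'   nrow = 1,
#'   dimnames = list(NULL, c("Tnp1_rep1", "Tnp1_rep2", "Tnp2_rep1",
#'                           "Tnp2_rep2", "Actin_rep1", "Actin_rep2",
#'                           "Actin_rep3"))
#' )
#' spectral_counts("Q91W50", "CSDE1", counts, control = "Actin")
#' @export
spectral_counts <- function(accession, gene, counts, control) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) {
    stop("count matrix must have '<sample>_rep<k>' column names")
  }
  parsed <- parse_count_columns(colnames(counts))
  # reorder columns: samples in order of first appearance, replicates ascending
  sample_order <- unique(parsed$sample)
  ord <- order(match(parsed$sample, sample_order), parsed$replicate)
  counts <- counts[, ord, drop = FALSE]
  parsed <- parsed[ord, , drop = FALSE]
  x <- structure(
    list(
      accession = as.character(accession),
      gene = as.character(gene),
      counts = counts,
      samples = parsed$sample,
      replicates = parsed$replicate,
      sample_order = sample_order,
      control = as.character(control)
    ),
    class = "spectral_counts"
  )
  validate_spectral_counts(x)
}

parse_count_columns <- function(headers, pattern = "^(.+)_rep([0-9]+)$") {
  m <- regmatches(headers, regexec(pattern, headers))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    stop("count column header(s) not matching '<sample>_rep<k>': ",
         paste(headers[bad], collapse = ", "))
  }
  data.frame(
    header = headers,
    sample = vapply(m, `[`, character(1), 2L),
    replicate = as.integer(vapply(m, `[`, character(1), 3L)),
    stringsAsFactors = FALSE
  )
}

validate_spectral_counts <- function(x) {
  stopifnot(inherits(x, "spectral_counts"))
  n <- length(x$accession)
  if (length(x$gene) != n) stop("accession and gene lengths differ")
  if (nrow(x$counts) != n) stop("count matrix has ", nrow(x$counts),
                                " rows for ", n, " proteins")
  if (n > 0 && any(!nzchar(x$accession) | is.na(x$accession))) {
    stop("empty or missing accession")
  }
  dup <- duplicated(x$accession)
  if (any(dup)) {
    stop("duplicate accession(s): ", paste(unique(x$accession[dup]), collapse = ", "))
  }
  if (anyNA(x$counts)) {
    idx <- which(is.na(x$counts), arr.ind = TRUE)[1, ]
    stop("missing count for protein '", x$accession[idx[1]], "' in column '",
         colnames(x$counts)[idx[2]],
         "' (use fill_missing = TRUE to treat absent proteins as zero)")
  }
  if (n > 0) {
    nonneg_int <- is.numeric(x$counts) & all(x$counts >= 0) &
      all(x$counts == trunc(x$counts))
    if (!isTRUE(nonneg_int)) {
      idx <- which(x$counts < 0 | x$counts != trunc(x$counts), arr.ind = TRUE)[1, ]
      stop("count for protein '", x$accession[idx[1]], "' in column '",
           colnames(x$counts)[idx[2]], "' is not a non-negative integer: ",
           x$counts[idx[1], idx[2]])
    }
  }
  storage.mode(x$counts) <- "integer"
  if (anyDuplicated(colnames(x$counts))) stop("duplicate count column headers")
  if (!x$control %in% x$samples) {
    stop("control sample '", x$control, "' not present among samples: ",
         paste(x$sample_order, collapse = ", "))
  }
  if (length(setdiff(x$sample_order, x$control)) < 1) {
    stop("need at least one bait sample besides the control")
  }
  x
}

#' @export
print.spectral_counts <- function(x, ...) {
  baits <- setdiff(x$sample_order, x$control)
  cat("spectral_counts: ", length(x$accession), " proteins, ",
      ncol(x$counts), " runs (baits: ", paste(baits, collapse = ", "),
      "; control: ", x$control, ")\n", sep = "")
  invisible(x)
}

#' Number of proteins / replicate columns of a sample
#' @rdname spectral_counts
#' @param x A `spectral_counts` table.
#' @param sample A sample label.
#' @export
sample_counts <- function(x, sample) {
  stopifnot(inherits(x, "spectral_counts"))
  if (!sample %in% x$samples) stop("unknown sample: ", sample)
  x$counts[, x$samples == sample, drop = FALSE]
}

bait_samples <- function(x) setdiff(x$sample_order, x$control)

#' Read a spectral-count table from TSV
#'
#' Expects a tab-separated file with an `accession` column, a `gene` column
#' and one count column per (sample, replicate) pair named `<sample>_rep<k>`
#' (configurable through `schema`). Empty count cells are an error unless
#' `fill_missing = TRUE`, in which case they become explicit zeros — the
#' conservative reading for proteins never identified in a pulldown.
#'
#' @param path Path to a TSV file.
#' @param control Name of the control sample.
#' @param fill_missing Replace empty count cells with 0 instead of erroring.
#' @param schema Column mapping, see [count_schema()].
#' @return A validated [spectral_counts()] table.
#' @export
read_spectral_counts <- function(path, control, fill_missing = FALSE,
                                 schema = count_schema()) {
  raw <- read.delim(path, check.names = FALSE, colClasses = "character",
                    na.strings = c("", "NA"))
  for (col in c(schema$accession, schema$gene)) {
    if (!col %in% names(raw)) stop("missing required column '", col, "' in ", path)
  }
  count_cols <- setdiff(names(raw), c(schema$accession, schema$gene))
  count_cols <- count_cols[grepl(schema$count_pattern, count_cols)]
  if (length(count_cols) == 0) stop("no count columns matching schema in ", path)
  counts <- matrix(NA_real_, nrow = nrow(raw), ncol = length(count_cols),
                   dimnames = list(NULL, count_cols))
  for (j in seq_along(count_cols)) {
    cell <- raw[[count_cols[j]]]
    if (fill_missing) cell[is.na(cell)] <- "0"
    bad <- !is.na(cell) & !grepl("^-?[0-9]+$", cell)
    if (any(bad)) {
      i <- which(bad)[1]
      stop("non-integer count '", cell[i], "' at row ", i, ", column '",
           count_cols[j], "' of ", path)
    }
    counts[, j] <- suppressWarnings(as.numeric(cell))
    neg <- !is.na(counts[, j]) & counts[, j] < 0
    if (any(neg)) {
      i <- which(neg)[1]
      stop("negative count '", cell[i], "' at row ", i, ", column '",
           count_cols[j], "' of ", path)
    }
  }
  spectral_counts(raw[[schema$accession]], raw[[schema$gene]], counts,
                  control = control)
}

#' Write a spectral-count table to TSV
#'
#' Deterministic column order: accession, gene, then samples in declared
#' order with replicate indices ascending. Re-reading the file with
#' [read_spectral_counts()] reproduces the table exactly.
#'
#' @param x A [spectral_counts()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectral_counts <- function(x, path) {
  validate_spectral_counts(x)
  df <- data.frame(accession = x$accession, gene = x$gene,
                   stringsAsFactors = FALSE, check.names = FALSE)
  df <- cbind(df, as.data.frame(x$counts, check.names = FALSE))
  write_tsv_(df, path)
  invisible(path)
}

write_tsv_ <- function(df, path) {
  con <- file(path, open = "wb")  # binary mode: identical bytes on any platform
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8", eol = "\n")
}

#' Cq (quantification-cycle) table
#'
#' Long-format RT-qPCR measurements: one row per technical replicate of a
#' (sample fraction, transcript) pair. Sample labels are free-form but the
#' delta-delta-Cq helpers expect `input` and `elution` by default.
#'
#' @param sample Sample-fraction label (e.g. `"input"`, `"elution"`).
#' @param transcript Transcript name.
#' @param is_reference Logical; `TRUE` for the reference (housekeeping)
#'   transcript.
#' @param tech_rep Technical-replicate index.
#' @param cq Quantification cycle, strictly positive.
#' @return A `data.frame` of class `cq_table`.
#' @export
cq_table <- function(sample, transcript, is_reference, tech_rep, cq) {
  x <- data.frame(sample = as.character(sample),
                  transcript = as.character(transcript),
                  is_reference = as.logical(is_reference),
                  tech_rep = as.integer(tech_rep),
                  cq = as.numeric(cq),
                  stringsAsFactors = FALSE)
  class(x) <- c("cq_table", "data.frame")
  validate_cq_table(x)
}

validate_cq_table <- function(x) {
  req <- c("sample", "transcript", "is_reference", "tech_rep", "cq")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols)) {
    stop("cq table missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyNA(x$cq) || any(x$cq <= 0)) {
    i <- which(is.na(x$cq) | x$cq <= 0)[1]
    stop("Cq must be > 0; offending value '", x$cq[i], "' at row ", i)
  }
  # reference flag must be consistent per transcript
  ref <- tapply(x$is_reference, x$transcript, function(v) length(unique(v)))
  if (any(ref > 1)) {
    stop("inconsistent is_reference flag for transcript(s): ",
         paste(names(ref)[ref > 1], collapse = ", "))
  }
  x
}

#' Read / write a Cq table (TSV: sample, transcript, is_reference, tech_rep, cq)
#' @param path Path to a TSV file.
#' @return A validated [cq_table()].
#' @export
read_cq_table <- function(path) {
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("sample", "transcript", "is_reference", "tech_rep", "cq")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  cq_table(raw$sample, raw$transcript, as.logical(raw$is_reference),
           raw$tech_rep, raw$cq)
}

#' @rdname read_cq_table
#' @param x A [cq_table()].
#' @export
write_cq_table <- function(x, path) {
  validate_cq_table(x)
  write_tsv_(as.data.frame(x), path)
  invisible(path)
}

#' Polysome-gradient fraction table
#'
#' Relative mRNA quantities per sucrose-gradient fraction, long format.
#' Fraction indices must be contiguous from 1 to n for every transcript.
#'
#' @param fraction Integer fraction index (1 = top of the gradient).
#' @param transcript Transcript name.
#' @param quantity Non-negative relative quantity (arbitrary units).
#' @return A `data.frame` of class `fraction_table`.
#' @export
fraction_table <- function(fraction, transcript, quantity) {
  x <- data.frame(fraction = as.integer(fraction),
                  transcript = as.character(transcript),
                  quantity = as.numeric(quantity),
                  stringsAsFactors = FALSE)
  class(x) <- c("fraction_table", "data.frame")
  validate_fraction_table(x)
}

validate_fraction_table <- function(x) {
  req <- c("fraction", "transcript", "quantity")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols)) {
    stop("fraction table missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyNA(x$quantity) || any(x$quantity < 0)) stop("quantity must be >= 0")
  for (tr in unique(x$transcript)) {
    f <- sort(x$fraction[x$transcript == tr])
    expected <- seq_len(length(f))
    if (!identical(f, expected)) {
      gap <- setdiff(seq_len(max(f)), f)
      stop("fractions for transcript '", tr, "' are not contiguous from 1: ",
           if (length(gap)) paste0("missing fraction(s) ", paste(gap, collapse = ", "))
           else paste0("indices ", paste(f, collapse = ",")))
    }
  }
  x
}

#' Read / write a fraction table (TSV: fraction, transcript, quantity)
#' @param path Path to a TSV file.
#' @return A validated [fraction_table()].
#' @export
read_fraction_table <- function(path) {
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("fraction", "transcript", "quantity")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  fraction_table(raw$fraction, raw$transcript, raw$quantity)
}

#' @rdname read_fraction_table
#' @param x A [fraction_table()].
#' @export
write_fraction_table <- function(x, path) {
  validate_fraction_table(x)
  write_tsv_(as.data.frame(x), path)
  invisible(path)
}
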
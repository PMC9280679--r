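#' Validate an expression matrix
#'
#' Normalized intensities are kept on the linear scale; statistical
#' operations apply log2 internally. Invariants: finite, strictly positive
#' values; unique gene and sample identifiers.
#'
#' @param x Numeric matrix, genes in rows (rownames = gene ids), samples in
#'   columns (colnames = sample ids).
#' @return `x`, invisibly, after checking the invariants.
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression matrix must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(x)))
    stop("duplicate gene id(s): ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicate sample id(s): ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  bad <- which(!is.finite(x) | x <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("non-positive or non-finite intensity at gene '",
         rownames(x)[bad[1L, 1L]], "', sample '", colnames(x)[bad[1L, 2L]],
         "' (", nrow(bad), " offending cell(s) in total)")
  invisible(x)
}

#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects a tab-separated file with a header row of sample ids and the
#' first column holding gene ids. Values must be strictly positive linear
#' intensities; missing or non-numeric cells are rejected with the offending
#' gene and sample named.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_matrix <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", quote = "")
  if (ncol(df) < 2L || nrow(df) < 1L)
    stop("expression TSV must have a gene-id column plus >=1 sample column")
  genes <- df[[1L]]
  if (anyDuplicated(genes))
    stop("duplicate gene id(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  samples <- colnames(df)[-1L]
  vals <- matrix(NA_real_, nrow(df), length(samples),
                 dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    col <- df[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) | !nzchar(trimws(col)))
    if (length(bad))
      stop("missing or non-numeric value at gene '", genes[bad[1L]],
           "', sample '", samples[j], "'")
    vals[, j] <- num
  }
  validate_expression_matrix(vals)
  vals
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_matrix()]: gene ids in the first column,
#' sample ids in the header.
#'
#' @param x Validated expression matrix.
#' @param path Output path.
#' @param digits Significant digits written (default keeps full precision).
#' @export
write_expression_matrix <- function(x, path, digits = NA) {
  validate_expression_matrix(x)
  df <- data.frame(gene = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.na(digits)) df[-1L] <- lapply(df[-1L], signif, digits = digits)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors of member gene ids.
#' @param classes Optional character vector of class labels, one per set
#'   (recycled from the GMT description field when reading).
#' @return Named list of class `gene_set_collection` with a `classes`
#'   attribute.
#' @export
gene_set_collection <- function(sets, classes = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be a named list of gene-id vectors")
  if (anyDuplicated(names(sets)))
    stop("duplicate gene-set name(s): ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  empty <- names(sets)[vapply(sets, length, 1L) == 0L]
  if (length(empty))
    stop("empty gene set(s): ", paste(empty, collapse = ", "))
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (is.null(classes)) classes <- rep(NA_character_, length(sets))
  names(classes) <- names(sets)
  structure(sets, classes = classes, class = "gene_set_collection")
}

#' Read gene sets from a GMT file or a one-column gene list
#'
#' GMT lines are `name <TAB> description <TAB> member ...`; the description
#' field is kept as the set's class label (e.g. a KEGG functional class or a
#' granule-compartment code). In `list` mode the file holds one gene symbol
#' per line and yields a single set.
#'
#' @param path Path to the file.
#' @param mode `"gmt"` (default) or `"list"`.
#' @param name Set name used in `list` mode (default: file base name).
#' @return A [gene_set_collection()].
#' @export
read_gene_sets <- function(path, mode = c("gmt", "list"), name = NULL) {
  mode <- match.arg(mode)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no gene sets in ", path)
  if (mode == "list") {
    if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
    genes <- unique(trimws(lines))
    return(gene_set_collection(stats::setNames(list(genes), name)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3L)
  if (length(short))
    stop("GMT line ", short[1L], " has no members (set '",
         fields[[short[1L]]][1L], "')")
  nms <- vapply(fields, `[[`, "", 1L)
  classes <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nms
  gene_set_collection(sets, classes)
}

#' Write a gene-set collection to GMT
#'
#' @param sets A [gene_set_collection()].
#' @param path Output path.
#' @export
write_gene_sets <- function(sets, path) {
  stopifnot(inherits(sets, "gene_set_collection"))
  classes <- attr(sets, "classes")
  classes[is.na(classes)] <- "na"
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, classes[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Construct and validate a sample table
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param group Character/factor of group labels; levels restricted to
#'   [granulosig_groups].
#' @return data.frame with columns `sample_id` and `group` (factor).
#' @export
sample_table <- function(sample_id, group) {
  sample_id <- as.character(sample_id)
  group <- as.character(group)
  if (!length(sample_id)) stop("sample table is empty")
  if (anyDuplicated(sample_id))
    stop("duplicate sample id(s): ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  bad <- setdiff(unique(group), granulosig_groups)
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(granulosig_groups, collapse = ", "))
  data.frame(sample_id = sample_id,
             group = factor(group, levels = granulosig_groups),
             stringsAsFactors = FALSE)
}

#' Read a sample table from CSV or TSV
#'
#' Requires columns `sample_id` and `group`; group labels must be one of
#' [granulosig_groups].
#'
#' @param path Path to the file; the delimiter is inferred from the header.
#' @return A validated [sample_table()].
#' @export
read_sample_table <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (!length(first) || !nzchar(first)) stop("sample table file is empty")
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   colClasses = "character", quote = "")
  need <- c("sample_id", "group")
  if (!all(need %in% colnames(df)))
    stop("sample table must have columns: ", paste(need, collapse = ", "))
  if (!nrow(df)) stop("sample table has no rows")
  sample_table(df$sample_id, df$group)
}

#' Write a sample table to CSV
#' @param samples A [sample_table()].
#' @param path Output path.
#' @export
write_sample_table <- function(samples, path) {
  write.table(samples, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cell-count table (cells/uL per maturation stage)
#'
#' Requires columns `sample_id`, `group`, and the five stage columns
#' LPM, MY, MM, BC, PMN. Counts must be non-negative numbers.
#'
#' @param path Path to a CSV/TSV file.
#' @return data.frame with factor `group` and numeric stage columns.
#' @export
read_cell_counts <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   quote = "")
  need <- c("sample_id", "group", granulosig_stages)
  if (!all(need %in% colnames(df)))
    stop("cell-count table must have columns: ", paste(need, collapse = ", "))
  st <- sample_table(df$sample_id, df$group)
  counts <- df[granulosig_stages]
  for (nm in granulosig_stages) {
    v <- counts[[nm]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0))
      stop("counts for stage ", nm, " must be finite and >= 0")
  }
  cbind(st, counts)
}

#' Write a cell-count table to CSV
#' @param counts Cell-count data.frame as returned by [read_cell_counts()].
#' @param path Output path.
#' @export
write_cell_counts <- function(counts, path) {
  write.table(counts, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a bead-array (QGP-style) plate
#'
#' Raw fluorescence signals in technical duplicate per gene and sample, a
#' single per-plate background value, and the id of the reference gene used
#' for normalization.
#'
#' @param signals data.frame with columns `gene`, `sample`, `rep1`, `rep2`
#'   (signals >= 0).
#' @param background Positive scalar plate background.
#' @param reference_gene Gene id present for every sample on the plate.
#' @return A list of class `qgp_plate`.
#' @export
qgp_plate <- function(signals, background, reference_gene) {
  need <- c("gene", "sample", "rep1", "rep2")
  if (!is.data.frame(signals) || !all(need %in% colnames(signals)))
    stop("signals must be a data.frame with columns: ",
         paste(need, collapse = ", "))
  if (!is.numeric(background) || length(background) != 1L || background <= 0)
    stop("background must be a positive scalar")
  for (nm in c("rep1", "rep2")) {
    v <- signals[[nm]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0))
      stop("signals in ", nm, " must be finite and >= 0")
  }
  signals$gene <- as.character(signals$gene)
  signals$sample <- as.character(signals$sample)
  if (anyDuplicated(signals[c("gene", "sample")]))
    stop("duplicate (gene, sample) rows on plate")
  all_samples <- unique(signals$sample)
  ref_samples <- signals$sample[signals$gene == reference_gene]
  missing_ref <- setdiff(all_samples, ref_samples)
  if (length(missing_ref))
    stop("reference gene '", reference_gene, "' missing for sample(s): ",
         paste(missing_ref, collapse = ", "))
  structure(list(signals = signals[need], background = background,
                 reference_gene = reference_gene),
            class = "qgp_plate")
}

#' Read a bead-array plate from TSV
#'
#' The file carries `#key=value` header lines for `background` and
#' `reference_gene`, followed by a tab-separated table with columns
#' `gene`, `sample`, `rep1`, `rep2`.
#'
#' @param path Path to the plate file.
#' @return A [qgp_plate()].
#' @export
read_qgp_plate <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- strsplit(sub("^#", "", hdr), "=", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, `[[`, "", 2L), vapply(kv, `[[`, "", 1L))
  if (!all(c("background", "reference_gene") %in% names(meta)))
    stop("plate header must define #background= and #reference_gene=")
  body <- lines[!grepl("^#", lines)]
  df <- read.delim(text = paste(body, collapse = "\n"), sep = "\t",
                   header = TRUE, check.names = FALSE, quote = "")
  qgp_plate(df, as.numeric(meta[["background"]]), meta[["reference_gene"]])
}

#' Write a bead-array plate to TSV
#' @param plate A [qgp_plate()].
#' @param path Output path.
#' @export
write_qgp_plate <- function(plate, path) {
  stopifnot(inherits(plate, "qgp_plate"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#background=", format(plate$background, digits = 15)),
               paste0("#reference_gene=", plate$reference_gene)), con)
  write.table(plate$signals, con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
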
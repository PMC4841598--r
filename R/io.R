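# Readers and writers for the on-disk TSV/GMT/JSON formats.  All tables are
# plain tab-separated text with a header row; gene ids live in the first
# column.  Readers enforce the container invariants at load time and report
# offending rows by line number (header = line 1).

#' Read a count matrix from TSV files
#'
#' @param counts_path TSV: header of sample names, first column `gene_id`,
#'   integer counts.
#' @param lengths_path TSV with columns `gene_id`, `length`.
#' @param lib_sizes_path optional TSV with columns `sample`, `library_size`.
#'   When omitted and `derive_lib_sizes = TRUE`, library sizes are the
#'   column sums (logged via `message()`).
#' @param derive_lib_sizes allow deriving library sizes from column sums.
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(counts_path, lengths_path,
                              lib_sizes_path = NULL,
                              derive_lib_sizes = FALSE) {
  tab <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (anyDuplicated(tab[[1]]))
    stop("read_count_matrix: duplicate gene id '",
         tab[[1]][anyDuplicated(tab[[1]])], "' at line ",
         anyDuplicated(tab[[1]]) + 1L, " of ", counts_path, call. = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    badcol <- which(!vapply(tab[-1], is.numeric, logical(1)))[1]
    badrow <- which(is.na(suppressWarnings(as.numeric(tab[[badcol + 1]]))))[1]
    stop("read_count_matrix: non-numeric count at line ", badrow + 1L,
         ", column '", names(tab)[badcol + 1L], "' of ", counts_path,
         call. = FALSE)
  }
  if (any(m < 0))
    stop("read_count_matrix: negative count at line ",
         which(rowSums(m < 0) > 0)[1] + 1L, " of ", counts_path,
         call. = FALSE)
  rownames(m) <- tab[[1]]
  len <- utils::read.delim(lengths_path, stringsAsFactors = FALSE)
  lengths <- stats::setNames(len[[2]], len[[1]])
  if (is.null(lib_sizes_path)) {
    if (!derive_lib_sizes)
      stop("read_count_matrix: no library-size table; pass ",
           "derive_lib_sizes = TRUE to use column sums", call. = FALSE)
    lib <- colSums(m)
    message("read_count_matrix: library sizes derived from column sums: ",
            paste(names(lib), lib, sep = "=", collapse = " "))
  } else {
    ls_tab <- utils::read.delim(lib_sizes_path, stringsAsFactors = FALSE)
    lib <- stats::setNames(ls_tab[[2]], ls_tab[[1]])
  }
  message("read_count_matrix: ", nrow(m), " genes x ", ncol(m), " samples")
  count_matrix(m, lib, lengths)
}

#' Write a count matrix to TSV files
#'
#' @param cm a [count_matrix()].
#' @param dir output directory; files `counts.tsv`, `gene_lengths.tsv`,
#'   `library_sizes.tsv` are created.
#' @return invisibly, the three paths.
#' @export
write_count_matrix <- function(cm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("counts.tsv", "gene_lengths.tsv",
                            "library_sizes.tsv"))
  write_matrix_tsv(cm$counts, paths[1])
  utils::write.table(
    data.frame(gene_id = names(cm$gene_lengths),
               length = unname(cm$gene_lengths)),
    paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = names(cm$library_sizes),
               library_size = unname(cm$library_sizes)),
    paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Write a matrix as TSV with an id column
#' @param m matrix with rownames.
#' @param path output path.
#' @param id_col name of the first column (default `"gene_id"`).
#' @export
write_matrix_tsv <- function(m, path, id_col = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a numeric matrix from TSV (ids in column 1)
#' @param path TSV path.
#' @return numeric matrix with rownames.
#' @export
read_matrix_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (anyDuplicated(tab[[1]]))
    stop("read_matrix_tsv: duplicate id at line ",
         anyDuplicated(tab[[1]]) + 1L, " of ", path, call. = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  m
}

#' Read a samples x traits table
#'
#' @param path TSV: first column `sample`, remaining columns numeric traits
#'   (e.g. malic acid, citric acid, quinic acid, fructose, glucose, sucrose,
#'   ABA).
#' @return numeric matrix, samples in rows.
#' @export
read_traits <- function(path) read_matrix_tsv(path)

#' Read a domain-hit table
#'
#' Accepts either a headered TSV with columns `gene_id`, `model_id`,
#' `e_value`, `score`, or a headerless whitespace-delimited table in that
#' column order with `#` comment lines (an hmmscan-tblout-compatible
#' subset).
#'
#' @param path file path.
#' @return data.frame `gene_id`, `model_id`, `e_value`, `score`.
#' @export
read_domain_hits <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("gene_id", first)) {
    hits <- utils::read.delim(path, stringsAsFactors = FALSE)
  } else {
    hits <- utils::read.table(path, comment.char = "#",
                              stringsAsFactors = FALSE,
                              col.names = c("gene_id", "model_id",
                                            "e_value", "score"))
  }
  if (!is.numeric(hits$e_value) || any(hits$e_value <= 0))
    stop("read_domain_hits: e-values must be positive numbers in ", path,
         call. = FALSE)
  hits
}

#' Read a TF family rule table
#'
#' @param path TSV with columns `family`, `required_models`,
#'   `forbidden_models` (comma-separated model ids; forbidden may be empty).
#' @return data.frame usable by [assign_tf_families()].
#' @export
read_family_rules <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    na.strings = NULL, colClasses = "character")
}

#' Shipped illustrative family rule table
#'
#' A small required/forbidden DNA-binding-domain scheme covering the
#' families most prominent in ripening fruit transcriptomes (ERF, Dof,
#' C2H2, bHLH, MYB, NAC, WRKY, GATA, LBD, bZIP, GRAS, HSF, SBP, ARF).
#' Replace with a full database-derived table for production use.
#'
#' @return data.frame of family rules.
#' @export
default_family_rules <- function() {
  read_family_rules(system.file("extdata", "tf_family_rules.tsv",
                                package = "ripenet", mustWork = TRUE))
}

#' Read gene sets from a GMT file
#'
#' @param path GMT: one tab-separated line per term — term id, description,
#'   then member gene ids.
#' @return named list term -> character vector of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t")
  bad <- which(lengths(parts) < 3)
  if (length(bad))
    stop("read_gmt: line ", bad[1], " has fewer than 3 fields", call. = FALSE)
  stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])),
                  vapply(parts, `[[`, character(1), 1))
}

#' Read a two-column gene-to-term table
#'
#' @param path TSV with columns `gene_id`, `term`.
#' @return data.frame usable by [hypergeometric_enrichment()].
#' @export
read_term_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "term") %in% names(tab)))
  tab
}
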
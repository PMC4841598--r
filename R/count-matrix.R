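#' Construct a count matrix object
#'
#' Bundles a genes x samples matrix of unambiguous clean-read counts with the
#' per-sample library sizes (total clean reads) and per-gene transcript
#' lengths needed for RPKM normalization and for the exact Poisson test.
#'
#' @param counts integer matrix, genes in rows, samples in columns; rownames
#'   are gene ids, colnames are sample labels (conventionally
#'   `<genotype><stage>`, e.g. `"MT170"`).
#' @param library_sizes named positive numeric vector of total clean reads,
#'   one per sample, in column order of `counts`.
#' @param gene_lengths named positive numeric vector of transcript lengths in
#'   bp, one per gene, in row order of `counts`.
#' @param sample_info optional data.frame with columns `genotype` and `stage`,
#'   one row per sample. When missing it is parsed from the sample labels.
#' @return An object of class `count_matrix`: a list with elements `counts`,
#'   `library_sizes`, `gene_lengths`, `sample_info`.
#' @examples
#' cm <- count_matrix(
#'   counts = matrix(c(10L, 0L, 5L, 7L), 2, 2,
#'                   dimnames = list(c("g1", "g2"), c("WT170", "MT170"))),
#'   library_sizes = c(WT170 = 1e6, MT170 = 1e6),
#'   gene_lengths = c(g1 = 1000, g2 = 2000))
#' compute_rpkm(cm)
#' @export
count_matrix <- function(counts, library_sizes, gene_lengths,
                         sample_info = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    stop("count_matrix: `counts` must have gene ids as rownames",
         call. = FALSE)
  if (is.null(colnames(counts)))
    stop("count_matrix: `counts` must have sample labels as colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(counts)))
    stop("count_matrix: duplicate gene ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "), call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("count_matrix: counts must be non-negative integers (first bad row: ",
         rownames(counts)[which(rowSums(counts < 0 | counts != round(counts)) > 0)[1]],
         ")", call. = FALSE)
  library_sizes <- .align_named(library_sizes, colnames(counts),
                                "library_sizes", "sample")
  gene_lengths <- .align_named(gene_lengths, rownames(counts),
                               "gene_lengths", "gene")
  if (any(library_sizes <= 0))
    stop("count_matrix: library_sizes must be positive", call. = FALSE)
  if (any(gene_lengths <= 0))
    stop("count_matrix: gene_lengths must be positive (gene ",
         names(gene_lengths)[which(gene_lengths <= 0)[1]], ")", call. = FALSE)
  over <- sweep(counts, 2, library_sizes, ">")
  if (any(over))
    stop("count_matrix: a gene's count exceeds its sample's library size (",
         rownames(counts)[which(rowSums(over) > 0)[1]], ")", call. = FALSE)
  if (is.null(sample_info))
    sample_info <- parse_sample_labels(colnames(counts))
  structure(list(counts = counts, library_sizes = library_sizes,
                 gene_lengths = gene_lengths, sample_info = sample_info),
            class = "count_matrix")
}

# match a possibly-unnamed vector against reference ids, in order
.align_named <- function(x, ids, what, unit) {
  if (is.null(names(x))) {
    if (length(x) == 1L) x <- rep(x, length(ids))
    if (length(x) != length(ids))
      stop("count_matrix: length of ", what, " (", length(x),
           ") does not match number of ", unit, "s (", length(ids), ")",
           call. = FALSE)
    names(x) <- ids
    return(x)
  }
  missing <- setdiff(ids, names(x))
  if (length(missing))
    stop("count_matrix: ", what, " missing for ", unit, " ",
         missing[1], call. = FALSE)
  x[ids]
}

#' Parse `<genotype><stage>` sample labels
#'
#' @param labels character vector such as `c("WT170", "MT190")`.
#' @return data.frame with columns `sample`, `genotype`, `stage`.
#' @export
parse_sample_labels <- function(labels) {
  m <- regmatches(labels, regexec("^([A-Za-z]+)([0-9]+)$", labels))
  geno <- vapply(m, function(x) if (length(x) == 3) x[2] else NA_character_,
                 character(1))
  stage <- vapply(m, function(x) if (length(x) == 3) x[3] else NA_character_,
                  character(1))
  data.frame(sample = labels, genotype = geno, stage = stage,
             stringsAsFactors = FALSE)
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples\n")
  cat("  samples:", paste(colnames(x$counts), collapse = " "), "\n")
  cat("  library sizes:",
      paste(format(x$library_sizes, big.mark = ","), collapse = " "), "\n")
  invisible(x)
}

#' Normalize counts to RPKM
#'
#' Reads per kilobase of transcript per million mapped reads:
#' `rpkm = 1e9 * count / (library_size * gene_length)`.
#'
#' @param cm a [count_matrix()] object.
#' @return numeric matrix of RPKM values, same dimnames as the counts.
#' @export
compute_rpkm <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  if (any(cm$gene_lengths <= 0) || anyNA(cm$gene_lengths))
    stop("compute_rpkm: zero or missing gene length (gene ",
         names(cm$gene_lengths)[which(!(cm$gene_lengths > 0))[1]], ")",
         call. = FALSE)
  1e9 * cm$counts / outer(cm$gene_lengths, cm$library_sizes)
}
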
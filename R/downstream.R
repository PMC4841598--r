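#' Venn partition of 2 or 3 gene sets
#'
#' Exact counts for every disjoint region plus the union; the counts satisfy
#' inclusion-exclusion by construction.
#'
#' @param sets named list of 2 or 3 character vectors of gene ids
#'   (duplicates within a set are collapsed).
#' @return data.frame `region`, `count`.  Regions are named by set
#'   membership (e.g. `"A_only"`, `"A&B"`, `"A&B&C"`, using the list names),
#'   with a final `"union"` row.
#' @export
venn_partition <- function(sets) {
  if (!is.list(sets) || length(sets) < 2 || length(sets) > 3)
    stop("venn_partition: supply a named list of 2 or 3 sets ",
         "(for more sets report a membership table instead)", call. = FALSE)
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    names(sets) <- LETTERS[seq_along(sets)]
  sets <- lapply(sets, unique)
  all_ids <- unique(unlist(sets))
  member <- vapply(sets, function(s) all_ids %in% s,
                   logical(length(all_ids)))
  if (length(all_ids) == 1) member <- matrix(member, nrow = 1)
  pattern <- apply(member, 1, paste, collapse = "")
  k <- length(sets)
  combos <- expand.grid(rep(list(c(TRUE, FALSE)), k))[-(2^k), k:1,
                                                      drop = FALSE]
  region_name <- function(inc) {
    nm <- names(sets)[unlist(inc)]
    if (length(nm) == 1) paste0(nm, "_only") else paste(nm, collapse = "&")
  }
  out <- data.frame(
    region = apply(combos, 1, region_name),
    count = apply(combos, 1, function(inc)
      sum(pattern == paste(as.logical(inc), collapse = ""))),
    stringsAsFactors = FALSE)
  rbind(out, data.frame(region = "union", count = length(all_ids)))
}

#' Eisen-style clustering of fold-change profiles
#'
#' Hierarchical clustering of gene x stage log2-ratio profiles with
#' uncentered correlation similarity and average linkage, cut to exactly
#' `k` clusters.  Cluster labels are Roman numerals (I, II, ...) assigned in
#' dendrogram order, matching how expression-pattern groups are reported.
#'
#' @param profiles genes x stages numeric matrix of log2 ratios, no missing
#'   values (impute fold changes with a floored [log2_ratio()] upstream).
#' @param k number of clusters (1 <= k <= number of genes).
#' @return list of class `fc_clusters`: `labels` (named character vector
#'   gene -> Roman numeral), `k`, `hclust` (the tree), `linkage`
#'   description.
#' @export
cluster_fc_profiles <- function(profiles, k = 6) {
  profiles <- as.matrix(profiles)
  if (anyNA(profiles))
    stop("cluster_fc_profiles: missing values; impute before clustering",
         call. = FALSE)
  if (k < 1 || k > nrow(profiles))
    stop("cluster_fc_profiles: k must be between 1 and the number of genes (",
         nrow(profiles), ")", call. = FALSE)
  norms <- sqrt(rowSums(profiles^2))
  if (any(norms == 0))
    stop("cluster_fc_profiles: all-zero profile for gene ",
         rownames(profiles)[which(norms == 0)[1]],
         " has undefined uncentered correlation", call. = FALSE)
  xn <- profiles / norms
  sim <- xn %*% t(xn)              # uncentered correlation (Eisen)
  d <- stats::as.dist(1 - sim)
  h <- stats::hclust(d, method = "average")
  cl <- stats::cutree(h, k = k)
  # relabel clusters I..k in dendrogram (leaf-order) appearance
  first_seen <- unique(cl[h$order])
  roman <- as.character(utils::as.roman(seq_len(k)))
  labels <- roman[match(cl, first_seen)]
  names(labels) <- rownames(profiles)
  structure(list(labels = labels, k = k, hclust = h,
                 linkage = "average linkage on 1 - uncentered correlation"),
            class = "fc_clusters")
}

#' Hypergeometric term over-representation
#'
#' One-sided upper-tail hypergeometric test per term: with `k` genes of the
#' study set annotated to the term, `K` background genes annotated, set size
#' `n` and background size `N`, `p = P(X >= k)`.  P-values are BH-adjusted
#' across terms and a term is enriched when the corrected p is below
#' `p_cut` (default 0.01).
#'
#' @param set character vector of study gene ids; must be contained in
#'   `background`.
#' @param background character vector of background gene ids.
#' @param term_table data.frame with columns `gene_id` and `term` (one row
#'   per annotation), or a named list of term -> gene ids as produced by
#'   [read_gmt()].
#' @param p_cut corrected-p enrichment cutoff (default 0.01).
#' @return data.frame `term`, `k`, `K`, `n`, `N`, `p`, `p_adj`, `enriched`,
#'   in the input term order.
#' @export
hypergeometric_enrichment <- function(set, background, term_table,
                                      p_cut = 0.01) {
  set <- unique(set); background <- unique(background)
  if (!all(set %in% background))
    stop("hypergeometric_enrichment: study set is not contained in the ",
         "background (e.g. ", setdiff(set, background)[1], ")",
         call. = FALSE)
  if (is.list(term_table) && !is.data.frame(term_table)) {
    terms <- names(term_table)
    genes_of <- term_table
  } else {
    stopifnot(all(c("gene_id", "term") %in% names(term_table)))
    terms <- unique(term_table$term)
    genes_of <- split(term_table$gene_id, term_table$term)[terms]
  }
  N <- length(background); n <- length(set)
  rows <- lapply(seq_along(terms), function(i) {
    tg <- intersect(unique(genes_of[[i]]), background)
    K <- length(tg)
    k <- length(intersect(tg, set))
    p <- if (k == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = terms[i], k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_fdr(out$p)
  out$enriched <- out$p_adj < p_cut
  out
}
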
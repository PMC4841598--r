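#' Exact Poisson p-value for a two-library count comparison
#'
#' Tests whether a gene is equally expressed in two sequencing libraries
#' without replicates.  With `x` reads in library 1 (total `N1` clean reads)
#' and `y` reads in library 2 (total `N2`), the latent Poisson rate is
#' marginalized, giving
#' \deqn{P(y|x) = (N2/N1)^y \frac{(x+y)!}{x!\,y!\,(1+N2/N1)^{x+y+1}}.}
#' The two-sided p-value doubles the lower cumulative
#' \eqn{C = \sum_{i=0}^{y} P(i|x)}: `p = 2C` when `C <= 0.5`, otherwise
#' `p = 2(1 - C)`, capped at 1.  Note the doubled tail includes the observed
#' point mass, so the rule is asymmetric around the point probability; this
#' literal construction is kept deliberately.
#'
#' All terms are evaluated in log space via `lgamma` and accumulated by
#' log-sum-exp, so counts up to 1e6 and beyond neither overflow nor
#' underflow.  The upper tail `1 - C` is itself summed directly (never as
#' one-minus) to avoid cancellation when `C` is close to 1.
#'
#' @param x,y non-negative integer read counts (vectorized, recycled).
#' @param N1,N2 positive library sizes (total clean reads).
#' @return numeric vector of p-values in (0, 1].
#' @examples
#' ac_test_pvalue(10, 0, 1e6, 1e6)   # 2 / 2^11 = 0.0009765625
#' ac_test_pvalue(100, 400, 1e6, 1e6)
#' @export
ac_test_pvalue <- function(x, y, N1, N2) {
  if (any(x < 0) || any(y < 0) || any(x != round(x)) || any(y != round(y)))
    stop("ac_test_pvalue: x and y must be non-negative integers",
         call. = FALSE)
  if (any(N1 <= 0) || any(N2 <= 0))
    stop("ac_test_pvalue: library sizes must be positive", call. = FALSE)
  n <- max(length(x), length(y), length(N1), length(N2))
  x <- rep_len(x, n); y <- rep_len(y, n)
  N1 <- rep_len(N1, n); N2 <- rep_len(N2, n)
  vapply(seq_len(n), function(i) .ac_p_one(x[i], y[i], N1[i], N2[i]),
         numeric(1))
}

.ac_p_one <- function(x, y, N1, N2) {
  logr <- log(N2) - log(N1)
  # log(1 + r), stable for both large and small r
  log1pr <- if (logr > 0) logr + log1p(exp(-logr)) else log1p(exp(logr))
  logC <- .ac_lower_logsum(x, y, logr, log1pr)
  if (logC <= log(0.5)) {
    p <- 2 * exp(logC)
  } else {
    p <- 2 * exp(.ac_upper_logsum(x, y, logr, log1pr))
  }
  max(min(p, 1), .Machine$double.xmin)
}

# log of sum_{i=0}^{y} P(i|x)
.ac_lower_logsum <- function(x, y, logr, log1pr) {
  i <- 0:y
  .logsumexp(.ac_logterm(x, i, logr, log1pr))
}

# log of sum_{i=y+1}^{Inf} P(i|x), summed in chunks until the geometric
# bound on the remainder is negligible
.ac_upper_logsum <- function(x, y, logr, log1pr, chunk = 512L) {
  total <- -Inf
  i0 <- y + 1
  logq_lim <- logr - log1pr            # limiting term ratio r/(1+r) < 1
  repeat {
    ii <- i0:(i0 + chunk - 1)
    lt <- .ac_logterm(x, ii, logr, log1pr)
    total <- .logsumexp(c(total, lt))
    iend <- i0 + chunk
    q <- exp(logq_lim) * (x + iend) / iend  # term ratio at chunk end
    if (q < 1) {
      log_rem_bound <- lt[chunk] + log(q) - log1p(-q)
      if (log_rem_bound < total - 40) break   # remainder < 4e-18 * sum
    }
    i0 <- i0 + chunk
  }
  total
}

.ac_logterm <- function(x, i, logr, log1pr) {
  i * logr + lgamma(x + i + 1) - lgamma(x + 1) - lgamma(i + 1) -
    (x + i + 1) * log1pr
}

.logsumexp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate control; output order matches input order.
#'
#' @param p_values numeric vector in \[0, 1\].
#' @return adjusted values, each in `[p, 1]`.
#' @export
bh_fdr <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0) || any(p_values > 1))
    stop("bh_fdr: p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Floored log2 fold change of two RPKM values
#'
#' `log2(max(num, floor) / max(den, floor))`: the floor substitutes only for
#' values below it, so the result is the exact log2 ratio whenever both
#' inputs are at least `floor`.  A small positive floor (default 0.001 RPKM)
#' keeps ratios finite when one side is absent and yields fold changes of
#' magnitude ~10 for on/off genes.
#'
#' @param rpkm_num,rpkm_den non-negative RPKM values (vectorized).  `NA`
#'   entries (a "-" in a report table: expression not detected) count as
#'   zero and thus take the floor.
#' @param floor positive pseudo-expression level in RPKM units.
#' @return numeric vector of log2 ratios.
#' @examples
#' log2_ratio(41.70, 97.95)  # -1.23 at 2 dp
#' log2_ratio(0, 1.31)       # about -10.36
#' @export
log2_ratio <- function(rpkm_num, rpkm_den, floor = 0.001) {
  rpkm_num[is.na(rpkm_num)] <- 0
  rpkm_den[is.na(rpkm_den)] <- 0
  if (any(rpkm_num < 0) || any(rpkm_den < 0))
    stop("log2_ratio: RPKM inputs must be non-negative", call. = FALSE)
  if (floor <= 0) {
    if (any(rpkm_num == 0 & rpkm_den == 0))
      stop("log2_ratio: 0/0 ratio is undefined without a positive floor",
           call. = FALSE)
    return(log2(rpkm_num / rpkm_den))
  }
  log2(pmax(rpkm_num, floor) / pmax(rpkm_den, floor))
}

#' Two-library differential expression test
#'
#' Runs the exact Poisson test gene-by-gene for one pairwise comparison
#' (conventionally mutant vs wild type at a matched ripening stage), computes
#' RPKM-based log2 fold changes with [log2_ratio()], adjusts p-values with
#' [bh_fdr()] per comparison, and flags DEGs with [call_degs()].
#'
#' @param cm a [count_matrix()].
#' @param numerator sample label whose expression forms the ratio numerator
#'   (e.g. `"MT170"`).
#' @param denominator sample label for the denominator (e.g. `"WT170"`).
#' @param fdr_cut,lfc_cut DEG thresholds (defaults FDR <= 0.001 and
#'   |log2 ratio| >= 1).
#' @param floor RPKM floor passed to [log2_ratio()].
#' @return data.frame with columns `gene_id`, `x`, `y`, `N1`, `N2`,
#'   `log2_ratio`, `p_value`, `fdr`, `is_deg`.  `x`/`N1` belong to the
#'   denominator library, `y`/`N2` to the numerator, so `log2_ratio` is
#'   oriented numerator-over-denominator (MT/WT).
#' @export
de_test <- function(cm, numerator, denominator,
                    fdr_cut = 0.001, lfc_cut = 1, floor = 0.001) {
  stopifnot(inherits(cm, "count_matrix"))
  for (s in c(numerator, denominator))
    if (!s %in% colnames(cm$counts))
      stop("de_test: sample not found: ", s, call. = FALSE)
  rpkm <- compute_rpkm(cm)
  x <- cm$counts[, denominator]
  y <- cm$counts[, numerator]
  N1 <- cm$library_sizes[[denominator]]
  N2 <- cm$library_sizes[[numerator]]
  res <- data.frame(
    gene_id = rownames(cm$counts),
    x = as.integer(x), y = as.integer(y),
    N1 = N1, N2 = N2,
    log2_ratio = log2_ratio(rpkm[, numerator], rpkm[, denominator],
                            floor = floor),
    p_value = ac_test_pvalue(x, y, N1, N2),
    stringsAsFactors = FALSE, row.names = NULL)
  res$fdr <- bh_fdr(res$p_value)
  call_degs(res, fdr_cut = fdr_cut, lfc_cut = lfc_cut)
}

#' Flag differentially expressed genes
#'
#' A gene is a DEG iff `fdr <= fdr_cut` and `|log2_ratio| >= lfc_cut`.
#'
#' @param results data.frame carrying `fdr` and `log2_ratio` columns (and
#'   `gene_id`).
#' @param fdr_cut,lfc_cut thresholds; defaults FDR <= 0.001, |log2| >= 1.
#' @return `results` with a logical `is_deg` column set consistently.  The
#'   DEG ids are attached as `attr(, "deg_ids")`.
#' @export
call_degs <- function(results, fdr_cut = 0.001, lfc_cut = 1) {
  stopifnot(all(c("fdr", "log2_ratio") %in% names(results)))
  results$is_deg <- results$fdr <= fdr_cut &
    abs(results$log2_ratio) >= lfc_cut
  attr(results, "deg_ids") <- results$gene_id[results$is_deg]
  results
}
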
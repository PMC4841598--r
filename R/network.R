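#' Network construction parameters
#'
#' Container for the unsigned weighted-network settings: soft power, minimum
#' module size 30, merge cut height 0.25, single-block limit 19000 genes and
#' the 0.3 RPKM expression floor.
#'
#' @param soft_power soft-thresholding exponent beta (default 6, the
#'   conventional unsigned default).
#' @param min_module_size smallest gene count a module may have (default 30).
#' @param merge_cut_height eigengene dissimilarity (1 - cor) below which two
#'   modules are merged (default 0.25).
#' @param max_block_size single-block gene limit (default 19000).
#' @param rpkm_floor expression filter threshold (default 0.3 RPKM).
#' @return a list of class `network_config`.
#' @export
network_config <- function(soft_power = 6, min_module_size = 30,
                           merge_cut_height = 0.25, max_block_size = 19000,
                           rpkm_floor = 0.3) {
  stopifnot(soft_power >= 1, min_module_size >= 2,
            merge_cut_height > 0, merge_cut_height < 1, max_block_size >= 2)
  structure(list(soft_power = soft_power,
                 min_module_size = min_module_size,
                 merge_cut_height = merge_cut_height,
                 max_block_size = max_block_size,
                 rpkm_floor = rpkm_floor,
                 network_type = "unsigned"),
            class = "network_config")
}

#' Filter genes by expression level
#'
#' Keeps genes whose maximum RPKM across samples exceeds the floor (default
#' 0.3), so stage-specific genes expressed in only one condition are
#' retained.  Set `stat = "mean"` for a mean-based filter.
#'
#' @param rpkm genes x samples numeric matrix.
#' @param floor RPKM threshold; strictly-greater comparison.
#' @param stat summary across samples: `"max"` (default) or `"mean"`.
#' @return the row-subset matrix; retained count is reported via `message()`.
#' @export
filter_expressed <- function(rpkm, floor = 0.3, stat = c("max", "mean")) {
  stat <- match.arg(stat)
  s <- if (stat == "max") apply(rpkm, 1, max) else rowMeans(rpkm)
  keep <- s > floor
  if (!any(keep))
    stop("filter_expressed: no genes exceed the ", floor,
         " RPKM floor; nothing to network", call. = FALSE)
  message("filter_expressed: retained ", sum(keep), " of ", nrow(rpkm),
          " genes (", stat, " RPKM > ", floor, ")")
  rpkm[keep, , drop = FALSE]
}

#' Unsigned weighted adjacency
#'
#' `a_ij = |pearson(g_i, g_j)|^beta`, with the diagonal set to zero so row
#' sums give the soft connectivity `k_i`.
#'
#' @param expr genes x samples matrix (rows must have nonzero variance).
#' @param beta soft power.
#' @return symmetric genes x genes matrix in \[0, 1\], diagonal 0.
#' @export
adjacency_unsigned <- function(expr, beta = 6) {
  v <- apply(expr, 1, stats::var)
  if (any(v == 0))
    stop("adjacency_unsigned: zero-variance gene: ",
         rownames(expr)[which(v == 0)[1]], call. = FALSE)
  a <- abs(stats::cor(t(expr)))^beta
  diag(a) <- 0
  a
}

#' Soft connectivity
#'
#' @param adjacency unsigned adjacency matrix with zero diagonal.
#' @return per-gene connectivity `k_i = sum_j a_ij`.
#' @export
soft_connectivity <- function(adjacency) rowSums(adjacency)

#' Pick the soft-thresholding power by scale-free fit
#'
#' For each candidate power the connectivity distribution is binned
#' (10 equal-width bins on k) and `log10 p(k)` regressed on `log10 k`; the
#' scale-free fit index is the regression R-squared signed against the slope
#' (positive-slope fits count as 0).  Returns the smallest power whose index
#' reaches `r2_cut`; if none does, the power maximizing the index, with a
#' warning.
#'
#' @param expr genes x samples matrix, at least 4 samples and 3 genes.
#' @param candidate_powers integer powers to scan (default 1:20).
#' @param r2_cut fit threshold (default 0.8).
#' @return list with `power`, and `fit_table` (power, r_squared, slope,
#'   mean_connectivity).
#' @export
pick_soft_threshold <- function(expr, candidate_powers = 1:20, r2_cut = 0.8) {
  if (ncol(expr) < 4)
    stop("pick_soft_threshold: at least 4 samples required", call. = FALSE)
  if (nrow(expr) < 3)
    stop("pick_soft_threshold: fewer than 3 genes", call. = FALSE)
  ac <- abs(stats::cor(t(expr)))
  diag(ac) <- 0
  fit <- lapply(candidate_powers, function(b) {
    k <- rowSums(ac^b)
    c(power = b, .scale_free_fit(k), mean_connectivity = mean(k))
  })
  fit <- as.data.frame(do.call(rbind, fit))
  ok <- which(fit$r_squared >= r2_cut)
  if (length(ok)) {
    power <- fit$power[ok[1]]
  } else {
    power <- fit$power[which.max(fit$r_squared)]
    warning("pick_soft_threshold: no candidate reaches fit R^2 >= ", r2_cut,
            "; returning the best-fitting power ", power, call. = FALSE)
  }
  list(power = power, fit_table = fit)
}

.scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 3)
    return(c(r_squared = 1, slope = -1))  # degenerate: all-equal connectivity
  br <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = br, include.lowest = TRUE)
  pk <- tapply(k, bin, length) / length(k)
  kmean <- tapply(k, bin, mean)
  keep <- !is.na(pk) & pk > 0
  if (sum(keep) < 3) return(c(r_squared = 0, slope = 0))
  fit <- stats::lm(log10(pk[keep]) ~ log10(kmean[keep]))
  r2 <- summary(fit)$r.squared
  slope <- stats::coef(fit)[2]
  c(r_squared = if (slope < 0) r2 else 0, slope = unname(slope))
}

#' Topological overlap matrix
#'
#' Unsigned TOM:
#' `tom_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' diagonal 1.  Genes that share all neighbors at full adjacency have
#' overlap 1; disconnected pairs with no shared neighbors have overlap 0.
#'
#' @param adjacency unsigned adjacency (zero diagonal).
#' @return symmetric matrix in \[0, 1\], diagonal 1.
#' @export
tom_similarity <- function(adjacency) {
  stopifnot(nrow(adjacency) == ncol(adjacency))
  k <- rowSums(adjacency)
  num <- adjacency %*% adjacency + adjacency
  den <- outer(k, k, pmin) + 1 - adjacency
  tom <- num / den
  # numerical guard: theory bounds entries to [0, 1]
  tom[tom > 1] <- 1
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}
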
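# standard module color sequence (largest module first); "grey" reserved
# for unassigned genes
.module_colors <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
  "paleturquoise", "violet", "darkolivegreen", "darkmagenta")

#' Detect coexpression modules from topological overlap
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`,
#' followed by a simplified tree cut: a grid of fixed cut heights over the
#' dendrogram merge range is scanned, each cut keeping only branches of at
#' least `min_module_size` genes; the cut yielding the most qualifying
#' modules (ties: most genes assigned, then the lower height) is retained.
#' Genes in sub-threshold branches become `"grey"`.  Modules whose eigengene
#' dissimilarity (1 - correlation of eigengenes) falls below
#' `merge_cut_height` are then merged iteratively until no pair qualifies.
#' Finally, genes whose module membership (|kME| to their own module
#' eigengene) falls below `min_kme_to_stay` are released to grey and the
#' eigengenes recomputed, so weakly attached genes swept up by the
#' fixed-height cut do not dilute the modules.  This is an approximation of
#' the dynamic hybrid tree cut; it honours the same minimum-size and
#' merge-height parameters.
#'
#' @param expr genes x samples expression matrix (used for eigengene
#'   merging); rownames must match `tom`.
#' @param tom topological overlap matrix from [tom_similarity()].
#' @param config a [network_config()].
#' @param n_heights number of candidate cut heights scanned (default 50).
#' @param min_kme_to_stay membership pruning threshold (default 0.5, the
#'   conventional core-membership level: a retained gene shares at least a
#'   quarter of its variance with the module eigengene).
#' @return list of class `module_partition`: `modules` (named character
#'   vector gene -> color, `"grey"` = unassigned), `eigengenes` (module x
#'   sample matrix), `var_explained`, `sizes`, `config`.
#' @export
detect_modules <- function(expr, tom, config = network_config(),
                           n_heights = 50, min_kme_to_stay = 0.5) {
  stopifnot(inherits(config, "network_config"),
            identical(rownames(expr), rownames(tom)))
  n <- nrow(tom)
  if (n > config$max_block_size)
    stop("detect_modules: ", n, " genes exceed max_block_size ",
         config$max_block_size,
         "; raise the limit in network_config()", call. = FALSE)
  h <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  heights <- unique(stats::quantile(h$height,
                                    probs = seq(0.05, 0.99,
                                                length.out = n_heights)))
  best <- NULL
  for (ht in heights) {
    cl <- stats::cutree(h, h = ht)
    sizes <- table(cl)
    good <- as.integer(names(sizes)[sizes >= config$min_module_size])
    score <- c(n_modules = length(good),
               n_assigned = sum(cl %in% good))
    if (is.null(best) ||
        score["n_modules"] > best$score["n_modules"] ||
        (score["n_modules"] == best$score["n_modules"] &&
         score["n_assigned"] > best$score["n_assigned"])) {
      best <- list(cl = cl, good = good, score = score, height = ht)
    }
  }
  labels <- rep("grey", n)
  names(labels) <- rownames(tom)
  if (length(best$good)) {
    for (g in best$good) labels[best$cl == g] <- paste0("raw", g)
    labels <- .merge_modules(expr, labels, config$merge_cut_height)
    labels <- .prune_by_kme(expr, labels, min_kme_to_stay,
                            config$min_module_size)
  }
  .finalize_partition(expr, labels, config)
}

# release weakly attached genes (|kME| to own module < threshold) to grey;
# modules shrinking below the minimum size dissolve entirely
.prune_by_kme <- function(expr, labels, min_kme_to_stay, min_module_size) {
  mods <- setdiff(unique(labels), "grey")
  for (m in mods) {
    members <- names(labels)[labels == m]
    e <- module_eigengene(expr, members)$eigengene
    kme <- stats::cor(t(expr[members, , drop = FALSE]), e)[, 1]
    drop <- members[abs(kme) < min_kme_to_stay]
    labels[drop] <- "grey"
    if (sum(labels == m) < min_module_size)
      labels[labels == m] <- "grey"
  }
  labels
}

# iterative eigengene-based merging: closest pair below the cut merges first
.merge_modules <- function(expr, labels, merge_cut_height) {
  repeat {
    mods <- setdiff(unique(labels), "grey")
    if (length(mods) < 2) return(labels)
    me <- t(vapply(mods, function(m) {
      module_eigengene(expr, names(labels)[labels == m])$eigengene
    }, numeric(ncol(expr))))
    diss <- 1 - stats::cor(t(me))
    diag(diss) <- Inf
    if (min(diss) >= merge_cut_height) return(labels)
    ij <- which(diss == min(diss), arr.ind = TRUE)[1, ]
    labels[labels == mods[ij[2]]] <- mods[ij[1]]
  }
}

# relabel by decreasing size with standard colors; compute eigengenes
.finalize_partition <- function(expr, labels, config) {
  mods <- setdiff(unique(labels), "grey")
  sizes <- vapply(mods, function(m) sum(labels == m), integer(1))
  mods <- mods[order(-sizes, mods)]
  colors <- .module_colors[seq_along(mods)]
  out <- labels
  for (i in seq_along(mods)) out[labels == mods[i]] <- colors[i]
  eg <- NULL; ve <- NULL
  if (length(mods)) {
    eg <- t(vapply(colors, function(cl) {
      module_eigengene(expr, names(out)[out == cl])$eigengene
    }, numeric(ncol(expr))))
    colnames(eg) <- colnames(expr)
    ve <- vapply(colors, function(cl) {
      module_eigengene(expr, names(out)[out == cl])$var_explained
    }, numeric(1))
  }
  structure(list(modules = out, eigengenes = eg, var_explained = ve,
                 sizes = table(out), config = config),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  mods <- setdiff(unique(x$modules), "grey")
  cat("module_partition:", length(mods), "modules over",
      length(x$modules), "genes (", sum(x$modules == "grey"), "grey )\n")
  print(sort(x$sizes, decreasing = TRUE))
  invisible(x)
}

#' Module eigengene
#'
#' First principal component of the module's genes x samples matrix after
#' per-gene standardization, rescaled to unit variance across samples and
#' sign-aligned so that its mean correlation with member expression is
#' non-negative.
#'
#' @param expr genes x samples matrix.
#' @param member_ids gene ids of the module (at least 2; at least 3 samples).
#' @return list with `eigengene` (named numeric, one value per sample) and
#'   `var_explained` (share of variance carried by the first component).
#' @export
module_eigengene <- function(expr, member_ids) {
  if (length(member_ids) < 2)
    stop("module_eigengene: a module needs at least 2 members", call. = FALSE)
  if (ncol(expr) < 3)
    stop("module_eigengene: at least 3 samples required", call. = FALSE)
  x <- expr[member_ids, , drop = FALSE]
  xs <- t(scale(t(x)))
  if (anyNA(xs))
    stop("module_eigengene: zero-variance member gene", call. = FALSE)
  sv <- svd(xs, nu = 0, nv = 1)
  e <- sv$v[, 1]
  if (mean(stats::cor(t(xs), e)) < 0) e <- -e
  e <- e / stats::sd(e)
  names(e) <- colnames(expr)
  list(eigengene = e, var_explained = sv$d[1]^2 / sum(sv$d^2))
}

# two-sided p-value of a Pearson correlation via the t distribution, n-2 df
cor_pvalue <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  t <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(t, df = n - 2, lower.tail = FALSE)
}

#' Module membership (kME) and gene significance (GS)
#'
#' kME is the Pearson correlation of each gene with each module eigengene;
#' GS is the correlation of each gene with each physiological trait.
#' P-values come from the t statistic with n - 2 degrees of freedom.
#'
#' @param expr genes x samples matrix.
#' @param eigengenes module x sample matrix (e.g. from [detect_modules()]).
#' @param traits optional samples x traits numeric matrix/data.frame with
#'   rownames matching the sample order of `expr`.
#' @return list with matrices `kme`, `kme_p` (genes x modules) and, when
#'   traits are given, `gs`, `gs_p` (genes x traits).
#' @export
compute_kme_gs <- function(expr, eigengenes, traits = NULL) {
  n <- ncol(expr)
  if (n < 3)
    stop("compute_kme_gs: at least 3 samples required", call. = FALSE)
  if (!identical(colnames(expr), colnames(eigengenes)))
    stop("compute_kme_gs: sample axes of expr and eigengenes are misaligned",
         call. = FALSE)
  kme <- stats::cor(t(expr), t(eigengenes))
  out <- list(kme = kme, kme_p = cor_pvalue(kme, n))
  if (!is.null(traits)) {
    traits <- as.matrix(traits)
    if (nrow(traits) != n)
      stop("compute_kme_gs: trait table rows must match samples",
           call. = FALSE)
    gs <- stats::cor(t(expr), traits)
    out$gs <- gs
    out$gs_p <- cor_pvalue(gs, n)
  }
  out
}

#' Module-trait (or module-TF) correlation
#'
#' Pearson correlation of each module eigengene with each trait column, with
#' t-based p-values; a pair is significant when `|r| > 0.8` and `p < 0.05`.
#' TF expression vectors can be passed in place of traits.
#'
#' @param eigengenes module x sample matrix.
#' @param traits samples x traits numeric matrix/data.frame; rows must match
#'   the eigengene sample axis (at least 3 shared samples).
#' @param r_cut,p_cut significance cutoffs (defaults 0.8 and 0.05).
#' @return data.frame `module`, `trait`, `r`, `p`, `significant`.
#' @export
module_trait_correlation <- function(eigengenes, traits,
                                     r_cut = 0.8, p_cut = 0.05) {
  traits <- as.matrix(traits)
  n <- ncol(eigengenes)
  if (nrow(traits) != n)
    stop("module_trait_correlation: samples misaligned (", n,
         " eigengene samples vs ", nrow(traits), " trait rows)",
         call. = FALSE)
  if (n < 3)
    stop("module_trait_correlation: at least 3 shared samples required",
         call. = FALSE)
  r <- stats::cor(t(eigengenes), traits)
  p <- cor_pvalue(r, n)
  out <- expand.grid(module = rownames(eigengenes),
                     trait = colnames(traits),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$r <- as.vector(r)
  out$p <- as.vector(p)
  out$significant <- abs(out$r) > r_cut & out$p < p_cut
  out
}

#' Screen hub genes by gene significance and module membership
#'
#' Keeps genes with `|GS| >= gs_cut` at `p < p_cut` for a trait and
#' `|kME| >= mm_cut` at `p < p_cut` for their own module.
#'
#' @param kme_gs output of [compute_kme_gs()] (must include GS tables).
#' @param modules named character vector gene -> module color.
#' @param gs_cut,mm_cut,p_cut cutoffs (defaults 0.8, 0.8, 0.05).
#' @return data.frame `gene_id`, `module`, `trait`, `gs`, `gs_p`, `kme`,
#'   `kme_p`, one row per passing gene x trait pair.
#' @export
hub_screen <- function(kme_gs, modules, gs_cut = 0.8, mm_cut = 0.8,
                       p_cut = 0.05) {
  stopifnot(!is.null(kme_gs$gs))
  genes <- rownames(kme_gs$kme)
  stopifnot(identical(genes, rownames(kme_gs$gs)))
  own <- modules[genes]
  keep_mod <- own %in% colnames(kme_gs$kme)
  rows <- lapply(which(keep_mod), function(i) {
    mm <- kme_gs$kme[i, own[i]]
    mm_p <- kme_gs$kme_p[i, own[i]]
    if (abs(mm) < mm_cut || mm_p >= p_cut) return(NULL)
    pass <- abs(kme_gs$gs[i, ]) >= gs_cut & kme_gs$gs_p[i, ] < p_cut
    if (!any(pass)) return(NULL)
    data.frame(gene_id = genes[i], module = unname(own[i]),
               trait = colnames(kme_gs$gs)[pass],
               gs = kme_gs$gs[i, pass], gs_p = kme_gs$gs_p[i, pass],
               kme = mm, kme_p = mm_p,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(0), module = character(0),
                      trait = character(0), gs = numeric(0),
                      gs_p = numeric(0), kme = numeric(0), kme_p = numeric(0))
  out
}

#' Permutation validation of a module's topological overlap
#'
#' A biologically meaningful module should show higher average topological
#' overlap among its members than random gene sets of the same size.  The
#' observed statistic is the mean off-diagonal TOM among members; the null
#' distribution resamples `B` same-size gene sets uniformly without
#' replacement.  The empirical p-value is
#' `(1 + #\{null >= observed\}) / (B + 1)`.
#'
#' @param tom topological overlap matrix.
#' @param member_ids module gene ids (at least 2).
#' @param B number of permutations (default 999).
#' @param seed RNG seed for the resampling.
#' @return list of class `permutation_report`: `observed`, `B`, `null`,
#'   `p_value`, `module_size`, `seed`.
#' @export
permute_module_to <- function(tom, member_ids, B = 999, seed = 1) {
  if (B < 1) stop("permute_module_to: B must be >= 1", call. = FALSE)
  if (length(member_ids) < 2)
    stop("permute_module_to: module must have at least 2 members",
         call. = FALSE)
  idx <- match(member_ids, rownames(tom))
  if (anyNA(idx))
    stop("permute_module_to: member ids absent from TOM", call. = FALSE)
  mean_to <- function(i) {
    m <- tom[i, i, drop = FALSE]
    sum(m[upper.tri(m)]) / (length(i) * (length(i) - 1) / 2)
  }
  observed <- mean_to(idx)
  null <- with_seed(seed, vapply(seq_len(B), function(b) {
    mean_to(sample(nrow(tom), length(idx)))
  }, numeric(1)))
  structure(list(observed = observed, B = B, null = null,
                 p_value = (1 + sum(null >= observed)) / (B + 1),
                 module_size = length(member_ids), seed = seed),
            class = "permutation_report")
}

#' @export
print.permutation_report <- function(x, ...) {
  cat("permutation_report: module of", x$module_size, "genes\n",
      " observed mean TO", format(x$observed, digits = 4),
      "| null mean", format(mean(x$null), digits = 4),
      "| B =", x$B, "| empirical p =", format(x$p_value, digits = 4), "\n")
  invisible(x)
}
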
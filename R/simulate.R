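#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so seeded generators never disturb the
#' caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Simulate Poisson RNA-seq counts with planted differential expression
#'
#' Emulates the two-genotype x three-stage replicate-free design: each gene
#' g in sample s draws `x_gs ~ Poisson(lambda_g * m_gs * N_s / 1e6)` where
#' `lambda_g` is the base expression rate (expected reads per million),
#' `N_s` the library size and `m_gs = 2^(+/- effect_log2)` for planted DE
#' genes in mutant samples (multiplier 1 elsewhere).  An optional
#' negative-binomial mode adds overdispersion the Poisson test does not
#' model, for honest calibration studies.
#'
#' @param n_genes number of genes (default 2000, ~1/10 of the study scale).
#' @param design data.frame with columns `genotype` (`"WT"`/`"MT"`) and
#'   `stage`; default the 2 x 3 plan at 170/190/210 DAF.
#' @param lib_sizes per-sample library sizes (scalar recycled; default 1e6).
#' @param base_rate base expression rates: a function of `n`, a single
#'   number, or a vector of length `n_genes`.  Default: log-normal rates
#'   (meanlog log(20), sdlog 1.3).
#' @param de_fraction fraction of genes with a planted effect in MT.
#' @param effect_log2 magnitude of the planted log2 effect; the sign is
#'   random per gene.
#' @param length_range gene length range in bp (uniform integer draw).
#' @param dispersion NULL for Poisson sampling (the test's own model), or a
#'   positive NB dispersion (counts ~ NB with `size = 1/dispersion`).
#' @param seed RNG seed.
#' @return list with `counts` (a [count_matrix()]) and `truth` (class
#'   `synthetic_truth`): `seed`, `de` (data.frame `gene_id`, `effect_log2`
#'   signed), `base_rate`, `gene_lengths`, `dispersion`.
#' @export
generate_counts <- function(n_genes = 2000,
                            design = default_design(),
                            lib_sizes = 1e6,
                            base_rate = NULL,
                            de_fraction = 0.1,
                            effect_log2 = 2,
                            length_range = c(300, 5000),
                            dispersion = NULL,
                            seed = 1) {
  if (de_fraction < 0 || de_fraction > 1)
    stop("generate_counts: de_fraction must lie in [0, 1]", call. = FALSE)
  if (any(lib_sizes <= 0))
    stop("generate_counts: library sizes must be positive", call. = FALSE)
  samples <- paste0(design$genotype, design$stage)
  n_s <- length(samples)
  lib_sizes <- rep_len(lib_sizes, n_s)
  names(lib_sizes) <- samples
  with_seed(seed, {
    gene_ids <- sprintf("g%04d", seq_len(n_genes))
    lambda <- if (is.function(base_rate)) base_rate(n_genes)
      else if (is.null(base_rate)) stats::rlnorm(n_genes, log(20), 1.3)
      else rep_len(base_rate, n_genes)
    lengths <- sample(length_range[1]:length_range[2], n_genes,
                      replace = TRUE)
    names(lengths) <- gene_ids
    n_de <- round(de_fraction * n_genes)
    de_idx <- if (n_de) sort(sample(n_genes, n_de)) else integer(0)
    sign <- if (n_de) sample(c(-1, 1), n_de, replace = TRUE) else numeric(0)
    mult <- matrix(1, n_genes, n_s, dimnames = list(gene_ids, samples))
    if (n_de)
      mult[de_idx, design$genotype == "MT"] <- 2^(sign * effect_log2)
    mu <- lambda * mult * rep(lib_sizes / 1e6, each = n_genes)
    counts <- if (is.null(dispersion)) stats::rpois(length(mu), mu)
      else stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    counts <- matrix(as.integer(counts), n_genes, n_s,
                     dimnames = list(gene_ids, samples))
    truth <- structure(list(
      seed = seed,
      de = data.frame(gene_id = gene_ids[de_idx],
                      effect_log2 = sign * effect_log2,
                      stringsAsFactors = FALSE),
      base_rate = stats::setNames(lambda, gene_ids),
      gene_lengths = lengths,
      dispersion = dispersion), class = "synthetic_truth")
    list(counts = count_matrix(counts, lib_sizes, lengths,
                               sample_info = cbind(sample = samples, design)),
         truth = truth)
  })
}

#' Default 2-genotype x 3-stage sample plan
#'
#' Wild type and mutant at 170, 190 and 210 days after flowering.
#'
#' @return data.frame with columns `genotype` and `stage`.
#' @export
default_design <- function() {
  data.frame(genotype = rep(c("WT", "MT"), each = 3),
             stage = rep(c(170, 190, 210), 2),
             stringsAsFactors = FALSE)
}

#' Simulate latent-factor coexpression modules and linked traits
#'
#' Each module m has a standardized latent factor `f_m` over samples; a
#' member gene's profile is `loading * f_m + noise_sd * e`, background genes
#' are pure noise.  With the default `noise_sd = sqrt(1 - loading^2)` the
#' profiles have unit variance and the expected within-module correlation is
#' `loading^2` (0.81 at loading 0.9).  Each linked trait is its module's
#' factor plus Gaussian noise.
#'
#' @param n_modules number of planted modules (default 5).
#' @param sizes module sizes (scalar recycled; default 50).
#' @param loading factor loading in (0, 1] (default 0.9).
#' @param noise_sd gene-level noise sd; default `sqrt(1 - loading^2)`.
#' @param n_background number of unstructured noise genes (default 50).
#' @param n_samples number of samples (default 20).
#' @param trait_links integer vector of module indices to receive a linked
#'   trait (default all modules).
#' @param trait_noise_sd noise sd on traits (default 0.3).
#' @param seed RNG seed.
#' @return list with `expr` (genes x samples matrix, log-scale expression
#'   z-scores), `traits` (samples x traits matrix, trait `t<m>` linked to
#'   module m), and `truth` (class `synthetic_truth`): `seed`, `membership`
#'   (named vector gene -> module index, 0 = background), `factors`
#'   (module x sample), `loading`, `trait_links`, `trait_noise_sd`.
#' @export
generate_coexpression <- function(n_modules = 5, sizes = 50, loading = 0.9,
                                  noise_sd = NULL, n_background = 50,
                                  n_samples = 20,
                                  trait_links = seq_len(n_modules),
                                  trait_noise_sd = 0.3, seed = 1) {
  if (loading <= 0 || loading > 1)
    stop("generate_coexpression: loading must lie in (0, 1]", call. = FALSE)
  sizes <- rep_len(sizes, n_modules)
  if (any(sizes < 2))
    stop("generate_coexpression: module sizes must be >= 2", call. = FALSE)
  if (is.null(noise_sd)) noise_sd <- sqrt(1 - loading^2)
  with_seed(seed, {
    samples <- sprintf("S%02d", seq_len(n_samples))
    f <- matrix(stats::rnorm(n_modules * n_samples), n_modules, n_samples)
    f <- t(scale(t(f)))  # standardized latent factors
    dimnames(f) <- list(paste0("M", seq_len(n_modules)), samples)
    membership <- rep(seq_len(n_modules), times = sizes)
    membership <- c(membership, rep(0L, n_background))
    gene_ids <- sprintf("g%04d", seq_along(membership))
    names(membership) <- gene_ids
    expr <- t(vapply(membership, function(m) {
      base <- if (m == 0) stats::rnorm(n_samples)
        else loading * f[m, ] + noise_sd * stats::rnorm(n_samples)
      base
    }, numeric(n_samples)))
    dimnames(expr) <- list(gene_ids, samples)
    traits <- NULL
    if (length(trait_links)) {
      traits <- vapply(trait_links, function(m) {
        f[m, ] + trait_noise_sd * stats::rnorm(n_samples)
      }, numeric(n_samples))
      dimnames(traits) <- list(samples, paste0("t", trait_links))
    }
    truth <- structure(list(seed = seed, membership = membership,
                            factors = f, loading = loading,
                            noise_sd = noise_sd, trait_links = trait_links,
                            trait_noise_sd = trait_noise_sd),
                       class = "synthetic_truth")
    list(expr = expr, traits = traits, truth = truth)
  })
}

#' Simulate domain-hit evidence for planted TF families
#'
#' Every TF gene emits a hit to its family's first required model with an
#' e-value drawn below 1e-10, except that a `miss_rate` fraction of genes
#' emit nothing.  Independently, a `decoy_rate` fraction of genes emit a hit
#' to a random model with e-value above the cutoff (which a 1e-10 filter
#' must discard).
#'
#' @param families named character vector gene -> family name (the truth).
#' @param rules family rule table mapping families to models; default the
#'   shipped rule table.
#' @param miss_rate,decoy_rate rates in \[0, 1).
#' @param seed RNG seed.
#' @return data.frame `gene_id`, `model_id`, `e_value`, `score`, plus
#'   attribute `"missed"` listing genes whose true hit was suppressed.
#' @export
generate_domain_hits <- function(families, rules = default_family_rules(),
                                 miss_rate = 0, decoy_rate = 0, seed = 1) {
  if (miss_rate < 0 || miss_rate >= 1 || decoy_rate < 0 || decoy_rate >= 1)
    stop("generate_domain_hits: rates must lie in [0, 1)", call. = FALSE)
  rl <- .parse_rules(rules)
  bad <- setdiff(unique(families), names(rl))
  if (length(bad))
    stop("generate_domain_hits: no rule for family ", bad[1], call. = FALSE)
  with_seed(seed, {
    n <- length(families)
    missed <- stats::runif(n) < miss_rate
    true_hits <- data.frame(
      gene_id = names(families)[!missed],
      model_id = vapply(families[!missed],
                        function(f) rl[[f]]$required[1], character(1)),
      e_value = 10^stats::runif(sum(!missed), -50, -11),
      score = stats::runif(sum(!missed), 100, 500),
      stringsAsFactors = FALSE, row.names = NULL)
    decoy <- stats::runif(n) < decoy_rate
    all_models <- unique(unlist(lapply(rl, `[[`, "required")))
    decoy_hits <- data.frame(
      gene_id = names(families)[decoy],
      model_id = sample(all_models, sum(decoy), replace = TRUE),
      e_value = 10^stats::runif(sum(decoy), -9, -1),
      score = stats::runif(sum(decoy), 5, 50),
      stringsAsFactors = FALSE, row.names = NULL)
    out <- rbind(true_hits, decoy_hits)
    out <- out[order(out$gene_id, out$e_value), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "missed") <- names(families)[missed]
    out
  })
}
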
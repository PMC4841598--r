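#' Published stage-wise RPKM and fold-change tables for 16 ripening TFs
#'
#' Loads the transcribed report tables shipped with the package: per-gene
#' MT and WT RPKM at 170/190/210 DAF and the corresponding published log2
#' fold changes (MT/WT).  Entries printed as "-" are stored as `NA`.
#'
#' @return list with data.frames `rpkm` and `log2fc`.
#' @export
tf_stage_tables <- function() {
  list(
    rpkm = utils::read.delim(
      system.file("extdata", "tf_stage_rpkm.tsv", package = "ripenet",
                  mustWork = TRUE), stringsAsFactors = FALSE),
    log2fc = utils::read.delim(
      system.file("extdata", "tf_stage_log2fc.tsv", package = "ripenet",
                  mustWork = TRUE), stringsAsFactors = FALSE))
}

#' Assemble a pipeline run configuration
#'
#' All thresholds of the analysis in one serializable list: DE calling
#' (FDR 0.001, |log2| 1, RPKM floor 0.001), network construction (power 6,
#' min module size 30, merge height 0.25, block limit 19000, 0.3 RPKM
#' filter), permutation count, fold-change cluster count and enrichment
#' cutoff.  The list round-trips losslessly through JSON.
#'
#' @param fdr_cut,lfc_cut DEG thresholds.
#' @param rpkm_log2_floor floor for [log2_ratio()].
#' @param network a [network_config()].
#' @param permutation_B permutations per module (default 199 for routine
#'   runs; raise to 999 for publication-grade validation).
#' @param cluster_k fold-change profile cluster count (default 6).
#' @param enrich_cut corrected-p enrichment cutoff (default 0.01).
#' @param seed RNG seed recorded in, and reused from, the manifest.
#' @return list of class `run_config`.
#' @export
run_config <- function(fdr_cut = 0.001, lfc_cut = 1,
                       rpkm_log2_floor = 0.001,
                       network = network_config(),
                       permutation_B = 199, cluster_k = 6,
                       enrich_cut = 0.01, seed = 1) {
  stopifnot(fdr_cut >= 0, fdr_cut <= 1, lfc_cut >= 0,
            rpkm_log2_floor > 0, permutation_B >= 1, cluster_k >= 1,
            enrich_cut > 0, enrich_cut <= 1)
  structure(c(list(fdr_cut = fdr_cut, lfc_cut = lfc_cut,
                   rpkm_log2_floor = rpkm_log2_floor),
              unclass(network),
              list(permutation_B = permutation_B, cluster_k = cluster_k,
                   enrich_cut = enrich_cut, seed = seed)),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stage sequence on a count matrix: RPKM normalization,
#' stage-matched MT-vs-WT differential expression, Venn partition of the
#' stage DEG sets, fold-change profile clustering of the union DEGs,
#' expression filtering, unsigned network and TOM, module detection,
#' permutation validation per module, module--trait correlation, kME/GS and
#' hub screening, and (optionally) TF family assignment and term
#' enrichment.  Every output table is written as TSV under `out_dir`
#' together with a JSON manifest recording parameters, seed and per-stage
#' row counts; rerunning with the same inputs and seed reproduces the
#' tables byte for byte.
#'
#' @param cm a [count_matrix()] whose samples follow the
#'   `<genotype><stage>` convention with genotypes WT and MT.
#' @param traits optional samples x traits matrix (rownames = sample
#'   labels).
#' @param hits,rules optional domain-hit table and family rules for TF
#'   assignment.
#' @param term_table optional gene-to-term annotation for enrichment of the
#'   union DEG set.
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @return invisibly, a list with all in-memory stage results plus
#'   `manifest`.
#' @export
run_pipeline <- function(cm, traits = NULL, hits = NULL, rules = NULL,
                         term_table = NULL, config = run_config(),
                         out_dir = tempfile("ripenet_run_")) {
  stopifnot(inherits(cm, "count_matrix"), inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "ripenet",
                   version = as.character(utils::packageVersion("ripenet")),
                   config = unclass(config), stages = list())
  res <- list()
  stage <- "rpkm"
  tryCatch({
    rpkm <- compute_rpkm(cm)
    write_matrix_tsv(rpkm, file.path(out_dir, "rpkm.tsv"))
    manifest$stages$rpkm <- list(genes = nrow(rpkm), samples = ncol(rpkm))

    stage <- "de"
    si <- cm$sample_info
    stages <- intersect(si$stage[si$genotype == "MT"],
                        si$stage[si$genotype == "WT"])
    de <- list()
    for (st in stages) {
      comp <- paste0("MT", st, "_vs_WT", st)
      de[[comp]] <- de_test(cm, paste0("MT", st), paste0("WT", st),
                            fdr_cut = config$fdr_cut,
                            lfc_cut = config$lfc_cut,
                            floor = config$rpkm_log2_floor)
      utils::write.table(de[[comp]],
                         file.path(out_dir, paste0("de_", comp, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    res$de <- de
    manifest$stages$de <- lapply(de, function(d) list(
      genes = nrow(d), degs = sum(d$is_deg)))

    stage <- "venn"
    deg_sets <- lapply(de, function(d) attr(d, "deg_ids"))
    if (length(deg_sets) %in% 2:3) {
      res$venn <- venn_partition(deg_sets)
      utils::write.table(res$venn, file.path(out_dir, "venn.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$stages$venn <- list(regions = nrow(res$venn))
    }

    stage <- "fc_clusters"
    union_degs <- unique(unlist(deg_sets))
    if (length(union_degs) >= config$cluster_k) {
      prof <- vapply(de, function(d)
        d$log2_ratio[match(union_degs, d$gene_id)],
        numeric(length(union_degs)))
      rownames(prof) <- union_degs
      prof <- prof[rowSums(prof^2) > 0, , drop = FALSE]
      if (nrow(prof) >= config$cluster_k) {
        res$fc_clusters <- cluster_fc_profiles(prof, k = config$cluster_k)
        utils::write.table(
          data.frame(gene_id = names(res$fc_clusters$labels),
                     cluster = unname(res$fc_clusters$labels)),
          file.path(out_dir, "fc_clusters.tsv"),
          sep = "\t", quote = FALSE, row.names = FALSE)
        manifest$stages$fc_clusters <- list(genes = nrow(prof),
                                            k = config$cluster_k)
      }
    }

    stage <- "tf"
    if (!is.null(hits)) {
      if (is.null(rules)) rules <- default_family_rules()
      res$tf <- assign_tf_families(hits, rules)
      res$tf_families <- family_distribution(res$tf)
      utils::write.table(res$tf, file.path(out_dir, "tf_assignments.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(res$tf_families,
                         file.path(out_dir, "tf_family_histogram.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$stages$tf <- list(
        genes = nrow(res$tf),
        assigned = sum(res$tf$family != "unassigned"))
    }

    stage <- "network"
    expr <- filter_expressed(rpkm, floor = config$rpkm_floor)
    expr <- log2(expr + 1)  # variance-stabilized scale for correlations
    expr <- expr[apply(expr, 1, stats::var) > 0, , drop = FALSE]
    adj <- adjacency_unsigned(expr, beta = config$soft_power)
    tom <- tom_similarity(adj)
    part <- detect_modules(expr, tom, config = network_config(
      soft_power = config$soft_power,
      min_module_size = config$min_module_size,
      merge_cut_height = config$merge_cut_height,
      max_block_size = config$max_block_size,
      rpkm_floor = config$rpkm_floor))
    res$modules <- part
    utils::write.table(
      data.frame(gene_id = names(part$modules),
                 module = unname(part$modules)),
      file.path(out_dir, "modules.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$network <- list(
      genes = nrow(expr),
      modules = length(setdiff(unique(part$modules), "grey")),
      grey = sum(part$modules == "grey"))

    stage <- "validate"
    if (!is.null(part$eigengenes)) {
      write_matrix_tsv(part$eigengenes,
                       file.path(out_dir, "eigengenes.tsv"),
                       id_col = "module")
      mods <- rownames(part$eigengenes)
      perm <- lapply(seq_along(mods), function(i) {
        r <- permute_module_to(tom,
                               names(part$modules)[part$modules == mods[i]],
                               B = config$permutation_B,
                               seed = config$seed + i)
        data.frame(module = mods[i], size = r$module_size,
                   observed_mean_to = r$observed,
                   null_mean_to = mean(r$null), B = r$B,
                   p_value = r$p_value, stringsAsFactors = FALSE)
      })
      res$permutation <- do.call(rbind, perm)
      utils::write.table(res$permutation,
                         file.path(out_dir, "module_permutation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$stages$validate <- list(
        modules = nrow(res$permutation), B = config$permutation_B)

      stage <- "traits"
      if (!is.null(traits)) {
        traits <- as.matrix(traits)[colnames(expr), , drop = FALSE]
        res$module_trait <- module_trait_correlation(part$eigengenes, traits)
        utils::write.table(res$module_trait,
                           file.path(out_dir, "module_trait.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        kg <- compute_kme_gs(expr, part$eigengenes, traits)
        res$kme_gs <- kg
        write_matrix_tsv(kg$kme, file.path(out_dir, "kme.tsv"))
        write_matrix_tsv(kg$gs, file.path(out_dir, "gs.tsv"))
        res$hubs <- hub_screen(kg, part$modules)
        utils::write.table(res$hubs, file.path(out_dir, "hub_genes.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        manifest$stages$traits <- list(
          traits = ncol(traits),
          significant_pairs = sum(res$module_trait$significant),
          hub_rows = nrow(res$hubs))
      }
    }

    stage <- "enrich"
    if (!is.null(term_table) && length(union_degs)) {
      res$enrichment <- hypergeometric_enrichment(
        union_degs, rownames(cm$counts), term_table,
        p_cut = config$enrich_cut)
      utils::write.table(res$enrichment,
                         file.path(out_dir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$stages$enrich <- list(
        terms = nrow(res$enrichment),
        enriched = sum(res$enrichment$enriched))
    }
  }, error = function(e) {
    stop("run_pipeline: stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  res$out_dir <- out_dir
  invisible(res)
}
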
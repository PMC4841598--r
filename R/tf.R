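#' Assign genes to transcription-factor families from domain hits
#'
#' Consumes a table of DNA-binding-domain model hits (hmmscan/BLAST-style)
#' and a family rule table.  Hits above the e-value cutoff are discarded.  A
#' family qualifies for a gene when every one of its required models is hit
#' and none of its forbidden models is; among qualifying families the one
#' whose best supporting hit has the smallest e-value wins, with ties broken
#' by larger score, then lexicographic family name.  Hits to models not
#' referenced by any rule are ignored (with a message).
#'
#' @param hits data.frame with columns `gene_id`, `model_id`, `e_value`,
#'   `score`.
#' @param rules data.frame with columns `family`, `required_models`,
#'   `forbidden_models`; model lists are comma-separated.  See
#'   [read_family_rules()] and the rule table shipped under
#'   `system.file("extdata", "tf_family_rules.tsv", package = "ripenet")` —
#'   an illustrative, user-replaceable subset of a required/forbidden
#'   DBD-model family scheme.
#' @param evalue_cutoff maximal e-value for a hit to count (default 1e-10).
#' @return data.frame, one row per gene appearing in `hits`: `gene_id`,
#'   `family` (`"unassigned"` when no family qualifies), `best_model`,
#'   `best_evalue`, `best_score`, `n_hits` (qualifying hits).
#' @export
assign_tf_families <- function(hits, rules, evalue_cutoff = 1e-10) {
  if (is.null(rules) || nrow(rules) == 0)
    stop("assign_tf_families: empty family rule table", call. = FALSE)
  stopifnot(all(c("gene_id", "model_id", "e_value", "score") %in% names(hits)))
  if (nrow(hits) && any(hits$e_value <= 0))
    stop("assign_tf_families: e-values must be positive", call. = FALSE)
  rl <- .parse_rules(rules)
  known <- unique(unlist(c(lapply(rl, `[[`, "required"),
                           lapply(rl, `[[`, "forbidden"))))
  unknown <- setdiff(unique(hits$model_id), known)
  if (length(unknown))
    message("assign_tf_families: ignoring hits to models without rules: ",
            paste(unknown, collapse = ", "))

  genes <- unique(hits$gene_id)
  out <- data.frame(gene_id = genes, family = "unassigned",
                    best_model = NA_character_, best_evalue = NA_real_,
                    best_score = NA_real_, n_hits = 0L,
                    stringsAsFactors = FALSE)
  keep <- hits$e_value <= evalue_cutoff & hits$model_id %in% known
  hq <- hits[keep, , drop = FALSE]
  if (!nrow(hq)) return(out)
  by_gene <- split(hq, hq$gene_id)
  for (g in names(by_gene)) {
    h <- by_gene[[g]]
    cand <- .best_family(h, rl)
    i <- match(g, out$gene_id)
    out$n_hits[i] <- nrow(h)
    if (!is.null(cand)) {
      out$family[i] <- cand$family
      out$best_model[i] <- cand$model
      out$best_evalue[i] <- cand$e_value
      out$best_score[i] <- cand$score
    }
  }
  out
}

.parse_rules <- function(rules) {
  split_models <- function(s) {
    s <- trimws(unlist(strsplit(s %||% "", "[,;]")))
    s[nzchar(s)]
  }
  rl <- lapply(seq_len(nrow(rules)), function(i) {
    req <- split_models(rules$required_models[i])
    forb <- if ("forbidden_models" %in% names(rules))
      split_models(rules$forbidden_models[i]) else character(0)
    if (!length(req))
      stop("assign_tf_families: rule for family ", rules$family[i],
           " has no required models", call. = FALSE)
    if (length(intersect(req, forb)))
      stop("assign_tf_families: family ", rules$family[i],
           " lists a model as both required and forbidden", call. = FALSE)
    list(family = rules$family[i], required = req, forbidden = forb)
  })
  names(rl) <- rules$family
  rl
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a

# evaluate every family rule against one gene's qualifying hits
.best_family <- function(h, rl) {
  best <- NULL
  models_hit <- unique(h$model_id)
  for (r in rl) {
    if (!all(r$required %in% models_hit)) next
    if (any(r$forbidden %in% models_hit)) next
    sup <- h[h$model_id %in% r$required, , drop = FALSE]
    j <- order(sup$e_value, -sup$score)[1]
    cand <- list(family = r$family, model = sup$model_id[j],
                 e_value = sup$e_value[j], score = sup$score[j])
    if (is.null(best) ||
        cand$e_value < best$e_value ||
        (cand$e_value == best$e_value && cand$score > best$score) ||
        (cand$e_value == best$e_value && cand$score == best$score &&
         cand$family < best$family))
      best <- cand
  }
  best
}

#' Family histogram of TF assignments
#'
#' @param assignments output of [assign_tf_families()].
#' @return data.frame `family`, `count`, sorted by descending count (ties
#'   alphabetical); unassigned genes are excluded.  Counts sum to the number
#'   of assigned genes.
#' @export
family_distribution <- function(assignments) {
  a <- assignments[assignments$family != "unassigned", , drop = FALSE]
  if (!nrow(a))
    return(data.frame(family = character(0), count = integer(0)))
  tab <- table(a$family)
  out <- data.frame(family = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$count, out$family), , drop = FALSE]
}
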
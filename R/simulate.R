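#' Synthetic multi-cohort study design
#'
#' Describes the generative model used to exercise the whole pipeline: a
#' shared gene universe across cohorts, one "disease" co-expression module
#' planted in every cohort, one cohort-specific module per cohort, latent
#' factor loadings on log2 scale, group-dependent shifts of the disease
#' module, a bipartite feature map concentrated on the disease module, and
#' exponential survival whose hazard depends on chosen genes' expression.
#'
#' Defaults emulate the multi-cohort structure the pipeline targets: three
#' cohorts of 150, 75 and 60 samples with control/NAFL/NASH groups in
#' proportions 0.2/0.3/0.5, a 60-gene disease module (per-gene loadings
#' drawn once from U(0.4, 0.95) and shared across cohorts so hub identity
#' is conserved; noise s.d. 0.3 on log2 scale) shifted by +1 log2FC in NAFL
#' and +1.5 in NASH on module average (each gene's shift scales with its
#' loading), a 45-gene cohort-specific module per cohort, 400
#' background genes in four weakly correlated blocks (Spearman ~0.45,
#' emulating the broad moderate co-expression of real transcriptomes that
#' the top-decile edge screen competes against, so the screen also prunes
#' the weakest within-module pairs and modules acquire hub structure) and
#' 50 lowly expressed genes that the TPM filter should remove.
#'
#' @param n_cohorts Number of cohorts (2-4).
#' @param samples_per_cohort Integer vector of cohort sizes.
#' @param group_levels Ordered group labels; the first is the reference.
#' @param group_proportions Proportions per group (summing to 1), recycled
#'   across cohorts.
#' @param disease_module_size Genes in the shared disease module.
#' @param specific_module_size Genes in each cohort-specific module.
#' @param loading Maximum latent-factor loading strength in (0, 1] for
#'   planted-module genes.
#' @param loading_min Minimum loading; each planted gene draws its loading
#'   once from `U(loading_min, loading)` and keeps it in every cohort, so
#'   modules have hub genes whose degree ranking is conserved across
#'   cohorts. Set equal to `loading` for homogeneous modules.
#' @param noise_sd Log2-scale noise standard deviation.
#' @param de_effects Named per-group log2 fold-changes applied to
#'   disease-module genes (reference group must be 0).
#' @param n_background_genes Background genes per cohort, split evenly into
#'   `n_background_blocks` weakly correlated blocks.
#' @param n_background_blocks Number of weak background co-expression blocks.
#' @param background_rho Target within-block correlation of background genes
#'   (0 for fully unstructured background).
#' @param n_low_genes Genes planted below the expression filter floor.
#' @param tf_n_features,tf_targets_per_feature,tf_concentrated_fraction
#'   Bipartite map design: number of features, targets per feature, and the
#'   fraction of features whose targets are drawn from the disease module.
#' @param surv_baseline_rate Baseline exponential hazard (per day).
#' @param surv_coefficients Named log-hazard coefficients on standardised
#'   log2(TPM+1); `NULL` defaults to +1 on the first disease-module gene
#'   and -1 on the first background gene.
#' @param surv_censoring_rate Rate of the independent exponential censoring
#'   process.
#' @param seed Integer master seed; each generator derives its own stream.
#' @return A validated list of class `synthetic_design`.
#' @export
synthetic_design <- function(n_cohorts = 3,
                             samples_per_cohort = c(150, 75, 60),
                             group_levels = c("control", "NAFL", "NASH"),
                             group_proportions = c(0.2, 0.3, 0.5),
                             disease_module_size = 60,
                             specific_module_size = 45,
                             loading = 0.95,
                             loading_min = 0.4,
                             noise_sd = 0.3,
                             de_effects = c(control = 0, NAFL = 1, NASH = 1.5),
                             n_background_genes = 400,
                             n_background_blocks = 4,
                             background_rho = 0.45,
                             n_low_genes = 50,
                             tf_n_features = 60,
                             tf_targets_per_feature = 10,
                             tf_concentrated_fraction = 0.25,
                             surv_baseline_rate = 0.002,
                             surv_coefficients = NULL,
                             surv_censoring_rate = 0.0015,
                             seed = 42L) {
  if (n_cohorts < 2 || n_cohorts > 4) stop("n_cohorts must be 2-4", call. = FALSE)
  if (length(samples_per_cohort) != n_cohorts) {
    stop("samples_per_cohort must have one entry per cohort", call. = FALSE)
  }
  if (abs(sum(group_proportions) - 1) > 1e-8) {
    stop("group proportions must sum to 1", call. = FALSE)
  }
  if (length(group_proportions) != length(group_levels)) {
    stop("one proportion per group level required", call. = FALSE)
  }
  if (!setequal(names(de_effects), group_levels) ||
      de_effects[[group_levels[1]]] != 0) {
    stop("de_effects must name every group, with 0 for the reference",
         call. = FALSE)
  }
  if (loading <= 0 || loading > 1) stop("loading must be in (0, 1]", call. = FALSE)
  if (loading_min <= 0 || loading_min > loading) {
    stop("loading_min must be in (0, loading]", call. = FALSE)
  }
  if (noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  if (disease_module_size < 2 || specific_module_size < 2) {
    stop("module sizes must be >= 2", call. = FALSE)
  }
  if (background_rho < 0 || background_rho >= 1) {
    stop("background_rho must be in [0, 1)", call. = FALSE)
  }
  if (n_background_blocks < 1) stop("need >= 1 background block", call. = FALSE)

  pad <- function(prefix, n) sprintf("%s_g%03d", prefix, seq_len(n))
  genes <- list(
    disease = pad("DIS", disease_module_size),
    specific = lapply(seq_len(n_cohorts), function(j) {
      pad(sprintf("C%dSPC", j), specific_module_size)
    }),
    background = pad("BG", n_background_genes),
    low = pad("LOW", n_low_genes)
  )
  all_genes <- c(genes$disease, unlist(genes$specific), genes$background, genes$low)
  stopifnot(!anyDuplicated(all_genes))
  if (is.null(surv_coefficients)) {
    # one unfavourable disease-module gene, one favourable background gene
    # (deliberately uncorrelated so neither effect masks the other)
    surv_coefficients <- setNames(c(1, -1),
                                  c(genes$disease[1], genes$background[1]))
  }
  if (!all(names(surv_coefficients) %in% all_genes)) {
    stop("surv_coefficients name genes outside the design", call. = FALSE)
  }
  if (tf_targets_per_feature > length(all_genes)) {
    stop("targets per feature exceed the gene universe", call. = FALSE)
  }

  structure(list(
    n_cohorts = n_cohorts,
    samples_per_cohort = as.integer(samples_per_cohort),
    group_levels = group_levels,
    group_proportions = group_proportions,
    disease_module_size = disease_module_size,
    specific_module_size = specific_module_size,
    loading = loading,
    loading_min = loading_min,
    noise_sd = noise_sd,
    de_effects = de_effects,
    n_background_genes = n_background_genes,
    n_background_blocks = n_background_blocks,
    background_rho = background_rho,
    n_low_genes = n_low_genes,
    genes = genes,
    tf_n_features = tf_n_features,
    tf_targets_per_feature = tf_targets_per_feature,
    tf_concentrated_fraction = tf_concentrated_fraction,
    surv_baseline_rate = surv_baseline_rate,
    surv_coefficients = surv_coefficients,
    surv_censoring_rate = surv_censoring_rate,
    seed = as.integer(seed)
  ), class = "synthetic_design")
}

#' @export
print.synthetic_design <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_design> %d cohorts (n = %s); disease module ",
                     "%d genes, %d specific genes/cohort, %d background\n"),
              x$n_cohorts, paste(x$samples_per_cohort, collapse = "/"),
              x$disease_module_size, x$specific_module_size,
              x$n_background_genes))
  invisible(x)
}

#' True planted module membership
#'
#' @param design A `synthetic_design`.
#' @return A tibble with columns `cohort_id`, `module_id`, `gene_id` giving
#'   the planted truth per cohort (`disease` plus that cohort's specific
#'   module).
#' @export
planted_truth <- function(design) {
  dplyr::bind_rows(lapply(seq_len(design$n_cohorts), function(j) {
    tibble::tibble(
      cohort_id = sprintf("cohort%d", j),
      module_id = rep(c("disease", "specific"),
                      c(design$disease_module_size, design$specific_module_size)),
      gene_id = c(design$genes$disease, design$genes$specific[[j]])
    )
  }))
}

#' Generate synthetic cohort expression matrices
#'
#' For each cohort and each planted module m a latent standard-normal sample
#' factor f_m drives log2 expression: gene g in module m reads
#' `baseline_g + loading * f_m + group shift (disease module only) + N(0, noise_sd)`;
#' background genes are baseline + noise, and the low-expression block sits
#' below the TPM filter floor. Values are returned on TPM-like scale via
#' `2^x`. Disease-module gene ids are identical in every cohort; the same
#' gene universe is present everywhere, but a cohort-specific module is
#' correlated only in its own cohort.
#'
#' @param design A `synthetic_design`.
#' @return A list: `expr` (named list of [expr_matrix], one per cohort),
#'   `metadata` (tibble `sample_id`, `cohort_id`, `group_label`), `truth`
#'   (tibble from [planted_truth()]).
#' @export
generate_cohorts <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  g <- design$genes
  all_genes <- c(g$disease, unlist(g$specific), g$background, g$low)
  out <- with_seed(derive_seed(design$seed, "cohorts"), {
    baseline <- c(
      runif(length(g$disease), 3, 8),
      runif(length(unlist(g$specific)), 2, 8),
      runif(length(g$background), 0, 8),
      runif(length(g$low), -3, -1)
    )
    names(baseline) <- all_genes
    # per-gene loadings drawn once so hub identity is shared across cohorts
    planted <- c(g$disease, unlist(g$specific))
    gene_loading <- setNames(
      runif(length(planted), design$loading_min, design$loading), planted)
    expr <- list()
    meta <- list()
    for (j in seq_len(design$n_cohorts)) {
      n <- design$samples_per_cohort[j]
      cohort_id <- sprintf("cohort%d", j)
      groups <- rep(design$group_levels,
                    diff(round(cumsum(c(0, design$group_proportions)) * n)))
      groups <- c(groups, rep(design$group_levels[length(design$group_levels)],
                              n - length(groups)))[seq_len(n)]
      sample_ids <- sprintf("%s_s%03d", cohort_id, seq_len(n))
      log2x <- matrix(baseline, nrow = length(all_genes), ncol = n,
                      dimnames = list(all_genes, sample_ids))
      # shared disease module; the group shift scales with each gene's
      # loading (hub genes are the most disease-responsive) but averages to
      # the design effect over the module
      f_dis <- rnorm(n)
      shift_scale <- gene_loading[g$disease] /
        mean(c(design$loading_min, design$loading))
      log2x[g$disease, ] <- log2x[g$disease, ] +
        gene_loading[g$disease] %o% f_dis +
        shift_scale %o% unname(design$de_effects[groups])
      # this cohort's specific module
      spc <- g$specific[[j]]
      f_spc <- rnorm(n)
      log2x[spc, ] <- log2x[spc, ] + gene_loading[spc] %o% f_spc
      # weak background co-expression blocks (the moderate genome-wide
      # correlation the top-decile edge screen competes against)
      if (design$background_rho > 0 && length(g$background) > 0) {
        bg_loading <- design$noise_sd *
          sqrt(design$background_rho / (1 - design$background_rho))
        block <- rep(seq_len(design$n_background_blocks),
                     length.out = length(g$background))
        for (b in seq_len(design$n_background_blocks)) {
          members <- g$background[block == b]
          f_b <- rnorm(n)
          log2x[members, ] <- log2x[members, ] +
            bg_loading * rep(f_b, each = length(members))
        }
      }
      log2x <- log2x + matrix(rnorm(length(log2x), 0, design$noise_sd),
                              nrow = nrow(log2x))
      expr[[cohort_id]] <- expr_matrix(2^log2x, "tpm")
      meta[[cohort_id]] <- tibble::tibble(
        sample_id = sample_ids, cohort_id = cohort_id, group_label = groups
      )
    }
    list(expr = expr, metadata = dplyr::bind_rows(meta))
  })
  out$truth <- planted_truth(design)
  out
}

#' Generate a bipartite feature-to-gene map
#'
#' A `tf_concentrated_fraction` of the features draw their target sets from
#' the planted disease module; the remainder draw uniformly from the whole
#' gene universe. Reproducible under the design seed.
#'
#' @param design A `synthetic_design`.
#' @param feature_kind `"transcription_factor"` (default) or `"metabolite"`.
#' @return A `feature_map` tibble with a logical `concentrated` annotation
#'   column.
#' @export
generate_feature_map <- function(design,
                                 feature_kind = c("transcription_factor",
                                                  "metabolite")) {
  feature_kind <- match.arg(feature_kind)
  stopifnot(inherits(design, "synthetic_design"))
  g <- design$genes
  all_genes <- c(g$disease, unlist(g$specific), g$background, g$low)
  k <- design$tf_targets_per_feature
  if (k > length(all_genes)) stop("targets per feature exceed the gene universe", call. = FALSE)
  n_conc <- round(design$tf_concentrated_fraction * design$tf_n_features)
  prefix <- if (feature_kind == "metabolite") "MET" else "TF"
  with_seed(derive_seed(design$seed, paste0("feature_map_", feature_kind)), {
    rows <- lapply(seq_len(design$tf_n_features), function(i) {
      pool <- if (i <= n_conc) g$disease else all_genes
      tibble::tibble(
        feature_id = sprintf("%s_%03d", prefix, i),
        gene = sample(pool, min(k, length(pool))),
        concentrated = i <= n_conc
      )
    })
    feature_map(dplyr::bind_rows(rows), feature_kind)
  })
}

#' Generate survival outcomes tied to expression
#'
#' Each sample's event time is exponential with rate
#' `baseline_rate * exp(sum(beta_g * z_g))`, where `z_g` is the per-gene
#' standardisation of log2(TPM+1) across samples; censoring is an
#' independent exponential clock at `surv_censoring_rate`. All times are
#' strictly positive.
#'
#' @param expr An [expr_matrix] containing every coefficient gene.
#' @param design A `synthetic_design` (uses the `surv_*` fields).
#' @param seed Optional override of the derived survival seed.
#' @return A survival tibble: `sample_id`, `time`, `event`.
#' @export
generate_survival <- function(expr, design, seed = NULL) {
  stopifnot(is_expr_matrix(expr), inherits(design, "synthetic_design"))
  beta <- design$surv_coefficients
  missing <- setdiff(names(beta), rownames(expr))
  if (length(missing) > 0) {
    stop("coefficient gene(s) not in matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  m <- log2(unclass(expr)[names(beta), , drop = FALSE] + 1)
  z <- t(scale(t(m)))
  z[is.na(z)] <- 0                      # constant gene: no hazard contribution
  lp <- drop(crossprod(z, beta))
  rate <- design$surv_baseline_rate * exp(lp)
  if (any(!is.finite(rate)) || any(rate <= 0)) {
    stop("non-finite hazard rate", call. = FALSE)
  }
  with_seed(seed %||% derive_seed(design$seed, "survival"), {
    t_event <- rexp(ncol(expr), rate)
    t_cens <- rexp(ncol(expr), design$surv_censoring_rate)
    tibble::tibble(
      sample_id = colnames(expr),
      time = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens)
    )
  })
}

#' Emit a full synthetic fixture set to disk
#'
#' Writes per-cohort expression TSVs, the sample metadata, a GMT built from
#' the planted modules (plus random decoy sets), TF-target and
#' gene-metabolite maps, and a survival table for the first cohort.
#'
#' @param design A `synthetic_design`.
#' @param out_dir Output directory (created if needed).
#' @return Named list of written file paths, invisibly.
#' @export
simulate_study <- function(design, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_cohorts(design)
  paths <- list()
  for (cid in names(sim$expr)) {
    paths[[paste0("expr_", cid)]] <-
      write_expression_tsv(sim$expr[[cid]], file.path(out_dir, paste0(cid, "_tpm.tsv")))
  }
  meta_path <- file.path(out_dir, "metadata.tsv")
  utils::write.table(sim$metadata, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$metadata <- meta_path

  truth <- sim$truth
  gmt <- with_seed(derive_seed(design$seed, "gmt"), {
    all_genes <- rownames(sim$expr[[1]])
    decoys <- lapply(1:5, function(i) sample(all_genes, 25))
    tibble::tibble(
      set_id = c("disease_module", paste0("decoy_", 1:5)),
      description = c("planted disease module", rep("random decoy set", 5)),
      genes = c(list(design$genes$disease), decoys)
    )
  })
  paths$gmt <- write_gmt(gmt, file.path(out_dir, "gene_sets.gmt"))

  tf <- generate_feature_map(design, "transcription_factor")
  tf_path <- file.path(out_dir, "tf_targets.tsv")
  utils::write.table(
    data.frame(tf$feature_id, tf$gene, ifelse(tf$concentrated, "Activation", "Unknown"),
               "synthetic"),
    tf_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  paths$tf_targets <- tf_path

  met <- generate_feature_map(design, "metabolite")
  met_path <- file.path(out_dir, "gene_metabolites.tsv")
  utils::write.table(
    data.frame(gene = met$gene, metabolite = met$feature_id,
               subsystem = ifelse(met$concentrated, "disease_module", "background")),
    met_path, sep = "\t", quote = FALSE, row.names = FALSE)
  paths$gene_metabolites <- met_path

  surv <- generate_survival(sim$expr[[1]], design)
  paths$survival <- write_survival_table(surv, file.path(out_dir, "survival.tsv"))
  invisible(paths)
}
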
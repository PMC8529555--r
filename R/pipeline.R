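#' Run the full co-expression analysis pipeline
#'
#' Orchestrates simulate -> differential expression -> network -> modules ->
#' conservation -> topology -> enrichment -> reporter -> survival from one
#' structured configuration, writing every stage's output under `out_dir`
#' and returning a run record with per-stage status and file checksums.
#' Identical seed + configuration + inputs give identical outputs.
#'
#' The configuration is a named list (or YAML file read with
#' [yaml::read_yaml()]) with optional entries:
#' \describe{
#'   \item{stages}{Character vector of stages to run; default all of
#'     `simulate`, `de`, `network`, `modules`, `conserve`, `topology`,
#'     `enrich`, `reporter`, `survival`. Later stages that depend on a
#'     skipped stage are skipped too.}
#'   \item{design}{Arguments for [synthetic_design()] (used by `simulate`);
#'     alternatively `expression_paths` + `metadata_path` point at existing
#'     TSVs.}
#'   \item{analysis}{Arguments for [analysis_config()].}
#'   \item{de_contrast}{Two group labels, reference first; default the first
#'     two group levels observed.}
#' }
#'
#' @param config Named list or path to a YAML file.
#' @param out_dir Output directory.
#' @param seed Top-level seed; each stage derives a stable sub-seed.
#' @return A `pipeline_run` record: list with `config`, `seed`, `stages`
#'   (tibble of stage, status, seconds, outputs) and `checksums`.
#' @export
run_pipeline <- function(config = list(), out_dir, seed = 1L) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  all_stages <- c("simulate", "de", "network", "modules", "conserve",
                  "topology", "enrich", "reporter", "survival")
  stages <- config$stages %||% all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)

  acfg <- do.call(analysis_config,
                  c(config$analysis %||% list(),
                    if (is.null(config$analysis$rng_seed)) list(rng_seed = derive_seed(seed, "analysis"))))
  design <- do.call(synthetic_design,
                    c(config$design %||% list(),
                      if (is.null(config$design$seed)) list(seed = derive_seed(seed, "simulate"))))

  state <- new.env(parent = emptyenv())
  record <- list()
  log_stage <- function(stage, status, outputs, secs) {
    record[[stage]] <<- tibble::tibble(
      stage = stage, status = status, seconds = round(secs, 2),
      outputs = paste(outputs, collapse = ";")
    )
  }
  run_stage <- function(stage, deps, fn) {
    if (!stage %in% stages) { log_stage(stage, "skipped", character(0), 0); return() }
    missing_dep <- deps[!vapply(deps, function(d) isTRUE(state[[paste0("ok_", d)]]), TRUE)]
    if (length(missing_dep) > 0) {
      log_stage(stage, paste0("skipped (needs ", paste(missing_dep, collapse = ","), ")"),
                character(0), 0)
      return()
    }
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(list(ok = TRUE, out = fn()),
                    error = function(e) list(ok = FALSE, out = conditionMessage(e)))
    secs <- proc.time()[["elapsed"]] - t0
    if (res$ok) {
      state[[paste0("ok_", stage)]] <- TRUE
      log_stage(stage, "ok", res$out, secs)
    } else {
      log_stage(stage, paste0("failed: ", res$out), character(0), secs)
    }
  }
  path <- function(...) file.path(out_dir, ...)

  run_stage("simulate", character(0), function() {
    if (!is.null(config$expression_paths)) {
      state$expr <- lapply(config$expression_paths, read_expression_tsv)
      names(state$expr) <- names(config$expression_paths) %||%
        sprintf("cohort%d", seq_along(state$expr))
      state$metadata <- tibble::as_tibble(
        utils::read.delim(config$metadata_path, sep = "\t", quote = ""))
      state$truth <- NULL
      character(0)
    } else {
      sim <- generate_cohorts(design)
      state$expr <- sim$expr
      state$metadata <- sim$metadata
      state$truth <- sim$truth
      p <- unlist(simulate_study(design, path("inputs")))
      unname(p)
    }
  })

  run_stage("de", "simulate", function() {
    md <- state$metadata
    cid <- names(state$expr)[1]
    groups <- config$de_contrast %||% unique(md$group_label)[1:2]
    de <- compute_de(state$expr[[cid]], md[md$cohort_id == cid, ],
                     groups[1], groups[2], deg_alpha = acfg$deg_alpha)
    state$de <- de
    f <- path("de_stats.tsv")
    utils::write.table(de, f, sep = "\t", quote = FALSE, row.names = FALSE)
    f
  })

  run_stage("network", "simulate", function() {
    state$networks <- lapply(names(state$expr), function(cid) {
      filtered <- filter_low_expression(state$expr[[cid]],
                                        acfg$tpm_filter_stat,
                                        acfg$tpm_filter_threshold)
      build_network(filtered, acfg, cohort_id = cid)
    })
    names(state$networks) <- names(state$expr)
    unname(vapply(names(state$networks), function(cid) {
      write_edge_list(state$networks[[cid]], path(paste0(cid, "_edges.tsv")))
    }, ""))
  })

  run_stage("modules", "network", function() {
    state$partitions <- lapply(state$networks, detect_modules, config = acfg)
    unname(vapply(names(state$partitions), function(cid) {
      write_module_table(state$partitions[[cid]], path(paste0(cid, "_modules.tsv")))
    }, ""))
  })

  run_stage("conserve", "modules", function() {
    if (length(state$partitions) < 2) stop("conservation needs >= 2 cohorts")
    cons <- all_pairs_conservation(state$partitions,
                                   overlap_alpha = acfg$overlap_alpha)
    state$conservation <- cons
    state$consensus <- extract_consensus(cons, state$partitions)
    f1 <- path("conservation.tsv")
    utils::write.table(as.data.frame(cons), f1, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    f2 <- path("consensus_modules.tsv")
    flat <- dplyr::mutate(state$consensus,
                          members = vapply(.data$members, paste, "", collapse = ","),
                          consensus_genes = vapply(.data$consensus_genes, paste, "",
                                                   collapse = ","))
    utils::write.table(as.data.frame(flat), f2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    c(f1, f2)
  })

  run_stage("topology", "modules", function() {
    rows <- list()
    for (cid in names(state$partitions)) {
      part <- state$partitions[[cid]]
      for (mid in names(part$modules)) {
        tp <- module_topology(state$networks[[cid]], part$modules[[mid]])
        rows[[paste(cid, mid)]] <- dplyr::bind_cols(
          tibble::tibble(cohort_id = cid, module_id = mid), tp)
      }
    }
    state$topology <- dplyr::bind_rows(rows)
    f <- path("topology.tsv")
    utils::write.table(state$topology, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    f
  })

  run_stage("enrich", "modules", function() {
    tf <- generate_feature_map(design, "transcription_factor")
    part1 <- state$partitions[[1]]
    bg <- state$networks[[1]]$nodes
    rows <- lapply(names(part1$modules), function(mid) {
      res <- tf_enrichment(part1$modules[[mid]], tf, bg,
                           q_alpha = acfg$enrich_q_alpha)
      dplyr::bind_cols(tibble::tibble(module_id = mid), tibble::as_tibble(res))
    })
    state$enrichment <- dplyr::bind_rows(rows)
    f <- path("tf_enrichment.tsv")
    utils::write.table(state$enrichment, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    f
  })

  run_stage("reporter", "de", function() {
    met <- generate_feature_map(design, "metabolite")
    rep_all <- reporter_scores(gene_zscores(state$de), met,
                               n_background = acfg$reporter_background_samples,
                               seed = derive_seed(seed, "reporter"))
    state$reporter <- rep_all
    f <- path("reporter_metabolites.tsv")
    utils::write.table(rep_all, f, sep = "\t", quote = FALSE, row.names = FALSE)
    f
  })

  run_stage("survival", "simulate", function() {
    cid <- names(state$expr)[1]
    surv <- generate_survival(state$expr[[cid]], design,
                              seed = derive_seed(seed, "survival"))
    keep <- design$genes$disease[1:min(10, length(design$genes$disease))]
    prog <- batch_prognosis(state$expr[[cid]][keep, ], surv, acfg)
    state$prognosis <- prog
    f <- path("prognosis.tsv")
    utils::write.table(prog, f, sep = "\t", quote = FALSE, row.names = FALSE)
    f
  })

  stage_tbl <- dplyr::bind_rows(record[all_stages])
  outputs <- unlist(strsplit(stage_tbl$outputs[stage_tbl$outputs != ""], ";"))
  checksums <- if (length(outputs)) tools::md5sum(outputs) else character(0)
  run <- structure(list(
    config = config,
    analysis_config = acfg,
    design = design,
    seed = seed,
    package_version = as.character(utils::packageVersion("coexmod")),
    stages = stage_tbl,
    checksums = tibble::tibble(path = names(checksums), md5 = unname(checksums)),
    results = state
  ), class = "pipeline_run")
  yaml::write_yaml(list(seed = seed,
                        package_version = run$package_version,
                        stages = as.data.frame(stage_tbl),
                        checksums = as.data.frame(run$checksums)),
                   file.path(out_dir, "run_record.yaml"))
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run> seed", x$seed, "\n")
  print(as.data.frame(x$stages[, c("stage", "status", "seconds")]), row.names = FALSE)
  invisible(x)
}
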
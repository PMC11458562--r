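#' Pipeline configuration
#'
#' One structured object driving the full workflow: synthetic-cohort
#' generation (or paths to existing inputs), QC thresholds, candidate
#' selection, group-wise sparse CCA, predictive validation, mediation and
#' enrichment. Can be loaded from a YAML file with [load_pipeline_config()].
#'
#' @param sim a [sim_config()] used when no input paths are given.
#' @param input_dir optional directory holding `geno.bed/bim/fam`,
#'   `pheno.tsv`, `sumstats.tsv`, `annotation.tsv`, `sets.gmt` (as written
#'   by [write_fixture()]); when `NULL` the cohort is simulated.
#' @param qc a [qc_thresholds()].
#' @param p_threshold,r2_threshold,window_kb candidate-selection controls.
#' @param tau1,tau2 sparse CCA budgets (`NULL` tau2 = inactive bound).
#' @param top_k SNPs selected per group.
#' @param folds,repeats elastic-net CV controls.
#' @param outcomes outcome columns for the model grid (`thickness` is the
#'   derived mean global thickness).
#' @param n_sim mediation parameter draws.
#' @param seed global seed propagated to every stochastic stage.
#' @return `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), input_dir = NULL,
                            qc = qc_thresholds(), p_threshold = 1e-4,
                            r2_threshold = 0.1, window_kb = 250,
                            tau1 = 4, tau2 = NULL, top_k = 10,
                            folds = 5, repeats = 10,
                            outcomes = c("thickness", "mmse", "cdr_sb"),
                            n_sim = 1000, seed = 1L) {
  cfg <- list(sim = sim, input_dir = input_dir, qc = qc,
              p_threshold = p_threshold, r2_threshold = r2_threshold,
              window_kb = window_kb, tau1 = tau1, tau2 = tau2,
              top_k = top_k, folds = folds, repeats = repeats,
              outcomes = outcomes, n_sim = n_sim, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; `sim` and
#' `qc` sub-sections mirror [sim_config()] and [qc_thresholds()].
#'
#' @param path YAML file.
#' @return `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- do.call(sim_config, y$sim %||% list())
  qc <- do.call(qc_thresholds, y$qc %||% list())
  rest <- y[setdiff(names(y), c("sim", "qc"))]
  do.call(pipeline_config, c(list(sim = sim, qc = qc), rest))
}

write_tsv_stamped <- function(df, path, stamp) {
  con <- file(path, "w")
  writeLines(paste0("# ", stamp), con)
  suppressWarnings(utils::write.table(df, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE))
  close(con)
  path
}

#' Read a pipeline output table (skipping the stamp comment)
#'
#' @param path TSV written by the pipeline.
#' @return data frame.
#' @export
read_tsv_stamped <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}

stage_marker_path <- function(out_dir, stage) {
  file.path(out_dir, "stages", paste0(stage, ".json"))
}

stage_current <- function(out_dir, stage, input_hash) {
  mp <- stage_marker_path(out_dir, stage)
  if (!file.exists(mp)) return(FALSE)
  m <- jsonlite::read_json(mp, simplifyVector = TRUE)
  if (!identical(m$input_hash, input_hash)) return(FALSE)
  files <- file.path(out_dir, names(m$outputs))
  all(file.exists(files)) &&
    identical(unname(tools::md5sum(files)), unname(unlist(m$outputs)))
}

stage_record <- function(out_dir, stage, input_hash, outputs) {
  dir.create(file.path(out_dir, "stages"), showWarnings = FALSE,
             recursive = TRUE)
  md5 <- as.list(tools::md5sum(file.path(out_dir, outputs)))
  names(md5) <- outputs
  jsonlite::write_json(list(stage = stage, input_hash = input_hash,
                            outputs = md5),
                       stage_marker_path(out_dir, stage),
                       auto_unbox = TRUE, pretty = TRUE)
}

derive_outcome <- function(pheno, name, rois) {
  if (name == "thickness") {
    gl <- grep("^global", rois, value = TRUE)
    cols <- if (length(gl)) gl else rois
    rowMeans(as.matrix(pheno[, cols, drop = FALSE]))
  } else {
    pheno[[name]]
  }
}

#' Run the full analysis workflow
#'
#' Executes, in order: cohort simulation (or loading), genotype QC,
#' summary-statistic filtering with LD clumping, group-wise sparse CCA
#' with top-k SNP selection, cross-group elastic-net validation plus the
#' three-model grid, the amyloid mediation screen, and gene-set
#' enrichment. Each stage writes TSV outputs stamped with the config hash
#' and seed, records a marker (input hash + output checksums) and caches
#' its computed state; with `resume = TRUE`, stages whose marker still
#' matches disk are skipped and their state reloaded. A failing stage
#' aborts with its name while earlier outputs stay on disk. The run
#' manifest (`manifest.json`) lists the checksums of every analysis
#' table.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @param resume skip up-to-date stages.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir, resume = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- object_md5(strip_classes(config))
  stamp <- sprintf("config=%s seed=%d", cfg_hash, config$seed)
  log <- file.path(out_dir, "pipeline.log")
  say <- function(...) {
    cat(format(Sys.time(), "%H:%M:%S "), sprintf(...), "\n",
        file = log, append = TRUE, sep = "")
  }

  stage <- function(name, compute) {
    state_f <- file.path(out_dir, "stages", paste0(name, ".rds"))
    if (resume && stage_current(out_dir, name, cfg_hash) &&
        file.exists(state_f)) {
      say("%s: up to date, skipped", name)
      return(readRDS(state_f))
    }
    st <- tryCatch(compute(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    dir.create(file.path(out_dir, "stages"), showWarnings = FALSE)
    saveRDS(st, state_f)
    stage_record(out_dir, name, cfg_hash, st$outputs)
    say("%s: done", name)
    st
  }

  # --- data ---------------------------------------------------------------
  if (is.null(config$input_dir)) {
    stage("simulate", function() {
      cohort <- simulate_cohort(config$sim)
      cohort$sumstats <- simulate_summary_stats(config$sim, cohort$truth,
                                                cohort$geno)
      cohort$annotation <- simulate_annotation(cohort$geno, cohort$truth,
                                               config$sim)
      cohort$gene_sets <- simulate_gene_sets(cohort$annotation, cohort$truth,
                                             seed = config$seed)
      write_fixture(cohort, file.path(out_dir, "data"))
      list(outputs = file.path("data", list.files(file.path(out_dir, "data"))))
    })
    src <- file.path(out_dir, "data")
  } else {
    src <- config$input_dir
    for (f in c("geno.bed", "geno.bim", "geno.fam", "pheno.tsv",
                "sumstats.tsv")) {
      if (!file.exists(file.path(src, f))) {
        stop("missing pipeline input: ", file.path(src, f))
      }
    }
  }
  pheno_all <- utils::read.delim(file.path(src, "pheno.tsv"),
                                 stringsAsFactors = FALSE)
  geno <- read_plink(file.path(src, "geno"))
  info_path <- file.path(src, "geno.info.tsv")
  if (file.exists(info_path)) {
    info <- utils::read.delim(info_path, stringsAsFactors = FALSE)
    geno$snps$info_r2 <- info$info_r2[match(geno$snps$id, info$id)]
  }
  sumstats <- utils::read.delim(file.path(src, "sumstats.tsv"),
                                stringsAsFactors = FALSE)
  annotation_path <- file.path(src, "annotation.tsv")
  annotation <- if (file.exists(annotation_path)) {
    utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  }
  gmt_path <- file.path(src, "sets.gmt")
  gene_sets <- if (file.exists(gmt_path)) read_gmt(gmt_path)
  stopifnot(identical(geno$sample_ids, pheno_all$sample_id))

  # --- qc -----------------------------------------------------------------
  st_qc <- stage("qc", function() {
    res <- apply_qc(geno, config$qc)
    write_tsv_stamped(res$report$table, file.path(out_dir, "qc_report.tsv"),
                      stamp)
    list(outputs = "qc_report.tsv", geno = res$geno, report = res$report)
  })
  geno_qc <- st_qc$geno
  pheno <- pheno_all[match(geno_qc$sample_ids, pheno_all$sample_id), ,
                     drop = FALSE]

  # --- select -------------------------------------------------------------
  st_sel <- stage("select", function() {
    panel <- clump(geno_qc, sumstats, config$p_threshold,
                   config$r2_threshold, config$window_kb)
    if (length(panel$index_snps) == 0) stop("no SNPs pass selection")
    panel_df <- data.frame(snp = panel$index_snps,
                           n_members = unname(lengths(panel$clumps)),
                           stringsAsFactors = FALSE)
    write_tsv_stamped(panel_df, file.path(out_dir, "panel.tsv"), stamp)
    list(outputs = "panel.tsv", panel = panel)
  })
  panel <- st_sel$panel

  pcols <- match(panel$index_snps, geno_qc$snps$id)
  dos <- mean_impute(geno_qc$dosages[, pcols, drop = FALSE])
  colnames(dos) <- panel$index_snps
  psnps <- geno_qc$snps[pcols, , drop = FALSE]
  rois <- grep("_(l|r)$", names(pheno), value = TRUE)
  if (length(rois) == 0) rois <- grep("^roi_", names(pheno), value = TRUE)

  # --- scca ---------------------------------------------------------------
  st_scca <- stage("scca", function() {
    y_raw <- as.matrix(pheno[, rois, drop = FALSE])
    covars <- as.matrix(pheno[, c("age", "sex", "education", "icv")])
    tau2 <- config$tau2 %||% sqrt(length(rois))
    gres <- groupwise_scca(dos, psnps, y_raw, covars, pheno$abeta,
                           tau1 = config$tau1, tau2 = tau2,
                           top_k = config$top_k)
    wt <- do.call(rbind, lapply(names(gres), function(nm) {
      tp <- gres[[nm]]$top
      tp$gene <- if (!is.null(annotation)) {
        annotation$gene[match(tp$id, annotation$snp)]
      } else NA_character_
      cbind(group = nm, tp, rho = gres[[nm]]$fit$rho)
    }))
    write_tsv_stamped(wt, file.path(out_dir, "scca_weights.tsv"), stamp)
    loads <- do.call(rbind, lapply(names(gres), function(nm) {
      data.frame(group = nm, roi = rois, weight = gres[[nm]]$fit$v,
                 stringsAsFactors = FALSE)
    }))
    write_tsv_stamped(loads, file.path(out_dir, "scca_roi_loadings.tsv"),
                      stamp)
    list(outputs = c("scca_weights.tsv", "scca_roi_loadings.tsv"),
         gres = gres)
  })
  top_neg <- st_scca$gres$negative$top$id
  top_pos <- st_scca$gres$positive$top$id

  # --- validate -----------------------------------------------------------
  stage("validate", function() {
    thick <- derive_outcome(pheno, "thickness", rois)
    # cross-group transfer uses the selected SNPs alone; covariate-based
    # models are handled by the three-model grid below
    features_fun <- function(ids) dos[, ids, drop = FALSE]
    cg <- cross_group_validate(features_fun, thick, pheno$abeta,
                               top_neg, top_pos, folds = config$folds,
                               repeats = config$repeats, seed = config$seed)
    write_tsv_stamped(cg, file.path(out_dir, "validation_cross_group.tsv"),
                      stamp)
    grid_rows <- list()
    for (grp in c("negative", "positive")) {
      sel <- pheno$abeta == (grp == "positive")
      tops <- if (grp == "negative") top_neg else top_pos
      for (oc in config$outcomes) {
        y <- derive_outcome(pheno, oc, rois)[sel]
        mg <- model_grid(pheno[sel, , drop = FALSE],
                         function(ids) dos[sel, ids, drop = FALSE],
                         panel$index_snps, tops, y,
                         outcome_type = if (oc == "thickness") "thickness"
                         else "cognitive",
                         folds = config$folds, repeats = config$repeats,
                         seed = config$seed)
        df <- cbind(group = grp, outcome = oc, mg$summary)
        df$p_vs_model1 <- ifelse(df$model == "model2",
                                 mg$comparisons$model2_vs_model1$p, NA)
        df$p_vs_model3 <- ifelse(df$model == "model2",
                                 mg$comparisons$model2_vs_model3$p, NA)
        grid_rows[[length(grid_rows) + 1L]] <- df
      }
    }
    write_tsv_stamped(do.call(rbind, grid_rows),
                      file.path(out_dir, "validation_models.tsv"), stamp)
    list(outputs = c("validation_cross_group.tsv", "validation_models.tsv"))
  })

  # --- mediate ------------------------------------------------------------
  stage("mediate", function() {
    med_panel <- unique(c(top_neg, top_pos))
    scr <- mediation_screen(dos, med_panel, pheno, rois,
                            n_sim = config$n_sim, seed = config$seed)
    write_tsv_stamped(scr$table, file.path(out_dir, "mediation.tsv"), stamp)
    dirm <- data.frame(snp = rownames(scr$ade), scr$ade,
                       check.names = FALSE)
    indm <- data.frame(snp = rownames(scr$acme), scr$acme,
                       check.names = FALSE)
    write_tsv_stamped(dirm, file.path(out_dir, "mediation_direct.tsv"),
                      stamp)
    write_tsv_stamped(indm, file.path(out_dir, "mediation_indirect.tsv"),
                      stamp)
    list(outputs = c("mediation.tsv", "mediation_direct.tsv",
                     "mediation_indirect.tsv"))
  })

  # --- enrich -------------------------------------------------------------
  if (!is.null(annotation) && !is.null(gene_sets)) {
    stage("enrich", function() {
      outs <- character(0)
      for (grp in c("negative", "positive")) {
        tops <- if (grp == "negative") top_neg else top_pos
        genes <- map_snps_to_genes(tops, annotation)
        er <- fisher_enrichment(genes, gene_sets,
                                universe = unique(annotation$gene))
        f <- sprintf("enrichment_%s.tsv", grp)
        write_tsv_stamped(er, file.path(out_dir, f), stamp)
        outs <- c(outs, f)
      }
      list(outputs = outs)
    })
  }

  # --- manifest -----------------------------------------------------------
  outputs <- sort(grep("^(stages/|pipeline\\.log|manifest\\.json)",
                       list.files(out_dir, recursive = TRUE),
                       invert = TRUE, value = TRUE))
  md5 <- as.list(tools::md5sum(file.path(out_dir, outputs)))
  names(md5) <- outputs
  manifest <- list(package = "igscca",
                   version = as.character(utils::packageVersion("igscca")),
                   seed = config$seed, config_hash = cfg_hash,
                   outputs = md5)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' One-command synthetic demonstration run
#'
#' Simulates a compact cohort and runs the entire workflow with
#' deterministic seeding. Two runs with the same seed produce
#' byte-identical tables and manifests.
#'
#' @param out_dir output directory.
#' @param seed global seed.
#' @param resume skip up-to-date stages.
#' @return invisibly, the run manifest.
#' @export
run_demo <- function(out_dir, seed = 1L, resume = FALSE) {
  cfg <- pipeline_config(
    sim = sim_config(n_samples = 400, n_snps = 2000, ld_block_size = 4,
                     n_causal = 6, decoy_fraction = 0.2, seed = seed),
    top_k = 10, repeats = 3, n_sim = 200,
    outcomes = c("thickness", "mmse"), seed = seed)
  run_pipeline(cfg, out_dir, resume = resume)
}
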
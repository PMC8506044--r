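# Configuration-driven pipeline tying the stages into the three analysis
# modes (isec / rule / ml), plus simulation. Each stage reads and writes
# plain files under the configured output directory, so stages can be run
# one at a time or end to end; run-all writes a manifest with versions,
# seeds and per-stage record counts. A thin command-line wrapper around
# run_pipeline() is installed at inst/cli/rnatmb.

pipeline_subcommands <- c("simulate", "filter", "featurize", "label",
                          "train", "predict", "tmb", "evaluate", "run-all")

config_schema <- list(
  top = c("seed", "out_dir", "mode", "thresholds", "train_fraction",
          "cutoff", "simulate", "filter", "train"),
  filter = c("exac_threshold", "allowed_rnaseq_filter_sets",
             "require_no_dbsnp"),
  train = c("n_iter", "n_folds", "stratified", "scale_pos_weight")
)

#' Validate a pipeline configuration
#'
#' Fills defaults and rejects unknown keys with a message naming the
#' offending key. The `simulate` block accepts the arguments of
#' [cohort_sim_config()], the `filter` block those of [filter_config()],
#' and the `train` block those of [search_config()].
#'
#' @param config Named list, or path to a YAML/JSON file containing one.
#' @return The validated config list with defaults filled in.
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a named list or a YAML path")
  check_keys <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad)) {
      stop("unknown config key", if (length(bad) > 1) "s", " in ", where,
           ": ", paste(bad, collapse = ", "))
    }
  }
  check_keys(config, config_schema$top, "top level")
  check_keys(config$simulate %||% list(),
             names(formals(cohort_sim_config)), "'simulate'")
  check_keys(config$filter %||% list(), config_schema$filter, "'filter'")
  check_keys(config$train %||% list(), config_schema$train, "'train'")
  config$seed <- as.integer(config$seed %||% 1L)
  config$out_dir <- config$out_dir %||% stop("config key 'out_dir' required")
  config$mode <- match.arg(config$mode %||% "ml", c("isec", "rule", "ml"))
  config$thresholds <- as.numeric(config$thresholds %||% c(6, 10, 20))
  config$train_fraction <- config$train_fraction %||% 0.5
  if (config$train_fraction <= 0 || config$train_fraction >= 1) {
    stop("config key 'train_fraction' must lie strictly between 0 and 1")
  }
  config$cutoff <- config$cutoff %||% 0.5
  config$simulate <- config$simulate %||% list()
  config$filter <- config$filter %||% list()
  config$train <- config$train %||% list()
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sim_dir <- function(cfg) file.path(cfg$out_dir, "sim")

load_cohort_callsets <- function(cfg, flavor = c("rna", "wes"),
                                 subdir = "sim") {
  flavor <- match.arg(flavor)
  d <- file.path(cfg$out_dir, subdir)
  paths <- sort(list.files(d, pattern = paste0("^", flavor, "_.*\\.vcf$"),
                           full.names = TRUE))
  if (!length(paths)) {
    stop("no ", flavor, " VCF files found under ", d,
         " (run the simulate stage first, or place inputs there)")
  }
  wes_source <- if (isTRUE((cfg$simulate$wes_mode %||% "matched") ==
                             "tumor_only")) "wes_tumor_only" else "wes_matched"
  src <- if (flavor == "rna") "rnaseq_tumor_only" else wes_source
  sets <- lapply(paths, read_callset, source = src)
  setNames(sets, vapply(sets, function(cs) cs$sample_id, character(1)))
}

filtered_wes <- function(cfg, wes) {
  lapply(wes, function(cs) {
    if (cs$source == "wes_matched") filter_wes_matched(cs)
    else filter_wes_tumor_only(cs, do.call(filter_config, cfg$filter))
  })
}

train_test_split <- function(sample_ids, train_fraction, seed) {
  set.seed(seed + 101L)
  ids <- sort(sample_ids)
  n_train <- max(1, min(length(ids) - 1,
                        round(length(ids) * train_fraction)))
  train <- sort(sample(ids, n_train))
  list(train = train, test = setdiff(ids, train))
}

#' Run the TMB pipeline
#'
#' Executes one stage or the whole chain
#' simulate -> filter -> featurize -> label -> train -> predict -> tmb ->
#' evaluate on the configured output directory. Stage artifacts are plain
#' files (VCF, BED, TSV, a serialized model, a JSON concordance report), so
#' any stage can be re-run in isolation against existing artifacts.
#'
#' @param config Named list or YAML path; see [validate_pipeline_config()].
#' @param subcommand One of `"simulate"`, `"filter"`, `"featurize"`,
#'   `"label"`, `"train"`, `"predict"`, `"tmb"`, `"evaluate"`, `"run-all"`.
#' @param quiet Suppress progress messages.
#' @return For `"evaluate"`/`"run-all"`, the `rnatmb_concordance` report
#'   (invisibly for other stages, the stage's main artifact path).
#' @export
run_pipeline <- function(config, subcommand = "run-all", quiet = FALSE) {
  subcommand <- match.arg(subcommand, pipeline_subcommands)
  cfg <- validate_pipeline_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  manifest <- list(package = "rnatmb",
                   version = as.character(packageVersion("rnatmb")),
                   r_version = R.version.string,
                   seed = cfg$seed, mode = cfg$mode, stages = list())
  note_stage <- function(name, ...) {
    manifest$stages[[name]] <<- list(...)
  }

  stage_simulate <- function() {
    sim_args <- cfg$simulate
    sim_args$seed <- sim_args$seed %||% cfg$seed
    cohort <- simulate_cohort(do.call(cohort_sim_config, sim_args),
                              dir = sim_dir(cfg))
    say("simulate: %d samples, %d truth variants", length(cohort$rnaseq),
        nrow(cohort$truth$variants))
    note_stage("simulate", n_samples = length(cohort$rnaseq),
               n_truth_variants = nrow(cohort$truth$variants))
    invisible(cohort)
  }

  stage_filter <- function() {
    rna <- load_cohort_callsets(cfg, "rna")
    wes <- load_cohort_callsets(cfg, "wes")
    fc <- do.call(filter_config, cfg$filter)
    d <- file.path(cfg$out_dir, "filtered")
    dir.create(d, showWarnings = FALSE)
    n_rna <- n_wes <- 0
    for (sid in names(rna)) {
      f <- filter_rnaseq_tumor_only(rna[[sid]], fc)
      n_rna <- n_rna + n_variants(f)
      write_callset(f, file.path(d, paste0("rna_", sid, ".vcf")))
    }
    for (sid in names(wes)) {
      f <- filtered_wes(cfg, wes[sid])[[1]]
      n_wes <- n_wes + n_variants(f)
      write_callset(f, file.path(d, paste0("wes_", sid, ".vcf")))
    }
    say("filter: retained %d RNA-seq and %d WES variants", n_rna, n_wes)
    note_stage("filter", n_rna_retained = n_rna, n_wes_retained = n_wes)
    invisible(d)
  }

  stage_featurize <- function() {
    rna <- load_cohort_callsets(cfg, "rna")
    pooled <- merge_callsets(unname(rna))
    fm <- build_feature_matrix(pooled)
    out <- file.path(cfg$out_dir, "features.tsv")
    df <- data.frame(key = rownames(fm), as.data.frame(unclass(fm)),
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.table(df, out, sep = "\t", quote = FALSE, row.names = FALSE)
    say("featurize: %d variants x %d features", nrow(fm), ncol(fm))
    note_stage("featurize", n_rows = nrow(fm), n_features = ncol(fm))
    invisible(out)
  }

  stage_label <- function() {
    rna <- load_cohort_callsets(cfg, "rna")
    wes <- filtered_wes(cfg, load_cohort_callsets(cfg, "wes"))
    pooled <- merge_callsets(unname(rna))
    lab <- label_by_wes(pooled, wes)
    out <- file.path(cfg$out_dir, "labels.tsv")
    v <- pooled$variants
    write.table(data.frame(key = paste0(v$sample_id, "|", variant_key(v)),
                           label = lab$labels, stringsAsFactors = FALSE),
                out, sep = "\t", quote = FALSE, row.names = FALSE)
    say("label: %d signal / %d noise", sum(lab$labels == "signal"),
        sum(lab$labels == "noise"))
    note_stage("label", n_signal = sum(lab$labels == "signal"),
               n_noise = sum(lab$labels == "noise"))
    invisible(out)
  }

  stage_train <- function() {
    rna <- load_cohort_callsets(cfg, "rna")
    wes <- filtered_wes(cfg, load_cohort_callsets(cfg, "wes"))
    split <- train_test_split(names(rna), cfg$train_fraction, cfg$seed)
    pooled <- merge_callsets(unname(rna[split$train]))
    lab <- label_by_wes(pooled, wes[split$train])
    fm <- build_feature_matrix(pooled)
    sc <- do.call(search_config, cfg$train)
    model <- train_noise_classifier(fm, lab$labels, sc, seed = cfg$seed)
    out <- file.path(cfg$out_dir, "model.bin")
    save_model(model, out)
    say("train: %d samples, %d variants, CV AUC %.4f",
        length(split$train), nrow(fm), cv_auc(model))
    note_stage("train", train_samples = split$train, n_rows = nrow(fm),
               cv_auc = cv_auc(model))
    invisible(out)
  }

  stage_predict <- function() {
    rna <- load_cohort_callsets(cfg, "rna")
    model <- load_model(file.path(cfg$out_dir, "model.bin"))
    split <- train_test_split(names(rna), cfg$train_fraction, cfg$seed)
    d <- file.path(cfg$out_dir, "mlfiltered")
    dir.create(d, showWarnings = FALSE)
    preds <- list()
    for (sid in split$test) {
      fm <- build_feature_matrix(rna[[sid]], model$registry)
      p <- predict_noise_probability(model, fm)
      preds[[sid]] <- data.frame(key = names(p), probability = unname(p),
                                 stringsAsFactors = FALSE)
      write_callset(apply_ml_filter(rna[[sid]], model, cfg$cutoff),
                    file.path(d, paste0("rna_", sid, ".vcf")))
    }
    out <- file.path(cfg$out_dir, "predictions.tsv")
    write.table(do.call(rbind, preds), out, sep = "\t", quote = FALSE,
                row.names = FALSE)
    say("predict: scored %d test samples", length(split$test))
    note_stage("predict", test_samples = split$test)
    invisible(out)
  }

  stage_tmb <- function() {
    regions <- read_regions(file.path(sim_dir(cfg), "regions.bed"))
    wes <- filtered_wes(cfg, load_cohort_callsets(cfg, "wes"))
    wes_mode <- wes[[1]]$source
    ests <- lapply(names(wes), function(sid) {
      compute_tmb(wes[[sid]], regions,
                  if (wes_mode == "wes_matched") "wes_matched"
                  else "wes_tumor_only")
    })
    rna_ests <- switch(
      cfg$mode,
      rule = {
        f <- load_cohort_callsets(cfg, "rna", subdir = "filtered")
        lapply(f, compute_tmb, regions = regions, mode = "rule")
      },
      isec = {
        raw <- load_cohort_callsets(cfg, "rna")
        lapply(names(raw), function(sid) {
          compute_tmb(intersect_callsets(raw[[sid]], wes[[sid]], "full_key"),
                      regions, "isec")
        })
      },
      ml = {
        f <- load_cohort_callsets(cfg, "rna", subdir = "mlfiltered")
        lapply(f, compute_tmb, regions = regions, mode = "ml")
      })
    out <- file.path(cfg$out_dir, "tmb.tsv")
    tbl <- rbind(tmb_table(rna_ests), tmb_table(ests))
    write.table(tbl, out, sep = "\t", quote = FALSE, row.names = FALSE)
    say("tmb: %d estimates (%s + WES gold)", nrow(tbl), cfg$mode)
    note_stage("tmb", n_estimates = nrow(tbl))
    invisible(out)
  }

  stage_evaluate <- function() {
    tbl <- read.table(file.path(cfg$out_dir, "tmb.tsv"), sep = "\t",
                      header = TRUE, stringsAsFactors = FALSE)
    rna <- tbl[tbl$mode %in% c("isec", "rule", "ml"), , drop = FALSE]
    wes <- tbl[startsWith(tbl$mode, "wes"), , drop = FALSE]
    wes <- wes[wes$sample_id %in% rna$sample_id, , drop = FALSE]
    report <- build_concordance_report(rna, wes, cfg$thresholds,
                                       mode = cfg$mode)
    out <- file.path(cfg$out_dir, "concordance.json")
    write_concordance_report(report, out)
    say("evaluate: Pearson %.3f, Spearman %.3f", report$pearson_r,
        report$spearman_rho)
    note_stage("evaluate", n_pairs = nrow(report$pairs),
               pearson_r = report$pearson_r)
    report
  }

  result <- switch(subcommand,
    "simulate" = stage_simulate(),
    "filter" = stage_filter(),
    "featurize" = stage_featurize(),
    "label" = stage_label(),
    "train" = stage_train(),
    "predict" = stage_predict(),
    "tmb" = stage_tmb(),
    "evaluate" = stage_evaluate(),
    "run-all" = {
      stage_simulate(); stage_filter(); stage_featurize(); stage_label()
      if (cfg$mode == "ml") { stage_train(); stage_predict() }
      stage_tmb()
      stage_evaluate()
    })
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (inherits(result, "rnatmb_concordance")) result else invisible(result)
}
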
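#' Assemble a pipeline configuration
#'
#' Collects every knob of the end-to-end workflow — cohort source, texture
#' extraction parameters, statistics level, classifier settings, permutation
#' trials and forest size — into one serializable list. A snapshot of the
#' config is written alongside every run's outputs.
#'
#' @param cohort Either a [cohort_spec()] (synthetic run) or the path to a
#'   cohort manifest CSV (see [ingest_cohort()]).
#' @param Ng,d,thetas,plane,symmetrize,bin_mode Texture parameters, see
#'   [region_features()].
#' @param alpha Significance level for the group tests.
#' @param C,gamma SVM parameters.
#' @param cv `"loo"` or `"kfold"`.
#' @param k Folds for `cv = "kfold"` AUC estimation.
#' @param normalize `"fold"` or `"global"` z-scoring, see [loocv_svm()].
#' @param n_trials Permutation trials (set 0 to skip the permutation stage).
#' @param n_trees Random-forest trees (set 0 to skip the importance stage).
#' @param seed Seed for classification/permutation/forest stages.
#' @param write_nifti Write simulated volumes and masks as NIfTI files.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            Ng = 32L, d = 1L, thetas = c(0, 45, 90, 135),
                            plane = 1L, symmetrize = FALSE,
                            bin_mode = "equalize",
                            alpha = 0.05, C = 1, gamma = 1,
                            cv = c("loo", "kfold"), k = 10L,
                            normalize = c("fold", "global"),
                            n_trials = 1000L, n_trees = 1000L,
                            seed = 1L, write_nifti = FALSE) {
  cv <- match.arg(cv)
  normalize <- match.arg(normalize)
  structure(list(cohort = cohort, Ng = as.integer(Ng), d = as.integer(d),
                 thetas = thetas, plane = plane, symmetrize = symmetrize,
                 bin_mode = bin_mode, alpha = alpha, C = C, gamma = gamma,
                 cv = cv, k = as.integer(k), normalize = normalize,
                 n_trials = as.integer(n_trials),
                 n_trees = as.integer(n_trees),
                 seed = as.integer(seed), write_nifti = write_nifti),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Config file; a top-level `cohort` block with a `spec` entry
#'   is interpreted as a [cohort_spec()], a `manifest` entry as a manifest
#'   path (relative to the config file's directory).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cohort <- raw$cohort
  if (!is.null(cohort$spec)) {
    cohort <- do.call(cohort_spec, cohort$spec)
  } else if (!is.null(cohort$manifest)) {
    cohort <- file.path(dirname(path), cohort$manifest)
  } else {
    stop("config must provide cohort$spec or cohort$manifest")
  }
  raw$cohort <- NULL
  do.call(pipeline_config, c(list(cohort = cohort), raw))
}

#' Load and validate a cohort from a manifest
#'
#' The manifest CSV has columns `subject_id`, `label`, `volume` (NIfTI
#' path), `mask` (first-rater NIfTI path) and optionally `mask2`. Paths are
#' resolved relative to the manifest's directory. Masks must be binary and
#' shape-matched to their volume; subjects whose mask is empty are dropped
#' with a warning (poor labelling quality), and more than two label values
#' is an error since the design is binary.
#'
#' @param manifest Path to the manifest CSV, or an equivalent data frame.
#' @param base Directory against which relative paths are resolved; defaults
#'   to the manifest's directory (or the working directory for a data frame).
#' @return List of subjects with `volume`, `mask_rater1`, `mask_rater2`
#'   (NULL if absent), `label`, `subject_id`.
#' @export
ingest_cohort <- function(manifest, base = NULL) {
  if (is.character(manifest)) {
    base <- base %||% dirname(manifest)
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  base <- base %||% "."
  req <- c("subject_id", "label", "volume", "mask")
  if (!all(req %in% names(manifest))) {
    stop("manifest must have columns: ", paste(req, collapse = ", "))
  }
  labs <- unique(manifest$label)
  if (length(labs) > 2L) {
    stop("binary design: manifest has ", length(labs), " label values (",
         paste(labs, collapse = ", "), ")")
  }
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  subjects <- list()
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$subject_id[i]
    vp <- resolve(manifest$volume[i]); mp <- resolve(manifest$mask[i])
    for (p in c(vp, mp)) {
      if (!file.exists(p)) stop("subject ", sid, ": file not found: ", p)
    }
    vol <- as.array(RNifti::readNifti(vp))
    msk <- as.array(RNifti::readNifti(mp))
    if (!identical(dim(vol), dim(msk))) {
      stop("subject ", sid, ": volume and mask shapes differ")
    }
    if (!all(msk %in% c(0, 1))) {
      stop("subject ", sid, ": mask is not binary")
    }
    if (sum(msk) == 0) {
      warning("subject ", sid, " dropped: empty mask")
      next
    }
    m2 <- NULL
    if (!is.null(manifest$mask2) && !is.na(manifest$mask2[i]) &&
        nzchar(manifest$mask2[i])) {
      m2 <- array(as.array(RNifti::readNifti(resolve(manifest$mask2[i]))) > 0,
                  dim = dim(vol))
    }
    subjects[[length(subjects) + 1L]] <-
      list(volume = vol, mask_rater1 = array(msk > 0, dim = dim(vol)),
           mask_rater2 = m2, label = as.integer(manifest$label[i]),
           subject_id = as.character(sid))
  }
  subjects
}

#' Write a simulated cohort to NIfTI files plus a manifest
#'
#' @param cohort Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest data frame (also written as
#'   `manifest.csv` in `dir`).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(s) {
    vp <- paste0(s$subject_id, "_vol.nii.gz")
    mp <- paste0(s$subject_id, "_mask1.nii.gz")
    m2p <- paste0(s$subject_id, "_mask2.nii.gz")
    RNifti::writeNifti(RNifti::asNifti(s$volume), file.path(dir, vp))
    RNifti::writeNifti(RNifti::asNifti(s$mask_rater1 * 1L), file.path(dir, mp))
    RNifti::writeNifti(RNifti::asNifti(s$mask_rater2 * 1L), file.path(dir, m2p))
    data.frame(subject_id = s$subject_id, label = s$label,
               volume = vp, mask = mp, mask2 = m2p,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Run the end-to-end pipeline
#'
#' Orchestrates simulate/ingest, feature extraction, group statistics,
#' LOOCV classification (plus k-fold AUC), random-forest importance and the
#' permutation test, writing one plain-text artifact per stage to
#' `out_dir`: `features.csv`, `group_stats.csv`, `classification.json`,
#' `importance.json`, `permutation.json`, a `config.json` snapshot, and
#' `run_log.txt` recording seeds, the config hash and package version.
#' Identical config + seed give identical artifacts (timestamps live only
#' in the log).
#'
#' @param config A [pipeline_config()] or the path to a YAML/JSON config.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with all in-memory stage results and
#'   `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # --- stage 0: config snapshot + hash
  cfg_json <- file.path(out_dir, "config.json")
  cfg_out <- config
  if (inherits(cfg_out$cohort, "cohort_spec")) {
    cfg_out$cohort <- unclass(cfg_out$cohort)
  }
  jsonlite::write_json(unclass(cfg_out), cfg_json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  cfg_hash <- unname(tools::md5sum(cfg_json))

  log_lines <- c(sprintf("roitexture %s", as.character(utils::packageVersion("roitexture"))),
                 sprintf("started: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
                 sprintf("config hash: %s", cfg_hash),
                 sprintf("seed: %d", config$seed))

  # --- stage 1: cohort
  cohort <- if (inherits(config$cohort, "cohort_spec")) {
    simulate_cohort(config$cohort)
  } else {
    ingest_cohort(config$cohort)
  }
  log_lines <- c(log_lines, sprintf("cohort: %d subjects", length(cohort)))
  if (isTRUE(config$write_nifti) && inherits(config$cohort, "cohort_spec")) {
    write_cohort(cohort, file.path(out_dir, "cohort"))
  }

  # --- stage 2: texture extraction
  table <- extract_cohort_features(cohort, plane = config$plane, d = config$d,
                                   thetas = config$thetas, Ng = config$Ng,
                                   symmetrize = config$symmetrize,
                                   bin_mode = config$bin_mode)
  utils::write.csv(cbind(table, config_hash = cfg_hash),
                   file.path(out_dir, "features.csv"), row.names = FALSE)

  # --- stage 3: group statistics (+ inter-rater Dice when masks exist)
  stats_df <- group_summary(table, alpha = config$alpha)
  utils::write.csv(stats_df, file.path(out_dir, "group_stats.csv"),
                   row.names = FALSE)
  dice <- vapply(cohort, function(s) {
    if (is.null(s$mask_rater2)) NA_real_
    else dice_coefficient(s$mask_rater1, s$mask_rater2)
  }, numeric(1))

  # --- stage 4: classification
  report <- loocv_svm(table, C = config$C, gamma = config$gamma,
                      normalize = config$normalize)
  auc <- kfold_auc(table, k = config$k, seed = config$seed, C = config$C,
                   gamma = config$gamma, normalize = config$normalize)
  cls <- list(config_hash = cfg_hash, seed = config$seed,
              confusion = list(TP = report$TP, TN = report$TN,
                               FP = report$FP, FN = report$FN),
              accuracy = report$accuracy, sensitivity = report$sensitivity,
              specificity = report$specificity,
              printed = as.list(report$printed),
              fold_auc = auc$fold_auc, mean_auc = auc$mean_auc,
              mean_dice = if (all(is.na(dice))) NULL else mean(dice, na.rm = TRUE))
  jsonlite::write_json(cls, file.path(out_dir, "classification.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # --- stage 5: random-forest importance
  imp <- NULL
  if (config$n_trees > 0L) {
    imp <- rf_root_importance(table, n_trees = config$n_trees,
                              seed = config$seed)
    jsonlite::write_json(list(config_hash = cfg_hash, seed = config$seed,
                              n_trees = imp$n_trees,
                              root_counts = as.list(imp$root_counts),
                              oob_importance = as.list(imp$oob_importance)),
                         file.path(out_dir, "importance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  # --- stage 6: permutation null
  perm <- NULL
  if (config$n_trials > 0L) {
    perm <- permutation_test(table, n_trials = config$n_trials,
                             seed = config$seed, C = config$C,
                             gamma = config$gamma,
                             normalize = config$normalize)
    jsonlite::write_json(list(config_hash = cfg_hash, seed = perm$seed,
                              n_trials = perm$n_trials, mean = perm$mean,
                              sd = perm$sd, median = perm$median,
                              observed = perm$observed, p = perm$p),
                         file.path(out_dir, "permutation.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  writeLines(c(log_lines, "completed"), file.path(out_dir, "run_log.txt"))
  invisible(list(cohort = cohort, features = table, group_stats = stats_df,
                 classification = report, auc = auc, importance = imp,
                 permutation = perm, dice = dice, config_hash = cfg_hash,
                 out_dir = out_dir))
}
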
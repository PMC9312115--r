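# End-to-end orchestration: simulate -> map -> preprocess -> segment ->
# cluster -> biomarker -> evaluate, with explicit seeds at every stage.

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run. All randomness derives from
#' `seed`; two runs with identical configs produce identical summaries.
#'
#' @param n_subjects,severity_mix Cohort composition (see [make_cohort()]).
#' @param shape Phantom side length in pixels.
#' @param snr Acquisition SNR (`NULL` = noiseless).
#' @param protocol A [mese_protocol()].
#' @param bias_field Apply receive-bias correction (the pipeline is robust
#'   with and without it; both variants are supported).
#' @param input_variant Stage-1 input: `"t2_pd"`, `"t2"`, `"pd"` or `"raw"`
#'   (the echo stack itself).
#' @param train_fraction Fraction of subjects used for training both stages.
#' @param unet An [unet_config()]; its `input_size` must match `shape`.
#' @param dcae A [dcae_config()].
#' @param stage2_method `"dcaetl"`, `"dcae_kmeans"`, `"dcae_dc"` or
#'   `"kmeans"`.
#' @param max_train_patches Cap on stage-2 training patches (subsampled
#'   deterministically when exceeded).
#' @param seed Master seed.
#' @param out_dir Output directory for artifacts, or `NULL` to keep results
#'   in memory only.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 12L,
                            severity_mix = c(mild = 4L, moderate = 4L, severe = 4L),
                            shape = 128L, snr = 50,
                            protocol = mese_protocol(),
                            bias_field = TRUE,
                            input_variant = c("t2_pd", "t2", "pd", "raw"),
                            train_fraction = 0.5,
                            unet = unet_config(input_size = 128L),
                            dcae = dcae_config(),
                            stage2_method = c("dcaetl", "dcae_kmeans", "dcae_dc", "kmeans"),
                            max_train_patches = 2000L,
                            seed = 1L, out_dir = NULL) {
  input_variant <- match.arg(input_variant)
  stage2_method <- match.arg(stage2_method)
  want_ch <- switch(input_variant, t2_pd = 2L, t2 = 1L, pd = 1L,
                    raw = protocol$n_echoes)
  if (unet$in_channels != want_ch) {
    unet$in_channels <- want_ch
  }
  if (unet$input_size != shape) unet$input_size <- as.integer(shape)
  structure(list(n_subjects = as.integer(n_subjects), severity_mix = severity_mix,
                 shape = as.integer(shape), snr = snr, protocol = protocol,
                 bias_field = bias_field, input_variant = input_variant,
                 train_fraction = train_fraction, unet = unet, dcae = dcae,
                 stage2_method = stage2_method,
                 max_train_patches = as.integer(max_train_patches),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

# stage-1 network input stack for one subject (H x W x C), plus the maps and
# fat-fraction image reused downstream
prepare_subject <- function(subject, dictionary, config) {
  series <- subject$series
  bias <- NULL
  if (config$bias_field) {
    bc <- correct_receiver_bias(series)
    series <- bc$series
    bias <- bc$bias_field_estimate
  }
  maps <- fit_t2_pd(series, dictionary)
  t2 <- maps$t2; t2[is.na(t2)] <- 0
  pd <- maps$pd; pd[is.na(pd)] <- 0
  t2n <- normalize_input(t2)$map
  pdn <- normalize_input(pd)$map
  input <- switch(config$input_variant,
    t2_pd = array(c(t2n, pdn), dim = c(dim(t2), 2L)),
    t2 = array(t2n, dim = c(dim(t2), 1L)),
    pd = array(pdn, dim = c(dim(t2), 1L)),
    raw = {
      ne <- dim(series$data)[3]
      out <- array(0, dim = dim(series$data))
      for (k in seq_len(ne)) out[, , k] <- normalize_input(series$data[, , k])$map
      out
    })
  list(series = series, maps = maps, t2n = t2n, pdn = pdn, input = input,
       bias_field = bias)
}

#' Run the full two-stage pipeline on a synthetic cohort
#'
#' Simulates the cohort, fits parametric maps, preprocesses, trains the
#' stage-1 U-net on the training subjects, derives weak labels from the
#' two-compartment fat fraction, trains the configured stage-2 clusterer,
#' classifies every test subject, and computes the IMAT-fraction biomarker
#' with its agreement against ground truth.
#'
#' @param config A [pipeline_config()].
#' @param dictionary Optional prebuilt dictionary (built from
#'   `config$protocol` when absent).
#' @param verbose Print stage progress.
#' @return An object of class `pipeline_result`: `summary` (list with
#'   stage-1 Dice, stage-2 metrics, biomarker regression), `per_subject`
#'   (data.frame), `manifest`, and the trained models. When
#'   `config$out_dir` is set, maps/masks/label maps are written as NIfTI and
#'   the summary as JSON.
#' @export
run_pipeline <- function(config, dictionary = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.null(dictionary)) dictionary <- build_dictionary(config$protocol)

  say("seed audit: master %d | cohort %d | unet %d | dcae %d | kmeans %d",
      config$seed, child_seed(config$seed, 1L), config$unet$seed,
      config$dcae$seed, child_seed(config$seed, 29L))
  say("[1/6] simulating %d-subject cohort", config$n_subjects)
  cohort <- make_cohort(config$n_subjects, config$severity_mix,
                        out_dir = NULL, seed = config$seed,
                        shape = config$shape, protocol = config$protocol,
                        dictionary = dictionary, snr = config$snr)
  n <- config$n_subjects
  # stratified split so the training set spans all severity bands present
  idx_train <- integer(0)
  for (sev in unique(cohort$manifest$severity)) {
    members <- which(cohort$manifest$severity == sev)
    take <- max(1L, round(config$train_fraction * length(members)))
    idx_train <- c(idx_train, members[seq_len(take)])
  }
  idx_train <- sort(idx_train)
  if (length(idx_train) < 2L) idx_train <- seq_len(min(2L, n))
  n_train <- length(idx_train)
  idx_test <- setdiff(seq_len(n), idx_train)
  if (!length(idx_test)) idx_test <- idx_train  # degenerate tiny cohorts

  say("[2/6] fitting parametric maps")
  prep <- lapply(cohort$subjects, prepare_subject, dictionary = dictionary,
                 config = config)

  say("[3/6] training stage-1 U-net (%d subjects)", n_train)
  h <- config$shape
  nc <- dim(prep[[1]]$input)[3]
  X <- array(0, dim = c(h, h, nc, n_train))
  M <- array(0, dim = c(h, h, n_train))
  for (i in seq_along(idx_train)) {
    X[, , , i] <- prep[[idx_train[i]]]$input
    M[, , i] <- cohort$subjects[[idx_train[i]]]$truth$muscle_region_mask
  }
  unet <- train_stage1(X, M, config$unet)

  say("[4/6] deriving weak labels and training stage-2 (%s)", config$stage2_method)
  train_sets <- list()
  for (i in idx_train) {
    truth <- cohort$subjects[[i]]$truth
    musc <- truth$muscle_region_mask
    ff <- fit_two_component(prep[[i]]$series, dictionary, mask = musc,
                            maps = prep[[i]]$maps)$fat_fraction
    weak <- label_tissue_gt(ff, musc)
    train_sets[[length(train_sets) + 1L]] <-
      extract_patches(prep[[i]]$t2n, prep[[i]]$pdn, musc, weak)
  }
  patchset <- combine_patch_sets(train_sets)
  m <- dim(patchset$patches)[4]
  if (m > config$max_train_patches) {
    keep <- with_seed(child_seed(config$seed, 23L),
                      sort(sample.int(m, config$max_train_patches)))
    patchset$patches <- patchset$patches[, , , keep, drop = FALSE]
    patchset$centers <- patchset$centers[keep, , drop = FALSE]
    patchset$weak_labels <- patchset$weak_labels[keep]
    patchset$source_slice <- patchset$source_slice[keep]
  }
  cluster_model <- switch(config$stage2_method,
    dcaetl = {
      enc <- train_dcaetl(patchset, config$dcae)
      fit_clusters(enc, patchset, seed = child_seed(config$seed, 29L))
    },
    dcae_kmeans = train_dcae_kmeans(patchset, config$dcae,
                                    seed = child_seed(config$seed, 29L)),
    dcae_dc = train_dcae_dc(patchset, config$dcae),
    kmeans = NULL)

  say("[5/6] segmenting and classifying all %d subjects", n)
  per <- data.frame()
  for (i in seq_len(n)) {
    truth <- cohort$subjects[[i]]$truth
    pred_mask <- predict_muscle_mask(unet, prep[[i]]$input)
    d1 <- dice(pred_mask, truth$muscle_region_mask)
    tl <- truth_label_map(truth)
    # weak labels on the predicted mask only where needed for the kmeans fallback
    pred_labels <- if (config$stage2_method == "kmeans") {
      ff <- fit_two_component(prep[[i]]$series, dictionary, mask = pred_mask,
                              maps = prep[[i]]$maps)$fat_fraction
      weak <- label_tissue_gt(ff, pred_mask)
      baseline_intensity_kmeans(prep[[i]]$t2n, prep[[i]]$pdn, pred_mask,
                                seed = child_seed(config$seed, 31L),
                                weak_label_map = weak)
    } else {
      classify_pixels(cluster_model, prep[[i]]$t2n, prep[[i]]$pdn, pred_mask)
    }
    ev <- evaluate_labels(pred_labels, tl, mask = pred_mask & truth$muscle_region_mask)
    rep_i <- biomarker_report(pred_labels, cohort$manifest$subject_id[i])
    per <- rbind(per, cbind(rep_i,
                            imat_fraction_true = truth$imat_fraction_true,
                            severity_true = severity_class(truth$imat_fraction_true),
                            is_test = i %in% idx_test,
                            dice_stage1 = d1, ev))
  }
  say("[6/6] biomarker agreement over %d subjects", nrow(per))
  agree <- if (nrow(per) >= 3L) {
    cohort_agreement(per$imat_fraction_true, per$imat_fraction)
  } else NULL
  test_rows <- per[per$is_test, , drop = FALSE]
  summary <- list(
    stage1_dice_mean = mean(test_rows$dice_stage1),
    stage2 = list(dice_viable = mean(test_rows$dice_viable),
                  dice_imat = mean(test_rows$dice_imat),
                  acc = mean(test_rows$acc), nmi = mean(test_rows$nmi),
                  ari = mean(test_rows$ari)),
    biomarker = agree,
    severity_agreement = mean(per$severity == per$severity_true),
    n_train = n_train, n_test = length(idx_test),
    stage2_method = config$stage2_method, seed = config$seed
  )
  result <- structure(list(summary = summary, per_subject = per,
                           manifest = cohort$manifest, unet = unet,
                           cluster_model = cluster_model, config = config),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_artifacts(result, cohort, prep)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("pipeline_result (%s): stage-1 Dice %.3f | stage-2 Dice v/i %.3f/%.3f ACC %.3f | biomarker r %s | severity %s\n",
              s$stage2_method, s$stage1_dice_mean, s$stage2$dice_viable,
              s$stage2$dice_imat, s$stage2$acc,
              if (is.null(s$biomarker)) "NA" else sprintf("%.3f", s$biomarker$pearson_r),
              fmt_pct(s$severity_agreement)))
  invisible(x)
}

write_pipeline_artifacts <- function(result, cohort, prep) {
  od <- result$config$out_dir
  dir.create(od, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$per_subject, file.path(od, "per_subject.csv"),
                   row.names = FALSE)
  utils::write.csv(result$manifest, file.path(od, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(result$summary, file.path(od, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (i in seq_along(prep)) {
    id <- result$manifest$subject_id[i]
    t2 <- prep[[i]]$maps$t2; t2[is.na(t2)] <- 0
    RNifti::writeNifti(RNifti::asNifti(t2), file.path(od, paste0(id, "_t2.nii.gz")))
  }
  invisible(od)
}

#' Leave-one-subject-out cross-validation of stage 1
#'
#' Trains the stage-1 U-net excluding each subject in turn and evaluates the
#' muscle-region Dice on the held-out subject. Folds are defined per subject,
#' never per slice.
#'
#' @param config A [pipeline_config()]; `n_subjects` must be >= 3.
#' @param dictionary Optional prebuilt dictionary.
#' @param verbose Print per-fold progress.
#' @return A list with `per_fold` (data.frame subject_id/dice) and
#'   `mean_dice`.
#' @export
run_lopo <- function(config, dictionary = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$n_subjects < 3L) stop("LOPO needs at least 3 subjects", call. = FALSE)
  if (is.null(dictionary)) dictionary <- build_dictionary(config$protocol)
  cohort <- make_cohort(config$n_subjects, config$severity_mix,
                        out_dir = NULL, seed = config$seed,
                        shape = config$shape, protocol = config$protocol,
                        dictionary = dictionary, snr = config$snr)
  prep <- lapply(cohort$subjects, prepare_subject, dictionary = dictionary,
                 config = config)
  n <- config$n_subjects
  h <- config$shape
  nc <- dim(prep[[1]]$input)[3]
  out <- data.frame()
  for (fold in seq_len(n)) {
    tr <- setdiff(seq_len(n), fold)
    X <- array(0, dim = c(h, h, nc, length(tr)))
    M <- array(0, dim = c(h, h, length(tr)))
    for (i in seq_along(tr)) {
      X[, , , i] <- prep[[tr[i]]]$input
      M[, , i] <- cohort$subjects[[tr[i]]]$truth$muscle_region_mask
    }
    cfg_f <- config$unet
    cfg_f$seed <- child_seed(config$unet$seed, 400L + fold)
    model <- train_stage1(X, M, cfg_f)
    pm <- predict_muscle_mask(model, prep[[fold]]$input)
    d <- dice(pm, cohort$subjects[[fold]]$truth$muscle_region_mask)
    if (verbose) message(sprintf("fold %d (%s): Dice %.3f", fold,
                                 cohort$manifest$subject_id[fold], d))
    out <- rbind(out, data.frame(subject_id = cohort$manifest$subject_id[fold],
                                 dice = d))
  }
  list(per_fold = out, mean_dice = mean(out$dice))
}
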
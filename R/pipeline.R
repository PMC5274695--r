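#' Run the full classification pipeline end to end
#'
#' Orchestrates phantom generation (or a supplied patch list), 8-fold
#' augmentation, CLAHE, subband decomposition, dense SIFT statistics,
#' weighted fusion, CNN training and the chosen classification head,
#' and evaluates on a grouped held-out split (augmented variants of a
#' source patch never straddle the train/test boundary). Fully
#' reproducible given `seed`.
#'
#' @param n_per_class phantom patches per class (ignored when `patches`
#'   is supplied).
#' @param method decomposition branch, `"dwt"` or `"curvelet"`.
#' @param head `"svm"`, `"softmax"`, or `"svm-cv10"` (10-fold grouped
#'   cross-validation instead of a single split).
#' @param patches optional list of labeled `mammo_patch` to use instead
#'   of phantoms.
#' @param phantom_cfg a [phantom_config()]; its seed is overridden by
#'   `seed`.
#' @param cnn_cfg a [cnn_config()]; its seed is overridden by `seed`.
#' @param test_fraction held-out fraction of source patches (single
#'   split heads only).
#' @param seed master seed for phantoms, splits and CNN training.
#' @param out_dir optional directory; when given, the data matrix
#'   (CSV), training history and the JSON report are written there
#'   together with a small run manifest.
#' @param verbose print stage progress.
#' @return list with `report` (a `metrics_report`, or the
#'   cross-validation summary for `head = "svm-cv10"`), `model`,
#'   `data` (the N x 785 matrix) and `config`.
#' @export
run_pipeline <- function(n_per_class = 20L,
                         method = c("dwt", "curvelet"),
                         head = c("svm", "softmax", "svm-cv10"),
                         patches = NULL,
                         phantom_cfg = phantom_config(),
                         cnn_cfg = cnn_config(),
                         test_fraction = 0.3,
                         seed = 1L,
                         out_dir = NULL,
                         verbose = FALSE) {
  method <- match.arg(method)
  head <- match.arg(head)
  t_all <- Sys.time()
  say <- function(stage, t0) if (verbose)
    message(sprintf("[%s] %s (%.1fs)", format(Sys.time(), "%H:%M:%S"),
                    stage, as.numeric(Sys.time() - t0, units = "secs")))
  if (is.null(patches)) {
    t0 <- Sys.time()
    phantom_cfg$seed <- as.integer(seed)
    patches <- generate_dataset(n_per_class, phantom_cfg)
    say("phantom generation", t0)
  }
  t0 <- Sys.time()
  data <- build_data_matrix(patches, method = method)
  say(paste("feature extraction,", method, "branch"), t0)
  grp <- attr(data, "group")
  y <- as.integer(data[, 785])
  cnn_cfg$seed <- as.integer(seed)
  if (head == "svm-cv10") {
    plan <- make_folds(y, k = 10L, groups = grp, seed = seed)
    t0 <- Sys.time()
    cv <- cross_validate(data, plan, cnn_cfg = cnn_cfg, head = "svm")
    say("10-fold cross-validation", t0)
    report <- cv
    model <- NULL
  } else {
    # grouped stratified held-out split: source patches, not rows
    src_lab <- tapply(y, grp, function(v) v[1])
    old <- .Random.seed_exists(); set.seed(seed + 1L)
    test_groups <- unlist(lapply(sort(unique(src_lab)), function(cl) {
      g <- names(src_lab)[src_lab == cl]
      sample(g, max(1, round(length(g) * test_fraction)))
    }))
    restore_seed(old)
    te <- as.character(grp) %in% test_groups
    tr <- !te
    t0 <- Sys.time()
    model <- cnn_train(cnn_cfg, data[tr, 1:784, drop = FALSE], y[tr])
    say("CNN training", t0)
    t0 <- Sys.time()
    if (head == "svm") {
      ftr <- penultimate_features(model, data[tr, 1:784, drop = FALSE])
      fte <- penultimate_features(model, data[te, 1:784, drop = FALSE])
      sv <- svm_fit(ftr, y[tr])
      pred <- svm_predict(sv, fte)
      scores <- svm_decision(sv, fte)
    } else {
      scores <- cnn_forward(model, data[te, 1:784, drop = FALSE])
      pred <- max.col(scores, ties.method = "first") - 1L
    }
    report <- metrics_report(y[te], pred, scores)
    say(paste(head, "head + evaluation"), t0)
  }
  cfg_out <- list(method = method, head = head, seed = seed,
                  n_per_class = if (is.null(patches)) n_per_class
                  else NA_integer_,
                  test_fraction = test_fraction)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(as.data.frame(data),
                     file.path(out_dir, "data_matrix.csv"),
                     row.names = FALSE)
    if (!is.null(model))
      utils::write.csv(model$history,
                       file.path(out_dir, "training_log.csv"),
                       row.names = FALSE)
    rep_json <- if (head == "svm-cv10")
      list(mean_accuracy = report$accuracy, macro = as.list(report$mean_report$macro))
    else list(overall_accuracy = report$overall_accuracy,
              per_class = report$per_class,
              macro = as.list(report$macro))
    jsonlite::write_json(rep_json, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest <- list(config = cfg_out,
                     n_rows = nrow(data),
                     data_hash = digest_rows(data),
                     timestamp = format(Sys.time(), usetz = TRUE))
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE)
  }
  say("pipeline total", t_all)
  list(report = report, model = model, data = data, config = cfg_out)
}

# content hash of a numeric matrix (modular polynomial hash over a
# subsampled, rounded byte stream); enough to detect any change to the
# data matrix across runs
digest_rows <- function(m) {
  v <- floor(abs(as.vector(m)) * 1e4) %% 256
  v <- v[seq(1, length(v), by = max(1, length(v) %/% 4096))]
  h <- 5381
  for (byte in v) h <- (h * 33 + byte) %% 2^31
  sprintf("%08x", as.integer(h))
}
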
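#' Pipeline configuration
#'
#' Settings for the end-to-end study: simulate phantoms, encrypt and
#' decrypt them (asserting the lossless round trip before anything
#' downstream sees the images), run the security analysis, optionally
#' reduce/segment, train the fuzzy convolutional classifier on the
#' decrypted images and evaluate it on a held-out split.
#'
#' @param n_images number of phantoms.
#' @param tumour_fraction fraction of positives.
#' @param phantom a [phantom_config()].
#' @param key a [chaos_key()].
#' @param cipher a [cipher_config()].
#' @param encrypt,ipca,segment stage toggles.
#' @param fcnn list of classifier settings (`n_kernels`, `kernel_size`,
#'   `pool_grid`, `epochs`, `rates`).
#' @param split training fraction of the train/test split.
#' @param n_pairs correlation sample size for the security report.
#' @param seed master seed recorded in the report.
#' @param report_path optional path for a JSON run report.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_images = 50L, tumour_fraction = 0.5,
                            phantom = phantom_config(width = 32L,
                                                     height = 32L,
                                                     tumour_radius = c(3, 6)),
                            key = chaos_key(),
                            cipher = cipher_config(),
                            encrypt = TRUE, ipca = TRUE, segment = TRUE,
                            fcnn = list(n_kernels = 4L, kernel_size = 3L,
                                        pool_grid = c(2L, 2L),
                                        epochs = 40L,
                                        rates = list(fc = 0.5, my = 0.05,
                                                     mz = 0.02, mx = 0.02)),
                            split = 0.75, n_pairs = 400L, seed = 7L,
                            report_path = NULL) {
  if (split <= 0 || split >= 1) stop("`split` must lie in (0, 1)")
  structure(list(n_images = as.integer(n_images),
                 tumour_fraction = tumour_fraction, phantom = phantom,
                 key = key, cipher = cipher, encrypt = encrypt,
                 ipca = ipca, segment = segment, fcnn = fcnn,
                 split = split, n_pairs = as.integer(n_pairs),
                 seed = as.integer(seed), report_path = report_path),
            class = "pipeline_config")
}

#' Run the full simulate-encrypt-classify pipeline
#'
#' Executes the enabled stages in order. When encryption is enabled every
#' image is encrypted and decrypted and the round trip is asserted to be
#' bit-exact before classification proceeds; a mismatch aborts the run.
#' The report carries every seed and setting needed to reproduce it.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_report` with `security`,
#'   `classification`, optional `ipca`/`segmentation` sections and the
#'   seeds/config echo.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  ds <- generate_dataset(config$n_images, config$tumour_fraction,
                         config$phantom, config$seed)
  report <- list(seed = config$seed, n_images = config$n_images,
                 package_version = as.character(
                   utils::packageVersion("medimcrypt")))
  images <- ds$images
  if (isTRUE(config$encrypt)) {
    if (config$cipher$use_compression)
      stop("the classification pipeline requires the lossless cipher mode")
    for (i in seq_along(images)) {
      enc <- encrypt_image(images[[i]], config$key, config$cipher)
      dec <- decrypt_image(enc, config$key)
      if (!identical(dec, images[[i]]))
        stop("stage encrypt: decrypted image ", i,
             " differs from the original; aborting before classification")
      images[[i]] <- dec
    }
    sec <- security_report(images[[1]], config$key, config$cipher,
                           n_pairs = config$n_pairs, seed = config$seed)
    report$security <- list(entropy_plain = sec$entropy_plain,
                            entropy_cipher = sec$entropy_cipher,
                            correlation_plain = as.list(sec$correlation_plain),
                            correlation_cipher = as.list(sec$correlation_cipher),
                            npcr = sec$npcr, uaci = sec$uaci)
  }
  if (isTRUE(config$ipca)) {
    flat <- t(vapply(images, function(im) as.numeric(im),
                     numeric(length(images[[1]]))))
    fit <- fit_ipca(flat, threshold = 0.85)
    report$ipca <- list(n_selected = fit$n_selected,
                        cumulative = fit$cumulative[fit$n_selected])
  }
  if (isTRUE(config$segment)) {
    pos <- which(ds$labels == 1)[1]
    seg <- segment_image(images[[pos]], k = 3L, seed = config$seed)
    mask <- ds$masks[[pos]]
    report$segmentation <- list(
      k = 3L, centers = as.numeric(seg$centers),
      tumour_top_label_fraction =
        mean(seg$labels[mask] == max(seg$labels)))
  }
  set.seed(config$seed)
  n <- length(images)
  n_train <- round(config$split * n)
  idx <- sample.int(n)
  tr <- idx[seq_len(n_train)]; te <- idx[-seq_len(n_train)]
  if (length(unique(ds$labels[tr])) < 2L || length(te) < 1L)
    stop("train/test split left a degenerate class distribution")
  fc <- config$fcnn
  model <- fcnn_model(n_kernels = fc$n_kernels,
                      kernel_size = fc$kernel_size,
                      pool_grid = fc$pool_grid, seed = config$seed)
  model <- fcnn_train(model, images[tr], ds$labels[tr],
                      epochs = fc$epochs, rates = fc$rates)
  pred <- fcnn_predict(model, images[te])
  cm <- confusion_counts(pred$class, ds$labels[te])
  report$classification <- list(
    n_train = length(tr), n_test = length(te),
    confusion = cm,
    metrics = as.list(classification_metrics(cm)),
    final_loss = utils::tail(attr(model, "loss"), 1))
  if (!is.null(config$report_path))
    jsonlite::write_json(report, config$report_path, auto_unbox = TRUE,
                         digits = NA)
  structure(report, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> seed", x$seed, "|", x$n_images, "phantoms\n")
  if (!is.null(x$security))
    cat(sprintf("  cipher: entropy %.4f, NPCR %.2f%%, UACI %.2f%%\n",
                x$security$entropy_cipher, x$security$npcr,
                x$security$uaci))
  if (!is.null(x$classification)) {
    m <- x$classification$metrics
    cat(sprintf("  classifier: accuracy %.3f, sensitivity %.3f, specificity %.3f (n_test %d)\n",
                m$accuracy, m$sensitivity, m$specificity,
                x$classification$n_test))
  }
  invisible(x)
}
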
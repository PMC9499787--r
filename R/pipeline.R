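# End-to-end orchestration: synthesize labeled records, preprocess
# (baseline subtraction + denoising), resample to the classifier rate,
# detect onsets, cut augmented segments, split, train and evaluate. Each
# stage block of the summary can also be produced by calling the module
# functions directly; this file only wires them together.

#' Per-class segment counts of the reference dataset layout
#'
#' The ten-class segment inventory the pipeline reproduces by default:
#' 59, 49, 79, 63, 63, 130, 54, 60, 50, 70 segments (677 in total) for
#' Changmai ... Xuanmai respectively.
#'
#' @return Named integer vector over [mai_classes()].
#' @export
#' @examples
#' sum(mai_segment_counts())
mai_segment_counts <- function() {
  c(
    Changmai = 59L, Chimai = 49L, Dongmai = 79L, Huamai = 63L, Huanmai = 63L,
    Jimai = 130L, Pingmai = 54L, Shimai = 60L, Weimai = 50L, Xuanmai = 70L
  )
}

#' Synthesize a labeled segment dataset through the full preprocessing path
#'
#' Generates synthetic records per class, subtracts the baseline, denoises
#' (wavelet by default), resamples to `out_fs`, detects beat onsets and cuts
#' overlapping onset-anchored segments, then keeps exactly the requested
#' number of segments per class.
#'
#' @param counts Named class -> segment-count map (default
#'   [mai_segment_counts()], 677 segments).
#' @param duration,fs,noise Record synthesis parameters (see
#'   [synthesize_record()]).
#' @param denoise `"wavelet"`, `"eemd"` or `"none"`.
#' @param out_fs,segment_length Resampling rate and segment length.
#' @param seed Base seed; fully deterministic given the seed.
#' @return A `segment_set` with exactly `sum(counts)` rows.
#' @export
synthesize_segment_dataset <- function(counts = mai_segment_counts(),
                                       duration = 12, fs = 200,
                                       noise = noise_spec(),
                                       denoise = c("wavelet", "eemd", "none"),
                                       out_fs = 50, segment_length = 300,
                                       seed = 0L) {
  denoise <- match.arg(denoise)
  counts <- unlist(counts)
  purrr::walk(names(counts), assert_mai_class)

  sets <- purrr::map(names(counts), function(cls) {
    needed <- counts[[cls]]
    got <- list()
    n_got <- 0
    rec_i <- 0
    while (n_got < needed) {
      rec_i <- rec_i + 1
      if (rec_i > 50 * length(counts)) {
        abort_pulsekit("Segment synthesis failed to reach the requested count.",
          "pulsekit_internal")
      }
      rec_seed <- derive_seed(seed, cls, rec_i)
      template <- make_template(cls, seed = rec_seed)
      rec <- synthesize_record(template, duration, fs, noise, seed = rec_seed)
      attr(rec, "source_id") <- sprintf("synth-%s-%03d", cls, rec_i)
      segs <- process_record_to_segments(rec, denoise, out_fs, segment_length)
      if (nrow(segs) > 0) {
        got[[length(got) + 1]] <- segs
        n_got <- n_got + nrow(segs)
      }
    }
    out <- combine_segments(got)
    out[seq_len(needed), ]
  })
  out <- dplyr::bind_rows(sets)
  class(out) <- c("segment_set", class(out))
  attr(out, "segment_length") <- as.integer(segment_length)
  out
}

process_record_to_segments <- function(rec, denoise, out_fs, segment_length) {
  rec <- subtract_baseline(rec)
  rec <- switch(denoise,
    wavelet = denoise_wavelet(rec),
    eemd = denoise_eemd(rec),
    none = rec
  )
  series <- densify_resample(rec, out_fs = out_fs)
  fid <- tryCatch(detect_fiducials(series), pulsekit_no_main_wave = function(e) NULL)
  if (is.null(fid) || nrow(fid) == 0) {
    return(segment_at_onsets(series, integer(0), length = segment_length))
  }
  suppressWarnings(segment_at_onsets(series, fid$b, length = segment_length))
}

#' Pipeline configuration
#'
#' Collects every stage parameter in one validated list; unknown arguments
#' are rejected.
#'
#' @param seed Global seed.
#' @param counts Class -> segment counts (default [mai_segment_counts()]).
#' @param duration,fs Record synthesis length (s) and rate (Hz).
#' @param noise A [noise_spec()].
#' @param denoise_method `"wavelet"` (default) or `"eemd"`.
#' @param out_fs,segment_length Classifier sampling rate and input length.
#' @param ratio Train:test ratio (default `c(7, 3)`).
#' @param epochs Training epochs (default 50).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 0L, counts = mai_segment_counts(),
                            duration = 12, fs = 200, noise = noise_spec(),
                            denoise_method = "wavelet", out_fs = 50,
                            segment_length = 300, ratio = c(7, 3),
                            epochs = 50) {
  structure(
    list(
      seed = as.integer(seed), counts = counts, duration = duration, fs = fs,
      noise = noise, denoise_method = denoise_method, out_fs = out_fs,
      segment_length = segment_length, ratio = ratio, epochs = epochs
    ),
    class = "pipeline_config"
  )
}

#' Run the full pulse-analysis pipeline
#'
#' Executes synth -> denoise -> fiducials -> features -> segment -> train ->
#' evaluate on synthetic data and returns a summary with one block per
#' stage. When `out` is given, the summary is also written as JSON together
#' with the confusion matrix as CSV.
#'
#' @param config A [pipeline_config()].
#' @param out Optional output directory.
#' @param verbose Print per-epoch training progress.
#' @return A list with elements `synth`, `denoise`, `fiducials`, `features`,
#'   `segment`, `train`, `evaluate`, plus `model` and `split`.
#' @export
run_pipeline <- function(config = pipeline_config(), out = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))

  # inspection record: first class, first seed — used for the per-stage
  # denoising / fiducial / feature report blocks
  cls1 <- names(config$counts)[1]
  rec_seed <- derive_seed(config$seed, cls1, 1)
  rec <- synthesize_record(make_template(cls1, rec_seed), config$duration,
    config$fs, config$noise, seed = rec_seed)
  rec_b <- subtract_baseline(rec)
  den <- if (config$denoise_method == "eemd") denoise_eemd(rec_b) else
    denoise_wavelet(rec_b)
  fid <- detect_fiducials(den)
  feat <- wavelet_energy(den)

  segments <- synthesize_segment_dataset(
    counts = config$counts, duration = config$duration, fs = config$fs,
    noise = config$noise, denoise = config$denoise_method,
    out_fs = config$out_fs, segment_length = config$segment_length,
    seed = config$seed
  )
  split <- split_segments(segments, ratio = config$ratio, seed = config$seed)
  model <- train_cnn(split,
    config = cnn_config(
      input_length = config$segment_length, epochs = config$epochs
    ),
    seed = config$seed, verbose = verbose
  )
  report <- evaluate_cnn(model, split$test)

  summary <- list(
    synth = list(
      classes = names(config$counts), requested = unname(config$counts),
      total = sum(config$counts)
    ),
    denoise = attr(den, "denoise_report") %||% attr(den, "eemd_report"),
    fiducials = list(beats = nrow(fid), counts = as.list(attr(fid, "counts"))),
    features = list(
      coefficient = feat$coefficient, share = feat$share,
      low_band_share = sum(feat$share[feat$coefficient %in% c("cA5", "cD5")])
    ),
    segment = list(
      n_segments = nrow(segments), segment_length = config$segment_length,
      n_train = nrow(split$train), n_test = nrow(split$test)
    ),
    train = list(
      epochs = config$epochs,
      final_loss = model$history$loss[nrow(model$history)],
      final_train_accuracy = model$final_train_accuracy
    ),
    evaluate = list(
      accuracy = report$accuracy, macro_precision = report$macro_precision,
      macro_recall = report$macro_recall, macro_f1 = report$macro_f1
    ),
    seed = config$seed
  )

  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(summary, file.path(out, "summary.json"),
      auto_unbox = TRUE, digits = NA, force = TRUE)
    utils::write.csv(as.data.frame.matrix(report$confusion),
      file.path(out, "confusion.csv"))
  }

  invisible(c(summary, list(model = model, split = split, report = report)))
}
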
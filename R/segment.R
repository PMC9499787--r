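# Classifier input preparation: cubic-spline densification of the
# (possibly non-uniform) raw samples, uniform resampling at 50 Hz,
# onset-anchored 6 s / 300-sample segments with cross-interception
# augmentation, and the unstratified 7:3 train/test split.

#' Densify and uniformly resample a pulse record
#'
#' Fits a natural cubic spline through the (time, pressure) samples — the
#' continuous-time densification of the discrete record — and reads it off
#' at exactly `out_fs` samples per second from the first to the last
#' timestamp. This removes the slight non-uniformity of hardware sampling
#' clocks. Duplicate or decreasing timestamps are rejected.
#'
#' @param record A `pulse_record` (or data frame with `time`, `pressure`).
#' @param factor Nominal densification factor of the spline stage (kept for
#'   the pipeline's bookkeeping; the spline is evaluated exactly at the
#'   output grid, which is equivalent to densify-then-intercept for any
#'   factor).
#' @param out_fs Output sampling rate in Hz (default 50).
#' @return A uniformly sampled `pulse_record` at `out_fs` (spacing exactly
#'   `1/out_fs`), carrying over label and source attributes.
#' @export
densify_resample <- function(record, factor = 10, out_fs = 50) {
  validate_record(record)
  t0 <- record$time[1]
  t1 <- record$time[nrow(record)]
  if (t1 - t0 < 1) {
    abort_pulsekit("Record must span at least 1 s.", "pulsekit_bad_argument")
  }
  sf <- splinefun(record$time, record$pressure, method = "natural")
  t_out <- seq(t0, t1, by = 1 / out_fs)
  p_out <- sf(t_out)
  new_pulse_record(t_out, p_out,
    label = attr(record, "label"), fs_nominal = out_fs,
    source_id = attr(record, "source_id") %||% "record"
  )
}

#' Cut onset-anchored fixed-length segments
#'
#' One segment starts at every onset (b point) that still has `length`
#' samples remaining — successive onsets give overlapping windows, which is
#' the cross-interception augmentation. Each segment is optionally min-max
#' scaled to `[0, 1]`.
#'
#' @param series A uniformly sampled record (data frame) or numeric vector.
#' @param b_points Integer onset sample indices (1-based), e.g. the `b`
#'   column of [detect_fiducials()].
#' @param length Segment length in samples (default 300 = 6 s at 50 Hz).
#' @param scale Min-max scale each segment to `[0, 1]` (default `TRUE`).
#' @param label,source_id Metadata attached to every segment; default taken
#'   from the record's attributes.
#' @return A `segment_set` tibble: `segment_id`, `source_id`, `label`,
#'   `onset`, and a `values` list column of length-`length` vectors.
#' @export
segment_at_onsets <- function(series, b_points, length = 300, scale = TRUE,
                              label = NULL, source_id = NULL) {
  sig <- if (is.data.frame(series)) series$pressure else as.numeric(series)
  label <- label %||% attr(series, "label") %||% NA_character_
  source_id <- source_id %||% attr(series, "source_id") %||% "series"
  n <- base::length(sig)
  b_points <- sort(unique(as.integer(b_points)))
  eligible <- b_points[b_points >= 1 & (b_points + length - 1) <= n]
  if (base::length(eligible) == 0) {
    warn("No onset leaves a full segment; returning an empty segment set.")
  }
  values <- purrr::map(eligible, function(b) {
    seg <- sig[b:(b + length - 1)]
    if (scale) {
      rng <- range(seg)
      seg <- if (rng[2] > rng[1]) (seg - rng[1]) / (rng[2] - rng[1]) else seg * 0
    }
    seg
  })
  out <- tibble(
    segment_id = if (base::length(eligible)) {
      sprintf("%s#%04d", source_id, eligible)
    } else {
      character(0)
    },
    source_id = rep(source_id, base::length(eligible)),
    label = rep(label, base::length(eligible)),
    onset = eligible,
    values = values
  )
  class(out) <- c("segment_set", class(out))
  attr(out, "segment_length") <- as.integer(length)
  out
}

combine_segments <- function(sets) {
  out <- dplyr::bind_rows(sets)
  class(out) <- c("segment_set", class(out))
  attr(out, "segment_length") <- attr(sets[[1]], "segment_length")
  out
}

#' Segment matrix and labels
#'
#' @param segments A `segment_set`.
#' @return A list with `x` (matrix, one row per segment) and `y` (factor of
#'   labels over the ten Mai classes).
#' @export
segment_matrix <- function(segments) {
  list(
    x = do.call(rbind, segments$values),
    y = factor(segments$label, levels = mai_classes())
  )
}

#' Random train/test split of a segment set
#'
#' A single unstratified random partition (class proportions are left to
#' chance, matching a global random allocation), with floor-to-train
#' rounding: 677 segments at 7:3 give exactly (473, 204). An optional
#' grouped mode keeps all segments of one source record on the same side,
#' preventing overlapping windows of a record from leaking across the
#' split.
#'
#' @param segments A `segment_set` (>= 10 segments).
#' @param ratio Two positive numbers, train : test (default `c(7, 3)`).
#' @param seed Integer seed; the partition is deterministic given the seed.
#' @param group_by_record Keep segments of one `source_id` together
#'   (default `FALSE`).
#' @return A `split_dataset` list with `train` and `test` segment sets.
#' @export
split_segments <- function(segments, ratio = c(7, 3), seed = 0L,
                           group_by_record = FALSE) {
  if (!inherits(segments, "segment_set") || nrow(segments) < 10) {
    abort_pulsekit("Need a segment_set with at least 10 segments.",
      "pulsekit_bad_argument")
  }
  if (base::length(ratio) != 2 || any(ratio <= 0)) {
    abort_pulsekit("`ratio` must be two positive numbers.", "pulsekit_bad_argument")
  }
  ntot <- nrow(segments)
  n_train <- floor(ratio[1] / sum(ratio) * ntot)
  idx <- if (group_by_record) {
    sources <- unique(segments$source_id)
    shuffled <- with_seed(derive_seed(seed, "split"), sample(sources))
    take <- character(0)
    count <- 0
    for (s in shuffled) {
      if (count >= n_train) break
      take <- c(take, s)
      count <- count + sum(segments$source_id == s)
    }
    which(segments$source_id %in% take)
  } else {
    with_seed(derive_seed(seed, "split"), sample(ntot))[seq_len(n_train)]
  }
  subset_set <- function(rows) {
    out <- segments[rows, ]
    class(out) <- c("segment_set", class(segments))
    attr(out, "segment_length") <- attr(segments, "segment_length")
    out
  }
  structure(
    list(
      train = subset_set(sort(idx)),
      test = subset_set(setdiff(seq_len(ntot), idx)),
      ratio = ratio, seed = as.integer(seed)
    ),
    class = "split_dataset"
  )
}

#' @export
print.split_dataset <- function(x, ...) {
  cat(sprintf(
    "<split_dataset> %d train / %d test (ratio %g:%g, seed %d)\n",
    nrow(x$train), nrow(x$test), x$ratio[1], x$ratio[2], x$seed
  ))
  invisible(x)
}
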
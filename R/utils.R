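# Internal helpers shared across modules.

#' The ten Mai class labels
#'
#' Character vector of the ten traditional pulse (Mai) categories the
#' classifier distinguishes, in alphabetical order.
#'
#' @return A character vector of length 10.
#' @export
#' @examples
#' mai_classes()
mai_classes <- function() {
  c(
    "Changmai", "Chimai", "Dongmai", "Huamai", "Huanmai",
    "Jimai", "Pingmai", "Shimai", "Weimai", "Xuanmai"
  )
}

# Stop with a classed condition so callers/tests can match on error class.
abort_pulsekit <- function(message, class, ...) {
  abort(message, class = c(class, "pulsekit_error"), ...)
}

assert_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_pulsekit(sprintf("`%s` must be a single finite number.", name),
      "pulsekit_bad_argument")
  }
  if ((strict_min && x <= min) || (!strict_min && x < min)) {
    abort_pulsekit(
      sprintf("`%s` must be %s %s.", name, if (strict_min) ">" else ">=", format(min)),
      "pulsekit_bad_argument"
    )
  }
  invisible(x)
}

assert_mai_class <- function(label) {
  if (!is.character(label) || length(label) != 1L || !(label %in% mai_classes())) {
    abort_pulsekit(
      paste0(
        "Unknown pulse class ", deparse(label), ". Valid classes: ",
        paste(mai_classes(), collapse = ", "), "."
      ),
      "pulsekit_unknown_class"
    )
  }
  invisible(label)
}

# Extract a numeric signal + sampling rate from either a pulse_record
# data frame or a bare numeric vector (then `fs` must be supplied).
resolve_signal <- function(x, fs = NULL, arg = "x") {
  if (is.data.frame(x)) {
    if (!all(c("time", "pressure") %in% names(x))) {
      abort_pulsekit(
        sprintf("`%s` must have `time` and `pressure` columns.", arg),
        "pulsekit_bad_argument"
      )
    }
    fs <- fs %||% attr(x, "fs") %||% infer_fs(x$time)
    list(signal = x$pressure, fs = fs, time = x$time)
  } else if (is.numeric(x)) {
    if (is.null(fs)) {
      abort_pulsekit("`fs` must be supplied when the input is a bare numeric vector.",
        "pulsekit_bad_argument")
    }
    list(signal = as.numeric(x), fs = fs, time = seq_along(x) / fs - 1 / fs)
  } else {
    abort_pulsekit(sprintf("`%s` must be a data frame or numeric vector.", arg),
      "pulsekit_bad_argument")
  }
}

infer_fs <- function(time) {
  dt <- median(diff(time))
  if (!is.finite(dt) || dt <= 0) {
    abort_pulsekit("Cannot infer a sampling rate from the timestamps.",
      "pulsekit_bad_argument")
  }
  1 / dt
}

rel_l2 <- function(a, b) {
  denom <- sqrt(sum(b^2))
  if (denom == 0) return(sqrt(sum((a - b)^2)))
  sqrt(sum((a - b)^2)) / denom
}

# Deterministic 32-bit sub-seed from a base seed and a stream of integers /
# strings, kept below 2^31 so set.seed() accepts it.
derive_seed <- function(seed, ...) {
  parts <- c(seed, vapply(list(...), function(p) {
    if (is.character(p)) sum(utf8ToInt(p) * seq_along(utf8ToInt(p))) else as.numeric(p)
  }, numeric(1)))
  s <- 0
  for (p in parts) s <- (s * 69069 + (p %% 2147483647) + 1) %% 2147483647
  as.integer(s)
}

# Evaluate `expr` with a locally-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

local_minima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] < x[1:(n - 2)] & x[2:(n - 1)] <= x[3:n]) + 1L
}

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}
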
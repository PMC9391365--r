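#' Online feedback primitives
#'
#' The real-time feedback value shown to the participant is derived from the
#' raw SN/VTA region average in three steps: (i) a reference level, the mean of
#' the last five volumes of the preceding REST block (robust to slow drift and
#' motion); (ii) a moving average over the current and up to two preceding
#' volumes to suppress high-frequency noise; (iii) the percent signal change of
#' the moving average against the reference, sign-flipped in the inverted arm
#' and clamped to +/- `clamp_psc` percent for display.
#'
#' @param rest_tail numeric vector of exactly five raw samples (the REST tail).
#' @return `fb_reference`: the arithmetic mean of the five samples.
#' @export
fb_reference <- function(rest_tail) {
  if (length(rest_tail) != 5)
    stop("reference requires exactly 5 REST samples (incomplete REST block)")
  mean(rest_tail)
}

#' @rdname fb_reference
#' @param samples most recent raw samples, oldest first; at most the last three
#'   are used.
#' @export
fb_moving_average <- function(samples) {
  n <- length(samples)
  if (n == 0) stop("moving average of an empty stream")
  mean(samples[max(1, n - 2):n])
}

#' @rdname fb_reference
#' @param value current (smoothed) signal value.
#' @param reference reference level; must be non-zero.
#' @export
psc <- function(value, reference) {
  if (any(reference == 0)) stop("reference is zero (degenerate baseline)")
  100 * (value - reference) / reference
}

#' Create a streaming feedback engine
#'
#' The engine is a small state machine stepped once per acquired volume with
#' [fb_step()]. It maintains the rolling REST tail, the current reference and
#' the last three raw samples, and emits one feedback-trace row per volume.
#' Until the first REST block has completed, no reference exists and the trace
#' rows are marked invalid (nothing would be displayed). A new reference is
#' latched at every REST to IMAGINE_REWARD transition; feedback continues to be
#' computed against the most recent reference during subsequent REST blocks.
#'
#' @param polarity "standard" (display rises with increasing PSC) or
#'   "inverted" (display rises with decreasing PSC).
#' @param clamp_psc display saturation in percent signal change; the displayed
#'   value is the polarity-signed PSC clamped to `[-clamp_psc, clamp_psc]`.
#' @param window moving-average window in volumes (current volume inclusive).
#' @param ref_window number of trailing REST volumes averaged into the
#'   reference.
#' @return an environment of class `fb_engine` holding the mutable state.
#' @examples
#' eng <- fb_engine("standard")
#' lab <- c(rep("REST", 10), rep("IMAGINE_REWARD", 3))
#' raw <- c(rep(100, 10), 102, 102, 102)
#' trace <- do.call(rbind, Map(function(x, l) fb_step(eng, x, l), raw, lab))
#' @export
fb_engine <- function(polarity = c("standard", "inverted"), clamp_psc = 2,
                      window = 3, ref_window = 5) {
  polarity <- match.arg(polarity)
  stopifnot(clamp_psc > 0, window >= 1, ref_window >= 1)
  e <- new.env(parent = emptyenv())
  e$polarity <- polarity
  e$clamp_psc <- clamp_psc
  e$window <- window
  e$ref_window <- ref_window
  e$reference <- NA_real_
  e$recent <- numeric(0)     # last <= window raw samples
  e$rest_tail <- numeric(0)  # last <= ref_window samples of the ongoing REST block
  e$prev_condition <- NA_character_
  class(e) <- "fb_engine"
  e
}

# core step: updates the engine in place, returns c(ma, reference, psc, displayed)
# (displayed and psc are NA while no reference exists)
fb_step_core <- function(engine, raw, condition) {
  # latch a new reference when REST completes and IMAGINE begins
  if (condition == "IMAGINE_REWARD" && identical(engine$prev_condition, "REST")) {
    if (length(engine$rest_tail) < engine$ref_window)
      stop("REST block completed with fewer samples than the reference window")
    engine$reference <- mean(engine$rest_tail)
  }
  if (condition == "REST" && !identical(engine$prev_condition, "REST"))
    engine$rest_tail <- numeric(0)

  engine$recent <- c(engine$recent, raw)
  if (length(engine$recent) > engine$window)
    engine$recent <- engine$recent[-1]
  if (condition == "REST") {
    engine$rest_tail <- c(engine$rest_tail, raw)
    if (length(engine$rest_tail) > engine$ref_window)
      engine$rest_tail <- engine$rest_tail[-1]
  }
  engine$prev_condition <- condition

  ma <- mean(engine$recent)
  if (is.na(engine$reference)) {
    p <- NA_real_
    d <- NA_real_
  } else {
    p <- psc(ma, engine$reference)
    d <- if (engine$polarity == "inverted") -p else p
    d <- max(-engine$clamp_psc, min(engine$clamp_psc, d))
  }
  c(ma, engine$reference, p, d)
}

#' Advance the feedback engine by one volume
#'
#' @param engine an engine created by [fb_engine()].
#' @param raw raw region-average signal of the current volume.
#' @param condition condition label of the current volume (`REST`,
#'   `IMAGINE_REWARD` or `LEAD_IN`).
#' @return one-row data.frame with columns `raw`, `moving_average`,
#'   `reference`, `psc`, `displayed`, `valid`. The engine is updated in place.
#' @export
fb_step <- function(engine, raw, condition) {
  s <- fb_step_core(engine, raw, condition)
  data.frame(raw = raw, moving_average = s[1], reference = s[2],
             psc = s[3], displayed = s[4], valid = !is.na(s[2]))
}

#' Replay a whole run through the feedback engine
#'
#' Batch equivalent of stepping [fb_step()] over every volume in order; the
#' result is bit-identical to streaming because the same state machine is run.
#'
#' @inheritParams fb_engine
#' @param raw numeric vector of raw region-average samples, one per volume.
#' @param conditions per-volume condition labels (same length as `raw`).
#' @return data.frame of class `fb_trace` with one row per volume (columns as
#'   in [fb_step()], plus `volume`).
#' @export
fb_replay <- function(raw, conditions, polarity = "standard", clamp_psc = 2,
                      window = 3, ref_window = 5) {
  stopifnot(length(raw) == length(conditions))
  eng <- fb_engine(polarity, clamp_psc, window, ref_window)
  n <- length(raw)
  ma <- ref <- p <- d <- numeric(n)
  for (i in seq_len(n)) {
    s <- fb_step_core(eng, raw[i], conditions[i])
    ma[i] <- s[1]; ref[i] <- s[2]; p[i] <- s[3]; d[i] <- s[4]
  }
  out <- data.frame(volume = seq_len(n), raw = raw, moving_average = ma,
                    reference = ref, psc = p, displayed = d, valid = !is.na(ref))
  class(out) <- c("fb_trace", "data.frame")
  out
}

#' Replay a recorded region time series from a TSV file
#'
#' Reads a table with columns `volume`, `raw`, `condition`, replays it through
#' the engine and writes (optionally) the resulting trace as TSV.
#'
#' @param path input TSV path.
#' @param out optional output TSV path for the trace.
#' @inheritParams fb_engine
#' @return the feedback trace data.frame, invisibly if `out` is given.
#' @export
fb_replay_tsv <- function(path, out = NULL, polarity = "standard",
                          clamp_psc = 2, window = 3, ref_window = 5) {
  x <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  for (col in c("volume", "raw", "condition"))
    if (!col %in% names(x)) stop("input is missing required column: ", col)
  trace <- fb_replay(x$raw[order(x$volume)], x$condition[order(x$volume)],
                     polarity, clamp_psc, window, ref_window)
  if (!is.null(out)) {
    utils::write.table(format(trace, digits = 17, trim = TRUE, scientific = FALSE),
                       out, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(trace))
  }
  trace
}
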
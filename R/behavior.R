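# Novel-object-recognition scoring: discrimination index, five-second visit
# concatenation, early/late familiarization splits, and the visit-epoch
# construction that feeds the neural analyses.

#' Visit table constructor
#'
#' @param object object labels per visit (`"novel"`/`"familiar"`, or
#'   `"left"`/`"right"` during familiarization).
#' @param start_s,end_s visit bounds, seconds.
#' @param phase task phase: `"familiarization"`, `"STM"` or `"LTM"`.
#' @return data frame of class `visit_record`, ordered by start time;
#'   overlapping visits are rejected.
#' @export
visit_record <- function(object, start_s, end_s, phase = "STM") {
  stopifnot(length(object) == length(start_s),
            length(start_s) == length(end_s))
  if (any(end_s <= start_s)) stop("visits must have end > start")
  o <- order(start_s)
  object <- object[o]; start_s <- start_s[o]; end_s <- end_s[o]
  if (length(start_s) > 1L && any(start_s[-1] < end_s[-length(end_s)])) {
    stop("visits must be non-overlapping")
  }
  structure(data.frame(object = object, start_s = start_s, end_s = end_s,
                       phase = phase, stringsAsFactors = FALSE),
            class = c("visit_record", "data.frame"))
}

#' Discrimination index
#'
#' `DI = (time visiting the novel object - time visiting the familiar
#' object) / total exploration time`, in \[-1, 1\]. Positive values indicate
#' preferential exploration of the novel object, i.e. intact recognition
#' memory.
#'
#' @param visits a `visit_record` (or data frame with `object`, `start_s`,
#'   `end_s`) with at least one visit to each object class.
#' @param novel,familiar the labels denoting the two classes.
#' @return object of class `memory_score`: `di`, `total_exploration_s`,
#'   per-object visit counts and durations, and `valid` (`TRUE` when total
#'   exploration is at least 10 s, the familiarization validity rule).
#' @export
discrimination_index <- function(visits, novel = "novel",
                                 familiar = "familiar") {
  durs <- visits$end_s - visits$start_s
  t_nov <- sum(durs[visits$object == novel])
  t_fam <- sum(durs[visits$object == familiar])
  if (t_nov == 0 || t_fam == 0) {
    stop("need at least one visit to each object class")
  }
  total <- t_nov + t_fam
  structure(list(di = (t_nov - t_fam) / total,
                 total_exploration_s = total,
                 n_visits = c(novel = sum(visits$object == novel),
                              familiar = sum(visits$object == familiar)),
                 time_s = c(novel = t_nov, familiar = t_fam),
                 valid = total >= 10),
            class = "memory_score")
}

#' @export
print.memory_score <- function(x, ...) {
  cat(sprintf(
    "<memory_score> DI = %.3f (novel %.1f s / familiar %.1f s over %d + %d visits)%s\n",
    x$di, x$time_s["novel"], x$time_s["familiar"],
    x$n_visits["novel"], x$n_visits["familiar"],
    if (x$valid) "" else " [exploration < 10 s]"))
  invisible(x)
}

#' Baseline discrimination screen
#'
#' Sessions enter the neural analyses only when the baseline DI exceeds a
#' cutoff (default 0.2), i.e. the animal demonstrably formed the memory.
#'
#' @param score a `memory_score` (or a bare DI).
#' @param cutoff minimum baseline DI.
#' @return logical.
#' @export
passes_di_screen <- function(score, cutoff = 0.2) {
  di <- if (inherits(score, "memory_score")) score$di else score
  di > cutoff
}

#' Concatenate visits up to a target duration
#'
#' Accumulates visits from the start (`order = "first"`) or the end
#' (`order = "last"`) of the session until the accumulated time reaches
#' `target_s`; the final contributing visit is truncated (its tail for
#' `"first"`, its head for `"last"`) so the accumulated time equals the
#' target exactly. Sessions with less than `target_s` of exploration return
#' everything, flagged short. Set `truncate = FALSE` to keep the last
#' contributing visit whole instead.
#'
#' @param visits a `visit_record`, ordered in time.
#' @param target_s target accumulated duration, seconds (default 5).
#' @param order `"first"` or `"last"`.
#' @param label label for the resulting epochs.
#' @param truncate truncate the final visit at the threshold (default TRUE).
#' @return an `epoch_set` of the contributing sub-intervals, with attributes
#'   `n_visits` (visits used), `total_s` (accumulated time) and `short`.
#' @export
concatenate_visits <- function(visits, target_s = 5.0,
                               order = c("first", "last"),
                               label = "visit", truncate = TRUE) {
  order <- match.arg(order)
  if (nrow(visits) == 0L) stop("no visits to concatenate")
  idx <- if (order == "first") seq_len(nrow(visits)) else rev(seq_len(nrow(visits)))
  acc <- 0
  starts <- numeric(); ends <- numeric()
  n_used <- 0L
  for (i in idx) {
    s <- visits$start_s[i]; e <- visits$end_s[i]
    d <- e - s
    take <- min(d, target_s - acc)
    if (take <= 0) break
    if (truncate && take < d) {
      if (order == "first") e <- s + take else s <- e - take
    }
    starts <- c(starts, s); ends <- c(ends, e)
    acc <- acc + (e - s)
    n_used <- n_used + 1L
    if (acc >= target_s) break
  }
  o <- order(starts)
  out <- epoch_set(starts[o], ends[o], label)
  attr(out, "n_visits") <- n_used
  attr(out, "total_s") <- acc
  attr(out, "short") <- acc < target_s
  out
}

#' Early/late split of the familiarization phase
#'
#' Early = the first `target_s` seconds of accumulated visit time (novelty
#' seeking), late = the last `target_s` seconds (memory just acquired),
#' objects pooled. Familiarization is valid only when the animal explored
#' for at least `min_total_s` (default 10 s), which also guarantees the two
#' partitions are disjoint.
#'
#' @param familiarization_visits a `visit_record` for the familiarization
#'   phase.
#' @param target_s accumulated time per partition, seconds.
#' @param min_total_s validity threshold on total exploration, seconds.
#' @return list with `early` and `late` `epoch_set`s.
#' @export
split_early_late <- function(familiarization_visits, target_s = 5.0,
                             min_total_s = 10.0) {
  total <- sum(familiarization_visits$end_s - familiarization_visits$start_s)
  if (total < min_total_s) {
    stop(sprintf(
      "invalid familiarization: %.1f s of exploration (< %g s required)",
      total, min_total_s))
  }
  list(early = concatenate_visits(familiarization_visits, target_s,
                                  order = "first", label = "early"),
       late = concatenate_visits(familiarization_visits, target_s,
                                 order = "last", label = "late"))
}

#' Visit epochs per object class for a memory test
#'
#' One concatenated `target_s`-second epoch per object class (the initial
#' visits to the novel and to the familiar object), tagged with the phase
#' and object. A missing object class is omitted with a warning; classes
#' with less than `target_s` of exploration are kept, short-flagged.
#'
#' @param visits a `visit_record` for the test.
#' @param phase `"STM"` or `"LTM"`.
#' @param target_s accumulated time per class, seconds.
#' @return named list of `epoch_set`s, one per object class present.
#' @export
label_visit_epochs <- function(visits, phase = c("STM", "LTM"),
                               target_s = 5.0) {
  phase <- match.arg(phase)
  out <- list()
  for (obj in unique(visits$object)) {
    vi <- visits[visits$object == obj, , drop = FALSE]
    out[[obj]] <- concatenate_visits(vi, target_s, order = "first",
                                     label = paste(phase, obj, sep = "_"))
  }
  expected <- c("novel", "familiar")
  missing <- setdiff(expected, names(out))
  if (length(missing) && all(unique(visits$object) %in% expected)) {
    warning(sprintf("no visits to: %s", paste(missing, collapse = ", ")))
  }
  out
}
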
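#' Define an auditory oddball stimulus protocol
#'
#' Describes a passive oddball train of a frequent "standard" stimulus
#' interleaved with two rare deviants (a word and a nonword), as used in
#' mismatch-negativity paradigms: a fixed standard:word:nonword presentation
#' ratio, a bounded number of standards between successive deviants, and an
#' initial habituation run of standards.
#'
#' @param n_trials Total number of trials in the session.
#' @param ratio Length-3 numeric vector of relative frequencies for
#'   standard, word deviant and nonword deviant (default `6:1:1`). `n_trials`
#'   must divide into exact per-condition counts under this ratio.
#' @param gap_range Inclusive integer interval `c(min, max)` for the number of
#'   standards between two successive deviants.
#' @param lead_in Number of standards presented before the first deviant so
#'   listeners habituate to the frequent stimulus. Lead-in standards count
#'   toward the standard total.
#' @param isi_ms Inter-stimulus interval in ms (offset of one stimulus to
#'   onset of the next).
#' @param stim_duration_ms Stimulus duration in ms.
#'
#' @return An `oddball_protocol` list with the validated fields plus the
#'   implied per-condition `counts`.
#' @examples
#' oddball_protocol()            # 1200 trials, 900/150/150, gaps 2-5
#' oddball_protocol(n_trials = 8, gap_range = c(1, 6), lead_in = 0)
#' @export
oddball_protocol <- function(n_trials = 1200L,
                             ratio = c(standard = 6, word_deviant = 1, nonword_deviant = 1),
                             gap_range = c(2L, 5L),
                             lead_in = 10L,
                             isi_ms = 800,
                             stim_duration_ms = 400) {
  n_trials <- stopifnot_scalar_count(n_trials, "n_trials", min = 1L)
  if (length(ratio) != 3L || any(!is.finite(ratio)) || any(ratio <= 0)) {
    abort("'ratio' must be three positive frequencies (standard, word, nonword)")
  }
  counts <- n_trials * ratio / sum(ratio)
  if (any(abs(counts - round(counts)) > 1e-9)) {
    abort(sprintf(
      "infeasible protocol: n_trials = %d does not divide into whole per-condition counts at ratio %s",
      n_trials, paste(ratio, collapse = ":")
    ))
  }
  counts <- as.integer(round(counts))
  names(counts) <- c("standard", "word_deviant", "nonword_deviant")
  if (length(gap_range) != 2L || gap_range[1] > gap_range[2] || gap_range[1] < 1L) {
    abort("'gap_range' must be c(min, max) with 1 <= min <= max")
  }
  lead_in <- stopifnot_scalar_count(lead_in, "lead_in", min = 0L)
  if (isi_ms < 0 || stim_duration_ms <= 0) abort("'isi_ms' must be >= 0 and 'stim_duration_ms' > 0")

  structure(
    list(
      n_trials = n_trials, ratio = unname(ratio), counts = counts,
      gap_range = as.integer(gap_range), lead_in = lead_in,
      isi_ms = isi_ms, stim_duration_ms = stim_duration_ms
    ),
    class = "oddball_protocol"
  )
}

#' @export
print.oddball_protocol <- function(x, ...) {
  cat(sprintf(
    "<oddball_protocol> %d trials (%d standard / %d word / %d nonword), gaps %d-%d, lead-in %d, SOA %g ms\n",
    x$n_trials, x$counts[1], x$counts[2], x$counts[3],
    x$gap_range[1], x$gap_range[2], x$lead_in, x$isi_ms + x$stim_duration_ms
  ))
  invisible(x)
}

#' Simulate a pseudo-random oddball trial sequence
#'
#' Draws a session satisfying the protocol exactly: per-condition counts match
#' the ratio, the first `lead_in` trials are standards, every run of standards
#' strictly between two deviants has a length inside `gap_range`, and deviant
#' subtypes (word vs nonword) are interleaved uniformly at random subject to
#' their exact counts. Gaps are first drawn uniformly from `gap_range` and
#' then repaired by +/-1 adjustments on randomly chosen gaps until the exact
#' standard count is met, so both the printed counts and the gap bounds hold
#' simultaneously.
#'
#' @param protocol An [oddball_protocol()].
#' @param seed Optional integer seed; when given the call is reproducible and
#'   leaves the global RNG stream untouched.
#'
#' @return A `trial_sequence` tibble with columns `trial`, `label`
#'   (`standard` / `word_deviant` / `nonword_deviant`) and `onset_ms`
#'   (stimulus onset, spaced by `stim_duration_ms + isi_ms`). The protocol is
#'   attached as attribute `protocol`.
#' @examples
#' seq <- simulate_trial_sequence(oddball_protocol(), seed = 1)
#' table(seq$label)
#' @export
simulate_trial_sequence <- function(protocol, seed = NULL) {
  stopifnot(inherits(protocol, "oddball_protocol"))
  counts <- protocol$counts
  n_dev <- counts[["word_deviant"]] + counts[["nonword_deviant"]]
  if (n_dev < 1L) abort("infeasible protocol: no deviant trials implied by the ratio")
  gap_std <- counts[["standard"]] - protocol$lead_in
  n_gaps <- n_dev - 1L
  gmin <- protocol$gap_range[1]
  gmax <- protocol$gap_range[2]
  if (gap_std < 0L) {
    abort(sprintf(
      "infeasible protocol: lead_in (%d) exceeds the standard count (%d)",
      protocol$lead_in, counts[["standard"]]
    ))
  }
  if (n_gaps > 0L && (gap_std < n_gaps * gmin || gap_std > n_gaps * gmax)) {
    abort(sprintf(
      paste0(
        "infeasible protocol: %d inter-deviant standards cannot be split into %d gaps ",
        "of %d-%d trials (feasible totals are %d-%d)"
      ),
      gap_std, n_gaps, gmin, gmax, n_gaps * gmin, n_gaps * gmax
    ))
  }
  if (n_gaps == 0L && gap_std != 0L) {
    abort("infeasible protocol: standards remain after the lead-in but there is at most one deviant")
  }

  with_seed_(seed, {
    gaps <- if (n_gaps > 0L) sample(seq.int(gmin, gmax), n_gaps, replace = TRUE) else integer()
    deficit <- gap_std - sum(gaps)
    while (deficit != 0L) {
      step <- sign(deficit)
      movable <- if (step > 0L) which(gaps < gmax) else which(gaps > gmin)
      pick <- movable[sample.int(length(movable), 1L)]
      gaps[pick] <- gaps[pick] + step
      deficit <- deficit - step
    }
    dev_labels <- sample(rep(
      c("word_deviant", "nonword_deviant"),
      c(counts[["word_deviant"]], counts[["nonword_deviant"]])
    ))
    labels <- c(rep("standard", protocol$lead_in), unlist(
      lapply(seq_len(n_dev), function(i) {
        c(dev_labels[i], if (i <= n_gaps) rep("standard", gaps[i]))
      })
    ))
    out <- tibble::tibble(
      trial = seq_along(labels),
      label = factor(labels, levels = c("standard", "word_deviant", "nonword_deviant")),
      onset_ms = (seq_along(labels) - 1) * (protocol$stim_duration_ms + protocol$isi_ms)
    )
    attr(out, "protocol") <- protocol
    class(out) <- c("trial_sequence", class(out))
    out
  })
}

#' Lengths of standard runs strictly between successive deviants
#'
#' Exhaustively scans a trial sequence and returns the length of every maximal
#' run of standards bounded by a deviant on both sides. The lead-in run and
#' any trailing run are excluded (they are not between two deviants).
#'
#' @param sequence A `trial_sequence` or a character/factor label vector.
#' @return Integer vector of run lengths (possibly empty).
#' @export
inter_deviant_gaps <- function(sequence) {
  labels <- if (is.data.frame(sequence)) as.character(sequence$label) else as.character(sequence)
  dev_pos <- which(labels != "standard")
  if (length(dev_pos) < 2L) return(integer())
  gaps <- diff(dev_pos) - 1L
  as.integer(gaps)
}
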
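#' The eleven experiential feature categories
#'
#' Fixed category labels used to code listed properties of abstract
#' concepts into modal feature types (seven sensorimotor channels plus
#' social, mental, emotional and verbal-associative content).
#'
#' @export
PROPERTY_CATEGORIES <- c(
  "visual", "motor-related", "acoustic", "tactile", "olfactory",
  "gustatory", "interoceptive", "social constellation", "mental state",
  "emotion", "verbal association"
)

#' Event design table
#'
#' @param onset event onsets in seconds from run start (strictly increasing).
#' @param duration event durations in seconds.
#' @param condition condition label per event.
#' @param run_length total run length in seconds.
#' @param tr repetition time in seconds.
#' @return an `event_design`: a data frame with columns `onset`,
#'   `duration`, `condition` and attributes `run_length` and `tr`.
#' @export
event_design <- function(onset, duration, condition, run_length, tr = 2) {
  if (tr <= 0) stop_arg("`tr` must be positive")
  if (length(onset) != length(duration) || length(onset) != length(condition)) {
    stop_arg("`onset`, `duration` and `condition` must have equal length")
  }
  if (any(diff(onset) <= 0)) stop_arg("onsets must be strictly increasing")
  if (any(onset + duration > run_length + 1e-9)) {
    stop_arg("events extend beyond `run_length`")
  }
  out <- data.frame(
    onset = as.numeric(onset), duration = as.numeric(duration),
    condition = as.character(condition), stringsAsFactors = FALSE
  )
  attr(out, "run_length") <- as.numeric(run_length)
  attr(out, "tr") <- as.numeric(tr)
  class(out) <- c("event_design", "data.frame")
  out
}

#' Check a condition sequence for forbidden runs
#'
#' `TRUE` iff no label repeats more than `max_run` consecutive times
#' (the trial-sequence constraint of the lexical decision task).
#'
#' @param labels character (or coercible) vector of condition labels.
#' @param max_run maximal allowed run length.
#' @return logical scalar.
#' @examples
#' sequence_ok(c("W", "W", "W", "P"), 3)  # TRUE
#' sequence_ok(c("W", "W", "W", "W"), 3)  # FALSE
#' @export
sequence_ok <- function(labels, max_run = 3) {
  if (length(labels) == 0) return(TRUE)
  all(rle(as.character(labels))$lengths <= max_run)
}

## draw a label sequence under the max-run constraint; constructive
## sampling with restart.
draw_sequence <- function(n_per_cond, max_run, max_tries = 1000L) {
  labs <- names(n_per_cond)
  n_max <- max(n_per_cond)
  n_rest <- sum(n_per_cond) - n_max
  if (n_max > (n_rest + 1L) * max_run) {
    stop_arg(
      "condition counts cannot satisfy the max-run constraint: ",
      n_max, " events of one condition against ", n_rest, " others at max_run = ",
      max_run
    )
  }
  for (try in seq_len(max_tries)) {
    remaining <- n_per_cond
    seqn <- character(sum(n_per_cond))
    run_lab <- ""
    run_len <- 0L
    ok <- TRUE
    for (i in seq_along(seqn)) {
      avail <- labs[remaining > 0L]
      if (run_len >= max_run) avail <- setdiff(avail, run_lab)
      if (length(avail) == 0L) {
        ok <- FALSE
        break
      }
      pick <- if (length(avail) == 1L) avail else {
        sample(avail, 1L, prob = remaining[avail])
      }
      seqn[i] <- pick
      remaining[pick] <- remaining[pick] - 1L
      if (pick == run_lab) run_len <- run_len + 1L else {
        run_lab <- pick
        run_len <- 1L
      }
    }
    if (ok) return(seqn)
  }
  stop_arg("could not draw a sequence satisfying the max-run constraint")
}

#' Simulate a jittered rapid event-related design
#'
#' Emulates the lexical decision run: a condition sequence under the
#' "no more than `max_run` consecutive repeats" constraint, fixed trial
#' duration, and intertrial intervals drawn from a right-skewed gamma
#' distribution matched to the requested mean and SD (truncated at zero
#' by construction).  Continuous ITIs jitter the onsets by sub-TR
#' fractions; `iti_sd_ms = 0` gives a constant, TR-locked ITI.
#'
#' @param n_per_cond named integer vector, events per condition
#'   (e.g. `c(word = 64, pseudoword = 64)`).
#' @param trial_ms trial duration in milliseconds (default 2400).
#' @param iti_mean_ms mean intertrial interval in ms (default 3173).
#' @param iti_sd_ms SD of the intertrial interval in ms (default 3435).
#' @param max_run maximal run of a single condition (default 3).
#' @param tr repetition time in seconds (default 2).
#' @param seed integer seed; the design is reproducible given the seed.
#' @param initial_rest_s rest before the first trial (seconds).
#' @param final_rest_s rest appended after the last trial, at least the
#'   HRF support so late responses stay inside the run.
#' @return an [event_design()].
#' @export
make_event_design <- function(n_per_cond, trial_ms = 2400, iti_mean_ms = 3173,
                              iti_sd_ms = 3435, max_run = 3, tr = 2, seed = 1,
                              initial_rest_s = 10, final_rest_s = 34) {
  if (is.null(names(n_per_cond)) || any(!nzchar(names(n_per_cond)))) {
    stop_arg("`n_per_cond` must be a named vector")
  }
  if (any(n_per_cond < 0) || sum(n_per_cond) < 1) stop_arg("need at least one event")
  if (max_run < 1) stop_arg("`max_run` must be >= 1")
  if (trial_ms <= 0 || iti_mean_ms <= 0 || iti_sd_ms < 0) {
    stop_arg("durations must be positive and `iti_sd_ms` non-negative")
  }
  n_per_cond <- n_per_cond[n_per_cond > 0]
  with_seed(seed, {
    labels <- draw_sequence(n_per_cond, max_run)
    n <- length(labels)
    itis <- draw_iti(n - 1L, iti_mean_ms / 1000, iti_sd_ms / 1000)
    dur <- trial_ms / 1000
    onsets <- initial_rest_s + c(0, cumsum(dur + itis))
    run_length <- ceiling((onsets[n] + dur + final_rest_s) / tr) * tr
    event_design(onsets, rep(dur, n), labels, run_length, tr)
  })
}

## gamma ITIs matched in mean and SD; sd = 0 degenerates to a constant
draw_iti <- function(n, mean_s, sd_s) {
  if (n <= 0) return(numeric(0))
  if (sd_s == 0) return(rep(mean_s, n))
  shape <- (mean_s / sd_s)^2
  stats::rgamma(n, shape = shape, rate = mean_s / sd_s^2)
}

#' Block-design timing of the three localizer protocols
#'
#' Returns the fixed block timing used to localize modal cortex:
#' \describe{
#'   \item{visual}{six 24 s picture blocks separated by 27.8 s rests.}
#'   \item{motor}{eight 26 s hand-squeezing blocks alternating with
#'     26 s rests (left/right-hand blocks merged into one condition).}
#'   \item{emotional}{twelve 23.8 s picture blocks, six emotional
#'     (pleasant and unpleasant merged) and six neutral, alternating,
#'     with 5.8 s fixation between blocks.}
#' }
#'
#' @param protocol one of `"visual"`, `"motor"`, `"emotional"`.
#' @param tr repetition time in seconds (default 2).
#' @return an [event_design()]; `run_length` matches the acquisition
#'   length of the corresponding localizer run.
#' @export
make_block_design <- function(protocol = c("visual", "motor", "emotional"), tr = 2) {
  protocol <- match.arg(protocol)
  switch(protocol,
    visual = {
      onsets <- 27.8 + (0:5) * (24 + 27.8)
      event_design(onsets, rep(24, 6), rep("visual", 6), run_length = 354, tr = tr)
    },
    motor = {
      onsets <- 26 + (0:7) * 52
      event_design(onsets, rep(26, 8), rep("motor", 8), run_length = 460, tr = tr)
    },
    emotional = {
      onsets <- 5.8 + (0:11) * (23.8 + 5.8)
      cond <- rep(c("neutral", "emotional"), 6)
      event_design(onsets, rep(23.8, 12), cond, run_length = 368, tr = tr)
    }
  )
}

#' German-style pseudoword from a word
#'
#' Replaces exactly one vowel with a different vowel and exactly one
#' consonant with a different consonant, preserving word length (the
#' pseudoword construction of the lexical decision stimuli; vowels
#' include the umlauts a-umlaut, o-umlaut, u-umlaut since the stimuli
#' are German).
#'
#' @param word a single word containing at least one vowel and one
#'   consonant (lower case).
#' @param seed integer seed.
#' @return a string of the same length differing from `word` at exactly
#'   two positions.
#' @export
generate_pseudoword <- function(word, seed = 1) {
  if (length(word) != 1 || !is.character(word) || !nzchar(word)) {
    stop_arg("`word` must be a single non-empty string")
  }
  vowels <- c("a", "e", "i", "o", "u", "ä", "ö", "ü")
  consonants <- setdiff(c(letters, "ß"), vowels)
  chars <- strsplit(word, "")[[1]]
  vpos <- which(chars %in% vowels)
  cpos <- which(chars %in% consonants)
  if (length(vpos) == 0) stop_arg("`word` contains no vowel")
  if (length(cpos) == 0) stop_arg("`word` contains no consonant")
  with_seed(seed, {
    iv <- if (length(vpos) == 1) vpos else sample(vpos, 1)
    ic <- if (length(cpos) == 1) cpos else sample(cpos, 1)
    vrep <- sample(setdiff(vowels, chars[iv]), 1)
    crep <- sample(setdiff(consonants, chars[ic]), 1)
    chars[iv] <- vrep
    chars[ic] <- crep
    paste(chars, collapse = "")
  })
}

#' Pooled-variance two-sample t test for stimulus length matching
#'
#' The check used to match word and pseudoword letter counts: a
#' two-sample t statistic with pooled variance, `df = n_a + n_b - 2`,
#' two-sided p value.  With zero pooled variance and equal means the
#' statistic is 0 by convention.
#'
#' @param lengths_a,lengths_b numeric vectors (at least two entries each).
#' @return list with elements `t`, `df`, `p`.
#' @export
length_match_test <- function(lengths_a, lengths_b) {
  na <- length(lengths_a)
  nb <- length(lengths_b)
  if (na < 2 || nb < 2) stop_arg("both samples need at least 2 entries")
  df <- na + nb - 2
  sp2 <- ((na - 1) * stats::var(lengths_a) + (nb - 1) * stats::var(lengths_b)) / df
  dm <- mean(lengths_a) - mean(lengths_b)
  if (sp2 == 0) {
    tval <- if (dm == 0) 0 else sign(dm) * Inf
  } else {
    tval <- dm / sqrt(sp2 * (1 / na + 1 / nb))
  }
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}
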
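#' Convert a tempo in BPM to an inter-beat interval in milliseconds
#'
#' The inter-beat interval (IBI) is the period of the musical beat,
#' \code{60000 / tempo}. The rounded value is the conventional way tempi are
#' reported (e.g. 132 BPM corresponds to a 455 ms IBI, 116 BPM to 517 ms);
#' beat-grid arithmetic should use \code{round = FALSE} to avoid accumulating
#' rounding error over a long trial.
#'
#' @param tempo_bpm tempo in beats per minute; must be positive.
#' @param round if \code{TRUE} (default) round to the nearest millisecond.
#' @return inter-beat interval in milliseconds.
#' @examples
#' bpm_to_ibi(132)            # 455
#' bpm_to_ibi(116)            # 517
#' bpm_to_ibi(120)            # 500
#' @export
bpm_to_ibi <- function(tempo_bpm, round = TRUE) {
  if (!is.numeric(tempo_bpm) || any(!is.finite(tempo_bpm)) || any(tempo_bpm <= 0)) {
    stop("`tempo_bpm` must be a positive finite number")
  }
  ibi <- 60000 / tempo_bpm
  if (round) round(ibi) else ibi
}

#' Describe one pacing stimulus
#'
#' A stimulus is a music excerpt or metronome with a fixed tempo, looped to a
#' fixed duration, plus the perceptual covariates used in the analysis: a
#' beat-saliency z-score (how clear the beat is, rated by an independent
#' listener panel) and, for music, a familiarity z-score.
#'
#' @param name stimulus label.
#' @param genre musical genre, or \code{"metronome"}.
#' @param tempo_bpm tempo in beats per minute (> 0).
#' @param duration_s stimulus duration in seconds (> 0); the study looped
#'   excerpts to 115 s.
#' @param beat_saliency_z beat-saliency z-score.
#' @param familiarity_z familiarity z-score (\code{NA} for metronomes).
#' @return an object of class \code{stimulus_spec}: a list with the above
#'   fields plus \code{ibi_ms} (rounded IBI).
#' @export
stimulus_spec <- function(name, genre, tempo_bpm, duration_s = 115,
                          beat_saliency_z = NA_real_,
                          familiarity_z = NA_real_) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.numeric(tempo_bpm) || tempo_bpm <= 0) {
    stop("`tempo_bpm` must be positive")
  }
  if (!is.numeric(duration_s) || duration_s <= 0) {
    stop("`duration_s` must be positive")
  }
  structure(
    list(
      name = name,
      genre = genre,
      tempo_bpm = tempo_bpm,
      ibi_ms = bpm_to_ibi(tempo_bpm),
      duration_s = duration_s,
      beat_saliency_z = beat_saliency_z,
      familiarity_z = familiarity_z
    ),
    class = "stimulus_spec"
  )
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf("<stimulus_spec> %s (%s), %g BPM (IBI %d ms), %g s, saliency z = %s\n",
              x$name, x$genre, x$tempo_bpm, x$ibi_ms, x$duration_s,
              format(x$beat_saliency_z)))
  invisible(x)
}

#' The idealized beat grid of a stimulus
#'
#' Beat k falls at \code{k * IBI} (unrounded IBI) for all beats strictly
#' inside the stimulus duration; the grid is isochronous because the study
#' stimuli were looped at a fixed tempo.
#'
#' @param stimulus a [stimulus_spec()].
#' @return numeric vector of beat times in seconds, starting at 0,
#'   strictly increasing.
#' @export
make_beat_grid <- function(stimulus) {
  stopifnot(inherits(stimulus, "stimulus_spec"))
  ibi_s <- bpm_to_ibi(stimulus$tempo_bpm, round = FALSE) / 1000
  n <- floor(stimulus$duration_s / ibi_s - 1e-12) + 1
  # final beat must be < duration; guard exact multiples
  grid <- (seq_len(n) - 1) * ibi_s
  grid[grid < stimulus$duration_s]
}

#' The study's stimulus set
#'
#' Reads the packaged stimulus table: six musical excerpts spanning a range
#' of beat saliency plus a metronome, with the metronome and the merengue
#' excerpt each presented at two tempi, for eight trial stimuli per movement
#' type. Tempi lie between 116 and 132 BPM (IBIs 455-517 ms) and every
#' stimulus lasts 115 s.
#'
#' @param path optional path to an alternative stimulus table (tab-separated
#'   with columns \code{name, genre, tempo_bpm, duration_s, beat_saliency_z,
#'   familiarity_z, is_metronome}).
#' @return a data.frame, one row per trial stimulus.
#' @export
study_stimuli <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "stimuli.tsv", package = "beatsync")
  }
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  needed <- c("name", "genre", "tempo_bpm", "duration_s",
              "beat_saliency_z", "familiarity_z", "is_metronome")
  if (!all(needed %in% names(df))) {
    stop("stimulus table is missing columns: ",
         paste(setdiff(needed, names(df)), collapse = ", "))
  }
  df$ibi_ms <- bpm_to_ibi(df$tempo_bpm)
  df
}

#' Turn one row of a stimulus table into a stimulus_spec
#' @param row a one-row data.frame from [study_stimuli()].
#' @return a [stimulus_spec()].
#' @export
as_stimulus_spec <- function(row) {
  stimulus_spec(
    name = row$name, genre = row$genre, tempo_bpm = row$tempo_bpm,
    duration_s = row$duration_s, beat_saliency_z = row$beat_saliency_z,
    familiarity_z = row$familiarity_z
  )
}
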
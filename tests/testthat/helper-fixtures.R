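# shared fixture builders

# uniform trace on [-lead, t_end] at fs, with given pupil/gaze generators
make_trace <- function(lead = 1, t_end = 4, fs = 500,
                       pupil = function(t) rep(10, length(t)),
                       gaze_x = function(t) numeric(length(t)),
                       gaze_y = function(t) numeric(length(t)),
                       blinks = matrix(numeric(0), ncol = 2)) {
  t <- (round(-lead * fs):round(t_end * fs)) / fs
  sample_trace(t, pupil(t), gaze_x(t), gaze_y(t),
               blink_intervals = blinks, sampling_rate = fs)
}

# condition table from a participants x 4 matrix
make_table <- function(m) {
  colnames(m) <- c("LA_high", "HA_high", "LA_low", "HA_low")
  data.frame(participant = sprintf("P%02d", seq_len(nrow(m))), m,
             check.names = FALSE, stringsAsFactors = FALSE)
}

# random condition table
random_table <- function(n = 8) {
  make_table(matrix(rnorm(n * 4, mean = 5), nrow = n))
}

# long format for aov oracles
table_to_long <- function(tab, group = NULL) {
  cells <- c("LA_high", "HA_high", "LA_low", "HA_low")
  long <- do.call(rbind, lapply(cells, function(cl) {
    amb <- substr(cl, 1, 2)
    cla <- sub("^.._", "", cl)
    data.frame(subject = tab$participant, y = tab[[cl]],
               ambiguity = amb, clarity = cla, stringsAsFactors = FALSE)
  }))
  if (!is.null(group)) long$group <- group[match(long$subject,
                                                 tab$participant)]
  long$subject <- factor(long$subject)
  long$ambiguity <- factor(long$ambiguity)
  long$clarity <- factor(long$clarity)
  long
}

# small full-rate sim config for end-to-end tests (kept light)
small_sim <- function(...) {
  sim_config(n_participants = 3, seed = 42, ...)
}
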
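#' Cue-aligned extraction window
#'
#' A trial window in seconds relative to cue onset. Windows are half-open
#' `[start, end)` in samples so that a 4 s window at 250 Hz yields exactly
#' 1000 samples.
#'
#' @param start_sec window start, seconds after cue onset.
#' @param end_sec window end, seconds after cue onset; must exceed `start_sec`
#'   and `(end_sec - start_sec) * fs` must be a whole number of samples at the
#'   recording's sampling rate.
#' @return an object of class `window_spec`.
#' @export
window_spec <- function(start_sec, end_sec) {
  if (!is.finite(start_sec) || !is.finite(end_sec) || end_sec <= start_sec) {
    stop("window_spec: end_sec must be greater than start_sec")
  }
  structure(list(start_sec = start_sec, end_sec = end_sec), class = "window_spec")
}

#' Number of samples a window spans at a given sampling rate
#' @param window a [window_spec()].
#' @param fs sampling rate in Hz.
#' @return integer sample count `(end_sec - start_sec) * fs`.
#' @export
window_samples <- function(window, fs) {
  stopifnot(inherits(window, "window_spec"))
  n <- (window$end_sec - window$start_sec) * fs
  if (abs(n - round(n)) > 1e-9 || n < 1) {
    stop("window length x fs must be a positive integer number of samples, got ", n)
  }
  as.integer(round(n))
}

# Channel/class contracts for the two supported benchmarks.
gdf_dataset_contract <- function(dataset_id) {
  switch(dataset_id,
    iv2a = list(n_eeg = 22L, n_classes = 4L,
                class_names = c("left", "right", "feet", "tongue")),
    iv2b = list(n_eeg = 3L, n_classes = 2L,
                class_names = c("left", "right")),
    stop("unknown dataset_id: ", dataset_id))
}

#' Load cue-aligned motor-imagery trials from a GDF session file
#'
#' Reads one BCI Competition IV-2a or IV-2b session recording (GDF format),
#' drops the three EOG channels, and cuts one trial per motor-imagery cue at
#' the requested window. Labels are mapped to contiguous 0-based indices:
#' left/right/feet/tongue -> 0..3 (IV-2a), left/right -> 0..1 (IV-2b). No
#' filtering or artifact correction is applied; standardization happens
#' downstream. Trials annotated as rejected are excluded by default.
#'
#' GDF parsing is delegated to the Python `mne` package, invoked through the
#' `python` binary on the PATH; the decoded trials are handed back through a
#' temporary binary exchange file.
#'
#' @param path path to a `.gdf` session file.
#' @param dataset_id `"iv2a"` or `"iv2b"`.
#' @param window a [window_spec()]; the benchmarks use (2, 6) s for IV-2a and
#'   (3, 7) s for IV-2b.
#' @param keep_rejected keep trials carrying a rejected-trial annotation
#'   (default `FALSE`).
#' @param python python interpreter to use (must have `mne` importable).
#' @return a `trial_set` with `C = 22, N = 4` (IV-2a) or `C = 3, N = 2`
#'   (IV-2b).
#' @export
load_gdf_trials <- function(path, dataset_id = c("iv2a", "iv2b"), window,
                            keep_rejected = FALSE, python = "python") {
  dataset_id <- match.arg(dataset_id)
  stopifnot(inherits(window, "window_spec"))
  if (!file.exists(path)) stop("cannot read GDF file: ", path)
  contract <- gdf_dataset_contract(dataset_id)

  out_bin <- tempfile(fileext = ".bin")
  out_hdr <- tempfile(fileext = ".hdr")
  script <- tempfile(fileext = ".py")
  on.exit(unlink(c(out_bin, out_hdr, script)), add = TRUE)
  writeLines(gdf_bridge_script(), script)
  status <- system2(python,
                    c(script, shQuote(path), dataset_id,
                      format(window$start_sec, digits = 12),
                      format(window$end_sec, digits = 12),
                      if (keep_rejected) "1" else "0",
                      shQuote(out_bin), shQuote(out_hdr)),
                    stdout = TRUE, stderr = TRUE)
  code <- attr(status, "status")
  if (!is.null(code) && code != 0L) {
    stop("GDF bridge failed (exit ", code, "):\n", paste(status, collapse = "\n"))
  }
  hdr <- strsplit(readLines(out_hdr), "\t")
  hv <- stats::setNames(vapply(hdr, `[[`, "", 2L), vapply(hdr, `[[`, "", 1L))
  n_tr <- as.integer(hv[["n_trials"]]); n_ch <- as.integer(hv[["n_channels"]])
  n_sm <- as.integer(hv[["n_samples"]]); fs <- as.numeric(hv[["fs"]])
  labels <- as.integer(strsplit(hv[["labels"]], ",")[[1L]])
  ch_names <- strsplit(hv[["channel_names"]], ",")[[1L]]
  if (n_ch != contract$n_eeg) {
    stop("GDF format error: expected ", contract$n_eeg, " EEG channels, got ", n_ch)
  }
  raw <- readBin(out_bin, "double", n = n_tr * n_ch * n_sm, endian = "little")
  # bridge writes trial-major (trial, channel, sample), sample fastest
  data <- aperm(array(raw, c(n_sm, n_ch, n_tr)), c(3L, 2L, 1L))
  trial_set(data, labels, fs, ch_names, contract$n_classes,
            subject_id = sub("\\.gdf$", "", basename(path), ignore.case = TRUE),
            session_tag = "train", prediction_only = TRUE)
}

# The python-side decoder. Cue event codes follow the benchmark conventions:
# IV-2a: 769-772 = left/right/feet/tongue (code 783 marks unlabeled cues);
# IV-2b: 769/770 = left/right; 1023 marks rejected trials.
gdf_bridge_script <- function() {
  c("import sys, struct",
    "import numpy as np",
    "import mne",
    "path, dataset_id, start_s, end_s, keep_rej, out_bin, out_hdr = sys.argv[1:8]",
    "start_s, end_s = float(start_s), float(end_s)",
    "raw = mne.io.read_raw_gdf(path, preload=True, verbose='error')",
    "eog = [ch for ch in raw.ch_names if 'EOG' in ch.upper()]",
    "if eog: raw.drop_channels(eog)",
    "ev, ev_id = mne.events_from_annotations(raw, verbose='error')",
    "codes = {'iv2a': ['769','770','771','772'], 'iv2b': ['769','770']}[dataset_id]",
    "cue_ids = {ev_id[c]: i for i, c in enumerate(codes) if c in ev_id}",
    "if not cue_ids: sys.exit('no MI cue events found in ' + path)",
    "rej_id = ev_id.get('1023')",
    "fs = raw.info['sfreq']",
    "i0 = int(round(start_s * fs)); i1 = int(round(end_s * fs))",
    "sig = raw.get_data()",
    "trials, labels = [], []",
    "rejected = set()",
    "if rej_id is not None and keep_rej == '0':",
    "    for s, _, c in ev:",
    "        if c == rej_id: rejected.add(s)",
    "for s, _, c in ev:",
    "    if c not in cue_ids: continue",
    "    if any(abs(int(s) - r) <= int(2 * fs) for r in rejected): continue",
    "    a, b = int(s) + i0, int(s) + i1",
    "    if b > sig.shape[1]: sys.exit('window extends past end of recording')",
    "    trials.append(sig[:, a:b]); labels.append(cue_ids[c])",
    "if not trials: sys.exit('no MI cue events found in ' + path)",
    "X = np.stack(trials) * 1e6  # volts -> microvolts",
    "X.astype('<f8').tofile(out_bin)",
    "with open(out_hdr, 'w') as fh:",
    "    fh.write('n_trials\\t%d\\n' % X.shape[0])",
    "    fh.write('n_channels\\t%d\\n' % X.shape[1])",
    "    fh.write('n_samples\\t%d\\n' % X.shape[2])",
    "    fh.write('fs\\t%g\\n' % fs)",
    "    fh.write('labels\\t%s\\n' % ','.join(str(l) for l in labels))",
    "    fh.write('channel_names\\t%s\\n' % ','.join(raw.ch_names))")
}
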
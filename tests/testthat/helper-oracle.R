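# Independent oracles used across the suite.

# Reference pyramidal DWT via PyWavelets (db4, periodization mode), called
# through the python binary. signals: [n x T] matrix; returns a list per
# signal with elements A (final approximation) and D1..Dlevels.
pywt_wavedec <- function(signals, levels = 1L) {
  if (is.null(dim(signals))) signals <- matrix(signals, 1L)
  infile <- tempfile(fileext = ".csv")
  outfile <- tempfile(fileext = ".json")
  utils::write.table(signals, infile, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  script <- sprintf("
import json, numpy as np, pywt
X = np.loadtxt(%s, delimiter=',', ndmin=2)
out = []
for row in X:
    c = pywt.wavedec(row, 'db4', mode='periodization', level=%d)
    out.append([v.tolist() for v in c])
json.dump(out, open(%s, 'w'))
", deparse(infile), levels, deparse(outfile))
  res <- system2("python", c("-c", shQuote(script)), stdout = TRUE,
                 stderr = TRUE)
  if (!file.exists(outfile)) {
    stop("pywt oracle failed: ", paste(res, collapse = "\n"))
  }
  raw <- jsonlite::read_json(outfile, simplifyVector = FALSE)
  lapply(seq_len(nrow(signals)), function(i) {
    cc <- lapply(raw[[i]], function(v) as.numeric(unlist(v)))
    names(cc) <- c("A", paste0("D", seq(levels, 1)))
    cc
  })
}

# Reference db4 decomposition filters from PyWavelets (reversed to the
# standard coefficient order used by the package).
pywt_db4_filters <- function() {
  outfile <- tempfile(fileext = ".json")
  script <- sprintf("
import json, pywt
w = pywt.Wavelet('db4')
json.dump({'dec_lo': list(w.dec_lo), 'dec_hi': list(w.dec_hi)}, open(%s, 'w'))
", deparse(outfile))
  system2("python", c("-c", shQuote(script)), stdout = TRUE, stderr = TRUE)
  raw <- jsonlite::read_json(outfile, simplifyVector = TRUE)
  list(g = rev(raw$dec_lo), h = rev(raw$dec_hi))
}

# Small labeled cohort shared by slower tests (built once per test run).
small_cohort_batches <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- synthetic_cohort_spec(
        n_patients = 4, n_channels = 3, seconds_per_class_per_patient = 15,
        class_amplitude = 2.5, seed = 11)
      cache <<- cohort_to_batches(generate_cohort(spec))
    }
    cache
  }
})

# Tiny model configuration used by gradient and training tests.
tiny_config <- function(n_patients = 3, ...) {
  model_config(n_channels = 2, n_patients = n_patients, window_len = 64,
               W = 4, E = 2, emb_kernel = 3, k = 16, h_c2 = 8,
               disc_widths = c(6, 5), ...)
}

tiny_inputs <- function(N = 12, C = 2, Tt = 64, P = 3, seed = 42) {
  set.seed(seed)
  list(X = array(stats::runif(N * C * Tt), c(N, C, Tt)),
       y = rep(c(0L, 1L), length.out = N),
       d = rep(seq_len(P), length.out = N))
}
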
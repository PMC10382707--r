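# Shared fixture builders (all fixtures are generated in code).

# Waveform on an exact-ms grid (fs = 20 kHz -> 0.05 ms steps), so constructed
# peak latencies land on samples exactly.
make_waveform <- function(v, fs = 20000, pre_ms = 5) {
  npre <- round(pre_ms * fs / 1000)
  t_ms <- (seq_along(v) - (npre + 1)) / fs * 1000
  audiogain:::new_waveform(v, fs, t_ms)
}

gauss_bump <- function(t_ms, center_ms, width_ms, amp) {
  amp * exp(-0.5 * ((t_ms - center_ms) / width_ms)^2)
}

time_axis <- function(fs = 20000, pre_ms = 5, post_ms = 15) {
  npre <- round(pre_ms * fs / 1000)
  npost <- round(post_ms * fs / 1000)
  (seq_len(npre + npost + 1) - (npre + 1)) / fs * 1000
}

# One-row-per-ear audiogram table builder.
aud_table <- function(animal_id, genotype, ear, thr, above_max = FALSE) {
  data.frame(animal_id = animal_id, genotype = genotype, ear = ear,
             stimulus = "click", age_weeks = 10, sex = NA_character_,
             threshold_db_spl = thr,
             above_max = rep_len(above_max, length(thr)),
             stringsAsFactors = FALSE)
}

# WT ear pair whose mean + 2.5 SD equals `cutoff` exactly (two ears with
# mean m and sample SD s solve m + 2.5 s = cutoff).
wt_pair_for_cutoff <- function(cutoff = 40.88, s = 4.3) {
  m <- cutoff - 2.5 * s
  d <- s * sqrt(2)
  c(m - d / 2, m + d / 2)
}

# Independent brute-force even-odd point-in-polygon (crossing number),
# scalar implementation; boundary points resolved as inside.
pip_bruteforce <- function(px, py, poly, eps = 1e-9) {
  n <- nrow(poly)
  vapply(seq_along(px), function(k) {
    x <- px[k]; y <- py[k]
    crossings <- 0L
    on_boundary <- FALSE
    for (i in seq_len(n)) {
      j <- if (i == 1) n else i - 1
      x1 <- poly[i, 1]; y1 <- poly[i, 2]
      x2 <- poly[j, 1]; y2 <- poly[j, 2]
      dx <- x2 - x1; dy <- y2 - y1
      L2 <- dx^2 + dy^2
      if (L2 > 0) {
        tt <- max(0, min(1, ((x - x1) * dx + (y - y1) * dy) / L2))
        if ((x - (x1 + tt * dx))^2 + (y - (y1 + tt * dy))^2 <= eps^2)
          on_boundary <- TRUE
      }
      if ((y1 > y) != (y2 > y)) {
        xint <- x1 + (y - y1) * (x2 - x1) / (y2 - y1)
        if (x < xint) crossings <- crossings + 1L
      }
    }
    on_boundary || (crossings %% 2L == 1L)
  }, TRUE)
}

# Random simple (star-shaped) polygon around a center.
random_polygon <- function(n = 8, r_mean = 400, jitter = 0.5,
                           center = c(500, 500)) {
  ang <- sort(stats::runif(n, 0, 2 * pi))
  r <- r_mean * (1 + jitter * (stats::runif(n) - 0.5))
  cbind(center[1] + r * cos(ang), center[2] + r * sin(ang))
}
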
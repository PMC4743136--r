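# Shared fixtures: all synthetic, built in code.

quiet_noise <- function() {
  noise_spec(background_amp = 0, line_amp = 0, white_sigma = 0)
}

# wrap a bare channels x samples matrix as a raw record
make_record <- function(samples, cfg = scan_config()) {
  if (nrow(samples) == 2) samples <- rbind(samples, samples)
  rownames(samples) <- c("LC", "LA", "RC", "RA")
  structure(list(samples = samples, cfg = cfg,
                 meta = list(subject = "fixture", record = 1L)),
            class = "raw_record")
}

# record whose four channels all carry the same single sinusoid
sinusoid_record <- function(freq_hz, amp = 1, cfg = scan_config()) {
  t <- (0:(cfg$samples_per_record - 1)) / cfg$pacing_rate
  x <- amp * sin(2 * pi * freq_hz * t)
  make_record(rbind(x, x, x, x), cfg)
}

# brute-force threshold sweep: direct evaluation of the L1 objective at
# every grid level (independent oracle for sweep_threshold)
brute_sweep <- function(cf, para, grid_min = 0.3, grid_max = 8,
                        grid_step = 0.001) {
  grid <- seq(grid_min, grid_max, by = grid_step)
  tot <- vapply(grid, function(th) sum(abs(cf - th)) + sum(abs(para - th)),
                numeric(1))
  grid[which(tot <= min(tot) + 1e-9 * max(1, abs(min(tot))))[1]]
}

# single-row normalized-feature tibble for classifier tests
nf_row <- function(r_cf = 1, r_para = 0, r25 = 0, r35 = 0, r55 = 0,
                   r65 = 0, usable = TRUE) {
  tibble::tibble(r_cf = r_cf, r_para = r_para, r25 = r25, r35 = r35,
                 r55 = r55, r65 = r65, usable = usable)
}

# harmonic-bin power (in units of f_s) of a signal, via power_spectrum
harm_power <- function(x, h, cfg = scan_config()) {
  spec <- power_spectrum(x, cfg$pacing_rate)
  vapply(h * cfg$f_s, function(f) spec$power[which.min(abs(spec$freq - f))],
         numeric(1))
}
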
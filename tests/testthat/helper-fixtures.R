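# Shared fixtures, built in code.

tiny_data <- function(seed = 1) make_fixture("tiny", seed = seed)

# A minimal paired table with hand-set values, for I/O and validation tests.
hand_table <- function(n = 3) {
  data.frame(site_id = paste0("H", seq_len(n)),
             pH = seq(6.8, 8.0, length.out = n),
             SOM = rep(34.55, n),
             S_T_Cd = seq(0.5, 4, length.out = n),
             A_Cd = seq(0.25, 2, length.out = n),
             S_T_As = seq(20, 80, length.out = n),
             A_As = seq(14, 57, length.out = n),
             C_Fe = rep(390, n), F_Fe = rep(34450, n), Am_Fe = rep(4190, n),
             C_Mn = rep(80, n), F_Mn = rep(1080, n), Am_Mn = rep(970, n),
             Rice_Cd = seq(0.05, 0.4, length.out = n),
             Rice_As = seq(0.1, 0.6, length.out = n),
             stringsAsFactors = FALSE)
}

# A 125-site single-bin table realizing prescribed quadrant counts against
# soil threshold `thr` and grain limit `lim` (factor-2 margins).
quadrant_fixture <- function(counts, element = "Cd", thr = 1, lim = 1) {
  n <- sum(counts)
  soil <- c(rep(2 * thr, counts[["I"]]), rep(thr / 2, counts[["II"]]),
            rep(thr / 2, counts[["III"]]), rep(2 * thr, counts[["IV"]]))
  rice <- c(rep(2 * lim, counts[["I"]]), rep(2 * lim, counts[["II"]]),
            rep(lim / 2, counts[["III"]]), rep(lim / 2, counts[["IV"]]))
  df <- data.frame(site_id = paste0("Q", seq_len(n)), pH = 7,
                   stringsAsFactors = FALSE)
  df[[paste0("S_T_", element)]] <- soil
  df[[paste0("Rice_", element)]] <- rice
  df
}

# Degenerate generator: covariates pinned at the regional means and pH at
# the bin representative values, so only the soil totals vary.
degenerate_config <- function(n, noise_sd = c(Cd = 0, As = 0)) {
  generator_config(
    n = n,
    ph_spec = list(weights = c(neutral = 0.256, alkaline = 0.744),
                   ranges = list(neutral = c(7, 7), alkaline = c(8, 8))),
    som_spec = list(mean = 34.55, sd = 1e-9, range = c(34.54, 34.56)),
    oxide_sdlog10 = 1e-9,
    noise_sd = noise_sd,
    available_as = list(slope = 0.721, intercept = -0.263, cv = 1e-9,
                        floor = 0.001))
}

printed_st <- c(Cd.neutral = 4.54, Cd.alkaline = 7.12,
                As.neutral = 91.43, As.alkaline = 92.30)
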
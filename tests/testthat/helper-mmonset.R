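# Shared fixtures: the reference USA parameter sets and the printed
# twin-study concordance fractions used across tests.

usa_mf <- usa_model_params("males+females")
usa_m  <- usa_model_params("males")
usa_f  <- usa_model_params("females")

# printed concordance fractions of the nine classical studies, plus the
# published derived columns (inherited susceptibility and prevalence)
study_expectations <- data.frame(
  investigator = c("Rosanoff et al.", "Essen-Moller", "Kallmann", "Slater",
                   "Inouye", "Harvald and Hauge", "Gottesman and Shields",
                   "Kringlen", "Hoffer and Pollin"),
  s_inher_printed = c(0.190, 0.224, 0.129, 0.116, 0.163, 0.167, 0.165,
                      0.283, 0.197),
  p_s_printed = c(0.812, 0.706, 0.816, 0.787, 0.750, 0.615, 0.588, 0.551,
                  0.242),
  stringsAsFactors = FALSE)

# random valid parameter sets for property-style loops
random_params <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    mmm_params(m1 = sample(1:25, 1),
               k1 = stats::runif(1, 0.02, 0.5),
               k2 = stats::runif(1, 0.02, 0.5),
               f_s = stats::runif(1, 1e-4, 1e-2),
               r = stats::runif(1, 0.3, 3)))
}
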
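# shared fixtures: the 13-class default grid with the standard allocation,
# the basic genetic parameter set and the two standard goals
default_grid <- function() allocate_animals(env_grid(), 5000, 100)
basic_params <- function(...) rn_params(...)

# printed 13-class reference table (bounds, proportions, conditional means,
# counts at 5000 reference animals / 100 progeny)
reference_table <- function() {
  data.frame(
    proportion = c(0.02, 0.03, 0.05, 0.08, 0.11, 0.14, 0.14,
                   0.14, 0.11, 0.08, 0.05, 0.03, 0.02),
    x_average = c(-2.37, -1.80, -1.44, -1.08, -0.72, -0.36, 0.00,
                  0.36, 0.72, 1.08, 1.44, 1.80, 2.37),
    n_reference = c(113.75, 140.66, 253.38, 400.47, 555.35, 675.71, 721.37,
                    675.71, 555.35, 400.47, 253.38, 140.66, 113.75),
    n_progeny = c(2.28, 2.81, 5.07, 8.01, 11.11, 13.51, 14.43,
                  13.51, 11.11, 8.01, 5.07, 2.81, 2.27))
}
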
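# shared fixtures built in code

# pairwise-average matrix of the c = 0.6, beta = 10 tournament as printed in
# the source tables (rows/cols M, R, U)
printed_supergame <- function() {
  supergame_matrix(matrix(c(0.154, 0.106, 0.047,
                            0.184, 0.140, 0.099,
                            0.187, 0.121, 0.066),
                          3, 3, byrow = TRUE),
                   c("M", "R", "U"))
}

# printed pairwise averages at c = 0.2, beta = 100 (Table-1-style row) plus
# the matching self payoffs
printed_c02_matrix <- function() {
  supergame_matrix(matrix(c(0.478, 0.377, 0.240,
                            0.402, 0.382, 0.246,
                            0.177, 0.138, 0.040),
                          3, 3, byrow = TRUE),
                   c("M", "R", "U"))
}

random_strategy <- function(space) strategy(runif(space_tag(space)$dimension), space)

WSLS <- function() strategy(c(1, 0, 0, 1))
TFT <- function() strategy(c(1, 0))
ALLC <- function() strategy(1)
ALLD <- function() strategy(0)
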
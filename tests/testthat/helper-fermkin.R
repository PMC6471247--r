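# shared fixtures, built in code

# the 9-point batch-fermentation sampling grid (hours)
t9 <- c(0, 2, 4, 6, 8, 10, 24, 30, 48)

# a noiseless fractional-conversion timecourse on the 9-point grid
make_tc <- function(C0, Cinf, K, donor = "O1", matrix = "Mnc",
                    replicate = 1, analyte = "acetate", corrected = TRUE) {
  timecourse(donor, matrix, replicate, analyte, t9,
             fractional_conversion(C0, Cinf, K, t9), corrected = corrected)
}

# a tiny two-species chain network A -> B (-> C), closed forms known
chain_network <- function(k1, k2 = NULL, A0 = 1) {
  if (is.null(k2)) {
    reaction_network(c("A", "B"),
                     data.frame(source = "A", target = "B",
                                k = k1, yield = 1),
                     initial = c(A = A0))
  } else {
    reaction_network(c("A", "B", "C"),
                     data.frame(source = c("A", "B"), target = c("B", "C"),
                                k = c(k1, k2), yield = 1),
                     initial = c(A = A0))
  }
}
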
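test_that("the default catabolic network is well-formed", {
  net <- build_default_network()
  expect_s3_class(net, "reaction_network")
  expect_true(all(net$edges$k > 0))
  expect_true(all(net$edges$yield > 0 & net$edges$yield <= 1))
  expect_false(any(net$edges$source == net$edges$target))
  expect_true(all(c(net$edges$source, net$edges$target) %in% net$species))
  # framed end-products of the catabolic scheme have no outgoing edges
  expect_true(all(c("3-hydroxyphenylacetic", "3-phenylpropionic")
                  %in% net$sinks))
  # every species is reachable from the three substrate pools
  reach <- reachable_species(net, c("procyanidins", "hydroxycinnamates",
                                    "carbohydrates"))
  expect_setequal(reach, net$species)
  # the optional flavonols shunt is off by default
  expect_false("flavonols" %in% net$species)
  expect_true("flavonols" %in% build_default_network(TRUE)$species)
})

test_that("network construction rejects invariant violations", {
  e <- data.frame(source = "A", target = "B", k = 0.1, yield = 1)
  expect_error(reaction_network(c("A", "B"),
                                transform(e, k = -1)), "positive")
  expect_error(reaction_network(c("A", "B"),
                                transform(e, yield = 1.5)), "yields")
  expect_error(reaction_network(c("A", "B"),
                                transform(e, target = "A")), "self-loops")
  expect_error(reaction_network(c("A"), e), "endpoints")
})

test_that("the simulator matches the Bateman closed forms", {
  tt <- c(0, 2, 4, 6, 8, 10, 24, 30, 48)
  # single edge: pure exponential decay of the source
  out1 <- simulate_network(chain_network(0.2), tt)
  expect_equal(out1[, "A"], exp(-0.2 * tt), tolerance = 1e-8)
  expect_equal(out1[, "B"], 1 - exp(-0.2 * tt), tolerance = 1e-8)
  # two-step chain: B(t) = A0 k1/(k2-k1) (e^{-k1 t} - e^{-k2 t})
  k1 <- 0.2; k2 <- 0.1
  out2 <- simulate_network(chain_network(k1, k2), tt)
  bateman <- k1 / (k2 - k1) * (exp(-k1 * tt) - exp(-k2 * tt))
  expect_equal(out2[, "B"], bateman, tolerance = 1e-8)
  expect_equal(out2[, "A"], exp(-k1 * tt), tolerance = 1e-8)
  expect_equal(out2[, "C"], 1 - out2[, "A"] - out2[, "B"], tolerance = 1e-8)
})

test_that("mass is conserved under unit yields", {
  tt <- seq(0, 48, by = 2)
  for (net in list(chain_network(0.3, 0.05), build_default_network())) {
    out <- simulate_network(net, tt)
    tot <- rowSums(out)
    expect_equal(tot, rep(tot[1], length(tt)), tolerance = 1e-8)
  }
})

test_that("simulator validates its time grid", {
  net <- chain_network(0.1)
  expect_error(simulate_network(net, c(2, 4)), "start at 0")
  expect_error(simulate_network(net, c(0, 4, 4)), "strictly increasing")
})

test_that("intermediate peak time matches its closed form and the simulator", {
  expect_equal(intermediate_peak_time(0.25, 0.25), 4)
  expect_equal(intermediate_peak_time(0.2, 0.1), log(0.5) / (-0.1),
               tolerance = 1e-12)
  expect_equal(intermediate_peak_time(0.2, 0.1),
               intermediate_peak_time(0.1, 0.2))
  expect_error(intermediate_peak_time(0, 0.1), "positive")
  # cross-check against the argmax of the simulated intermediate
  fine <- seq(0, 48, by = 0.01)
  out <- simulate_network(chain_network(0.2, 0.1), fine)
  expect_equal(fine[which.max(out[, "B"])],
               intermediate_peak_time(0.2, 0.1), tolerance = 0.01)
})

test_that("default rates give transients peaking at 2-10 h", {
  net <- build_default_network()
  fine <- seq(0, 48, by = 0.05)
  out <- simulate_network(net, fine)
  for (sp in c("3,4-dihydroxyphenylacetic", "3,4-dihydroxyvalerolactone",
               "3-hydroxyvalerolactone", "3,4-dihydroxyphenylpropionic")) {
    tpk <- fine[which.max(out[, sp])]
    expect_gt(tpk, 1.5)
    expect_lt(tpk, 10.5)
  }
  # end-products effectively plateau by 48 h (relative slope is tiny)
  for (sp in c("3-hydroxyphenylacetic", "acetate")) {
    y <- out[, sp]
    slope <- (y[length(y)] - y[length(y) - 20]) / 1  # last hour
    expect_lt(slope / max(y), 0.01)
  }
})

test_that("generated studies have the full factorial layout", {
  design <- study_design()
  study <- generate_study(design, seed = 5)
  # 4 donors x (3 matrices + control) x 3 replicates x 12 analytes
  expect_length(study, 4 * 4 * 3 * 12)
  df <- do.call(rbind, lapply(study, as.data.frame))
  expect_setequal(unique(df$donor), design$donors)
  expect_setequal(unique(df$matrix), c(design$matrices, "control"))
  expect_equal(max(df$replicate), 3)
  expect_true(all(df$conc_mM >= 0))
})

test_that("noise-free control arms with zero baselines are identically zero", {
  study0 <- generate_study(study_design(replicates = 1),
                           noise = noise_model(sigma_rel = 0),
                           baselines = c(acetate = 0), seed = 1)
  ctl <- Filter(function(tc) tc$matrix == "control", study0)
  expect_gt(length(ctl), 0)
  for (tc in ctl) expect_equal(tc$conc, rep(0, 9))
})

test_that("the generator is bit-reproducible and seed-sensitive", {
  a <- generate_study(seed = 42)
  b <- generate_study(seed = 42)
  c <- generate_study(seed = 43)
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("generator validates multipliers and baselines", {
  expect_error(study_design(donors = c("O1", "O9")), "O9")
  expect_error(study_design(matrices = c("Mxx")), "Mxx")
  expect_error(generate_study(baselines = c(acetate = 2), seed = 1),
               "\\[0, 1\\]")
  bad <- study_design(matrix_multipliers = list(
    Mno = c(scfa = 0.5), Mnc = c(scfa = 1, polyphenol = 1),
    Mcov = c(scfa = 1, polyphenol = 1)))
  expect_error(generate_study(bad, seed = 1), "polyphenol")
})

test_that("noise-free round trip recovers the generating source rates within 2%", {
  design <- study_design(replicates = 1)
  study <- generate_study(design, noise = noise_model(sigma_rel = 0), seed = 1)
  net <- build_default_network()
  key <- function(tc) paste(tc$donor, tc$matrix, tc$replicate, tc$analyte,
                            sep = "|")
  names(study) <- vapply(study, key, character(1))
  k_pca <- sum(net$edges$k[net$edges$source == "procyanidins"])
  k_carb <- sum(net$edges$k[net$edges$source == "carbohydrates"])
  for (donor in c("O1", "O3")) {
    dmul <- design$donor_multipliers[[donor]]
    for (mat in c("Mno", "Mcov")) {
      mmul <- design$matrix_multipliers[[mat]]
      ctl <- study[[paste(donor, "control", 1, "procyanidins", sep = "|")]]
      tc <- subtract_background(
        study[[paste(donor, mat, 1, "procyanidins", sep = "|")]], ctl)
      fit <- fit_fractional_conversion(tc)
      expected <- k_pca * dmul * mmul[["polyphenol"]]
      expect_lt(abs(fit$K - expected) / expected, 0.02)
      # acetate rises with the total carbohydrate-pool decay rate
      ctl_a <- study[[paste(donor, "control", 1, "acetate", sep = "|")]]
      tca <- subtract_background(
        study[[paste(donor, mat, 1, "acetate", sep = "|")]], ctl_a)
      fita <- fit_fractional_conversion(tca)
      expected_a <- k_carb * dmul * mmul[["scfa"]]
      expect_lt(abs(fita$K - expected_a) / expected_a, 0.02)
    }
  }
})

test_that("end-product series are non-decreasing without noise", {
  study <- generate_study(study_design(replicates = 1),
                          noise = noise_model(sigma_rel = 0), seed = 1)
  ends <- c("acetate", "propionate", "butyrate", "3-hydroxyphenylacetic",
            "3-phenylpropionic")
  for (tc in study) {
    if (tc$matrix != "control" && tc$analyte %in% ends)
      expect_true(all(diff(tc$conc) >= -1e-10))
  }
})
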
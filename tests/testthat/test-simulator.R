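test_that("HWE haplotype frequencies are per-locus products", {
  f1 <- hwe_hap_frequencies(0.3, 4L)
  expect_equal(unname(f1["0000"]), 0.7^4)          # 0.2401
  expect_equal(unname(f1["1100"]), 0.3^2 * 0.7^2)  # 0.0441
  expect_equal(unname(f1["1101"]), 0.3^3 * 0.7)    # 0.0189
  expect_equal(sum(f1), 1)
  f2 <- hwe_hap_frequencies(0.2, 4L)
  expect_equal(unname(f2["0000"]), 0.4096)
  expect_equal(sum(f2), 1)
})

test_that("frequency rescaling preserves the risk-haplotype ratio and sums to 1", {
  f1 <- hwe_hap_frequencies(0.3, 4L)
  # the base risk pair already sums to 0.063, so that target is a no-op
  same <- rescale_frequencies(f1, c("1100", "1101"), 0.0441 + 0.0189)
  expect_equal(same, f1)

  up <- rescale_frequencies(f1, c("1100", "1101"), 0.2)
  expect_equal(unname(up["1100"]), 0.14)  # ratio 0.0441:0.0189 = 7:3
  expect_equal(unname(up["1101"]), 0.06)
  expect_equal(unname(up["0000"]), 0.2401 * 0.8 / 0.937)
  expect_equal(sum(up), 1)
  expect_error(rescale_frequencies(f1, "1100", 1.2),
               class = "pixhap_config_error")
})

test_that("datasets are deterministic given the seed and sized as configured", {
  cfg <- scenario_config("null-hwe", n_families = 250L)
  set.seed(123); a <- simulate_triads(cfg)
  set.seed(123); b <- simulate_triads(cfg)
  expect_identical(a$father, b$father)
  expect_identical(a$child, b$child)
  expect_equal(n_families(a), 250L)
  set.seed(124)
  expect_false(identical(simulate_triads(cfg)$father, a$father))
})

test_that("re-phasing a simulated dataset recovers the generator's truth exactly", {
  cfg <- scenario_config("A", n_families = 300L)
  set.seed(125)
  ts <- simulate_triads(cfg)
  truth <- attr(ts, "truth")
  ph <- phase_triads(ts)
  expect_equal(ph$n_missing + ph$n_mendelian, 0L)
  expect_identical(ph$paternal, truth$paternal)
  expect_identical(ph$mat_trans, truth$mat_trans)
  expect_identical(ph$mat_untrans, truth$mat_untrans)
})

test_that("null ascertainment leaves parental haplotype frequencies untouched", {
  set.seed(126)
  cfg <- scenario_config("null-hwe", n_families = 4000L)
  ph <- phase_triads(simulate_triads(cfg))
  counts <- tabulate(phased_codes(ph), nbins = 16L)
  expected <- hwe_hap_frequencies(0.3, 4L) * 3 * 4000
  gof <- chisq.test(counts, p = hwe_hap_frequencies(0.3, 4L))
  expect_gt(gof$p.value, 0.01)
  # scenario A with all relative risks 1 reduces to the null generator
  null_map <- data.frame(haplotype = "1100", rb = 1, rg1 = 1, rg2 = 1)
  cfg2 <- sim_config(hwe_hap_frequencies(0.3, 4L), risk_map = null_map,
                     n_families = 2000L)
  set.seed(127)
  ph2 <- phase_triads(simulate_triads(cfg2))
  gof2 <- chisq.test(tabulate(phased_codes(ph2), nbins = 16L),
                     p = hwe_hap_frequencies(0.3, 4L))
  expect_gt(gof2$p.value, 0.01)
})

test_that("PHE holds by construction: the father's slot is exchangeable", {
  set.seed(128)
  cfg <- scenario_config("A", n_families = 6000L, risk_frequency = 0.2)
  ts <- simulate_triads(cfg)
  truth <- attr(ts, "truth")
  codes <- phased_codes(truth)
  distinct <- apply(codes, 1, function(x) length(unique(x)) == 3L)
  # rank of the father's code among the three drawn haplotypes is uniform
  ranks <- apply(codes[distinct, ], 1, function(x) rank(x)[1L])
  expect_gt(chisq.test(table(factor(ranks, 1:3)))$p.value, 0.01)
})

test_that("risk haplotype transmission odds from heterozygous mothers to boys approach the male relative risk", {
  set.seed(129)
  cfg <- scenario_config("A", n_families = 20000L, risk_frequency = 0.2)
  ts <- simulate_triads(cfg)
  truth <- attr(ts, "truth")
  risk <- hap_parse("1100")
  male <- truth$child_sex == "male"
  m1 <- hap_encode(truth$mat_trans); m2 <- hap_encode(truth$mat_untrans)
  het <- male & ((m1 == risk) + (m2 == risk) == 1L)
  transmitted <- mean(m1[het] == risk)
  # P(transmit risk | heterozygous mother, affected boy) = 1.5 / 2.5
  expect_equal(transmitted, 1.5 / 2.5, tolerance = 0.03)
})

test_that("configs validate frequencies and risk maps", {
  expect_error(sim_config(c(0.5, 0.4)), class = "pixhap_config_error")
  bad <- hwe_hap_frequencies(0.3, 4L); bad[1] <- bad[1] + 0.01
  expect_error(sim_config(bad), class = "pixhap_config_error")
  cfg <- scenario_config("B")
  expect_equal(cfg$rb[hap_parse("1101")], 1.2)
  expect_equal(cfg$rg1[hap_parse("1101")], sqrt(1.2))
  cfgC <- scenario_config("C")
  expect_equal(cfgC$rb[hap_parse("1101")], 1 / 1.2)
  expect_equal(cfgC$rg2[hap_parse("1100")], 1.5)
  strat <- scenario_config("null-stratified")
  expect_equal(strat$baseline_risk_ratio, 4)
  expect_equal(strat$n_subpop, 2L)
})
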
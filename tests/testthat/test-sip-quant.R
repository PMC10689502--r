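# Total-protein-approach quantification

test_that("relative abundance normalizes intensities within each sample", {
  lfq <- data.frame(sample_id = "s1", protein_id = c("p1", "p2"),
                    lfq_intensity = c(3, 1))
  rel <- relative_protein_abundance(lfq, "s1")
  expect_equal(rel, c(p1 = 0.75, p2 = 0.25))

  one <- data.frame(sample_id = "s1", protein_id = "p1", lfq_intensity = 7)
  expect_equal(relative_protein_abundance(one, "s1"), c(p1 = 1.0))

  set.seed(42)
  big <- data.frame(sample_id = "s1",
                    protein_id = sprintf("p%02d", 1:50),
                    lfq_intensity = rlnorm(50))
  expect_lt(abs(sum(relative_protein_abundance(big, "s1")) - 1), 1e-9)

  zero <- data.frame(sample_id = "s1", protein_id = c("p1", "p2"),
                     lfq_intensity = c(0, 0))
  expect_error(relative_protein_abundance(zero, "s1"), "all-zero")
})

test_that("absolute concentrations conserve the sample total", {
  rel <- c(p1 = 0.75, p2 = 0.25)
  g <- total_protein_g_per_l(rel, 1.0)
  expect_equal(unname(g), c(0.75, 0.25))
  expect_equal(sum(g), 1.0)
  expect_equal(total_protein_g_per_l(c(p1 = 0.25), 0.2), c(p1 = 0.05))
  expect_equal(unname(total_protein_g_per_l(rel, 0)), c(0, 0))
  expect_error(total_protein_g_per_l(rel, -1), "non-negative")
})

test_that("molar conversion uses molecular weights and round-trips", {
  prot <- data.frame(protein_id = c("p1", "p2"), mag_id = "m",
                     molecular_weight = c(5e4, 2.5e4))
  g <- c(p1 = 0.05, p2 = 0)
  nmol <- total_protein_nmol_per_l(g, prot)
  expect_equal(unname(nmol), c(1000, 0))
  back <- nmol * c(5e4, 2.5e4) / 1e9
  expect_equal(unname(back), unname(g), tolerance = 1e-12)
  expect_error(total_protein_nmol_per_l(c(p3 = 1), prot), "p3")
})

test_that("per-MAG 13C protein follows the mean-RIA x mean-LR aggregation", {
  prot <- data.frame(protein_id = c("p1", "p2"), mag_id = "magA",
                     molecular_weight = 5e4)
  g <- c(p1 = 0.010, p2 = 0.006)  # 10 and 6 mg/L
  lab <- data.frame(sample_id = "s1", protein_id = c("p1", "p2"),
                    ria = c(0.4, 0.6), lr = c(0.3, 0.7))
  out <- mag_c13_protein(g, lab, prot, "s1")
  expect_equal(out$total_protein, 16)
  expect_equal(out$c13_protein, 16 * 0.5 * 0.5)  # 4 mg/L

  lab0 <- transform(lab, lr = 0)
  expect_equal(mag_c13_protein(g, lab0, prot, "s1")$c13_protein, 0)

  pct <- transform(lab, ria = ria * 100)
  expect_error(mag_c13_protein(g, pct, prot, "s1"), "percent/fraction")
})

test_that("13C protein never exceeds total protein and scales linearly in LR", {
  set.seed(7)
  prot <- data.frame(protein_id = sprintf("p%03d", 1:60),
                     mag_id = rep(c("a", "b", "c"), each = 20),
                     molecular_weight = runif(60, 1e4, 1e5))
  g <- setNames(rlnorm(60) / 1e3, prot$protein_id)
  lab <- data.frame(sample_id = "s1", protein_id = prot$protein_id,
                    ria = runif(60), lr = runif(60))
  out <- mag_c13_protein(g, lab, prot, "s1")
  expect_true(all(out$c13_protein <= out$total_protein + 1e-12))
  expect_true(all(out$c13_protein >= 0))
  for (cf in c(0.2, 0.5, 1)) {
    scaled <- transform(lab, lr = lr * cf)
    out2 <- mag_c13_protein(g, scaled, prot, "s1")
    expect_equal(out2$c13_protein, out$c13_protein * cf, tolerance = 1e-12)
  }
})

test_that("proteins in several MAGs are excluded from the label means", {
  prot <- data.frame(protein_id = c("p1", "p2", "p2"),
                     mag_id = c("a", "a", "b"),
                     molecular_weight = 5e4)
  g <- c(p1 = 0.010, p2 = 0.010)
  lab <- data.frame(sample_id = "s1", protein_id = c("p1", "p2"),
                    ria = c(0.5, 0.9), lr = c(0.5, 0.9))
  out <- mag_c13_protein(g, lab, prot, "s1")
  a <- out[out$mag_id == "a", ]
  expect_equal(a$mean_ria, 0.5)  # p2's labels ignored
  expect_equal(a$n_labeled, 1L)
})

test_that("biomass yield reproduces the reported per-MAG arithmetic", {
  # 8 + 4 + 2 + 1 mg/L of 13C protein, 3000 mg/L acetate
  y <- biomass_yield(c(8, 4, 2, 1), 3000)
  expect_equal(y$vss_yield, 0.01)
  expect_equal(y$cod_yield, (30 * 1.42) / (3000 * 64 / 59), tolerance = 1e-12)
  expect_equal(round(y$cod_yield, 4), 0.0131)
  expect_equal(biomass_yield(numeric(0), 3000)$vss_yield, 0)
  expect_error(biomass_yield(c(1, 2), 0), "positive")
})

test_that("metaproteome fractions sum MAG-wise and recover designed shares", {
  prot <- data.frame(protein_id = c("p1", "p2", "p3"),
                     mag_id = c("a", "a", "b"),
                     molecular_weight = 5e4)
  rel <- c(p1 = 0.4, p2 = 0.2, p3 = 0.4)
  fr <- metaproteome_fraction(rel, prot)
  expect_equal(fr, c(a = 0.6, b = 0.4))
  expect_equal(sum(fr), 1)
  expect_equal(metaproteome_fraction(c(p1 = 0.6, p2 = 0.4), prot),
               c(a = 1.0))
})

test_that("synthetic community recovers per-MAG 13C protein and shares", {
  design <- community_design(
    mags = data.frame(mag_id = c("m1", "saob", "m2", "other"),
                      proteome_share = c(0.50, 0.23, 0.18, 0.09),
                      n_proteins = c(500, 500, 500, 200),
                      label_uptake_rate = c(0.010, 0.012, 0.008, 0.004)),
    noise_cv = 0.1)
  sim <- simulate_proteomics(design, seed = 11)
  q <- quantify_sip_proteome(sim$proteins, sim$lfq, sim$labels, sim$samples)

  # designed (noise-free) truth at the final time point
  last <- q$per_mag[q$per_mag$sample_id == "t408_r1", ]
  tr <- sim$truth[sim$truth$sample_id == "t408_r1", ]
  total_mg <- 0.036 * 1e3
  for (m in design$mags$mag_id) {
    d <- tr[tr$mag_id == m, ]
    designed_c13 <- d$designed_share * total_mg *
      (0.98 * d$designed_sat) * d$designed_sat
    est <- last$c13_protein[last$mag_id == m]
    expect_lt(abs(est - designed_c13) / designed_c13, 0.10)
  }

  rel <- relative_protein_abundance(sim$lfq, "t024_r1")
  fr <- metaproteome_fraction(rel, sim$proteins)
  expect_true(all(abs(fr[design$mags$mag_id] -
                        design$mags$proteome_share) < 0.02))
})

test_that("label reader converts percent tables to fractions", {
  d <- tempfile(fileext = ".tsv")
  writeLines(c("# MetaProSIP-style export",
               "sample_id\tprotein_id\tria\tlr\tunit",
               "s1\tp1\t45.0\t30.0\tpercent",
               "s1\tp2\t0.5\t0.25\tfraction"), d)
  tab <- read_label_table(d)
  expect_equal(tab$ria, c(0.45, 0.5))
  expect_equal(tab$lr, c(0.30, 0.25))
})
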
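# Ground-truthed synthetic data for every pipeline stage.
#
# The proteomics generator emulates the shape of a time-resolved SIP
# incubation of an enriched consortium: a handful of dominant genomes with
# fixed metaproteome shares, lognormal LFQ intensities, and RIA/LR label
# time courses that rise saturating toward the tracer purity. The headspace
# generator runs the two-source mixing model forward. Truth files carry the
# exact quantities every downstream estimator should recover.

#' Design of a synthetic SIP community
#'
#' Defaults mirror the enrichment studied by the package: three dominant
#' genomes holding 50/23/18 percent of the metaproteome (a hydrogen-only
#' methanogen, the acetate oxidizer, and a formate-plus-hydrogen methanogen)
#' plus a 9 percent tail of other genomes; triplicate sampling at 24, 144
#' and 408 h; 3000 mg/L acetate; tracer purity 0.98.
#'
#' @param mags data.frame with `mag_id`, `proteome_share`, `n_proteins`,
#'   `label_uptake_rate` (1/h)
#' @param time_h sampling times (hours)
#' @param n_replicates biological replicates per time point
#' @param total_protein_g_per_l total protein concentration at each time
#'   point (recycled to `length(time_h)`)
#' @param acetate_dose_mg_l acetate fed, mg/L
#' @param tracer_purity 13C atom fraction of the tracer
#' @param noise_cv coefficient of variation of the multiplicative
#'   measurement noise
#' @return list of class `sip_design`
#' @export
community_design <- function(mags = NULL,
                             time_h = c(24, 144, 408),
                             n_replicates = 3,
                             total_protein_g_per_l = c(0.020, 0.028, 0.036),
                             acetate_dose_mg_l = 3000,
                             tracer_purity = 0.98,
                             noise_cv = 0.1) {
  if (is.null(mags)) {
    mags <- data.frame(
      mag_id = c("methanothermobacter_1", "dtu068_1",
                 "methanothermobacter_2", "other"),
      proteome_share = c(0.50, 0.23, 0.18, 0.09),
      n_proteins = c(300, 300, 300, 100),
      label_uptake_rate = c(0.010, 0.012, 0.008, 0.004),
      stringsAsFactors = FALSE)
  }
  if (abs(sum(mags$proteome_share) - 1) > 1e-9)
    stopf("proteome shares must sum to 1")
  if (any(mags$n_proteins < 1)) stopf("each MAG needs at least one protein")
  if (noise_cv < 0) stopf("noise_cv must be non-negative")
  structure(list(mags = mags, time_h = time_h, n_replicates = n_replicates,
                 total_protein_g_per_l =
                   rep_len(total_protein_g_per_l, length(time_h)),
                 acetate_dose_mg_l = acetate_dose_mg_l,
                 tracer_purity = tracer_purity, noise_cv = noise_cv),
            class = "sip_design")
}

#' Simulate a SIP metaproteomics experiment
#'
#' Per-protein molecular weights are drawn uniformly on 10-150 kg/mol; LFQ
#' intensities are lognormal with MAG-level means proportional to the
#' designed proteome shares; per-protein RIA and LR follow saturating
#' curves `purity * (1 - exp(-k t))` (RIA capped at the tracer purity) with
#' multiplicative lognormal noise of the designed CV. The truth list
#' records, per sample and MAG, the exact total protein and 13C protein
#' implied by the generated tables with the noise included — i.e. what a
#' perfect estimator reading the same tables would return — along with the
#' designed (noise-free) values.
#'
#' @param design a [community_design()]
#' @param seed RNG seed; the same seed yields identical tables
#' @return list with `proteins`, `lfq`, `labels`, `samples` data.frames and
#'   `truth`
#' @export
simulate_proteomics <- function(design, seed = 1) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  mags <- design$mags
  proteins <- do.call(rbind, lapply(seq_len(nrow(mags)), function(i) {
    n <- mags$n_proteins[i]
    data.frame(protein_id = sprintf("%s_p%04d", mags$mag_id[i], seq_len(n)),
               mag_id = mags$mag_id[i],
               molecular_weight = stats::runif(n, 1e4, 1.5e5),
               stringsAsFactors = FALSE)
  }))
  # per-protein expected intensity: MAG share split unevenly within the MAG
  w <- unlist(lapply(seq_len(nrow(mags)), function(i) {
    wi <- stats::rlnorm(mags$n_proteins[i], 0, 1)
    mags$proteome_share[i] * wi / sum(wi)
  }))
  sdlog <- sqrt(log(1 + design$noise_cv^2))
  samples <- expand.grid(time_h = design$time_h,
                         replicate = seq_len(design$n_replicates))
  samples <- samples[order(samples$time_h, samples$replicate), ]
  samples$sample_id <- sprintf("t%03d_r%d", samples$time_h, samples$replicate)
  samples$total_protein_g_per_l <-
    design$total_protein_g_per_l[match(samples$time_h, design$time_h)]
  samples <- samples[, c("sample_id", "time_h", "replicate",
                         "total_protein_g_per_l")]
  rownames(samples) <- NULL

  k_of <- stats::setNames(mags$label_uptake_rate, mags$mag_id)
  lfq <- list(); labels <- list(); truth_rows <- list()
  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample_id[i]
    t <- samples$time_h[i]
    noise <- stats::rlnorm(nrow(proteins), -sdlog^2 / 2, sdlog)
    intensity <- 1e9 * w * noise
    lfq[[i]] <- data.frame(sample_id = sid,
                           protein_id = proteins$protein_id,
                           lfq_intensity = intensity,
                           stringsAsFactors = FALSE)
    sat <- 1 - exp(-k_of[proteins$mag_id] * t)
    ria <- pmin(design$tracer_purity,
                design$tracer_purity * sat *
                  stats::rlnorm(nrow(proteins), -sdlog^2 / 2, sdlog))
    lr <- pmin(1, sat * stats::rlnorm(nrow(proteins), -sdlog^2 / 2, sdlog))
    labels[[i]] <- data.frame(sample_id = sid,
                              protein_id = proteins$protein_id,
                              ria = as.numeric(ria), lr = as.numeric(lr),
                              stringsAsFactors = FALSE)
    # exact bookkeeping of labeled mass in the generated tables
    rel <- intensity / sum(intensity)
    mg <- rel * samples$total_protein_g_per_l[i] * 1e3
    for (m in mags$mag_id) {
      sel <- proteins$mag_id == m
      truth_rows[[length(truth_rows) + 1]] <- data.frame(
        sample_id = sid, mag_id = m,
        total_protein_mg_l = sum(mg[sel]),
        mean_ria = mean(ria[sel]), mean_lr = mean(lr[sel]),
        c13_protein_mg_l = sum(mg[sel]) * mean(ria[sel]) * mean(lr[sel]),
        designed_share = mags$proteome_share[mags$mag_id == m],
        designed_sat = 1 - exp(-k_of[m] * t),
        stringsAsFactors = FALSE)
    }
  }
  list(proteins = proteins,
       lfq = do.call(rbind, lfq),
       labels = do.call(rbind, labels),
       samples = samples,
       truth = do.call(rbind, truth_rows))
}

#' Write simulated SIP tables as TSV files
#'
#' @param sim output of [simulate_proteomics()]
#' @param dir output directory
#' @return invisibly the written paths
#' @export
write_sip_tables <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(proteins = file.path(dir, "proteins.tsv"),
             lfq = file.path(dir, "lfq.tsv"),
             labels = file.path(dir, "labels.tsv"),
             samples = file.path(dir, "samples.tsv"),
             truth = file.path(dir, "truth.tsv"))
  for (nm in names(paths))
    utils::write.table(sim[[nm]], paths[[nm]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(paths)
}

#' Simulate headspace isotope measurements
#'
#' Forward two-source mixing model under methyl-labeled acetate: the CO2
#' pool label rises as methyl-derived 13CO2 dilutes into the initially
#' unlabeled DIC pool, `a_co2(t) = a_bg + (a_methyl - a_bg) * w_max *
#' (1 - exp(-r t))`; the CH4 label mixes the two routes,
#' `a_ch4 = f_sao * a_co2 + (1 - f_sao) * a_methyl`. Multiplicative
#' Gaussian noise is added to both measured pools.
#'
#' @param f_sao true SAO share of the methane-forming carbon flux, in
#'   \[0, 1\]
#' @param a_methyl tracer atom fraction (default 0.98)
#' @param a_background DIC background atom fraction (default 0.0111)
#' @param w_max asymptotic labeled fraction of the DIC pool. Under
#'   methyl-labeled acetate only one of the two acetate carbons carries the
#'   tracer and the generated CO2 dilutes into the pre-existing unlabeled
#'   DIC and headspace CO2, so the pool label saturates near one half
#'   (default 0.5)
#' @param rate turnover rate of the DIC pool, 1/h
#' @param n_obs number of observations
#' @param t_max time span, hours
#' @param noise relative (multiplicative) noise standard deviation
#' @param seed RNG seed
#' @return list with `headspace` data.frame (`time_h`, `a_co2`, `a_ch4`)
#'   and `truth`
#' @export
simulate_headspace <- function(f_sao, a_methyl = 0.98, a_background = 0.0111,
                               w_max = 0.5, rate = 0.02, n_obs = 20,
                               t_max = 408, noise = 0.05, seed = 1) {
  if (f_sao < 0 || f_sao > 1) stopf("f_sao must be in [0, 1]")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  t <- seq(t_max / n_obs, t_max, length.out = n_obs)
  w <- w_max * (1 - exp(-rate * t))
  a_co2 <- a_background + (a_methyl - a_background) * w
  a_ch4 <- f_sao * a_co2 + (1 - f_sao) * a_methyl
  obs_co2 <- pmin(1, pmax(0, a_co2 * (1 + stats::rnorm(n_obs, 0, noise))))
  obs_ch4 <- pmin(1, pmax(0, a_ch4 * (1 + stats::rnorm(n_obs, 0, noise))))
  list(headspace = data.frame(time_h = t, a_co2 = obs_co2, a_ch4 = obs_ch4),
       truth = list(f_sao = f_sao, a_methyl = a_methyl,
                    a_background = a_background,
                    a_co2_true = a_co2, a_ch4_true = a_ch4))
}
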
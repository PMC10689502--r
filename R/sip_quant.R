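# Total-protein-approach quantification of SIP metaproteomics.
#
# The chain is: label-free quantification (LFQ) intensities are normalized to
# relative abundances (g/g), scaled by the sample's measured total protein
# concentration (g/L), optionally converted to molar units, and combined with
# the per-protein isotope-labeling metrics (RIA = 13C atom fraction of the
# labeled peptides, LR = fraction of peptide signal in the labeled
# isotopologue cluster) into per-genome (MAG) 13C-protein concentrations.

#' Relative protein abundance within a sample
#'
#' Normalizes LFQ intensities of one sample to fractions (g protein per g
#' total sample protein): each protein's summed unique-PSM intensity divided
#' by the summed intensity over all proteins detected in the sample.
#'
#' @param lfq data.frame with columns `sample_id`, `protein_id`,
#'   `lfq_intensity` (non-negative, arbitrary units)
#' @param sample_id sample to normalize
#' @return named numeric vector, protein_id -> fraction; sums to 1
#' @export
relative_protein_abundance <- function(lfq, sample_id) {
  rows <- lfq[lfq$sample_id == sample_id, , drop = FALSE]
  if (nrow(rows) == 0) stopf("no LFQ rows for sample '%s'", sample_id)
  if (anyDuplicated(rows$protein_id))
    stopf("duplicate protein rows for sample '%s'", sample_id)
  if (any(rows$lfq_intensity < 0))
    stopf("negative LFQ intensity in sample '%s'", sample_id)
  tot <- sum(rows$lfq_intensity)
  if (tot <= 0)
    stopf("all-zero LFQ intensities in sample '%s': relative abundance undefined",
          sample_id)
  stats::setNames(rows$lfq_intensity / tot, rows$protein_id)
}

#' Absolute protein concentration (g/L)
#'
#' Scales relative abundances by the sample's total protein concentration.
#'
#' @param rel_abund named vector from [relative_protein_abundance()]
#' @param total_protein_conc total protein in the sample, g/L
#' @return named numeric vector, protein_id -> g/L; sums to
#'   `total_protein_conc`
#' @export
total_protein_g_per_l <- function(rel_abund, total_protein_conc) {
  if (length(total_protein_conc) != 1 || is.na(total_protein_conc) ||
      total_protein_conc < 0)
    stopf("total_protein_conc must be a single non-negative number (g/L)")
  rel_abund * total_protein_conc
}

#' Molar protein concentration (nmol/L)
#'
#' Converts mass concentrations to molar concentrations using per-protein
#' molecular weights inferred from the amino-acid sequence.
#'
#' @param total_g_per_l named vector from [total_protein_g_per_l()]
#' @param proteins data.frame with columns `protein_id`, `mag_id`,
#'   `molecular_weight` (g/mol)
#' @return named numeric vector, protein_id -> nmol/L
#' @export
total_protein_nmol_per_l <- function(total_g_per_l, proteins) {
  mw <- stats::setNames(proteins$molecular_weight, proteins$protein_id)
  ids <- names(total_g_per_l)
  missing <- ids[!(ids %in% names(mw)) | is.na(mw[ids])]
  if (length(missing) > 0)
    stopf("no molecular weight for protein(s): %s",
          paste(utils::head(missing, 5), collapse = ", "))
  if (any(mw[ids] <= 0)) stopf("molecular weights must be positive")
  total_g_per_l / mw[ids] * 1e9
}

#' Per-MAG 13C-protein concentration (mg/L)
#'
#' For each MAG, multiplies the summed absolute protein concentration of its
#' proteins (mg/L) by the unweighted mean RIA and the unweighted mean LR over
#' the MAG's labeled proteins in the sample. Proteins with LFQ signal but no
#' label row contribute to total protein but not to the means; proteins
#' mapped to more than one MAG are excluded from the label means. MAGs with
#' no labeled proteins get 0 mg/L of 13C protein.
#'
#' @param total_g_per_l named vector from [total_protein_g_per_l()]
#' @param labels data.frame with columns `sample_id`, `protein_id`, `ria`,
#'   `lr`, both stored as fractions in \[0, 1\]
#' @param proteins protein table (see [total_protein_nmol_per_l()])
#' @param sample_id sample being summarized
#' @return data.frame with columns `mag_id`, `sample_id`, `total_protein`
#'   (mg/L), `mean_ria`, `mean_lr`, `c13_protein` (mg/L), `n_labeled`
#' @export
mag_c13_protein <- function(total_g_per_l, labels, proteins, sample_id) {
  check_fraction(labels$ria, "RIA")
  check_fraction(labels$lr, "LR")
  mag_of <- stats::setNames(proteins$mag_id, proteins$protein_id)
  n_mags <- tapply(proteins$mag_id, proteins$protein_id,
                   function(m) length(unique(m)))
  ambiguous <- names(n_mags)[n_mags > 1]

  ids <- names(total_g_per_l)
  unknown <- ids[!ids %in% names(mag_of)]
  if (length(unknown) > 0)
    stopf("protein(s) without MAG assignment: %s",
          paste(utils::head(unknown, 5), collapse = ", "))
  mg_l <- total_g_per_l * 1e3

  lab <- labels[labels$sample_id == sample_id &
                  labels$protein_id %in% ids &
                  !(labels$protein_id %in% ambiguous), , drop = FALSE]
  lab$mag_id <- mag_of[lab$protein_id]

  mags <- sort(unique(mag_of[ids]))
  out <- data.frame(mag_id = mags, sample_id = sample_id,
                    total_protein = NA_real_, mean_ria = 0, mean_lr = 0,
                    c13_protein = 0, n_labeled = 0L,
                    stringsAsFactors = FALSE)
  for (k in seq_along(mags)) {
    m <- mags[k]
    out$total_protein[k] <- sum(mg_l[mag_of[ids] == m])
    lm <- lab[lab$mag_id == m, , drop = FALSE]
    if (nrow(lm) > 0) {
      out$mean_ria[k] <- mean(lm$ria)
      out$mean_lr[k] <- mean(lm$lr)
      out$n_labeled[k] <- nrow(lm)
      out$c13_protein[k] <- out$total_protein[k] * out$mean_ria[k] * out$mean_lr[k]
    }
  }
  out
}

#' Community biomass yield from labeled protein
#'
#' Converts the total 13C-protein produced (summed over MAGs at the final
#' time point) into a community biomass yield on acetate, using a
#' protein-to-biomass ratio (g protein per g volatile suspended solids, VSS)
#' and a VSS-to-COD conversion. The chemical-oxygen-demand (COD) equivalent
#' of the acetate ion defaults to 64/59 g-COD/g (2 mol O2 per mol acetate).
#'
#' @param c13_totals numeric vector of per-MAG 13C protein, mg/L
#' @param acetate_dose acetate fed, mg/L
#' @param protein_per_vss g protein per g VSS (default 0.5)
#' @param cod_per_vss g COD biomass per g VSS (default 1.42)
#' @param cod_per_g_acetate g COD per g acetate ion (default 64/59)
#' @return list with `vss_yield` (g-VSS/g-acetate) and `cod_yield`
#'   (g-COD biomass / g-COD acetate)
#' @export
biomass_yield <- function(c13_totals, acetate_dose, protein_per_vss = 0.5,
                          cod_per_vss = 1.42, cod_per_g_acetate = 64 / 59) {
  if (acetate_dose <= 0) stopf("acetate_dose must be positive (mg/L)")
  vss <- sum(c13_totals) / protein_per_vss / acetate_dose
  cod <- vss * cod_per_vss / cod_per_g_acetate
  list(vss_yield = vss, cod_yield = cod)
}

#' Per-MAG share of the metaproteome
#'
#' Sums relative protein abundances by MAG; shares total 1 across all MAGs
#' detected in the sample.
#'
#' @inheritParams total_protein_nmol_per_l
#' @param rel_abund named vector from [relative_protein_abundance()]
#' @return named numeric vector, mag_id -> fraction
#' @export
metaproteome_fraction <- function(rel_abund, proteins) {
  mag_of <- stats::setNames(proteins$mag_id, proteins$protein_id)
  ids <- names(rel_abund)
  unknown <- ids[!ids %in% names(mag_of)]
  if (length(unknown) > 0)
    stopf("protein(s) without MAG assignment: %s",
          paste(utils::head(unknown, 5), collapse = ", "))
  shares <- tapply(rel_abund, mag_of[ids], sum)
  stats::setNames(as.numeric(shares), names(shares))
}

#' Run the full SIP quantification chain over all samples
#'
#' Convenience wrapper applying the quantification equations sample by
#' sample and assembling per-protein and per-MAG outputs.
#'
#' @param proteins protein table (`protein_id`, `mag_id`, `molecular_weight`)
#' @param lfq LFQ table (`sample_id`, `protein_id`, `lfq_intensity`)
#' @param labels label table (`sample_id`, `protein_id`, `ria`, `lr`),
#'   fractions
#' @param samples sample table (`sample_id`, `time_h`, `replicate`,
#'   `total_protein_g_per_l`)
#' @return list with `per_protein` (sample_id, protein_id, g_per_l,
#'   nmol_per_l) and `per_mag` (MAG label summaries, all samples)
#' @export
quantify_sip_proteome <- function(proteins, lfq, labels, samples) {
  per_protein <- list(); per_mag <- list()
  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample_id[i]
    rel <- relative_protein_abundance(lfq, sid)
    gpl <- total_protein_g_per_l(rel, samples$total_protein_g_per_l[i])
    npl <- total_protein_nmol_per_l(gpl, proteins)
    per_protein[[i]] <- data.frame(sample_id = sid, protein_id = names(gpl),
                                   rel_abund = as.numeric(rel),
                                   g_per_l = as.numeric(gpl),
                                   nmol_per_l = as.numeric(npl),
                                   stringsAsFactors = FALSE)
    pm <- mag_c13_protein(gpl, labels, proteins, sid)
    pm$time_h <- samples$time_h[i]
    pm$replicate <- samples$replicate[i]
    per_mag[[i]] <- pm
  }
  list(per_protein = do.call(rbind, per_protein),
       per_mag = do.call(rbind, per_mag))
}

#' Read a label table, accepting percent or fraction units
#'
#' MetaProSIP reports RIA as a percentage; this reader converts percent
#' columns to the package-internal fraction convention using the table's
#' `unit` column (`percent` or `fraction`) or an explicit override.
#'
#' @param path TSV with columns `sample_id`, `protein_id`, `ria`, `lr` and
#'   optionally `unit`
#' @param unit `"auto"` (use the table's unit column, default `fraction`),
#'   `"fraction"`, or `"percent"`
#' @return data.frame with `ria`, `lr` as fractions
#' @export
read_label_table <- function(path, unit = c("auto", "fraction", "percent")) {
  unit <- match.arg(unit)
  x <- read_tsv_table(path, required = c("sample_id", "protein_id", "ria", "lr"))
  u <- if (unit == "auto") {
    if ("unit" %in% names(x)) x$unit else rep("fraction", nrow(x))
  } else rep(unit, nrow(x))
  pct <- u == "percent"
  x$ria[pct] <- x$ria[pct] / 100
  x$lr[pct] <- x$lr[pct] / 100
  x$unit <- NULL
  check_fraction(x$ria, "RIA")
  check_fraction(x$lr, "LR")
  x
}
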
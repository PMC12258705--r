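#!/usr/bin/env Rscript
# Stage 3: comparative stability analytics on the PSI databases -
# residue-position matrices, genotype differences, P2 contrasts,
# charge/property analyses, and P1/P2 enrichment.
#
# Input:  results/db/        Output: results/analytics/

suppressMessages(library(psifive))

outdir <- "results/analytics"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

wt <- read_database("results/db/WT_psi.tsv")
ko <- read_database("results/db/CLPS_KO_psi.tsv")
message("WT motifs: ", nrow(wt), "; ClpS- motifs: ", nrow(ko))

# residue-by-position mean PSI and the WT - ClpS- difference heatmap
m_wt <- mean_psi_matrix(wt)
m_ko <- mean_psi_matrix(ko)
d <- delta_matrix(m_wt, m_ko)
write_matrix_tsv(m_wt, file.path(outdir, "mean_psi_WT.tsv"))
write_matrix_tsv(m_ko, file.path(outdir, "mean_psi_CLPS_KO.tsv"))
write_matrix_tsv(d, file.path(outdir, "delta_psi_WT_minus_CLPS_KO.tsv"))
p1 <- sort(unclass(d)[, "P1"])
message("most destabilizing P1 residues (delta PSI): ",
        paste(sprintf("%s %.2f", names(p1)[1:4], p1[1:4]), collapse = ", "))

# P2 contrasts on motifs with a canonically destabilizing P1
dest <- AA_GROUPS$CanonicalDestabilizing
for (res in c("P", "G", "Q")) {
  ct <- subset_contrast(
    wt,
    function(m) substr(m, 1, 1) %in% dest & substr(m, 2, 2) == res,
    function(m) substr(m, 1, 1) %in% dest & substr(m, 2, 2) != res)
  message(sprintf(
    "P2 %s with destabilizing P1: mean dPSI %+0.2f, ES %.2f, p %.2g %s",
    res, ct$mean_diff, ct$es, ct$p, ct$annotation))
}

# net-charge profile of P2-P5 for destabilizing-P1 motifs
chg <- net_charge(wt$motif, positions = 2:5)
dest_p1 <- substr(wt$motif, 1, 1) %in% dest
charge_psi <- aggregate(psi ~ charge,
                        data.frame(psi = wt$psi[dest_p1],
                                   charge = chg[dest_p1]), mean)
write.table(charge_psi, file.path(outdir, "net_charge_psi.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("mean PSI by P2-P5 net charge written (",
        nrow(charge_psi), " charge levels)")

# Gly/Ser counts downstream of a destabilizing P1
gs <- group_count(wt$motif, c("G", "S"), positions = 2:5)
gs_psi <- aggregate(psi ~ gs, data.frame(psi = wt$psi[dest_p1],
                                         gs = gs[dest_p1]), mean)
write.table(gs_psi, file.path(outdir, "glyser_count_psi.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# bulky x acidic crosstab for canonically stable P1
ct <- crosstab_bulky_negative(wt)
write_matrix_tsv(ct, file.path(outdir, "crosstab_bulky_negative.tsv"),
                 what = "mean delta PSI vs (0,0)")

# P1/P2 stable/unstable enrichment and the low-PSI composition logo
e <- tryCatch(p1p2_enrichment(wt), error = function(e) NULL)
if (!is.null(e)) {
  write_matrix_tsv(e, file.path(outdir, "p1p2_log2_enrichment.tsv"),
                   what = "log2 stable/unstable enrichment")
}
low <- wt[wt$psi < 3 &
            !substr(wt$motif, 1, 1) %in% c(dest, "P"), , drop = FALSE]
class(low) <- class(wt)
if (nrow(low) > 20) {
  logo <- enrichment_logo(low, wt)
  write_matrix_tsv(logo, file.path(outdir, "low_psi_logo.tsv"))
  message("low-PSI logo over ", nrow(low), " motifs written")
}

# MetAP position-shift comparison
mp <- metap_comparison(wt)
write.table(mp, file.path(outdir, "metap_comparison.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("analytics written to ", outdir)
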
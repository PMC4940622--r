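#!/usr/bin/env Rscript
# Stage 3 — linear-model statistics.
#
# Accession x treatment x block ANOVA for biomass and the GSL summary
# traits, broad-sense heritability from expected mean squares, and the
# uptake analysis restricted to AOP2-null accessions (whose treated-arm
# allyl content is exogenous uptake only).

suppressPackageStartupMessages(library(allylgwa))

traits <- read_phenotype_tsv("results/trait_table.tsv")

focal <- default_gwa_traits()
anova_all <- do.call(rbind, lapply(focal, function(tr) {
  cbind(trait = tr, as.data.frame(fit_anova(traits, tr)))
}))
write_phenotype_tsv(anova_all, "results/anova.tsv")

cat("biomass ANOVA (accession / treatment / interaction / block):\n")
print(as.data.frame(anova_all[anova_all$trait == "biomass_mg",
                              c("term", "df", "sumsq", "statistic",
                                "p.value")]),
      row.names = FALSE, digits = 3)

h2 <- data.frame(
  trait = focal,
  H2 = vapply(focal, function(tr) broad_sense_h2(traits, tr)$H2,
              numeric(1))
)
write_phenotype_tsv(h2, "results/heritability.tsv")
cat("\nbroad-sense heritability:\n")
print(h2, row.names = FALSE, digits = 3)

# uptake: AOP2-null accessions, treated arm only
uptake <- traits[!traits$aop2_functional & traits$treatment != "MS", ]
tab_u <- fit_anova(uptake, "Allyl", c("accession", "block"))
h2_u <- broad_sense_h2(uptake, "Allyl")
cat(sprintf("\nallyl uptake (%d AOP2-null accessions): accession df = %d, H2 = %.2f\n",
            length(unique(uptake$accession)),
            tab_u$df[tab_u$term == "accession"], h2_u$H2))
cat(sprintf("grand mean foliar allyl from uptake: %.3f umol/g fw (range %.2f-%.2f across accessions)\n",
            mean(uptake$Allyl),
            min(tapply(uptake$Allyl, uptake$accession, mean)),
            max(tapply(uptake$Allyl, uptake$accession, mean))))
write_phenotype_tsv(cbind(as.data.frame(tab_u),
                          H2 = c(h2_u$H2, rep(NA, nrow(tab_u) - 1))),
                    "results/uptake_anova.tsv")
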
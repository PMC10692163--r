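# Developer script: regenerate R/oracle-constants.R from the full enumeration
# space of the packaged default synthon sets. Run from the package root after
# any change to default_synthon_sets() or the .g_raw weights.
devtools::load_all(".", quiet = TRUE)

sets <- default_synthon_sets()
data <- alscreen:::.synthon_data(sets)
total <- alscreen:::.space_size(data)
cat("enumeration space:", total, "\n")

cfg <- library_config(n_molecules = total, seed = 1L)
lib <- generate_library(cfg)

x <- cbind(mw = lib$mw, clogp = lib$clogp, n_hba = lib$n_hba,
           n_aromatic_rings = lib$n_aromatic_rings)
mu <- colMeans(x)
sg <- apply(x, 2, sd)
w <- c(mw = -0.30, clogp = 0.25, n_hba = -0.25, n_aromatic_rings = -0.20)
acid <- as.numeric(lib$n_acid > 0)
u <- as.vector(scale(x, center = mu, scale = sg) %*% w) - 0.55 * acid

zs <- seq(-4.9, 4.9, by = 0.02)
probs <- pnorm(zs)
uq <- unname(quantile(u, probs, type = 8))
# enforce strict monotonicity: collapse duplicate-u knots, averaging z
keep <- !duplicated(uq)
agg <- tapply(zs, uq, mean)
ku <- as.numeric(names(agg)); kz <- as.numeric(agg)
o <- order(ku); ku <- ku[o]; kz <- kz[o]
cat("knots:", length(ku), "\n")

fmt <- function(v) paste(formatC(v, format = "g", digits = 10), collapse = ",\n  ")
out <- sprintf(
'# Frozen calibration constants for the tier-1 descriptor signal, generated
# from the full enumeration space (%d products) of the packaged default
# synthon sets by tools/dev-calibrate.R. The quantile map sends the raw
# standardized descriptor combination to a standard-normal marginal over that
# space; regenerate whenever the packaged sets or signal weights change.

.g_standardization <- list(
  mean = c(mw = %.10g, clogp = %.10g, n_hba = %.10g, n_aromatic_rings = %.10g),
  sd = c(mw = %.10g, clogp = %.10g, n_hba = %.10g, n_aromatic_rings = %.10g)
)

.g_knots_u <- c(
  %s
)

.g_knots_z <- c(
  %s
)
', total, mu[1], mu[2], mu[3], mu[4], sg[1], sg[2], sg[3], sg[4], fmt(ku), fmt(kz))
writeLines(out, "R/oracle-constants.R")
cat("wrote R/oracle-constants.R\n")
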
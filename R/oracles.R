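# Two synthetic scoring oracles standing in for a fast docking tier and a
# slow physics-based rescoring tier.
#
# Tier-1 scores are mu_1 + sigma_1 * z1 with
#   z1 = sqrt(signal_fraction) * g + sqrt(1 - signal_fraction) * h
# where g is a fixed, monotone descriptor signal (quantile-mapped to a
# standard-normal marginal over the default library; see vignette) and h is a
# deterministic hash-derived standard-normal deviate of (id, seed). Tier-2
# scores share the tier-1 latent through
#   z2 = rho * z1 + sqrt(1 - rho^2) * eps(id, seed)
# rescaled to mu_2 / sigma_2, giving a global Pearson correlation of rho.

#' Parameters of the synthetic scoring oracles
#'
#' @param mu_1,sigma_1 tier-1 score location/scale in kcal/mol; the defaults
#'   place the normal 1e-4 quantile (top 0.01 percent) at -9.0 kcal/mol
#' @param signal_fraction share of tier-1 score variance carried by the
#'   descriptor signal (learnable by a surrogate), in `[0, 1]`
#' @param rho global tier-1/tier-2 correlation, in `[-1, 1]`
#' @param mu_2,sigma_2 tier-2 score location/scale in kcal/mol
#' @param seed integer seed of the hash-noise streams
#' @return an object of class `oracle_params`
#' @export
oracle_params <- function(mu_1 = -5.70, sigma_1 = 0.887, signal_fraction = 0.64,
                          rho = 0.42, mu_2 = -40, sigma_2 = 8, seed = 1L) {
  stopifnot(sigma_1 > 0, sigma_2 > 0, abs(rho) <= 1,
            signal_fraction >= 0, signal_fraction <= 1,
            length(seed) == 1, is.finite(seed))
  structure(list(mu_1 = mu_1, sigma_1 = sigma_1,
                 signal_fraction = signal_fraction, rho = rho,
                 mu_2 = mu_2, sigma_2 = sigma_2, seed = as.integer(seed)),
            class = "oracle_params")
}

# standardized descriptor combination (before the quantile map); weights are
# fixed constants: size, polarity, acceptor count, aromatic surface and a
# carboxylic-acid indicator (acids score better, echoing phosphate-mimetic
# binding at a Walker A motif)
.g_raw <- function(records) {
  need <- c("mw", "clogp", "n_hba", "n_aromatic_rings", "n_acid")
  if (!all(need %in% names(records))) {
    stop("records lack descriptor columns: ",
         paste(setdiff(need, names(records)), collapse = ", "))
  }
  s <- .g_standardization
  z_mw <- (records$mw - s$mean[["mw"]]) / s$sd[["mw"]]
  z_lp <- (records$clogp - s$mean[["clogp"]]) / s$sd[["clogp"]]
  z_hba <- (records$n_hba - s$mean[["n_hba"]]) / s$sd[["n_hba"]]
  z_ar <- (records$n_aromatic_rings - s$mean[["n_aromatic_rings"]]) / s$sd[["n_aromatic_rings"]]
  acid <- as.numeric(records$n_acid > 0)
  -0.30 * z_mw + 0.25 * z_lp - 0.25 * z_hba - 0.20 * z_ar - 0.55 * acid
}

# monotone map from the raw combination to a standard-normal marginal over the
# default enumeration space; linear tail extrapolation beyond the knots
.g_map <- function(u) {
  ku <- .g_knots_u; kz <- .g_knots_z
  out <- approx(ku, kz, xout = u, rule = 2, ties = "ordered")$y
  n <- length(ku)
  lo <- u < ku[1]
  hi <- u > ku[n]
  if (any(lo)) {
    slope <- (kz[2] - kz[1]) / (ku[2] - ku[1])
    out[lo] <- kz[1] + (u[lo] - ku[1]) * slope
  }
  if (any(hi)) {
    slope <- (kz[n] - kz[n - 1]) / (ku[n] - ku[n - 1])
    out[hi] <- kz[n] + (u[hi] - ku[n]) * slope
  }
  out
}

.g_signal <- function(records) .g_map(.g_raw(records))

.hash_normal <- function(ids, seed, salt) qnorm(cpp_hash_unit(ids, seed, salt))

.tier1_latent <- function(records, params) {
  a <- sqrt(params$signal_fraction)
  b <- sqrt(1 - params$signal_fraction)
  a * .g_signal(records) + b * .hash_normal(records$id, params$seed, 101L)
}

#' Score molecules with the tier-1 (docking-like) oracle
#'
#' Deterministic in (molecule, params): identical inputs always yield
#' identical scores. Over the default library the marginal distribution is
#' approximately Normal(mu_1, sigma_1^2), calibrated so the 1e-4 quantile sits
#' at -9.0 kcal/mol.
#'
#' @param records a `molecule_records` data frame (descriptors required)
#' @param params an [oracle_params()]
#' @return numeric vector of scores in kcal/mol (lower = better)
#' @export
score_tier1 <- function(records, params = oracle_params()) {
  stopifnot(inherits(params, "oracle_params"))
  params$mu_1 + params$sigma_1 * .tier1_latent(records, params)
}

#' Score molecules with the tier-2 (rescoring) oracle
#'
#' Shares a latent component with tier-1 so that the two tiers correlate
#' globally at Pearson `rho` (default 0.42).
#'
#' @inheritParams score_tier1
#' @return numeric vector of tier-2 scores in kcal/mol (lower = better)
#' @export
score_tier2 <- function(records, params = oracle_params()) {
  stopifnot(inherits(params, "oracle_params"))
  z1 <- .tier1_latent(records, params)
  eps <- .hash_normal(records$id, params$seed, 202L)
  z2 <- params$rho * z1 + sqrt(1 - params$rho^2) * eps
  params$mu_2 + params$sigma_2 * z2
}
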